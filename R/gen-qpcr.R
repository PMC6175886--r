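#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Emulates the quantification design: groups x genes x biological
#' replicates x technical replicates. Ct decreases by one cycle per true
#' doubling of template (`ct = base_ct - log2fc`). Each (group, biological
#' replicate) sample gets a shared Ct offset (template-amount variation)
#' applied to every gene, which reference-gene normalisation cancels;
#' technical replicates add i.i.d. Gaussian noise.
#'
#' @param log2fc Named list or vector: per target gene, a named numeric
#'   vector of true log2 fold changes by group (control group 0). E.g.
#'   `list(seud1 = c(California = 0, RS5200B = -1.5))`. Reference genes are
#'   fixed at 0 in every group.
#' @param ref_genes Character vector of reference gene ids.
#' @param n_bio,n_tech Biological and technical replicates (default 3 x 3).
#' @param tech_sd Technical-replicate Gaussian noise SD on Ct.
#' @param bio_sd SD of the shared per-sample Ct offset.
#' @param base_ct Baseline Ct for every gene in the control condition.
#' @param run Optional run label attached to all rows (for combining runs
#'   with different primer sets).
#' @param seed Optional integer seed for reproducibility.
#' @return A `ct_table` with attribute `truth` (the `log2fc` input).
#' @export
gen_ct_table <- function(log2fc, ref_genes = c("tbb-4", "Y45F10D"),
                         n_bio = 3L, n_tech = 3L, tech_sd = 0,
                         bio_sd = 0, base_ct = 22, run = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- names(log2fc)
  if (is.null(targets) || !length(targets)) stop("log2fc must name target genes")
  groups <- unique(unlist(lapply(log2fc, names)))
  if (is.null(groups)) stop("each log2fc entry must name its groups")
  genes <- c(targets, ref_genes)
  rows <- list()
  for (g in groups) {
    for (b in seq_len(n_bio)) {
      sample_off <- stats::rnorm(1, 0, bio_sd)
      for (gene in genes) {
        fc <- if (gene %in% targets) unname(log2fc[[gene]][g]) else 0
        if (is.na(fc)) fc <- 0
        mu <- base_ct - fc + sample_off
        for (t in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, gene = gene, bio_rep = b, tech_rep = t,
            ct = mu + stats::rnorm(1, 0, tech_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(run)) df$run <- run
  out <- ct_table(df$group, df$gene, df$bio_rep, df$tech_rep, df$ct)
  if (!is.null(run)) out$run <- run
  attr(out, "truth") <- log2fc
  out
}

#' Generate a noise-free titration series for a given efficiency
#'
#' @param factor True per-cycle amplification factor.
#' @param n_points Dilution points (default 6 spanning 5 logs).
#' @param ct_top Ct of the most concentrated input.
#' @param sd Gaussian noise on Ct.
#' @return Data frame `log10_dilution`, `ct` for [efficiency()].
#' @export
gen_titration <- function(factor = 2, n_points = 6L, ct_top = 15, sd = 0) {
  log10_dilution <- seq(0, -5, length.out = n_points)
  slope <- -1 / log10(factor)
  ct <- ct_top + slope * log10_dilution + stats::rnorm(n_points, 0, sd)
  data.frame(log10_dilution = log10_dilution, ct = ct)
}
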