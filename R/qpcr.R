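#' PCR amplification efficiency from a titration series
#'
#' Least-squares slope of Ct on log10 template input over a dilution
#' series; the per-cycle amplification factor is `10^(-1/slope)` (slope
#' -log2(10) = -3.3219 corresponds to perfect doubling, factor 2).
#'
#' @param log10_dilution Numeric vector of log10 relative input amounts.
#' @param ct Observed Ct at each dilution.
#' @return List with `slope`, `factor`, `r_squared`.
#' @export
efficiency <- function(log10_dilution, ct) {
  if (length(log10_dilution) < 3)
    stop("titration needs at least 3 points")
  if (diff(range(log10_dilution)) < 2)
    stop("titration must span at least 2 logs of input")
  fit <- stats::lm(ct ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  # noise-free titrations fit perfectly; the summary warning is meaningless
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = slope, factor = 10^(-1 / slope), r_squared = r2)
}

#' Construct a Ct record table
#'
#' @param group,gene,bio_rep,tech_rep,ct Column vectors (recycled).
#' @return A `ct_table` data frame.
#' @export
ct_table <- function(group, gene, bio_rep, tech_rep, ct) {
  df <- data.frame(group = as.character(group), gene = as.character(gene),
                   bio_rep = as.integer(bio_rep),
                   tech_rep = as.integer(tech_rep), ct = as.numeric(ct),
                   stringsAsFactors = FALSE)
  if (any(df$ct <= 0)) stop("Ct values must be > 0")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Per-biological-replicate delta-Ct against reference genes
#'
#' Technical replicates are averaged per (group, gene, biological
#' replicate); the target's mean Ct is normalised by the arithmetic mean of
#' the reference genes' Cts (geometric mean of the linear quantities) in
#' the same sample. One or more reference genes are supported.
#'
#' @param ct A `ct_table`.
#' @param target Target gene id.
#' @param refs Character vector of reference gene ids (>= 1).
#' @return Data frame `group`, `bio_rep`, `delta_ct`.
#' @export
delta_ct <- function(ct, target, refs) {
  if (!length(refs)) stop("need at least one reference gene")
  missing_genes <- setdiff(c(target, refs), unique(ct$gene))
  if (length(missing_genes))
    stop("gene(s) absent from Ct table: ", paste(missing_genes, collapse = ", "))
  means <- stats::aggregate(ct ~ group + gene + bio_rep, data = ct, FUN = mean)
  samples <- unique(means[, c("group", "bio_rep")])
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    g <- samples$group[i]; b <- samples$bio_rep[i]
    sub <- means[means$group == g & means$bio_rep == b, ]
    tgt <- sub$ct[sub$gene == target]
    ref <- sub$ct[sub$gene %in% refs]
    if (length(tgt) != 1L || length(ref) != length(refs))
      stop("sample (", g, ", bio ", b, ") lacks target or reference Cts")
    data.frame(group = g, bio_rep = b, delta_ct = tgt - mean(ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct log2 fold changes against a control group
#'
#' `ddct = delta_ct - mean(control delta_ct)`; fold change is
#' `factor^(-ddct)` with the amplification `factor` (default 2, or from a
#' titration via [efficiency()]), so `log2_fc = -ddct * log2(factor)`.
#'
#' @param dct Output of [delta_ct()].
#' @param control Control group id (the ddCt reference).
#' @param factor Amplification factor per cycle.
#' @return `dct` with `ddct`, `fold_change` and `log2_fc` columns added.
#' @export
ddct_log2fc <- function(dct, control, factor = 2) {
  if (!control %in% dct$group) stop("control group ", control, " not present")
  ctrl_mean <- mean(dct$delta_ct[dct$group == control])
  dct$ddct <- dct$delta_ct - ctrl_mean
  dct$fold_change <- factor^(-dct$ddct)
  dct$log2_fc <- log2(dct$fold_change)
  dct
}

#' Compare expression across groups with Tukey HSD
#'
#' Biological-replicate log2 fold changes are compared by a one-way
#' fixed-effects analysis (aov) with Tukey honest-significant-difference
#' adjustment via the studentized range. With balanced designs this is the
#' fixed-effects equivalent of a repeated-measures mixed model after
#' aggregating technical replicates to biological-replicate means.
#'
#' @param fc Data frame with `group` and `log2_fc` (one row per biological
#'   replicate), as from [ddct_log2fc()].
#' @return List with `anova_p` (overall F-test p) and `comparisons`, a data
#'   frame of pairwise differences with Tukey-adjusted p-values.
#' @export
compare_expression <- function(fc) {
  fc$group <- factor(fc$group)
  if (nlevels(fc$group) < 2) stop("need at least two groups")
  fit <- stats::aov(log2_fc ~ group, data = fc)
  tk <- stats::TukeyHSD(fit)$group
  comp <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                     lower = tk[, "lwr"], upper = tk[, "upr"],
                     p_adjusted = tk[, "p adj"], row.names = NULL,
                     stringsAsFactors = FALSE)
  pval <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(anova_p = pval, comparisons = comp)
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' Chains [delta_ct()], [ddct_log2fc()] and (with >= 2 groups)
#' [compare_expression()].
#'
#' @param ct A `ct_table`.
#' @param target,refs,control,factor See the stage functions.
#' @return List with `per_replicate` (log2 fold changes per biological
#'   replicate), `by_group` (group means), and `comparisons` (or `NULL`).
#' @export
ddct_analysis <- function(ct, target, refs, control, factor = 2) {
  fc <- ddct_log2fc(delta_ct(ct, target, refs), control, factor)
  by_group <- stats::aggregate(log2_fc ~ group, data = fc, FUN = mean)
  comparisons <- if (length(unique(fc$group)) >= 2) compare_expression(fc)
                 else NULL
  list(per_replicate = fc, by_group = by_group, comparisons = comparisons)
}
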