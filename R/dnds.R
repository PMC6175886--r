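#' Synonymous and nonsynonymous site counts of one codon
#'
#' Nei-Gojobori (1986) counting: at each of the three positions, the
#' synonymous fraction is the share of the three possible single-base
#' changes that preserve the amino acid; changes creating a stop codon
#' count as nonsynonymous (standard convention). `s + n = 3` per codon.
#'
#' @param codon A sense codon.
#' @return Numeric vector `c(s = ..., n = ...)`.
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbours(codon, pos)
    s <- s + sum(translate_codon(nb) == aa) / 3
  }
  c(s = s, n = 3 - s)
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Differences are averaged over all minimal substitution pathways between
#' the codons; pathways passing through a stop codon are excluded and the
#' rest equally weighted. If every pathway passes through a stop, the
#' direct end states decide: all differences count as synonymous when the
#' two codons encode the same amino acid, otherwise as nonsynonymous.
#' `sd + nd` equals the number of differing positions.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Numeric vector `c(sd = ..., nd = ...)`.
#' @export
codon_diffs <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  nd_tot <- length(pos)
  if (nd_tot == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(pos)
  path_sd <- numeric(0)
  for (i in seq_len(nrow(paths))) {
    cur <- codon_a
    sd <- 0
    ok <- TRUE
    for (p in paths[i, ]) {
      nxt <- cur
      substring(nxt, p, p) <- substring(codon_b, p, p)
      if (is_stop_codon(nxt) && nxt != codon_b) { ok <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) sd <- sd + 1
      cur <- nxt
    }
    if (ok) path_sd <- c(path_sd, sd)
  }
  if (!length(path_sd)) {
    same_aa <- translate_codon(codon_a) == translate_codon(codon_b)
    return(c(sd = if (same_aa) nd_tot else 0,
             nd = if (same_aa) 0 else nd_tot))
  }
  sd <- mean(path_sd)
  c(sd = sd, nd = nd_tot - sd)
}

# all orderings of a vector (n <= 3 here)
perms <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(x[i], perms(x[-i]))
  }))
  out
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and differences (pathway-averaged per codon), converts the proportions
#' `pS = Sd/S`, `pN = Nd/N` to distances with the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)`, and reports `omega = dN/dS`.
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, divisible by
#'   3, no gaps, no internal stop codons). A shared terminal stop codon is
#'   stripped before counting.
#' @return An `ng86` object: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `omega` (NA with `omega_defined = FALSE` when `dS = 0`), `n_codons`.
#' @export
ng86 <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned to equal length")
  if (grepl("-", paste0(seq_a, seq_b), fixed = TRUE))
    stop("gap characters must be stripped upstream")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  n_cod <- length(ca)
  if (n_cod == 0L) stop("empty alignment")
  # strip a shared terminal stop codon; internal stops are invalid
  if (is_stop_codon(ca[n_cod]) && is_stop_codon(cb[n_cod])) {
    ca <- ca[-n_cod]; cb <- cb[-n_cod]; n_cod <- n_cod - 1L
  }
  if (n_cod == 0L) stop("alignment contains only a stop codon")
  if (any(is_stop_codon(ca)) || any(is_stop_codon(cb)))
    stop("internal stop codon in alignment")
  sites_a <- rowSums(vapply(ca, codon_sites, numeric(2)))["s"]
  sites_b <- rowSums(vapply(cb, codon_sites, numeric(2)))["s"]
  S <- unname((sites_a + sites_b) / 2)
  N <- 3 * n_cod - S
  diffs <- mapply(codon_diffs, ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- Sd / S; pN <- Nd / N
  dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
  omega_defined <- dS > 0
  structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
    omega = if (omega_defined) dN / dS else NA_real_,
    omega_defined = omega_defined, n_codons = n_cod
  ), class = "ng86")
}

jukes_cantor <- function(p) {
  if (p >= 0.75)
    stop("proportion of differences ", signif(p, 3),
         " >= 3/4: Jukes-Cantor correction undefined")
  d <- -0.75 * log(1 - 4 * p / 3)
  d + 0  # normalise -0 to 0 when p = 0
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("NG86 pairwise dN/dS over %d codons\n", x$n_codons))
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %.4f  dN = %.4f  omega = %s\n", x$dS, x$dN,
              if (x$omega_defined) sprintf("%.3f", x$omega) else
                "undefined (dS = 0)"))
  invisible(x)
}

#' Read a two-sequence aligned FASTA for dN/dS
#'
#' @param path Aligned FASTA with exactly two sequences.
#' @return List with `seq_a`, `seq_b` character strings.
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 2L) stop("alignment must contain exactly two sequences")
  list(seq_a = as.character(ss[[1]]), seq_b = as.character(ss[[2]]))
}

#' Amino-acid identity of an aligned coding pair
#'
#' @param seq_a,seq_b Aligned coding sequences.
#' @return Fraction of aligned amino-acid positions that are identical.
#' @export
aa_identity <- function(seq_a, seq_b) {
  pa <- strsplit(translate_cds(seq_a), "")[[1]]
  pb <- strsplit(translate_cds(seq_b), "")[[1]]
  mean(pa == pb)
}
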