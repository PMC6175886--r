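# Independent oracles used to cross-check the package implementations.

# --- coding-impact oracle: rebuild the full mutant CDS and translate it ----
# Classifies one variant by comparing the wild-type and mutant proteins of
# the containing gene (translation via Biostrings::translate), independent
# of the per-codon arithmetic in classify_impact().
oracle_impact <- function(contig, pos, alt, annotation, genome) {
  genes <- annotation_genes(annotation)
  hit <- NULL
  for (g in genes) {
    if (g$contig == contig && pos >= min(g$exons$start) &&
        pos <= max(g$exons$end)) { hit <- g; break }
  }
  if (is.null(hit)) return("noncoding")
  exonic <- any(pos >= hit$exons$start & pos <= hit$exons$end)
  if (!exonic) {
    near <- any((pos >= hit$exons$start - 2 & pos < hit$exons$start) |
                  (pos <= hit$exons$end + 2 & pos > hit$exons$end))
    return(if (near) "splice_site" else "noncoding")
  }
  mut_genome <- genome
  contig_seq <- as.character(mut_genome[[contig]])
  substring(contig_seq, pos, pos) <- alt
  mut_genome[[contig]] <- Biostrings::DNAString(contig_seq)
  wt_cds <- extract_cds_oracle(hit, genome)
  mut_cds <- extract_cds_oracle(hit, mut_genome)
  wt_aa <- as.character(Biostrings::translate(Biostrings::DNAString(wt_cds)))
  mut_aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut_cds)))
  if (wt_aa == mut_aa) return("synonymous")
  # premature stop anywhere before the terminal position => nonsense
  mut_body <- substring(mut_aa, 1, nchar(mut_aa) - 1)
  if (grepl("*", mut_body, fixed = TRUE)) return("nonsense")
  "missense"
}

extract_cds_oracle <- function(gene, genome) {
  pieces <- character(0)
  for (k in seq_len(nrow(gene$exons))) {
    p <- substring(as.character(genome[[gene$contig]]),
                   gene$exons$start[k], gene$exons$end[k])
    pieces <- c(pieces, p)
  }
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") {
    cds <- paste(pieces, collapse = "")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      paste(rev(pieces), collapse = ""))))
  }
  cds
}

# --- NG86 oracle: independent brute force -----------------------------------
# Site counts and pathway-averaged difference counts recomputed with seqinr
# translation and a recursive depth-first pathway enumeration.
oracle_codon_sites <- function(codon) {
  aa <- seqinr::translate(seqinr::s2c(codon))
  s <- 0
  for (i in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- b
      if (seqinr::translate(seqinr::s2c(mut)) == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

oracle_codon_diffs <- function(a, b) {
  stops <- c("TAA", "TAG", "TGA")
  results <- new.env(parent = emptyenv())
  results$paths <- list()
  dfs <- function(cur, sd, nd) {
    if (cur == b) {
      results$paths[[length(results$paths) + 1L]] <- c(sd = sd, nd = nd)
      return(invisible())
    }
    for (i in 1:3) {
      if (substr(cur, i, i) != substr(b, i, i)) {
        nxt <- cur
        substr(nxt, i, i) <- substr(b, i, i)
        if (nxt %in% stops && nxt != b) next
        syn <- identical(seqinr::translate(seqinr::s2c(nxt)),
                         seqinr::translate(seqinr::s2c(cur)))
        dfs(nxt, sd + as.integer(syn), nd + as.integer(!syn))
      }
    }
  }
  dfs(a, 0L, 0L)
  ndiff <- sum(seqinr::s2c(a) != seqinr::s2c(b))
  if (!length(results$paths)) {
    same_aa <- identical(seqinr::translate(seqinr::s2c(a)),
                         seqinr::translate(seqinr::s2c(b)))
    return(c(sd = if (same_aa) ndiff else 0, nd = if (same_aa) 0 else ndiff))
  }
  m <- do.call(rbind, results$paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  stops <- c("TAA", "TAG", "TGA")
  k <- length(ca)
  if (ca[k] %in% stops && cb[k] %in% stops) { ca <- ca[-k]; cb <- cb[-k] }
  Sa <- sum(vapply(ca, function(x) oracle_codon_sites(x)["s"], numeric(1)))
  Sb <- sum(vapply(cb, function(x) oracle_codon_sites(x)["s"], numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- mapply(oracle_codon_diffs, ca, cb)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3) + 0
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(pS), dN = jc(pN))
}

# --- exact binomial CI oracle: root-finding on the binomial tails ----------
oracle_clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) -
                     alpha / 2, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  upper <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  c(lower = lower, upper = upper)
}

# --- Benjamini-Hochberg step-up oracle --------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# --- small fixture helpers --------------------------------------------------
default_screen <- function(seed) {
  p <- screen_params(seed = seed)
  ref <- gen_reference(p)
  scr <- gen_screen_dataset(ref, p)
  list(params = p, ref = ref, scr = scr)
}

run_default_mapping <- function(fx) {
  run_mapping(fx$scr$tables$mutant_a, fx$scr$tables$mutant_b,
              backgrounds = list(fx$scr$tables$parental,
                                 fx$scr$tables$marker),
              annotation = fx$ref$annotation, genome = fx$ref$genome)
}

# tiny hand-built single-contig genome + one- or two-exon gene for toy tests
toy_genome <- function(contig_seq) {
  g <- Biostrings::DNAStringSet(contig_seq)
  names(g) <- "chr1"
  g
}

toy_annotation <- function(exons, strand = "+", gene_id = "toy_1") {
  polyswitch:::new_annotation(stats::setNames(list(
    list(gene_id = gene_id, contig = "chr1", strand = strand,
         exons = exons, n_exons = nrow(exons))
  ), gene_id))
}
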