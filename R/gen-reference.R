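#' Generate a synthetic reference genome and gene annotation
#'
#' Builds `n_contigs x genes_per_contig` protein-coding genes, each a spliced
#' multi-exon CDS (start codon ATG, terminal stop, no internal stop, length
#' divisible by 3) separated by canonical GT..AG introns and intergenic
#' spacers. Gene strands alternate so both orientations are always present.
#' The causal gene (by `causal_gene_index`) is given `causal_n_exons` exons so
#' the designated lesion exons exist. Exon coordinates are 1-based inclusive.
#'
#' @param params A [screen_params()] object.
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a `genome_annotation` object; see [annotation_genes()]).
#' @export
gen_reference <- function(params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  set.seed(params$seed)
  n_genes_total <- params$n_contigs * params$genes_per_contig
  if (n_genes_total == 0L) {
    genome <- Biostrings::DNAStringSet()
    return(list(genome = genome,
                annotation = new_annotation(list())))
  }
  contig_seqs <- character(params$n_contigs)
  genes <- vector("list", n_genes_total)
  gi <- 0L
  for (ci in seq_len(params$n_contigs)) {
    contig_id <- sprintf("contig_%02d", ci)
    pieces <- character(0)
    offset <- 0L
    for (gj in seq_len(params$genes_per_contig)) {
      gi <- gi + 1L
      spacer <- random_dna(sample(800:1600, 1L))
      offset <- offset + nchar(spacer)
      is_causal <- gi == params$causal_gene_index
      n_exons <- if (is_causal) params$causal_n_exons else sample(2:8, 1L)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      g <- build_gene(sprintf("gene_%04d", gi), contig_id, strand,
                      params$gene_length_mean, n_exons, offset,
                      required_stop_exons =
                        if (is_causal) params$lesion_exons else integer(0))
      pieces <- c(pieces, spacer, g$seq)
      offset <- offset + nchar(g$seq)
      genes[[gi]] <- g$model
    }
    pieces <- c(pieces, random_dna(sample(800:1600, 1L)))
    contig_seqs[ci] <- paste(pieces, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contig_seqs)
  names(genome) <- sprintf("contig_%02d", seq_len(params$n_contigs))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  list(genome = genome, annotation = new_annotation(genes))
}

# One gene: spliced CDS cut into n_exons pieces separated by GT..AG introns.
# `offset` is the 0-based genomic position immediately before the gene.
# Returns the genomic-strand sequence and the gene model with exon intervals
# in transcript order (1-based inclusive genomic coordinates).
build_gene <- function(gene_id, contig, strand, cds_mean, n_exons, offset,
                       required_stop_exons = integer(0)) {
  # exon lengths: minimum 30 bp each (90 bp for exons that must be able to
  # host a planted nonsense change), remainder spread uniformly
  min_len <- rep(30L, n_exons)
  min_len[required_stop_exons] <- 90L
  n_codons <- max(2L + ceiling(sum(min_len) / 3) + n_exons * 5L,
                  as.integer(round(stats::rnorm(1, cds_mean, cds_mean / 8) / 3)))
  for (attempt in 1:50) {
    cds <- paste0("ATG",
                  paste(sample_sense_codons(n_codons - 2L), collapse = ""),
                  sample(STOP_CODONS, 1L))
    cds_len <- nchar(cds)
    extra <- cds_len - sum(min_len)
    stopifnot(extra >= 0L)
    cuts <- sort(sample.int(extra + 1L, n_exons - 1L, replace = TRUE) - 1L)
    exon_len <- diff(c(0L, cuts, extra)) + min_len
    ok <- all(vapply(required_stop_exons, function(ex) {
      lo <- if (ex == 1L) 1L else sum(exon_len[1:(ex - 1L)]) + 1L
      cds_range_has_stop_site(cds, lo, lo + exon_len[ex] - 1L)
    }, logical(1)))
    if (ok) break
    if (attempt == 50L)
      stop("could not build a gene with nonsense-capable exon(s) ",
           paste(required_stop_exons, collapse = ", "))
  }
  intron_len <- if (n_exons > 1L) sample(60:150, n_exons - 1L, replace = TRUE)
                else integer(0)
  # sense-coordinate layout within the gene
  sense_start <- integer(n_exons)
  sense_end <- integer(n_exons)
  pos <- 0L
  sense_pieces <- character(0)
  cds_cursor <- 0L
  for (k in seq_len(n_exons)) {
    ex <- substring(cds, cds_cursor + 1L, cds_cursor + exon_len[k])
    cds_cursor <- cds_cursor + exon_len[k]
    sense_start[k] <- pos + 1L
    pos <- pos + exon_len[k]
    sense_end[k] <- pos
    sense_pieces <- c(sense_pieces, ex)
    if (k < n_exons) {
      intron <- paste0("GT", random_dna(intron_len[k] - 4L), "AG")
      sense_pieces <- c(sense_pieces, intron)
      pos <- pos + intron_len[k]
    }
  }
  sense_seq <- paste(sense_pieces, collapse = "")
  glen <- nchar(sense_seq)
  if (strand == "+") {
    genomic_seq <- sense_seq
    start <- offset + sense_start
    end <- offset + sense_end
  } else {
    genomic_seq <- revcomp(sense_seq)
    start <- offset + (glen - sense_end + 1L)
    end <- offset + (glen - sense_start + 1L)
  }
  model <- list(gene_id = gene_id, contig = contig, strand = strand,
                exons = data.frame(start = start, end = end),
                n_exons = n_exons)
  list(seq = genomic_seq, model = model)
}

# Does any CDS position in [lo, hi] admit a single-base change creating a
# premature stop codon? (Start and terminal stop codons excluded.)
cds_range_has_stop_site <- function(cds, lo, hi) {
  codons <- split_codons(cds)
  n_codons <- length(codons)
  for (p in lo:hi) {
    idx <- (p - 1L) %/% 3L + 1L
    if (idx <= 1L || idx >= n_codons) next
    within <- (p - 1L) %% 3L + 1L
    for (alt in setdiff(BASES, substring(codons[idx], within, within))) {
      mut <- codons[idx]
      substring(mut, within, within) <- alt
      if (is_stop_codon(mut)) return(TRUE)
    }
  }
  FALSE
}

new_annotation <- function(genes) {
  structure(list(genes = genes), class = "genome_annotation")
}

#' Access the gene models of an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return Named list of gene models. Each model has `gene_id`, `contig`,
#'   `strand`, `n_exons`, and `exons`, a data frame of 1-based inclusive
#'   genomic intervals in transcript order (for minus-strand genes transcript
#'   exon 1 is the rightmost interval). All exons are coding.
#' @export
annotation_genes <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  annotation$genes
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$genes), "genes on",
      length(unique(vapply(x$genes, `[[`, character(1), "contig"))),
      "contig(s)\n")
  invisible(x)
}

# Extract the spliced CDS (transcript orientation) of one gene.
spliced_cds <- function(gene, genome) {
  seqs <- vapply(seq_len(nrow(gene$exons)), function(k) {
    piece <- Biostrings::subseq(genome[[gene$contig]],
                                gene$exons$start[k], gene$exons$end[k])
    if (gene$strand == "-")
      piece <- Biostrings::reverseComplement(piece)
    as.character(piece)
  }, character(1))
  paste(seqs, collapse = "")
}

# Map a genomic position inside an exon to its 1-based CDS coordinate.
# Returns NA if the position is not exonic.
cds_position <- function(gene, genomic_pos) {
  cum <- 0L
  for (k in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[k]; e <- gene$exons$end[k]
    if (genomic_pos >= s && genomic_pos <= e) {
      off <- if (gene$strand == "+") genomic_pos - s else e - genomic_pos
      return(cum + off + 1L)
    }
    cum <- cum + (e - s + 1L)
  }
  NA_integer_
}

# Inverse of cds_position.
genomic_position <- function(gene, cds_pos) {
  cum <- 0L
  for (k in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[k]; e <- gene$exons$end[k]
    len <- e - s + 1L
    if (cds_pos <= cum + len) {
      off <- cds_pos - cum - 1L
      return(if (gene$strand == "+") s + off else e - off)
    }
    cum <- cum + len
  }
  stop("cds_pos ", cds_pos, " beyond CDS of ", gene$gene_id)
}
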