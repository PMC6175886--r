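#' Write a synthetic genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Export a gene annotation to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with 1-based inclusive
#' coordinates; every exon is coding, so exon and CDS intervals coincide.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation_genes(annotation)
  rows <- lapply(genes, function(g) {
    span_start <- min(g$exons$start)
    span_end <- max(g$exons$end)
    n <- nrow(g$exons)
    exon_len <- g$exons$end - g$exons$start + 1L
    # CDS phase: bases to skip before the first complete codon of each
    # exon, from the cumulative CDS length in transcript order
    before <- cumsum(c(0L, exon_len))[seq_len(n)]
    phase <- (3L - before %% 3L) %% 3L
    data.frame(
      seqnames = g$contig,
      start = c(span_start, span_start, g$exons$start, g$exons$start),
      end = c(span_end, span_end, g$exons$end, g$exons$end),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", n), rep("CDS", n)),
      ID = c(g$gene_id, paste0(g$gene_id, ".t1"),
             paste0(g$gene_id, ".t1.exon", seq_len(n)),
             paste0(g$gene_id, ".t1.cds", seq_len(n))),
      Parent = c(NA, g$gene_id, rep(paste0(g$gene_id, ".t1"), 2L * n)),
      phase = c(NA, NA, rep(NA, n), phase),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type, ID = df$ID, Parent = df$Parent, phase = df$phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Import a gene annotation from GFF3
#'
#' Rebuilds the package's gene models from `exon` features grouped by their
#' `Parent` transcript. Exons are ordered in transcript orientation.
#'
#' @param path GFF3 file with gene/mRNA/exon features.
#' @return A `genome_annotation`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- vapply(as.list(ex$Parent), function(p) sub("\\.t1$", "", p[1]),
                   character(1))
  genes <- lapply(split(seq_along(ex), parent), function(idx) {
    e <- ex[idx]
    strand <- as.character(BiocGenerics::strand(e)[1])
    ord <- order(BiocGenerics::start(e), decreasing = (strand == "-"))
    e <- e[ord]
    list(gene_id = parent[idx[1]],
         contig = as.character(GenomicRanges::seqnames(e)[1]),
         strand = strand,
         exons = data.frame(start = BiocGenerics::start(e),
                            end = BiocGenerics::end(e)),
         n_exons = length(e))
  })
  new_annotation(genes[order(names(genes))])
}
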