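HARMFUL_CLASSES <- c("nonsense", "missense", "splice_site")
SPLICE_WINDOW <- 2L  # bp into the intron at each exon boundary (GT/AG)

#' Filter variants on quality and depth
#'
#' Automated stand-in for manual curation of artefactual calls: a record is
#' retained iff `qual >= min_qual` and `depth >= min_depth`.
#'
#' @param tab A `variant_table`.
#' @param min_qual,min_depth Non-negative thresholds (defaults 20 and 5).
#' @return The filtered `variant_table`.
#' @export
quality_filter <- function(tab, min_qual = 20, min_depth = 5) {
  if (min_qual < 0 || min_depth < 0) stop("thresholds must be >= 0")
  out <- tab[tab$qual >= min_qual & tab$depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  validate_variant_table(out)
}

#' Subtract variants shared with background strains
#'
#' Removes from `target` every record whose (contig, pos, ref, alt) key
#' occurs in any background table; the strain field is ignored for matching.
#'
#' @param target A `variant_table`.
#' @param backgrounds A list of `variant_table`s (may be empty).
#' @return The `variant_table` of target-specific records.
#' @export
subtract_shared <- function(target, backgrounds = list()) {
  if (inherits(backgrounds, "variant_table")) backgrounds <- list(backgrounds)
  if (!length(backgrounds)) return(target)
  bg_keys <- unique(unlist(lapply(backgrounds, variant_key)))
  out <- target[!variant_key(target) %in% bg_keys, , drop = FALSE]
  rownames(out) <- NULL
  validate_variant_table(out)
}

#' Classify the coding impact of SNVs
#'
#' Each variant is located against the gene models: exonic variants are
#' classified by mutating and translating the affected codon (alleles are
#' complemented for minus-strand genes), intronic variants within 2 bp of an
#' exon boundary (the canonical GT/AG dinucleotides) are `splice_site`, and everything
#' else is `noncoding`. The reference allele must match the genome.
#'
#' @param tab A `variant_table`.
#' @param annotation A `genome_annotation`.
#' @param genome A [Biostrings::DNAStringSet] of the contigs.
#' @return An `impact_table`: the variant columns plus `gene`, `impact`
#'   (`nonsense`, `missense`, `synonymous`, `splice_site`, `noncoding`),
#'   `codon_index`, `aa_ref` and `aa_alt` (NA outside coding sequence).
#' @export
classify_impact <- function(tab, annotation, genome) {
  genes <- annotation_genes(annotation)
  idx <- gene_index(genes)
  cds_cache <- new.env(parent = emptyenv())
  n <- nrow(tab)
  gene_id <- rep(NA_character_, n)
  impact <- rep("noncoding", n)
  codon_index <- rep(NA_integer_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  contig_chars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  for (i in seq_len(n)) {
    contig <- tab$contig[i]; pos <- tab$pos[i]
    if (!contig %in% names(contig_chars))
      stop("variant contig ", contig, " not in genome")
    gref <- contig_chars[[contig]][pos]
    if (is.na(gref) || gref != tab$ref[i])
      stop("reference mismatch at ", contig, ":", pos, " (variant ref ",
           tab$ref[i], ", genome ", gref, ")")
    g <- locate_gene(idx, genes, contig, pos)
    if (is.null(g)) next
    gene_id[i] <- g$gene_id
    cpos <- cds_position(g, pos)
    if (is.na(cpos)) {
      impact[i] <- if (near_splice(g, pos)) "splice_site" else "noncoding"
      next
    }
    cds <- get_cached_cds(cds_cache, g, genome)
    codon_idx <- (cpos - 1L) %/% 3L + 1L
    within <- (cpos - 1L) %% 3L + 1L
    codon <- substring(cds, 3L * codon_idx - 2L, 3L * codon_idx)
    alt_cds <- if (g$strand == "-") unname(complement_base(tab$alt[i])) else tab$alt[i]
    mut <- codon
    substring(mut, within, within) <- alt_cds
    a_ref <- translate_codon(codon)
    a_alt <- translate_codon(mut)
    codon_index[i] <- codon_idx
    aa_ref[i] <- a_ref
    aa_alt[i] <- a_alt
    impact[i] <- if (a_alt == a_ref) "synonymous"
    else if (a_alt == "*") "nonsense"
    else "missense"
  }
  out <- cbind(as.data.frame(tab),
               data.frame(gene = gene_id, impact = impact,
                          codon_index = codon_index, aa_ref = aa_ref,
                          aa_alt = aa_alt, stringsAsFactors = FALSE))
  class(out) <- c("impact_table", "data.frame")
  out
}

# Per-contig lookup of gene spans (introns included).
gene_index <- function(genes) {
  if (!length(genes)) return(list())
  df <- data.frame(
    contig = vapply(genes, `[[`, character(1), "contig"),
    start = vapply(genes, function(g) min(g$exons$start), integer(1)),
    end = vapply(genes, function(g) max(g$exons$end), integer(1)),
    id = names(genes), stringsAsFactors = FALSE
  )
  split(df, df$contig)
}

locate_gene <- function(idx, genes, contig, pos) {
  spans <- idx[[contig]]
  if (is.null(spans)) return(NULL)
  hit <- which(spans$start <= pos & spans$end >= pos)
  if (!length(hit)) return(NULL)
  genes[[spans$id[hit[1]]]]
}

near_splice <- function(gene, pos) {
  # within SPLICE_WINDOW bp into an intron from either flanking exon end
  for (k in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[k]; e <- gene$exons$end[k]
    if ((pos < s && pos >= s - SPLICE_WINDOW) ||
        (pos > e && pos <= e + SPLICE_WINDOW)) {
      # must be intronic, i.e. not inside any exon (caller guarantees) and
      # inside the gene span, which holds for internal boundaries
      return(TRUE)
    }
  }
  FALSE
}

get_cached_cds <- function(cache, gene, genome) {
  if (!is.null(cache[[gene$gene_id]])) return(cache[[gene$gene_id]])
  cds <- spliced_cds(gene, genome)
  assign(gene$gene_id, cds, envir = cache)
  cds
}

#' Keep only potentially harmful impact calls
#'
#' Harmful classes are nonsense, missense and splice-site.
#'
#' @param calls An `impact_table`.
#' @return The harmful subset, same class.
#' @export
harmful_subset <- function(calls) {
  out <- calls[calls$impact %in% HARMFUL_CLASSES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect harmful candidate genes across two mutant alleles
#'
#' A gene qualifies when each allele contributes at least one harmful call in
#' it and the two alleles' harmful variant sets in the gene are not
#' identical (independent lesions).
#'
#' @param harmful_a,harmful_b Harmful `impact_table`s for the two alleles.
#' @return A `candidate_report`: one row per gene carrying harmful calls in
#'   either allele, with per-allele harmful counts and a `qualifying` flag;
#'   the per-gene calls are kept in the `calls` attribute.
#' @export
intersect_candidates <- function(harmful_a, harmful_b) {
  coding_a <- harmful_a[!is.na(harmful_a$gene), , drop = FALSE]
  coding_b <- harmful_b[!is.na(harmful_b$gene), , drop = FALSE]
  all_genes <- sort(unique(c(coding_a$gene, coding_b$gene)))
  rows <- lapply(all_genes, function(g) {
    va <- coding_a[coding_a$gene == g, , drop = FALSE]
    vb <- coding_b[coding_b$gene == g, , drop = FALSE]
    ka <- sort(variant_key(va)); kb <- sort(variant_key(vb))
    qual <- nrow(va) >= 1L && nrow(vb) >= 1L && !identical(ka, kb)
    data.frame(gene = g, n_harmful_a = nrow(va), n_harmful_b = nrow(vb),
               qualifying = qual, stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_harmful_a = integer(0),
               n_harmful_b = integer(0), qualifying = logical(0))
  attr(report, "calls") <- list(a = coding_a, b = coding_b)
  class(report) <- c("candidate_report", "data.frame")
  report
}

#' Run the full two-allele mapping cascade
#'
#' Applies, in order: quality/depth filtering, subtraction of the shared
#' backgrounds, coding-impact classification, restriction to harmful calls,
#' and cross-allele candidate intersection. A provenance log of record
#' counts after each stage is attached as the `log` attribute.
#'
#' @param mutant_a,mutant_b `variant_table`s (or VCF/TSV paths) for the two
#'   alleles.
#' @param backgrounds List of `variant_table`s (or paths) to subtract.
#' @param annotation A `genome_annotation` (or a GFF3 path).
#' @param genome A [Biostrings::DNAStringSet] (or a FASTA path).
#' @param min_qual,min_depth Quality-filter thresholds.
#' @return A `candidate_report` (see [intersect_candidates()]) with a `log`
#'   attribute of per-stage counts.
#' @export
run_mapping <- function(mutant_a, mutant_b, backgrounds = list(),
                        annotation, genome, min_qual = 20, min_depth = 5) {
  as_tab <- function(x) if (is.character(x)) load_variants(x) else x
  mutant_a <- as_tab(mutant_a); mutant_b <- as_tab(mutant_b)
  backgrounds <- lapply(backgrounds, as_tab)
  if (is.character(annotation)) annotation <- read_annotation_gff3(annotation)
  if (is.character(genome)) genome <- read_genome_fasta(genome)

  log <- list(loaded = c(a = nrow(mutant_a), b = nrow(mutant_b)))
  qa <- quality_filter(mutant_a, min_qual, min_depth)
  qb <- quality_filter(mutant_b, min_qual, min_depth)
  log$quality_filtered <- c(a = nrow(qa), b = nrow(qb))
  sa <- subtract_shared(qa, backgrounds)
  sb <- subtract_shared(qb, backgrounds)
  log$background_subtracted <- c(a = nrow(sa), b = nrow(sb))
  ia <- classify_impact(sa, annotation, genome)
  ib <- classify_impact(sb, annotation, genome)
  ha <- harmful_subset(ia)
  hb <- harmful_subset(ib)
  log$harmful <- c(a = nrow(ha), b = nrow(hb))
  report <- intersect_candidates(ha, hb)
  log$qualifying_genes <- sum(report$qualifying)
  attr(report, "log") <- log
  report
}

#' Write a candidate report as TSV and JSON
#'
#' @param report A `candidate_report`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_candidate_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(report), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(report), json, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}
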