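#' Generate a two-allele suppressor-screen variant dataset
#'
#' Emulates resequencing of two backcrossed suppressor mutants that share a
#' mutagenised parental background: both mutant tables contain the shared
#' parental SNVs plus strain-specific EMS background SNVs (G:C -> A:T biased)
#' plus one planted nonsense lesion each, in two designated exons of a single
#' causal gene. A parental-strain table and a marker-strain table carry the
#' shared background for subtraction.
#'
#' @param reference Output of [gen_reference()].
#' @param params The [screen_params()] used to build the reference.
#' @return A list with `tables` (named list of `variant_table`s:
#'   `mutant_a`, `mutant_b`, `parental`, `marker`) and `truth`, a record of
#'   the causal gene, the planted lesions, the morph-decision parameters and
#'   the complementation grouping of the simulated mutants.
#' @export
gen_screen_dataset <- function(reference, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  genome <- reference$genome
  genes <- annotation_genes(reference$annotation)
  set.seed((params$seed + 1000003L) %% .Machine$integer.max)
  contig_chars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])

  causal <- genes[[params$causal_gene_index]]
  lesion_a <- plant_nonsense(causal, genome, params$lesion_exons[1],
                             params$ems_transition_bias)
  lesion_b <- plant_nonsense(causal, genome, params$lesion_exons[2],
                             params$ems_transition_bias,
                             exclude_pos = lesion_a$pos)

  taken <- c(lesion_a$pos_key, lesion_b$pos_key)
  parental <- random_snvs(contig_chars, params$shared_parental_variants,
                          params$ems_transition_bias, taken)
  taken <- c(taken, paste(parental$contig, parental$pos))
  bg_a <- random_snvs(contig_chars, stats::rpois(1, params$n_background_variants),
                      params$ems_transition_bias, taken)
  taken <- c(taken, paste(bg_a$contig, bg_a$pos))
  bg_b <- random_snvs(contig_chars, stats::rpois(1, params$n_background_variants),
                      params$ems_transition_bias, taken)
  taken <- c(taken, paste(bg_b$contig, bg_b$pos))
  bg_m <- random_snvs(contig_chars, stats::rpois(1, params$n_background_variants),
                      params$ems_transition_bias, taken)

  mk <- function(df, strain) {
    n <- nrow(df)
    variant_table(contig = df$contig, pos = df$pos, ref = df$ref,
                  alt = df$alt,
                  qual = round(stats::runif(n, 30, 60), 1),
                  depth = stats::rpois(n, 20) + 5L,
                  strain = strain)
  }
  lesion_df <- function(l) data.frame(contig = l$contig, pos = l$pos,
                                      ref = l$ref, alt = l$alt,
                                      stringsAsFactors = FALSE)
  tab_a <- mk(rbind(parental, bg_a, lesion_df(lesion_a)), "mutant_a")
  tab_b <- mk(rbind(parental, bg_b, lesion_df(lesion_b)), "mutant_b")
  tab_p <- mk(parental, "parental")
  tab_m <- mk(rbind(parental, bg_m), "marker")

  truth <- list(
    causal_gene = causal$gene_id,
    lesions = data.frame(
      strain = c("mutant_a", "mutant_b"),
      contig = c(lesion_a$contig, lesion_b$contig),
      pos = c(lesion_a$pos, lesion_b$pos),
      ref = c(lesion_a$ref, lesion_b$ref),
      alt = c(lesion_a$alt, lesion_b$alt),
      exon = params$lesion_exons,
      codon_index = c(lesion_a$codon_index, lesion_b$codon_index),
      impact = "nonsense",
      stringsAsFactors = FALSE
    ),
    morph_params = morph_params(),
    complementation = c(mutant_a = "group_1", mutant_b = "group_1")
  )
  list(tables = list(mutant_a = tab_a, mutant_b = tab_b,
                     parental = tab_p, marker = tab_m),
       truth = truth)
}

# Strain-specific or shared background SNVs with EMS transition bias.
# `exclude` is a character vector of "contig pos" strings already in use.
random_snvs <- function(contig_chars, n, bias, exclude = character(0)) {
  n <- as.integer(n)
  out <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  lens <- vapply(contig_chars, length, integer(1))
  taken <- exclude
  contigs <- names(contig_chars)
  while (nrow(out) < n) {
    # An EMS event is a G:C -> A:T transition on a G/C site; a non-EMS event
    # is any other substitution, so the realised transition fraction equals
    # `bias` exactly.
    ems <- stats::runif(1) < bias
    repeat {
      ci <- sample.int(length(contigs), 1L, prob = lens)
      pos <- sample.int(lens[ci], 1L)
      key <- paste(contigs[ci], pos)
      if (key %in% taken) next
      ref <- contig_chars[[ci]][pos]
      if (!ref %in% BASES) next
      if (ems) {
        if (!ref %in% c("G", "C")) next
        alt <- if (ref == "G") "A" else "T"
      } else {
        forbidden <- c(ref, if (ref == "G") "A", if (ref == "C") "T")
        alt <- sample(setdiff(BASES, forbidden), 1L)
      }
      break
    }
    taken <- c(taken, key)
    out <- rbind(out, data.frame(contig = contigs[ci], pos = pos,
                                 ref = ref, alt = alt,
                                 stringsAsFactors = FALSE))
  }
  out
}

# Choose a single-base change creating a premature stop codon within the
# designated transcript exon of `gene`. EMS-compatible (G:C -> A:T on the
# coding strand) candidates are preferred when available.
plant_nonsense <- function(gene, genome, exon_ordinal, bias,
                           exclude_pos = integer(0)) {
  if (exon_ordinal > nrow(gene$exons))
    stop("gene ", gene$gene_id, " has no exon ", exon_ordinal)
  cds <- spliced_cds(gene, genome)
  n_codons <- nchar(cds) %/% 3L
  exon_len <- gene$exons$end - gene$exons$start + 1L
  cds_lo <- if (exon_ordinal == 1L) 1L else sum(exon_len[1:(exon_ordinal - 1L)]) + 1L
  cds_hi <- cds_lo + exon_len[exon_ordinal] - 1L
  codons <- split_codons(cds)
  cand <- list()
  for (p in cds_lo:cds_hi) {
    codon_idx <- (p - 1L) %/% 3L + 1L
    if (codon_idx <= 1L || codon_idx >= n_codons) next  # skip start & stop codons
    codon <- codons[codon_idx]
    within <- (p - 1L) %% 3L + 1L
    ref_b <- substring(codon, within, within)
    for (alt_b in setdiff(BASES, ref_b)) {
      mut <- codon
      substring(mut, within, within) <- alt_b
      if (is_stop_codon(mut)) {
        gpos <- genomic_position(gene, p)
        if (gpos %in% exclude_pos) next
        ems <- (ref_b == "G" && alt_b == "A") || (ref_b == "C" && alt_b == "T")
        cand[[length(cand) + 1L]] <- list(cds_pos = p, gpos = gpos,
                                          cds_ref = ref_b, cds_alt = alt_b,
                                          codon_index = codon_idx, ems = ems)
      }
    }
  }
  if (!length(cand))
    stop("no room for a nonsense change in exon ", exon_ordinal,
         " of ", gene$gene_id)
  ems_ok <- vapply(cand, `[[`, logical(1), "ems")
  pool <- if (any(ems_ok)) cand[ems_ok] else cand
  pick <- pool[[sample.int(length(pool), 1L)]]
  minus <- gene$strand == "-"
  list(contig = gene$contig,
       pos = pick$gpos,
       ref = if (minus) unname(complement_base(pick$cds_ref)) else pick$cds_ref,
       alt = if (minus) unname(complement_base(pick$cds_alt)) else pick$cds_alt,
       codon_index = pick$codon_index,
       cds_pos = pick$cds_pos,
       pos_key = paste(gene$contig, pick$gpos))
}
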