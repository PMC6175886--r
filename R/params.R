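#' Parameters for the synthetic suppressor-screen fixture
#'
#' Bundles and validates every tunable of the screen generator: the size of
#' the synthetic genome, the density of EMS-induced background variants, the
#' shared parental background, and where the two causal nonsense lesions are
#' planted. Defaults mirror the study design the generator emulates: two
#' mutant alleles sharing a mutagenised parental background, with nonsense
#' lesions in exon ordinals 8 and 1 of one ten-exon causal gene.
#'
#' @param n_contigs Number of contigs in the synthetic genome.
#' @param genes_per_contig Genes placed on each contig.
#' @param gene_length_mean Mean CDS length in bp (rounded to whole codons).
#' @param n_background_variants Poisson mean of strain-specific EMS SNVs per
#'   mutant genome. The default emulates the residual unlinked background of
#'   a mutant backcrossed four to six times, scaled to the mini-genome: a
#'   real screen retains on the order of ten unlinked EMS variants across
#'   tens of thousands of genes, i.e. well below one per hundred genes.
#' @param shared_parental_variants Number of SNVs shared by both mutants with
#'   the parental (and marker) background strains.
#' @param causal_gene_index Index (1-based, genome-wide) of the gene that
#'   receives the planted lesions. This gene is generated with
#'   `causal_n_exons` exons.
#' @param lesion_exons Integer pair: transcript exon ordinals receiving the
#'   nonsense lesion in mutant A and mutant B respectively.
#' @param causal_n_exons Exon count of the causal gene; must cover
#'   `lesion_exons`.
#' @param ems_transition_bias Probability that a background mutation is a
#'   G:C -> A:T transition (EMS chemistry).
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(n_contigs = 2L,
                          genes_per_contig = 50L,
                          gene_length_mean = 450L,
                          n_background_variants = 0.5,
                          shared_parental_variants = 40L,
                          causal_gene_index = 13L,
                          lesion_exons = c(8L, 1L),
                          causal_n_exons = 10L,
                          ems_transition_bias = 0.85,
                          seed = 1L) {
  p <- list(
    n_contigs = as.integer(n_contigs),
    genes_per_contig = as.integer(genes_per_contig),
    gene_length_mean = as.integer(gene_length_mean),
    n_background_variants = as.numeric(n_background_variants),
    shared_parental_variants = as.integer(shared_parental_variants),
    causal_gene_index = as.integer(causal_gene_index),
    lesion_exons = as.integer(lesion_exons),
    causal_n_exons = as.integer(causal_n_exons),
    ems_transition_bias = as.numeric(ems_transition_bias),
    seed = as.integer(seed)
  )
  counts <- c(p$n_contigs, p$genes_per_contig, p$gene_length_mean,
              p$shared_parental_variants)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (p$n_background_variants < 0) stop("n_background_variants must be >= 0")
  if (p$ems_transition_bias < 0 || p$ems_transition_bias > 1)
    stop("ems_transition_bias must lie in [0, 1]")
  if (length(p$lesion_exons) != 2L || any(p$lesion_exons < 1L))
    stop("lesion_exons must be two exon ordinals >= 1")
  if (any(p$lesion_exons > p$causal_n_exons))
    stop("lesion_exons refer to exons beyond the causal gene's exon count")
  n_genes <- p$n_contigs * p$genes_per_contig
  if (n_genes > 0L &&
      (p$causal_gene_index < 1L || p$causal_gene_index > n_genes))
    stop("causal_gene_index outside the generated gene set")
  structure(p, class = "screen_params")
}

#' Parameters of the dosage-to-morph decision
#'
#' The simulated morph decision is logistic in the log2 ratio of functional
#' eud-1 to seud-1 copies: P(Eu) = logistic(a + b * log2(E/S)), with hard
#' boundaries at S = 0 (all-Eu) and E = 0 (all-St). Defaults place the
#' balanced 2:2 genotype at 90% Eu, the reference-strain phenotype, with a
#' slope steep enough that the dosage panel spans near-all-St to near-all-Eu.
#' Intermediate-morph animals arise independently at a small rate and are
#' excluded from analysis denominators downstream.
#'
#' @param intercept Log-odds of Eu at a balanced (E = S) dosage.
#' @param slope Log-odds change per unit log2(E/S).
#' @param intermediate_rate Probability an individual is an intermediate.
#' @return An object of class `morph_params`.
#' @export
morph_params <- function(intercept = stats::qlogis(0.9),
                         slope = 2,
                         intermediate_rate = 0.005) {
  if (intermediate_rate < 0 || intermediate_rate > 1)
    stop("intermediate_rate must lie in [0, 1]")
  structure(list(intercept = intercept, slope = slope,
                 intermediate_rate = intermediate_rate),
            class = "morph_params")
}
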