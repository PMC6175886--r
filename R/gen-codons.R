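#' Evolve a coding-sequence pair by planted substitutions
#'
#' Derives a second sequence from `cds` that differs by exactly `n_syn`
#' synonymous and `n_nonsyn` nonsynonymous single-base substitutions, each
#' in a distinct codon, never creating a stop codon. Validation input for
#' [ng86()] with known ground truth.
#'
#' @param cds A valid coding sequence (a terminal stop codon, if present,
#'   is left untouched).
#' @param n_syn,n_nonsyn Numbers of substitutions of each class.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `seq_a` (the input), `seq_b` (the evolved copy), and
#'   `changes`, a data frame of the applied substitutions (codon index,
#'   position within codon, bases, class).
#' @export
evolve_codon_pair <- function(cds, n_syn, n_nonsyn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- toupper(as.character(cds))
  codons <- split_codons(cds)
  n_cod <- length(codons)
  editable <- which(!is_stop_codon(codons))
  # classify each editable codon's available single-base moves
  syn_moves <- lapply(codons, codon_moves, synonymous = TRUE)
  nonsyn_moves <- lapply(codons, codon_moves, synonymous = FALSE)
  can_syn <- intersect(editable, which(lengths(syn_moves) > 0))
  can_nonsyn <- intersect(editable, which(lengths(nonsyn_moves) > 0))
  if (length(can_syn) < n_syn || n_syn + n_nonsyn > length(editable) ||
      length(setdiff(can_nonsyn, character(0))) < n_nonsyn)
    stop("requested substitutions infeasible for this CDS")
  pick_syn <- can_syn[sample.int(length(can_syn), n_syn)]
  pool_nonsyn <- setdiff(can_nonsyn, pick_syn)
  if (length(pool_nonsyn) < n_nonsyn)
    stop("requested substitutions infeasible for this CDS")
  pick_nonsyn <- pool_nonsyn[sample.int(length(pool_nonsyn), n_nonsyn)]
  out <- codons
  changes <- list()
  apply_move <- function(idx, moves, class) {
    mv <- moves[[idx]][[sample.int(length(moves[[idx]]), 1L)]]
    out[idx] <<- mv$codon
    changes[[length(changes) + 1L]] <<- data.frame(
      codon_index = idx, pos_in_codon = mv$pos, ref = mv$ref, alt = mv$alt,
      class = class, stringsAsFactors = FALSE)
  }
  for (i in pick_syn) apply_move(i, syn_moves, "synonymous")
  for (i in pick_nonsyn) apply_move(i, nonsyn_moves, "nonsynonymous")
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(codon_index = integer(0), pos_in_codon = integer(0),
               ref = character(0), alt = character(0), class = character(0))
  list(seq_a = cds, seq_b = paste(out, collapse = ""), changes = changes)
}

# single-base moves from a codon that are (non)synonymous and not stops
codon_moves <- function(codon, synonymous) {
  if (is_stop_codon(codon)) return(list())
  aa <- translate_codon(codon)
  moves <- list()
  for (pos in 1:3) {
    ref <- substring(codon, pos, pos)
    for (alt in setdiff(BASES, ref)) {
      mut <- codon
      substring(mut, pos, pos) <- alt
      if (is_stop_codon(mut)) next
      same <- translate_codon(mut) == aa
      if (same == synonymous)
        moves[[length(moves) + 1L]] <- list(codon = mut, pos = pos,
                                            ref = ref, alt = alt)
    }
  }
  moves
}

#' Generate a random coding sequence
#'
#' ATG start, sense codons, terminal stop.
#'
#' @param n_codons Total codon count including start and stop.
#' @param seed Optional integer seed for reproducibility.
#' @return A character CDS.
#' @export
gen_cds <- function(n_codons = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_codons >= 3L)
  paste0("ATG", paste(sample_sense_codons(n_codons - 2L), collapse = ""),
         sample(STOP_CODONS, 1L))
}
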