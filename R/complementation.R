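#' Construct a complementation matrix
#'
#' @param fails Square logical matrix with mutant ids as dimnames; `TRUE`
#'   means the pair fails to complement (same gene). Must be symmetric with
#'   an all-`TRUE` diagonal (every mutant fails to complement itself).
#' @return A `complementation_matrix`.
#' @export
complementation_matrix <- function(fails) {
  if (!is.matrix(fails) || !is.logical(fails) || nrow(fails) != ncol(fails))
    stop("fails must be a square logical matrix")
  if (is.null(rownames(fails)) || !identical(rownames(fails), colnames(fails)))
    stop("fails must have identical row and column mutant ids")
  if (!isSymmetric(unname(fails)))
    stop("complementation matrix must be symmetric")
  if (!all(diag(fails)))
    stop("diagonal must be fails_to_complement (TRUE)")
  structure(fails, class = c("complementation_matrix", "matrix"))
}

#' Partition mutants into complementation groups
#'
#' Groups are the connected components of the fails-to-complement graph.
#' Consistent data makes every component a clique; intransitive data (A
#' fails with B, B fails with C, but A complements C) raises an error
#' listing the offending triples.
#'
#' @param m A [complementation_matrix()].
#' @return Named list of character vectors, one per group, ordered by first
#'   member.
#' @export
complementation_groups <- function(m) {
  if (!inherits(m, "complementation_matrix")) m <- complementation_matrix(m)
  ids <- rownames(m)
  n <- length(ids)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(m[v, ] & comp == 0L))
    }
  }
  # transitivity: every component must be a clique
  bad <- list()
  for (g in seq_len(cur)) {
    members <- which(comp == g)
    for (a in members) for (b in members) if (a < b && !m[a, b]) {
      # find a witness c linking a and b
      cc <- members[m[a, members] & m[b, members]]
      cc <- setdiff(cc, c(a, b))
      witness <- if (length(cc)) ids[cc[1]] else NA_character_
      bad[[length(bad) + 1L]] <- c(ids[a], witness, ids[b])
    }
  }
  if (length(bad)) {
    trip <- vapply(bad, function(t) paste(t, collapse = " ~ "), character(1))
    stop("intransitive complementation data; offending triple(s): ",
         paste(trip, collapse = "; "))
  }
  split(ids, paste0("group_", comp))
}

#' Generate a consistent complementation matrix with planted groups
#'
#' Synthetic fixture for the screen summary: mutants are partitioned into
#' groups of the given sizes; pairs within a group fail to complement,
#' pairs across groups complement. With the default sizes, the first two
#' mutants form the two-allele group of the causal gene.
#'
#' @param group_sizes Integer vector of group sizes (default `c(2, 2, 3)`:
#'   seven mutants in three groups).
#' @param ids Optional mutant ids, default `mutant_1 ... mutant_n`.
#' @return A `complementation_matrix` with a `truth` attribute giving the
#'   planted group of each mutant.
#' @export
gen_complementation_matrix <- function(group_sizes = c(2L, 2L, 3L),
                                       ids = NULL) {
  n <- sum(group_sizes)
  if (is.null(ids)) ids <- sprintf("mutant_%d", seq_len(n))
  stopifnot(length(ids) == n)
  grp <- rep(seq_along(group_sizes), group_sizes)
  fails <- outer(grp, grp, `==`)
  dimnames(fails) <- list(ids, ids)
  out <- complementation_matrix(fails)
  attr(out, "truth") <- stats::setNames(paste0("group_", grp), ids)
  out
}

#' Read / write a complementation matrix as TSV
#'
#' The TSV holds `complements` / `fails_to_complement` strings with mutant
#' ids as the first column and the header.
#'
#' @param m A `complementation_matrix` (for writing).
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_complementation_tsv <- function(m, path) {
  txt <- ifelse(m, "fails_to_complement", "complements")
  utils::write.table(txt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_complementation_tsv
#' @export
read_complementation_tsv <- function(path) {
  txt <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  complementation_matrix(txt == "fails_to_complement")
}
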