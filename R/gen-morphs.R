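#' Simulate morph counts for a dosage class
#'
#' Individuals become intermediates independently at
#' `params$intermediate_rate`; the remainder develop Eu with probability
#' [morph_probability()] for the class (logistic in log2(E/S), with hard
#' all-Eu / all-St boundaries at S = 0 / E = 0).
#'
#' @param E,S Functional *eud-1* / *seud-1* copy counts (not both 0).
#' @param n Individuals scored.
#' @param params A [morph_params()].
#' @param line,replicate Labels for the returned row.
#' @param seed Optional integer seed for reproducibility.
#' @return A `morph_count` data frame row: `line`, `replicate`, `n_eu`,
#'   `n_st`, `n_intermediate`. The analysis denominator downstream is
#'   `n_eu + n_st`.
#' @export
simulate_morph_counts <- function(E, S, n, params = morph_params(),
                                  line = paste0(E, ":", S), replicate = 1L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (E < 0 || S < 0 || n < 0) stop("E, S and n must be >= 0")
  p <- morph_probability(E, S, params)  # errors when E = S = 0
  n_int <- stats::rbinom(1L, n, params$intermediate_rate)
  n_rem <- n - n_int
  n_eu <- stats::rbinom(1L, n_rem, p)
  morph_count(line = line, replicate = replicate, n_eu = n_eu,
              n_st = n_rem - n_eu, n_intermediate = n_int)
}

#' Construct a morph-count table
#'
#' @param line,replicate Identifiers.
#' @param n_eu,n_st,n_intermediate Non-negative tallies.
#' @return A `morph_count` data frame.
#' @export
morph_count <- function(line, replicate = 1L, n_eu, n_st,
                        n_intermediate = 0L) {
  df <- data.frame(line = as.character(line), replicate = replicate,
                   n_eu = as.integer(n_eu), n_st = as.integer(n_st),
                   n_intermediate = as.integer(n_intermediate),
                   stringsAsFactors = FALSE)
  if (any(df$n_eu < 0 | df$n_st < 0 | df$n_intermediate < 0))
    stop("counts must be >= 0")
  class(df) <- c("morph_count", "data.frame")
  df
}

#' Simulate a morph-count panel across dosage classes
#'
#' @param classes Data frame with columns `E` and `S` (and optionally
#'   `line`), e.g. from [offspring_dosages()].
#' @param n Individuals per class and replicate.
#' @param replicates Replicates per class.
#' @param params A [morph_params()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `morph_count` table with one row per class x replicate and the
#'   generating `E`, `S` columns attached.
#' @export
simulate_morph_panel <- function(classes, n = 100L, replicates = 1L,
                                 params = morph_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(classes))) {
    line <- if ("line" %in% names(classes)) classes$line[i]
            else paste0(classes$E[i], ":", classes$S[i])
    for (r in seq_len(replicates)) {
      mc <- simulate_morph_counts(classes$E[i], classes$S[i], n, params,
                                  line = line, replicate = r)
      mc$E <- classes$E[i]; mc$S <- classes$S[i]
      rows[[length(rows) + 1L]] <- mc
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
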