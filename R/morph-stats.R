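#' Eu proportion with an exact (Clopper-Pearson) 95% confidence interval
#'
#' Intermediates are excluded: the denominator is `n_eu + n_st`. The bounds
#' invert the exact binomial tail probabilities (via [stats::binom.test()]).
#'
#' @param n_eu,n_st Morph tallies (`n_eu + n_st >= 1`). A `morph_count` row
#'   may be given as `n_eu` instead.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `estimate`, `lower`, `upper`, `n`.
#' @export
eu_fraction <- function(n_eu, n_st = NULL, conf_level = 0.95) {
  if (is.data.frame(n_eu)) {
    n_st <- sum(n_eu$n_st); n_eu <- sum(n_eu$n_eu)
  }
  n <- n_eu + n_st
  if (n < 1) stop("need at least one scored (non-intermediate) individual")
  bt <- stats::binom.test(n_eu, n, conf.level = conf_level)
  list(estimate = n_eu / n, lower = bt$conf.int[1], upper = bt$conf.int[2],
       n = n)
}

#' Pairwise Pearson chi-square test on two morph counts
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic on the
#' 2x2 table of Eu/St tallies; p-value from the chi-square distribution
#' with 1 df. Degenerate tables with a zero margin give statistic 0, p = 1.
#'
#' @param a,b `morph_count` rows (or lists with `n_eu`, `n_st`).
#' @return List with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(a, b) {
  res <- pearson_chi2(sum(a$n_eu), sum(a$n_st), sum(b$n_eu), sum(b$n_st))
  list(statistic = res$stat, p_value = res$p)
}

# Vectorised uncorrected Pearson chi-square for 2x2 tables
# rows (a_eu, a_st), (b_eu, b_st).
pearson_chi2 <- function(a_eu, a_st, b_eu, b_st) {
  n <- a_eu + a_st + b_eu + b_st
  r1 <- a_eu + a_st; r2 <- b_eu + b_st
  c1 <- a_eu + b_eu; c2 <- a_st + b_st
  stat <- n * (a_eu * b_st - a_st * b_eu)^2 / (r1 * r2 * c1 * c2)
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat[degenerate] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p)
}

#' Two-proportion Z test (pooled variance)
#'
#' @param a,b `morph_count` rows (or lists with `n_eu`, `n_st`).
#' @return List with `z`, `p_value`. The squared statistic equals the
#'   uncorrected Pearson chi-square on the same table.
#' @export
z_two_proportions <- function(a, b) {
  n1 <- sum(a$n_eu) + sum(a$n_st); n2 <- sum(b$n_eu) + sum(b$n_st)
  p1 <- sum(a$n_eu) / n1; p2 <- sum(b$n_eu) / n2
  pp <- (sum(a$n_eu) + sum(b$n_eu)) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order, bounded by 1.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Fit a binomial GLM with logit link to morph counts
#'
#' Wraps [stats::glm()] (iteratively reweighted least squares; convergence
#' at relative deviance change < 1e-10, at most 100 iterations). Complete
#' separation (an all-Eu or all-St group) is unavoidable at the dosage
#' boundaries: the fit is reported on a clamped probability scale
#' `[1e-8, 1 - 1e-8]` with `separated = TRUE`.
#'
#' @param counts A `morph_count` table; extra covariate columns (e.g. a
#'   dosage covariate) may be present and referenced in `formula`.
#' @param formula Right-hand-side model formula on the count columns,
#'   default `~ line` (genotype as the explanatory variable).
#' @return A `glm_fit` list: `coefficients` (log-odds scale), `fitted`
#'   (clamped proportions), `deviance`, `null_deviance`, `iterations`,
#'   `converged`, `separated`, and the underlying `model`.
#' @export
fit_binomial_glm <- function(counts, formula = ~ line) {
  if (nrow(counts) < 1) stop("need at least one group")
  if (any(counts$n_eu + counts$n_st < 1)) stop("denominators must be >= 1")
  # drop factor terms with a single level (e.g. a one-group fit -> intercept)
  vars <- all.vars(formula)
  single <- Filter(function(v) {
    x <- counts[[v]]
    !is.null(x) && !is.numeric(x) && length(unique(x)) < 2
  }, vars)
  if (length(single)) {
    keep <- setdiff(vars, single)
    rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
    formula <- stats::as.formula(paste("~", rhs))
  }
  full <- stats::update(formula, cbind(n_eu, n_st) ~ .)
  fit <- suppressWarnings(stats::glm(
    full, family = stats::binomial("logit"), data = counts,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  eps <- 1e-8
  fitted_raw <- stats::fitted(fit)
  separated <- any(fitted_raw > 1 - 1e-6 | fitted_raw < 1e-6)
  structure(list(
    coefficients = stats::coef(fit),
    fitted = pmin(pmax(fitted_raw, eps), 1 - eps),
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance,
    iterations = fit$iter,
    converged = fit$converged,
    separated = separated,
    model = fit
  ), class = "glm_fit")
}

#' Likelihood-ratio test between two nested binomial GLM fits
#'
#' @param fit_null,fit_full `glm_fit` objects from [fit_binomial_glm()].
#' @return List with `statistic` (deviance difference), `df`, `p_value`.
#' @export
glm_lrt <- function(fit_null, fit_full) {
  stat <- fit_null$deviance - fit_full$deviance
  df <- length(fit_full$coefficients) - length(fit_null$coefficients)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pairwise morph-ratio comparisons with BH adjustment
#'
#' Pools replicates within lines, then runs the requested pairwise test on
#' every line pair and adjusts p-values by Benjamini-Hochberg.
#'
#' @param counts A `morph_count` table.
#' @param test `"chisq"` or `"z"`.
#' @return Data frame of line pairs with estimates, statistic, `p_value`
#'   and `p_adjusted`.
#' @export
pairwise_morph_tests <- function(counts, test = c("chisq", "z")) {
  test <- match.arg(test)
  pooled <- stats::aggregate(cbind(n_eu, n_st) ~ line, data = counts, FUN = sum)
  lines <- pooled$line
  if (length(lines) < 2) stop("need at least two lines")
  pairs <- utils::combn(seq_along(lines), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- pooled[ij[1], ]; b <- pooled[ij[2], ]
    res <- if (test == "chisq") chisq_2x2(a, b) else z_two_proportions(a, b)
    data.frame(line_a = a$line, line_b = b$line,
               prop_a = a$n_eu / (a$n_eu + a$n_st),
               prop_b = b$n_eu / (b$n_eu + b$n_st),
               statistic = res[[1]], p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
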