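#' Shapiro-Wilk normality p-value
#'
#' Thin gate used to choose between the parametric and rank-based branch of
#' the non-inferiority test: the paired t-test is used only when the
#' oriented per-case differences look normal. A zero-variance input has no
#' normal fit and returns p = 0 with a warning.
#'
#' @param values Numeric vector, 3 <= n <= 5000 after removing NAs.
#' @return P-value in `[0, 1]` for the null hypothesis of normality.
#' @export
shapiro_normality_p <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop("Shapiro test needs at least 3 values", call. = FALSE)
  }
  if (length(values) > 5000L) {
    stop("Shapiro test supports at most 5000 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    warning("constant input: no normal fit, returning p = 0")
    return(0)
  }
  stats::shapiro.test(values)$p.value
}

#' One-sided Wilcoxon signed-rank test
#'
#' Tests H1: the distribution of `deltas` is shifted above zero. Zeros are
#' discarded by default (Wilcoxon's method) or kept with Pratt's method.
#' With at most 20 non-zero values and no tied absolute values the p-value
#' is exact (the full null distribution of the positive-rank sum);
#' otherwise a normal approximation with continuity correction and the
#' usual tie/zero variance corrections is used.
#'
#' @param deltas Numeric vector of paired differences.
#' @param zero_handling `"discard"` (default) or `"pratt"`.
#' @param exact_n_max Largest n for which the exact distribution is used.
#' @return A list with `p` (one-sided, greater), `statistic` (positive-rank
#'   sum V), `n_used`, `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_signed_rank_one_sided <- function(deltas,
                                           zero_handling = c("discard", "pratt"),
                                           exact_n_max = 20L) {
  zero_handling <- match.arg(zero_handling)
  deltas <- deltas[!is.na(deltas)]
  if (all(deltas == 0)) {
    if (length(deltas) == 0L) {
      stop("no non-missing differences", call. = FALSE)
    }
    return(list(p = 1, statistic = 0, n_used = 0L, method = "degenerate",
                note = "all differences zero"))
  }
  nz <- deltas[deltas != 0]
  n0 <- length(deltas) - length(nz)
  if (zero_handling == "discard") {
    x <- nz
  } else {
    x <- deltas
  }
  n <- length(x)
  if (length(nz) < 5L) {
    stop("need at least 5 non-zero differences after zero handling",
         call. = FALSE)
  }
  absx <- abs(x)
  r <- rank(absx)      # average ranks for ties (zeros rank lowest in pratt)
  v <- sum(r[x > 0])
  ties <- any(duplicated(absx))

  if (zero_handling == "discard" && !ties && n <= exact_n_max) {
    # exact: V ~ signed-rank null; one-sided P(V >= v)
    p <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    return(list(p = p, statistic = v, n_used = n, method = "exact"))
  }

  # normal approximation; under pratt, zero-ranks contribute to neither sum
  # and are removed from the mean/variance (Pratt 1959)
  if (zero_handling == "pratt") {
    mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - n0 * (n0 + 1) * (2 * n0 + 1) / 24
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
  }
  tab <- table(absx[if (zero_handling == "pratt") x != 0 else TRUE])
  tie_corr <- sum(tab^3 - tab) / 48
  sig2 <- sig2 - tie_corr
  if (sig2 <= 0) {
    # every non-zero difference identical in absolute value and sign pattern
    # may still vary; fall back to sign-test-like binomial on signs
    npos <- sum(x > 0)
    nnz <- sum(x != 0)
    p <- stats::pbinom(npos - 1, nnz, 0.5, lower.tail = FALSE)
    return(list(p = p, statistic = v, n_used = n, method = "sign_fallback"))
  }
  z <- (v - mu - 0.5) / sqrt(sig2)
  list(p = stats::pnorm(z, lower.tail = FALSE), statistic = v, n_used = n,
       method = "normal_approx")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Familywise-error-controlling step-down correction: the i-th smallest
#' p-value is multiplied by (m - i + 1), monotonicity is enforced by a
#' running maximum, and results are capped at 1 and returned in input
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_bonferroni <- function(p_raw) {
  if (!is.numeric(p_raw) || anyNA(p_raw) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "holm")
}

#' Percentile bootstrap confidence interval for the median
#'
#' Resamples `values` with replacement `n_boot` times and takes the
#' percentile interval of the resampled medians. Deterministic for a fixed
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param values Numeric vector, n >= 2, no NAs.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A list with `median`, `lower`, `upper`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, level = 0.95,
                                seed = 1L) {
  if (anyNA(values)) stop("`values` must not contain NAs", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a bootstrap CI", call. = FALSE)
  meds <- local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    sorted <- apply(matrix(values[idx], nrow = n), 2, sort)
    if (n %% 2L == 1L) {
      sorted[(n + 1L) %/% 2L, ]
    } else {
      (sorted[n %/% 2L, ] + sorted[n %/% 2L + 1L, ]) / 2
    }
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(median = stats::median(values), lower = ci[1], upper = ci[2])
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, e.g. between per-case
#' lesion volumes of two raters. Constant input has no rank ordering and
#' returns NA with a warning.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return Correlation in `[-1, 1]`, or NA if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# reproducible child seeds below 2^31 from a master seed
derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 69069 + as.double(x) * 999331 + 1) %% 2147483647
  as.integer(s)
}
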