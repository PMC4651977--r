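# The statistical battery: Spearman correlation with qualitative agreement
# bins, Bland-Altman bias / limits of agreement / coefficient of
# repeatability, Levene's variance-comparison test (classic, group-mean
# centred), the Wilcoxon matched-pairs signed-rank test (exact under ties
# via a convolution of the rank distribution), and the D'Agostino-Pearson
# omnibus normality test.

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties.  The 95% CI uses the
#' Fisher z transform with variance `1.06 / (n - 3)` (the Fieller
#' correction for rank correlations); `NA` bounds when `n <= 4`.
#'
#' @param x,y Paired measurements (same length, >= 3 pairs).
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `r`, `conf_low`, `conf_high`, `n`, `agreement`
#'   (see [classify_agreement()]).
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 pairs.")
  r <- cor(x, y, method = "spearman")
  if (n > 4 && is.finite(r) && abs(r) < 1) {
    z <- atanh(r)
    se <- sqrt(1.06 / (n - 3))
    q <- qnorm(1 - (1 - conf_level) / 2)
    lo <- tanh(z - q * se); hi <- tanh(z + q * se)
  } else {
    lo <- NA_real_; hi <- NA_real_
  }
  tibble(r = r, conf_low = lo, conf_high = hi, n = n,
         agreement = classify_agreement(r))
}

#' Qualitative agreement category of a correlation
#'
#' Bins a Spearman r into the conventional qualitative categories:
#' r >= 0.80 excellent; (0.60, 0.80) good; (0.40, 0.60] satisfactory;
#' (0.20, 0.40] fair; r <= 0.20 poor.  The 0.80 boundary is assigned
#' upward (excellent); the other stated ranges are closed at their upper
#' edge.
#'
#' @param r Correlation in `[-1, 1]` (vectorized).
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_agreement(c(0.82, 0.66, 0.50, 0.35, 0.1))
classify_agreement <- function(r) {
  if (any(is.finite(r) & (r < -1 | r > 1))) abort("`r` must lie in [-1, 1].")
  dplyr::case_when(
    !is.finite(r) ~ NA_character_,
    r >= 0.80 ~ "excellent",
    r > 0.60 ~ "good",
    r > 0.40 ~ "satisfactory",
    r > 0.20 ~ "fair",
    TRUE ~ "poor"
  )
}

#' Bland-Altman repeatability analysis of paired measurements
#'
#' Differences are `v1 - v2`; `bias` is their mean, `sd_diff` the sample
#' SD (n - 1 denominator), the limits of agreement `bias +/- 1.96 *
#' sd_diff`, and the coefficient of repeatability `CR = 2 * sd_diff`
#' (small CR = high repeatability).  Pair means `(v1 + v2) / 2` are kept
#' for plotting, and pairs where exactly one member is zero — detections
#' in one scan only, which fall on the line `diff = 2 * mean` (slope
#' arctan 2, about 63.4 degrees) of the plot — are flagged and counted.
#'
#' @param v1,v2 Paired measurements (>= 2 pairs).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @param cr_multiplier Coefficient-of-repeatability multiplier (default 2).
#' @return An object of class `bland_altman`: a list with the summary
#'   statistics and a `pairs` tibble; has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 12, 9, 11), c(11, 11, 10, 10))
#' tidy(ba)
bland_altman <- function(v1, v2, loa_multiplier = 1.96, cr_multiplier = 2) {
  stopifnot(length(v1) == length(v2))
  keep <- is.finite(v1) & is.finite(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 2) abort("Bland-Altman analysis needs at least 2 pairs.")
  d <- v1 - v2
  m <- (v1 + v2) / 2
  bias <- mean(d)
  sdd <- sd(d)
  one_zero <- xor(v1 == 0, v2 == 0)
  structure(list(
    bias = bias, sd_diff = sdd,
    loa_low = bias - loa_multiplier * sdd,
    loa_high = bias + loa_multiplier * sdd,
    cr = cr_multiplier * sdd,
    n_pairs = length(d), n_single_detection = sum(one_zero),
    loa_multiplier = loa_multiplier, cr_multiplier = cr_multiplier,
    pairs = tibble(v1 = v1, v2 = v2, mean = m, diff = d,
                   single_detection = one_zero)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d; bias %.3g; SD of differences %.3g; CR %.3g; LoA [%.3g, %.3g]; %d single-scan detections\n",
    x$n_pairs, x$bias, x$sd_diff, x$cr, x$loa_low, x$loa_high,
    x$n_single_detection))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, cr = x$cr, n_pairs = x$n_pairs,
         n_single_detection = x$n_single_detection)
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy(x)

#' Levene's test for equality of variances (group-mean centred)
#'
#' The classic form: absolute deviations from each group's mean are
#' compared by a one-way ANOVA; `W` is the F statistic with `(k - 1,
#' N - k)` degrees of freedom.
#'
#' @param ... Two or more numeric vectors (each of length >= 2), or a
#'   single list of them.
#' @return One-row tibble: `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' levene_test(rnorm(20), rnorm(20, sd = 3))
levene_test <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  groups <- lapply(groups, function(g) g[is.finite(g)])
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 2)) {
    abort("Levene's test needs >= 2 groups with >= 2 observations each.")
  }
  z <- lapply(groups, function(g) abs(g - mean(g)))
  ni <- lengths(z)
  N <- sum(ni)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  num <- sum(ni * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), numeric(1))) / (N - k)
  W <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else num / den
  p <- if (is.infinite(W)) 0 else if (W == 0 && den == 0) 1 else
    pf(W, k - 1, N - k, lower.tail = FALSE)
  tibble(statistic = W, df1 = k - 1, df2 = N - k, p_value = p)
}

# exact distribution of the positive-rank sum W+ under H0, supporting tied
# (average) ranks: convolution over doubled ranks, which are integers
wilcoxon_exact_p <- function(w_plus, ranks) {
  R <- as.integer(round(2 * ranks))
  f <- c(1, rep(0, sum(R)))          # f[s + 1] = #subsets with doubled sum s
  for (r in R) {
    f[(r + 1):length(f)] <- f[(r + 1):length(f)] + f[1:(length(f) - r)]
  }
  tot <- 2^length(R)
  w2 <- as.integer(round(2 * w_plus))
  p_le <- sum(f[1:(w2 + 1)]) / tot
  p_ge <- sum(f[(w2 + 1):length(f)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test that paired differences are symmetric about zero.
#' Zero differences are dropped; |differences| are ranked with average
#' ranks for ties.  For `n <= 25` non-zero differences the p-value is
#' exact (full enumeration of the signed-rank distribution, valid under
#' ties); for larger `n` a normal approximation with continuity and tie
#' correction is used.  If every difference is zero the test is undefined
#' and a flagged result (`p_value = NA`, `degenerate = TRUE`) is returned
#' rather than a p-value.
#'
#' @param v1,v2 Paired measurements; or give `v1` alone as differences and
#'   leave `v2 = NULL`.
#' @return One-row tibble: `statistic` (W+, the positive-rank sum),
#'   `n_nonzero`, `p_value`, `method`, `degenerate`.
#' @export
#' @examples
#' wilcoxon_matched_pairs(c(5, 6, 7, 9), c(1, 2, 3, 4))
wilcoxon_matched_pairs <- function(v1, v2 = NULL) {
  d <- if (is.null(v2)) v1 else {
    stopifnot(length(v1) == length(v2))
    v1 - v2
  }
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = NA_real_, n_nonzero = 0L, p_value = NA_real_,
                  method = "undefined", degenerate = TRUE))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  if (n <= 25) {
    p <- wilcoxon_exact_p(w_plus, rk)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_plus - mu) * 0.5
    z <- (w_plus - mu - cc) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble(statistic = w_plus, n_nonzero = n, p_value = min(1, p),
         method = method, degenerate = FALSE)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino's Z1) and kurtosis
#' (Anscombe-Glynn's Z2) into `K2 = Z1^2 + Z2^2`, referred to a chi-square
#' distribution with 2 degrees of freedom.  Requires `n >= 20` for the
#' transformations to be reliable.
#'
#' @param x Numeric sample (n >= 20).
#' @return One-row tibble: `statistic` (K2), `z_skewness`, `z_kurtosis`,
#'   `p_value`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) abort("the D'Agostino-Pearson test needs n >= 20.")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) abort("sample is constant; normality test undefined.")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  cbrt <- function(v) sign(v) * abs(v)^(1 / 3) # real cube root
  Z2 <- ((1 - 2 / (9 * A)) -
           cbrt((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  tibble(statistic = K2, z_skewness = Z1, z_kurtosis = Z2,
         p_value = pchisq(K2, df = 2, lower.tail = FALSE), n = n)
}
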