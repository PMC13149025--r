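#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The two-sided
#' p-value uses the exact conditional distribution when
#' `n_a * n_b <= 10^4` (and no cross-sample ties prevent it), otherwise the
#' asymptotic Kolmogorov distribution.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return list of class `mfx_test`: `statistic = "KS_D"`, `value`,
#'   `p_value`, `n = c(n_a, n_b)`, `tails = "two-sided"`, `method`.
#' @export
ks_test <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop_mfx("both samples must be non-empty")
  n_a <- length(sample_a); n_b <- length(sample_b)
  pooled <- sort(unique(c(sample_a, sample_b)))
  D <- max(abs(vapply(pooled, function(q)
    mean(sample_a <= q) - mean(sample_b <= q), numeric(1))))
  exact <- n_a * n_b <= 1e4
  p <- if (exact) {
    # exact conditional null distribution of D (handles ties)
    1 - stats::psmirnov(D, sizes = c(n_a, n_b),
                        z = c(sample_a, sample_b),
                        two.sided = TRUE, exact = TRUE)
  } else {
    n_eff <- n_a * n_b / (n_a + n_b)
    kolmogorov_sf(sqrt(n_eff) * D)
  }
  structure(list(statistic = "KS_D", value = D,
                 p_value = min(max(p, 0), 1), n = c(n_a, n_b),
                 tails = "two-sided",
                 method = if (exact) "exact" else "asymptotic"),
            class = "mfx_test")
}

# Survival function of the Kolmogorov distribution.
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))))
}

#' F test of equality of variances
#'
#' The statistic is the larger sample variance over the smaller (so
#' `F >= 1`); the two-sided p doubles the upper tail of the F distribution
#' with the matching degrees of freedom.
#'
#' @param sample_a,sample_b numeric vectors with at least two values each.
#' @return list of class `mfx_test` (`statistic = "F"`, `df`, etc.).
#' @export
f_test_var <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop_mfx("need at least 2 observations per sample")
  v <- c(var(sample_a), var(sample_b))
  n <- c(length(sample_a), length(sample_b))
  if (min(v) == 0) stop_mfx("zero variance in denominator sample")
  big <- which.max(v); small <- 3 - big
  F <- v[big] / v[small]
  df <- c(n[big] - 1, n[small] - 1)
  p <- min(1, 2 * pf(F, df[1], df[2], lower.tail = FALSE))
  structure(list(statistic = "F", value = F, p_value = p, df = df, n = n,
                 tails = "two-sided"), class = "mfx_test")
}

#' Percentile bootstrap CI of the median
#'
#' @param sample numeric vector, n >= 3.
#' @param n_boot number of resamples (default 10,000).
#' @param seed RNG seed (bit-for-bit reproducible).
#' @param conf confidence level.
#' @return list of class `mfx_median_ci`: `median, ci_lo, ci_hi, n, n_boot,
#'   seed`.
#' @export
bootstrap_median_ci <- function(sample, n_boot = 10000, seed = 1L,
                                conf = 0.95) {
  if (length(sample) < 3) stop_mfx("need n >= 3 for a bootstrap median CI")
  check_scalar(n_boot, "n_boot", lo = 1, integerish = TRUE)
  n <- length(sample)
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(matrix(sample[idx], nrow = n), 2, median)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(meds, c(alpha, 1 - alpha), type = 7))
  structure(list(median = median(sample), ci_lo = ci[1], ci_hi = ci[2],
                 n = n, n_boot = as.integer(n_boot), seed = seed),
            class = "mfx_median_ci")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected H statistic with a chi-squared p-value, followed by all
#' pairwise Dunn z statistics on the shared ranks with multiplicity
#' adjustment (Bonferroni by default, Holm available). With every value
#' identical across all groups the result is flagged degenerate
#' (tie correction 0/0 is defined as H = 0).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param p_adjust `"bonferroni"` or `"holm"`.
#' @return list: `kw` (class `mfx_test`, statistic `"H"`), `dunn`
#'   (data.frame `group_a, group_b, z, p_value, p_adjusted`), `degenerate`.
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = c("bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop_mfx("'groups' must be a list of >= 2 numeric vectors")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop_mfx("every group needs at least one observation")
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)  # average ranks for ties
  nj <- tapply(r, g, length)[names(groups)]
  rbar <- tapply(r, g, mean)[names(groups)]
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  degenerate <- length(unique(x)) == 1
  H_raw <- 12 / (N * (N + 1)) * sum(nj * (rbar - (N + 1) / 2)^2)
  corr <- 1 - tie_sum / (N^3 - N)
  H <- if (degenerate || corr == 0) 0 else H_raw / corr
  p <- if (degenerate) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  kw <- structure(list(statistic = "H", value = H, p_value = p, df = k - 1,
                       n = as.integer(nj), tails = "two-sided",
                       degenerate = degenerate), class = "mfx_test")

  pairs <- utils::combn(names(groups), 2)
  sigma2_base <- (N * (N + 1) / 12) - tie_sum / (12 * (N - 1))
  dunn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(sigma2_base * (1 / nj[[a]] + 1 / nj[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p_value = 2 * pnorm(-abs(z)))
  }))
  dunn$p_adjusted <- p.adjust(dunn$p_value, method = p_adjust)
  rownames(dunn) <- NULL
  list(kw = kw, dunn = dunn, degenerate = degenerate)
}

#' @export
print.mfx_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, two-sided p = %.3g (n = %s)\n",
              x$statistic, x$value, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
print.mfx_median_ci <- function(x, ...) {
  cat(sprintf("median = %.4g, 95%% bootstrap CI [%.4g, %.4g] (n = %d, %d resamples)\n",
              x$median, x$ci_lo, x$ci_hi, x$n, x$n_boot))
  invisible(x)
}
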