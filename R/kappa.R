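# Weighted kappa for 2x2 split-by-outcome tables, its confidence interval,
# and the Pearson chi-square gate. These are the quantities the signal
# detection analysis optimises and tests at every candidate split.
#
# Table layout (counts):
#   a = split-positive & severe    b = split-positive & minor
#   c = split-negative & severe    d = split-negative & minor
# with P = (a+c)/n the outcome prevalence, Q = (a+b)/n the split level,
# SE = a/(a+c) sensitivity, SP = d/(b+d) specificity.

check_counts <- function(a, b, c, d) {
  v <- cbind(a, b, c, d)
  if (any(!is.finite(v)) || any(v < 0)) stop_domain("cell counts must be nonnegative and finite.")
  n <- a + b + c + d
  if (any(n < 1)) stop_domain("table total must be >= 1.")
  n
}

#' Weighted kappa of a 2x2 split-by-outcome table
#'
#' The chance-corrected agreement family
#' \deqn{\kappa(r) = \frac{(ad - bc)/n^2}{r\,P(1-Q) + (1-r)\,(1-P)\,Q}}
#' where `P` is the outcome prevalence and `Q` the proportion
#' split-positive. The weight `r` in `[0, 1]` sets the relative cost of
#' false positives versus false negatives: `r = 0.5` is Cohen's kappa,
#' `r = 1` the quality index of sensitivity `(SE - Q)/(1 - Q)`, and `r = 0`
#' the quality index of specificity `(SP - (1 - Q))/Q`. A degenerate margin
#' (zero denominator) returns 0. Vectorised over tables.
#'
#' @param a,b,c,d Cell counts: `a` split-positive severe, `b` split-positive
#'   minor, `c` split-negative severe, `d` split-negative minor.
#' @param r Weight in `[0, 1]`; default `0.5` (Cohen's kappa).
#' @return Kappa value(s) in `[-1, 1]`.
#' @export
#' @examples
#' weighted_kappa(10, 0, 0, 10)          # perfect agreement: 1
#' weighted_kappa(5, 5, 5, 5)            # independence: 0
weighted_kappa <- function(a, b, c, d, r = 0.5) {
  n <- check_counts(a, b, c, d)
  if (any(r < 0 | r > 1)) stop_domain("`r` must be in [0, 1].")
  P <- (a + c) / n
  Q <- (a + b) / n
  num <- (a * d - b * c) / n^2
  den <- r * P * (1 - Q) + (1 - r) * (1 - P) * Q
  ifelse(den == 0, 0, num / den)
}

# Fleiss-Cohen-Everitt large-sample standard error of Cohen's kappa for a
# 2x2 table, in the general agreement-table form specialised to 2 categories.
kappa_se_fce <- function(a, b, c, d) {
  n <- a + b + c + d
  p11 <- a / n; p12 <- b / n; p21 <- c / n; p22 <- d / n
  p1. <- p11 + p12; p2. <- p21 + p22
  p.1 <- p11 + p21; p.2 <- p12 + p22
  po <- p11 + p22
  pe <- p1. * p.1 + p2. * p.2
  k <- ifelse(pe == 1, 0, (po - pe) / (1 - pe))
  A <- p11 * (1 - (p1. + p.1) * (1 - k))^2 + p22 * (1 - (p2. + p.2) * (1 - k))^2
  B <- (1 - k)^2 * (p12 * (p.1 + p2.)^2 + p21 * (p.2 + p1.)^2)
  C <- (k - pe * (1 - k))^2
  v <- (A + B - C) / (n * (1 - pe)^2)
  out <- sqrt(pmax(v, 0))
  out[pe == 1] <- 0
  out
}

#' Confidence interval for the weighted kappa
#'
#' At `r = 0.5` (Cohen's kappa) a symmetric normal-approximation interval
#' `kappa +/- z * se` with the Fleiss-Cohen-Everitt asymptotic standard
#' error; for any other weight a seeded nonparametric bootstrap (multinomial
#' resampling of the `n` subjects over the four cells, percentile interval).
#' Intervals are clipped to `[-1, 1]`. The lower bound is the third stopping
#' rule of the partitioning: recursion halts when it reaches below zero.
#'
#' @inheritParams weighted_kappa
#' @param level Coverage, default `0.95`.
#' @param n_boot Bootstrap resamples when `r != 0.5` (at least 1000).
#' @param boot_seed Seed for the bootstrap so fits are reproducible.
#' @return Named numeric `c(lower, upper)`.
#' @export
kappa_confidence_interval <- function(a, b, c, d, r = 0.5, level = 0.95,
                                      n_boot = 1000, boot_seed = 20170602) {
  n <- check_counts(a, b, c, d)
  if (n < 2) stop_domain("confidence interval requires n >= 2.")
  k <- weighted_kappa(a, b, c, d, r)
  if (identical(r, 0.5) || isTRUE(all.equal(r, 0.5))) {
    se <- kappa_se_fce(a, b, c, d)
    z <- qnorm(1 - (1 - level) / 2)
    ci <- c(k - z * se, k + z * se)
  } else {
    probs <- c(a, b, c, d) / n
    ks <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(boot_seed)
      draws <- rmultinom(n_boot, size = n, prob = probs)
      weighted_kappa(draws[1, ], draws[2, ], draws[3, ], draws[4, ], r)
    })
    alpha2 <- (1 - level) / 2
    ci <- unname(quantile(ks, c(alpha2, 1 - alpha2), names = FALSE))
  }
  ci <- pmin(pmax(ci, -1), 1)
  c(lower = ci[1], upper = ci[2])
}

# Vectorised Pearson X^2 for 2x2 tables (closed form over margins);
# zero-margin tables return statistic 0 with p = 1. stats::chisq.test gives
# the same statistic (correct = FALSE) but cannot be vectorised over the
# thousands of candidate cuts scored per node, hence the closed form here.
chi2_stat_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(den == 0, 0, n * (a * d - b * c)^2 / den)
}

#' Pearson chi-square test for a 2x2 split-by-outcome table
#'
#' Without continuity correction, 1 degree of freedom. Tables with a zero
#' margin return statistic 0 and p-value 1. This is the significance gate of
#' the partitioning: a selected split must reach `p < alpha`.
#'
#' @inheritParams weighted_kappa
#' @return A tibble with columns `statistic` and `p_value` (one row per
#'   table; vectorised).
#' @export
chi_square_test <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  stat <- chi2_stat_2x2(a, b, c, d)
  tibble(statistic = stat,
         p_value = ifelse(stat == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE)))
}
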