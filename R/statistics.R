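#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the omnibus statistic
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared distribution with
#' 2 degrees of freedom.
#'
#' @param x Numeric sample, n >= 8.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("omnibus normality test requires n >= 8",
                   class = "spinemorph_parameter_error")
  if (sd(x) == 0) abort("sample is constant", class = "spinemorph_parameter_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform
  eg2 <- -6 / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = 1 - pchisq(k2, df = 2),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality gate for the two-group workflow
#'
#' Applies the omnibus normality test when the sample is large enough;
#' smaller samples report `applicable = FALSE` and the workflow defaults to
#' the nonparametric branch.
#'
#' @param x Numeric sample.
#' @param alpha Significance level of the gate.
#' @param min_n Minimum sample size for the omnibus test.
#' @return List with `p_value`, `passes`, `applicable`.
#' @export
normality_gate <- function(x, alpha = 0.05, min_n = 8L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    return(list(p_value = NA_real_, passes = FALSE, applicable = FALSE))
  res <- dagostino_pearson(x)
  list(p_value = res$p_value, passes = res$p_value > alpha, applicable = TRUE)
}

new_test_result <- function(test_name, statistic, p_value, n1, n2,
                            normality_p1 = NA_real_, normality_p2 = NA_real_,
                            gate_applied = FALSE, alpha = 0.05) {
  tibble::tibble(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 normality_p1 = normality_p1, normality_p2 = normality_p2,
                 gate_applied = gate_applied, alpha = alpha,
                 significant = p_value < alpha)
}

#' Normality-gated two-group comparison
#'
#' The comparison workflow for two independent groups: both samples are
#' screened with the omnibus normality test; if both pass, a two-sided
#' unpaired Student's t test (equal variance by default) is used, otherwise
#' a two-sided Mann-Whitney test (exact for small samples without ties,
#' normal approximation with tie correction otherwise).
#'
#' @param a,b Numeric samples, n >= 2 each.
#' @param alpha Significance level.
#' @param gate Apply the normality gate? `FALSE` forces the choice in `test`.
#' @param test `"auto"` (gated), `"t"`, or `"mw"`.
#' @param welch Use the Welch (unequal variance) t variant?
#' @return A one-row `TestResult` tibble: `test_name`, `statistic`,
#'   `p_value`, `n1`, `n2`, `normality_p1`, `normality_p2`, `gate_applied`,
#'   `alpha`, `significant`.
#' @examples
#' compare_two_groups(rnorm(30), rnorm(30, 1))
#' @export
compare_two_groups <- function(a, b, alpha = 0.05, gate = TRUE,
                               test = c("auto", "t", "mw"), welch = FALSE) {
  test <- match.arg(test)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    abort("both samples need n >= 2", class = "spinemorph_parameter_error")
  if (sd(a) == 0 && sd(b) == 0 && a[1] == b[1])
    abort("both samples are identical constants",
          class = "spinemorph_parameter_error")
  p1 <- p2 <- NA_real_
  gate_applied <- FALSE
  if (test == "auto" && gate) {
    gate_applied <- TRUE
    g1 <- normality_gate(a, alpha)
    g2 <- normality_gate(b, alpha)
    p1 <- g1$p_value
    p2 <- g2$p_value
    use_t <- g1$applicable && g2$applicable && g1$passes && g2$passes
  } else {
    use_t <- test == "t"
  }
  if (use_t) {
    ht <- t.test(a, b, var.equal = !welch)
    new_test_result("students_t", ht$statistic, ht$p.value,
                    length(a), length(b), p1, p2, gate_applied, alpha)
  } else {
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    new_test_result("mann_whitney", ht$statistic, ht$p.value,
                    length(a), length(b), p1, p2, gate_applied, alpha)
  }
}

#' Two-sample Kolmogorov-Smirnov test against a reference group
#'
#' `D` is the supremum distance between the two empirical cumulative
#' distributions; the p-value uses the asymptotic Kolmogorov distribution
#' with effective sample size `n1 n2 / (n1 + n2)`, or exhaustive
#' permutation when the pooled sample is small.
#'
#' @param reference Reference sample (the comparison baseline).
#' @param sample Sample compared against the reference.
#' @param alpha Significance level.
#' @param method `"auto"` uses exact permutation when `n1 + n2 <= 16`,
#'   asymptotic otherwise.
#' @return A one-row `TestResult` tibble (see [compare_two_groups()]).
#' @export
ks_two_sample <- function(reference, sample, alpha = 0.05,
                          method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  x <- reference[is.finite(reference)]
  y <- sample[is.finite(sample)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty",
                              class = "spinemorph_parameter_error")
  d_obs <- ks_statistic(x, y)
  if (method == "exact" || (method == "auto" && n1 + n2 <= 16)) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    ds <- apply(idx, 2, function(ii) ks_statistic(pooled[ii], pooled[-ii]))
    p <- mean(ds >= d_obs - 1e-12)
    name <- "ks_two_sample"
  } else {
    ne <- n1 * n2 / (n1 + n2)
    p <- kolmogorov_sf(sqrt(ne) * d_obs)
    name <- "ks_two_sample"
  }
  new_test_result(name, d_obs, p, n1, n2, alpha = alpha)
}

ks_statistic <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  max(abs(fx - fy))
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Empirical cumulative distribution table
#'
#' @param x Numeric sample, n >= 1.
#' @return Tibble with sorted unique `value` and cumulative `fraction`
#'   (right-continuous step heights; duplicated values collapse into one
#'   step of proportionally larger height).
#' @examples
#' ecdf_table(c(1, 2, 2, 3))
#' @export
ecdf_table <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1) abort("sample must be non-empty",
                           class = "spinemorph_parameter_error")
  v <- sort(unique(x))
  tibble::tibble(value = v,
                 fraction = vapply(v, function(q) mean(x <= q), numeric(1)))
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Within-cell (paired) comparison on non-normalized values; exact null
#' distribution for n <= 20 pairs without ties, normal approximation
#' otherwise.
#'
#' @param x,y Paired samples of equal length.
#' @param alpha Significance level.
#' @return A one-row `TestResult` tibble.
#' @export
wilcoxon_matched_pairs <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    abort("paired samples must have equal length",
          class = "spinemorph_parameter_error")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  d <- x - y
  exact <- length(d) <= 20 && !any(d == 0) && !any(duplicated(abs(d)))
  ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  new_test_result("wilcoxon_matched_pairs", ht$statistic, ht$p.value,
                  length(x), length(y), alpha = alpha)
}

#' Compare grouped ECDFs in a plot
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) of the measured value and
#'   grouping variable.
#' @return A ggplot of cumulative distributions by group.
#' @export
plot_ecdf_comparison <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes({{ value }}, colour = {{ group }})) +
    ggplot2::stat_ecdf(pad = FALSE) +
    ggplot2::labs(y = "cumulative fraction")
}
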