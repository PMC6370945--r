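# Shared statistical kernel: the tests the analyses report, with explicit
# degenerate-input contracts and the significance-star convention
# p <= 0.05 *, p <= 0.01 **, p <= 0.001 ***.

new_test_result <- function(test, statistic, df, p, estimate = NA_real_,
                            sd = NA_real_, n = NA_integer_,
                            adjusted = FALSE, method = NA_character_,
                            flag = NA_character_) {
  structure(list(test = test, statistic = statistic, df = df,
                 p = p, estimate = estimate, sd = sd, n = n,
                 adjusted = adjusted, method = method,
                 stars = significance_stars(p), flag = flag),
            class = "wingpol_test")
}

#' @export
print.wingpol_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g %s\n", x$test,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p, x$stars))
  invisible(x)
}

#' Significance stars
#'
#' Star convention used throughout: `p <= 0.05` *, `p <= 0.01` **,
#' `p <= 0.001` ***, otherwise `ns`.
#' @param p p value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns"))))
}

#' One-sample t test
#'
#' Two-sided test of `mean(values) == mu0`; the workhorse for per-wing
#' mutant/wild-type ratios tested against 1.0.
#'
#' @param values numeric vector, `n >= 2`.
#' @param mu0 null value (default 1).
#' @return a `wingpol_test` with statistic, df, p, estimate (mean), sd, n.
#' @export
one_sample_t <- function(values, mu0 = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("one_sample_t needs at least 2 values")
  if (stats::sd(values) == 0) stop("one_sample_t undefined: zero variance")
  ht <- stats::t.test(values, mu = mu0)
  new_test_result("one-sample t", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, estimate = mean(values), sd = stats::sd(values),
                  n = n)
}

#' Paired t test
#'
#' @param x,y paired measurements (e.g. wild-type and mutant values from the
#'   same wings), equal length `>= 2`.
#' @return a `wingpol_test`; estimate is the mean difference `x - y`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (length(d) < 2) stop("paired_t needs at least 2 pairs")
  if (stats::sd(d) == 0) stop("paired_t undefined: differences have zero variance")
  ht <- stats::t.test(x, y, paired = TRUE)
  new_test_result("paired t", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, estimate = mean(d), sd = stats::sd(d),
                  n = length(d))
}

#' Unpaired (two-sample) t test
#'
#' Equal-variance (Student) form by default; set `var_equal = FALSE` for the
#' Welch form.
#'
#' @param a,b numeric vectors, each `n >= 2`.
#' @param var_equal pool the variances (default `TRUE`).
#' @return a `wingpol_test`; estimate is `mean(a) - mean(b)`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("unpaired_t needs >= 2 values per group")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    stop("unpaired_t undefined: zero variance in both groups")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_test_result("unpaired t", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, estimate = mean(a) - mean(b),
                  n = length(a) + length(b))
}

#' D'Agostino–Pearson omnibus normality test
#'
#' The K^2 omnibus statistic combining the transformed skewness and kurtosis
#' z scores (D'Agostino, Belanger & D'Agostino 1990), referred to a
#' chi-squared distribution with 2 df. Requires `n >= 8`.
#'
#' @param values numeric vector.
#' @return a `wingpol_test` with `statistic = K2`, `df = 2`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("dagostino_pearson undefined: zero variance")
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  zk <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) *
    sqrt(9 * a / 2)

  k2 <- zs^2 + zk^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  new_test_result("D'Agostino-Pearson K2", k2, 2, p, n = n)
}

#' Normality gate preceding parametric testing
#'
#' Runs the D'Agostino–Pearson omnibus test when the sample is large enough
#' (`n >= n_min`, default 8) and reports whether parametric tests are
#' supported; smaller samples are flagged `not-assessed` and analyzed
#' parametrically, mirroring common practice for small per-wing samples.
#'
#' @param values numeric vector.
#' @param n_min minimum n at which the omnibus test is attempted.
#' @param alpha rejection level for the normality test.
#' @return list with `decision` (`"parametric-ok"`, `"non-normal"` or
#'   `"not-assessed"`) and `test` (a `wingpol_test` or `NULL`).
#' @export
normality_gate <- function(values, n_min = 8, alpha = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) < n_min) {
    return(list(decision = "not-assessed", test = NULL))
  }
  tst <- dagostino_pearson(x)
  list(decision = if (tst$p > alpha) "parametric-ok" else "non-normal",
       test = tst)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way ANOVA across groups and compares every non-control group
#' to the control with Dunnett's single-step adjustment (via
#' \pkg{multcomp}). Unadjusted per-comparison p values are reported
#' alongside.
#'
#' @param values numeric responses.
#' @param group grouping vector (coerced to factor).
#' @param control the control group's level (default: first level).
#' @return list with `anova` (a `wingpol_test` for the F test) and
#'   `comparisons` (data frame: `group`, `estimate`, `p_unadjusted`,
#'   `p_adjusted`, `stars`).
#' @export
anova_dunnett <- function(values, group, control = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("anova_dunnett needs at least 2 groups")
  if (!is.null(control)) group <- stats::relevel(group, ref = as.character(control))
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  fres <- new_test_result("one-way ANOVA F", an[["F value"]][1],
                          c(an[["Df"]][1], an[["Df"]][2]),
                          an[["Pr(>F)"]][1], n = length(values))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  adj <- summary(gl)
  unadj <- summary(gl, test = multcomp::univariate())
  comp <- data.frame(group = levels(group)[-1],
                     estimate = unname(adj$test$coefficients),
                     p_unadjusted = unname(unadj$test$pvalues),
                     p_adjusted = unname(as.numeric(adj$test$pvalues)),
                     stringsAsFactors = FALSE)
  comp$stars <- significance_stars(comp$p_adjusted)
  list(anova = fres, comparisons = comp)
}
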