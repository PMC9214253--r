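# The statistical layer: transforms, GC regression-out, ANOVA/Tukey HSD,
# normality checks, multiplicity correction, exact binomial machinery,
# rank/t tests, Poisson regression, and the generation-time formula.
# Standard procedures delegate to base R / nortest; only the conventions
# (two-sided rules, corrections) are pinned down here.

#' Construct a test-result record
#'
#' @param method label of the procedure.
#' @param statistic test statistic.
#' @param p p-value.
#' @param df degrees of freedom (optional).
#' @param estimate point estimate (optional).
#' @param ci length-2 confidence bounds (optional).
#' @param conf_level confidence level of `ci`.
#' @return an object of class `flux_test`.
#' @export
flux_test <- function(method, statistic = NA_real_, p = NA_real_,
                      df = NULL, estimate = NULL, ci = NULL,
                      conf_level = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  if (!is.null(ci)) stopifnot(length(ci) == 2L, ci[1] <= ci[2])
  structure(list(method = method, statistic = unname(statistic),
                 p = unname(p), df = unname(df),
                 estimate = unname(estimate), ci = unname(ci),
                 conf_level = conf_level),
            class = "flux_test")
}

#' @export
print.flux_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat("  statistic:", format(x$statistic), "\n")
  if (!is.null(x$df)) cat("  df:", format(x$df), "\n")
  cat("  p:", format.pval(x$p), "\n")
  if (!is.null(x$estimate)) cat("  estimate:", format(x$estimate), "\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% CI: [%s, %s]\n", 100 * (x$conf_level %||% 0.95),
                format(x$ci[1]), format(x$ci[2])))
  }
  invisible(x)
}

#' log2(x + 1) transform
#'
#' Count-like window features have variance roughly proportional to the
#' mean; all window models are fitted on this scale.
#'
#' @param x non-negative numeric vector.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log2p1 requires non-negative input")
  log2(x + 1)
}

#' Remove the effect of a covariate by OLS regression
#'
#' Returns residuals of `y ~ x` (with intercept); downstream group
#' contrasts are then run on the residuals.
#'
#' @param y response vector.
#' @param x covariate vector of the same length.
#' @export
regress_out <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3L)
  if (stats::var(x) == 0) stop("covariate is constant; nothing to regress out")
  stats::residuals(stats::lm(y ~ x))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `anova` (a [flux_test()]) and `tukey` (data.frame of
#'   pairwise mean differences with studentized-range adjusted p and CI).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  stopifnot(all(vapply(groups, length, 0L) >= 2L))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  if (stats::var(y) == 0) stop("all observations identical; ANOVA undefined")
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  hsd <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(hsd),
                      diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                      upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(anova = flux_test("one-way ANOVA",
                         statistic = tab[["F value"]][1L],
                         p = tab[["Pr(>F)"]][1L],
                         df = c(tab[["Df"]][1L], tab[["Df"]][2L])),
       tukey = tukey)
}

#' Anderson-Darling normality test
#'
#' Case-3 statistic (mean and variance estimated) with the Stephens
#' small-sample correction, used to confirm that the log2(x+1) transform
#' normalizes model residuals.
#'
#' @param values numeric vector, n >= 8.
#' @export
anderson_darling <- function(values) {
  stopifnot(length(values) >= 8L)
  if (stats::var(values) == 0) stop("constant input; normality test undefined")
  res <- nortest::ad.test(values)
  flux_test("Anderson-Darling normality test",
            statistic = res$statistic, p = res$p.value)
}

#' Dunn-Sidak family-wise alpha correction
#'
#' @param alpha initial alpha level.
#' @param m number of independent tests in the family.
#' @return the corrected per-test alpha `1 - (1 - alpha)^(1/m)`.
#' @export
dunn_sidak <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  1 - (1 - alpha)^(1 / m)
}

#' Exact binomial test with Clopper-Pearson interval
#'
#' Two-sided p-value by the minimum-likelihood rule (the sum of P(k) over
#' all outcomes no more likely than the observed one); the confidence
#' interval comes from beta quantiles, so for `x = 0` the upper bound is
#' the closed form `1 - (alpha/2)^(1/n)`.
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param p0 null success probability.
#' @param conf confidence level.
#' @export
exact_binomial <- function(x, n, p0 = 0.5, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, p0 > 0, p0 < 1)
  res <- stats::binom.test(x, n, p = p0, conf.level = conf)
  flux_test("exact binomial test", statistic = x, p = res$p.value,
            estimate = x / n, ci = as.numeric(res$conf.int),
            conf_level = conf)
}

#' Welch two-sample t-test
#' @param x,y numeric samples (each n >= 2).
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: no within-sample variance; t is 0 (equal means) or
    # undefined (report NA statistic with p by convention 0)
    eq <- mean(x) == mean(y)
    return(flux_test("Welch two-sample t-test",
                     statistic = if (eq) 0 else NA_real_,
                     p = if (eq) 1 else 0,
                     df = length(x) + length(y) - 2L,
                     estimate = mean(x) - mean(y)))
  }
  res <- stats::t.test(x, y)
  flux_test("Welch two-sample t-test", statistic = res$statistic,
            p = res$p.value, df = res$parameter,
            estimate = diff(rev(res$estimate)) * -1)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' @param groups named list of numeric vectors.
#' @param correction p adjustment (only "bonferroni" supported; p is
#'   multiplied by the number of pairs and capped at 1).
#' @return data.frame with one row per pair: `a, b, p_raw, p_adj`.
#' @export
wilcoxon_pairwise <- function(groups, correction = "bonferroni") {
  stopifnot(length(groups) >= 2L, correction == "bonferroni")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  usable <- vapply(groups, length, 0L) >= 2L
  if (any(!usable)) {
    warning("skipping group(s) with n < 2: ",
            paste(names(groups)[!usable], collapse = ", "))
  }
  nm <- names(groups)[usable]
  pairs <- utils::combn(nm, 2L)
  m <- ncol(pairs)
  p_raw <- vapply(seq_len(m), function(i) {
    suppressWarnings(stats::wilcox.test(groups[[pairs[1L, i]]],
                                        groups[[pairs[2L, i]]]))$p.value
  }, 0)
  data.frame(a = pairs[1L, ], b = pairs[2L, ], p_raw = p_raw,
             p_adj = pmin(1, p_raw * m), stringsAsFactors = FALSE)
}

#' Poisson regression with log link
#'
#' Fitted by iteratively reweighted least squares (deviance tolerance
#' 1e-8, at most 100 iterations).
#'
#' @param y non-negative integer counts.
#' @param covariates data.frame (or vector) of covariates; NULL fits an
#'   intercept-only model.
#' @return list with `coefficients`, `se`, `test` (a [flux_test()] on the
#'   last covariate's slope, or the intercept when intercept-only), and
#'   the `fit`.
#' @export
poisson_glm <- function(y, covariates = NULL) {
  stopifnot(all(y >= 0), all(y == round(y)))
  dat <- if (is.null(covariates)) data.frame(y = y)
         else cbind(data.frame(y = y), as.data.frame(covariates))
  form <- if (is.null(covariates)) y ~ 1 else y ~ .
  fit <- stats::glm(form, data = dat, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("Poisson IRLS did not converge in 100 iterations")
  cf <- summary(fit)$coefficients
  k <- nrow(cf)
  list(coefficients = cf[, "Estimate"], se = cf[, "Std. Error"],
       test = flux_test("Poisson GLM (log link)",
                        statistic = cf[k, "z value"], p = cf[k, "Pr(>|z|)"],
                        estimate = cf[k, "Estimate"]),
       fit = fit)
}

#' Generation time from maturity age and adult survival
#'
#' `g = a + s / (1 - s)` with `a` the age at sexual maturity in years and
#' `s` the expected annual adult survival fraction.
#'
#' @param a age at sexual maturity (years, > 0).
#' @param s expected adult survival (0 <= s < 1).
#' @return generation time in years.
#' @export
generation_time <- function(a, s) {
  stopifnot(a > 0, s >= 0)
  if (s >= 1) stop("adult survival must be < 1")
  a + s / (1 - s)
}
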