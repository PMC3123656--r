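# Goodness-of-fit battery: RMSEA with noncentral 90% CI, CFI, NNFI, AIC,
# and the per-group independence baseline they require.

#' Independence baseline model (closed form)
#'
#' Per-group independence model with free item variances and means and zero
#' covariances, no cross-group constraints. The ML solution is closed form
#' (variances = sample variances, means = sample means), so
#' `T_b = sum_g (n_g - 1) * (-ln|R_g|)` with `R_g` the sample correlation
#' matrix, and `df_b = G * p(p-1)/2`.
#'
#' @param groups an `mgcfa_summary` or list of them.
#' @return list with `T`, `df`, `q`, `N`, `G` (class `mgcfa_baseline`).
#' @export
baseline_model <- function(groups) {
  if (inherits(groups, "mgcfa_summary")) groups <- list(groups)
  G <- length(groups)
  n <- vapply(groups, function(g) g$n, numeric(1))
  p <- nrow(groups[[1]]$S)
  has_mean <- !is.null(groups[[1]]$xbar)
  Tb <- sum(vapply(groups, function(g) {
    R <- stats::cov2cor(g$S)
    (g$n - 1) * (-determinant(R, logarithm = TRUE)$modulus)
  }, numeric(1)))
  structure(list(T = max(Tb, 0), df = as.integer(G * p * (p - 1) / 2),
                 q = as.integer(G * p * (1 + has_mean)),
                 N = sum(n), G = G), class = "mgcfa_baseline")
}

# solve pchisq(T, df, ncp) = prob for ncp >= 0; NA if unattainable
solve_ncp <- function(T, df, prob) {
  if (stats::pchisq(T, df) <= prob) return(0)
  hi <- max(T, df) * 2 + 10
  while (stats::pchisq(T, df, ncp = hi) > prob) hi <- hi * 2
  stats::uniroot(function(l) stats::pchisq(T, df, ncp = l) - prob,
                 c(0, hi), tol = 1e-8)$root
}

#' RMSEA with noncentral 90% confidence interval
#'
#' Point estimate `sqrt(G) * sqrt(max(T - df, 0) / (df * (N - G)))` (the
#' multi-group `sqrt(G)` multiplier convention; switchable via
#' `group_multiplier`). Confidence bounds map the noncentrality parameters
#' whose noncentral chi-square distributions place `T` at the upper/lower
#' tail probability through the same transformation.
#'
#' @param T chi-square statistic.
#' @param df model degrees of freedom (> 0).
#' @param N total sample size; `G` number of groups.
#' @param conf confidence level (default 0.90).
#' @param group_multiplier apply the `sqrt(G)` convention (default `TRUE`).
#' @return list with `est`, `lower`, `upper`.
#' @export
rmsea <- function(T, df, N, G = 1, conf = 0.90, group_multiplier = TRUE) {
  if (df <= 0) stop("RMSEA undefined for df = 0", call. = FALSE)
  if (N <= G) stop("N must exceed G", call. = FALSE)
  mult <- if (group_multiplier) sqrt(G) else 1
  to_rmsea <- function(lambda) mult * sqrt(lambda / (df * (N - G)))
  alpha <- (1 - conf) / 2
  l_lo <- solve_ncp(T, df, 1 - alpha)  # T at the (1-alpha) quantile
  l_hi <- solve_ncp(T, df, alpha)      # T at the alpha quantile
  list(est = to_rmsea(max(T - df, 0)), lower = to_rmsea(l_lo),
       upper = to_rmsea(l_hi))
}

#' Comparative and non-normed fit indices
#'
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)` (0/0 treated as
#' perfect fit) and `NNFI = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)`,
#' reported unclipped (NNFI may exceed 1).
#'
#' @param T,df target model statistic and df.
#' @param T_b,df_b baseline (independence) statistic and df on the same
#'   data.
#' @return list with `CFI` and `NNFI` (`NNFI` is `NA` with a warning when
#'   the baseline is no worse than saturated, `T_b/df_b <= 1`).
#' @export
cfi_nnfi <- function(T, df, T_b, df_b) {
  stopifnot(df > 0, df_b > 0)
  num <- max(T - df, 0)
  den <- max(T_b - df_b, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- T_b / df_b
  if (rb <= 1) {
    warning("baseline fits no worse than saturated (T_b/df_b <= 1); ",
            "NNFI undefined")
    nnfi <- NA_real_
  } else {
    nnfi <- (rb - T / df) / (rb - 1)
  }
  list(CFI = cfi, NNFI = nnfi)
}

#' Akaike information criterion
#'
#' `AIC = T + 2q` with `q` the free-parameter count; lower ranks better.
#'
#' @param T chi-square statistic.
#' @param q number of free parameters (>= 0).
#' @return numeric AIC.
#' @export
aic <- function(T, q) {
  stopifnot(q >= 0)
  T + 2 * q
}

#' Full fit-index battery for a fitted model
#'
#' @param fit an `mgcfa_fit`.
#' @param baseline optional [baseline_model()] result on the same data
#'   (computed from the fit's groups if omitted).
#' @param conf RMSEA confidence level.
#' @return An `mgcfa_indices` list: `T`, `df`, `RMSEA` (est/lower/upper),
#'   `CFI`, `NNFI`, `AIC`, `T_b`, `df_b`, `N`, `G`.
#' @export
fit_indices <- function(fit, baseline = NULL, conf = 0.90) {
  stopifnot(inherits(fit, "mgcfa_fit"))
  if (is.null(baseline)) baseline <- baseline_model(fit$groups)
  cn <- cfi_nnfi(fit$T, fit$df, baseline$T, baseline$df)
  structure(list(
    T = fit$T, df = fit$df,
    RMSEA = rmsea(fit$T, fit$df, fit$N, fit$G, conf = conf),
    CFI = cn$CFI, NNFI = cn$NNFI,
    AIC = aic(fit$T, fit$q),
    T_b = baseline$T, df_b = baseline$df,
    N = fit$N, G = fit$G), class = "mgcfa_indices")
}

#' @export
print.mgcfa_indices <- function(x, ...) {
  cat(sprintf(
    "chi2 = %.3f (df %d), CFI = %.3f, NNFI = %.3f, AIC = %.1f\n",
    x$T, x$df, x$CFI, x$NNFI, x$AIC))
  cat(sprintf("RMSEA = %.3f (90%% CI %.3f, %.3f)\n",
              x$RMSEA$est, x$RMSEA$lower, x$RMSEA$upper))
  invisible(x)
}
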