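# Latent mean comparison (Hancock's d) and McDonald's omega reliability.

#' Hancock's standardized latent mean difference
#'
#' `d = (m2 - m1) / s_pooled` with the pooled latent standard deviation
#' using (n - 1) weights:
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,sd1,n1 latent mean, latent SD and size of the first
#'   (reference) group.
#' @param m2,sd2,n2 same for the second group.
#' @return the effect size `d` (sign follows `m2 - m1`).
#' @examples
#' hancock_d(0, 0.482, 4903, -0.261, 0.324, 1903)  # -0.589
#' @export
hancock_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled latent SD is zero", call. = FALSE)
  (m2 - m1) / pooled
}

#' Latent mean comparison from a fitted invariance model
#'
#' Requires a model with free factor means in the non-reference group(s)
#' (scalar or stricter, possibly partial). Reports, per factor: the
#' reference mean (exactly 0 by identification), the non-reference mean
#' estimate with standard error and large-sample z (two-sided p), the
#' model-estimated latent SDs (`sqrt(Phi_jj)`) per group, and Hancock's d
#' computed from those latent SDs and the group sample sizes.
#'
#' @param fit an `mgcfa_fit` with free non-reference factor means; standard
#'   errors are computed if absent.
#' @return data.frame (class `mgcfa_latent_means`) with one row per factor
#'   and non-reference group.
#' @export
latent_mean_comparison <- function(fit) {
  stopifnot(inherits(fit, "mgcfa_fit"))
  tpl <- fit$template
  if (!tpl$mean_structure)
    stop("model has no mean structure", call. = FALSE)
  free_any <- any(!is.na(unlist(lapply(tpl$groups, `[[`, "kap_par"))))
  if (!free_any)
    stop("model has no free factor means (fit a scalar or stricter ",
         "profile)", call. = FALSE)
  if (is.null(fit$se)) fit <- standard_errors(fit)
  ref <- tpl$reference_group
  refsd <- sqrt(diag(fit$params[[ref]]$Phi))
  n <- fit$n
  out <- list()
  for (g in setdiff(tpl$group_names, ref)) {
    kp <- tpl$groups[[g]]$kap_par
    est <- fit$params[[g]]$kappa
    se <- rep(NA_real_, tpl$m)
    se[!is.na(kp)] <- fit$se[kp[!is.na(kp)]]
    gsd <- sqrt(diag(fit$params[[g]]$Phi))
    d <- vapply(seq_len(tpl$m), function(j)
      hancock_d(0, refsd[j], n[[ref]], est[j], gsd[j], n[[g]]),
      numeric(1))
    z <- est / se
    out[[g]] <- data.frame(
      factor = tpl$factors, group = g, reference = ref,
      mean_ref = 0, sd_ref = refsd, mean = est, se = se, z = z,
      p = 2 * stats::pnorm(-abs(z)), sd = gsd, d = d,
      n_ref = n[[ref]], n = n[[g]], row.names = NULL)
  }
  structure(do.call(rbind, out), class = c("mgcfa_latent_means",
                                           "data.frame"))
}

#' @export
print.mgcfa_latent_means <- function(x, digits = 3, ...) {
  cat("Latent mean comparison (reference fixed to 0:", x$reference[1],
      ")\n")
  df <- data.frame(factor = x$factor, group = x$group,
                   mean = round(x$mean, digits), se = round(x$se, digits),
                   z = round(x$z, 2),
                   p = signif(x$p, 2), sd_ref = round(x$sd_ref, digits),
                   sd = round(x$sd, digits), d = round(x$d, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' McDonald's omega reliability for one factor
#'
#' `omega = (sum lambda)^2 phi / ((sum lambda)^2 phi + sum Theta)`; with
#' standardized inputs (`phi = 1`, standardized loadings/uniquenesses) the
#' value is identical.
#'
#' @param loadings per-item loadings on the factor (>= 2 items).
#' @param uniquenesses per-item residual variances (> 0).
#' @param factor_variance the factor variance `phi` (default 1, for
#'   standardized input).
#' @return omega in (0, 1] for nonnegative loadings.
#' @export
omega <- function(loadings, uniquenesses, factor_variance = 1) {
  stopifnot(length(loadings) >= 2, length(uniquenesses) == length(loadings))
  if (any(uniquenesses <= 0))
    stop("uniquenesses must be > 0", call. = FALSE)
  num <- sum(loadings)^2 * factor_variance
  den <- num + sum(uniquenesses)
  if (den <= 0) stop("non-positive denominator", call. = FALSE)
  num / den
}

#' Omega reliability per factor per group from a fitted model
#'
#' @param fit an `mgcfa_fit` (first-order factor models).
#' @return data.frame with columns `group`, `factor`, `omega`.
#' @export
omega_table <- function(fit) {
  stopifnot(inherits(fit, "mgcfa_fit"))
  spec <- fit$spec
  out <- list()
  for (g in fit$group_names) {
    ps <- fit$params[[g]]
    om <- vapply(spec$factors, function(f) {
      its <- spec$loadings[[f]]
      omega(ps$Lambda[its, f], ps$Theta[its], ps$Phi[f, f])
    }, numeric(1))
    out[[g]] <- data.frame(group = g, factor = spec$factors, omega = om,
                           row.names = NULL)
  }
  do.call(rbind, out)
}
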