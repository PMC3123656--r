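# Maximum-likelihood estimation of mean-and-covariance-structure factor
# models, single- and multi-group, under cross-group constraint profiles.
#
# The multi-group ML discrepancy is
#   F = sum_g w_g F_g,   w_g = (n_g - 1) / (N - G),
#   F_g = ln|Sigma_g| + tr(S_g Sigma_g^-1) - ln|S_g| - p
#         + (xbar_g - mu_g)' Sigma_g^-1 (xbar_g - mu_g)
# and the chi-square statistic is T = (N - G) * F. Optimization is
# quasi-Newton (nlminb) on transformed parameters (log scale for variances)
# with analytic gradients.

#' Implied moments of a parameter set
#'
#' `Sigma = Lambda Phi Lambda' + diag(Theta)` and
#' `mu = nu + Lambda kappa`. With a second-order layer,
#' `Phi = Gamma phi2 Gamma' + diag(D)`.
#'
#' @param params list with `Lambda` (p x m), `Theta` (length p), `Phi`
#'   (m x m) or second-order fields `Gamma`, `phi2`, `D`; optionally `nu`
#'   and `kappa` for the mean structure.
#' @return list with `Sigma` (p x p) and `mu` (length p, `NULL` without a
#'   mean structure).
#' @export
implied_moments <- function(params) {
  Lambda <- as.matrix(params$Lambda)
  p <- nrow(Lambda); m <- ncol(Lambda)
  Phi <- params$Phi
  if (is.null(Phi)) {
    if (is.null(params$Gamma))
      stop("params must contain Phi or a second-order layer", call. = FALSE)
    phi2 <- if (is.null(params$phi2)) 1 else params$phi2
    Phi <- tcrossprod(params$Gamma) * phi2 + diag(params$D, m)
  }
  Phi <- as.matrix(Phi)
  if (nrow(Phi) != m || length(params$Theta) != p)
    stop("dimension mismatch between Lambda, Phi and Theta", call. = FALSE)
  Sigma <- Lambda %*% Phi %*% t(Lambda)
  diag(Sigma) <- diag(Sigma) + params$Theta
  mu <- NULL
  if (!is.null(params$nu)) {
    kappa <- if (is.null(params$kappa)) numeric(m) else params$kappa
    mu <- drop(params$nu + Lambda %*% kappa)
  }
  list(Sigma = Sigma, mu = mu)
}

#' ML discrepancy between a group summary and implied moments
#'
#' Nonnegative, and zero exactly when `Sigma = S` and `mu = xbar`.
#'
#' @param summary an `mgcfa_summary`.
#' @param Sigma implied covariance (positive definite).
#' @param mu implied mean vector (omitted for covariance-only models).
#' @return the scalar discrepancy `F_g`.
#' @export
ml_discrepancy <- function(summary, Sigma, mu = NULL) {
  S <- summary$S
  p <- nrow(S)
  Rs <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite", call. = FALSE))
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("implied covariance is not positive definite", call. = FALSE))
  ld_Sigma <- 2 * sum(log(diag(R)))
  ld_S <- 2 * sum(log(diag(Rs)))
  Sinv <- chol2inv(R)
  f <- ld_Sigma + sum(Sinv * S) - ld_S - p
  if (!is.null(mu)) {
    d <- summary$xbar - mu
    f <- f + sum(backsolve(R, d, transpose = TRUE)^2)
  }
  max(f, 0)
}

# ---- internal objective / gradient over a template ------------------------

# Precompute static per-group data for the optimizer.
fit_env <- function(tpl, groups) {
  G <- length(groups)
  n <- vapply(groups, function(g) g$n, numeric(1))
  N <- sum(n)
  w <- (n - 1) / (N - G)
  dat <- lapply(groups, function(g) {
    S <- g$S[tpl$items, tpl$items]
    xb <- if (!is.null(g$xbar)) g$xbar[tpl$items] else NULL
    list(S = S, xbar = xb, ld_S = 2 * sum(log(diag(chol(S)))))
  })
  list(G = G, N = N, n = n, w = w, dat = dat)
}

values_of <- function(tpl, x) {
  v <- x
  lg <- tpl$par$log
  v[lg] <- exp(x[lg])
  v
}

# lean per-group matrix build (no dimnames)
group_mats <- function(tpl, gt, v) {
  p <- tpl$p; m <- tpl$m
  Lambda <- matrix(0, p, m)
  Lambda[gt$lam_fix_pos] <- 1
  Lambda[gt$lam_pos] <- v[gt$lam_par]
  Theta <- v[gt$th_par]
  if (tpl$second_order) {
    Gamma <- v[gt$gam_par]
    Phi <- tcrossprod(Gamma) + diag(v[gt$d_par], m)
  } else {
    Gamma <- NULL
    Phi <- matrix(0, m, m)
    Phi[cbind(gt$phi_row, gt$phi_col)] <- v[gt$phi_par]
    Phi[cbind(gt$phi_col, gt$phi_row)] <- v[gt$phi_par]
  }
  nu <- if (!is.null(gt$nu_par)) v[gt$nu_par] else NULL
  kappa <- NULL
  if (tpl$mean_structure) {
    kappa <- numeric(m)
    fk <- !is.na(gt$kap_par)
    kappa[fk] <- v[gt$kap_par[fk]]
  }
  list(Lambda = Lambda, Theta = Theta, Phi = Phi, Gamma = Gamma,
       nu = nu, kappa = kappa)
}

objective_fn <- function(tpl, env) {
  p <- tpl$p
  function(x) {
    v <- values_of(tpl, x)
    f <- 0
    for (g in seq_len(env$G)) {
      gt <- tpl$groups[[g]]; dg <- env$dat[[g]]
      mats <- group_mats(tpl, gt, v)
      Sigma <- mats$Lambda %*% mats$Phi %*% t(mats$Lambda)
      diag(Sigma) <- diag(Sigma) + mats$Theta
      R <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      fg <- 2 * sum(log(diag(R))) + sum(chol2inv(R) * dg$S) - dg$ld_S - p
      if (!is.null(dg$xbar)) {
        d <- dg$xbar - mats$nu - drop(mats$Lambda %*% mats$kappa)
        fg <- fg + sum(backsolve(R, d, transpose = TRUE)^2)
      }
      f <- f + env$w[g] * fg
    }
    f
  }
}

gradient_fn <- function(tpl, env) {
  q <- tpl$q
  lg <- tpl$par$log
  function(x) {
    v <- values_of(tpl, x)
    grad <- numeric(q)
    for (g in seq_len(env$G)) {
      gt <- tpl$groups[[g]]; dg <- env$dat[[g]]
      mats <- group_mats(tpl, gt, v)
      Lambda <- mats$Lambda; Phi <- mats$Phi
      Sigma <- Lambda %*% Phi %*% t(Lambda)
      diag(Sigma) <- diag(Sigma) + mats$Theta
      R <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(R)) return(grad)  # outside admissible region
      Sinv <- chol2inv(R)
      E <- Sigma - dg$S
      A <- Sinv %*% E %*% Sinv
      has_mean <- !is.null(dg$xbar)
      if (has_mean) {
        d <- dg$xbar - mats$nu - drop(Lambda %*% mats$kappa)
        r <- drop(Sinv %*% d)
        A <- A - tcrossprod(r)
        gmu <- -2 * r
      }
      w <- env$w[g]
      dLam <- 2 * A %*% (Lambda %*% Phi)
      if (has_mean && any(mats$kappa != 0))
        dLam <- dLam + tcrossprod(gmu, mats$kappa)
      grad[gt$lam_par] <- grad[gt$lam_par] + w * dLam[gt$lam_pos]
      grad[gt$th_par] <- grad[gt$th_par] + w * diag(A)
      P <- crossprod(Lambda, A) %*% Lambda
      if (tpl$second_order) {
        grad[gt$gam_par] <- grad[gt$gam_par] + w * drop(2 * P %*% mats$Gamma)
        grad[gt$d_par] <- grad[gt$d_par] + w * diag(P)
      } else {
        off <- gt$phi_row != gt$phi_col
        pv <- P[cbind(gt$phi_row, gt$phi_col)]
        pv[off] <- 2 * pv[off]
        grad[gt$phi_par] <- grad[gt$phi_par] + w * pv
      }
      if (has_mean) {
        grad[gt$nu_par] <- grad[gt$nu_par] + w * gmu
        fk <- !is.na(gt$kap_par)
        if (any(fk))
          grad[gt$kap_par[fk]] <- grad[gt$kap_par[fk]] +
            w * drop(crossprod(Lambda, gmu))[fk]
      }
    }
    grad[lg] <- grad[lg] * v[lg]  # chain rule for log-scale parameters
    grad
  }
}

# ---- start values ---------------------------------------------------------

# data-driven defaults: markers 1, other loadings from marker covariance
# ratios, intercepts = observed means, Theta = half observed variances, Phi
# from marker covariances, kappa = 0. Shared parameters take the
# weight-averaged value across groups.
default_start <- function(tpl, env) {
  q <- tpl$q
  acc <- numeric(q); wt <- numeric(q)
  add <- function(ids, vals, w) {
    acc[ids] <<- acc[ids] + w * vals
    wt[ids] <<- wt[ids] + w
  }
  m <- tpl$m
  mark_items <- vapply(seq_len(m), function(j)
    tpl$spec$markers[[tpl$factors[j]]], character(1))
  mark_idx <- match(mark_items, tpl$items)
  for (g in seq_along(tpl$groups)) {
    gt <- tpl$groups[[g]]; S <- env$dat[[g]]$S; w <- env$w[g]
    svar <- diag(S)
    phi0 <- pmax(svar[mark_idx] / 2, 1e-3)
    if (length(gt$lam_par)) {
      it <- gt$lam_pos %% tpl$p; it[it == 0] <- tpl$p
      fa <- (gt$lam_pos - it) %/% tpl$p + 1L
      if (tpl$identification == "marker") {
        l0 <- S[cbind(it, mark_idx[fa])] / svar[mark_idx[fa]]
      } else {
        l0 <- S[cbind(it, mark_idx[fa])] / svar[mark_idx[fa]] * sqrt(phi0[fa])
      }
      add(gt$lam_par, l0, w)
    }
    if (!is.null(gt$nu_par)) add(gt$nu_par, env$dat[[g]]$xbar, w)
    add(gt$th_par, pmax(svar / 2, 1e-3), w)
    if (tpl$second_order) {
      add(gt$gam_par, sqrt(phi0 / 2), w)
      add(gt$d_par, phi0 / 2, w)
    } else {
      diag_el <- gt$phi_row == gt$phi_col
      vals <- numeric(length(gt$phi_par))
      vals[diag_el] <- if (tpl$identification == "marker")
        phi0[gt$phi_row[diag_el]] else 1
      cov0 <- S[cbind(mark_idx[gt$phi_row[!diag_el]],
                      mark_idx[gt$phi_col[!diag_el]])]
      if (tpl$identification == "variance")
        cov0 <- pmin(pmax(cov0 / sqrt(phi0[gt$phi_row[!diag_el]] *
                                      phi0[gt$phi_col[!diag_el]]), -0.8), 0.8)
      vals[!diag_el] <- cov0
      add(gt$phi_par, vals, w)
    }
    fk <- !is.na(gt$kap_par)
    if (any(fk)) add(gt$kap_par[fk], numeric(sum(fk)), 1)
  }
  wt[wt == 0] <- 1
  acc / wt
}

# start values from per-group parameter sets (e.g. a previous fit or the
# generating parameters); shared parameters take the weighted mean.
start_from_params <- function(tpl, paramsets, env) {
  q <- tpl$q
  acc <- numeric(q); wt <- numeric(q)
  add <- function(ids, vals, w) {
    ok <- !is.na(ids)
    acc[ids[ok]] <<- acc[ids[ok]] + w * vals[ok]
    wt[ids[ok]] <<- wt[ids[ok]] + w
  }
  for (g in seq_along(tpl$groups)) {
    gt <- tpl$groups[[g]]
    ps <- paramsets[[min(g, length(paramsets))]]
    w <- env$w[g]
    Lam <- as.matrix(ps$Lambda)[tpl$items, tpl$factors, drop = FALSE]
    add(gt$lam_par, Lam[gt$lam_pos], w)
    if (!is.null(gt$nu_par)) add(gt$nu_par, ps$nu[tpl$items], w)
    add(gt$th_par, pmax(ps$Theta[tpl$items], 1e-5), w)
    if (tpl$second_order) {
      if (!is.null(ps$Gamma)) {
        add(gt$gam_par, ps$Gamma, w)
        add(gt$d_par, pmax(ps$D, 1e-5), w)
      } else {
        phid <- diag(as.matrix(ps$Phi))
        add(gt$gam_par, sqrt(pmax(phid, 1e-3) / 2), w)
        add(gt$d_par, pmax(phid, 1e-3) / 2, w)
      }
    } else {
      Phi <- as.matrix(ps$Phi)
      add(gt$phi_par, Phi[cbind(gt$phi_row, gt$phi_col)], w)
    }
    fk <- !is.na(gt$kap_par)
    if (any(fk)) {
      kap <- if (is.null(ps$kappa)) numeric(tpl$m) else ps$kappa
      add(gt$kap_par[fk], kap[fk], w)
    }
  }
  wt[wt == 0] <- 1
  acc / wt
}

# ---- main fit -------------------------------------------------------------

#' Fit a (multi-group) confirmatory factor model by maximum likelihood
#'
#' Minimizes the multi-group ML discrepancy over the free parameters defined
#' by the model spec and constraint profile; cross-group equality
#' constraints are realized by shared underlying parameters. Residual and
#' disturbance variances are optimized on the log scale with a floor of
#' `1e-6` (a variance pinned at the floor is reported as a Heywood
#' diagnostic).
#'
#' @param spec an `mgcfa_spec`.
#' @param groups an `mgcfa_summary`, or (named) list of them for multi-group
#'   fits.
#' @param profile an `mgcfa_profile`; defaults to configural (no cross-group
#'   equality).
#' @param start optional warm start: a previous `mgcfa_fit` or a list of
#'   per-group parameter sets.
#' @param se compute standard errors from the numerically differentiated
#'   Hessian of the fit function at the optimum (adds a pass of `2q`
#'   gradient evaluations; off by default, see [standard_errors()]).
#' @param identification `"marker"` or `"variance"` (see
#'   [free_parameter_count()]).
#' @param control list passed to [stats::nlminb()]'s control (defaults:
#'   `rel.tol 1e-10`, `iter.max 500`).
#' @return An object of class `mgcfa_fit` with per-group parameter sets,
#'   discrepancy `F`, chi-square `T = (N - G) F`, `df`, free-parameter count
#'   `q`, convergence record, and per-group implied moments.
#' @export
fit_mgcfa <- function(spec, groups, profile = constraint_profile("configural"),
                      start = NULL, se = FALSE, identification = "marker",
                      control = list()) {
  if (inherits(groups, "mgcfa_summary")) groups <- list(groups)
  gnames <- names(groups)
  if (is.null(gnames)) {
    gnames <- vapply(seq_along(groups), function(i) {
      gl <- groups[[i]]$group
      if (is.null(gl)) paste0("g", i) else gl
    }, character(1))
    names(groups) <- gnames
  }
  tpl <- build_template(spec, gnames, profile,
                        identification = identification)
  env <- fit_env(tpl, groups)
  df <- env$G * (tpl$p * (tpl$p + 1) / 2 +
                 if (tpl$mean_structure) tpl$p else 0) - tpl$q
  if (df < 0) stop("model is under-identified (df < 0)", call. = FALSE)

  if (is.null(start)) {
    v0 <- default_start(tpl, env)
  } else if (inherits(start, "mgcfa_fit")) {
    v0 <- start_from_params(tpl, start$params, env)
  } else {
    v0 <- start_from_params(tpl, start, env)
  }
  x0 <- v0
  x0[tpl$par$log] <- log(pmax(v0[tpl$par$log], 1e-5))

  obj <- objective_fn(tpl, env)
  gr <- gradient_fn(tpl, env)
  lower <- rep(-Inf, tpl$q)
  lower[tpl$par$log] <- log(1e-6)
  ctrl <- utils::modifyList(list(iter.max = 500L, eval.max = 2000L,
                                 rel.tol = 1e-10), control)
  opt <- stats::nlminb(x0, obj, gradient = gr, lower = lower, control = ctrl)
  v <- values_of(tpl, opt$par)
  names(v) <- tpl$par$label

  params <- lapply(gnames, function(g) {
    ps <- template_matrices(tpl, v, g)
    class(ps) <- "mgcfa_params"
    ps
  })
  names(params) <- gnames
  moments <- lapply(params, implied_moments)
  gnorm <- sqrt(sum(gr(opt$par)^2))
  heywood <- tpl$par$label[tpl$par$log & v <= 1.05e-6 &
                           tpl$par$class %in% c("uniqueness", "disturbance")]
  fit <- structure(list(
    spec = spec, profile = profile, template = tpl, group_names = gnames,
    n = env$n, N = env$N, G = env$G,
    est = v, params = params, implied = moments,
    F = opt$objective, T = (env$N - env$G) * opt$objective,
    df = as.integer(df), q = tpl$q,
    converged = opt$convergence == 0,
    conv = list(status = opt$convergence, message = opt$message,
                iterations = opt$iterations, grad_norm = gnorm),
    heywood = heywood, se = NULL, vcov = NULL,
    groups = groups), class = "mgcfa_fit")
  if (length(heywood))
    fit$conv$heywood <- paste("variance at floor:",
                              paste(heywood, collapse = ", "))
  if (se) fit <- standard_errors(fit)
  fit
}

#' Standard errors for a fitted model
#'
#' Inverts the numerically evaluated Hessian of `(N - G)/2 * F` at the
#' optimum (central differences over the analytic gradient). Standard errors
#' for log-scale parameters are mapped back to the variance scale by the
#' delta method.
#'
#' @param fit an `mgcfa_fit`.
#' @return the fit with `$se` (named vector, value scale) and `$vcov` (free
#'   parameter covariance, value scale) filled in.
#' @export
standard_errors <- function(fit) {
  tpl <- fit$template
  env <- fit_env(tpl, fit$groups)
  gr <- gradient_fn(tpl, env)
  x <- fit$est
  x[tpl$par$log] <- log(pmax(x[tpl$par$log], 1e-12))
  scale <- (fit$N - fit$G) / 2
  q <- tpl$q
  H <- matrix(0, q, q)
  for (i in seq_len(q)) {
    h <- max(1e-5, 1e-5 * abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    H[, i] <- scale * (gr(xp) - gr(xm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  d <- ifelse(tpl$par$log, fit$est, 1)  # delta method d value / d x
  Vv <- V * tcrossprod(d)
  se <- sqrt(pmax(diag(Vv), 0))
  names(se) <- tpl$par$label
  dimnames(Vv) <- list(tpl$par$label, tpl$par$label)
  fit$se <- se
  fit$vcov <- Vv
  fit
}

#' Free-parameter table of a fitted model
#'
#' @param fit an `mgcfa_fit` (run [standard_errors()] first for `se`/`z`
#'   columns).
#' @return data.frame with class, item, group, estimate and (if available)
#'   standard error, z and two-sided p.
#' @export
parameter_table <- function(fit) {
  out <- fit$template$par[, c("label", "class", "item", "group")]
  out$estimate <- unname(fit$est)
  if (!is.null(fit$se)) {
    out$se <- unname(fit$se)
    out$z <- out$estimate / out$se
    out$p <- 2 * stats::pnorm(-abs(out$z))
  }
  out
}

#' @export
print.mgcfa_fit <- function(x, ...) {
  cat("Multi-group CFA fit (", x$G, " group(s), N = ", x$N, ")\n", sep = "")
  cat("  profile:", x$profile$level,
      if (nrow(x$profile$exemptions))
        paste0("(", nrow(x$profile$exemptions), " released)"), "\n")
  cat(sprintf("  chi-square T = %.3f, df = %d, free parameters q = %d\n",
              x$T, x$df, x$q))
  cat("  converged:", x$converged,
      sprintf("(iter %d, |grad| %.2e)\n", x$conv$iterations,
              x$conv$grad_norm))
  if (length(x$heywood))
    cat("  Heywood diagnostics:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' Standardize a parameter set
#'
#' Rescales to the standardized metric of the implied moments:
#' `lambda*_ij = lambda_ij sqrt(Phi_jj) / sqrt(Sigma_ii)`,
#' `theta*_i = Theta_i / Sigma_ii`, `nu*_i = nu_i / sqrt(Sigma_ii)`.
#'
#' @param params a parameter set (as in [implied_moments()]).
#' @param Sigma optional implied covariance; computed from `params` if
#'   omitted.
#' @return list with standardized `Lambda`, `Theta`, `nu` (if present) and
#'   the factor correlation matrix `Phi`.
#' @export
standardize_params <- function(params, Sigma = NULL) {
  if (is.null(Sigma)) Sigma <- implied_moments(params)$Sigma
  sds <- sqrt(diag(Sigma))
  if (any(sds <= 0)) stop("zero implied variance", call. = FALSE)
  Phi <- params$Phi
  if (is.null(Phi))
    Phi <- tcrossprod(params$Gamma) *
      (if (is.null(params$phi2)) 1 else params$phi2) +
      diag(params$D, ncol(params$Lambda))
  fsd <- sqrt(diag(as.matrix(Phi)))
  Lams <- sweep(sweep(as.matrix(params$Lambda), 2, fsd, `*`), 1, sds, `/`)
  out <- list(Lambda = Lams,
              Theta = params$Theta / sds^2,
              Phi = stats::cov2cor(as.matrix(Phi)))
  if (!is.null(params$nu)) out$nu <- params$nu / sds
  out
}
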