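# Two-group CES-D-like data generator. Defaults reproduce the published
# two-sample calibration (Chinese n = 4903, Dutch n = 1903): unstandardized
# loadings, intercepts and uniquenesses of the partial-uniqueness model, and
# latent means/SDs of the latent mean comparison. Items are generated in
# analysis orientation (positive-affect items already reversed).

#' Default CES-D generating parameters for the two-sample calibration
#'
#' Returns the per-group parameter sets of the four-factor model used by the
#' generator: loadings equal across groups; intercepts equal except
#' `Failure` (0.57 vs 0.30) and `Good` (1.54 vs 0.68); uniquenesses equal
#' except `Depressed` (0.30 vs 0.13), `Failure` (0.41 vs 0.09), `Fearful`
#' (0.31 vs 0.14), `Good` (1.20 vs 0.72) and `Dislike` (0.23 vs 0.08);
#' latent means 0 in the first (reference) group and
#' (-0.261, -0.259, -0.125, -0.323) in the second; latent SDs
#' (0.482, 0.570, 0.354, 0.574) and (0.324, 0.318, 0.329, 0.184) for
#' SOM/DEP/POS/INT.
#'
#' Latent correlations are not part of the published calibration and are a
#' package assumption, configurable via `factor_cor`. The default (in
#' SOM/DEP/POS/INT order) puts 0.70 between somatic complaints and
#' depressive affect, 0.60 between positive affect and interpersonal
#' problems, and 0.30-0.35 across those blocks: all positive (items are in
#' analysis orientation), and deliberately *not* of the rank-one form a
#' single second-order factor would imply, so that the four-factor
#' structure is the identifiable generating truth in model comparisons.
#'
#' @param factor_cor a full m x m latent correlation matrix, or a single
#'   common correlation for all factor pairs; default as described above.
#' @return list with `params` (two `mgcfa_params` sets, named `chinese` and
#'   `dutch`), `sizes` (4903, 1903) and the `mgcfa_spec` they follow.
#' @export
default_cesd_params <- function(factor_cor = NULL) {
  spec <- builtin_spec("four_factor")
  items <- ordered_items(spec)
  p <- length(items); m <- length(spec$factors)

  load <- c(Bothered = 1.00, Appetite = 1.03, Mind = 1.18, Effort = 1.29,
            Sleep = 1.07, Talk = 1.02, GetGoing = 1.26,
            Blues = 1.00, Depressed = 1.13, Failure = 0.82, Fearful = 0.91,
            Lonely = 1.11, Crying = 0.92, Sad = 1.06,
            Good = 1.00, Hopeful = 1.66, Happy = 2.30, Enjoyed = 2.29,
            Unfriendly = 1.00, Dislike = 0.94)
  nu1 <- c(Bothered = 0.69, Appetite = 0.56, Mind = 0.78, Effort = 0.81,
           Sleep = 0.88, Talk = 0.74, GetGoing = 0.70,
           Blues = 0.52, Depressed = 0.55, Failure = 0.57, Fearful = 0.42,
           Lonely = 0.57, Crying = 0.50, Sad = 0.56,
           Good = 1.54, Hopeful = 1.36, Happy = 1.16, Enjoyed = 1.08,
           Unfriendly = 0.44, Dislike = 0.41)
  nu2 <- nu1; nu2[["Failure"]] <- 0.30; nu2[["Good"]] <- 0.68
  th1 <- c(Bothered = 0.45, Appetite = 0.37, Mind = 0.39, Effort = 0.40,
           Sleep = 0.57, Talk = 0.51, GetGoing = 0.37,
           Blues = 0.29, Depressed = 0.30, Failure = 0.41, Fearful = 0.31,
           Lonely = 0.29, Crying = 0.27, Sad = 0.24,
           Good = 1.20, Hopeful = 0.81, Happy = 0.32, Enjoyed = 0.32,
           Unfriendly = 0.19, Dislike = 0.23)
  th2 <- th1
  th2[c("Depressed", "Failure", "Fearful", "Good", "Dislike")] <-
    c(0.13, 0.09, 0.14, 0.72, 0.08)

  sds <- list(c(0.482, 0.570, 0.354, 0.574),
              c(0.324, 0.318, 0.329, 0.184))
  kappas <- list(c(0, 0, 0, 0), c(-0.261, -0.259, -0.125, -0.323))

  if (is.null(factor_cor)) {
    Rmat <- matrix(c(1.00, 0.70, 0.30, 0.35,
                     0.70, 1.00, 0.30, 0.35,
                     0.30, 0.30, 1.00, 0.60,
                     0.35, 0.35, 0.60, 1.00), m, m)
  } else if (is.matrix(factor_cor)) {
    Rmat <- factor_cor
  } else {
    Rmat <- matrix(factor_cor, m, m); diag(Rmat) <- 1
  }
  fac_of <- integer(p); names(fac_of) <- items
  for (j in seq_len(m)) fac_of[spec$loadings[[spec$factors[j]]]] <- j
  Lambda <- matrix(0, p, m, dimnames = list(items, spec$factors))
  Lambda[cbind(seq_len(p), fac_of)] <- load[items]

  mk <- function(nu, th, sd, kap) {
    Phi <- diag(sd) %*% Rmat %*% diag(sd)
    dimnames(Phi) <- list(spec$factors, spec$factors)
    names(kap) <- spec$factors
    structure(list(Lambda = Lambda, nu = nu[items], Theta = th[items],
                   Phi = Phi, kappa = kap), class = "mgcfa_params")
  }
  list(params = list(chinese = mk(nu1, th1, sds[[1]], kappas[[1]]),
                     dutch = mk(nu2, th2, sds[[2]], kappas[[2]])),
       sizes = c(chinese = 4903L, dutch = 1903L),
       spec = spec)
}

#' Generator configuration
#'
#' @param params list of per-group `mgcfa_params` (generating parameter
#'   sets); default [default_cesd_params()].
#' @param sizes named integer vector of group sizes.
#' @param battery the item battery the generated table follows.
#' @param likert discretize responses to the battery's integer scale using
#'   thresholds at the quartiles of each item's marginal distribution in the
#'   first group (default `FALSE`: continuous responses, the metric the ML
#'   analysis assumes).
#' @param missing_rate MCAR missingness fraction in `[0, 0.05]` (default
#'   0.01, matching the "< 1 percent" missingness the calibration assumes).
#' @param seed optional integer seed applied by [generate_items()].
#' @return An object of class `mgcfa_genconfig`.
#' @export
generator_config <- function(params = NULL, sizes = NULL,
                             battery = cesd_battery(), likert = FALSE,
                             missing_rate = 0.01, seed = NULL) {
  if (is.null(params)) {
    d <- default_cesd_params()
    params <- d$params
    if (is.null(sizes)) sizes <- d$sizes
  }
  if (is.null(sizes)) stop("group sizes required", call. = FALSE)
  if (is.null(names(sizes))) names(sizes) <- names(params)
  if (missing_rate < 0 || missing_rate > 0.05)
    stop("missing_rate must be in [0, 0.05]", call. = FALSE)
  p <- nrow(params[[1]]$Lambda)
  if (any(sizes < p + 1))
    stop("group sizes must exceed the number of items", call. = FALSE)
  for (ps in params) {
    ev <- eigen(ps$Phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("factor covariance matrix is not positive definite",
           call. = FALSE)
  }
  structure(list(params = params, sizes = sizes, battery = battery,
                 likert = isTRUE(likert), missing_rate = missing_rate,
                 seed = seed, edits = list()),
            class = "mgcfa_genconfig")
}

#' Generate a two-group item data table from a factor model
#'
#' Per respondent in group g: factor scores
#' `eta ~ N(kappa_g, Phi_g)`, residuals `e ~ N(0, diag(Theta_g))`, response
#' `y = nu_g + Lambda_g eta + e`. With `likert = TRUE`, responses are cut at
#' the quartiles of each item's implied marginal distribution in the first
#' group; an MCAR mask is applied last. Fully reproducible from the seed.
#'
#' @param config an [generator_config()] (default: the CES-D two-sample
#'   calibration).
#' @param seed integer seed (overrides `config$seed`).
#' @return An `mgcfa_items` table (continuous responses unless `likert`).
#' @export
generate_items <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "mgcfa_genconfig"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  items <- rownames(config$params[[1]]$Lambda)
  p <- length(items)
  blocks <- vector("list", length(config$sizes))
  for (g in seq_along(config$sizes)) {
    ps <- config$params[[g]]
    n <- config$sizes[[g]]
    m <- ncol(ps$Lambda)
    eta <- MASS::mvrnorm(n, mu = ps$kappa, Sigma = ps$Phi)
    e <- matrix(stats::rnorm(n * p, sd = rep(sqrt(ps$Theta), each = n)),
                n, p)
    y <- matrix(ps$nu, n, p, byrow = TRUE) + eta %*% t(ps$Lambda) + e
    colnames(y) <- items
    blocks[[g]] <- y
  }
  if (config$likert) {
    ref <- implied_moments(config$params[[1]])
    lo <- config$battery$scale_min; hi <- config$battery$scale_max
    probs <- seq_len(hi - lo) / (hi - lo + 1)  # quartiles for a 1..4 scale
    for (g in seq_along(blocks)) {
      for (j in seq_len(p)) {
        cuts <- stats::qnorm(probs, mean = ref$mu[j],
                             sd = sqrt(ref$Sigma[j, j]))
        blocks[[g]][, j] <- lo + findInterval(blocks[[g]][, j], cuts)
      }
    }
  }
  y <- do.call(rbind, blocks)
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(y)) < config$missing_rate
    y[mask] <- NA
  }
  df <- data.frame(group = rep(names(config$sizes), config$sizes), y,
                   check.names = FALSE)
  # continuous tables bypass integer-scale validation by construction
  structure(df, battery = config$battery,
            class = c("mgcfa_items", "data.frame"))
}

#' Plant non-invariance into a generator configuration
#'
#' Applies additive edits to named parameters of one group, returning a new
#' configuration whose edit log records the planted truth (for recovery
#' tests of the invariance-decision machinery).
#'
#' @param config an `mgcfa_genconfig`.
#' @param edits list of edits, each a list/vector with fields `class`
#'   (`"loading"`, `"intercept"`, `"uniqueness"`), `item`, `group` (label or
#'   index), `delta` (additive shift).
#' @return the edited configuration (class `mgcfa_genconfig`), with
#'   `$edits` extended.
#' @export
planted_noninvariance <- function(config, edits) {
  stopifnot(inherits(config, "mgcfa_genconfig"))
  for (e in edits) {
    e <- as.list(e)
    g <- e$group
    if (is.character(g)) g <- match(g, names(config$params))
    if (is.na(g) || g < 1 || g > length(config$params))
      stop("unknown group in edit", call. = FALSE)
    ps <- config$params[[g]]
    it <- e$item
    if (!it %in% rownames(ps$Lambda))
      stop("unknown item in edit: ", it, call. = FALSE)
    delta <- as.numeric(e$delta)
    switch(as.character(e$class),
      loading = {
        j <- which(ps$Lambda[it, ] != 0)
        ps$Lambda[it, j] <- ps$Lambda[it, j] + delta
      },
      intercept = ps$nu[it] <- ps$nu[it] + delta,
      uniqueness = {
        if (ps$Theta[it] + delta <= 0)
          stop("edit drives uniqueness of '", it, "' non-positive",
               call. = FALSE)
        ps$Theta[it] <- ps$Theta[it] + delta
      },
      stop("unknown edit class: ", e$class, call. = FALSE))
    config$params[[g]] <- ps
    config$edits[[length(config$edits) + 1L]] <-
      list(class = e$class, item = it,
           group = names(config$params)[g], delta = delta)
  }
  config
}
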