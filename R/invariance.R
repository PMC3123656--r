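# The measurement-invariance ladder: configural -> metric -> scalar ->
# uniqueness, with delta-fit decision rules and the partial-invariance
# constraint-release search.

#' Decision cutoffs for nested invariance comparisons
#'
#' A step is acceptable when the fit deterioration relative to the previous
#' accepted model stays below the cutoffs: `delta CFI < 0.01` and
#' `delta RMSEA < 0.015` (Chen's recommendations). With
#' `require_both = TRUE` (default) both indices must satisfy their cutoff.
#'
#' @param delta_cfi_max maximum acceptable CFI drop (default 0.01).
#' @param delta_rmsea_max maximum acceptable RMSEA increase (default 0.015).
#' @param require_both both criteria must hold (default `TRUE`); otherwise
#'   either suffices.
#' @return An object of class `mgcfa_cutoffs`.
#' @export
cutoff_config <- function(delta_cfi_max = 0.01, delta_rmsea_max = 0.015,
                          require_both = TRUE) {
  if (delta_cfi_max <= 0 || delta_rmsea_max <= 0)
    stop("cutoffs > 0 required", call. = FALSE)
  structure(list(delta_cfi_max = delta_cfi_max,
                 delta_rmsea_max = delta_rmsea_max,
                 require_both = isTRUE(require_both)),
            class = "mgcfa_cutoffs")
}

#' Compare two nested fits
#'
#' The restricted model's constraints must contain the free model's (same
#' data). Deltas follow the invariance-testing convention:
#' `delta chi2 = T_r - T_f` (floored at 0 with a tolerance flag),
#' `delta df = df_r - df_f`, `delta CFI = CFI_f - CFI_r`,
#' `delta RMSEA = RMSEA_r - RMSEA_f`.
#'
#' @param free,restricted invariance steps: lists with elements `fit` (an
#'   `mgcfa_fit`) and `indices` (an `mgcfa_indices`), as produced inside
#'   [run_invariance()]; a bare `mgcfa_fit` is also accepted (indices are
#'   computed).
#' @param cutoffs a [cutoff_config()].
#' @return list with the deltas, a chi-square difference p value (reported,
#'   never used for the decision), and `accepted` per the cutoffs.
#' @export
compare_nested <- function(free, restricted, cutoffs = cutoff_config()) {
  as_step <- function(x) {
    if (inherits(x, "mgcfa_fit")) list(fit = x, indices = fit_indices(x))
    else x
  }
  free <- as_step(free); restricted <- as_step(restricted)
  ddf <- restricted$fit$df - free$fit$df
  if (ddf < 0)
    stop("models are not nested in the stated order (df_r < df_f)",
         call. = FALSE)
  dchisq <- restricted$fit$T - free$fit$T
  nonmonotone <- dchisq < -1e-4 * max(1, free$fit$T)
  dchisq <- max(dchisq, 0)
  dcfi <- free$indices$CFI - restricted$indices$CFI
  drmsea <- restricted$indices$RMSEA$est - free$indices$RMSEA$est
  ok_cfi <- dcfi < cutoffs$delta_cfi_max
  ok_rmsea <- drmsea < cutoffs$delta_rmsea_max
  accepted <- if (cutoffs$require_both) ok_cfi && ok_rmsea
              else ok_cfi || ok_rmsea
  list(delta_chisq = dchisq, delta_df = as.integer(ddf),
       p_chisq = stats::pchisq(dchisq, ddf, lower.tail = FALSE),
       delta_cfi = dcfi, delta_rmsea = drmsea,
       nonmonotone = nonmonotone, accepted = accepted)
}

level_class <- c(metric = "loading", scalar = "intercept",
                 uniqueness = "uniqueness")

# items whose `class` constraint may be released at this step: currently
# equated, not a fixed marker loading, and (for intercepts with free factor
# means) not the factor's last equated intercept.
release_candidates <- function(spec, class, exemptions) {
  items <- ordered_items(spec)
  markers <- unlist(spec$markers)
  ex_items <- exemptions$item[exemptions$class == class]
  cand <- setdiff(items, ex_items)
  if (class == "loading") cand <- setdiff(cand, markers)
  if (class == "intercept") {
    for (f in spec$factors) {
      left <- setdiff(spec$loadings[[f]], ex_items)
      if (length(left) <= 1) cand <- setdiff(cand, left)
    }
  }
  cand
}

#' Partial-invariance constraint-release search
#'
#' For a rejected step, iteratively refits the step's model with each
#' currently-equated parameter of the step's class released one at a time,
#' permanently releases the one yielding the largest chi-square improvement,
#' and stops as soon as the deltas against the previous accepted model
#' satisfy the cutoffs — or the candidate set is exhausted (the level is
#' then reported as non-invariant). Ties in the chi-square gain are broken
#' by battery item order.
#'
#' @param failed_step a rejected step: list with `fit`, `indices`, `level`.
#' @param previous_accepted the previous accepted step (list with `fit`,
#'   `indices`).
#' @param cutoffs a [cutoff_config()].
#' @param baseline optional [baseline_model()] (recomputed otherwise).
#' @return list: `released` (data.frame of class/item in release order),
#'   `step` (the refitted step with decision `"partial-accepted"` or
#'   `"rejected"`), and `trail` (per-release candidate chi-square gains).
#' @export
partial_search <- function(failed_step, previous_accepted,
                           cutoffs = cutoff_config(), baseline = NULL) {
  fit <- failed_step$fit
  level <- fit$profile$level
  cls <- level_class[[level]]
  if (is.null(cls))
    stop("no constrained class to release at level '", level, "'",
         call. = FALSE)
  if (is.null(baseline)) baseline <- baseline_model(fit$groups)
  spec <- fit$spec
  exemptions <- fit$profile$exemptions
  released <- data.frame(class = character(), item = character())
  trail <- list()
  current <- failed_step
  # a step that already satisfies the cutoffs needs no releases
  pre <- compare_nested(previous_accepted, current, cutoffs)
  if (pre$accepted) {
    current$delta <- pre
    current$decision <- "accepted"
    return(list(released = released, step = current, trail = trail))
  }
  repeat {
    cand <- release_candidates(spec, cls, exemptions)
    if (!length(cand)) {
      current$decision <- "rejected"
      return(list(released = released, step = current, trail = trail))
    }
    fits <- lapply(cand, function(it) {
      prof <- constraint_profile(
        level, rbind(exemptions, data.frame(class = cls, item = it)),
        reference_group = fit$profile$reference_group)
      fit_mgcfa(spec, fit$groups, prof, start = current$fit)
    })
    gains <- current$fit$T - vapply(fits, function(f) f$T, numeric(1))
    best <- which.max(gains)  # ties: first in item order
    trail[[length(trail) + 1L]] <-
      data.frame(item = cand, gain = gains)
    exemptions <- rbind(exemptions,
                        data.frame(class = cls, item = cand[best]))
    released <- rbind(released,
                      data.frame(class = cls, item = cand[best]))
    current <- list(level = level, fit = fits[[best]],
                    indices = fit_indices(fits[[best]], baseline))
    delta <- compare_nested(previous_accepted, current, cutoffs)
    current$delta <- delta
    if (delta$accepted) {
      current$decision <- "partial-accepted"
      return(list(released = released, step = current, trail = trail))
    }
  }
}

#' Run the measurement-invariance sequence
#'
#' Fits configural (no cross-group equalities, factor means fixed to 0 in
#' every group), metric (loadings equated), scalar (loadings + intercepts
#' equated, factor means free in non-reference groups) and uniqueness
#' (residual variances additionally equated) models in order. Each step
#' after the first is compared with the previous *accepted* (possibly
#' partial) model under the delta cutoffs; a failing step triggers the
#' partial-invariance search when `allow_partial`. Exemptions accumulate
#' down the ladder, and items whose intercepts were released at the scalar
#' level are also exempted from uniqueness equality. The configural step is
#' judged on absolute fit (CFI >= 0.90 and RMSEA <= 0.08). The ladder stops
#' at the first level that cannot be made acceptable.
#'
#' @param spec an `mgcfa_spec`.
#' @param groups list of >= 2 `mgcfa_summary` objects (or an `mgcfa_items`
#'   table, summarized per group).
#' @param cutoffs a [cutoff_config()].
#' @param allow_partial run [partial_search()] on failing steps (default
#'   `TRUE`).
#' @param reference_group label of the group whose factor means are fixed
#'   to 0 (default: first group).
#' @return An `mgcfa_invariance` report: ordered `steps`, each carrying the
#'   constraint profile, fitted model, fit indices, deltas versus the
#'   previous accepted model, decision, and released constraints.
#' @export
run_invariance <- function(spec, groups, cutoffs = cutoff_config(),
                           allow_partial = TRUE, reference_group = NULL) {
  if (inherits(groups, "mgcfa_items")) groups <- summarize_groups(groups)
  if (length(groups) < 2)
    stop("invariance testing needs >= 2 groups", call. = FALSE)
  baseline <- baseline_model(groups)
  exemptions <- data.frame(class = character(), item = character())
  steps <- list()
  prev <- NULL
  for (level in c("configural", "metric", "scalar", "uniqueness")) {
    ex <- exemptions
    if (level == "uniqueness") {
      # inherit: scalar-released items are exempt from uniqueness equality
      sc <- ex$item[ex$class == "intercept"]
      if (length(sc))
        ex <- unique(rbind(ex, data.frame(class = "uniqueness", item = sc)))
    }
    prof <- constraint_profile(level, ex, reference_group = reference_group)
    fit <- fit_mgcfa(spec, groups, prof,
                     start = if (!is.null(prev)) prev$fit)
    step <- list(level = level, fit = fit,
                 indices = fit_indices(fit, baseline),
                 released = data.frame(class = character(),
                                       item = character()))
    if (is.null(prev)) {
      step$delta <- NULL
      step$decision <- if (step$indices$CFI >= 0.90 &&
                           step$indices$RMSEA$est <= 0.08)
        "accepted" else "rejected"
    } else {
      step$delta <- compare_nested(prev, step, cutoffs)
      step$decision <- if (step$delta$accepted) "accepted" else "rejected"
      if (step$decision == "rejected" && allow_partial) {
        sr <- partial_search(step, prev, cutoffs, baseline)
        step <- sr$step
        step$released <- sr$released
        step$search_trail <- sr$trail
      }
    }
    steps[[level]] <- step
    if (step$decision == "rejected") break
    prev <- step
    exemptions <- unique(rbind(step$fit$profile$exemptions, step$released))
  }
  structure(list(steps = steps, cutoffs = cutoffs, baseline = baseline,
                 spec = spec,
                 reference_group =
                   steps[[1]]$fit$template$reference_group),
            class = "mgcfa_invariance")
}

#' @export
print.mgcfa_invariance <- function(x, digits = 3, ...) {
  cat("Measurement-invariance sequence (reference group:",
      x$reference_group, ")\n")
  cat(sprintf("cutoffs: dCFI < %.3g, dRMSEA < %.3g\n\n",
              x$cutoffs$delta_cfi_max, x$cutoffs$delta_rmsea_max))
  hdr <- sprintf("%-12s %10s %4s %8s %6s %6s %6s  %s", "model", "chi2",
                 "df", "AIC", "CFI", "NNFI", "RMSEA", "decision")
  cat(hdr, "\n")
  for (s in x$steps) {
    i <- s$indices
    lab <- if (nrow(s$released)) paste0("partial ", s$level) else s$level
    cat(sprintf("%-12s %10.3f %4d %8.1f %6.3f %6.3f %6.3f  %s\n",
                lab, i$T, i$df, i$AIC, i$CFI, i$NNFI, i$RMSEA$est,
                s$decision))
    if (!is.null(s$delta))
      cat(sprintf("%12s dchi2 = %.3f (ddf %d), dCFI = %.4f, dRMSEA = %.4f\n",
                  "", s$delta$delta_chisq, s$delta$delta_df,
                  s$delta$delta_cfi, s$delta$delta_rmsea))
    if (nrow(s$released))
      cat(sprintf("%12s released: %s\n", "",
                  paste(s$released$class, s$released$item, sep = ":",
                        collapse = ", ")))
  }
  invisible(x)
}
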