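# Model comparison, report assembly and plain-text serialization.

#' Compare factor structures across groups
#'
#' Fits each requested structure to each group separately (and optionally
#' jointly as a configural multi-group model) and tabulates the fit battery
#' side by side, flagging the best-fitting structure per group by AIC and by
#' RMSEA.
#'
#' @param groups an `mgcfa_summary`, list of them, or an `mgcfa_items`
#'   table.
#' @param models character vector of [builtin_spec()] names, or a named
#'   list of `mgcfa_spec` objects.
#' @param joint also fit each structure as a joint configural multi-group
#'   model (default `FALSE`).
#' @return An `mgcfa_comparison`: `table` (data.frame with group, model,
#'   chi2, df, AIC, CFI, NNFI, RMSEA and CI), `best` (per group), `fits`.
#'   Estimation failures are recorded per model without aborting the batch.
#' @export
compare_models <- function(groups,
                           models = c("four_factor", "second_order",
                                      "three_factor", "one_factor"),
                           joint = FALSE) {
  if (inherits(groups, "mgcfa_items")) groups <- summarize_groups(groups)
  if (inherits(groups, "mgcfa_summary")) groups <- list(groups)
  if (is.character(models)) {
    specs <- lapply(models, builtin_spec)
    names(specs) <- models
  } else specs <- models
  rows <- list(); fits <- list()
  add_row <- function(gname, mname, fit, err = NULL) {
    if (!is.null(err)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        group = gname, model = mname, chisq = NA, df = NA, AIC = NA,
        CFI = NA, NNFI = NA, RMSEA = NA, RMSEA_lo = NA, RMSEA_hi = NA,
        error = err)
      return(invisible())
    }
    i <- fit_indices(fit)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = gname, model = mname, chisq = i$T, df = i$df, AIC = i$AIC,
      CFI = i$CFI, NNFI = i$NNFI, RMSEA = i$RMSEA$est,
      RMSEA_lo = i$RMSEA$lower, RMSEA_hi = i$RMSEA$upper,
      error = NA_character_)
    fits[[paste(gname, mname, sep = ".")]] <<- fit
  }
  for (mname in names(specs)) {
    for (g in seq_along(groups)) {
      gname <- if (!is.null(names(groups))) names(groups)[g]
               else paste0("g", g)
      res <- tryCatch(fit_mgcfa(specs[[mname]], groups[g]),
                      error = function(e) e)
      if (inherits(res, "error")) add_row(gname, mname, NULL,
                                          conditionMessage(res))
      else add_row(gname, mname, res)
    }
    if (joint && length(groups) > 1) {
      res <- tryCatch(fit_mgcfa(specs[[mname]], groups,
                                constraint_profile("configural")),
                      error = function(e) e)
      if (inherits(res, "error")) add_row("joint", mname, NULL,
                                          conditionMessage(res))
      else add_row("joint", mname, res)
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    d <- d[!is.na(d$AIC), ]
    if (!nrow(d)) return(NULL)
    data.frame(group = d$group[1],
               best_aic = d$model[which.min(d$AIC)],
               best_rmsea = d$model[which.min(d$RMSEA)])
  }))
  structure(list(table = tab, best = best, fits = fits),
            class = "mgcfa_comparison")
}

#' @export
print.mgcfa_comparison <- function(x, digits = 3, ...) {
  tab <- x$table
  cat(sprintf("%-8s %-13s %10s %4s %9s %6s %6s %6s\n", "group", "model",
              "chi2", "df", "AIC", "CFI", "NNFI", "RMSEA"))
  for (k in seq_len(nrow(tab))) {
    r <- tab[k, ]
    if (!is.na(r$error)) {
      cat(sprintf("%-8s %-13s  estimation failed: %s\n", r$group, r$model,
                  r$error))
    } else {
      cat(sprintf("%-8s %-13s %10.3f %4d %9.1f %6.3f %6.3f %6.3f\n",
                  r$group, r$model, r$chisq, r$df, r$AIC, r$CFI, r$NNFI,
                  r$RMSEA))
    }
  }
  if (!is.null(x$best) && nrow(x$best)) {
    cat("\nbest by AIC / RMSEA per group:\n")
    print.data.frame(x$best, row.names = FALSE)
  }
  invisible(x)
}

# ---- serialization --------------------------------------------------------

#' Serialize a model spec (and optional profile) to YAML
#'
#' @param spec an `mgcfa_spec`.
#' @param path output file; `NULL` returns the YAML string.
#' @param profile optional `mgcfa_profile` stored alongside.
#' @export
spec_to_yaml <- function(spec, path = NULL, profile = NULL) {
  obj <- list(
    items = spec$battery$item_names,
    reverse_coded = spec$battery$reverse_coded,
    scale = c(spec$battery$scale_min, spec$battery$scale_max),
    factors = lapply(spec$loadings, as.list),
    markers = as.list(spec$markers),
    second_order = spec$second_order,
    second_order_label = spec$second_order_label,
    mean_structure = spec$mean_structure)
  if (!is.null(profile)) {
    obj$constraint <- list(
      level = profile$level,
      exemptions = if (nrow(profile$exemptions))
        unname(apply(profile$exemptions, 1, as.list)) else list(),
      reference_group = profile$reference_group)
  }
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a model spec (and optional profile) from YAML
#'
#' @param path file written by [spec_to_yaml()] (or hand-authored in the
#'   same dialect).
#' @return list with `spec` and (if present) `profile`.
#' @export
spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  battery <- item_battery(obj$items,
                          reverse_coded = unlist(obj$reverse_coded),
                          scale_min = obj$scale[[1]],
                          scale_max = obj$scale[[2]])
  spec <- model_spec(battery,
                     loadings = lapply(obj$factors, unlist),
                     markers = unlist(obj$markers),
                     second_order = isTRUE(obj$second_order),
                     second_order_label = obj$second_order_label %||% "GEN",
                     mean_structure = !isFALSE(obj$mean_structure))
  out <- list(spec = spec)
  if (!is.null(obj$constraint)) {
    ex <- obj$constraint$exemptions
    out$profile <- constraint_profile(
      obj$constraint$level,
      exemptions = if (length(ex))
        data.frame(class = vapply(ex, function(e) e$class, ""),
                   item = vapply(ex, function(e) e$item, "")) else NULL,
      reference_group = obj$constraint$reference_group)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_to_list <- function(fit) {
  per_group <- lapply(fit$group_names, function(g) {
    ps <- fit$params[[g]]
    std <- standardize_params(ps, fit$implied[[g]]$Sigma)
    tab <- data.frame(
      item = rownames(ps$Lambda),
      factor = fit$template$factors[fit$template$fac_of],
      loading = ps$Lambda[cbind(seq_len(nrow(ps$Lambda)),
                                fit$template$fac_of)],
      loading_std = std$Lambda[cbind(seq_len(nrow(ps$Lambda)),
                                     fit$template$fac_of)],
      intercept = if (!is.null(ps$nu)) unname(ps$nu) else NA,
      intercept_std = if (!is.null(std$nu)) unname(std$nu) else NA,
      uniqueness = unname(ps$Theta),
      uniqueness_std = unname(std$Theta))
    list(group = g, n = fit$n[[g]], parameters = tab,
         factor_cov = unname(ps$Phi),
         factor_means = if (!is.null(ps$kappa)) unname(ps$kappa))
  })
  list(T = fit$T, df = fit$df, q = fit$q, F = fit$F,
       profile = list(level = fit$profile$level,
                      exemptions = fit$profile$exemptions),
       convergence = fit$conv, heywood = fit$heywood,
       groups = per_group)
}

#' Write a full invariance analysis report (JSON + markdown)
#'
#' Emits `report.json` (machine-readable: configuration, every step with
#' fit, indices, deltas, decisions and released constraints, latent means,
#' omega tables) and `report.md` (tables shaped like the published
#' comparison/latent-mean layouts) in `dir`. The JSON carries the package
#' version and the seed/configuration supplied, so a rerun with the same
#' inputs is byte-identical.
#'
#' @param report an `mgcfa_invariance` from [run_invariance()].
#' @param dir output directory (created if needed).
#' @param seed the seed used to produce the data, recorded for
#'   reproducibility.
#' @param config optional resolved run configuration (recorded verbatim).
#' @return (invisibly) the paths written.
#' @export
write_invariance_report <- function(report, dir, seed = NULL,
                                    config = NULL) {
  stopifnot(inherits(report, "mgcfa_invariance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  final <- report$steps[[length(report$steps)]]
  lm <- om <- NULL
  if (final$decision != "rejected" &&
      final$fit$profile$free_factor_means && !report$spec$second_order) {
    lm <- latent_mean_comparison(final$fit)
    om <- omega_table(final$fit)
  }
  obj <- list(
    package = "mgcfa",
    version = as.character(utils::packageVersion("mgcfa")),
    seed = seed, config = config,
    reference_group = report$reference_group,
    cutoffs = unclass(report$cutoffs),
    baseline = unclass(report$baseline),
    steps = lapply(report$steps, function(s) list(
      level = s$level, decision = s$decision,
      released = s$released,
      indices = list(T = s$indices$T, df = s$indices$df,
                     CFI = s$indices$CFI, NNFI = s$indices$NNFI,
                     AIC = s$indices$AIC,
                     RMSEA = s$indices$RMSEA),
      delta = s$delta,
      fit = fit_to_list(s$fit))),
    latent_means = lm, omega = om)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)

  md <- c("# Measurement invariance report", "",
          paste0("Reference group: ", report$reference_group), "",
          "| model | chi2 | df | AIC | CFI | NNFI | RMSEA | decision |",
          "|---|---|---|---|---|---|---|---|")
  for (s in report$steps) {
    i <- s$indices
    lab <- if (nrow(s$released)) paste("partial", s$level) else s$level
    md <- c(md, sprintf("| %s | %.3f | %d | %.1f | %.3f | %.3f | %.3f | %s |",
                        lab, i$T, i$df, i$AIC, i$CFI, i$NNFI, i$RMSEA$est,
                        s$decision))
  }
  if (!is.null(lm)) {
    md <- c(md, "", "## Latent mean differences", "",
            "| factor | M ref | SD ref | M | SD | z | d |",
            "|---|---|---|---|---|---|---|",
            sprintf("| %s | 0.000 | %.3f | %.3f | %.3f | %.2f | %.3f |",
                    lm$factor, lm$sd_ref, lm$mean, lm$sd, lm$z, lm$d))
  }
  if (!is.null(om)) {
    md <- c(md, "", "## Omega reliability", "",
            "| group | factor | omega |", "|---|---|---|",
            sprintf("| %s | %s | %.3f |", om$group, om$factor, om$omega))
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}
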