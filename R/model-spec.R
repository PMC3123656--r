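#' Define a confirmatory factor model for an item battery
#'
#' Each item loads on exactly one factor (simple structure). The latent scale
#' is set by marker-variable identification: one item per factor has its
#' loading fixed to 1 (by default the first item listed for that factor).
#' Optionally a single second-order factor is placed over the first-order
#' factors, in which case the first-order covariance matrix is structured as
#' `Phi = Gamma %*% t(Gamma) + diag(D)` with the second-order variance fixed
#' to 1.
#'
#' @param battery an [item_battery()].
#' @param loadings named list: factor label -> character vector of item
#'   labels loading on that factor.
#' @param markers optional named character vector (factor -> marker item);
#'   defaults to the first item of each factor.
#' @param second_order logical; add a single second-order factor over all
#'   first-order factors.
#' @param second_order_label label for the second-order factor.
#' @param mean_structure logical; model item intercepts and factor means
#'   (required for scalar invariance and latent mean comparison).
#' @return An object of class `mgcfa_spec`.
#' @seealso [builtin_spec()] for the CES-D structures, [validate_spec()].
#' @export
model_spec <- function(battery, loadings, markers = NULL,
                       second_order = FALSE, second_order_label = "GEN",
                       mean_structure = TRUE) {
  stopifnot(inherits(battery, "mgcfa_battery"))
  factors <- names(loadings)
  if (is.null(factors) || any(factors == ""))
    stop("'loadings' must be a fully named list (factor -> items)",
         call. = FALSE)
  all_items <- unlist(loadings, use.names = FALSE)
  if (anyDuplicated(all_items))
    stop("items assigned to more than one factor: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(all_items, battery$item_names)
  if (length(unknown))
    stop("items not in battery: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(markers))
    markers <- vapply(loadings, `[`, character(1), 1L)
  if (is.null(names(markers))) names(markers) <- factors
  for (f in factors)
    if (!markers[[f]] %in% loadings[[f]])
      stop("marker item '", markers[[f]], "' does not load on factor '",
           f, "'", call. = FALSE)
  structure(
    list(battery = battery,
         factors = factors,
         loadings = lapply(loadings, as.character),
         markers = markers[factors],
         second_order = isTRUE(second_order),
         second_order_label = second_order_label,
         mean_structure = isTRUE(mean_structure)),
    class = "mgcfa_spec")
}

#' Built-in CES-D factor structures
#'
#' The four structures commonly tested for the 20-item CES-D:
#' \describe{
#'   \item{`one_factor`}{all 20 items on a single depression factor.}
#'   \item{`three_factor`}{somatic complaints and depressive affect combined
#'     into one 14-item factor, plus positive affect (4) and interpersonal
#'     problems (2).}
#'   \item{`four_factor`}{Radloff's structure: somatic complaints (7),
#'     depressive affect (7), positive affect (4), interpersonal problems
#'     (2).}
#'   \item{`second_order`}{the four-factor structure with the four factors
#'     depending on a single second-order depression factor.}
#' }
#' Markers are the first item per factor (Bothered, Blues, Good, Unfriendly
#' in the four-factor model).
#'
#' @param name one of `"one_factor"`, `"three_factor"`, `"four_factor"`,
#'   `"second_order"`.
#' @return An `mgcfa_spec`.
#' @examples
#' spec <- builtin_spec("four_factor")
#' lengths(spec$loadings)
#' @export
builtin_spec <- function(name = c("four_factor", "three_factor",
                                  "one_factor", "second_order")) {
  name <- match.arg(name)
  b <- cesd_battery()
  som <- c("Bothered", "Appetite", "Mind", "Effort", "Sleep", "Talk",
           "GetGoing")
  dep <- c("Blues", "Depressed", "Failure", "Fearful", "Lonely", "Crying",
           "Sad")
  pos <- c("Good", "Hopeful", "Happy", "Enjoyed")
  int <- c("Unfriendly", "Dislike")
  switch(name,
    one_factor = model_spec(b, list(DEPR = b$item_names)),
    three_factor = model_spec(b, list(AFFSOM = c(som, dep), POS = pos,
                                      INT = int)),
    four_factor = model_spec(b, list(SOM = som, DEP = dep, POS = pos,
                                     INT = int)),
    second_order = model_spec(b, list(SOM = som, DEP = dep, POS = pos,
                                      INT = int),
                              second_order = TRUE,
                              second_order_label = "DEPR"))
}

#' Validate a model specification
#'
#' Returns diagnostics rather than raising: unassigned battery items,
#' single-item factors, and an under-identified second-order layer (< 3
#' first-order factors).
#'
#' @param spec an `mgcfa_spec`.
#' @return character vector of diagnostics; empty for a well-formed spec.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "mgcfa_spec"))
  out <- character()
  assigned <- unlist(spec$loadings, use.names = FALSE)
  unassigned <- setdiff(spec$battery$item_names, assigned)
  if (length(unassigned))
    out <- c(out, paste0("items not assigned to any factor: ",
                         paste(unassigned, collapse = ", ")))
  single <- names(spec$loadings)[lengths(spec$loadings) < 2]
  if (length(single))
    out <- c(out, paste0("factors with fewer than 2 items: ",
                         paste(single, collapse = ", ")))
  if (spec$second_order && length(spec$factors) < 3)
    out <- c(out, paste0("second-order factor over ", length(spec$factors),
                         " first-order factors is under-identified ",
                         "(needs >= 3)"))
  out
}

#' @export
print.mgcfa_spec <- function(x, ...) {
  cat("CFA model spec:", length(x$factors), "factor(s) over",
      length(unlist(x$loadings)), "items",
      if (x$second_order) "+ second-order factor" else "", "\n")
  for (f in x$factors)
    cat(sprintf("  %-8s (%d items, marker %s): %s\n", f,
                length(x$loadings[[f]]), x$markers[[f]],
                paste(x$loadings[[f]], collapse = ", ")))
  invisible(x)
}

#' Cross-group constraint profile
#'
#' Describes one rung of the measurement-invariance ladder: which parameter
#' classes are constrained equal across groups, which individual (class,
#' item) pairs are released from that equality (partial invariance), and how
#' factor means are identified.
#'
#' Levels constrain cumulatively: `metric` equates non-marker loadings,
#' `scalar` additionally equates all intercepts, `uniqueness` additionally
#' equates residual variances. At `scalar` and above the reference group's
#' factor means are fixed to 0 and the other groups' are free; below that
#' all factor means are fixed to 0 (no mean information is modelled beyond
#' the intercepts).
#'
#' Marker-item loadings are never equated by constraint (they are fixed to 1
#' in every group) and marker loadings/intercepts can never be exempted: an
#' anchor is required for the cross-group comparison to be identified.
#'
#' @param level one of `"configural"`, `"metric"`, `"scalar"`,
#'   `"uniqueness"`.
#' @param exemptions a data.frame with columns `class`
#'   (`"loading"`/`"intercept"`/`"uniqueness"`) and `item`, or a list of
#'   `c(class, item)` pairs; parameters released from cross-group equality.
#' @param reference_group group label whose factor means are fixed to 0;
#'   defaults to the first group encountered at fit time.
#' @param free_factor_means logical; free factor means in non-reference
#'   groups. Defaults to `TRUE` at levels `scalar`/`uniqueness`, `FALSE`
#'   below.
#' @return An object of class `mgcfa_profile`.
#' @export
constraint_profile <- function(level = c("configural", "metric", "scalar",
                                         "uniqueness"),
                               exemptions = NULL, reference_group = NULL,
                               free_factor_means = NULL) {
  level <- match.arg(level)
  lvl <- match(level, c("configural", "metric", "scalar", "uniqueness")) - 1L
  if (is.null(free_factor_means)) free_factor_means <- lvl >= 2L
  if (lvl >= 2L && !free_factor_means)
    stop("factor means must be free in non-reference groups at level '",
         level, "'", call. = FALSE)
  ex <- normalize_exemptions(exemptions)
  class_level <- c(loading = 1L, intercept = 2L, uniqueness = 3L)
  bad <- ex$class[class_level[ex$class] > lvl]
  if (length(bad))
    stop("exemptions reference classes not constrained at level '", level,
         "': ", paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(
    list(level = level, lvl = lvl, exemptions = ex,
         reference_group = reference_group,
         free_factor_means = isTRUE(free_factor_means)),
    class = "mgcfa_profile")
}

normalize_exemptions <- function(exemptions) {
  if (is.null(exemptions))
    return(data.frame(class = character(), item = character()))
  if (is.data.frame(exemptions)) {
    ex <- data.frame(class = as.character(exemptions$class),
                     item = as.character(exemptions$item))
  } else {
    ex <- do.call(rbind, lapply(exemptions, function(e)
      data.frame(class = e[[1]], item = e[[2]])))
  }
  ok <- c("loading", "intercept", "uniqueness")
  if (!all(ex$class %in% ok))
    stop("exemption classes must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  unique(ex)
}

is_exempt <- function(profile, class, item) {
  any(profile$exemptions$class == class & profile$exemptions$item == item)
}

#' @export
print.mgcfa_profile <- function(x, ...) {
  cat("Constraint profile:", x$level, "\n")
  if (nrow(x$exemptions)) {
    cat("  released:",
        paste(x$exemptions$class, x$exemptions$item, sep = ":",
              collapse = ", "), "\n")
  }
  if (!is.null(x$reference_group))
    cat("  reference group:", x$reference_group, "\n")
  invisible(x)
}

#' Count free parameters of a (multi-group) model
#'
#' Counts distinct free parameters across `n_groups` groups under a
#' constraint profile: per group the non-marker loadings, all intercepts (if
#' the mean structure is on), all uniquenesses, the factor covariance
#' parameters (or second-order loadings and disturbances), plus free factor
#' means per the profile. Cross-group equality collapses a parameter to a
#' single count; each exemption restores the per-group copies.
#'
#' @param spec an `mgcfa_spec`.
#' @param n_groups number of groups.
#' @param profile an `mgcfa_profile`; defaults to configural.
#' @param identification `"marker"` (marker loading fixed to 1) or
#'   `"variance"` (factor variances fixed to 1, all loadings free; only
#'   available without cross-group equality constraints). Both yield the
#'   same count for a given model — degrees of freedom do not depend on the
#'   scaling choice.
#' @return integer count of free parameters.
#' @export
free_parameter_count <- function(spec, n_groups = 1L,
                                 profile = constraint_profile("configural"),
                                 identification = "marker") {
  # counting uses placeholder group names; which group is the reference
  # does not affect the count
  profile$reference_group <- NULL
  tpl <- build_template(spec, paste0("g", seq_len(n_groups)), profile,
                        identification = identification)
  tpl$q
}

#' Degrees of freedom of a (multi-group) model
#'
#' `n_groups * (p(p+1)/2 + p)` sample moments with a mean structure (or
#' `p(p+1)/2` per group without) minus [free_parameter_count()]. A negative
#' value signals an under-identified model and triggers a warning.
#'
#' @inheritParams free_parameter_count
#' @return integer degrees of freedom.
#' @examples
#' degrees_of_freedom(builtin_spec("four_factor"))            # 164
#' degrees_of_freedom(builtin_spec("four_factor"), 2)         # 328 (configural)
#' @export
degrees_of_freedom <- function(spec, n_groups = 1L,
                               profile = constraint_profile("configural"),
                               identification = "marker") {
  p <- length(unlist(spec$loadings))
  moments <- n_groups * (p * (p + 1) / 2 + if (spec$mean_structure) p else 0)
  df <- as.integer(moments - free_parameter_count(spec, n_groups, profile,
                                                  identification))
  if (df < 0) warning("negative df: model is under-identified")
  df
}
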