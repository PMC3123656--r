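#' Respondent-level item data table
#'
#' A light wrapper around a data.frame with one `group` column and one
#' integer column per battery item (battery order). Non-missing responses
#' must lie within the battery's scale bounds.
#'
#' @param data data.frame with a `group` column plus one column per item.
#' @param battery an [item_battery()] giving item order and scale bounds.
#' @return An object of class `mgcfa_items` (a data.frame).
#' @export
item_data <- function(data, battery) {
  stopifnot(inherits(battery, "mgcfa_battery"))
  if (!"group" %in% names(data))
    stop("data must contain a 'group' column", call. = FALSE)
  missing_cols <- setdiff(battery$item_names, names(data))
  if (length(missing_cols))
    stop("missing item columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data[, c("group", battery$item_names)]
  out$group <- as.character(out$group)
  for (it in battery$item_names) {
    v <- out[[it]]
    if (!is.numeric(v))
      stop("item column '", it, "' is not numeric", call. = FALSE)
    bad <- which(!is.na(v) & (v < battery$scale_min | v > battery$scale_max |
                              v != round(v)))
    if (length(bad))
      stop("out-of-range or non-integer response in item '", it,
           "', row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
  }
  structure(out, battery = battery, class = c("mgcfa_items", "data.frame"))
}

#' Reverse-code items
#'
#' Maps each listed item's responses through `x -> scale_min + scale_max - x`
#' (an involution); missing values stay missing, other items are untouched.
#' With no `items` argument the battery's declared reverse-coded set is used
#' (for the CES-D: the four positive-affect items).
#'
#' @param table an `mgcfa_items` table.
#' @param items item labels to reverse; default: the battery's
#'   `reverse_coded` set.
#' @return The table with the listed items reversed.
#' @export
reverse_code <- function(table, items = NULL) {
  battery <- attr(table, "battery")
  stopifnot(inherits(table, "mgcfa_items"))
  if (is.null(items)) items <- battery$reverse_coded
  unknown <- setdiff(items, battery$item_names)
  if (length(unknown))
    stop("unknown item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (it in items)
    table[[it]] <- battery$scale_min + battery$scale_max - table[[it]]
  table
}

#' Per-group summary statistics (pairwise-available-case)
#'
#' Means use all available values per item; each covariance entry uses all
#' rows where both items are observed, with denominator `n_pair - 1`
#' (equivalent to complete-case covariance when nothing is missing). The
#' sample size attached to the summary — the `n` entering the fit function —
#' is the group's row count; with the small missingness rates this package
#' targets (< 1%) per-pair differences are negligible.
#'
#' @param table an `mgcfa_items` table.
#' @param group group label to summarize; if `NULL`, a list of summaries for
#'   all groups (in order of first appearance) is returned.
#' @return An `mgcfa_summary` (or named list of them): fields `S` (p x p
#'   covariance), `xbar` (means), `n`, `item_names`, `group`.
#' @export
summarize_groups <- function(table, group = NULL) {
  stopifnot(inherits(table, "mgcfa_items"))
  if (is.null(group)) {
    gs <- unique(table$group)
    out <- lapply(gs, function(g) summarize_groups(table, g))
    names(out) <- gs
    return(out)
  }
  rows <- table$group == group
  if (!any(rows)) stop("empty group: ", group, call. = FALSE)
  battery <- attr(table, "battery")
  x <- as.matrix(as.data.frame(table)[rows, battery$item_names])
  storage.mode(x) <- "double"
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2))
    stop("item(s) with fewer than 2 observed values in group '", group,
         "': ", paste(battery$item_names[n_obs < 2], collapse = ", "),
         call. = FALSE)
  group_summary(S = stats::cov(x, use = "pairwise.complete.obs"),
                xbar = colMeans(x, na.rm = TRUE),
                n = sum(rows), item_names = battery$item_names,
                group = group)
}

#' Construct a group summary directly
#'
#' For workflows starting from published or precomputed summary statistics
#' rather than respondent-level data.
#'
#' @param S symmetric p x p sample covariance matrix.
#' @param xbar length-p mean vector (may be `NULL` for covariance-only
#'   models).
#' @param n sample size used in the fit function.
#' @param item_names item labels (length p).
#' @param group optional group label.
#' @return An object of class `mgcfa_summary`.
#' @export
group_summary <- function(S, xbar = NULL, n, item_names = NULL,
                          group = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (ncol(S) != p || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be a symmetric square matrix", call. = FALSE)
  S <- (S + t(S)) / 2
  if (any(diag(S) < 0)) stop("S has negative diagonal", call. = FALSE)
  if (!is.null(xbar) && length(xbar) != p)
    stop("xbar length does not match S", call. = FALSE)
  if (is.null(item_names)) item_names <- rownames(S)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(p))
  if (n < p + 1)
    warning("n <= p: sample covariance is singular or near-singular")
  dimnames(S) <- list(item_names, item_names)
  if (!is.null(xbar)) names(xbar) <- item_names
  structure(list(S = S, xbar = xbar, n = as.integer(n),
                 item_names = item_names, group = group),
            class = "mgcfa_summary")
}

#' @export
print.mgcfa_summary <- function(x, ...) {
  cat("Group summary", if (!is.null(x$group)) paste0("'", x$group, "'"),
      ": n =", x$n, ",", length(x$item_names), "items\n")
  invisible(x)
}

#' Read respondent-level item data from CSV
#'
#' Expects columns `group,<item1>,...,<itemp>` named per the battery;
#' missing responses as empty cells or `NA`. Out-of-range entries are
#' rejected with row and item context.
#'
#' @param path CSV file path.
#' @param battery an [item_battery()].
#' @return An `mgcfa_items` table.
#' @export
load_item_csv <- function(path, battery = cesd_battery()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  item_data(df, battery)
}

#' Write an item table to CSV
#' @param table an `mgcfa_items` table.
#' @param path output path.
#' @export
write_item_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a group summary (or list of them) to JSON
#'
#' Covariance stored row-major with means, n and item order, so summaries
#' can round-trip without respondent-level data.
#'
#' @param summary an `mgcfa_summary` or named list of them.
#' @param path output path.
#' @export
write_summary <- function(summary, path) {
  as_rec <- function(s)
    list(group = s$group, n = s$n, item_names = s$item_names,
         xbar = unname(s$xbar), S = unname(s$S))
  obj <- if (inherits(summary, "mgcfa_summary")) as_rec(summary)
         else lapply(summary, as_rec)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read group summaries from JSON written by [write_summary()]
#' @param path JSON file path.
#' @return An `mgcfa_summary` or named list of them.
#' @export
read_summary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_rec <- function(r)
    group_summary(S = r$S, xbar = r$xbar, n = r$n,
                  item_names = r$item_names, group = r$group)
  if (!is.null(obj$S)) from_rec(obj) else lapply(obj, from_rec)
}
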