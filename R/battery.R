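#' Item battery definition
#'
#' An item battery records the ordered item labels of a questionnaire, which
#' items are reverse-coded before analysis, and the integer response scale.
#'
#' @param item_names character vector of unique item labels, in instrument
#'   order.
#' @param reverse_coded character vector (subset of `item_names`) of items to
#'   reverse before analysis.
#' @param scale_min,scale_max integer bounds of the response scale
#'   (`scale_min < scale_max`).
#' @return An object of class `mgcfa_battery`.
#' @examples
#' b <- cesd_battery()
#' b$item_names
#' @export
item_battery <- function(item_names, reverse_coded = character(),
                         scale_min = 1L, scale_max = 4L) {
  item_names <- as.character(item_names)
  if (anyDuplicated(item_names))
    stop("item names must be unique", call. = FALSE)
  if (!all(reverse_coded %in% item_names))
    stop("reverse_coded items not in battery: ",
         paste(setdiff(reverse_coded, item_names), collapse = ", "),
         call. = FALSE)
  scale_min <- as.integer(scale_min); scale_max <- as.integer(scale_max)
  if (!(scale_min < scale_max))
    stop("scale_min must be < scale_max", call. = FALSE)
  structure(
    list(item_names = item_names,
         reverse_coded = as.character(reverse_coded),
         scale_min = scale_min, scale_max = scale_max),
    class = "mgcfa_battery")
}

#' The 20-item CES-D battery
#'
#' The Center for Epidemiological Studies Depression Scale: 20 items scored on
#' a 4-point frequency scale (1 = symptom on no days during the past week,
#' 4 = five days or more). The four positive-affect items (Good, Hopeful,
#' Happy, Enjoyed) are reverse-coded before analysis so that higher scores
#' mean more depressive symptoms on every item.
#'
#' @return An `mgcfa_battery` with the 20 CES-D item labels.
#' @export
cesd_battery <- function() {
  item_battery(
    item_names = c("Bothered", "Appetite", "Mind", "Effort", "Sleep",
                   "Talk", "GetGoing", "Blues", "Depressed", "Failure",
                   "Fearful", "Lonely", "Crying", "Sad", "Good",
                   "Hopeful", "Happy", "Enjoyed", "Unfriendly", "Dislike"),
    reverse_coded = c("Good", "Hopeful", "Happy", "Enjoyed"),
    scale_min = 1L, scale_max = 4L)
}

#' @export
print.mgcfa_battery <- function(x, ...) {
  cat("Item battery:", length(x$item_names), "items, scale",
      x$scale_min, "..", x$scale_max, "\n")
  cat("  items:", paste(x$item_names, collapse = ", "), "\n")
  if (length(x$reverse_coded))
    cat("  reverse-coded:", paste(x$reverse_coded, collapse = ", "), "\n")
  invisible(x)
}
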