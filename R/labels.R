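# UPDRS-III labels: 27 motor signs scored 0-4, total 0-108.

# Fixed allocation scheme over sign categories.  The motor exam scores tremor,
# bradykinesia and axial signs on several body sides/parts; the remaining signs
# (speech, facial expression, rigidity, ...) are grouped as "other" because a
# wrist/ankle gyroscope cannot observe them directly.
.updrs_item_category <- c(
  rep("tremor", 7),         # rest + postural/kinetic tremor, several body parts
  rep("bradykinesia", 12),  # finger taps, hand movements, leg agility, gait, ...
  rep("axial", 4),          # arising from chair, posture, postural stability
  rep("other", 4)           # speech, facial expression, rigidity summaries
)

# Relative share of total severity attributed to each category.
.updrs_category_weight <- c(
  tremor = 0.30, bradykinesia = 0.45, axial = 0.15, other = 0.10
)

#' Construct a UPDRS-III label
#'
#' Bundles the 27 motor-sign item scores (each 0--4) with their total
#' (0--108) and a flag for the most-affected body side.
#'
#' @param items Integer vector of 27 item scores, each in 0..4.
#' @param side_dominant `"left"` or `"right"`; the most-affected side, i.e.
#'   the side the sensors are mounted on.
#' @return An object of class `updrs_label`: a list with `items`, `total`
#'   and `side_dominant`.
#' @export
#' @examples
#' lab <- updrs_label(rep(1L, 27))
#' lab$total
updrs_label <- function(items, side_dominant = "right") {
  items <- as.integer(items)
  if (length(items) != 27L) {
    stop("a UPDRS-III label has exactly 27 item scores, got ", length(items))
  }
  if (anyNA(items) || any(items < 0L | items > 4L)) {
    stop("every UPDRS-III item score must be an integer in 0..4")
  }
  structure(
    list(items = items, total = sum(items), side_dominant = side_dominant),
    class = "updrs_label"
  )
}

#' @export
print.updrs_label <- function(x, ...) {
  cat("<updrs_label> total =", x$total, "of 108;",
      "tremor subtotal =", updrs_subtotal(x, "tremor"), ";",
      "bradykinesia subtotal =", updrs_subtotal(x, "bradykinesia"), "\n")
  invisible(x)
}

#' Category subtotal of a UPDRS-III label
#'
#' @param label An [updrs_label()].
#' @param category One of `"tremor"`, `"bradykinesia"`, `"axial"`, `"other"`.
#' @return Integer subtotal of the item scores in that category.
#' @export
updrs_subtotal <- function(label, category = c("tremor", "bradykinesia",
                                               "axial", "other")) {
  category <- match.arg(category)
  sum(label$items[.updrs_item_category == category])
}

#' Sample a UPDRS-III label with a given total severity
#'
#' Allocates `round(severity_target)` points over the 27 items by repeatedly
#' drawing an item with probability proportional to a fixed category weight
#' (tremor 0.30, bradykinesia 0.45, axial 0.15, other 0.10, split uniformly
#' within each category) and incrementing it, skipping items already at 4.
#' The allocation always sums to the rounded target (108 points saturate all
#' items at 4) and is deterministic for a fixed RNG state.
#'
#' @param severity_target Real total severity in \[0, 108\].
#' @param side_dominant Most-affected side flag, stored on the label.
#' @return An [updrs_label()] with `total == round(severity_target)`.
#' @export
#' @examples
#' set.seed(1)
#' sample_updrs_label(30)$total
sample_updrs_label <- function(severity_target, side_dominant = "right") {
  if (!is.numeric(severity_target) || length(severity_target) != 1L ||
      is.na(severity_target) || severity_target < 0 || severity_target > 108) {
    stop("severity_target must be a single number in [0, 108]")
  }
  points <- as.integer(round(severity_target))
  items <- integer(27)
  w <- .updrs_category_weight[.updrs_item_category]
  w <- w / ave(rep(1, 27), .updrs_item_category, FUN = sum)  # split within category
  while (points > 0L) {
    open <- items < 4L
    if (!any(open)) break  # points == 108 exactly fills all items
    k <- sample.int(27L, 1L, prob = w * open)
    items[k] <- items[k] + 1L
    points <- points - 1L
  }
  updrs_label(items, side_dominant = side_dominant)
}
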