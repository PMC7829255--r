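#' Map a 7-point difficulty rating onto the unit interval
#'
#' The individual labelling scheme places the seven ratings equidistantly on
#' \[0, 1\]: `label = (rating - 1) / 6`, so a rating of 1 maps to 0, a rating
#' of 2 to 0.1667, and a rating of 7 to 1. One workload level therefore spans
#' 1/6 of label space.
#'
#' @param rating Integer rating(s) in 1..7.
#' @return Label(s) in \[0, 1\].
#' @export
individual_label <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1 | rating > 7) ||
      any(rating != round(rating))) {
    stop_invalid("ratings must be integers in 1..7")
  }
  (rating - 1) / 6
}

#' Recover the rating from an individual label
#' @param label Label(s) produced by [individual_label()].
#' @return Integer rating(s).
#' @export
individual_rating <- function(label) as.integer(round(label * 6 + 1))

#' Width of one workload level in label space
#' @return 1/6.
#' @export
level_width <- function() 1 / 6

#' Map per-puzzle mean ratings onto group labels
#'
#' Min--max normalization of the per-puzzle average ratings: the puzzle with
#' the lowest mean rating gets label 0, the highest gets 1, the rest fall
#' proportionally in between. Group labels are therefore generally not
#' equidistant. Full precision is kept internally; round only for display.
#'
#' @param mean_ratings Numeric vector of per-puzzle mean ratings (length
#'   `>= 2`, not all equal); names, if present, are preserved.
#' @return Numeric labels in \[0, 1\], same names as the input.
#' @export
group_labels <- function(mean_ratings) {
  if (length(mean_ratings) < 2L) {
    stop_invalid("group labelling needs at least 2 puzzles")
  }
  rng <- range(mean_ratings)
  if (rng[1] == rng[2]) {
    stop_degenerate("all mean ratings are equal; group labels are undefined")
  }
  (mean_ratings - rng[1]) / (rng[2] - rng[1])
}

#' Convert a mean absolute label error to levels of workload (LoW)
#'
#' One level of the 7-point workload scale spans 1/6 of the \[0, 1\] label
#' space, so an error of `e` in label space corresponds to `6 e` levels.
#'
#' @param mean_abs_label_error Non-negative error in label space.
#' @return Error in levels of workload.
#' @export
low_from_error <- function(mean_abs_label_error) {
  if (any(!is.finite(mean_abs_label_error)) || any(mean_abs_label_error < 0)) {
    stop_invalid("error must be >= 0")
  }
  mean_abs_label_error * 6
}

#' Cronbach's alpha of a rating matrix
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`,
#' with sample variances (n-1 denominator). With puzzles as items the matrix
#' is used as participants x puzzles; with participants as items it is
#' transposed first. Rows containing missing values are dropped (listwise
#' deletion).
#'
#' @param mat Numeric matrix, observations x items before orientation.
#' @param orientation `"puzzles-as-items"` (default; columns are items) or
#'   `"participants-as-items"` (rows become items).
#' @return Alpha (a real number, at most 1).
#' @export
cronbach_alpha <- function(mat, orientation = c("puzzles-as-items",
                                                "participants-as-items")) {
  orientation <- match.arg(orientation)
  mat <- as.matrix(mat)
  if (orientation == "participants-as-items") mat <- t(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2L || nrow(mat) < 2L) {
    stop_invalid("alpha needs >= 2 items and >= 2 observations")
  }
  total_var <- stats::var(rowSums(mat))
  if (total_var == 0) stop_degenerate("zero total variance; alpha undefined")
  item_vars <- apply(mat, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
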