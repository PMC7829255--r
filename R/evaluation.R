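#' Mean absolute label error
#'
#' @param predictions,labels Equal-length numeric vectors in label space.
#' @return Mean of `|prediction - label|`.
#' @export
mean_abs_error <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    stop_invalid("predictions and labels must be non-empty and equal length")
  }
  mean(abs(predictions - labels))
}

#' Fraction of samples predicted within a workload-level tolerance
#'
#' A sample counts as within tolerance when its absolute label error does
#' not exceed `tolerance_levels` workload levels, one level spanning 1/6 of
#' label space.
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @param tolerance_levels Non-negative tolerance in levels of workload.
#' @return Fraction in \[0, 1\].
#' @export
within_fraction <- function(predictions, labels, tolerance_levels = 1) {
  if (tolerance_levels < 0) stop_invalid("tolerance must be >= 0")
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    stop_invalid("predictions and labels must be non-empty and equal length")
  }
  tol <- tolerance_levels * level_width()
  mean(abs(predictions - labels) <= tol + 1e-12)
}

#' Bin a prediction to the nearest label value
#'
#' @param prediction Numeric prediction(s) in \[0, 1\].
#' @param label_values Sorted vector of class label values.
#' @return Integer index (1-based) of the closest label; exact midpoint ties
#'   go to the lower index.
#' @export
bin_to_nearest_label <- function(prediction, label_values) {
  if (length(label_values) == 0L) stop_invalid("label_values must be non-empty")
  vapply(prediction, function(p) {
    d <- abs(label_values - p)
    which.min(d)   # which.min takes the first (lower) index on ties
  }, integer(1))
}

#' Nearest-label confusion matrix
#'
#' Rows are true classes, columns the classes obtained by placing each
#' prediction into its nearest label value. Each cell carries a count; row
#' proportions normalize by the row total. Accuracy is the trace over n;
#' off-by-one accuracy also accepts predictions one class away.
#'
#' @param predictions Numeric predictions.
#' @param labels True labels; every value must equal one of `label_values`.
#' @param label_values Sorted vector of class label values.
#' @return List with `counts`, `proportions` (row-relative), `accuracy`,
#'   `off_by_one_accuracy`, `n`.
#' @export
confusion_matrix <- function(predictions, labels, label_values) {
  k <- length(label_values)
  true_idx <- vapply(labels, function(l) {
    i <- which(abs(label_values - l) < 1e-9)
    if (length(i) != 1L) stop_invalid("label ", l, " is not one of label_values")
    i
  }, integer(1))
  pred_idx <- bin_to_nearest_label(predictions, label_values)
  counts <- matrix(0L, k, k, dimnames = list(
    true = format(label_values, digits = 3),
    predicted = format(label_values, digits = 3)))
  for (i in seq_along(true_idx)) {
    counts[true_idx[i], pred_idx[i]] <- counts[true_idx[i], pred_idx[i]] + 1L
  }
  row_tot <- rowSums(counts)
  proportions <- counts / ifelse(row_tot == 0, 1, row_tot)
  n <- length(labels)
  list(counts = counts, proportions = proportions,
       accuracy = sum(diag(counts)) / n,
       off_by_one_accuracy = sum(counts[abs(row(counts) - col(counts)) <= 1]) / n,
       n = n)
}

#' Chance-level accuracy of a uniform random classifier
#'
#' With `neighbourhood = 0` this is the plain chance level `100 / n_classes`
#' per cent. With a neighbourhood of c classes accepted on either side, the
#' `uniform-approximation` mode returns `(2c + 1) / n_classes` (capped at 1)
#' -- the conventional approximation that ignores edge classes -- while
#' `exact-edge-aware` enumerates all true/predicted pairs of a uniform
#' predictor under uniform true labels, so edge classes with fewer
#' neighbours are handled exactly.
#'
#' @param n_classes Number of classes (`>= 1`).
#' @param neighbourhood Classes accepted on either side of the truth.
#' @param mode `"uniform-approximation"` (default) or `"exact-edge-aware"`.
#' @return Accuracy in per cent.
#' @export
chance_accuracy <- function(n_classes, neighbourhood = 0,
                            mode = c("uniform-approximation",
                                     "exact-edge-aware")) {
  mode <- match.arg(mode)
  if (n_classes < 1 || neighbourhood < 0) {
    stop_invalid("n_classes >= 1 and neighbourhood >= 0 required")
  }
  if (mode == "uniform-approximation") {
    100 * min(1, (2 * neighbourhood + 1) / n_classes)
  } else {
    hits <- sum(abs(outer(seq_len(n_classes), seq_len(n_classes), `-`)) <=
                  neighbourhood)
    100 * hits / n_classes^2
  }
}

#' Signed-error histogram of predictions around their true labels
#'
#' Labels and predictions are offset so every true label sits at zero; the
#' distribution of the signed errors `prediction - label` is histogrammed,
#' with reference bounds at plus/minus one workload level (1/6).
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @param bin_width Histogram bin width (default 1/24, four bins per level).
#' @return List with `breaks`, `counts`, `mids`, `mu` (mean signed error),
#'   `sigma` (SD), and `level_bounds = c(-1/6, 1/6)`.
#' @export
error_histogram <- function(predictions, labels, bin_width = 1 / 24) {
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    stop_invalid("predictions and labels must be non-empty and equal length")
  }
  err <- predictions - labels
  lo <- floor(min(err, -bin_width) / bin_width) * bin_width
  hi <- ceiling(max(err, bin_width) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(err, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       mu = mean(err),
       sigma = if (length(err) > 1L) stats::sd(err) else 0,
       level_bounds = c(-level_width(), level_width()))
}

#' Full evaluation report for one set of predictions
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @param label_values Class label values for binning (defaults to the seven
#'   individual labels `(0:6)/6`).
#' @return List: `mean_abs_error`, `low` (levels of workload),
#'   `within_1_level`, `within_1p5_levels`, `histogram`, `confusion`,
#'   `chance_accuracy`, `off_by_one_chance`.
#' @export
eval_report <- function(predictions, labels, label_values = (0:6) / 6) {
  mae <- mean_abs_error(predictions, labels)
  conf <- confusion_matrix(predictions, labels, label_values)
  list(mean_abs_error = mae,
       low = low_from_error(mae),
       within_1_level = within_fraction(predictions, labels, 1),
       within_1p5_levels = within_fraction(predictions, labels, 1.5),
       histogram = error_histogram(predictions, labels),
       confusion = conf,
       chance_accuracy = chance_accuracy(length(label_values)),
       off_by_one_chance = chance_accuracy(length(label_values), 1))
}

#' Unimodal ablation study
#'
#' Trains and cross-validates every (variant, modality subset) configuration
#' with the supplied per-variant hyperparameters; the all-modality
#' configuration is always included as the reference row. Hyperparameter
#' search is not repeated per subset -- each subset reuses the
#' hyperparameters that proved most effective for its variant.
#'
#' @param sample_set A `sample_set`.
#' @param variants Character vector of model variants.
#' @param modality_subsets List of non-empty modality subsets; the full set
#'   is appended when absent.
#' @param train_config A [train_config()] used as the base configuration.
#' @param hp_per_variant Optional named list: variant -> list with any of
#'   `lr_max`, `momentum`, `dropout_rate`.
#' @param input_shapes,width_scale Passed to [model_spec()].
#' @return Data frame with one row per configuration: `variant`,
#'   `modalities`, `mean_abs_error`, `low`.
#' @export
run_ablation <- function(sample_set, variants = "S_MLP",
                         modality_subsets = as.list(MODALITIES),
                         train_config = train_config(),
                         hp_per_variant = NULL,
                         input_shapes = default_input_shapes(),
                         width_scale = 1) {
  if (any(vapply(modality_subsets, length, integer(1)) == 0L)) {
    stop_invalid("modality subsets must be non-empty")
  }
  has_all <- any(vapply(modality_subsets,
                        function(s) setequal(s, MODALITIES), logical(1)))
  if (!has_all) modality_subsets <- c(modality_subsets, list(MODALITIES))
  rows <- list()
  for (v in variants) {
    cfg <- train_config
    hp <- hp_per_variant[[v]]
    if (!is.null(hp$lr_max)) cfg$lr_max <- hp$lr_max
    if (!is.null(hp$momentum)) cfg$momentum <- hp$momentum
    dropout <- hp$dropout_rate %||% 0.1
    for (subset in modality_subsets) {
      spec <- model_spec(v, modalities = subset, dropout_rate = dropout,
                         input_shapes = input_shapes,
                         width_scale = width_scale)
      cv <- cross_validate(spec, sample_set, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, modalities = paste(spec$modalities, collapse = "+"),
        mean_abs_error = cv$mean_error, low = low_from_error(cv$mean_error),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
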