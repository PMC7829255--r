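#' Training configuration
#'
#' @param lr_max Peak learning rate of the one-cycle schedule (`> 0`).
#' @param momentum SGD momentum in \[0, 1).
#' @param batch_size Mini-batch size.
#' @param epochs Epochs per training run (25 per fold in the reference
#'   protocol).
#' @param folds Number of cross-validation folds (default 5).
#' @param holdout_fraction Test share of the random holdout split
#'   (default 0.10, i.e. a 90--10 split).
#' @param seed Integer seed governing shuffling, splits and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_max = 0.01, momentum = 0.9, batch_size = 32L,
                         epochs = 25L, folds = 5L, holdout_fraction = 0.10,
                         seed = 1L) {
  assert_scalar_number(lr_max, "lr_max", lower = 1e-12)
  assert_scalar_number(momentum, "momentum", lower = 0, upper = 1 - 1e-9)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_invalid("holdout_fraction must be in (0, 1)")
  }
  if (epochs < 1 || folds < 1) stop_invalid("epochs and folds must be >= 1")
  structure(list(lr_max = lr_max, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Triangular one-cycle learning-rate schedule
#'
#' A single pyramidal cycle over all training steps: the rate rises linearly
#' from `lr_max / 10` to `lr_max` at the midpoint, then falls linearly back
#' to `lr_max / 10` at the final step.
#'
#' @param step Current step(s), `0 <= step <= total_steps`.
#' @param total_steps Total number of optimization steps (`> 0`).
#' @param lr_max Peak learning rate.
#' @return Learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, lr_max) {
  if (length(total_steps) != 1L || !is.finite(total_steps) || total_steps <= 0) {
    stop_invalid("total_steps must be a positive number")
  }
  if (any(step < 0 | step > total_steps)) {
    stop_invalid("step must lie in [0, total_steps]")
  }
  base <- lr_max / 10
  half <- total_steps / 2
  frac <- ifelse(step <= half, step / half, (total_steps - step) / half)
  base + (lr_max - base) * frac
}

#' Train an intermediate-fusion model
#'
#' Stochastic gradient descent with momentum on the mean squared error
#' between the sigmoid output and the label in \[0, 1\], under the
#' [one_cycle_lr()] schedule spanning all `epochs * batches` steps. Inputs
#' are standardized per modality channel using statistics of the training
#' samples (stored on the returned handle and re-applied at prediction
#' time). Data are reshuffled every epoch with the seeded generator, so a
#' fixed seed gives identical runs.
#'
#' @param spec A [model_spec()].
#' @param sample_set A non-empty `sample_set` whose window shapes match the
#'   spec.
#' @param config A [train_config()].
#' @return An `mwl_model` handle: the trained network, the normalization
#'   statistics and `history` (per-epoch mean training loss).
#' @export
train_model <- function(spec, sample_set, config = train_config()) {
  samples <- sample_set$samples
  if (length(samples) == 0L) stop_invalid("sample set is empty")
  set.seed(config$seed)
  net <- build_model(spec)
  norm <- normalization_stats(samples, spec$modalities)
  labels <- set_labels(sample_set)
  n <- length(samples)
  full <- batch_arrays(samples, spec$modalities, norm)
  batches_per_epoch <- max(1L, ceiling(n / config$batch_size))
  total_steps <- config$epochs * batches_per_epoch
  history <- numeric(config$epochs)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n)
    epoch_loss <- 0
    for (bi in seq_len(batches_per_epoch)) {
      idx <- order_idx[(((bi - 1L) * config$batch_size) + 1L):
                         min(bi * config$batch_size, n)]
      batch <- lapply(full, function(a) a[idx, , , drop = FALSE])
      y <- labels[idx]
      fw <- forward_network(net, batch, training = TRUE)
      net <- fw$net
      err <- fw$pred - y
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(errorCondition("training diverged to non-finite loss",
                            class = c("mwlfuse_divergence", "error"),
                            history = history[seq_len(epoch - 1L)]))
      }
      epoch_loss <- epoch_loss + loss
      lr <- one_cycle_lr(step + 0.5, total_steps, config$lr_max)
      grads <- backward_network(net, fw$caches, 2 * err / length(err))
      net <- update_network(net, grads, lr, config$momentum)
      step <- step + 1L
    }
    history[epoch] <- epoch_loss / batches_per_epoch
  }
  structure(list(network = net, spec = spec, norm = norm,
                 history = history, config = config),
            class = "mwl_model")
}

#' @export
print.mwl_model <- function(x, ...) {
  cat(sprintf("<mwl_model %s: %d epochs, final training MSE %.4g>\n",
              x$spec$variant, length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict workload labels for multimodal samples
#'
#' Inference is deterministic (dropout disabled, batch norm uses running
#' statistics); batched and single-sample predictions agree elementwise.
#'
#' @param object An `mwl_model` from [train_model()].
#' @param newdata A `sample_set` or list of samples.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric predictions in \[0, 1\], one per sample.
#' @export
predict.mwl_model <- function(object, newdata, batch_size = 256L, ...) {
  samples <- if (inherits(newdata, "sample_set")) newdata$samples else newdata
  if (length(samples) == 0L) return(numeric())
  preds <- numeric(length(samples))
  starts <- seq(1L, length(samples), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(samples))
    batch <- batch_arrays(samples[idx], object$spec$modalities, object$norm)
    preds[idx] <- forward_network(object$network, batch, training = FALSE)$pred
  }
  preds
}

#' K-fold cross-validation of a model configuration
#'
#' The samples are partitioned into `config$folds` disjoint test folds
#' (every sample appears in exactly one). For each fold a fresh model is
#' trained on the remaining folds and scored by the mean absolute label
#' error on the held-out fold; the returned objective is the mean over
#' folds.
#'
#' @param spec A [model_spec()].
#' @param sample_set A `sample_set` with at least `config$folds` samples.
#' @param config A [train_config()].
#' @return List with `folds` (per-fold: `fold`, `error`, `history`,
#'   `test_idx`) and `mean_error`.
#' @export
cross_validate <- function(spec, sample_set, config = train_config()) {
  n <- length(sample_set$samples)
  k <- config$folds
  if (n < k) stop_invalid("need at least as many samples as folds")
  set.seed(config$seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  labels <- set_labels(sample_set)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train_set <- subset_samples(sample_set, which(fold_id != f))
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_model(spec, train_set, cfg)
    preds <- predict(model, sample_set$samples[test_idx])
    folds[[f]] <- list(fold = f,
                       error = mean_abs_error(preds, labels[test_idx]),
                       history = model$history, test_idx = test_idx)
  }
  list(folds = folds,
       mean_error = mean(vapply(folds, `[[`, numeric(1), "error")))
}

#' Train on a random 90--10 split and predict the held-out share
#'
#' @param spec A [model_spec()].
#' @param sample_set A `sample_set` with at least 10 samples.
#' @param config A [train_config()]; `holdout_fraction` sets the test share.
#' @return List with `model`, `predictions`, `labels`, `train_idx`,
#'   `test_idx`.
#' @export
holdout_train <- function(spec, sample_set, config = train_config()) {
  n <- length(sample_set$samples)
  if (n < 10L) stop_invalid("holdout training needs at least 10 samples")
  set.seed(config$seed)
  n_train <- floor((1 - config$holdout_fraction) * n)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  model <- train_model(spec, subset_samples(sample_set, train_idx), config)
  preds <- predict(model, sample_set$samples[test_idx])
  list(model = model, predictions = preds,
       labels = set_labels(sample_set)[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Mean absolute error of the best constant (label-mean) predictor
#'
#' The reference a learning model must beat: predict the training-label mean
#' for every sample.
#'
#' @param sample_set A `sample_set`.
#' @return Mean absolute deviation of the labels from their mean.
#' @export
constant_baseline <- function(sample_set) {
  labels <- set_labels(sample_set)
  mean(abs(labels - mean(labels)))
}
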