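#' Hyperparameter search space
#'
#' Learning rate is sampled log-uniformly, dropout and momentum uniformly,
#' and the model variant as a categorical choice. Default ranges bracket the
#' regime in which the one-cycle policy with momentum-bearing SGD operates.
#'
#' @param lr_range Log-uniform range for the peak learning rate.
#' @param dropout_range Uniform range for the dropout rate.
#' @param momentum_range Uniform range for the SGD momentum.
#' @param models Categorical model choices, subset of
#'   `c("MLP", "S_MLP", "LIT", "S_LIT")`; a search batch may restrict this
#'   to mirror staged studies (full-size models first, small models after).
#' @return A `search_space` list.
#' @export
search_space <- function(lr_range = c(1e-4, 1e-1),
                         dropout_range = c(0, 0.5),
                         momentum_range = c(0.5, 0.99),
                         models = VARIANTS) {
  check_range <- function(r, name, strict = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) ||
        (if (strict) r[1] >= r[2] else r[1] > r[2])) {
      stop_invalid(name, " must be a non-empty range (lower < upper)")
    }
  }
  check_range(lr_range, "lr_range")
  check_range(dropout_range, "dropout_range", strict = FALSE)
  check_range(momentum_range, "momentum_range", strict = FALSE)
  if (lr_range[1] <= 0) stop_invalid("lr_range must be positive")
  if (length(models) == 0L || !all(models %in% VARIANTS)) {
    stop_invalid("models must be a non-empty subset of ",
                 paste(VARIANTS, collapse = ", "))
  }
  structure(list(lr_range = lr_range, dropout_range = dropout_range,
                 momentum_range = momentum_range, models = models),
            class = "search_space")
}

sample_uniform <- function(r) stats::runif(1, r[1], r[2])

sample_log_uniform <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))

random_suggestion <- function(space) {
  list(lr_max = sample_log_uniform(space$lr_range),
       dropout_rate = sample_uniform(space$dropout_range),
       momentum = sample_uniform(space$momentum_range),
       model = sample(space$models, 1))
}

# Parzen density of x under Gaussian kernels centred at obs.
parzen_density <- function(x, obs, bw) {
  if (length(obs) == 0L) return(1)
  mean(stats::dnorm(x, mean = obs, sd = bw))
}

# Tree-structured Parzen estimator step: split past trials into the best
# gamma-quantile ("good") and the rest, draw candidates from the good
# Parzen mixture, keep the candidate maximizing the good/bad density ratio.
# Categorical choices use Laplace-smoothed class frequencies the same way.
tpe_suggestion <- function(space, trials, gamma = 0.25, n_candidates = 24L) {
  objectives <- vapply(trials, `[[`, numeric(1), "objective")
  n_good <- max(1L, ceiling(gamma * length(trials)))
  good <- order(objectives)[seq_len(n_good)]
  is_good <- seq_along(trials) %in% good
  pick_continuous <- function(getter, range, log_scale = FALSE) {
    vals <- vapply(trials, getter, numeric(1))
    if (log_scale) { vals <- log(vals); range <- log(range) }
    if (range[2] <= range[1]) {
      return(if (log_scale) exp(range[1]) else range[1])
    }
    bw <- max((range[2] - range[1]) / max(sqrt(sum(is_good)), 1), 1e-3)
    cand <- stats::rnorm(n_candidates, mean = sample(vals[is_good],
                                                     n_candidates, replace = TRUE),
                         sd = bw)
    cand <- pmin(pmax(cand, range[1]), range[2])
    score <- vapply(cand, function(x) {
      parzen_density(x, vals[is_good], bw) /
        (parzen_density(x, vals[!is_good], bw) + 1e-12)
    }, numeric(1))
    best <- cand[which.max(score)]
    if (log_scale) exp(best) else best
  }
  pick_categorical <- function(getter, choices) {
    vals <- vapply(trials, getter, character(1))
    w_good <- (table(factor(vals[is_good], levels = choices)) + 1)
    w_bad <- (table(factor(vals[!is_good], levels = choices)) + 1)
    cand <- sample(choices, n_candidates, replace = TRUE,
                   prob = as.numeric(w_good) / sum(w_good))
    ratio <- (as.numeric(w_good) / sum(w_good)) / (as.numeric(w_bad) / sum(w_bad))
    names(ratio) <- choices
    cand[which.max(ratio[cand])]
  }
  list(lr_max = pick_continuous(function(t) t$params$lr_max, space$lr_range,
                                log_scale = TRUE),
       dropout_rate = pick_continuous(function(t) t$params$dropout_rate,
                                      space$dropout_range),
       momentum = pick_continuous(function(t) t$params$momentum,
                                  space$momentum_range),
       model = pick_categorical(function(t) t$model, space$models))
}

#' Run a cross-validated hyperparameter study
#'
#' Each trial samples a learning rate, dropout rate, momentum and model
#' variant from `space` (first with random search, then -- for the TPE
#' sampler -- with a Tree-structured Parzen Estimator over past trials),
#' trains it with [cross_validate()], and records the mean absolute label
#' error over folds as the objective to minimise. The sampler is seeded:
#' identical (seed, space, data) reproduce the full trial sequence.
#'
#' @param sample_set A `sample_set`.
#' @param space A [search_space()].
#' @param n_trials Number of trials (`>= 1`).
#' @param sampler `"TPE"` (default) or `"random"`.
#' @param seed Integer seed for the sampler.
#' @param train_config Base [train_config()]; each trial overrides
#'   `lr_max` and `momentum` with its sampled values.
#' @param input_shapes,width_scale Passed to [model_spec()].
#' @param n_startup Random trials before TPE takes over (default 5).
#' @return A `study_result`: list with `trials` (each: `trial`, `model`,
#'   `params`, `objective`, `duration`) and `best` (the minimal-objective
#'   trial, earliest on ties).
#' @export
run_study <- function(sample_set, space = search_space(), n_trials = 20L,
                      sampler = c("TPE", "random"), seed = 1L,
                      train_config = train_config(),
                      input_shapes = default_input_shapes(),
                      width_scale = 1, n_startup = 5L) {
  sampler <- match.arg(sampler)
  if (n_trials < 1L) stop_invalid("n_trials must be >= 1")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(seed + 1000L * i)
    params <- if (sampler == "TPE" && i > n_startup) {
      tpe_suggestion(space, trials[seq_len(i - 1L)])
    } else {
      random_suggestion(space)
    }
    spec <- model_spec(params$model, dropout_rate = params$dropout_rate,
                       input_shapes = input_shapes, width_scale = width_scale)
    cfg <- train_config
    cfg$lr_max <- params$lr_max
    cfg$momentum <- params$momentum
    cfg$seed <- train_config$seed + i
    t0 <- Sys.time()
    objective <- tryCatch(cross_validate(spec, sample_set, cfg)$mean_error,
                          mwlfuse_divergence = function(e) Inf)
    trials[[i]] <- list(trial = i, model = params$model,
                        params = params[c("lr_max", "dropout_rate", "momentum")],
                        objective = objective,
                        duration = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
  }
  study <- structure(list(trials = trials), class = "study_result")
  study$best <- best_trial(study)
  study
}

#' Best trial of a study
#'
#' @param study A `study_result` from [run_study()].
#' @return The trial record with the minimal objective; ties are broken by
#'   the earliest trial index.
#' @export
best_trial <- function(study) {
  if (length(study$trials) == 0L) stop_invalid("study has no trials")
  objectives <- vapply(study$trials, `[[`, numeric(1), "objective")
  study$trials[[which.min(objectives)]]
}

#' Export a study as a data frame (trial, model, difference, LoW, duration)
#'
#' @param study A `study_result`.
#' @return Data frame mirroring the conventional study table layout.
#' @export
study_table <- function(study) {
  do.call(rbind, lapply(study$trials, function(t) {
    data.frame(trial = t$trial, model = t$model,
               difference = t$objective,
               low = low_from_error(t$objective),
               lr_max = t$params$lr_max,
               dropout_rate = t$params$dropout_rate,
               momentum = t$params$momentum,
               duration_s = t$duration, stringsAsFactors = FALSE)
  }))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d trials, best %s with objective %.4f>\n",
              length(x$trials), x$best$model, x$best$objective))
  invisible(x)
}
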