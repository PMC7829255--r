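#' Assemble a pipeline configuration
#'
#' One document drives an end-to-end run: simulate (or load) recordings,
#' segment, label, optionally search hyperparameters, train on a 90--10
#' holdout and evaluate. Exactly one data source must be given: the
#' simulator (`simulate`) or paths to existing recordings (`recordings`).
#'
#' @param simulate `NULL`, or a list with `n_participants` and optional
#'   overrides for [sim_config()] fields (e.g. `n_puzzles`,
#'   `puzzle_duration`, `jitter_sd`).
#' @param recordings `NULL`, or a list with `paths` (recording containers)
#'   and `ratings` (a ratings CSV with participant_id, puzzle_id, rating).
#' @param segmentation List of [segmentation_config()] overrides.
#' @param labelling List with `scheme` (`"individual"` or `"group"`).
#' @param model List with `variant`, optional `modalities`, `dropout_rate`,
#'   `width_scale`; ignored when `search` is given.
#' @param search `NULL`, or list with [search_space()] overrides plus
#'   `n_trials` and `sampler`.
#' @param training List of [train_config()] overrides.
#' @param seed Global seed propagated to every stage unless overridden.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(n_participants = 2L),
                            recordings = NULL,
                            segmentation = list(),
                            labelling = list(scheme = "individual"),
                            model = list(variant = "S_MLP"),
                            search = NULL,
                            training = list(),
                            seed = 1L,
                            out_dir = tempfile("mwlfuse-run-"),
                            log_level = "info") {
  structure(list(simulate = simulate, recordings = recordings,
                 segmentation = segmentation, labelling = labelling,
                 model = model, search = search, training = training,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()] (or plain list with the same fields,
#'   e.g. parsed from YAML).
#' @return Character vector of problems, each naming the offending field
#'   path; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  has_sim <- !is.null(config$simulate)
  has_rec <- !is.null(config$recordings)
  if (has_sim && has_rec) {
    add("simulate/recordings: exactly one data source must be configured, not both")
  }
  if (!has_sim && !has_rec) {
    add("simulate/recordings: one data source must be configured")
  }
  if (has_sim) {
    np <- config$simulate$n_participants %||% 1L
    if (!is.numeric(np) || np < 1) add("simulate.n_participants: must be >= 1")
    jit <- config$simulate$jitter_sd %||% 0
    if (jit < 0) add("simulate.jitter_sd: must be >= 0")
  }
  wl <- config$segmentation$window_length %||% 8
  if (!is.numeric(wl) || wl <= 0) add("segmentation.window_length: must be > 0")
  scheme <- config$labelling$scheme %||% "individual"
  if (!scheme %in% c("individual", "group")) {
    add("labelling.scheme: must be 'individual' or 'group'")
  }
  if (is.null(config$search)) {
    v <- config$model$variant %||% "S_MLP"
    if (!v %in% VARIANTS) add("model.variant: must be one of MLP, S_MLP, LIT, S_LIT")
    mods <- config$model$modalities %||% MODALITIES
    if (length(mods) == 0L || !all(mods %in% MODALITIES)) {
      add("model.modalities: must be a non-empty subset of PPG, GSR, ET, fNIRS")
    }
  } else {
    nt <- config$search$n_trials %||% 20L
    if (!is.numeric(nt) || nt < 1) add("search.n_trials: must be >= 1")
  }
  hf <- config$training$holdout_fraction %||% 0.10
  if (!is.numeric(hf) || hf <= 0 || hf >= 1) {
    add("training.holdout_fraction: must be in (0, 1)")
  }
  ep <- config$training$epochs %||% 25L
  if (!is.numeric(ep) || ep < 1) add("training.epochs: must be >= 1")
  problems
}

pipe_log <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level %||% "info"]] >= levels[[level]]) {
    message(sprintf("[mwlfuse %s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...)))
  }
}

resolve_train_config <- function(config) {
  tr <- config$training
  train_config(lr_max = tr$lr_max %||% 0.01,
               momentum = tr$momentum %||% 0.9,
               batch_size = tr$batch_size %||% 32L,
               epochs = tr$epochs %||% 25L,
               folds = tr$folds %||% 5L,
               holdout_fraction = tr$holdout_fraction %||% 0.10,
               seed = tr$seed %||% config$seed)
}

#' Run the full pipeline from one configuration
#'
#' Stages run in order -- simulate (or load), segment + label, optional
#' hyperparameter search, holdout training, evaluation -- with every
#' intermediate artifact written under `config$out_dir` and checksummed in
#' the returned manifest. A failing stage raises a structured error naming
#' the stage; artifacts of completed stages remain on disk.
#'
#' @param config A valid [pipeline_config()].
#' @return List with `manifest` (resolved config, artifact paths, MD5
#'   checksums, package version) and `report` (the [eval_report()] of the
#'   held-out predictions).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop_invalid("invalid pipeline config:\n  ",
                 paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  stage <- function(name, fn) {
    pipe_log(config, "info", "stage: ", name)
    tryCatch(fn(), error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("mwlfuse_stage_error", "error"), stage = name))
    })
  }
  scheme <- config$labelling$scheme %||% "individual"

  data <- stage("data", function() {
    if (!is.null(config$simulate)) {
      np <- as.integer(config$simulate$n_participants %||% 1L)
      recs <- list(); truths <- list()
      for (p in seq_len(np)) {
        args <- config$simulate
        args$n_participants <- NULL
        args$participant_id <- sprintf("P%02d", p)
        args$seed <- (config$simulate$seed %||% config$seed) + p
        cfg <- do.call(sim_config, args)
        sim <- simulate_session(cfg)
        dir_p <- file.path(config$out_dir, "recordings", args$participant_id)
        write_recording(sim$recording, dir_p)
        write_ratings(sim$truth, args$participant_id,
                      file.path(dir_p, "ratings.csv"))
        recs[[args$participant_id]] <- sim$recording
        truths[[args$participant_id]] <- sim$truth$puzzles
      }
      artifacts$recordings <<- file.path(config$out_dir, "recordings")
      list(recordings = recs, ratings = truths)
    } else {
      paths <- config$recordings$paths
      recs <- lapply(paths, read_recording)
      names(recs) <- vapply(seq_along(recs), function(i) {
        recs[[i]]$metadata$participant_id %||% basename(paths[[i]])
      }, character(1))
      ratings <- utils::read.csv(config$recordings$ratings,
                                 stringsAsFactors = FALSE)
      truths <- split(ratings[c("puzzle_id", "rating")], ratings$participant_id)
      list(recordings = recs, ratings = truths)
    }
  })

  sample_set <- stage("segment", function() {
    seg <- segmentation_config(
      window_length = config$segmentation$window_length %||% 8,
      gap_factor = config$segmentation$gap_factor %||% 2.5)
    group_map <- NULL
    if (scheme == "group") {
      all_ratings <- do.call(rbind, lapply(data$ratings, function(df) {
        df[c("puzzle_id", "rating")]
      }))
      means <- tapply(all_ratings$rating, all_ratings$puzzle_id, mean)
      group_map <- group_labels(as.numeric(means))
      names(group_map) <- names(means)
    }
    sets <- lapply(names(data$recordings), function(pid) {
      ratings <- data$ratings[[pid]]
      if (scheme == "group") {
        ratings <- data.frame(puzzle_id = names(group_map),
                              label = as.numeric(group_map))
      }
      rec <- data$recordings[[pid]]
      set <- build_sample_set(rec, ratings, seg, scheme = scheme)
      write_marker_selection(rec, set$selection_mask,
                             file.path(config$out_dir,
                                       sprintf("selection-%s.csv", pid)))
      set
    })
    combined <- do.call(combine_sample_sets, sets)
    shard_dir <- file.path(config$out_dir, "samples")
    write_sample_set(combined, shard_dir)
    artifacts$samples <<- shard_dir
    pipe_log(config, "info", "segment: ", length(combined), " samples")
    combined
  })

  tr_cfg <- resolve_train_config(config)
  window_length <- config$segmentation$window_length %||% 8
  shapes <- default_input_shapes(window_length = window_length)
  width_scale <- config$model$width_scale %||% 1

  spec <- stage("model", function() {
    if (!is.null(config$search)) {
      space <- search_space(
        lr_range = config$search$lr_range %||% c(1e-4, 1e-1),
        dropout_range = config$search$dropout_range %||% c(0, 0.5),
        momentum_range = config$search$momentum_range %||% c(0.5, 0.99),
        models = config$search$models %||% VARIANTS)
      study <- run_study(sample_set, space,
                         n_trials = config$search$n_trials %||% 20L,
                         sampler = config$search$sampler %||% "TPE",
                         seed = config$seed, train_config = tr_cfg,
                         input_shapes = shapes, width_scale = width_scale)
      utils::write.csv(study_table(study),
                       file.path(config$out_dir, "study.csv"),
                       row.names = FALSE)
      artifacts$study <<- file.path(config$out_dir, "study.csv")
      best <- best_trial(study)
      tr_cfg$lr_max <<- best$params$lr_max
      tr_cfg$momentum <<- best$params$momentum
      model_spec(best$model, dropout_rate = best$params$dropout_rate,
                 input_shapes = shapes, width_scale = width_scale)
    } else {
      model_spec(config$model$variant %||% "S_MLP",
                 modalities = config$model$modalities %||% MODALITIES,
                 dropout_rate = config$model$dropout_rate %||% 0.1,
                 input_shapes = shapes, width_scale = width_scale)
    }
  })

  fit <- stage("train", function() holdout_train(spec, sample_set, tr_cfg))

  report <- stage("evaluate", function() {
    label_values <- if (scheme == "individual") (0:6) / 6 else
      sort(unique(set_labels(sample_set)))
    rep <- eval_report(fit$predictions, fit$labels, label_values)
    jsonlite::write_json(
      list(mean_abs_error = rep$mean_abs_error, low = rep$low,
           within_1_level = rep$within_1_level,
           within_1p5_levels = rep$within_1p5_levels,
           accuracy = rep$confusion$accuracy,
           off_by_one_accuracy = rep$confusion$off_by_one_accuracy,
           chance_accuracy = rep$chance_accuracy,
           off_by_one_chance = rep$off_by_one_chance),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    artifacts$report <<- file.path(config$out_dir, "report.json")
    rep
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = unclass(config[setdiff(names(config), "out_dir")]),
    artifacts = artifacts,
    checksums = as.list(tools::md5sum(files[!grepl("manifest\\.json$", files)])),
    package_version = as.character(utils::packageVersion("mwlfuse")),
    r_version = as.character(getRversion())
  )
  manifest$config$simulate$action_rate <- NULL   # closures are not serialized
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, report = report, model = fit$model, spec = spec)
}
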