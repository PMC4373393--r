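# End-to-end experiment runner: data preparation, preprocessing, per-model
# training, and the robustness evaluation (accuracy curves with raw baseline
# and ablations, cosine stability, code sparseness), collected into a long-
# format report. All randomness flows from one global seed through named
# substreams (data, occlusion, per-model/per-repeat initialization).

#' Default experiment configuration
#'
#' The quick profile: synthetic digits (2,000 train / 500 test), 64 units per
#' model, occlusion levels 0/0.2/0.4, one repeat. The full-scale experiment
#' corresponds to MNIST IDX paths, 288 units, levels 0 to 0.60 in steps of
#' 0.05, 10 repeats, and the models' full presentation counts.
#'
#' @return Nested config list; override entries and pass to
#'   [run_experiment].
#' @export
default_config <- function() {
  list(
    data = list(source = "synthetic", n_train = 2000, n_test = 500),
    preprocessing = list(resize_factor = 0.40, f0_ratio = 200 / 256),
    models = c("fastica", "nmfsc", "pcbc", "hnn"),
    n_units = 64,
    fastica = list(),
    nmfsc = list(s_y = 0.85, max_epochs = 100),
    pcbc = list(n_presentations = 20000),
    hnn = list(n_presentations = 100000),
    ablations = TRUE,
    occlusion_levels = c(0, 0.2, 0.4),
    stability_levels = c(0.2, 0.4),
    repeats = 1,
    seed = 1,
    output_dir = NULL
  )
}

validate_config <- function(config) {
  base <- default_config()
  bad <- setdiff(names(config), names(base))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  stopifnot(all(cfg$models %in% c("fastica", "nmfsc", "pcbc", "hnn")),
            all(cfg$occlusion_levels >= 0 & cfg$occlusion_levels <= 1),
            cfg$repeats >= 1, cfg$n_units >= 2)
  cfg
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON config file; keys
#'   override [default_config].
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("[.]ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

experiment_data <- function(cfg) {
  d <- cfg$data
  if (identical(d$source, "synthetic")) {
    data_seed <- substream_seed(cfg$seed, 1)
    list(train = generate_digits(d$n_train, seed = data_seed),
         test = generate_digits(d$n_test, seed = data_seed + 1))
  } else if (identical(d$source, "idx")) {
    list(train = read_idx(d$train_images, d$train_labels),
         test = read_idx(d$test_images, d$test_labels))
  } else stop("unknown data source: ", d$source)
}

fit_model <- function(name, cfg, X, seed) {
  args <- cfg[[name]]
  switch(name,
    fastica = do.call(fastica, c(list(X = X, n_components = cfg$n_units,
                                      seed = seed), args)),
    nmfsc = do.call(nmfsc, c(list(X = X, n_units = cfg$n_units, seed = seed),
                             args)),
    pcbc = do.call(pcbc, c(list(X = X, n_units = cfg$n_units, seed = seed),
                           args)),
    hnn = do.call(hnn, c(list(X = X, n_units = cfg$n_units, seed = seed),
                         args)))
}

report_rows <- function(model_id, rep, metric, level, value) {
  data.frame(model = model_id, repeat_id = rep, metric = metric,
             level = level, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

#' Run the full robustness experiment
#'
#' Executes every stage: data preparation, preprocessing (fitted on the
#' training set), training of the configured models on the non-occluded
#' training inputs, and evaluation -- LDA accuracy per occlusion level (with
#' a raw-input baseline and, if `ablations` is on, competition-ablated PC/BC
#' and HNN curves), cosine stability at the configured levels, and mean code
#' sparseness. Stochastic stages re-run `repeats` times with distinct
#' initialization seeds; occluded test inputs are identical across models and
#' repeats.
#'
#' @param config config list (see [default_config]) or a path readable by
#'   [read_config]. Missing entries take their defaults.
#' @return Object of class `robustness_report`: list with `report` (long
#'   data.frame: model, repeat_id, metric, level, value), `models` (last
#'   repeat's fitted models), `preprocessor`, and the resolved `config`.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(cfg$output_dir, "experiment_cache.rds")
    if (file.exists(cache)) {
      cached <- readRDS(cache)
      if (identical(cached$config, cfg)) {
        message("reusing cached experiment for identical config")
        return(cached)
      }
    }
  }

  dat <- experiment_data(cfg)
  pp <- fit_preprocessor(dat$train, cfg$preprocessing$resize_factor,
                         cfg$preprocessing$f0_ratio)
  train_in <- preprocess(pp, dat$train)
  occl_seed <- substream_seed(cfg$seed, 2)
  test_grid <- occlusion_grid_inputs(pp, dat$test, cfg$occlusion_levels,
                                     seed = occl_seed)
  clean_test <- preprocess(pp, dat$test)
  stab_in <- lapply(cfg$stability_levels, function(lv) {
    preprocess(pp, occlude(dat$test, lv, occl_seed))
  })

  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df

  # raw-input baseline
  acc_raw <- accuracy_curve(NULL, train_in, test_grid)
  add(report_rows("raw", 1, "accuracy", cfg$occlusion_levels, acc_raw))

  models <- list()
  deterministic <- c("fastica", "nmfsc")   # one repeat suffices (zero error)
  for (name in cfg$models) {
    n_rep <- if (name %in% deterministic) 1 else cfg$repeats
    for (rep in seq_len(n_rep)) {
      seed_m <- substream_seed(cfg$seed, 10 + 10 * match(name, cfg$models) +
                                 rep)
      fit <- fit_model(name, cfg, train_in$X, seed_m)
      models[[name]] <- fit
      add(report_rows(name, rep, "accuracy", cfg$occlusion_levels,
                      accuracy_curve(fit, train_in, test_grid)))
      add(report_rows(name, rep, "cosine", cfg$stability_levels,
                      vapply(stab_in, function(o)
                        cosine_stability(fit, clean_test, o), numeric(1))))
      add(report_rows(name, rep, "sparseness", NA_real_,
                      mean_code_sparseness(fit, train_in)))
      if (cfg$ablations && name %in% c("pcbc", "hnn")) {
        ab <- ablate(fit)
        models[[paste0(name, "_ablated")]] <- ab
        add(report_rows(paste0(name, "_ablated"), rep, "accuracy",
                        cfg$occlusion_levels,
                        accuracy_curve(ab, train_in, test_grid)))
        add(report_rows(paste0(name, "_ablated"), rep, "sparseness",
                        NA_real_, mean_code_sparseness(ab, train_in)))
      }
    }
  }

  out <- structure(list(report = do.call(rbind, rows), models = models,
                        preprocessor = pp, config = cfg),
                   class = "robustness_report")
  if (!is.null(cfg$output_dir)) {
    utils::write.csv(out$report,
                     file.path(cfg$output_dir, "robustness_report.csv"),
                     row.names = FALSE)
    saveRDS(out, file.path(cfg$output_dir, "experiment_cache.rds"))
  }
  out
}

#' @export
print.robustness_report <- function(x, ...) {
  acc <- x$report[x$report$metric == "accuracy", ]
  wide <- stats::aggregate(value ~ model + level, acc, mean)
  tab <- stats::reshape(wide, idvar = "model", timevar = "level",
                        direction = "wide")
  names(tab) <- sub("^value[.]", "occl ", names(tab))
  cat("Robustness report: mean LDA accuracy by occlusion level\n")
  print(tab, row.names = FALSE, digits = 3)
  sp <- x$report[x$report$metric == "sparseness", ]
  if (nrow(sp)) {
    cat("\nMean code sparseness (Hoyer):\n")
    print(stats::aggregate(value ~ model, sp, mean),
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
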