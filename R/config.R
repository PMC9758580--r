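# YAML configuration and command-line entry points.

#' Default run configuration
#'
#' The fully resolved nested configuration: dataset geometry, architecture
#' preset, optimizer, augmentation, replay, scheduler, and protocol
#' settings. Every run manifest serialises this structure.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    dataset = list(n_classes = 10L, n_train = 117L, n_val = 13L, n_test = 5L,
                   image_size = 64L, similarity_mode = "none",
                   difficulty = 0.7, seed = 1L),
    model = list(preset = "mini",
                 pretrain = list(enabled = TRUE, n_classes = 20L,
                                 epochs = 5L, n_per_class = 58L)),
    optimizer = list(learning_rate = 3e-4, batch_size = 36L),
    augment = list(max_rotation_deg = 20, max_shift_frac = 0.2,
                   max_zoom_frac = 0.2, horizontal_flip = TRUE),
    replay = list(downsample_factors = list(pool_1 = 8L, pool_2 = 4L,
                                            pool_3 = 4L, pool_4 = 2L,
                                            pool_5 = 1L),
                  n_samples_per_class = NULL, covariance_jitter = 1e-6,
                  clip_nonnegative = FALSE),
    scheduler = list(side_lr = 0.001, side_epochs = 50L, temperature = 1,
                     mode = "online"),
    protocol = list(condition = "generative", cut_point = "pool_4",
                    n_days = 10L, n_models = 10L,
                    exemplars_per_class = NULL, master_seed = 1L),
    output_dir = "runs"
  )
}

# strict recursive merge: every key in `user` must exist in `defaults`
merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    dv <- defaults[[key]]; uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv)) {
        stop(sprintf("configuration key '%s' must be a mapping", full),
             call. = FALSE)
      }
      defaults[[key]] <- merge_config(dv, uv, c(path, key))
    } else {
      if (!is.null(dv) && !is.null(uv) && is.numeric(dv) && !is.numeric(uv)) {
        stop(sprintf("configuration key '%s' must be numeric", full),
             call. = FALSE)
      }
      defaults[[key]] <- uv
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, fills every unset key from [default_config()], and
#' rejects unknown keys by name. An empty file resolves to all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The resolved nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

# Build the component objects from a resolved config.
config_objects <- function(cfg) {
  list(
    optimizer = optimizer_config(cfg$optimizer$learning_rate,
                                 cfg$optimizer$batch_size),
    augment = augment_config(cfg$augment$max_rotation_deg,
                             cfg$augment$max_shift_frac,
                             cfg$augment$max_zoom_frac,
                             cfg$augment$horizontal_flip),
    replay = replay_config(unlist(cfg$replay$downsample_factors),
                           cfg$replay$n_samples_per_class,
                           cfg$replay$covariance_jitter,
                           cfg$replay$clip_nonnegative)
  )
}

config_bundle <- function(cfg) {
  ds <- cfg$dataset
  protos <- generate_prototypes(ds$n_classes, seed = ds$seed,
                                similarity_mode = ds$similarity_mode,
                                difficulty_profile = rep(ds$difficulty,
                                                         ds$n_classes))
  build_dataset(protos, ds$n_train, ds$n_val, ds$n_test,
                size = c(ds$image_size, ds$image_size), seed = ds$seed)
}

config_protocol <- function(cfg, overrides = list()) {
  pr <- utils::modifyList(cfg$protocol, overrides)
  obj <- config_objects(cfg)
  protocol_config(condition = pr$condition, cut_point = pr$cut_point,
                  n_days = pr$n_days, n_models = pr$n_models,
                  exemplars_per_class = pr$exemplars_per_class,
                  master_seed = pr$master_seed,
                  optimizer = obj$optimizer, augment = obj$augment,
                  replay = obj$replay,
                  side_lr = cfg$scheduler$side_lr,
                  side_epochs = cfg$scheduler$side_epochs,
                  temperature = cfg$scheduler$temperature,
                  scheduler_mode = cfg$scheduler$mode,
                  pretrain = cfg$model$pretrain)
}

write_run_outputs <- function(log, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  write.csv(as.data.frame(log), csv, row.names = FALSE)
  jsonlite::write_json(attr(log, "manifest"),
                       file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  csv
}

cli_usage <- function() {
  cat("usage: replaysim <command> [options]\n",
      "commands:\n",
      "  generate-data     --config <yml> --out <dir>\n",
      "  train             --config <yml> --days <n> --seed <s> --out <dir>\n",
      "  replay-experiment --config <yml> [--condition c] [--days n]\n",
      "                    [--cut pool_k] [--models n] [--seed s] --out <dir>\n",
      "  sweep             --config <yml> --exemplars 20,40,... --out <dir>\n",
      "  report            --out <dir> (reads <dir>/*.csv)\n", sep = "")
}

parse_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a),
                                   call. = FALSE)
    if (i == length(argv)) stop(sprintf("missing value for '%s'", a),
                                call. = FALSE)
    opts[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `generate-data` writes an image-folder dataset;
#' `train` runs the no-replay protocol; `replay-experiment` runs any
#' condition and writes a tidy CSV plus a JSON manifest; `sweep` repeats
#' the experiment over exemplar counts; `report` summarises previously
#' written CSVs into one table (and a PNG of the curves).
#'
#' @param argv Character vector of arguments (default: the process's).
#' @return Integer exit code, invisibly (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0) { cli_usage(); return(invisible(1L)) }
    cmd <- argv[1]
    opts <- parse_args(argv[-1])
    cfg <- load_config(opts$config)
    if (!is.null(opts$seed)) cfg$protocol$master_seed <- as.integer(opts$seed)
    if (!is.null(opts$days)) cfg$protocol$n_days <- as.integer(opts$days)
    if (!is.null(opts$models)) cfg$protocol$n_models <- as.integer(opts$models)
    if (!is.null(opts$condition)) cfg$protocol$condition <- opts$condition
    if (!is.null(opts$cut)) cfg$protocol$cut_point <- opts$cut
    out <- opts$out %||% cfg$output_dir
    if (cmd == "generate-data") {
      bundle <- config_bundle(cfg)
      write_image_folder(bundle, out)
      message(sprintf("wrote image folder to %s", out))
    } else if (cmd == "train") {
      cfg$protocol$condition <- "none"
      log <- run_condition(config_protocol(cfg), config_bundle(cfg))
      message(sprintf("wrote %s", write_run_outputs(log, out, "train")))
    } else if (cmd == "replay-experiment") {
      log <- run_condition(config_protocol(cfg), config_bundle(cfg))
      name <- paste0(cfg$protocol$condition, "_", cfg$protocol$cut_point)
      message(sprintf("wrote %s", write_run_outputs(log, out, name)))
    } else if (cmd == "sweep") {
      ks <- as.integer(strsplit(opts$exemplars %||%
                                  "20,40,60,80,100", ",")[[1]])
      bundle <- config_bundle(cfg)
      for (k in ks) {
        log <- run_condition(config_protocol(cfg,
                                             list(exemplars_per_class = k)),
                             bundle)
        message(sprintf("wrote %s",
                        write_run_outputs(log, out,
                                          sprintf("exemplars_%03d", k))))
      }
    } else if (cmd == "report") {
      files <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
      files <- files[!grepl("summary", files)]
      if (length(files) == 0) stop("no CSVs found to report on", call. = FALSE)
      logs <- lapply(files, read.csv)
      summary <- summarize_logs(logs)
      write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
      plot_generalization(summary, file.path(out, "summary.png"))
      message(sprintf("wrote %s", file.path(out, "summary.csv")))
    } else {
      cli_usage()
      stop(sprintf("unknown command '%s'", cmd), call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
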