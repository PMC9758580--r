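# Day-night protocol orchestration and derived metrics.

#' Protocol configuration for a day-night experiment
#'
#' Conditions:
#' * `"none"` - days of image training only (baseline).
#' * `"generative"` - each day is followed by a night in which per-class
#'   Gaussians are refitted from that day's activations and sampled.
#' * `"veridical"` - nights replay the exact captured activations.
#' * `"continuous"` - a single day of real images; distributions are fitted
#'   once from that day and every subsequent day-night cycle runs two replay
#'   epochs with no real images.
#' * `"rl_generative"` - as `"generative"` but nights are scheduled one
#'   36-item batch at a time by the reinforcement-learning side network.
#'
#' @param condition One of the five condition names.
#' @param cut_point Pooling layer where replay is injected.
#' @param n_days Number of day(-night) cycles (>= 1; >= 2 for continuous).
#' @param n_models Replicate count; replicate m depends only on
#'   `(master_seed, m)`.
#' @param exemplars_per_class Restrict training (and replay sample counts)
#'   to this many images per class; `NULL` = all.
#' @param master_seed Master seed from which all per-replicate streams are
#'   derived.
#' @param optimizer,augment,replay Component configurations.
#' @param side_lr,side_epochs,temperature,scheduler_mode Side-network
#'   settings (rl mode); see [scheduler_state()].
#' @param pretrain List `(enabled, n_classes, epochs, n_per_class, seed)`
#'   controlling pretraining of the convolutional base on a disjoint
#'   synthetic class set before transfer, emulating an experienced visual
#'   system meeting new categories.
#' @param arch An [arch_spec()]; `NULL` = mini preset sized to the bundle.
#' @return A `"protocol_config"`.
#' @export
protocol_config <- function(condition = c("none", "generative", "veridical",
                                          "continuous", "rl_generative"),
                            cut_point = "pool_4", n_days = 10L,
                            n_models = 10L, exemplars_per_class = NULL,
                            master_seed = 1L,
                            optimizer = optimizer_config(),
                            augment = augment_config(),
                            replay = replay_config(),
                            side_lr = 0.001, side_epochs = 50L,
                            temperature = 1,
                            scheduler_mode = c("online", "buffer"),
                            pretrain = list(enabled = TRUE, n_classes = 20L,
                                            epochs = 5L, n_per_class = 58L),
                            arch = NULL) {
  condition <- match.arg(condition)
  scheduler_mode <- match.arg(scheduler_mode)
  n_days <- assert_scalar_int(n_days, "n_days")
  if (condition == "continuous" && n_days < 2) {
    stop("continuous replay needs n_days >= 2", call. = FALSE)
  }
  structure(list(condition = condition, cut_point = cut_point,
                 n_days = n_days,
                 n_models = assert_scalar_int(n_models, "n_models"),
                 exemplars_per_class = exemplars_per_class,
                 master_seed = as.integer(master_seed),
                 optimizer = optimizer, augment = augment, replay = replay,
                 side_lr = side_lr, side_epochs = side_epochs,
                 temperature = temperature, scheduler_mode = scheduler_mode,
                 pretrain = pretrain, arch = arch),
            class = "protocol_config")
}

# Architecture matched to a bundle under the mini preset.
arch_for_bundle <- function(cfg, bundle) {
  cfg$arch %||% arch_spec("mini", n_outputs = bundle$n_classes,
                          input_shape = bundle$dim)
}

#' Pretrain a convolutional base on a disjoint synthetic class set
#'
#' Trains a classifier of the same block structure on freshly generated
#' categories (disjoint from any experiment dataset by seed derivation), to
#' be passed as `pretrained_base` when building transfer models.
#'
#' @param cfg A [protocol_config()] (supplies pretraining sizes and
#'   optimizer/augmentation settings).
#' @param bundle The experiment bundle (fixes image geometry).
#' @param seed Integer seed for the pretraining stream.
#' @return A `"layered_classifier"` trained on the disjoint set.
#' @export
pretrain_base <- function(cfg, bundle, seed) {
  pt <- cfg$pretrain
  protos <- generate_prototypes(pt$n_classes, seed = mix_seed(seed, "preprotos"))
  pre_bundle <- build_dataset(protos, pt$n_per_class, 1L, 1L,
                              size = bundle$dim[1:2],
                              seed = mix_seed(seed, "predata"))
  spec <- arch_spec("mini", n_outputs = pt$n_classes, input_shape = bundle$dim)
  model <- build_model(spec, init_seed = mix_seed(seed, "preinit"))
  with_seed(mix_seed(seed, "pretrain"), {
    for (e in seq_len(pt$epochs)) {
      model <- train_epoch(model, pre_bundle, cfg$optimizer, cfg$augment)$model
    }
  })
  model
}

# generative-night replay volume: one count per class, matching the number
# of training images actually used per class (exposure parity)
samples_per_class <- function(cfg, bundle) {
  if (!is.null(cfg$replay$n_samples_per_class)) {
    return(rep(cfg$replay$n_samples_per_class, bundle$n_classes))
  }
  as.vector(table(factor(bundle$labels[bundle$split == "train"],
                         levels = seq_len(bundle$n_classes))))
}

#' Run one experimental condition
#'
#' Executes the day-night protocol for every replicate and returns a tidy
#' log: one row per (model, day, class) holding the day's overall test
#' accuracy, training (or replay) loss, per-class test accuracy, and - in
#' the rl condition - per-class nightly selection counts. Day 0 records the
#' untrained (chance-level) evaluation. Evaluation happens once per
#' day-night cycle, after the night.
#'
#' @param cfg A [protocol_config()].
#' @param bundle A [build_dataset()] bundle with as many classes as the
#'   model has outputs.
#' @param base_models Optional list of `n_models` pretrained base
#'   classifiers (one per replicate); defaults to pretraining per replicate
#'   when `cfg$pretrain$enabled`, else random initialisation.
#' @return An `"experiment_log"` data frame; the resolved configuration and
#'   seeds are attached as attribute `"manifest"`. Attribute
#'   `"final_val_acc"` holds the per-replicate, per-class validation
#'   accuracies after the final cycle; in the rl condition
#'   `"rl_baseline_val_acc"` additionally records them after day-1 training,
#'   before any replay.
#' @export
run_condition <- function(cfg, bundle, base_models = NULL) {
  stopifnot(inherits(cfg, "protocol_config"),
            inherits(bundle, "dataset_bundle"))
  if (!is.null(cfg$exemplars_per_class)) {
    bundle <- limit_exemplars(bundle, cfg$exemplars_per_class)
  }
  spec <- arch_for_bundle(cfg, bundle)
  rows <- list()
  rl_baseline <- NULL   # rl mode: pre-replay day-1 val per-class accs
  final_val <- NULL     # all modes: final val per-class accs per replicate
  for (m in seq_len(cfg$n_models)) {
    seed_m <- mix_seed(cfg$master_seed, "model", m)
    base <- if (!is.null(base_models)) base_models[[m]]
            else if (isTRUE(cfg$pretrain$enabled)) pretrain_base(cfg, bundle, seed_m)
            else NULL
    model <- build_model(spec, init_seed = mix_seed(seed_m, "transfer"),
                         pretrained_base = base)
    rows[[length(rows) + 1L]] <-
      log_rows(cfg, m, 0L, evaluate(model, bundle, "test"), NA_real_, NULL)
    state <- NULL
    dists <- NULL   # continuous: fitted once
    with_seed(mix_seed(seed_m, "protocol"), {
      for (day in seq_len(cfg$n_days)) {
        loss <- NA_real_
        sel <- NULL
        if (cfg$condition == "none") {
          tr <- train_epoch(model, bundle, cfg$optimizer, cfg$augment)
          model <- tr$model; loss <- tr$loss
        } else if (cfg$condition %in% c("generative", "veridical",
                                        "rl_generative")) {
          tr <- train_epoch(model, bundle, cfg$optimizer, cfg$augment)
          model <- tr$model; loss <- tr$loss
          if (cfg$condition == "veridical") {
            batch <- capture_veridical(model, cfg$cut_point, bundle)
            model <- replay_night(model, cfg$cut_point, batch,
                                  cfg$optimizer)$model
          } else {
            acts <- activations_at(model, cfg$cut_point, bundle, "train")
            dists <- fit_all_classes(acts, bundle_labels(bundle, "train"),
                                     cfg$cut_point, cfg$replay)
            if (cfg$condition == "generative") {
              nps <- samples_per_class(cfg, bundle)
              batches <- Map(sample_distribution, dists, nps,
                             clip_nonnegative = cfg$replay$clip_nonnegative)
              model <- replay_night(model, cfg$cut_point, batches,
                                    cfg$optimizer)$model
            } else {
              if (day == 1L) {
                # pre-replay baseline: how well each class was "originally"
                # learned from real images alone
                rl_baseline <- rbind(rl_baseline,
                                     evaluate(model, bundle,
                                              "val")$per_class_accuracy)
              }
              if (is.null(state)) {
                state <- scheduler_state(bundle$n_classes, cfg$side_lr,
                                         cfg$side_epochs, cfg$temperature,
                                         cfg$scheduler_mode %||% "online")
                ini <- initialize_values(model, dists, bundle, state,
                                         cfg$cut_point, cfg$optimizer)
                state <- ini$state; model <- ini$model
              }
              nsteps <- ceiling(sum(samples_per_class(cfg, bundle)) /
                                  cfg$optimizer$batch_size)
              night <- rl_replay_night(model, state, dists, bundle, nsteps,
                                       cfg$cut_point, cfg$optimizer)
              model <- night$model; state <- night$state
              sel <- night$selection_counts
            }
          }
        } else if (cfg$condition == "continuous") {
          if (day == 1L) {
            tr <- train_epoch(model, bundle, cfg$optimizer, cfg$augment)
            model <- tr$model; loss <- tr$loss
            acts <- activations_at(model, cfg$cut_point, bundle, "train")
            dists <- fit_all_classes(acts, bundle_labels(bundle, "train"),
                                     cfg$cut_point, cfg$replay)
          } else {
            nps <- samples_per_class(cfg, bundle)
            for (slot in 1:2) {  # day-slot and night-slot are both replay
              batches <- Map(sample_distribution, dists, nps,
                             clip_nonnegative = cfg$replay$clip_nonnegative)
              rn <- replay_night(model, cfg$cut_point, batches, cfg$optimizer)
              model <- rn$model; loss <- rn$loss
            }
          }
        }
        rows[[length(rows) + 1L]] <-
          log_rows(cfg, m, day, evaluate(model, bundle, "test"), loss, sel)
      }
      final_val <- rbind(final_val,
                         evaluate(model, bundle, "val")$per_class_accuracy)
    })
  }
  log <- do.call(rbind, rows)
  class(log) <- c("experiment_log", class(log))
  attr(log, "final_val_acc") <- final_val
  if (!is.null(rl_baseline)) attr(log, "rl_baseline_val_acc") <- rl_baseline
  attr(log, "manifest") <- list(config = manifest_config(cfg),
                                generation_seed = bundle$generation_seed,
                                n_classes = bundle$n_classes,
                                package_version =
                                  as.character(utils::packageVersion("replaysim")))
  log
}

log_rows <- function(cfg, m, day, report, loss, sel) {
  C <- length(report$per_class_accuracy)
  data.frame(condition = cfg$condition, model = m, day = day,
             overall_acc = report$overall_accuracy, loss = loss,
             class_id = seq_len(C),
             class_acc = report$per_class_accuracy,
             selection_count = if (is.null(sel)) NA_integer_ else sel)
}

manifest_config <- function(cfg) {
  lapply(unclass(cfg), function(v) if (is.list(v)) lapply(unclass(v), identity)
         else v)
}

#' Day-over-day relative improvement
#'
#' For a per-day accuracy series, the improvement from day n to day n+1
#' divided by the room left for improvement on day n:
#' `r_n = (a[n+1] - a[n]) / (1 - a[n])`. Where `a[n] = 1` the ratio is
#' undefined and reported as `NA`.
#'
#' @param acc Numeric vector of accuracies in `[0, 1]`.
#' @return Numeric vector of length `length(acc) - 1`.
#' @export
#' @examples
#' relative_improvement(c(0.5, 0.6))  # 0.2
relative_improvement <- function(acc) {
  stopifnot(all(acc >= 0 & acc <= 1))
  n <- length(acc)
  if (n < 2) return(numeric(0))
  a <- acc[-n]; b <- acc[-1]
  ifelse(a == 1, NA_real_, (b - a) / (1 - a))
}

#' Relative increase over a baseline accuracy
#'
#' `(acc_replay - acc_base) / acc_base`; negative when replay decreased
#' performance.
#'
#' @param acc_replay,acc_base Accuracies; `acc_base > 0`.
#' @return Scalar relative increase.
#' @export
#' @examples
#' relative_increase_from_baseline(0.5, 0.4)  # 0.25
relative_increase_from_baseline <- function(acc_replay, acc_base) {
  if (any(acc_base <= 0)) stop("baseline accuracy must be > 0", call. = FALSE)
  (acc_replay - acc_base) / acc_base
}

#' Regression of replay-selection counts on baseline accuracy
#'
#' Ordinary least squares of per-class selection counts on per-class
#' baseline accuracy. A negative slope means weakly learned classes were
#' replayed more often (rebalancing). A constant predictor yields `NA`
#' markers rather than an error.
#'
#' @param selection_counts,baseline_per_class_acc Equal-length numeric
#'   vectors (length >= 3).
#' @return `list(slope, intercept, r_squared)`.
#' @export
rebalancing_regression <- function(selection_counts, baseline_per_class_acc) {
  stopifnot(length(selection_counts) == length(baseline_per_class_acc),
            length(selection_counts) >= 3)
  if (sd(baseline_per_class_acc) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  fit <- lm(selection_counts ~ baseline_per_class_acc)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((selection_counts - mean(selection_counts))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

#' Summarise experiment logs over replicates
#'
#' Mean and standard error of the mean of overall test accuracy per
#' condition and day; a single replicate reports `NA` s.e.m.
#'
#' @param logs An `"experiment_log"` or a list of them.
#' @return Data frame with columns `condition`, `day`, `mean_acc`, `sem`,
#'   `n_models`.
#' @export
summarize_logs <- function(logs) {
  if (inherits(logs, "experiment_log") || is.data.frame(logs)) logs <- list(logs)
  df <- do.call(rbind, lapply(logs, as.data.frame))
  # one accuracy per (condition, model, day): drop per-class duplication
  key <- !duplicated(df[, c("condition", "model", "day")])
  df <- df[key, c("condition", "model", "day", "overall_acc")]
  out <- do.call(rbind, lapply(split(df, list(df$condition, df$day),
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1], day = g$day[1],
               mean_acc = mean(g$overall_acc),
               sem = if (nrow(g) > 1) sd(g$overall_acc) / sqrt(nrow(g))
                     else NA_real_,
               n_models = nrow(g))
  }))
  out <- out[order(out$condition, out$day), ]
  rownames(out) <- NULL
  out
}

#' Plot mean generalization curves
#'
#' Basic per-condition mean accuracy curves (one line per condition) written
#' to a PNG when `file` is given, otherwise drawn on the active device.
#'
#' @param summary Output of [summarize_logs()].
#' @param file Optional PNG path.
#' @export
plot_generalization <- function(summary, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  conds <- unique(summary$condition)
  days <- sort(unique(summary$day))
  mat <- sapply(conds, function(cn) {
    s <- summary[summary$condition == cn, ]
    s$mean_acc[match(days, s$day)]
  })
  graphics::matplot(days, mat, type = "b", pch = 19, lty = 1,
                    xlab = "day", ylab = "generalization accuracy",
                    ylim = c(0, 1))
  graphics::legend("bottomright", legend = conds, col = seq_along(conds),
                   pch = 19, lty = 1, bty = "n")
  invisible(summary)
}
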