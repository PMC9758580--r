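# Offline replay: downsampling, per-class Gaussian fitting and sampling,
# veridical buffers, and night training of the truncated head.
#
# Downsampling is per-channel block-mean pooling; upsampling is
# nearest-neighbour replication. Both are linear maps built once per
# (shape, factor) as small per-axis operator matrices, so the round trip
# downsample(upsample(x, f), f) == x holds exactly and sampling at scale is
# one GEMM. When the factor does not divide a spatial side, the trailing
# partial block is averaged as-is and replication is cropped back, mirroring
# how a fractional-factor pooling is usually handled.

# h2 x h block-mean operator (rows average blocks of size <= f)
block_mean_op <- function(h, f) {
  groups <- ceiling(seq_len(h) / f)
  h2 <- max(groups)
  M <- matrix(0, h2, h)
  for (j in seq_len(h)) M[groups[j], j] <- 1
  M / rowSums(M)
}

# h x h2 replication operator (transpose pattern of block_mean_op, 0/1)
block_rep_op <- function(h, f) {
  groups <- ceiling(seq_len(h) / f)
  U <- matrix(0, h, max(groups))
  for (j in seq_len(h)) U[j, groups[j]] <- 1
  U
}

#' Downsample or upsample a spatial activation map
#'
#' `downsample_activations` reduces an `(H, W, C)` activation array by
#' per-channel block-mean pooling with blocks of `factor x factor`;
#' `upsample_activations` replicates each cell of an `(h, w, C)` array into
#' a `factor x factor` block (nearest neighbour). `factor = 1` is the
#' identity for both.
#'
#' @param act A 3-D numeric array.
#' @param factor Integer >= 1, at most the spatial side for downsampling.
#' @return The resampled 3-D array.
#' @export
#' @examples
#' a <- array(1:16, c(4, 4, 1))
#' downsample_activations(a, 2)
downsample_activations <- function(act, factor) {
  d <- dim(act)
  stopifnot(length(d) == 3)
  factor <- assert_scalar_int(factor, "factor")
  if (factor > min(d[1:2])) {
    stop("factor exceeds the spatial side of the activation map", call. = FALSE)
  }
  if (factor == 1L) return(act)
  Mr <- block_mean_op(d[1], factor)
  Mc <- block_mean_op(d[2], factor)
  out <- array(0, c(nrow(Mr), nrow(Mc), d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Mr %*% act[, , ch] %*% t(Mc)
  out
}

#' @rdname downsample_activations
#' @export
upsample_activations <- function(act, factor) {
  d <- dim(act)
  stopifnot(length(d) == 3)
  factor <- assert_scalar_int(factor, "factor")
  if (factor == 1L) return(act)
  Ur <- block_rep_op(d[1] * factor, factor)
  Uc <- block_rep_op(d[2] * factor, factor)
  out <- array(0, c(d[1] * factor, d[2] * factor, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ur %*% act[, , ch] %*% t(Uc)
  out
}

# Dense (d2 x d) downsampling operator for flattened (h, w, c) columns,
# and its (d x d2) replication adjoint cropped to the original shape.
flat_down_op <- function(shape, factor) {
  kronecker(diag(shape[3]),
            kronecker(block_mean_op(shape[2], factor),
                      block_mean_op(shape[1], factor)))
}

flat_up_op <- function(shape, factor) {
  kronecker(diag(shape[3]),
            kronecker(block_rep_op(shape[2], factor),
                      block_rep_op(shape[1], factor)))
}

#' Replay configuration
#'
#' Controls the generative replay stage: the per-cut-point spatial
#' downsampling factors used before fitting the class Gaussians (fitting a
#' joint covariance over the raw early layers would be intractable), the
#' number of samples drawn per class each night (`NULL` = match the number
#' of training images per class), the covariance regularisation, and whether
#' samples are clamped to be nonnegative. Defaults downsample by 8, 4, 4, 2
#' for the first four pooling layers and leave the last untouched; samples
#' are drawn from the fitted normal as-is (no clamping).
#'
#' @param downsample_factors Named integer vector, cut point -> factor.
#' @param n_samples_per_class Samples drawn per class per night, or `NULL`.
#' @param covariance_jitter Ridge added to the covariance diagonal, as a
#'   multiple of the mean diagonal entry.
#' @param clip_nonnegative Clamp generative samples at zero (off by default;
#'   the fitted normal is sampled faithfully even though true pooled
#'   activations are nonnegative).
#' @return A `"replay_config"`.
#' @export
replay_config <- function(downsample_factors = c(pool_1 = 8L, pool_2 = 4L,
                                                 pool_3 = 4L, pool_4 = 2L,
                                                 pool_5 = 1L),
                          n_samples_per_class = NULL,
                          covariance_jitter = 1e-6,
                          clip_nonnegative = FALSE) {
  stopifnot(all(downsample_factors >= 1), covariance_jitter >= 0)
  structure(list(downsample_factors = downsample_factors,
                 n_samples_per_class = n_samples_per_class,
                 covariance_jitter = covariance_jitter,
                 clip_nonnegative = clip_nonnegative),
            class = "replay_config")
}

#' Fit the class-conditional activation distribution
#'
#' Downsamples every activation map, flattens it, and fits a single
#' multivariate normal for the class: the sample mean and sample covariance
#' (plus a small diagonal jitter, since with more dimensions than samples
#' the sample covariance is singular) over the fitted examples.
#'
#' @param acts d x n activation matrix with attribute `shape = c(h, w, c)`
#'   as returned by [activations_at()] (n >= 2).
#' @param class_id Integer class label.
#' @param cut_point Pooling-layer id the activations came from.
#' @param cfg A [replay_config()] (supplies factor and jitter).
#' @return An `"activation_distribution"`: list with `mean`, `covariance`,
#'   `spatial_shape` (downsampled), `layer_shape` (full), `downsample_factor`,
#'   `n_fit`, `class_id`, `cut_point`.
#' @export
fit_class_distribution <- function(acts, class_id, cut_point,
                                   cfg = replay_config()) {
  if (ncol(acts) < 2) {
    stop("need at least 2 activation arrays to fit a distribution",
         call. = FALSE)
  }
  shape <- attr(acts, "shape")
  stopifnot(!is.null(shape), length(shape) == 3)
  factor <- as.integer(cfg$downsample_factors[[cut_point]] %||% 1L)
  xd <- if (factor > 1L) flat_down_op(shape, factor) %*% acts else acts
  mu <- rowMeans(xd)
  S <- cov(t(xd))
  jit <- cfg$covariance_jitter * mean(diag(S))
  if (!is.finite(jit) || jit <= 0) jit <- cfg$covariance_jitter
  S <- S + diag(jit, nrow(S))
  down_shape <- c(ceiling(shape[1] / factor), ceiling(shape[2] / factor),
                  shape[3])
  structure(list(mean = mu, covariance = S,
                 spatial_shape = as.integer(down_shape),
                 layer_shape = as.integer(shape),
                 downsample_factor = factor,
                 n_fit = ncol(acts),
                 class_id = as.integer(class_id),
                 cut_point = cut_point),
            class = "activation_distribution")
}

#' Sample novel replay representations from a fitted distribution
#'
#' Draws `n` independent multivariate-normal samples (one Cholesky
#' factorisation per call, then n matrix-vector products), reshapes them to
#' the downsampled spatial shape, and upsamples back to the full layer
#' resolution by nearest-neighbour replication. These are the "imagined"
#' prototype representations used for generative replay.
#'
#' @param dist An `"activation_distribution"`.
#' @param n Number of samples (>= 1).
#' @param clip_nonnegative Clamp samples at zero before upsampling.
#' @return A `"replay_batch"`: list with `x` (d x n matrix at full layer
#'   resolution), `shape`, `labels`, `provenance = "generative"`.
#' @export
sample_distribution <- function(dist, n, clip_nonnegative = FALSE) {
  stopifnot(inherits(dist, "activation_distribution"))
  n <- assert_scalar_int(n, "n")
  d <- length(dist$mean)
  L <- tryCatch(chol(dist$covariance), error = function(e) {
    jit <- 1e-8 * mean(diag(dist$covariance))
    tryCatch(chol(dist$covariance + diag(jit * 100, d)), error = function(e2) {
      stop(sprintf(paste0("covariance for class %d at %s is not positive ",
                          "definite even after regularization: %s"),
                   dist$class_id, dist$cut_point, conditionMessage(e2)),
           call. = FALSE)
    })
  })
  z <- matrix(rnorm(d * n), d, n)
  xs <- crossprod(L, z) + dist$mean
  if (clip_nonnegative) xs[xs < 0] <- 0
  if (dist$downsample_factor > 1L) {
    up <- flat_up_op(dist$layer_shape, dist$downsample_factor)
    xs <- up %*% xs
  }
  structure(list(x = xs, shape = dist$layer_shape,
                 labels = rep(dist$class_id, n),
                 provenance = "generative"),
            class = "replay_batch")
}

#' Capture veridical replay buffers
#'
#' Stores the exact activations of every image of a split at the cut point,
#' at full layer resolution (no downsampling) - replay of each individual
#' experience as it happened.
#'
#' @inheritParams activations_at
#' @return A `"replay_batch"` with `provenance = "veridical"`.
#' @export
capture_veridical <- function(model, cut_point, bundle, split = "train") {
  acts <- activations_at(model, cut_point, bundle, split)
  structure(list(x = acts, shape = attr(acts, "shape"),
                 labels = bundle_labels(bundle, split),
                 provenance = "veridical"),
            class = "replay_batch")
}

#' @export
print.replay_batch <- function(x, ...) {
  cat(sprintf("<replay_batch> %s, %d samples of %s\n", x$provenance,
              ncol(x$x), paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Run one night of replay training
#'
#' Truncates the model at the cut point, trains the head for one epoch on
#' the pooled replay samples (shuffled minibatches, same optimizer settings
#' as day training, dropout active, fresh Adam state for the night), and
#' reattaches the head. Weights at or before the cut are untouched by
#' construction; head weights persist into the next day.
#'
#' @param model A `"layered_classifier"`.
#' @param cut_point Pooling-layer id.
#' @param batches A `"replay_batch"` or list of them (e.g. one per class).
#' @param opt An [optimizer_config()].
#' @return `list(model = updated classifier, loss = mean replay loss)`.
#' @export
replay_night <- function(model, cut_point, batches, opt = optimizer_config()) {
  if (inherits(batches, "replay_batch")) batches <- list(batches)
  shape <- cut_shape(model, cut_point)
  for (b in batches) {
    if (!identical(as.integer(b$shape), as.integer(shape))) {
      stop("replay batch shape does not match the cut layer", call. = FALSE)
    }
  }
  x <- do.call(cbind, lapply(batches, `[[`, "x"))
  labels <- unlist(lapply(batches, `[[`, "labels"))
  head <- truncate_at(model, cut_point)
  res <- head_train_epoch(head, x, labels, opt)
  list(model = reattach(model, res$head), loss = res$loss)
}

#' Save or load a set of activation distributions
#'
#' Round-trips a list of `"activation_distribution"` records bit-exactly
#' through a single RDS archive.
#'
#' @param dists List of distributions.
#' @param path File path.
#' @export
save_distributions <- function(dists, path) {
  saveRDS(dists, path)
  invisible(path)
}

#' @rdname save_distributions
#' @export
load_distributions <- function(path) {
  dists <- readRDS(path)
  stopifnot(all(vapply(dists, inherits, logical(1), "activation_distribution")))
  dists
}

#' Fit one activation distribution per class
#'
#' Splits a single activation capture by class label and fits a
#' [fit_class_distribution()] for each class present.
#'
#' @param acts Activation matrix with `shape` attribute from
#'   [activations_at()].
#' @param labels Integer class labels, one per column of `acts`.
#' @param cut_point Pooling-layer id.
#' @param cfg A [replay_config()].
#' @return List of `"activation_distribution"`, ordered by class id.
#' @export
fit_all_classes <- function(acts, labels, cut_point, cfg = replay_config()) {
  shape <- attr(acts, "shape")
  lapply(sort(unique(labels)), function(cl) {
    a <- acts[, labels == cl, drop = FALSE]
    attr(a, "shape") <- shape
    fit_class_distribution(a, cl, cut_point, cfg)
  })
}
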