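# Training, evaluation, activation capture, and truncation.

#' Optimizer configuration
#'
#' Adam with categorical cross-entropy, the training setup used for both
#' daytime image learning and nighttime replay. Defaults: learning rate
#' 3e-4 (a deliberately small step, treating category learning as fine
#' tuning of an already capable visual system) and minibatch size 36.
#'
#' @param learning_rate Positive step size.
#' @param batch_size Minibatch size (>= 1). The final partial batch of an
#'   epoch is kept, not dropped.
#' @return An object of class `"optimizer_config"`.
#' @export
optimizer_config <- function(learning_rate = 3e-4, batch_size = 36L) {
  stopifnot(length(learning_rate) == 1, learning_rate >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = assert_scalar_int(batch_size, "batch_size")),
            class = "optimizer_config")
}

# Centering vector for a flattened image batch: per-channel mean subtraction.
center_input <- function(x, dim, means) {
  if (is.null(means)) return(x)
  x - rep(means, each = dim[1] * dim[2])
}

# Forward pass in chunks (bounds im2col memory); returns n_outputs x n probs.
forward_probs <- function(layers, x, chunk = 128L) {
  n <- ncol(x)
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    p <- net_forward_cpp(layers, x[, idx, drop = FALSE])
    if (is.null(out)) out <- matrix(0, nrow(p), n)
    out[, idx] <- p
  }
  out
}

#' Run one training epoch
#'
#' One full pass over the training split in shuffled minibatches: every image
#' is augmented once (fresh transform draws per epoch), inputs are centered by
#' the bundle's per-channel training means, and Adam minimises the categorical
#' cross-entropy. Adam moments persist in the model across epochs. All
#' randomness (augmentation draws, shuffling, dropout masks) comes from R's
#' global RNG, so runs are reproducible under `set.seed()`.
#'
#' @param model A [build_model()] classifier.
#' @param bundle A [build_dataset()] bundle (or any bundle-like list).
#' @param opt An [optimizer_config()].
#' @param aug An [augment_config()], or `NULL` to train on raw images.
#' @param split Split to train on (default `"train"`).
#' @param center Subtract the bundle's per-channel training means.
#' @return `list(model = updated classifier, loss = mean epoch loss)`.
#' @export
train_epoch <- function(model, bundle, opt = optimizer_config(),
                        aug = augment_config(), split = "train",
                        center = TRUE) {
  x <- bundle_images(bundle, split)
  y <- bundle_labels(bundle, split)
  if (ncol(x) == 0) stop(sprintf("split '%s' is empty", split), call. = FALSE)
  if (!is.null(aug)) {
    x <- augment_matrix(x, bundle$dim, aug)
  }
  if (center) x <- center_input(x, bundle$dim, bundle$channel_means)
  ord <- sample.int(ncol(x)) - 1L
  res <- net_train_epoch_cpp(model$layers, x, as.integer(y) - 1L,
                             model$opt_state %||% list(),
                             opt$learning_rate, opt$batch_size, ord,
                             model$spec$n_outputs)
  model$layers <- res$layers
  model$opt_state <- res$adam
  list(model = model, loss = res$loss)
}

#' Evaluate generalization performance
#'
#' Deterministic evaluation on a held-out split: dropout inactive, no
#' augmentation. Reports overall accuracy together with per-class correct
#' and total counts (the inputs to the scheduler's chi-square reward).
#'
#' @inheritParams train_epoch
#' @param split `"val"` or `"test"` (any nonempty split is accepted).
#' @return An `"eval_report"`: list with `overall_accuracy`,
#'   `per_class_accuracy`, `per_class_correct`, `per_class_total`,
#'   `predictions`, and `split`.
#' @export
evaluate <- function(model, bundle, split = "test", center = TRUE) {
  x <- bundle_images(bundle, split)
  y <- bundle_labels(bundle, split)
  if (ncol(x) == 0) stop(sprintf("split '%s' is empty", split), call. = FALSE)
  if (center) x <- center_input(x, bundle$dim, bundle$channel_means)
  probs <- forward_probs(model$layers, x)
  pred <- max.col(t(probs), ties.method = "first")
  report_from_predictions(pred, y, model$spec$n_outputs, split)
}

report_from_predictions <- function(pred, y, n_classes, split) {
  total <- tabulate(y, nbins = n_classes)
  correct <- tabulate(y[pred == y], nbins = n_classes)
  structure(list(overall_accuracy = sum(correct) / sum(total),
                 per_class_accuracy = ifelse(total > 0, correct / total, NA_real_),
                 per_class_correct = correct,
                 per_class_total = total,
                 predictions = pred,
                 split = split),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split=%s overall=%.3f (n=%d)\n",
              x$split, x$overall_accuracy, sum(x$per_class_total)))
  invisible(x)
}

#' Capture layer activations at a replay cut point
#'
#' Runs the network forward (dropout inactive) up to the pooling layer named
#' by `cut_point` and returns the activations. Inputs are centered exactly as
#' in training so captured activations match what the head sees.
#'
#' @inheritParams train_epoch
#' @param cut_point Pooling-layer id, `"pool_1"` ... `"pool_5"`.
#' @param x Optional raw image matrix (d x n, flattened column per image);
#'   when supplied, `bundle`/`split` are only used for centering means.
#' @return A d x n matrix of activations with attribute `shape = c(h, w, c)`,
#'   columns flattened in `(h, w, c)` array order.
#' @export
activations_at <- function(model, cut_point, bundle, split = "train",
                           x = NULL, center = TRUE) {
  idx <- cut_index(model, cut_point)
  if (is.null(x)) {
    x <- bundle_images(bundle, split)
    if (ncol(x) == 0) stop(sprintf("split '%s' is empty", split), call. = FALSE)
  }
  if (center) x <- center_input(x, bundle$dim, bundle$channel_means)
  n <- ncol(x)
  out <- NULL
  for (start in seq(1L, n, by = 128L)) {
    cols <- start:min(n, start + 127L)
    a <- net_activations_cpp(model$layers, x[, cols, drop = FALSE], idx)
    if (is.null(out)) out <- matrix(0, nrow(a), n)
    out[, cols] <- a
  }
  attr(out, "shape") <- cut_shape(model, cut_point)
  out
}

#' Truncate a classifier at a replay cut point
#'
#' Returns the "head": all layers strictly after the named pooling layer,
#' accepting flattened activation arrays of that layer's output shape.
#' Training the head and calling [reattach()] writes the trained head layers
#' back into the parent, leaving every layer at or before the cut untouched.
#'
#' @inheritParams activations_at
#' @return An object of class `"truncated_head"`.
#' @export
truncate_at <- function(model, cut_point) {
  idx <- cut_index(model, cut_point)
  structure(list(layers = model$layers[(idx + 1L):length(model$layers)],
                 cut_point = cut_point,
                 cut_index = idx,
                 input_shape = cut_shape(model, cut_point),
                 n_outputs = model$spec$n_outputs,
                 opt_state = NULL),
            class = "truncated_head")
}

#' @rdname truncate_at
#' @param head A `"truncated_head"` previously produced by [truncate_at()]
#'   from the same model.
#' @export
reattach <- function(model, head) {
  stopifnot(inherits(head, "truncated_head"))
  idx <- head$cut_index
  if (!identical(cut_shape(model, head$cut_point), head$input_shape)) {
    stop("head does not match the model's cut layer shape", call. = FALSE)
  }
  model$layers[(idx + 1L):length(model$layers)] <- head$layers
  model
}

# Head forward on activation inputs (d x n matrix), eval mode.
head_forward <- function(head, x) {
  forward_probs(head$layers, x)
}

# One epoch of head training on activation inputs. Adam state persists on
# the head object across calls (fresh when head$opt_state is NULL).
head_train_epoch <- function(head, x, labels, opt, shuffle = TRUE) {
  if (nrow(x) != prod(head$input_shape)) {
    stop("replay batch shape does not match the cut layer", call. = FALSE)
  }
  ord <- if (shuffle) sample.int(ncol(x)) - 1L else seq_len(ncol(x)) - 1L
  res <- net_train_epoch_cpp(head$layers, x, as.integer(labels) - 1L,
                             head$opt_state %||% list(),
                             opt$learning_rate, opt$batch_size, ord,
                             head$n_outputs)
  head$layers <- res$layers
  head$opt_state <- res$adam
  list(head = head, loss = res$loss)
}

# Per-class correct/total counts from a head evaluated on cached activations.
head_counts <- function(head, acts, labels, n_classes) {
  pred <- max.col(t(head_forward(head, acts)), ties.method = "first")
  list(correct = tabulate(labels[pred == labels], nbins = n_classes),
       total = tabulate(labels, nbins = n_classes))
}
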