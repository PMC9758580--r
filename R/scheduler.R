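# Reinforcement-learning replay scheduler (the "hippocampal" side network).
#
# The side network is a bias-free linear regression with one input per class
# and one output, the predicted value of replaying that class. Classes are
# drawn from a softmax over the weights; after each replay the weight of the
# chosen class is trained (Adam, MSE) toward the observed reward: the
# reduction in a chi-square gap between perfect and observed classification
# on the validation set. Because inputs are one-hot and there is no bias,
# each update moves only the chosen class's weight.

#' Chi-square gap between perfect and observed classification
#'
#' Pearson chi-square statistic with perfect prediction as the expectation:
#' `sum((total_c - correct_c)^2 / total_c)`. Zero exactly when every item is
#' classified correctly; strictly decreases when any class's correct count
#' rises with totals fixed. Its reduction after a replay is the scheduler's
#' reward.
#'
#' @param per_class_correct,per_class_total Integer vectors,
#'   `0 <= correct_c <= total_c`, `total_c > 0`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' chi_square_gap(c(5, 10), c(10, 10))  # 2.5
chi_square_gap <- function(per_class_correct, per_class_total) {
  stopifnot(length(per_class_correct) == length(per_class_total))
  if (any(per_class_total <= 0)) {
    stop("all per-class totals must be positive", call. = FALSE)
  }
  if (any(per_class_correct < 0 | per_class_correct > per_class_total)) {
    stop("correct counts must lie in [0, total]", call. = FALSE)
  }
  sum((per_class_total - per_class_correct)^2 / per_class_total)
}

#' Create a replay scheduler state
#'
#' @param n_classes Number of classes.
#' @param side_lr Learning rate of the side network (default 0.001).
#' @param side_epochs Gradient steps per reward observation (default 50).
#' @param temperature Softmax temperature for class selection.
#' @param mode `"online"` (default) trains on the most recent
#'   (one-hot, reward) pair only, so a class's value tracks its latest
#'   reward; `"buffer"` trains on all logged pairs, so values estimate each
#'   class's mean reward over the whole history.
#' @return A `"scheduler_state"` with zero values, uninitialised.
#' @export
scheduler_state <- function(n_classes, side_lr = 0.001, side_epochs = 50L,
                            temperature = 1, mode = c("online", "buffer")) {
  n_classes <- assert_scalar_int(n_classes, "n_classes")
  structure(list(class_values = numeric(n_classes),
                 side_lr = side_lr,
                 side_epochs = assert_scalar_int(side_epochs, "side_epochs"),
                 temperature = temperature,
                 mode = match.arg(mode),
                 adam = list(m = numeric(n_classes), v = numeric(n_classes),
                             t = integer(n_classes)),
                 selection_log = data.frame(step = integer(0),
                                            class_id = integer(0),
                                            reward = numeric(0)),
                 initialized = FALSE),
            class = "scheduler_state")
}

#' Class-selection probabilities
#'
#' Softmax over the side network's class values; strictly positive and
#' summing to one.
#'
#' @param state A `"scheduler_state"`.
#' @return Probability vector of length `n_classes`.
#' @export
selection_probabilities <- function(state) {
  v <- state$class_values / state$temperature
  e <- exp(v - max(v))
  e / sum(e)
}

#' Select the next class to replay
#'
#' Draws one class id from the softmax over learned values.
#'
#' @param state An initialised `"scheduler_state"`.
#' @return Integer class id.
#' @export
select_class <- function(state) {
  if (!isTRUE(state$initialized)) {
    stop("scheduler state is not initialized; run initialize_values() first",
         call. = FALSE)
  }
  sample.int(length(state$class_values), 1L,
             prob = selection_probabilities(state))
}

#' Update the scheduler after an observed reward
#'
#' Trains the side network for `side_epochs` full-batch Adam steps (MSE
#' loss). In `"online"` mode the training set is the single newest pair
#' one-hot(chosen) -> reward: with one-hot input and no bias the gradient is
#' nonzero only for the chosen class, whose weight moves toward the reward,
#' and Adam moments for that weight persist across updates. In `"buffer"`
#' mode the training set is every logged pair, so each class's weight moves
#' toward the mean reward that class has produced so far.
#'
#' @param state A `"scheduler_state"`.
#' @param chosen Class id that was replayed.
#' @param reward Observed chi-square reduction (finite).
#' @return The updated state (reward appended to the selection log).
#' @export
update_scheduler <- function(state, chosen, reward) {
  chosen <- assert_scalar_int(chosen, "chosen")
  if (chosen > length(state$class_values)) {
    stop("invalid class id", call. = FALSE)
  }
  if (!is.finite(reward)) stop("reward must be finite", call. = FALSE)
  state$selection_log <- rbind(state$selection_log,
                               data.frame(step = nrow(state$selection_log) + 1L,
                                          class_id = chosen, reward = reward))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  if (identical(state$mode %||% "online", "online")) {
    active <- chosen
    # gradient of (w_c - reward)^2 at the newest pair only
    grad_of <- function(w) 2 * (w[chosen] - reward)
  } else {
    lg <- state$selection_log
    active <- sort(unique(lg$class_id))
    targets <- vapply(active, function(cl) mean(lg$reward[lg$class_id == cl]),
                      numeric(1))
    counts <- vapply(active, function(cl) sum(lg$class_id == cl), numeric(1))
    # full-batch MSE gradient over all logged one-hot pairs
    grad_of <- function(w) 2 * counts * (w[active] - targets) / nrow(lg)
  }
  w <- state$class_values
  m <- state$adam$m[active]; v <- state$adam$v[active]
  t <- state$adam$t[active]
  for (i in seq_len(state$side_epochs)) {
    t <- t + 1L
    g <- grad_of(w)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    w[active] <- w[active] - state$side_lr * mhat / (sqrt(vhat) + eps)
  }
  state$class_values <- w
  state$adam$m[active] <- m
  state$adam$v[active] <- v
  state$adam$t[active] <- t
  state
}

# chi-square gap of a head evaluated on cached cut-point activations
head_chi2 <- function(head, acts, labels, n_classes) {
  cnt <- head_counts(head, acts, labels, n_classes)
  chi_square_gap(cnt$correct, cnt$total)
}

#' Initialise side-network values
#'
#' Replays one minibatch of each class through the truncated main network
#' and sets that class's initial value to the chi-square reduction it
#' produces on the validation split. Each class is probed from the same
#' starting head state (the probe updates are measurements, discarded
#' afterwards), so the initial values are comparable headroom estimates
#' rather than artefacts of the probing order; the returned model is
#' unchanged.
#'
#' @param model A `"layered_classifier"`.
#' @param distributions One fitted `"activation_distribution"` per class.
#' @param bundle Dataset bundle supplying the validation split.
#' @param state A fresh [scheduler_state()].
#' @param cut_point Pooling-layer id where replay is implemented.
#' @param opt An [optimizer_config()]; `batch_size` items are sampled per
#'   class.
#' @details In `"online"` mode the probe rewards become the initial values
#'   directly. In `"buffer"` mode they are logged as the first reward
#'   observations of each class and the side network is trained on them, so
#'   initial values start at the network's own estimates and every later
#'   night reward revises the class's running mean on equal footing.
#' @return `list(state = initialised state, model = the input classifier)`.
#' @export
initialize_values <- function(model, distributions, bundle, state,
                              cut_point = "pool_4",
                              opt = optimizer_config()) {
  C <- length(state$class_values)
  if (length(distributions) != C) {
    stop("need one fitted distribution per class", call. = FALSE)
  }
  va <- activations_at(model, cut_point, bundle, "val")
  vy <- bundle_labels(bundle, "val")
  head0 <- truncate_at(model, cut_point)
  chi0 <- head_chi2(head0, va, vy, C)
  for (cl in seq_len(C)) {
    batch <- sample_distribution(distributions[[cl]], opt$batch_size)
    probe <- head_train_epoch(head0, batch$x, batch$labels, opt)$head
    reward <- chi0 - head_chi2(probe, va, vy, C)
    if (identical(state$mode %||% "online", "buffer")) {
      state <- update_scheduler(state, cl, reward)
    } else {
      state$class_values[cl] <- reward
    }
  }
  state$initialized <- TRUE
  list(state = state, model = model)
}

#' Run one night of reinforcement-learning-scheduled replay
#'
#' Loops `n_steps` times: select a class from the softmax, sample one
#' generative minibatch for it, replay it through the truncated network
#' (one Adam step), measure the chi-square change on the validation split,
#' and update the scheduler with that reward. Validation activations at the
#' cut are computed once per night (replay only changes the head, so they
#' are constant throughout the night).
#'
#' @inheritParams initialize_values
#' @param n_steps Number of select-replay-update iterations (>= 1).
#' @return `list(model, state, selection_counts, chi2)` where
#'   `selection_counts` sums to `n_steps`.
#' @export
rl_replay_night <- function(model, state, distributions, bundle,
                            n_steps, cut_point = "pool_4",
                            opt = optimizer_config()) {
  n_steps <- assert_scalar_int(n_steps, "n_steps")
  C <- length(state$class_values)
  va <- activations_at(model, cut_point, bundle, "val")
  vy <- bundle_labels(bundle, "val")
  head <- truncate_at(model, cut_point)
  chi_before <- head_chi2(head, va, vy, C)
  counts <- integer(C)
  for (step in seq_len(n_steps)) {
    cl <- select_class(state)
    counts[cl] <- counts[cl] + 1L
    batch <- sample_distribution(distributions[[cl]], opt$batch_size)
    res <- head_train_epoch(head, batch$x, batch$labels, opt)
    head <- res$head
    chi_after <- head_chi2(head, va, vy, C)
    state <- update_scheduler(state, cl, chi_before - chi_after)
    chi_before <- chi_after
  }
  list(model = reattach(model, head), state = state,
       selection_counts = counts, chi2 = chi_before)
}

#' Serialise a scheduler state to JSON
#'
#' @param state A `"scheduler_state"`.
#' @param path Output file.
#' @export
save_scheduler <- function(state, path) {
  jsonlite::write_json(list(class_values = state$class_values,
                            side_lr = state$side_lr,
                            side_epochs = state$side_epochs,
                            temperature = state$temperature,
                            selection_log = state$selection_log),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
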