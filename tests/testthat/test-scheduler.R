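test_that("chi-square gap follows the Pearson form with perfect-prediction expectation", {
  # hand-summed oracles
  expect_equal(chi_square_gap(c(10, 10), c(10, 10)), 0)
  expect_equal(chi_square_gap(c(5, 10), c(10, 10)), (10 - 5)^2 / 10)
  expect_equal(chi_square_gap(0, 10), 10)
  # zero law: gap = 0 iff every item correct
  expect_gt(chi_square_gap(c(10, 9), c(10, 10)), 0)
  # strictly decreases when any correct count rises with totals fixed
  expect_lt(chi_square_gap(c(6, 10), c(10, 10)),
            chi_square_gap(c(5, 10), c(10, 10)))
  expect_error(chi_square_gap(c(1), c(0)), "positive")
  expect_error(chi_square_gap(c(11), c(10)), "correct")
})

test_that("selection probabilities are a softmax: positive, normalised, monotone", {
  st <- scheduler_state(10)
  expect_equal(selection_probabilities(st), rep(0.1, 10))
  st$class_values <- c(log(2), 0)
  st$adam <- list(m = numeric(2), v = numeric(2), t = integer(2))
  # closed-form softmax oracle
  expect_equal(selection_probabilities(st), c(2 / 3, 1 / 3))
  # monotone in the value
  p_of <- function(v) {
    st$class_values <- c(v, 0)
    selection_probabilities(st)[1]
  }
  expect_true(all(diff(vapply(seq(-2, 2, 0.5), p_of, numeric(1))) > 0))
  expect_equal(sum(selection_probabilities(st)), 1, tolerance = 1e-9)
})

test_that("class selection frequencies match the softmax within a 99% binomial band", {
  st <- scheduler_state(2)
  st$class_values <- c(log(2), 0)
  st$initialized <- TRUE
  set.seed(1)
  draws <- replicate(10000, select_class(st))
  n1 <- sum(draws == 1)
  band <- qbinom(c(0.005, 0.995), 10000, 2 / 3)
  expect_gte(n1, band[1])
  expect_lte(n1, band[2])
  expect_error(select_class(scheduler_state(2)), "initialized")
})

test_that("scheduler updates move only the chosen class and match the Adam recurrence", {
  st <- scheduler_state(3)
  st$initialized <- TRUE
  st2 <- update_scheduler(st, 2L, 0.8)
  expect_gt(st2$class_values[2], 0)
  expect_equal(st2$class_values[c(1, 3)], c(0, 0))
  # reward equal to the current predicted value: zero gradient, no movement
  same <- update_scheduler(st, 1L, 0)
  expect_equal(same$class_values[1], 0)
  # oracle: independent step-by-step Adam iteration on one weight
  adam_oracle <- function(w, r, lr, steps, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
    m <- v <- 0
    for (t in seq_len(steps)) {
      g <- 2 * (w - r)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      w <- w - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    }
    w
  }
  expect_equal(st2$class_values[2], adam_oracle(0, 0.8, 0.001, 50),
               tolerance = 1e-10)
  # moments persist across updates (second call continues the recurrence)
  st3 <- update_scheduler(st2, 2L, 0.8)
  expect_gt(st3$class_values[2], st2$class_values[2])
  expect_error(update_scheduler(st, 1L, NaN), "finite")
  expect_error(update_scheduler(st, 9L, 0.1), "class")
  # log is append-only
  expect_equal(st3$selection_log$class_id, c(2L, 2L))
})

test_that("initialization replays one batch per class and ranks a planted winner first", {
  b <- tiny_bundle(difficulty = 0.3)
  m <- build_model(tiny_spec(), init_seed = 1)
  set.seed(2)
  for (i in 1:2) m <- train_epoch(m, b)$model
  acts <- activations_at(m, "pool_2", b, "train")
  dists <- fit_all_classes(acts, bundle_labels(b, "train"), "pool_2")
  st <- scheduler_state(3)
  set.seed(3)
  ini <- initialize_values(m, dists, b, st, "pool_2",
                           optimizer_config(batch_size = 36))
  expect_true(ini$state$initialized)
  expect_length(ini$state$class_values, 3)
  # probes are measurements: the model is unchanged
  expect_identical(ini$model$layers, m$layers)
  expect_error(initialize_values(m, dists[1:2], b, st, "pool_2"), "per class")
})

test_that("a mock learner concentrates selections on the weakest class", {
  # oracle: if replaying class c only ever improves class c, softmax values
  # grow fastest for the class with most headroom (lowest starting accuracy)
  C <- 3
  st <- scheduler_state(C)
  st$initialized <- TRUE
  correct <- c(2, 9, 10); total <- rep(10, C)
  set.seed(4)
  counts <- integer(C)
  for (step in 1:300) {
    cl <- select_class(st)
    counts[cl] <- counts[cl] + 1L
    chi_before <- chi_square_gap(correct, total)
    correct[cl] <- min(correct[cl] + 1, total[cl])  # replay improves only cl
    chi_after <- chi_square_gap(correct, total)
    st <- update_scheduler(st, cl, chi_before - chi_after)
    correct[cl] <- max(correct[cl] - 1, 0)  # learner forgets (keeps rewards flowing)
  }
  expect_equal(sum(counts), 300)
  expect_equal(which.max(counts), 1L)
  expect_equal(sum(st$selection_log$step == seq_len(300)), 300)
})

test_that("rl nights conserve selection counts and spare upstream weights", {
  b <- tiny_bundle(difficulty = 0.3)
  m <- build_model(tiny_spec(), init_seed = 5)
  set.seed(6)
  m <- train_epoch(m, b)$model
  cp <- "pool_2"
  acts <- activations_at(m, cp, b, "train")
  dists <- fit_all_classes(acts, bundle_labels(b, "train"), cp)
  st <- scheduler_state(3)
  set.seed(7)
  st <- initialize_values(m, dists, b, st, cp)$state
  before <- weights_digest(m, m$cut_points[[cp]])
  set.seed(8)
  night <- rl_replay_night(m, st, dists, b, n_steps = 7, cut_point = cp,
                           opt = optimizer_config(batch_size = 12))
  expect_equal(sum(night$selection_counts), 7)
  expect_identical(weights_digest(night$model, m$cut_points[[cp]]), before)
  expect_equal(nrow(night$state$selection_log) -
                 nrow(st$selection_log), 7)
  # reward sign correctness: reward > 0 exactly when chi-square dropped
  rewards <- utils::tail(night$state$selection_log$reward, 7)
  expect_true(all(is.finite(rewards)))
})

test_that("scheduler state serialises to JSON", {
  st <- scheduler_state(4)
  st <- update_scheduler(st, 1L, 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  save_scheduler(st, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$class_values, st$class_values)
  expect_equal(back$side_epochs, 50)
})
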