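test_that("block-mean downsampling matches the brute-force oracle", {
  # 4x4 map with entries 1..16 row-major, factor 2
  a <- array(0, c(4, 4, 1))
  a[, , 1] <- matrix(1:16, 4, 4, byrow = TRUE)
  got <- downsample_activations(a, 2)
  expect_equal(got[, , 1], matrix(c(3.5, 11.5, 5.5, 13.5), 2, 2))
  # brute-force block averaging oracle on a random map
  set.seed(1)
  b <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  got <- downsample_activations(b, 4)
  for (ch in 1:3) {
    for (i in 1:2) for (j in 1:2) {
      expect_equal(got[i, j, ch],
                   mean(b[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), ch]))
    }
  }
  # constant maps stay constant; shape contract at factor 8
  cst <- array(2.5, c(32, 32, 8))
  expect_equal(unique(as.vector(downsample_activations(cst, 8))), 2.5)
  expect_equal(dim(downsample_activations(cst, 8)), c(4, 4, 8))
  expect_error(downsample_activations(cst, 64), "factor")
})

test_that("upsampling replicates blocks and inverts downsampling exactly", {
  set.seed(2)
  a <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  expect_identical(upsample_activations(a, 1), a)
  up <- upsample_activations(a, 8)
  expect_equal(dim(up), c(32, 32, 2))
  # 8x8 constant blocks
  expect_equal(up[1:8, 1:8, 1], matrix(a[1, 1, 1], 8, 8))
  # round trip: downsample(upsample(x, f), f) == x
  expect_equal(downsample_activations(up, 8), a, tolerance = 1e-12)
})

test_that("fitting recovers distribution moments and degenerate cases", {
  cfg <- replay_config(covariance_jitter = 1e-9)
  # identical arrays: mean equals the array, covariance ~ jitter * I
  x <- matrix(rep(c(1, 2, 3, 4), 6), 4, 6)
  attr(x, "shape") <- c(2L, 2L, 1L)
  d <- fit_class_distribution(x, 1L, "pool_5", cfg)
  expect_equal(d$mean, c(1, 2, 3, 4))
  expect_equal(d$covariance, diag(1e-9, 4), tolerance = 1e-12)
  expect_equal(d$n_fit, 6L)
  expect_error(fit_class_distribution(x[, 1, drop = FALSE], 1L, "pool_5", cfg),
               "at least 2")
  # oracle: known diagonal gaussian, 2000 draws as 2x2x1 maps (factor 1)
  mu <- c(1, -2, 0.5, 3)
  sd_true <- c(0.5, 1, 1.5, 2)
  set.seed(11)
  xs <- matrix(rnorm(4 * 2000, mu, sd_true), 4, 2000)
  attr(xs, "shape") <- c(2L, 2L, 1L)
  d <- fit_class_distribution(xs, 2L, "pool_5", cfg)
  expect_lt(max(abs(d$mean - mu)), 0.1)
  expect_lt(max(abs(diag(d$covariance) / sd_true^2 - 1)), 0.15)
})

test_that("sampling reproduces stored moments within Monte-Carlo tolerance", {
  mu <- c(0.5, -1, 2, 0)
  S <- diag(c(0.2, 0.5, 1, 2))
  S[1, 2] <- S[2, 1] <- 0.15
  dist <- structure(list(mean = mu, covariance = S,
                         spatial_shape = c(2L, 2L, 1L),
                         layer_shape = c(2L, 2L, 1L),
                         downsample_factor = 1L, n_fit = 100L,
                         class_id = 1L, cut_point = "pool_5"),
                    class = "activation_distribution")
  set.seed(5)
  batch <- sample_distribution(dist, 10000)
  expect_equal(ncol(batch$x), 10000)
  expect_equal(batch$provenance, "generative")
  expect_true(all(batch$labels == 1L))
  # 3 standard errors on the mean; variances within a few percent
  se <- sqrt(diag(S) / 10000)
  expect_true(all(abs(rowMeans(batch$x) - mu) < 3 * se))
  emp <- cov(t(batch$x))
  expect_lt(max(abs(diag(emp) - diag(S)) / diag(S)), 0.1)
  expect_equal(emp[1, 2], 0.15, tolerance = 0.05)
  # degenerate: jitter-only covariance collapses onto the mean map
  dist$covariance <- diag(1e-18, 4)
  set.seed(6)
  tight <- sample_distribution(dist, 50)
  expect_lt(max(abs(tight$x - mu)), 1e-6)
})

test_that("fit -> sample -> refit round trip recovers the distribution", {
  b <- tiny_bundle()
  m <- build_model(tiny_spec(), init_seed = 1)
  acts <- activations_at(m, "pool_2", b, "train")  # 4x4x6 maps
  cfg <- replay_config()
  d <- fit_class_distribution(acts, 1L, "pool_2", cfg)  # factor 4 -> d = 6
  set.seed(7)
  batch <- sample_distribution(d, 5000)
  expect_equal(dim(batch$x), c(4 * 4 * 6, 5000))
  # refit from the samples (downsampling the upsampled draws is lossless)
  attr(batch$x, "shape") <- batch$shape
  d2 <- fit_class_distribution(batch$x, 1L, "pool_2", cfg)
  se <- sqrt(diag(d$covariance) / 5000)
  expect_true(all(abs(d2$mean - d$mean) < 3 * se))
  expect_lt(max(abs(diag(d2$covariance) / diag(d$covariance) - 1)), 0.2)
})

test_that("one distribution is fitted per class at a cut point", {
  b <- tiny_bundle()
  m <- build_model(tiny_spec(), init_seed = 1)
  acts <- activations_at(m, "pool_2", b, "train")
  dists <- fit_all_classes(acts, bundle_labels(b, "train"), "pool_2")
  expect_length(dists, 3)
  expect_equal(vapply(dists, `[[`, integer(1), "class_id"), 1:3)
  expect_true(all(vapply(dists, `[[`, integer(1), "n_fit") == 12L))
  # covariance symmetric PSD-after-jitter
  ev <- eigen(dists[[1]]$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("veridical capture stores exact full-resolution activations", {
  b <- tiny_bundle()
  m <- build_model(tiny_spec(), init_seed = 2)
  batch <- capture_veridical(m, "pool_2", b, "train")
  expect_equal(batch$provenance, "veridical")
  expect_equal(ncol(batch$x), 36)
  acts <- activations_at(m, "pool_2", b, "train")
  expect_equal(unname(batch$x), unname(acts), ignore_attr = TRUE)
  # head forward on the veridical batch reproduces full-network probabilities
  head <- truncate_at(m, "pool_2")
  x <- bundle_images(b, "train")
  xc <- x - rep(b$channel_means, each = 16 * 16)
  expect_equal(replaysim:::head_forward(head, batch$x),
               replaysim:::forward_probs(m$layers, xc), tolerance = 1e-5)
})

test_that("replay nights train the head, spare the base, and lower replay loss", {
  b <- tiny_bundle(difficulty = 0.2)
  m <- build_model(tiny_spec(), init_seed = 1)
  set.seed(3)
  for (i in 1:2) m <- train_epoch(m, b)$model
  cp <- "pool_2"
  acts <- activations_at(m, cp, b, "train")
  dists <- fit_all_classes(acts, bundle_labels(b, "train"), cp)
  set.seed(4)
  batches <- lapply(dists, sample_distribution, n = 24)
  # lr = 0: model unchanged
  frozen <- replay_night(m, cp, batches, optimizer_config(learning_rate = 0))
  expect_identical(frozen$model$layers, m$layers)
  # upstream weights bit-identical before/after a real night
  before <- weights_digest(m, m$cut_points[[cp]])
  set.seed(5)
  night1 <- replay_night(m, cp, batches, optimizer_config())
  expect_identical(weights_digest(night1$model, m$cut_points[[cp]]), before)
  # repeated nights on the same separable batches reduce the replay loss
  set.seed(6)
  mm <- night1$model
  for (i in 1:5) {
    rn <- replay_night(mm, cp, batches, optimizer_config())
    mm <- rn$model
  }
  expect_lt(rn$loss, night1$loss)
  # shape mismatch is rejected
  expect_error(replay_night(m, "pool_1", batches), "shape")
})

test_that("distribution archives round-trip bit-exactly", {
  b <- tiny_bundle()
  m <- build_model(tiny_spec(), init_seed = 1)
  acts <- activations_at(m, "pool_1", b, "train")
  dists <- fit_all_classes(acts, bundle_labels(b, "train"), "pool_1")
  path <- withr::local_tempfile(fileext = ".rds")
  save_distributions(dists, path)
  expect_identical(load_distributions(path), dists)
})
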