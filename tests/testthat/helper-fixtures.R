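# Shared fixtures: tiny nets and tiny datasets, built in code.

# A very small 2-block classifier on 16x16x3 input (fast to train).
tiny_spec <- function(n_outputs = 3L) {
  arch_spec("mini", n_outputs = n_outputs, input_shape = c(16L, 16L, 3L),
            blocks = list(c(1L, 4L), c(1L, 6L)), head = c(16L))
}

# Tiny 3-class dataset: 12 train / 4 val / 4 test per class, 16x16.
tiny_bundle <- function(seed = 1L, n_classes = 3L, difficulty = 0.5) {
  protos <- generate_prototypes(n_classes, seed = seed,
                                difficulty_profile = rep(difficulty, n_classes))
  build_dataset(protos, 12L, 4L, 4L, size = c(16L, 16L), seed = seed)
}

# Deterministic mock counts for scheduler tests.
perfect_counts <- function(C, n_per_class) {
  list(correct = rep(n_per_class, C), total = rep(n_per_class, C))
}

# Reference softmax for oracle checks.
ref_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Reference cross-entropy loss of a model on a split (eval-mode forward).
model_loss <- function(model, bundle, split = "train") {
  x <- bundle_images(bundle, split)
  x <- x - rep(bundle$channel_means, each = bundle$dim[1] * bundle$dim[2])
  y <- bundle_labels(bundle, split)
  p <- replaysim:::forward_probs(model$layers, x)
  -mean(log(pmax(p[cbind(y, seq_along(y))], 1e-12)))
}

# Hash of all weights at or before a cut point (frozenness checks).
weights_digest <- function(model, upto_index) {
  unlist(lapply(model$layers[seq_len(upto_index)], function(L) {
    if (L$type %in% c("conv", "dense")) c(L$W, L$b) else numeric(0)
  }))
}
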