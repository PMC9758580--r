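# Architecture description and model construction.
#
# A network is a flat list of layer descriptors consumed by the C++ core:
#   conv    3x3, stride 1, 'same' zero padding, ReLU; fields W (Cout x 9*Cin),
#           b, and the input spatial dims h, w, c
#   pool    2x2 max pooling, stride 2
#   dense   fully connected; act = "relu" or "softmax"
#   dropout inverted dropout, active only during training
# Each convolutional block is a run of conv layers ended by exactly one pool;
# those pools (pool_1, pool_2, ...) are the only legal replay cut points.

#' Describe a layered classifier architecture
#'
#' Builds an architecture specification: an ordered list of convolutional
#' blocks (each `n_conv` 3x3 convolution layers with `n_filters` filters,
#' ended by one 2x2 max-pooling layer), followed by a fully connected head
#' whose hidden layers are each followed by dropout (rate 0.5), and a
#' softmax output layer.
#'
#' Two presets are provided. `"mini"` is the desk-scale default: five blocks
#' of (1,6), (1,12), (1,24), (1,48), (2,48) convolution layers on 64x64x3
#' input with head widths (96, 96), preserving the five-block / five-cut-point
#' topology of the full-scale network at a size that trains in minutes on one
#' CPU. `"vgg16"` encodes the classical 16-layer configuration: blocks
#' (2,64), (2,128), (3,256), (3,512), (3,512) on 224x224x3 input, head
#' (4096, 4096), and 1,000 outputs by default (138,357,544 parameters).
#'
#' @param preset `"mini"` or `"vgg16"`.
#' @param n_outputs Number of classes (overrides the preset default; a
#'   transfer head typically uses 10).
#' @param input_shape Length-3 integer vector (H, W, channels).
#' @param blocks List of `c(n_conv, n_filters)` pairs (overrides preset).
#' @param head Integer vector of fully connected widths (overrides preset).
#' @param dropout_rate Dropout rate after each hidden dense layer.
#' @return An object of class `"arch_spec"`.
#' @export
#' @examples
#' spec <- arch_spec("mini", n_outputs = 10)
#' count_parameters(spec)
arch_spec <- function(preset = c("mini", "vgg16"), n_outputs = NULL,
                      input_shape = NULL, blocks = NULL, head = NULL,
                      dropout_rate = 0.5) {
  preset <- match.arg(preset)
  if (preset == "mini") {
    input_shape <- input_shape %||% c(64L, 64L, 3L)
    blocks <- blocks %||% list(c(1L, 6L), c(1L, 12L), c(1L, 24L),
                               c(1L, 48L), c(2L, 48L))
    head <- head %||% c(96L, 96L)
    n_outputs <- n_outputs %||% 10L
  } else {
    input_shape <- input_shape %||% c(224L, 224L, 3L)
    blocks <- blocks %||% list(c(2L, 64L), c(2L, 128L), c(3L, 256L),
                               c(3L, 512L), c(3L, 512L))
    head <- head %||% c(4096L, 4096L)
    n_outputs <- n_outputs %||% 1000L
  }
  stopifnot(length(input_shape) == 3, all(input_shape >= 1),
            length(blocks) >= 1, dropout_rate >= 0, dropout_rate < 1)
  h <- input_shape[1]; w <- input_shape[2]
  if (h %% 2^length(blocks) != 0 || w %% 2^length(blocks) != 0) {
    stop("input H and W must be divisible by 2^n_blocks", call. = FALSE)
  }
  structure(list(input_shape = as.integer(input_shape),
                 blocks = lapply(blocks, as.integer),
                 head = as.integer(head),
                 n_outputs = assert_scalar_int(n_outputs, "n_outputs"),
                 dropout_rate = dropout_rate,
                 preset = preset),
            class = "arch_spec")
}

# Expand an arch_spec into the flat layer skeleton (shapes, no weights).
# Returns list(layers, cut_points): cut_points maps "pool_k" to the index
# of the pooling layer ending block k.
spec_skeleton <- function(spec) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; c_in <- spec$input_shape[3]
  layers <- list(); cut_points <- integer(0)
  for (bi in seq_along(spec$blocks)) {
    blk <- spec$blocks[[bi]]
    for (ci in seq_len(blk[1])) {
      layers[[length(layers) + 1L]] <- list(type = "conv", h = h, w = w,
                                            c = c_in, cout = blk[2])
      c_in <- blk[2]
    }
    layers[[length(layers) + 1L]] <- list(type = "pool", h = h, w = w, c = c_in)
    cut_points[paste0("pool_", bi)] <- length(layers)
    h <- h %/% 2L; w <- w %/% 2L
  }
  d <- h * w * c_in
  for (width in spec$head) {
    layers[[length(layers) + 1L]] <- list(type = "dense", d_in = d,
                                          d_out = width, act = "relu")
    layers[[length(layers) + 1L]] <- list(type = "dropout",
                                          rate = spec$dropout_rate)
    d <- width
  }
  layers[[length(layers) + 1L]] <- list(type = "dense", d_in = d,
                                        d_out = spec$n_outputs, act = "softmax")
  list(layers = layers, cut_points = cut_points)
}

#' Count trainable parameters
#'
#' Exact number of weight and bias entries, either from the shape arithmetic
#' of an [arch_spec()] (no allocation) or by summing array lengths of a built
#' [build_model()] classifier. Both routes agree for any model.
#'
#' @param x An `"arch_spec"` or `"layered_classifier"`.
#' @return Integer-valued double: total parameter count.
#' @export
#' @examples
#' count_parameters(arch_spec("vgg16"))  # 138357544
count_parameters <- function(x) {
  if (inherits(x, "layered_classifier")) {
    return(sum(vapply(x$layers, function(L) {
      if (L$type %in% c("conv", "dense")) length(L$W) + length(L$b) else 0
    }, numeric(1))))
  }
  stopifnot(inherits(x, "arch_spec"))
  sk <- spec_skeleton(x)
  sum(vapply(sk$layers, function(L) {
    switch(L$type,
           conv = 9 * L$c * L$cout + L$cout,
           dense = L$d_in * L$d_out + L$d_out,
           0)
  }, numeric(1)))
}

# Glorot (variance-scaling) uniform initialisation, rounded to float.
glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  float_round(matrix(runif(nrow * ncol, -lim, lim), nrow, ncol))
}

#' Build a layered classifier
#'
#' Allocates weights for an architecture specification. New layers are
#' initialised with variance-scaling (Glorot) uniform draws seeded by
#' `init_seed`; biases start at zero. If a `pretrained_base` classifier is
#' given, its convolutional-block weights are copied in (the "experienced"
#' base) and only the fully connected head is freshly initialised, mirroring
#' transfer of a pretrained visual backbone to a new, smaller output layer.
#' All parameters remain trainable.
#'
#' @param spec An [arch_spec()].
#' @param init_seed Integer seed for head/weight initialisation.
#' @param pretrained_base Optional `"layered_classifier"` whose convolutional
#'   layers match `spec` in shape.
#' @return An object of class `"layered_classifier"` with fields `spec`,
#'   `layers`, and `cut_points` (named pooling-layer ids `pool_1`, ...).
#' @export
build_model <- function(spec, init_seed = 1L, pretrained_base = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  sk <- spec_skeleton(spec)
  layers <- with_seed(mix_seed(init_seed, "init"), {
    lapply(sk$layers, function(L) {
      if (L$type == "conv") {
        L$W <- glorot(L$cout, 9L * L$c, 9 * L$c, 9 * L$cout)
        L$b <- numeric(L$cout)
      } else if (L$type == "dense") {
        L$W <- glorot(L$d_out, L$d_in, L$d_in, L$d_out)
        L$b <- numeric(L$d_out)
      }
      L
    })
  })
  n_pools <- length(sk$cut_points)
  if (!is.null(pretrained_base)) {
    stopifnot(inherits(pretrained_base, "layered_classifier"))
    base_end <- pretrained_base$cut_points[[paste0("pool_", n_pools)]]
    own_end <- sk$cut_points[[paste0("pool_", n_pools)]]
    if (base_end != own_end) {
      stop("pretrained base has a different block structure", call. = FALSE)
    }
    for (i in seq_len(base_end)) {
      src <- pretrained_base$layers[[i]]
      if (src$type == "conv") {
        if (!identical(dim(src$W), dim(layers[[i]]$W))) {
          stop(sprintf("pretrained layer %d shape mismatch", i), call. = FALSE)
        }
        layers[[i]]$W <- src$W
        layers[[i]]$b <- src$b
      }
    }
  }
  structure(list(spec = spec, layers = layers, cut_points = sk$cut_points,
                 opt_state = NULL),
            class = "layered_classifier")
}

#' @export
print.layered_classifier <- function(x, ...) {
  cat(sprintf("<layered_classifier> %s preset, input %s, %d outputs\n",
              x$spec$preset, paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_outputs))
  cat(sprintf("  %d layers, %s parameters, cut points: %s\n",
              length(x$layers), format(count_parameters(x), big.mark = ","),
              paste(names(x$cut_points), collapse = ", ")))
  invisible(x)
}

# Spatial output shape (h, w, c) at a named cut point.
cut_shape <- function(model, cut_point) {
  idx <- cut_index(model, cut_point)
  L <- model$layers[[idx]]
  c(L$h %/% 2L, L$w %/% 2L, L$c)
}

cut_index <- function(model, cut_point) {
  idx <- model$cut_points[cut_point]
  if (length(idx) != 1 || is.na(idx)) {
    stop(sprintf("unknown cut point '%s'; legal cut points: %s", cut_point,
                 paste(names(model$cut_points), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(idx)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the architecture
#' specification and per-layer weight arrays. Loading validates all layer
#' shapes against the stored specification.
#'
#' @param model A `"layered_classifier"`.
#' @param path File path.
#' @return `load_model` returns the validated classifier.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "layered_classifier"))
  saveRDS(list(spec = unclass(model$spec), layers = model$layers,
               cut_points = model$cut_points), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  spec <- structure(obj$spec, class = "arch_spec")
  sk <- spec_skeleton(spec)
  if (length(sk$layers) != length(obj$layers)) {
    stop("checkpoint layer count does not match its specification", call. = FALSE)
  }
  for (i in seq_along(sk$layers)) {
    L <- sk$layers[[i]]; S <- obj$layers[[i]]
    if (L$type != S$type) stop("checkpoint layer type mismatch", call. = FALSE)
    if (L$type == "conv" &&
        !identical(dim(S$W), c(L$cout, 9L * L$c))) {
      stop(sprintf("checkpoint conv layer %d has wrong shape", i), call. = FALSE)
    }
    if (L$type == "dense" &&
        !identical(dim(S$W), c(L$d_out, L$d_in))) {
      stop(sprintf("checkpoint dense layer %d has wrong shape", i), call. = FALSE)
    }
  }
  structure(list(spec = spec, layers = obj$layers, cut_points = obj$cut_points,
                 opt_state = NULL),
            class = "layered_classifier")
}
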