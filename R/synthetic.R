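# Procedural synthetic image categories.
#
# Each category is defined by a prototype: a parameter vector controlling a
# coloured composition (background colour, three Gaussian colour blobs, one
# oriented sinusoidal grating). Rendering an exemplar jitters every prototype
# parameter and adds pixel noise; all jitter scales grow strictly with the
# prototype's difficulty, so harder classes have larger within-class
# variability at every spatial scale (global background, mid-scale blobs,
# fine-scale grating and noise).

PROTO_PARAM_NAMES <- c(
  paste0("bg_", c("r", "g", "b")),
  as.vector(outer(c("x", "y", "r", "cr", "cg", "cb"),
                  paste0("_blob", 1:3), function(a, b) paste0(a, b))),
  paste0("grat_", c("theta", "freq", "amp", "phase"))
)
# indices perturbed per class in the grouped (similar-classes) regime:
# blob colours and the grating orientation
GROUPED_FREE_PARAMS <- c(as.vector(outer(c("cr", "cg", "cb"),
                                         paste0("_blob", 1:3),
                                         function(a, b) paste0(a, b))),
                         "grat_theta")

#' Generate category prototypes
#'
#' Draws `n_classes` category prototypes. In `similarity_mode = "none"`
#' every prototype's feature parameters are drawn independently, giving
#' visually diverse categories. In `"grouped"` mode all classes share one
#' base parameter vector and differ only by small perturbations of blob
#' colours and grating orientation, emulating a set of conceptually highly
#' similar categories (the "all plants" regime).
#'
#' @param n_classes Number of categories (>= 1).
#' @param seed Integer seed; prototype generation is a pure function of it.
#' @param similarity_mode `"none"` or `"grouped"`.
#' @param difficulty_profile Optional numeric vector in `[0,1]` of length
#'   `n_classes`; per-class difficulty scales every within-class jitter
#'   strictly monotonically. Empty/NULL means uniform 0.7.
#' @return List of `"category_prototype"` objects with fields `class_id`,
#'   `feature_params`, `difficulty`, `similarity_group`.
#' @export
#' @examples
#' protos <- generate_prototypes(4, seed = 7)
generate_prototypes <- function(n_classes, seed = 1L,
                                similarity_mode = c("none", "grouped"),
                                difficulty_profile = NULL) {
  n_classes <- assert_scalar_int(n_classes, "n_classes")
  similarity_mode <- match.arg(similarity_mode)
  if (is.null(difficulty_profile) || length(difficulty_profile) == 0) {
    difficulty_profile <- rep(0.7, n_classes)
  }
  if (length(difficulty_profile) != n_classes ||
      any(difficulty_profile < 0 | difficulty_profile > 1)) {
    stop("difficulty_profile must be empty or n_classes values in [0,1]",
         call. = FALSE)
  }
  np <- length(PROTO_PARAM_NAMES)
  with_seed(mix_seed(seed, "prototypes"), {
    base <- if (similarity_mode == "grouped") runif(np) else NULL
    lapply(seq_len(n_classes), function(i) {
      if (similarity_mode == "none") {
        p <- runif(np)
        grp <- NA_integer_
      } else {
        p <- base
        free <- match(GROUPED_FREE_PARAMS, PROTO_PARAM_NAMES)
        p[free] <- clamp01(base[free] + runif(length(free), -0.15, 0.15))
        grp <- 1L
      }
      names(p) <- PROTO_PARAM_NAMES
      structure(list(class_id = i, feature_params = p,
                     difficulty = difficulty_profile[i],
                     similarity_group = grp),
                class = "category_prototype")
    })
  })
}

# jitter scales: strictly increasing in difficulty d
jitter_scales <- function(d) {
  list(pos = 0.015 + 0.155 * d,   # blob position (image fraction)
       col = 0.03 + 0.21 * d,     # colour offsets
       theta = 0.05 + 0.43 * d,   # grating orientation (radians)
       phase = 0.30 + 2.30 * d,   # grating phase (radians)
       radius = 0.06 + 0.43 * d,  # log blob radius
       noise = 0.03 + 0.31 * d)   # iid pixel noise s.d.
}

#' Render one exemplar image of a category
#'
#' Deterministic given `(prototype, variation_seed, size)`; different
#' variation seeds give different exemplars of the same category. Pixel
#' values lie in `[0, 1]`.
#'
#' @param prototype A `"category_prototype"`.
#' @param variation_seed Integer seed for the within-class jitter.
#' @param size `c(H, W)`, both >= 16.
#' @return An H x W x 3 numeric array.
#' @export
render_image <- function(prototype, variation_seed, size = c(64L, 64L)) {
  stopifnot(inherits(prototype, "category_prototype"))
  if (length(size) != 2 || any(size < 16)) {
    stop("size must be c(H, W) with H, W >= 16", call. = FALSE)
  }
  H <- as.integer(size[1]); W <- as.integer(size[2])
  p <- prototype$feature_params
  js <- jitter_scales(prototype$difficulty)
  with_seed(mix_seed(variation_seed, prototype$class_id, "render"), {
    xs <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
    ys <- matrix(seq(0, 1, length.out = H), H, W)
    img <- array(0, c(H, W, 3))
    bg <- 0.35 + 0.3 * p[c("bg_r", "bg_g", "bg_b")]
    for (ch in 1:3) img[, , ch] <- bg[ch]
    # oriented grating (fine-scale structure)
    theta <- p[["grat_theta"]] * pi + rnorm(1, 0, js$theta)
    freq <- 2 + 8 * p[["grat_freq"]]
    amp <- 0.06 + 0.18 * p[["grat_amp"]]
    phase <- 2 * pi * p[["grat_phase"]] + rnorm(1, 0, js$phase)
    g <- amp * sin(2 * pi * freq * (xs * cos(theta) + ys * sin(theta)) + phase)
    wts <- c(1, 0.7, 0.4)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + wts[ch] * g
    # colour blobs (mid-scale structure)
    for (k in 1:3) {
      cx <- p[[paste0("x_blob", k)]] + rnorm(1, 0, js$pos)
      cy <- p[[paste0("y_blob", k)]] + rnorm(1, 0, js$pos)
      rad <- (0.08 + 0.14 * p[[paste0("r_blob", k)]]) * exp(rnorm(1, 0, js$radius))
      bump <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * rad^2))
      for (ch in 1:3) {
        col <- p[[paste0("c", c("r", "g", "b")[ch], "_blob", k)]] +
          rnorm(1, 0, js$col)
        img[, , ch] <- img[, , ch] + bump * 0.9 * (col - 0.5)
      }
    }
    img <- img + array(rnorm(H * W * 3, 0, js$noise), c(H, W, 3))
    array(clamp01(img), c(H, W, 3))
  })
}

#' Build a labelled train/val/test dataset
#'
#' Renders `n_train + n_val + n_test` exemplars per class with disjoint,
#' per-image derived seeds, so no image is shared between splits and
#' regeneration with the same seed is bit-identical. The canonical split
#' ratio is 117:13:5 per class (117/13/5 at desk scale; 1,170/130/50 at
#' full scale). Per-channel means of the training split are stored for
#' preprocessing (mean subtraction).
#'
#' @param prototypes List from [generate_prototypes()].
#' @param n_train,n_val,n_test Per-class split sizes (each >= 1).
#' @param size `c(H, W)` image size.
#' @param seed Integer seed.
#' @return A `"dataset_bundle"`: list with `x` (d x N matrix of flattened
#'   images, d = H*W*3), `labels`, `split` (factor train/val/test), `dim`,
#'   `n_classes`, `channel_means`, `difficulty`, `generation_seed`.
#' @export
build_dataset <- function(prototypes, n_train, n_val, n_test,
                          size = c(64L, 64L), seed = 1L) {
  stopifnot(length(prototypes) >= 1,
            all(vapply(prototypes, inherits, logical(1), "category_prototype")))
  n_train <- assert_scalar_int(n_train, "n_train")
  n_val <- assert_scalar_int(n_val, "n_val")
  n_test <- assert_scalar_int(n_test, "n_test")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  C <- length(prototypes)
  per_class <- n_train + n_val + n_test
  N <- C * per_class
  x <- matrix(0, H * W * 3L, N)
  labels <- integer(N)
  split <- character(N)
  col <- 0L
  for (i in seq_len(C)) {
    for (j in seq_len(per_class)) {
      col <- col + 1L
      vseed <- mix_seed(seed, "image", i, j)
      x[, col] <- as.vector(render_image(prototypes[[i]], vseed, c(H, W)))
      labels[col] <- i
      split[col] <- if (j <= n_train) "train"
                    else if (j <= n_train + n_val) "val" else "test"
    }
  }
  split <- factor(split, levels = c("train", "val", "test"))
  means <- channel_means_of(x[, split == "train", drop = FALSE], c(H, W, 3L))
  structure(list(x = x, labels = labels, split = split,
                 dim = c(H, W, 3L), n_classes = C,
                 channel_means = means,
                 difficulty = vapply(prototypes, `[[`, numeric(1), "difficulty"),
                 generation_seed = as.integer(seed)),
            class = "dataset_bundle")
}

channel_means_of <- function(x, dim) {
  hw <- dim[1] * dim[2]
  vapply(seq_len(dim[3]), function(ch) {
    mean(x[((ch - 1) * hw + 1):(ch * hw), , drop = FALSE])
  }, numeric(1))
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d classes, %sx%sx3, splits %s (seed %s)\n",
              x$n_classes, x$dim[1], x$dim[2],
              paste(table(x$split), collapse = "/"),
              x$generation_seed))
  invisible(x)
}

#' Access images or labels of one split
#'
#' @param bundle A `"dataset_bundle"`.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @return `bundle_images`: d x n matrix, one flattened image per column;
#'   `bundle_labels`: integer class ids.
#' @export
bundle_images <- function(bundle, split = "train") {
  bundle$x[, bundle$split == split, drop = FALSE]
}

#' @rdname bundle_images
#' @export
bundle_labels <- function(bundle, split = "train") {
  bundle$labels[bundle$split == split]
}

#' Restrict the training split to k exemplars per class
#'
#' Keeps the first `k` training images of every class (validation and test
#' untouched); used by the exemplar-count sweep. A vector `k` (one entry
#' per class) engineers per-class difficulty through data scarcity:
#' classes with fewer exemplars are learned more weakly while their
#' exemplars remain equally prototypical.
#'
#' @param bundle A `"dataset_bundle"`.
#' @param k Exemplars per class to keep: a scalar, or one value per class.
#' @return The reduced bundle (channel means recomputed).
#' @export
limit_exemplars <- function(bundle, k) {
  k <- vapply(k, assert_scalar_int, integer(1), name = "k")
  if (length(k) == 1L) k <- rep(k, bundle$n_classes)
  stopifnot(length(k) == bundle$n_classes)
  keep <- rep(TRUE, length(bundle$labels))
  for (i in seq_len(bundle$n_classes)) {
    idx <- which(bundle$split == "train" & bundle$labels == i)
    if (length(idx) < k[i]) stop("fewer training images than k", call. = FALSE)
    keep[idx[-seq_len(k[i])]] <- FALSE
  }
  bundle$x <- bundle$x[, keep, drop = FALSE]
  bundle$labels <- bundle$labels[keep]
  bundle$split <- bundle$split[keep]
  bundle$channel_means <- channel_means_of(
    bundle$x[, bundle$split == "train", drop = FALSE], bundle$dim)
  bundle
}

#' Augmentation configuration
#'
#' Random affine augmentation applied once per image per epoch: rotation up
#' to `max_rotation_deg` degrees, horizontal/vertical shifts up to
#' `max_shift_frac` of the image side, zoom in `[1 - max_zoom_frac,
#' 1 + max_zoom_frac]`, and optional horizontal flipping. Each parameter is
#' drawn uniformly within its bounds. Exposed borders are always filled by
#' symmetric reflection of the image content; interpolation is bilinear
#' about the image centre.
#'
#' @param max_rotation_deg Maximum absolute rotation, degrees, in `[0, 180]`.
#' @param max_shift_frac,max_zoom_frac Fractions in `[0, 1]`.
#' @param horizontal_flip Flip horizontally with probability 1/2.
#' @return An `"augment_config"`.
#' @export
augment_config <- function(max_rotation_deg = 20, max_shift_frac = 0.2,
                           max_zoom_frac = 0.2, horizontal_flip = TRUE) {
  stopifnot(max_rotation_deg >= 0, max_rotation_deg <= 180,
            max_shift_frac >= 0, max_shift_frac <= 1,
            max_zoom_frac >= 0, max_zoom_frac <= 1,
            is.logical(horizontal_flip))
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_frac = max_shift_frac,
                 max_zoom_frac = max_zoom_frac,
                 horizontal_flip = horizontal_flip,
                 fill_mode = "reflect"),
            class = "augment_config")
}

# Draw one transform parameter set per image from the ambient RNG.
# Rows: angle (rad), shift_x (px), shift_y (px), zoom, flip.
sample_augment_params <- function(cfg, n, dim) {
  rbind(runif(n, -cfg$max_rotation_deg, cfg$max_rotation_deg) * pi / 180,
        runif(n, -cfg$max_shift_frac, cfg$max_shift_frac) * dim[2],
        runif(n, -cfg$max_shift_frac, cfg$max_shift_frac) * dim[1],
        runif(n, 1 - cfg$max_zoom_frac, 1 + cfg$max_zoom_frac),
        if (cfg$horizontal_flip) as.double(runif(n) < 0.5) else numeric(n))
}

augment_matrix <- function(x, dim, cfg) {
  params <- sample_augment_params(cfg, ncol(x), dim)
  augment_batch_cpp(x, dim[1], dim[2], params)
}

#' Randomly augment one image
#'
#' Applies one transform draw from `cfg` (rotation, shift, zoom, optional
#' flip; reflection fill) using the ambient RNG. Output values stay in
#' `[0, 1]` (bilinear interpolation of reflected content is a convex
#' combination of input pixels).
#'
#' @param image H x W x 3 numeric array with values in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @return Augmented array of the same shape.
#' @export
augment_image <- function(image, cfg = augment_config()) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  out <- augment_matrix(matrix(as.vector(image), ncol = 1), d, cfg)
  array(out, d)
}

#' Write or read an image-folder dataset
#'
#' Standard image-folder convention: `<root>/<split>/<class_NNN>/<index>.png`
#' with 8-bit PNGs. Reading back returns a `"dataset_bundle"` (labels from
#' directory names, channel means recomputed from the training split);
#' 8-bit quantisation makes the round trip exact to within 1/255 per pixel.
#'
#' @param bundle A `"dataset_bundle"`.
#' @param root Output directory root.
#' @return `write_image_folder` returns `root`; `read_image_folder` a bundle.
#' @export
write_image_folder <- function(bundle, root) {
  for (sp in levels(bundle$split)) {
    xs <- bundle_images(bundle, sp)
    ys <- bundle_labels(bundle, sp)
    for (i in sort(unique(ys))) {
      dir <- file.path(root, sp, sprintf("class_%03d", i))
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      cols <- which(ys == i)
      for (j in seq_along(cols)) {
        img <- array(xs[, cols[j]], bundle$dim)
        png::writePNG(img, file.path(dir, sprintf("%05d.png", j)))
      }
    }
  }
  invisible(root)
}

#' @rdname write_image_folder
#' @export
read_image_folder <- function(root) {
  splits <- intersect(c("train", "val", "test"), list.dirs(root, recursive = FALSE,
                                                           full.names = FALSE))
  if (length(splits) == 0) stop("no split directories found", call. = FALSE)
  xs <- list(); labels <- integer(0); split <- character(0)
  dims <- NULL
  for (sp in splits) {
    classes <- sort(list.dirs(file.path(root, sp), recursive = FALSE,
                              full.names = FALSE))
    for (ci in seq_along(classes)) {
      files <- sort(list.files(file.path(root, sp, classes[ci]),
                               pattern = "\\.png$", full.names = TRUE))
      for (f in files) {
        img <- png::readPNG(f)
        if (is.null(dims)) dims <- dim(img)
        xs[[length(xs) + 1L]] <- as.vector(img)
        labels <- c(labels, ci)
        split <- c(split, sp)
      }
    }
  }
  x <- do.call(cbind, xs)
  split <- factor(split, levels = c("train", "val", "test"))
  structure(list(x = x, labels = labels, split = split,
                 dim = as.integer(dims),
                 n_classes = length(unique(labels)),
                 channel_means = channel_means_of(
                   x[, split == "train", drop = FALSE], dims),
                 difficulty = NULL,
                 generation_seed = NA_integer_),
            class = "dataset_bundle")
}
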