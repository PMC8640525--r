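#' Configuration for the hierarchical synthetic image generator
#'
#' The generator emulates the statistical structure of a CIFAR-100-like
#' dataset: balanced fine classes nested in balanced superclasses, with
#' within-superclass visual similarity exceeding between-superclass
#' similarity. Each superclass gets a prototype image (a smoothed random
#' field of scale `sigma_sup`); each class perturbs its superclass prototype
#' by a smoothed field of scale `sigma_cls`; each image adds i.i.d. pixel
#' noise of scale `sigma_noise` and is clipped to `[0, 1]`. Requiring
#' `sigma_cls < sigma_sup` makes superclass structure dominate class
#' structure, the prerequisite for hierarchy-sensitive degeneration readouts.
#'
#' @param n_superclasses,classes_per_superclass Hierarchy shape (defaults 5 x 4).
#' @param images_per_class_train,images_per_class_test Per-class image counts.
#' @param image_size Square image side in pixels.
#' @param channels Image channels; 1 (default) or 3 for a CIFAR-like mode.
#' @param sigma_sup,sigma_cls,sigma_noise Non-negative scales of the
#'   superclass field, class offset field, and per-image pixel noise.
#' @param blur_radius Box-blur radius (pixels) applied to prototype fields so
#'   images carry local spatial structure a convolution can exploit.
#' @param seed Integer root seed; prototype/train/test streams are derived
#'   from it by the counter rule `seed`, `seed + 1`, `seed + 2`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_superclasses = 5,
                             classes_per_superclass = 4,
                             images_per_class_train = 100,
                             images_per_class_test = 50,
                             image_size = 16,
                             channels = 1,
                             sigma_sup = 0.5,
                             sigma_cls = 0.15,
                             sigma_noise = 0.1,
                             blur_radius = 2,
                             seed = 1) {
  cfg <- list(
    n_superclasses = check_count(n_superclasses, "n_superclasses", min = 2L),
    classes_per_superclass = check_count(classes_per_superclass, "classes_per_superclass"),
    images_per_class_train = check_count(images_per_class_train, "images_per_class_train"),
    images_per_class_test = check_count(images_per_class_test, "images_per_class_test"),
    image_size = check_count(image_size, "image_size"),
    channels = check_count(channels, "channels"),
    sigma_sup = check_scalar_number(sigma_sup, "sigma_sup", min = 0),
    sigma_cls = check_scalar_number(sigma_cls, "sigma_cls", min = 0),
    sigma_noise = check_scalar_number(sigma_noise, "sigma_noise", min = 0),
    blur_radius = check_count(blur_radius, "blur_radius", min = 0L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$sigma_cls >= cfg$sigma_sup) {
    abort("`sigma_cls` must be < `sigma_sup` so superclass structure dominates.",
          class = "degensim_invalid_argument")
  }
  structure(cfg, class = "generator_config")
}

#' Construct a stimulus set
#'
#' Low-level constructor binding an image tensor to labels and a hierarchy.
#' Images are a numeric array `[n, H, W, channels]` with values in `[0, 1]`;
#' labels are 0-based class ids drawn from the hierarchy.
#'
#' @param images Numeric 4-d array `[n, H, W, channels]`.
#' @param labels Integer vector of class ids, length `n`.
#' @param hierarchy A `class_hierarchy`.
#' @param split_tag `"train"` or `"test"`.
#' @return A `stimulus_set` object.
#' @export
stimulus_set <- function(images, labels, hierarchy, split_tag = c("train", "test")) {
  split_tag <- match.arg(split_tag)
  validate_hierarchy(hierarchy)
  if (length(dim(images)) != 4L) {
    abort("`images` must be a 4-d array [n, H, W, channels].",
          class = "degensim_invalid_argument")
  }
  labels <- as.integer(labels)
  if (dim(images)[1] != length(labels)) {
    abort("Image count and label count differ.", class = "degensim_invalid_argument")
  }
  if (!all(labels %in% hierarchy$class_id)) {
    abort("All labels must appear in the hierarchy.", class = "degensim_invalid_argument")
  }
  structure(list(images = images, labels = labels, hierarchy = hierarchy,
                 split_tag = split_tag),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<stimulus_set:%s> %d images %dx%dx%d, %d classes\n",
              x$split_tag, d[1], d[2], d[3], d[4], n_classes(x$hierarchy)))
  invisible(x)
}

# Box blur with edge replication; radius r means a (2r+1)^2 kernel.
box_blur <- function(mat, r) {
  if (r == 0L) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(0, H, W)
  for (di in -r:r) {
    ri <- pmin(pmax(seq_len(H) + di, 1L), H)
    for (dj in -r:r) {
      cj <- pmin(pmax(seq_len(W) + dj, 1L), W)
      out <- out + mat[ri, cj]
    }
  }
  out / (2 * r + 1)^2
}

smoothed_field <- function(H, W, channels, scale, r) {
  a <- array(0, dim = c(H, W, channels))
  for (ch in seq_len(channels)) {
    a[, , ch] <- box_blur(matrix(rnorm(H * W, sd = 1), H, W), r) * scale
  }
  a
}

#' Generate a hierarchical synthetic dataset
#'
#' Draws superclass prototypes, class prototypes and train/test stimulus sets
#' under the hierarchical generative model described in
#' [generator_config()]. Deterministic given `cfg$seed`; train and test
#' images are disjoint draws from independent streams.
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_dataset` list with elements `train` and `test`
#'   (stimulus sets), `hierarchy`, `prototypes` (array `[C, H, W, channels]`
#'   of clipped class prototypes), and `config`.
#' @examples
#' ds <- generate_dataset(generator_config(images_per_class_train = 2,
#'                                         images_per_class_test = 1))
#' ds$train
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  H <- W <- cfg$image_size
  ch <- cfg$channels
  S <- cfg$n_superclasses
  K <- cfg$classes_per_superclass
  C <- S * K
  hierarchy <- make_hierarchy(S, K)

  # Stream 1: prototypes (base image 0.5 so clipping is symmetric).
  protos <- withr::with_seed(derive_seed(cfg$seed, 0L), {
    p <- array(0, dim = c(C, H, W, ch))
    for (s in seq_len(S)) {
      mu_s <- smoothed_field(H, W, ch, cfg$sigma_sup, cfg$blur_radius)
      for (k in seq_len(K)) {
        cls <- (s - 1L) * K + k
        delta <- smoothed_field(H, W, ch, cfg$sigma_cls, cfg$blur_radius)
        p[cls, , , ] <- 0.5 + mu_s + delta
      }
    }
    p
  })

  draw_split <- function(n_per_class, stream, tag) {
    withr::with_seed(derive_seed(cfg$seed, stream), {
      n <- n_per_class * C
      imgs <- array(0, dim = c(n, H, W, ch))
      labels <- integer(n)
      i <- 0L
      for (cls in seq_len(C)) {
        proto <- array(protos[cls, , , ], dim = c(H, W, ch))
        for (rep in seq_len(n_per_class)) {
          i <- i + 1L
          eps <- array(rnorm(H * W * ch, sd = cfg$sigma_noise), dim = c(H, W, ch))
          imgs[i, , , ] <- pmin(pmax(proto + eps, 0), 1)
          labels[i] <- cls - 1L
        }
      }
      stimulus_set(imgs, labels, hierarchy, tag)
    })
  }

  structure(list(
    train = draw_split(cfg$images_per_class_train, 1L, "train"),
    test = draw_split(cfg$images_per_class_test, 2L, "test"),
    hierarchy = hierarchy,
    prototypes = pmin(pmax(protos, 0), 1),
    config = cfg
  ), class = "synthetic_dataset")
}

#' Prototype distance structure of a generated dataset
#'
#' Mean pixelwise Euclidean distance between class prototypes, split into
#' within-superclass and between-superclass pairs. Under the generative
#' model the within mean is smaller — the hierarchical structure downstream
#' analyses rely on.
#'
#' @param ds A `synthetic_dataset`.
#' @return A tibble with columns `pair_type` and `mean_distance`.
#' @export
prototype_distances <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  C <- n_classes(ds$hierarchy)
  flat <- matrix(ds$prototypes, nrow = C)
  d <- as.matrix(stats::dist(flat))
  sup <- ds$hierarchy$superclass_id
  same <- outer(sup, sup, "==") & upper.tri(d)
  diff <- outer(sup, sup, "!=") & upper.tri(d)
  tibble::tibble(
    pair_type = c("within_superclass", "between_superclass"),
    mean_distance = c(mean(d[same]), mean(d[diff]))
  )
}
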