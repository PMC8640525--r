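#' Penultimate-layer activations
#'
#' Post-activation outputs of the model's designated penultimate layer
#' (default `"dense_2"`) for every stimulus, with dropout inactive —
#' the representation analysed by representational similarity analysis.
#'
#' @param model A `classifier_model` with a valid penultimate designation.
#' @param stimuli A `stimulus_set` or `[n, H, W, C]` image array.
#' @return Numeric matrix: rows = stimuli, columns = penultimate neurons.
#' @export
penultimate_activations <- function(model, stimuli) {
  stopifnot(inherits(model, "classifier_model"))
  if (is.null(model$penultimate) ||
      !model$penultimate %in% model$layer_names) {
    abort("Model has no valid penultimate-layer designation.",
          class = "degensim_invalid_argument")
  }
  images <- if (inherits(stimuli, "stimulus_set")) stimuli$images else stimuli
  up <- model$meta$training$input_upscale %||% 1L
  if (up > 1L) images <- upscale_images(images, up)
  acts <- model_forward(model, images, training = FALSE,
                        capture = model$penultimate)$captured
  if (is.null(acts)) {
    abort("Penultimate layer produced no activations.",
          class = "degensim_invalid_argument")
  }
  acts
}

#' Build a representational dissimilarity matrix
#'
#' Pairwise dissimilarity `1 - Pearson correlation` between the activation
#' patterns of every pair of stimuli. The result is symmetric with an exact
#' zero diagonal and entries in `[0, 2]`. Rows with zero variance (dead
#' representations, routine under heavy injury) cannot be correlated; by
#' convention they get dissimilarity 1 against every other row, and a
#' message reports how many rows were degenerate.
#'
#' @param acts Activation matrix, rows = stimuli (>= 2), columns = neurons
#'   (>= 2).
#' @param condition_ids Optional condition identifiers (default `1:n`).
#' @return An `rdm` object: dissimilarity matrix `D` plus `condition_ids`.
#' @export
build_rdm <- function(acts, condition_ids = NULL) {
  acts <- as.matrix(acts)
  if (nrow(acts) < 2L) {
    abort("Need >= 2 stimuli to build an RDM.",
          class = "degensim_invalid_argument")
  }
  if (ncol(acts) < 2L) {
    abort("Need >= 2 neurons; Pearson correlation is undefined otherwise.",
          class = "degensim_invalid_argument")
  }
  condition_ids <- condition_ids %||% seq_len(nrow(acts))
  sds <- apply(acts, 1, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  R <- suppressWarnings(cor(t(acts)))
  D <- 1 - R
  if (any(degenerate)) {
    inform(sprintf(
      "build_rdm: %d zero-variance row(s); using dissimilarity 1 by convention.",
      sum(degenerate)))
    D[degenerate, ] <- 1
    D[, degenerate] <- 1
  }
  D[is.na(D)] <- 1
  D <- pmin(pmax(D, 0), 2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  new_rdm(D, condition_ids)
}

new_rdm <- function(D, condition_ids) {
  structure(list(D = D, condition_ids = condition_ids), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, dissimilarity range [%.3f, %.3f]\n",
              nrow(x$D), min(x$D), max(x$D)))
  invisible(x)
}

#' @export
as.matrix.rdm <- function(x, ...) x$D

#' Upper-triangle vector of an RDM
#'
#' Strict upper-triangle entries in row-major order
#' (`D[1,2], D[1,3], ..., D[1,n], D[2,3], ...`), length `n(n-1)/2` — the
#' canonical vectorisation compared across RDMs.
#'
#' @param rdm An `rdm` object or a symmetric matrix.
#' @return Numeric vector.
#' @export
utv <- function(rdm) {
  D <- if (inherits(rdm, "rdm")) rdm$D else rdm
  t(D)[lower.tri(D)]
}

#' Kendall's tau-a rank correlation
#'
#' `tau_A = (concordant - discordant) / (n(n-1)/2)`: every unordered pair
#' counts in the denominator; tied pairs contribute zero to the numerator
#' but are not removed — the defining difference from tau-b, and the
#' variant conventionally used for RDM comparison. Below 10^4 pairs an
#' O(n^2) vectorised pair count is used; above, a merge-sort-based
#' O(n log n) counter. The two agree to machine precision on their overlap.
#'
#' @param v1,v2 Equal-length numeric vectors, length >= 2.
#' @param method `"auto"` (size-based dispatch), `"brute"`, or `"fast"`.
#' @return tau-a in `[-1, 1]`.
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 2/3
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 1, 2, 3))  # 5/6: the tie stays in n0
#' @export
kendall_tau_a <- function(v1, v2, method = c("auto", "brute", "fast")) {
  method <- match.arg(method)
  n <- length(v1)
  if (length(v2) != n || n < 2L) {
    abort("`v1` and `v2` must have equal length >= 2.",
          class = "degensim_invalid_argument")
  }
  if (method == "auto") {
    method <- if (n * (n - 1) / 2 < 1e4) "brute" else "fast"
  }
  if (method == "brute") {
    s1 <- sign(outer(v1, v1, "-"))
    s2 <- sign(outer(v2, v2, "-"))
    up <- upper.tri(s1)
    sum(s1[up] * s2[up]) / (n * (n - 1) / 2)
  } else {
    kendall_tau_a_cpp(as.double(v1), as.double(v2))
  }
}

#' Compare two RDMs with Kendall's tau-a
#'
#' Rank-correlates the upper-triangle vectors of two RDMs over identical
#' condition sets — e.g. an injured network's RDM against the same
#' network's uninjured reference.
#'
#' @param a,b `rdm` objects with identical condition ids in identical order.
#' @return A one-row tibble: `tau_a`, `n_pairs`.
#' @export
compare_rdms <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$condition_ids, b$condition_ids)) {
    abort("RDMs must share identical condition ids and order.",
          class = "degensim_invalid_argument")
  }
  va <- utv(a)
  tibble::tibble(tau_a = kendall_tau_a(va, utv(b)),
                 n_pairs = length(va))
}

#' Scrambled-RDM noise floor
#'
#' The tau-a expected when no representational structure remains: the RDM
#' is compared against scrambled versions of itself. The default scramble
#' permutes the upper-triangle entries uniformly (destroying all structure);
#' `"conditions"` instead permutes condition rows/columns jointly,
#' preserving the entry multiset's geometric constraints.
#'
#' @param rdm An `rdm` with >= 3 conditions.
#' @param n_reps Number of scrambles (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param scramble `"entries"` (default) or `"conditions"`.
#' @return A `noise_floor` object: `mean_tau_a` (signed mean across reps),
#'   `mean_abs_tau_a`, and the per-rep `tau_a` values.
#' @export
scrambled_noise_floor <- function(rdm, n_reps = 25, seed = 1,
                                  scramble = c("entries", "conditions")) {
  stopifnot(inherits(rdm, "rdm"))
  scramble <- match.arg(scramble)
  n_reps <- check_count(n_reps, "n_reps")
  n <- nrow(rdm$D)
  if (n < 3L) {
    abort("Noise floor needs >= 3 conditions (>= 3 dissimilarity entries).",
          class = "degensim_invalid_argument")
  }
  v <- utv(rdm)
  taus <- withr::with_seed(seed, vapply(seq_len(n_reps), function(r) {
    vs <- if (scramble == "entries") {
      v[sample.int(length(v))]
    } else {
      p <- sample.int(n)
      utv(rdm$D[p, p])
    }
    kendall_tau_a(v, vs)
  }, numeric(1)))
  structure(list(mean_tau_a = mean(taus), mean_abs_tau_a = mean(abs(taus)),
                 tau_a = taus, n_reps = n_reps, scramble = scramble),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf(
    "<noise_floor> mean tau_a %.5f (mean |tau_a| %.5f) over %d %s scrambles\n",
    x$mean_tau_a, x$mean_abs_tau_a, x$n_reps, x$scramble))
  invisible(x)
}

#' Superclass-level RDM by block averaging
#'
#' Aggregates a stimulus-level RDM to an S x S superclass RDM: entry (s, t)
#' is the mean dissimilarity over all stimulus pairs with one member in s
#' and one in t; the diagonal holds the mean over distinct within-superclass
#' pairs (it is retained, not re-zeroed, and is excluded from tau-a
#' comparisons automatically because [utv()] takes the strict upper
#' triangle).
#'
#' @param rdm A stimulus-level `rdm`.
#' @param labels 0-based class id per condition (same order as the RDM).
#' @param hierarchy A `class_hierarchy` mapping classes to superclasses.
#' @return An `rdm` whose condition ids are the superclass ids.
#' @export
superclass_rdm <- function(rdm, labels, hierarchy) {
  stopifnot(inherits(rdm, "rdm"))
  validate_hierarchy(hierarchy)
  n <- nrow(rdm$D)
  if (length(labels) != n) {
    abort("`labels` must give one class id per RDM condition.",
          class = "degensim_invalid_argument")
  }
  sup <- superclass_of(hierarchy, labels)
  sup_ids <- sort(unique(sup))
  if (length(sup_ids) < 2L) {
    abort("Need conditions from >= 2 superclasses.",
          class = "degensim_invalid_argument")
  }
  counts <- table(factor(sup, levels = sup_ids))
  if (any(counts < 2L)) {
    abort("Every superclass needs >= 2 stimuli for its within-class diagonal.",
          class = "degensim_invalid_argument")
  }
  g <- factor(sup, levels = sup_ids)
  block_sums <- as.matrix(rowsum(t(rowsum(rdm$D, g)), g))  # S x S sums
  # within-superclass means are over distinct pairs only: drop the i == i
  # terms from the diagonal blocks (zero for a proper RDM, but kept general)
  diag(block_sums) <- diag(block_sums) - as.vector(rowsum(diag(rdm$D), g))
  ns <- as.numeric(counts)
  denom <- outer(ns, ns)
  diag(denom) <- ns * (ns - 1)                   # distinct pairs, both orders
  new_rdm(block_sums / denom, as.integer(sup_ids))
}

#' Elementwise average of RDMs
#'
#' Mean dissimilarity across replicate networks' RDMs over a shared
#' condition set; symmetry and the zero diagonal are preserved.
#'
#' @param rdms Non-empty list of `rdm` objects with identical condition ids.
#' @return An `rdm`.
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0L) {
    abort("Need at least one RDM to average.",
          class = "degensim_invalid_argument")
  }
  stopifnot(all(vapply(rdms, inherits, logical(1), "rdm")))
  ids <- rdms[[1]]$condition_ids
  for (r in rdms) {
    if (!identical(r$condition_ids, ids)) {
      abort("All RDMs must share identical condition ids.",
            class = "degensim_invalid_argument")
    }
  }
  D <- Reduce(`+`, lapply(rdms, `[[`, "D")) / length(rdms)
  new_rdm(D, ids)
}
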