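#' Predict class labels for a stimulus set
#'
#' Inference-mode forward pass followed by arg-max over the softmax scores.
#' Ties are broken deterministically toward the lowest class id — this only
#' matters for degenerate (heavily injured) models whose scores collapse to
#' equality.
#'
#' @param model A `classifier_model`.
#' @param stimuli A `stimulus_set` with labels drawn from a hierarchy whose
#'   class count matches the model's output width.
#' @return A `prediction_batch`: tibble with integer columns `predicted` and
#'   `true` (0-based class ids), carrying the hierarchy as an attribute.
#' @export
predict_labels <- function(model, stimuli) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(stimuli, "stimulus_set"))
  if (n_classes(stimuli$hierarchy) != model$n_classes) {
    abort("Model output dimension does not match the stimulus hierarchy.",
          class = "degensim_invalid_argument")
  }
  images <- stimuli$images
  up <- model$meta$training$input_upscale %||% 1L
  if (up > 1L) images <- upscale_images(images, up)
  probs <- model_forward(model, images, training = FALSE)$probs
  pred <- max.col(probs, ties.method = "first") - 1L
  prediction_batch(pred, stimuli$labels, stimuli$hierarchy)
}

#' Construct a prediction batch
#'
#' @param predicted,true Equal-length integer vectors of 0-based class ids,
#'   all present in `hierarchy`.
#' @param hierarchy A `class_hierarchy`.
#' @return A `prediction_batch` tibble.
#' @export
prediction_batch <- function(predicted, true, hierarchy) {
  validate_hierarchy(hierarchy)
  predicted <- as.integer(predicted)
  true <- as.integer(true)
  if (length(predicted) != length(true)) {
    abort("`predicted` and `true` must have equal length.",
          class = "degensim_invalid_argument")
  }
  if (!all(predicted %in% hierarchy$class_id) ||
      !all(true %in% hierarchy$class_id)) {
    abort("All ids must be valid classes of the hierarchy.",
          class = "degensim_invalid_argument")
  }
  structure(tibble::tibble(predicted = predicted, true = true),
            class = c("prediction_batch", class(tibble::tibble())),
            hierarchy = hierarchy)
}

#' Classification accuracy
#'
#' @param batch A `prediction_batch`.
#' @return Fraction of stimuli with `predicted == true`, in `[0, 1]`.
#' @export
accuracy <- function(batch) {
  stopifnot(inherits(batch, "prediction_batch"))
  if (nrow(batch) == 0L) {
    abort("Cannot compute accuracy of an empty batch.",
          class = "degensim_invalid_argument")
  }
  mean(batch$predicted == batch$true)
}

#' Analytic chance-level accuracy
#'
#' Expected accuracy of a uniform random guesser over the label alphabet:
#' `sum_l (count_l / total) * (1 / L)`, which reduces to `1 / L` — e.g. 1%
#' for 100 balanced classes and 5% for 20 balanced superclasses.
#'
#' @param label_counts Named or unnamed numeric vector of per-label counts
#'   (one entry per label in the alphabet).
#' @return Chance accuracy in `(0, 1]`.
#' @export
chance_accuracy <- function(label_counts) {
  if (length(label_counts) == 0L || sum(label_counts) <= 0) {
    abort("`label_counts` must be a non-empty vector with positive total.",
          class = "degensim_invalid_argument")
  }
  L <- length(label_counts)
  # sum_l (count_l / total) * (1/L) = (1/L) * sum_l count_l / total = 1/L;
  # computed in closed form so the analytic chance level is exact
  1 / L
}

#' Within-superclass error rate
#'
#' Restricted to misclassified stimuli, the fraction whose predicted class
#' falls in the true class's superclass: the predicted class label is
#' converted to its (indirectly predicted) superclass and compared with the
#' true superclass. Returns `NA_real_` — an explicit "undefined" marker,
#' not an error and not 0 — when the batch contains no errors, since the
#' statistic's denominator is the error set.
#'
#' @param batch A `prediction_batch` (its hierarchy supplies the mapping).
#' @return Fraction in `[0, 1]`, or `NA_real_` when there are no errors.
#' @export
within_superclass_error_rate <- function(batch) {
  stopifnot(inherits(batch, "prediction_batch"))
  hierarchy <- attr(batch, "hierarchy")
  wrong <- batch$predicted != batch$true
  if (!any(wrong)) return(NA_real_)
  pred_sup <- superclass_of(hierarchy, batch$predicted[wrong])
  true_sup <- superclass_of(hierarchy, batch$true[wrong])
  mean(pred_sup == true_sup)
}

#' Superclass chance conventions for the error analysis
#'
#' Two reference levels for the within-superclass error rate: `"marginal"`
#' (the default) is `1 / S`, the probability of selecting the correct
#' superclass out of `S`; `"conditional"` is the exact expectation for a
#' uniform class-level guesser restricted to wrong classes,
#' `(K - 1) / (C - 1)` for balanced hierarchies (K classes per superclass,
#' C classes total) — e.g. 4/99 for a 100-class, 20-superclass hierarchy.
#' Both are exposed; the marginal convention is the conventional reference.
#'
#' @param hierarchy A `class_hierarchy`.
#' @param convention `"marginal"` or `"conditional"`.
#' @return Chance level in `(0, 1)`.
#' @export
superclass_chance <- function(hierarchy, convention = c("marginal",
                                                        "conditional")) {
  validate_hierarchy(hierarchy)
  convention <- match.arg(convention)
  if (convention == "marginal") {
    1 / n_superclasses(hierarchy)
  } else {
    sup <- hierarchy$superclass_id
    C <- n_classes(hierarchy)
    # averaged over a uniformly drawn true class
    mean(vapply(seq_len(C), function(i)
      (sum(sup == sup[i]) - 1) / (C - 1), numeric(1)))
  }
}
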