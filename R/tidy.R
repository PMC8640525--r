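#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a degeneration experiment
#'
#' `tidy()` returns the per-replicate records (one row per replicate x
#' injured fraction); `glance()` a one-row overview of the run.
#'
#' @param x A `degeneration_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.degeneration_experiment <- function(x, ...) {
  x$records
}

#' @rdname tidy.degeneration_experiment
#' @export
glance.degeneration_experiment <- function(x, ...) {
  recs <- x$records
  f0 <- dplyr::filter(recs, .data$injured_fraction == 0)
  fmax <- dplyr::filter(recs,
                        .data$injured_fraction == max(recs$injured_fraction))
  tibble::tibble(
    n_replicates = length(unique(recs$replicate_id)),
    n_fractions = length(unique(recs$injured_fraction)),
    max_fraction = max(recs$injured_fraction),
    baseline_accuracy = mean(f0$accuracy),
    final_accuracy = mean(fmax$accuracy),
    baseline_within_superclass_error =
      mean(f0$within_superclass_error_rate, na.rm = TRUE),
    final_tau_a_object = mean(fmax$tau_a_object, na.rm = TRUE),
    noise_floor_tau_a = mean(x$noise_floor$mean_tau_a),
    mode = x$config$mode,
    seed = x$config$seed
  )
}
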