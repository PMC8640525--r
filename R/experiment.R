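#' Configuration of a full degeneration experiment
#'
#' Bundles the synthetic-data generator, training profile, replicate count,
#' injury schedule and mode, and the RSA condition set. One base `seed`
#' derives every stream by a fixed counter rule: the generator uses
#' `derive_seed(seed, 0)`, replicate training `derive_seed(seed, 1000) + r`,
#' the per-replicate injury course `derive_seed(seed, 2000 + r)`, and the
#' noise-floor scrambles `derive_seed(seed, 3000 + r)`.
#'
#' @param generator A [generator_config()]; its seed is overridden from
#'   `seed`.
#' @param training A [training_config()]; its seed is overridden from `seed`.
#' @param n_replicates Number of uninjured replicate networks.
#' @param schedule An [injury_schedule()]. The default desk-scale schedule
#'   steps by 0.005 to 0.5 with checkpoints
#'   `{0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5}`.
#' @param mode Injury mode: `"ablate-zero"`, `"ablate-node"`, `"randomize"`.
#' @param rsa_stimuli_per_class Test stimuli per class entering the RDMs
#'   (a balanced, deterministic subset; RDM cost grows quadratically in the
#'   condition count).
#' @param noise_floor_reps Scrambles per replicate for the noise floor.
#' @param seed Base seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              training = training_config("small-cnn"),
                              n_replicates = 5,
                              schedule = injury_schedule(
                                increment = 0.005, max_fraction = 0.5,
                                rsa_checkpoints = c(0, 0.01, 0.05, 0.1,
                                                    0.2, 0.3, 0.5)),
                              mode = c("ablate-zero", "ablate-node",
                                       "randomize"),
                              rsa_stimuli_per_class = 10,
                              noise_floor_reps = 25,
                              seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(generator, "generator_config"),
            inherits(training, "training_config"),
            inherits(schedule, "injury_schedule"))
  seed <- check_count(seed, "seed", min = 0L)
  generator$seed <- derive_seed(seed, 0L)
  training$seed <- derive_seed(seed, 1000L)
  structure(list(generator = generator, training = training,
                 n_replicates = check_count(n_replicates, "n_replicates"),
                 schedule = schedule, mode = mode,
                 rsa_stimuli_per_class = check_count(rsa_stimuli_per_class,
                                                     "rsa_stimuli_per_class"),
                 noise_floor_reps = check_count(noise_floor_reps,
                                                "noise_floor_reps"),
                 seed = seed),
            class = "experiment_config")
}

# Balanced deterministic RSA condition subset: the first k test stimuli of
# each class, in class order.
rsa_condition_subset <- function(test, k) {
  idx <- unlist(lapply(sort(unique(test$labels)), function(cl) {
    head(which(test$labels == cl), k)
  }))
  idx
}

#' Run the full degeneration experiment
#'
#' For each replicate: train (or reuse) an uninjured network, compute its
#' object- and superclass-level reference RDMs and scrambled noise floor,
#' then walk the cumulative injury schedule. Accuracy and the
#' within-superclass error rate are recorded at every increment; at each
#' RSA checkpoint the injured RDMs are compared to the same replicate's
#' uninjured reference with Kendall's tau-a. Results are averaged across
#' replicates (mean and sample SD).
#'
#' @param cfg An [experiment_config()].
#' @param dataset Optional pre-generated `synthetic_dataset` (skips
#'   generation).
#' @param replicates Optional pre-trained `replicate_set` (skips training).
#' @param out_dir Optional directory; when given, results are exported via
#'   [export_results()] before returning.
#' @param verbose Emit per-stage progress messages.
#' @return A `degeneration_experiment`: `records` (one row per replicate x
#'   fraction), `summaries`, `rdms` (replicate-averaged object-level RDMs
#'   per checkpoint), `noise_floor` tibble, `replicates` metadata,
#'   `manifest` (all seeds), and the `config`.
#' @export
run_experiment <- function(cfg, dataset = NULL, replicates = NULL,
                           out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) inform(sprintf(...))

  say("stage=data action=generate seed=%d", cfg$generator$seed)
  dataset <- dataset %||% generate_dataset(cfg$generator)
  hierarchy <- dataset$hierarchy

  say("stage=train n_replicates=%d", cfg$n_replicates)
  replicates <- replicates %||%
    train_replicates(cfg$n_replicates, dataset$train, cfg$training,
                     test = dataset$test)
  n_rep <- length(replicates$models)

  cond_idx <- rsa_condition_subset(dataset$test, cfg$rsa_stimuli_per_class)
  rsa_images <- dataset$test$images[cond_idx, , , , drop = FALSE]
  rsa_labels <- dataset$test$labels[cond_idx]

  checkpoints <- cfg$schedule$rsa_checkpoints
  is_checkpoint <- function(f) any(abs(checkpoints - f) < 1e-9)

  records <- list()
  ckpt_rdms <- list()
  floors <- numeric(n_rep)
  injury_seeds <- integer(n_rep)

  for (r in seq_len(n_rep)) {
    model <- replicates$models[[r]]
    catalog <- build_catalog(model)
    sel_catalog <- if (cfg$mode == "ablate-node") build_unit_catalog(model)
                   else catalog

    ref_acts <- penultimate_activations(model, rsa_images)
    ref_rdm <- build_rdm(ref_acts, condition_ids = cond_idx)
    ref_sup <- superclass_rdm(ref_rdm, rsa_labels, hierarchy)
    nf <- scrambled_noise_floor(ref_rdm, n_reps = cfg$noise_floor_reps,
                                seed = derive_seed(cfg$seed, 3000L + r))
    floors[r] <- nf$mean_tau_a

    injury_seeds[r] <- derive_seed(cfg$seed, 2000L + r)
    state <- injury_state(sel_catalog, seed = injury_seeds[r], mode = cfg$mode)
    working <- model

    for (f in cfg$schedule$fractions) {
      state <- advance_injury(state, f, sel_catalog, model = working)
      working <- apply_injury(model, state, catalog)
      batch <- predict_labels(working, dataset$test)
      acc <- accuracy(batch)
      wse <- within_superclass_error_rate(batch)
      tau_o <- NA_real_
      tau_s <- NA_real_
      if (is_checkpoint(f)) {
        acts <- penultimate_activations(working, rsa_images)
        rdm <- build_rdm(acts, condition_ids = cond_idx)
        tau_o <- compare_rdms(rdm, ref_rdm)$tau_a
        tau_s <- compare_rdms(superclass_rdm(rdm, rsa_labels, hierarchy),
                              ref_sup)$tau_a
        key <- sprintf("%.6f", f)
        ckpt_rdms[[key]] <- c(ckpt_rdms[[key]], list(rdm))
        say("stage=rsa replicate=%d fraction=%.3f tau_object=%.3f tau_superclass=%.3f",
            r, f, tau_o, tau_s)
      }
      records[[length(records) + 1L]] <- tibble::tibble(
        replicate_id = r, injured_fraction = f, accuracy = acc,
        within_superclass_error_rate = wse,
        tau_a_object = tau_o, tau_a_superclass = tau_s)
    }
    say("stage=injury replicate=%d done final_accuracy=%.3f", r, acc)
  }

  records <- dplyr::bind_rows(records)
  summaries <- summarize_records(records)
  avg_rdms <- lapply(ckpt_rdms, average_rdms)

  manifest <- list(
    package_version = as.character(utils::packageVersion("degensim")),
    base_seed = cfg$seed,
    generator_seed = cfg$generator$seed,
    training_seeds = replicates$seeds,
    injury_seeds = injury_seeds,
    noise_floor_seeds = derive_seed(cfg$seed, 3000L) + seq_len(n_rep),
    mode = cfg$mode,
    n_rsa_conditions = length(cond_idx))

  result <- structure(list(
    records = records, summaries = summaries, rdms = avg_rdms,
    noise_floor = tibble::tibble(replicate_id = seq_len(n_rep),
                                 mean_tau_a = floors),
    replicates = replicates$metadata, manifest = manifest, config = cfg),
    class = "degeneration_experiment")

  if (!is.null(out_dir)) {
    export_results(records, summaries, out_dir, rdms = avg_rdms,
                   manifest = manifest)
  }
  result
}

#' @export
print.degeneration_experiment <- function(x, ...) {
  cat(sprintf(
    "<degeneration_experiment> %d replicates, %d fractions (mode %s)\n",
    max(x$records$replicate_id), length(unique(x$records$injured_fraction)),
    x$config$mode))
  base <- dplyr::filter(x$summaries, .data$injured_fraction == 0,
                        .data$metric == "accuracy")
  cat(sprintf("  baseline accuracy %.3f +/- %.3f; noise floor tau_a %.5f\n",
              base$mean, base$sd, mean(x$noise_floor$mean_tau_a)))
  invisible(x)
}

#' Summarise degeneration records across replicates
#'
#' Mean and sample (n-1 denominator) standard deviation per injured
#' fraction per metric. Undefined within-superclass values (error-free
#' batches) are excluded from that metric's `n`; fractions where a metric
#' was not evaluated (non-checkpoint tau-a) are dropped for that metric.
#' A single contributing replicate reports `sd = 0` with `n = 1`.
#'
#' @param records The records tibble from [run_experiment()].
#' @return A long tibble: `injured_fraction`, `metric`, `mean`, `sd`, `n`,
#'   ordered by fraction.
#' @export
summarize_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a non-empty data frame.",
          class = "degensim_invalid_argument")
  }
  records |>
    tidyr::pivot_longer(cols = c("accuracy", "within_superclass_error_rate",
                                 "tau_a_object", "tau_a_superclass"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$injured_fraction, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) sd(.data$value) else 0,
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$injured_fraction, .data$metric)
}

#' Export experiment results as delimited text
#'
#' Writes `records.csv` (column order fixed: `replicate_id,
#' injured_fraction, accuracy, within_superclass_error_rate, tau_a_object,
#' tau_a_superclass`; missing metrics are empty fields, never 0),
#' `summaries.csv`, a `manifest.json`, and — when supplied — each
#' checkpoint-averaged RDM as a float64 tensor file with a JSON header.
#' Re-export over an existing directory is idempotent.
#'
#' @param records,summaries Tibbles from [run_experiment()] /
#'   [summarize_records()].
#' @param directory Output directory (created if needed).
#' @param rdms Optional named list of `rdm` objects (names = fraction keys).
#' @param manifest Optional manifest list to serialise.
#' @return Tibble of written paths, invisibly.
#' @export
export_results <- function(records, summaries, directory, rdms = NULL,
                           manifest = NULL) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  cols <- c("replicate_id", "injured_fraction", "accuracy",
            "within_superclass_error_rate", "tau_a_object",
            "tau_a_superclass")
  stopifnot(all(cols %in% names(records)))
  paths <- c(records = file.path(directory, "records.csv"),
             summaries = file.path(directory, "summaries.csv"))
  readr::write_csv(records[, cols], paths[["records"]], na = "")
  readr::write_csv(summaries, paths[["summaries"]], na = "")
  if (!is.null(manifest)) {
    p <- file.path(directory, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, manifest = p)
  }
  for (key in names(rdms)) {
    stem <- file.path(directory, paste0("rdm_object_f", key))
    r <- rdms[[key]]
    con <- file(paste0(stem, ".bin"), "wb")
    writeBin(as.double(r$D), con, size = 8, endian = "little")
    close(con)
    jsonlite::write_json(
      list(format = "degensim-rdm", shape = dim(r$D),
           dtype = "float64", condition_ids = r$condition_ids),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, stats::setNames(paste0(stem, ".bin"),
                                      paste0("rdm_", key)))
  }
  invisible(tibble::tibble(artifact = names(paths), path = unname(paths)))
}

#' Read back exported records and summaries
#'
#' @param directory Directory written by [export_results()].
#' @return List with `records` and `summaries` tibbles.
#' @export
read_results <- function(directory) {
  rp <- file.path(directory, "records.csv")
  if (!file.exists(rp)) {
    abort(sprintf("No records.csv in `%s`.", directory),
          class = "degensim_format_error")
  }
  records <- readr::read_csv(rp, col_types = "iddddd", na = "",
                             show_col_types = FALSE)
  sp <- file.path(directory, "summaries.csv")
  summaries <- if (file.exists(sp)) {
    readr::read_csv(sp, col_types = "dcddi", na = "", show_col_types = FALSE)
  } else NULL
  list(records = records, summaries = summaries)
}
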