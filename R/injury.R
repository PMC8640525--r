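# RNG plumbing: injury states carry their own generator state so each
# replicate's degeneration course is an independent, reproducible stream.

capture_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  get(".Random.seed", globalenv())
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, globalenv())
  }
}

rng_eval <- function(rstate, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  assign(".Random.seed", rstate, globalenv())
  result <- fn()
  list(result = result, rng = get(".Random.seed", globalenv()))
}

#' Catalog of ablatable connection weights
#'
#' Enumerates every inter-layer connection weight in the model as one global
#' index: convolutional kernels and dense weight matrices counted
#' elementwise, in layer order and column-major order within each tensor.
#' Bias terms are excluded — they are per-neuron offsets, not inter-neuron
#' connections, and the injury model targets synapses. Pretrained
#' (e.g. vgg19) convolutional weights are included like any others.
#'
#' @param model A `classifier_model`.
#' @return A `weight_catalog`: tensor names, sizes, cumulative offsets and
#'   total count `N`.
#' @export
build_catalog <- function(model) {
  stopifnot(inherits(model, "classifier_model"))
  kn <- grep("/kernel$", names(model$weights), value = TRUE)
  if (length(kn) == 0L) {
    abort("Model has no connection-weight tensors.",
          class = "degensim_invalid_argument")
  }
  sizes <- vapply(model$weights[kn], length, numeric(1))
  structure(list(tensors = kn, sizes = as.double(sizes),
                 offsets = cumsum(c(0, sizes[-length(sizes)])),
                 N = sum(sizes)),
            class = "weight_catalog")
}

#' @export
print.weight_catalog <- function(x, ...) {
  cat(sprintf("<weight_catalog> %d weights in %d tensors\n",
              x$N, length(x$tensors)))
  invisible(x)
}

# global index -> per-tensor (tensor, position) split
split_catalog_indices <- function(catalog, idx) {
  t_idx <- findInterval(idx - 0.5, catalog$offsets)
  split(idx - catalog$offsets[t_idx], catalog$tensors[t_idx])
}

#' Number of weights injured at a nominal fraction
#'
#' Nearest-integer rounding, half away from zero, so that stepping a
#' cumulative schedule and jumping directly to the same fraction injure
#' identical counts.
#'
#' @param f Fraction in `[0, 1]`.
#' @param N Catalog size.
#' @return Integer count; 0 at `f = 0`, `N` at `f = 1`, monotone in `f`.
#' @export
target_count <- function(f, N) {
  f <- check_fraction(f, "f")
  N <- check_count(N, "N", min = 0L)
  as.integer(round_half_away(f * N))
}

#' Create an uninjured injury state
#'
#' @param catalog A [build_catalog()] result (or a unit catalog for
#'   `"ablate-node"`).
#' @param seed Integer seed for this state's private selection stream.
#' @param mode `"ablate-zero"` (weights set to 0), `"ablate-node"` (whole
#'   units lesioned), or `"randomize"` (weights reset to random values).
#' @return An `injury_state` at fraction 0.
#' @export
injury_state <- function(catalog, seed, mode = c("ablate-zero", "ablate-node",
                                                 "randomize")) {
  mode <- match.arg(mode)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(injured = integer(0), fraction = 0, mode = mode,
                 rng = capture_rng(seed), seed = seed,
                 injured_units = integer(0), replacements = numeric(0)),
            class = "injury_state")
}

#' @export
print.injury_state <- function(x, ...) {
  cat(sprintf("<injury_state:%s> fraction %.4f, %d weights injured\n",
              x$mode, x$fraction, length(x$injured)))
  invisible(x)
}

#' Advance a cumulative injury to a higher fraction
#'
#' Selects exactly `target_count(new_fraction, N) - target_count(fraction,
#' N)` additional victims uniformly at random, without replacement, from
#' the not-yet-injured pool, consuming the state's private generator.
#' Previously injured entries are never revisited — injury is irreversible
#' and the injured set at any lower fraction is a subset of the set at any
#' higher fraction.
#'
#' For `"ablate-node"` the selection pool is network units (conv channels
#' and hidden dense neurons; see [build_unit_catalog()]) and the fraction is
#' interpreted over units. For `"randomize"` the newly selected weights are
#' assigned fresh draws from a zero-mean normal whose scale matches their
#' layer's weight standard deviation at selection time, which requires the
#' current `model`.
#'
#' @param state An `injury_state`.
#' @param new_fraction Target fraction, `>= state$fraction`.
#' @param catalog The matching [build_catalog()] (weight modes) or
#'   [build_unit_catalog()] (node mode).
#' @param model Current model; required for `"randomize"`.
#' @return The advanced `injury_state`.
#' @export
advance_injury <- function(state, new_fraction, catalog, model = NULL) {
  stopifnot(inherits(state, "injury_state"))
  new_fraction <- check_fraction(new_fraction, "new_fraction")
  if (new_fraction < state$fraction) {
    abort("Injury is irreversible: `new_fraction` must be >= current fraction.",
          class = "degensim_invalid_argument")
  }
  if (state$mode == "ablate-node") {
    return(advance_node(state, new_fraction, catalog))
  }
  N <- catalog$N
  want <- target_count(new_fraction, N)
  k <- want - length(state$injured)
  if (k > 0) {
    pool <- setdiff(seq_len(N), state$injured)
    ev <- rng_eval(state$rng, function() {
      picked <- pool[sample.int(length(pool), k)]
      repl <- NULL
      if (state$mode == "randomize") {
        if (is.null(model)) {
          abort("`randomize` mode needs `model` to scale replacement draws.",
                class = "degensim_invalid_argument")
        }
        by_tensor <- split_catalog_indices(catalog, picked)
        repl <- numeric(length(picked))
        for (nm in names(by_tensor)) {
          s <- sd(model$weights[[nm]])
          sel <- match(by_tensor[[nm]] + catalog$offsets[match(nm, catalog$tensors)],
                       picked)
          repl[sel] <- rnorm(length(sel), mean = 0, sd = s)
        }
      }
      list(picked = picked, repl = repl)
    })
    state$injured <- c(state$injured, ev$result$picked)
    if (state$mode == "randomize") {
      state$replacements <- c(state$replacements, ev$result$repl)
    }
    state$rng <- ev$rng
  }
  state$fraction <- new_fraction
  state
}

#' Advance an injury in a Discussion-variant mode
#'
#' Thin validated wrapper over [advance_injury()] for the `"ablate-node"`
#' and `"randomize"` variants.
#'
#' @inheritParams advance_injury
#' @param mode `"ablate-node"` or `"randomize"`; must match the state.
#' @export
advance_variant <- function(state, new_fraction, catalog, mode, model = NULL) {
  if (!mode %in% c("ablate-node", "randomize")) {
    abort(sprintf("Unknown variant mode `%s`.", mode),
          class = "degensim_invalid_argument")
  }
  if (!identical(state$mode, mode)) {
    abort("`mode` does not match the state's mode.",
          class = "degensim_invalid_argument")
  }
  advance_injury(state, new_fraction, catalog, model = model)
}

advance_node <- function(state, new_fraction, unit_catalog) {
  stopifnot(inherits(unit_catalog, "unit_catalog"))
  Nu <- length(unit_catalog$units)
  want <- target_count(new_fraction, Nu)
  k <- want - length(state$injured_units)
  if (k > 0) {
    pool <- setdiff(seq_len(Nu), state$injured_units)
    ev <- rng_eval(state$rng, function() pool[sample.int(length(pool), k)])
    state$injured_units <- c(state$injured_units, ev$result)
    new_w <- unlist(lapply(unit_catalog$units[ev$result],
                           function(u) u$weight_indices))
    state$injured <- union(state$injured, new_w)
    state$rng <- ev$rng
  }
  state$fraction <- new_fraction
  state
}

#' Apply an injury state to a model
#'
#' Returns an injured copy: the selected weights are set to exactly zero
#' (`ablate-zero`, `ablate-node`) or to their stored replacement values
#' (`randomize`). All uninjured weights and all biases are bit-identical to
#' the input model, which is never modified.
#'
#' @param model The uninjured (or previously copied) `classifier_model`.
#' @param state An `injury_state`.
#' @param catalog The weight catalog built from the same architecture. For
#'   `"ablate-node"` pass the weight-level [build_catalog()] here; the
#'   state's injured weight set was derived from the unit catalog.
#' @return An injured `classifier_model` copy.
#' @export
apply_injury <- function(model, state, catalog) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(state, "injury_state"),
            inherits(catalog, "weight_catalog"))
  sizes <- vapply(model$weights[catalog$tensors], length, numeric(1))
  if (!identical(as.double(sizes), catalog$sizes)) {
    abort("Catalog does not match the model's weight tensors.",
          class = "degensim_invalid_argument")
  }
  if (length(state$injured) == 0L) return(model)
  idx <- state$injured
  values <- if (state$mode == "randomize") state$replacements else
    numeric(length(idx))
  t_idx <- findInterval(idx - 0.5, catalog$offsets)
  for (nm in unique(catalog$tensors[t_idx])) {
    sel <- t_idx == match(nm, catalog$tensors)
    pos <- idx[sel] - catalog$offsets[match(nm, catalog$tensors)]
    w <- model$weights[[nm]]
    w[pos] <- values[sel]
    model$weights[[nm]] <- w
  }
  model
}

#' Catalog of ablatable units for node ablation
#'
#' Units are convolutional channels and hidden dense neurons (output-layer
#' neurons are the class scores themselves and are not lesioned). Ablating
#' a unit zeroes all of its incoming weights (its kernel slice / dense
#' column) and all of its outgoing weights (the consuming layer's kernel
#' slice, dense row, or — across a flatten — the dense rows fed by that
#' channel's spatial positions).
#'
#' @param model A `classifier_model`.
#' @return A `unit_catalog`: list of units, each carrying the global weight
#'   indices (into [build_catalog()]) it touches.
#' @export
build_unit_catalog <- function(model) {
  catalog <- build_catalog(model)
  shapes <- layer_input_shapes(model$layers, model$input_shape)
  layers <- model$layers
  toff <- function(nm) catalog$offsets[match(paste0(nm, "/kernel"),
                                             catalog$tensors)]
  units <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!(l$type %in% c("conv", "dense"))) next
    if (l$type == "dense" && identical(l$activation, "softmax")) next
    n_units <- if (l$type == "conv") l$filters else l$units

    # locate the next weighted layer and the shape it consumes
    j <- i + 1L
    while (j <= length(layers) && !(layers[[j]]$type %in% c("conv", "dense")))
      j <- j + 1L
    nxt <- if (j <= length(layers)) layers[[j]] else NULL
    nxt_in <- if (!is.null(nxt)) shapes[[j]] else NULL

    for (u in seq_len(n_units)) {
      if (l$type == "conv") {
        k <- l$kernel
        cin <- shapes[[i]][3]
        incoming <- toff(l$name) + (u - 1L) * k * k * cin + seq_len(k * k * cin)
      } else {
        cin <- shapes[[i]]
        incoming <- toff(l$name) + (u - 1L) * cin + seq_len(cin)
      }
      outgoing <- integer(0)
      if (!is.null(nxt)) {
        if (nxt$type == "conv") {
          k2 <- nxt$kernel
          cin2 <- nxt_in[3]
          per_f <- k2 * k2 * cin2
          outgoing <- as.vector(outer(
            (u - 1L) * k2 * k2 + seq_len(k2 * k2),
            (seq_len(nxt$filters) - 1L) * per_f, "+")) + toff(nxt$name)
        } else if (l$type == "conv") {
          # conv unit feeding a dense layer across the flatten: its channel
          # occupies a contiguous row block (H fastest, then W, then C)
          hw <- nxt_in %/% l$filters
          rows <- (u - 1L) * hw + seq_len(hw)
          outgoing <- as.vector(outer(rows, (seq_len(nxt$units) - 1L) * nxt_in,
                                      "+")) + toff(nxt$name)
        } else {
          outgoing <- toff(nxt$name) + u + (seq_len(nxt$units) - 1L) * nxt_in
        }
      }
      units[[length(units) + 1L]] <- list(
        layer = l$name, unit = u,
        weight_indices = c(incoming, outgoing))
    }
  }
  structure(list(units = units, weight_catalog = catalog, N = length(units)),
            class = "unit_catalog")
}

#' Injury schedule
#'
#' A cumulative schedule of nominal injured fractions: `increment` steps
#' from 0 up to `max_fraction` (default increment 0.001, i.e. 0.1% per
#' step), with a subset of fractions designated as RSA checkpoints where
#' representational readouts are computed.
#'
#' @param increment Step size in `(0, max_fraction]`.
#' @param max_fraction Final injured fraction, `<= 1`.
#' @param rsa_checkpoints Fractions (subset of the achievable grid) at which
#'   RDMs and tau-a are evaluated. Defaults to `c(0, max_fraction)`.
#' @return An `injury_schedule` with the full fraction grid.
#' @export
injury_schedule <- function(increment = 0.001, max_fraction = 0.3,
                            rsa_checkpoints = NULL) {
  increment <- check_scalar_number(increment, "increment", min = 0)
  max_fraction <- check_fraction(max_fraction, "max_fraction")
  if (increment <= 0 || (max_fraction > 0 && increment > max_fraction)) {
    abort("Need 0 < increment <= max_fraction <= 1 (or max_fraction = 0 for an uninjured baseline).",
          class = "degensim_invalid_argument")
  }
  n_steps <- floor(max_fraction / increment + 1e-9)
  fractions <- c(0, increment * seq_len(n_steps))
  if (abs(fractions[length(fractions)] - max_fraction) > 1e-9) {
    fractions <- c(fractions, max_fraction)
  }
  rsa_checkpoints <- rsa_checkpoints %||% c(0, max_fraction)
  ok <- vapply(rsa_checkpoints,
               function(f) any(abs(fractions - f) < 1e-9), logical(1))
  if (!all(ok)) {
    abort("All `rsa_checkpoints` must lie on the schedule's fraction grid.",
          class = "degensim_invalid_argument")
  }
  structure(list(increment = increment, max_fraction = max_fraction,
                 fractions = fractions,
                 rsa_checkpoints = sort(rsa_checkpoints)),
            class = "injury_schedule")
}
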