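#' Construct a layered network with stochastically releasing synapses
#'
#' Each synapse `i` carries a strength `m_i` and a release probability
#' `p_i`; on every presentation it transmits `w_i = r_i * m_i` with
#' `r_i ~ Bernoulli(p_i)`, so the expected strength is `wbar_i = p_i * m_i`.
#' Hidden layers use the rectifier nonlinearity, the readout layer a
#' softmax; there are no bias terms. Strengths are initialised uniformly on
#' `[-1/sqrt(fan_in), +1/sqrt(fan_in)]` (the Kaiming-uniform bound
#' `sqrt(6/fan_in)` divided by `sqrt(6)`), using R's global RNG, so
#' `set.seed()` makes the initialisation reproducible.
#'
#' @param sizes Integer vector of at least two layer widths, e.g.
#'   `c(784, 200, 200, 10)`.
#' @param p_init Initial release probability for every synapse, in
#'   `[p_min, 1]`. The default 0.25 is also the lower clamp.
#' @param p_min Lower clamp for release probabilities.
#' @param ghost If `TRUE`, transmission probabilities are fixed at 0.5 and a
#'   parallel "ghost" probability array (initialised at `p_init`) is
#'   attached; the metaplasticity rule then drives the ghost array while
#'   transmission stays at 0.5. Used for the consolidation-only ablation.
#' @return An object of class `stoch_net`: a list with elements `layers`
#'   (each a list with matrices `m`, `p`, `frozen` of shape
#'   fan_in x fan_out, plus `p_ghost` when `ghost`), `sizes`, `p_min`,
#'   and `ghost`.
#' @examples
#' set.seed(1)
#' net <- stochastic_network(c(8, 5, 3))
#' range(net$layers[[1]]$m)  # within [-1/sqrt(8), 1/sqrt(8)]
#' @export
stochastic_network <- function(sizes, p_init = 0.25, p_min = 0.25,
                               ghost = FALSE) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L) stop("`sizes` needs at least two layer widths")
  if (any(sizes <= 0L)) stop("layer sizes must be positive")
  if (p_init < p_min || p_init > 1) stop("`p_init` must lie in [p_min, 1]")
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    bound <- 1 / sqrt(fan_in)
    m <- matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
    p <- matrix(if (ghost) 0.5 else p_init, fan_in, fan_out)
    layer <- list(m = m, p = p,
                  frozen = matrix(FALSE, fan_in, fan_out))
    if (ghost) layer$p_ghost <- matrix(p_init, fan_in, fan_out)
    layers[[l]] <- layer
  }
  structure(list(layers = layers, sizes = sizes, p_min = p_min,
                 ghost = ghost),
            class = "stoch_net")
}

#' @export
print.stoch_net <- function(x, ...) {
  cat("<stoch_net> ", paste(x$sizes, collapse = "-"),
      if (x$ghost) " (ghost transmission p = 0.5)" else "", "\n", sep = "")
  cat(sprintf("  %d synapses | mean p = %.3f | frozen = %.1f%% | energy = %.3f\n",
              n_synapses(x), mean(unlist(lapply(x$layers, `[[`, "p"))),
              100 * mean(unlist(lapply(x$layers, `[[`, "frozen"))),
              synaptic_energy(x)))
  invisible(x)
}

#' Number of synapses in a network
#' @param net A `stoch_net`.
#' @return Integer count over all layers.
#' @export
n_synapses <- function(net) {
  sum(vapply(net$layers, function(l) length(l$m), numeric(1)))
}

#' Expected synaptic weights
#'
#' The elementwise product `wbar = p * m` per layer: the mean postsynaptic
#' effect of each synapse, and the quantity both the strength-learning rule
#' and the energy measure operate on.
#'
#' @param net A `stoch_net`.
#' @return List of matrices, one per layer.
#' @export
expected_weights <- function(net) {
  lapply(net$layers, function(l) l$p * l$m)
}

#' The metaplastic probability array of a layer
#'
#' In the ghost ablation the learned array is `p_ghost` while transmission
#' uses a fixed probability; everywhere else the learned and transmitting
#' arrays coincide.
#' @noRd
plastic_p <- function(net, l) {
  if (net$ghost) net$layers[[l]]$p_ghost else net$layers[[l]]$p
}

layer_matrices <- function(net, field) lapply(net$layers, `[[`, field)

#' Draw release masks for a network or one layer
#'
#' Independent Bernoulli draws with each synapse's release probability:
#' `r_i ~ Bernoulli(p_i)`. A fixed `seed` reproduces the mask bit-exactly.
#'
#' @param net A `stoch_net`.
#' @param layer Layer index, or `NULL` for all layers.
#' @param seed Integer seed for the mask RNG; drawn from R's global RNG
#'   when `NULL`.
#' @return A 0/1 integer matrix (single layer) or list of such matrices.
#' @export
sample_release <- function(net, layer = NULL, seed = NULL) {
  if (is.null(seed)) seed <- kernel_seed()
  if (!is.null(layer)) {
    return(cpp_sample_mask(net$layers[[layer]]$p, seed))
  }
  lapply(seq_along(net$layers), function(l)
    cpp_sample_mask(net$layers[[l]]$p, seed + l - 1))
}

#' Stochastic forward pass for a single input
#'
#' Draws one fresh release mask per synapse and computes each neuron's
#' stochastic weighted sum `sigma(sum_i r_i m_i a_i)`; hidden layers apply
#' the rectifier and the readout a softmax. The returned cache (per-layer
#' activations, preactivations, and masks) supports gradient computation.
#'
#' @param net A `stoch_net`.
#' @param input Numeric vector of length `sizes[1]`.
#' @param seed Mask seed; drawn from R's global RNG when `NULL`. Example
#'   `e` of a batch processed by [compute_update_direction()] with seed `s`
#'   uses mask seed `s + e - 1`, so `forward_stochastic(net, x, seed = s)`
#'   reproduces the masks of the first batch example exactly.
#' @return A list of class `stoch_forward` with `output` (class
#'   probabilities), `activations`, `preactivations`, `masks`, `seed`.
#' @export
forward_stochastic <- function(net, input, seed = NULL) {
  if (length(input) != net$sizes[1]) {
    stop("input length does not match first-layer fan-in")
  }
  if (is.null(seed)) seed <- kernel_seed()
  res <- cpp_forward_example(layer_matrices(net, "m"), layer_matrices(net, "p"),
                             as.numeric(input), TRUE, seed)
  structure(list(output = res$output, activations = res$activations,
                 preactivations = res$preactivations, masks = res$masks,
                 seed = seed),
            class = "stoch_forward")
}

#' Deterministic forward pass under expected weights
#'
#' Replaces every sampled release by its expectation, i.e. runs the network
#' with weights `wbar = p * m`. With `p = 1` everywhere this is an ordinary
#' deterministic multilayer perceptron.
#'
#' @inheritParams forward_stochastic
#' @return Numeric vector of class probabilities.
#' @export
forward_expected <- function(net, input) {
  if (length(input) != net$sizes[1]) {
    stop("input length does not match first-layer fan-in")
  }
  res <- cpp_forward_example(layer_matrices(net, "m"), layer_matrices(net, "p"),
                             as.numeric(input), FALSE, 0)
  res$output
}

#' Serialise a network to a structured JSON file
#'
#' Writes architecture metadata and the per-layer `p`, `m`, `frozen` (and
#' ghost) arrays; [read_network()] restores the object bit-exactly. Real
#' arrays are stored as decimal strings with 17 significant digits, which
#' round-trips IEEE doubles without loss.
#'
#' @param net A `stoch_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  num <- function(v) sprintf("%.17g", as.numeric(v))
  payload <- list(
    format = "stochsyn-network",
    version = 1L,
    sizes = net$sizes,
    p_min = net$p_min,
    ghost = net$ghost,
    layers = lapply(net$layers, function(l) {
      out <- list(m = num(l$m), p = num(l$p),
                  frozen = as.logical(l$frozen))
      if (!is.null(l$p_ghost)) out$p_ghost <- num(l$p_ghost)
      out
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a network written by [write_network()]
#' @param path File written by [write_network()].
#' @return A `stoch_net`.
#' @export
read_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "stochsyn-network")) {
    stop("not a stochsyn network file")
  }
  sizes <- as.integer(payload$sizes)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    src <- if (is.data.frame(payload$layers)) {
      lapply(payload$layers, function(col) col[[l]])
    } else payload$layers[[l]]
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    layer <- list(m = matrix(as.numeric(src$m), fan_in, fan_out),
                  p = matrix(as.numeric(src$p), fan_in, fan_out),
                  frozen = matrix(src$frozen, fan_in, fan_out))
    if (!is.null(src$p_ghost) && !all(is.na(src$p_ghost))) {
      layer$p_ghost <- matrix(as.numeric(src$p_ghost), fan_in, fan_out)
    }
    layers[[l]] <- layer
  }
  structure(list(layers = layers, sizes = sizes, p_min = payload$p_min,
                 ghost = isTRUE(payload$ghost)),
            class = "stoch_net")
}
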