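#' Tidy a network into a per-synapse tibble
#'
#' One row per synapse: layer, presynaptic and postsynaptic indices,
#' strength `m`, release probability `p`, expected weight `wbar`, frozen
#' flag (and `p_ghost` when present).
#'
#' @param x A `stoch_net`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stoch_net <- function(x, ...) {
  purrr::map_dfr(seq_along(x$layers), function(l) {
    lay <- x$layers[[l]]
    out <- tibble::tibble(
      layer = l,
      pre = as.vector(row(lay$m)),
      post = as.vector(col(lay$m)),
      m = as.vector(lay$m),
      p = as.vector(lay$p),
      wbar = as.vector(lay$p * lay$m),
      frozen = as.vector(lay$frozen))
    if (!is.null(lay$p_ghost)) out$p_ghost <- as.vector(lay$p_ghost)
    out
  })
}

#' One-row summary of a network
#'
#' @param x A `stoch_net`.
#' @param ... Unused.
#' @return A tibble with `n_synapses`, `mean_p`, `frac_frozen`, `energy`,
#'   `frac_high_p` (share of synapses with p >= 0.9).
#' @export
glance.stoch_net <- function(x, ...) {
  p <- unlist(lapply(x$layers, `[[`, "p"))
  tibble::tibble(
    n_synapses = n_synapses(x),
    mean_p = mean(p),
    frac_high_p = mean(p >= 0.9),
    frac_frozen = mean(unlist(lapply(x$layers, `[[`, "frozen"))),
    energy = synaptic_energy(x))
}

#' Tidy a Fisher estimate, joined with the release probabilities
#'
#' @param x A `fisher_estimate`.
#' @param net Optional `stoch_net` supplying `p` and `m` columns.
#' @param ... Unused.
#' @return A tibble with `layer`, `pre`, `post`, `fisher` (and `p`, `m`).
#' @export
tidy.fisher_estimate <- function(x, net = NULL, ...) {
  out <- purrr::map_dfr(seq_along(x$F), function(l) {
    f <- x$F[[l]]
    tibble::tibble(layer = l, pre = as.vector(row(f)),
                   post = as.vector(col(f)), fisher = as.vector(f))
  })
  if (!is.null(net)) {
    syn <- tidy(net)
    out$p <- syn$p
    out$m <- syn$m
  }
  out
}

#' Tidy an evaluation into joint label/prediction counts
#'
#' @param x A `stoch_eval`.
#' @param ... Unused.
#' @return A tibble with `label`, `prediction`, `count`.
#' @export
tidy.stoch_eval <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts,
                                        responseName = "count")) |>
    dplyr::transmute(label = as.integer(as.character(.data$Var1)),
                     prediction = as.integer(as.character(.data$Var2)),
                     count = as.integer(.data$count))
}

#' One-row summary of an evaluation
#'
#' @param x A `stoch_eval`.
#' @param ... Unused.
#' @return A tibble with `n`, `accuracy`, `mutual_information` (bits).
#' @export
glance.stoch_eval <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 mutual_information = mutual_information(x$counts),
                 mode = x$mode)
}

#' Per-neuron table of a sparsity report
#'
#' @param x A `sparsity_report`.
#' @param ... Unused.
#' @return The per-neuron tibble.
#' @export
tidy.sparsity_report <- function(x, ...) x$neurons

#' One-row summary of a sparsity report
#'
#' @param x A `sparsity_report`.
#' @param ... Unused.
#' @return A tibble with the KS statistic, neuron counts, and the
#'   input/output importance correlation.
#' @export
glance.sparsity_report <- function(x, ...) {
  tibble::tibble(ks_statistic = x$ks_statistic, n_low = x$n_low,
                 n_medium = x$n_medium, n_high = x$n_high,
                 correlation_in_out = x$correlation_in_out,
                 p_important = x$p_important, layer = x$layer)
}

#' Final per-task accuracies of a lifelong run
#'
#' @param x A `lifelong_run`.
#' @param ... Unused.
#' @return A tibble with `first_task_final`, `mean_final`, `variant`.
#' @export
glance.lifelong_run <- function(x, ...) {
  fin <- dplyr::filter(x$accuracy, .data$checkpoint == max(.data$checkpoint))
  tibble::tibble(
    variant = x$variant,
    first_task_final = fin$accuracy[fin$task == 1],
    mean_final = mean(fin$accuracy))
}
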