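#' Synaptic energy of a network
#'
#' The dominant metabolic cost of neural signalling is reversing
#' postsynaptic ion fluxes, whose model analogue is the expected
#' postsynaptic current. Energy is therefore the summed magnitude of the
#' expected synaptic strengths, `sum_i |p_i * m_i|` (model units).
#'
#' @param net A `stoch_net`.
#' @param per_synapse If `TRUE`, return per-layer matrices of `|p * m|`
#'   instead of the total.
#' @return A nonnegative scalar, or a list of matrices.
#' @export
synaptic_energy <- function(net, per_synapse = FALSE) {
  e <- lapply(expected_weights(net), abs)
  if (per_synapse) e else sum(unlist(e))
}

#' Plug-in mutual information of a joint count table
#'
#' `I(Y; Z) = H(Y) - H(Y | Z)` of the empirical joint distribution, in
#' bits. Used with `Y` the ground-truth label and `Z` the network's
#' prediction, it measures how much task-relevant information reaches the
#' network output.
#'
#' @param counts Nonnegative matrix of joint counts (labels in rows,
#'   predictions in columns); total must be positive.
#' @return Mutual information in bits.
#' @examples
#' mutual_information(diag(2) * 50)  # a perfectly predicted fair bit: 1
#' @export
mutual_information <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("empty count table")
  pj <- counts / n
  py <- rowSums(pj)
  pz <- colSums(pj)
  ind <- outer(py, pz)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / ind[nz]))
}

#' Evaluate network predictions on a labelled dataset
#'
#' Predicts the arg-max class for every example, either from class scores
#' averaged over `K` independent release-mask draws (`"sampled"`, the
#' default, reflecting transmission stochasticity) or from the expected
#' weights (`"expected"`).
#'
#' @param net A `stoch_net`.
#' @param data A [labelled_dataset()].
#' @param mode `"sampled"` or `"expected"`.
#' @param K Number of mask draws averaged in sampled mode.
#' @param seed Mask seed; from R's global RNG when `NULL`.
#' @return A list of class `stoch_eval`: `counts` (label x prediction joint
#'   count table), `accuracy`, `n`, `mode`.
#' @export
evaluate_predictions <- function(net, data, mode = c("sampled", "expected"),
                                 K = 10, seed = NULL) {
  mode <- match.arg(mode)
  data <- as_labelled_dataset(data)
  if (ncol(data$x) != net$sizes[1]) {
    stop("dataset dimension does not match first-layer fan-in")
  }
  if (is.null(seed)) seed <- kernel_seed()
  scores <- cpp_evaluate_scores(layer_matrices(net, "m"),
                                layer_matrices(net, "p"), data$x,
                                if (mode == "sampled") 1L else 0L,
                                as.integer(K), seed)
  pred <- max.col(scores, ties.method = "first") - 1L
  ncls <- max(data$n_classes, ncol(scores))
  counts <- table(factor(data$y, levels = 0:(ncls - 1)),
                  factor(pred, levels = 0:(ncls - 1)))
  counts <- unclass(as.matrix(counts))
  structure(list(counts = counts,
                 accuracy = mean(pred == data$y),
                 n = length(data$y), mode = mode),
            class = "stoch_eval")
}

#' @export
print.stoch_eval <- function(x, ...) {
  cat(sprintf("<stoch_eval> n=%d accuracy=%.4f MI=%.4f bits (%s mode)\n",
              x$n, x$accuracy, mutual_information(x$counts), x$mode))
  invisible(x)
}

#' Diagonal empirical Fisher information per synapse
#'
#' The mean over examples of the squared per-example gradient of the loss
#' with respect to the expected strengths, `F_i = E[g_i(X, y)^2]` with
#' empirical labels. Per-example gradients are used (never batch-averaged),
#' taken through sampled release masks by default - the same gradients that
#' drive learning.
#'
#' @param net A `stoch_net`.
#' @param data A [labelled_dataset()]; must be non-empty.
#' @param mode Gradient mode, `"sampled"` or `"expected"`.
#' @param seed Mask seed.
#' @return A list of class `fisher_estimate`: per-layer nonnegative
#'   matrices `F`, plus `n` examples used.
#' @export
empirical_fisher <- function(net, data, mode = c("sampled", "expected"),
                             seed = NULL) {
  mode <- match.arg(mode)
  data <- as_labelled_dataset(data)
  if (length(data$y) == 0) stop("empty dataset")
  if (is.null(seed)) seed <- kernel_seed()
  res <- cpp_batch_grad(layer_matrices(net, "m"), layer_matrices(net, "p"),
                        data$x, data$y, mode == "sampled", seed, TRUE)
  structure(list(F = res$fisher, n = length(data$y), mode = mode),
            class = "fisher_estimate")
}

#' @export
print.fisher_estimate <- function(x, ...) {
  cat(sprintf("<fisher_estimate> %d layers, n=%d, median F=%.3g\n",
              length(x$F), x$n, median(unlist(x$F))))
  invisible(x)
}

# Global synapse order used for lesioning: release probability ascending,
# ties broken by |m| ascending, then by linear index.
lesion_order <- function(net) {
  p <- unlist(lapply(net$layers, `[[`, "p"))
  m <- unlist(lapply(net$layers, `[[`, "m"))
  order(p, abs(m), seq_along(p))
}

#' Lesion experiment: remove synapses and track accuracy
#'
#' Cumulatively removes (zeroes the strength of) a growing fraction of
#' synapses, either lowest release probability first or in a random order,
#' and evaluates test accuracy at each fraction. If high-`p` synapses
#' carry the task, the low-`p`-first curve stays high far longer than the
#' random-order control.
#'
#' @param net A trained `stoch_net`.
#' @param data Evaluation [labelled_dataset()].
#' @param ordering `"low_p_first"` or `"random"`.
#' @param fractions Increasing removal fractions in `[0, 1]`.
#' @param mode,K Evaluation mode passed to [evaluate_predictions()].
#' @param seed Seed for the random removal order and sampled evaluation.
#' @return A tibble of class `lesion_curve` with columns `fraction`,
#'   `accuracy`, `ordering`.
#' @export
lesion_curve <- function(net, data, ordering = c("low_p_first", "random"),
                         fractions = seq(0, 1, by = 0.125),
                         mode = "sampled", K = 10, seed = NULL) {
  ordering <- match.arg(ordering)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  fractions <- sort(fractions)
  if (!is.null(seed)) set.seed(seed)
  n_syn <- n_synapses(net)
  ord <- if (ordering == "low_p_first") lesion_order(net) else sample(n_syn)
  sizes <- vapply(net$layers, function(l) length(l$m), numeric(1))
  layer_of <- rep(seq_along(net$layers), sizes)
  offset <- c(0, cumsum(sizes))
  acc <- numeric(length(fractions))
  lesioned <- net
  removed <- 0L
  for (k in seq_along(fractions)) {
    target <- floor(fractions[k] * n_syn)
    if (target > removed) {
      idx <- ord[(removed + 1L):target]
      for (l in seq_along(lesioned$layers)) {
        il <- idx[layer_of[idx] == l] - offset[l]
        if (length(il)) lesioned$layers[[l]]$m[il] <- 0
      }
      removed <- target
    }
    acc[k] <- evaluate_predictions(lesioned, data, mode = mode, K = K)$accuracy
  }
  structure(tibble::tibble(fraction = fractions, accuracy = acc,
                           ordering = ordering),
            class = c("lesion_curve", class(tibble::tibble())))
}

#' Paired lesion curves (importance order vs random control)
#'
#' Convenience wrapper running [lesion_curve()] with both orderings on the
#' same network and dataset.
#' @inheritParams lesion_curve
#' @return A `lesion_curve` tibble with both orderings stacked.
#' @export
lesion_experiment <- function(net, data, fractions = seq(0, 1, by = 0.125),
                              mode = "sampled", K = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- dplyr::bind_rows(
    lesion_curve(net, data, "low_p_first", fractions, mode, K),
    lesion_curve(net, data, "random", fractions, mode, K))
  structure(out, class = c("lesion_curve", class(tibble::tibble())))
}

#' Neuron-level sparsity of important synapses
#'
#' Classifies synapses as "important" when their release probability is at
#' least `p_important`, then asks whether important synapses concentrate on
#' few neurons. For each neuron of the chosen hidden layer it reports the
#' fraction of important input synapses, compares the distribution of these
#' fractions to a baseline in which importance labels are shuffled
#' uniformly over the layer's synapses (two-sample Kolmogorov-Smirnov
#' statistic), counts neurons whose important-input count lies two shuffled
#' standard deviations above/below the shuffled mean ("high"/"low"
#' importance neurons), and correlates per-neuron important-input and
#' important-output counts (Pearson r).
#'
#' @param net A trained `stoch_net`.
#' @param layer Hidden-layer index: neurons of layer `layer` receive the
#'   columns of weight matrix `layer` and emit the rows of matrix
#'   `layer + 1`.
#' @param p_important Importance threshold on the release probability.
#' @param n_shuffles Number of shuffled baselines pooled.
#' @param seed Seed for the shuffles.
#' @return A list of class `sparsity_report`: `neurons` (tibble with
#'   per-neuron counts and fractions), `shuffled_fractions`,
#'   `ks_statistic`, `n_low`, `n_medium`, `n_high`, `correlation_in_out`,
#'   `p_important`.
#' @export
sparsity_report <- function(net, layer = 1, p_important = 0.9,
                            n_shuffles = 100, seed = NULL) {
  if (layer < 1 || layer > length(net$layers) - 1) {
    stop("`layer` must index a hidden layer with an outgoing layer")
  }
  if (!is.null(seed)) set.seed(seed)
  w_in <- net$layers[[layer]]
  w_out <- net$layers[[layer + 1]]
  imp_in <- w_in$p >= p_important
  imp_out <- w_out$p >= p_important
  fan_in <- nrow(imp_in)
  n_neuron <- ncol(imp_in)

  n_imp_in <- colSums(imp_in)
  frac_in <- n_imp_in / fan_in
  n_imp_out <- rowSums(imp_out)

  # uniform shuffle of importance labels over the layer's synapses
  flat <- as.vector(imp_in)
  shuffled_counts <- replicate(n_shuffles,
    colSums(matrix(sample(flat), fan_in, n_neuron)))
  shuffled_frac <- as.vector(shuffled_counts) / fan_in

  ks <- suppressWarnings(ks.test(frac_in, shuffled_frac))
  mu <- mean(shuffled_counts)
  sdev <- sd(as.vector(shuffled_counts))
  hi <- if (sdev > 0) n_imp_in >= mu + 2 * sdev else rep(FALSE, n_neuron)
  lo <- if (sdev > 0) n_imp_in <= mu - 2 * sdev else rep(FALSE, n_neuron)

  r <- if (sd(n_imp_in) > 0 && sd(n_imp_out) > 0) {
    cor(n_imp_in, n_imp_out)
  } else NA_real_

  structure(list(
    neurons = tibble::tibble(neuron = seq_len(n_neuron),
                             n_important_in = n_imp_in,
                             frac_important_in = frac_in,
                             n_important_out = n_imp_out,
                             high_importance = hi, low_importance = lo),
    shuffled_fractions = shuffled_frac,
    ks_statistic = unname(ks$statistic),
    n_low = sum(lo), n_high = sum(hi),
    n_medium = n_neuron - sum(lo) - sum(hi),
    correlation_in_out = r,
    p_important = p_important, layer = layer),
    class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("<sparsity_report> layer %d, threshold p >= %.2f\n",
              x$layer, x$p_important))
  cat(sprintf("  KS D = %.3f vs shuffled | low/medium/high neurons: %d/%d/%d\n",
              x$ks_statistic, x$n_low, x$n_medium, x$n_high))
  cat(sprintf("  in/out importance correlation r = %.3f\n",
              x$correlation_in_out))
  invisible(x)
}

#' Histogram of release probabilities
#'
#' @param net A `stoch_net`.
#' @param breaks Bin breaks over `[0, 1]`.
#' @return A tibble with `bin_mid` and `count`.
#' @export
release_probability_histogram <- function(net, breaks = seq(0, 1, by = 0.05)) {
  p <- unlist(lapply(net$layers, `[[`, "p"))
  h <- graphics::hist(p, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_mid = h$mids, count = h$counts)
}
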