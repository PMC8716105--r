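#' Metaplasticity rule constants
#'
#' Bundles the constants of the presynaptic learning rule: the probability
#' increments `p_up`/`p_down`, the gradient-magnitude threshold `g_lim`
#' that decides between them, the lower clamp `p_min`, the freezing
#' threshold `p_freeze`, the base learning rate `eta0`, and the switches
#' for consolidation (learning-rate modulation by `1 - p` plus freezing)
#' and the ghost-probability ablation.
#'
#' All three rule constants are shared between all synapses. `lambda_l2`
#' adds an l2 penalty `lambda * wbar` to the update direction, used by the
#' energy experiments to encourage low-energy solutions.
#'
#' @param p_up,p_down Release-probability increments, in (0, 1).
#' @param g_lim Gradient-magnitude threshold, > 0. `|g| > g_lim` increments
#'   `p`; `|g| <= g_lim` decrements it.
#' @param eta0 Base learning rate for the expected-strength update.
#' @param p_min Lower clamp (and conventional initial value) for `p`.
#' @param p_freeze Freezing threshold in `(p_min, 1]`; active only with
#'   `consolidation = TRUE`.
#' @param lambda_l2 l2 coefficient on the expected weights, >= 0.
#' @param consolidation Enable learning-rate modulation `eta0 * (1 - p)`
#'   and permanent freezing of `p` once it reaches `p_freeze`.
#' @param ghost Drive a ghost probability array (transmission stays fixed);
#'   requires a network built with `stochastic_network(..., ghost = TRUE)`.
#' @return A validated list of class `meta_config`.
#' @seealso [energy_config()], [lifelong_config()], [perceptron_config()]
#'   for the constants used by the package's experiments.
#' @export
metaplasticity_config <- function(p_up, p_down, g_lim, eta0,
                                  p_min = 0.25, p_freeze = 0.9,
                                  lambda_l2 = 0, consolidation = FALSE,
                                  ghost = FALSE) {
  stopifnot(p_up > 0, p_up < 1, p_down > 0, p_down < 1,
            g_lim > 0, eta0 > 0, lambda_l2 >= 0,
            p_min >= 0, p_min <= p_freeze, p_freeze <= 1)
  structure(list(p_up = p_up, p_down = p_down, g_lim = g_lim, eta0 = eta0,
                 p_min = p_min, p_freeze = p_freeze, lambda_l2 = lambda_l2,
                 consolidation = isTRUE(consolidation),
                 ghost = isTRUE(ghost)),
            class = "meta_config")
}

#' Rule constants for the energy-efficiency experiments
#'
#' `p_up = p_down = 0.07`, `g_lim = 0.001`, `eta = 0.05`, consolidation
#' off.
#' @param lambda_l2 l2 coefficient on expected weights.
#' @return A `meta_config`.
#' @export
energy_config <- function(lambda_l2 = 0) {
  metaplasticity_config(p_up = 0.07, p_down = 0.07, g_lim = 0.001,
                        eta0 = 0.05, lambda_l2 = lambda_l2,
                        consolidation = FALSE)
}

#' Rule constants for the lifelong-learning experiments
#'
#' `p_up = 0.0516`, `p_down = 0.0520`, `g_lim = 0.001`, consolidation on
#' with `p_freeze = 0.9`.
#' @param eta0 Base learning rate, conventionally 0.01 or 0.001.
#' @param ghost Ghost-probability ablation switch.
#' @param consolidation Consolidation switch (off for the
#'   no-consolidation ablation).
#' @return A `meta_config`.
#' @export
lifelong_config <- function(eta0 = 0.01, ghost = FALSE, consolidation = TRUE) {
  metaplasticity_config(p_up = 0.0516, p_down = 0.0520, g_lim = 0.001,
                        eta0 = eta0, p_freeze = 0.9,
                        consolidation = consolidation, ghost = ghost)
}

#' Rule constants for the perceptron experiments
#'
#' `g_lim = 0.1`, `p_up = p_down = 0.2`, `p_min = 0.25`,
#' `p_freeze = 0.9`; the classical perceptron rule has unit base rate.
#' @return A `meta_config`.
#' @export
perceptron_config <- function() {
  metaplasticity_config(p_up = 0.2, p_down = 0.2, g_lim = 0.1, eta0 = 1,
                        p_min = 0.25, p_freeze = 0.9, consolidation = TRUE)
}

#' @export
print.meta_config <- function(x, ...) {
  cat(sprintf(
    "<meta_config> p_up=%.4g p_down=%.4g g_lim=%.4g eta0=%.4g lambda=%.4g\n",
    x$p_up, x$p_down, x$g_lim, x$eta0, x$lambda_l2))
  cat(sprintf("  p_min=%.2f p_freeze=%.2f consolidation=%s ghost=%s\n",
              x$p_min, x$p_freeze, x$consolidation, x$ghost))
  invisible(x)
}

#' Mini-batch update direction for the expected strengths
#'
#' Computes `g_i = dL/dwbar_i`, the gradient of the cross-entropy loss with
#' respect to the expected synaptic strengths, averaged over the examples
#' of the mini-batch. In `"sampled"` mode (default) the gradient is taken
#' through the stochastically sampled network: each example draws one fresh
#' release mask per synapse, `dL/dm_i` carries the drawn `r_i`, and the
#' chain rule `dL/dwbar_i = (1/p_i) dL/dm_i` converts to expected-strength
#' coordinates; a synapse that failed to release (`r_i = 0`) contributes no
#' strength gradient for that example. In `"expected"` mode the network is
#' evaluated at `wbar` directly.
#'
#' When `cfg` carries `lambda_l2 > 0` the penalty term `lambda * wbar` is
#' added to `g`.
#'
#' @param net A `stoch_net`.
#' @param x Input matrix (examples in rows) or a single input vector.
#' @param y Integer labels in `0, ..., n_classes - 1`.
#' @param cfg Optional `meta_config`, consulted only for `lambda_l2`.
#' @param mode `"sampled"` or `"expected"`.
#' @param seed Mask seed (sampled mode); example `e` uses `seed + e - 1`.
#' @param fisher If `TRUE`, also accumulate the mean per-example squared
#'   gradient (diagonal empirical Fisher) before the l2 term.
#' @return A list of class `update_direction`: `g` (list of per-layer
#'   matrices), `loss`, `accuracy`, `pred`, `seed`, and `fisher` when
#'   requested.
#' @export
compute_update_direction <- function(net, x, y, cfg = NULL,
                                     mode = c("sampled", "expected"),
                                     seed = NULL, fisher = FALSE) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("inputs and labels disagree in length")
  if (is.null(seed)) seed <- kernel_seed()
  res <- cpp_batch_grad(layer_matrices(net, "m"), layer_matrices(net, "p"),
                        x, y, mode == "sampled", seed, fisher)
  g <- res$g
  if (!is.null(cfg) && cfg$lambda_l2 > 0) {
    wbar <- expected_weights(net)
    g <- Map(function(gl, wl) gl + cfg$lambda_l2 * wl, g, wbar)
  }
  structure(list(g = g, loss = res$loss, accuracy = res$accuracy,
                 pred = res$pred, fisher = res$fisher, seed = seed,
                 mode = mode),
            class = "update_direction")
}

#' Metaplastic update of the release probabilities
#'
#' Applies the threshold rule to every unfrozen synapse:
#' `p <- p + p_up` where `|g| > g_lim`, `p <- p - p_down` where
#' `|g| <= g_lim`, then clips to `[p_min, 1]`. With consolidation enabled,
#' synapses whose probability would reach or surpass `p_freeze` are frozen
#' permanently *at* `p_freeze`: freezing below 1 guarantees that the
#' modulated learning rate `eta0 * (1 - p)` stays positive, so strengths
#' retain a small degree of plasticity. In ghost mode the same dynamics
#' drive the ghost array while the transmission probability stays fixed.
#'
#' @param net A `stoch_net`.
#' @param g An `update_direction` (or bare list of gradient matrices).
#' @param cfg A `meta_config`.
#' @return The updated network.
#' @export
update_release_probabilities <- function(net, g, cfg) {
  gl <- if (inherits(g, "update_direction")) g$g else g
  field <- if (cfg$ghost) "p_ghost" else "p"
  if (cfg$ghost && !net$ghost) {
    stop("ghost config requires a network built with ghost = TRUE")
  }
  for (l in seq_along(net$layers)) {
    p <- net$layers[[l]][[field]]
    frozen <- net$layers[[l]]$frozen
    delta <- ifelse(abs(gl[[l]]) > cfg$g_lim, cfg$p_up, -cfg$p_down)
    p_new <- pmin(pmax(p + delta, cfg$p_min), 1)
    if (cfg$consolidation) {
      crossing <- p_new >= cfg$p_freeze
      p_new[crossing] <- cfg$p_freeze
      net$layers[[l]]$frozen <- frozen | crossing
    }
    p_new[frozen] <- p[frozen]
    net$layers[[l]][[field]] <- p_new
  }
  net
}

#' Gradient update of the expected strengths
#'
#' Updates `wbar <- wbar - eta_eff * g` and re-derives the strength as
#' `m = wbar / p` under the network's current release probabilities. With
#' consolidation enabled the per-synapse learning rate is modulated as
#' `eta_eff = eta0 * (1 - p)` (ghost mode: `1 - p_ghost`), so synapses
#' with high release probability are stabilised while retaining a small
#' degree of plasticity as long as `p < 1`.
#'
#' When the release probabilities are updated in the same step, pass the
#' pre-update probabilities as `p_before`: the expected weight entering the
#' update and the learning-rate modulation are formed from the pre-update
#' state (`wbar(t) = p(t) m(t)`), while the division back to strengths uses
#' the fresh probabilities, i.e. `m(t+1) = (p(t) m(t) - eta g) / p(t+1)`
#' (see [plasticity_step()]).
#'
#' @param net A `stoch_net`.
#' @param g An `update_direction` (or bare list of gradient matrices).
#' @param cfg A `meta_config`.
#' @param p_before Optional list of pre-update probability matrices used
#'   for the learning-rate modulation; defaults to the current ones.
#' @return The updated network.
#' @export
update_expected_strengths <- function(net, g, cfg, p_before = NULL) {
  gl <- if (inherits(g, "update_direction")) g$g else g
  if (any(!vapply(gl, function(m) all(is.finite(m)), logical(1)))) {
    stop("non-finite entries in the update direction")
  }
  ghost_field <- if (cfg$ghost) "p_ghost" else "p"
  for (l in seq_along(net$layers)) {
    p_mod <- if (is.null(p_before)) {
      net$layers[[l]][[ghost_field]]
    } else p_before[[l]]
    # the transmission p of the pre-update state; in ghost mode the
    # transmitting array never changes, so current p is p(t)
    p_t <- if (is.null(p_before) || cfg$ghost) {
      net$layers[[l]]$p
    } else p_before[[l]]
    eta_eff <- if (cfg$consolidation) cfg$eta0 * (1 - p_mod) else cfg$eta0
    wbar <- p_t * net$layers[[l]]$m - eta_eff * gl[[l]]
    net$layers[[l]]$m <- wbar / net$layers[[l]]$p
  }
  net
}

#' One full learning step on a mini-batch
#'
#' Runs the complete update in the rule's canonical order: compute the
#' batch update direction `g`; update the release probabilities with the
#' threshold rule; update the expected strengths with the learning rate
#' modulated by the *pre-update* probabilities; re-derive
#' `m = wbar / p_new`.
#'
#' @inheritParams compute_update_direction
#' @param cfg A `meta_config`.
#' @param p_dynamics If `FALSE`, release probabilities are left untouched
#'   (deterministic / fixed-release control variants).
#' @return A list with the updated `net` and scalar step diagnostics
#'   (`loss`, `accuracy`, `mean_abs_g`, `frac_up`, `frac_frozen`).
#' @export
plasticity_step <- function(net, x, y, cfg,
                            mode = c("sampled", "expected"),
                            seed = NULL, p_dynamics = TRUE) {
  mode <- match.arg(mode)
  upd <- compute_update_direction(net, x, y, cfg, mode = mode, seed = seed)
  n_up <- 0; n_frozen <- 0; sum_absg <- 0; n_syn <- 0
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    res <- cpp_apply_update(
      lay$m, if (cfg$ghost) lay$p_ghost else lay$p, lay$p, lay$frozen,
      upd$g[[l]], cfg$p_up, cfg$p_down, cfg$g_lim, cfg$p_min, cfg$p_freeze,
      cfg$eta0, cfg$consolidation, p_dynamics, cfg$ghost)
    net$layers[[l]]$m <- res$m
    net$layers[[l]]$frozen <- res$frozen
    if (cfg$ghost) {
      net$layers[[l]]$p_ghost <- res$p_learn
    } else {
      net$layers[[l]]$p <- res$p_learn
    }
    absg <- abs(upd$g[[l]])
    sum_absg <- sum_absg + sum(absg)
    n_up <- n_up + sum(absg > cfg$g_lim)
    n_frozen <- n_frozen + sum(res$frozen)
    n_syn <- n_syn + length(absg)
  }
  list(net = net, loss = upd$loss, accuracy = upd$accuracy,
       mean_abs_g = sum_absg / n_syn,
       frac_up = n_up / n_syn,
       frac_frozen = n_frozen / n_syn)
}

#' Probability that the threshold rule increments a release probability
#'
#' Under a zero-mean Gaussian model of the per-step update direction,
#' `g ~ N(0, sigma^2)`, the probability of the increase branch is
#' `Pr[|g| > g_lim] = erfc(g_lim / (sigma * sqrt(2)))`. It is monotonically
#' increasing in `sigma^2 = E[g^2]`, the diagonal empirical Fisher
#' information, which is why synapses with high Fisher information end up
#' with high release probabilities.
#'
#' @param sigma Gradient standard deviation(s), > 0.
#' @param g_lim Threshold of the metaplasticity rule, >= 0.
#' @return The increase probability, vectorised over `sigma`.
#' @examples
#' analytic_increase_probability(1, 1)  # erfc(1/sqrt(2)) ~ 0.3173
#' @export
analytic_increase_probability <- function(sigma, g_lim) {
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  if (g_lim < 0) stop("`g_lim` must be nonnegative")
  # erfc(g_lim / (sigma*sqrt(2))) written via the normal CDF
  2 * pnorm(-g_lim / sigma)
}
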