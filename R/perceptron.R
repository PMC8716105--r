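#' Sign-unit perceptron with stochastic release
#'
#' A single sign-activation unit whose input synapses transmit
#' stochastically, for gradient-free pattern memorisation. The
#' `"stochastic_consolidated"` variant carries learnable release
#' probabilities with the full metaplasticity and consolidation machinery;
#' the `"standard"` variant is the classical perceptron (`p = 1`
#' everywhere, no probability dynamics). Strengths start at zero.
#'
#' @param dim Number of input synapses.
#' @param variant `"stochastic_consolidated"` or `"standard"`.
#' @param p_init Initial release probability (consolidated variant).
#' @param p_min Lower clamp.
#' @return A list of class `stoch_perceptron` with vectors `m`, `p`,
#'   `frozen` and the `variant`.
#' @export
stochastic_perceptron <- function(dim,
                                  variant = c("stochastic_consolidated",
                                              "standard"),
                                  p_init = 0.25, p_min = 0.25) {
  variant <- match.arg(variant)
  p <- if (variant == "standard") rep(1, dim) else rep(p_init, dim)
  structure(list(m = rep(0, dim), p = p, frozen = rep(FALSE, dim),
                 variant = variant, p_min = p_min),
            class = "stoch_perceptron")
}

#' @export
print.stoch_perceptron <- function(x, ...) {
  cat(sprintf("<stoch_perceptron> %s, N=%d, mean p=%.3f, frozen=%.1f%%\n",
              x$variant, length(x$m), mean(x$p), 100 * mean(x$frozen)))
  invisible(x)
}

#' Perceptron prediction for one pattern
#'
#' `sign(sum_i r_i m_i a_i)` with `r_i ~ Bernoulli(p_i)` in sampled mode,
#' or `sign(sum_i p_i m_i a_i)` under expected weights. A zero weighted sum
#' is broken towards `+1`. The standard variant is deterministic either
#' way. Sampled draws use R's global RNG.
#'
#' @param state A `stoch_perceptron`.
#' @param pattern Numeric vector of length `dim` (entries conventionally
#'   +-1).
#' @param mode `"sampled"` or `"expected"`.
#' @return `+1` or `-1`.
#' @export
perceptron_predict <- function(state, pattern,
                               mode = c("sampled", "expected")) {
  mode <- match.arg(mode)
  if (length(pattern) != length(state$m)) stop("pattern length mismatch")
  s <- if (mode == "sampled" && state$variant != "standard") {
    r <- runif(length(state$p)) < state$p
    sum(state$m[r] * pattern[r])
  } else {
    sum(state$p * state$m * pattern)
  }
  if (s >= 0) 1 else -1
}

#' Averaged perceptron update on a small batch
#'
#' Each example contributes the classical Rosenblatt correction
#' `(label - prediction) / 2 * pattern` (zero when correct, `label *
#' pattern` when wrong); the update direction `g` is the batch mean of
#' these contributions, here playing the role the loss gradient plays in
#' the multilayer network. The expected strength moves by `+eta_eff * g`
#' with `eta_eff = 1 - p` in the consolidated variant, and the release
#' probabilities follow the same threshold rule as the network
#' ([update_release_probabilities()]): `+p_up` where `|g| > g_lim`,
#' `-p_down` otherwise, clamped to `[p_min, 1]`, frozen at `p_freeze`.
#' Training predictions sample release, so learning sees the transmission
#' noise.
#'
#' @param state A `stoch_perceptron`.
#' @param x Pattern matrix (rows are examples; batches of 5 by
#'   convention, the last batch may be smaller).
#' @param y Labels, +-1.
#' @param cfg A `meta_config`; defaults to [perceptron_config()].
#' @return The updated state.
#' @export
perceptron_batch_update <- function(state, x, y, cfg = perceptron_config()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("empty batch")
  consolidated <- state$variant != "standard"
  contrib <- matrix(0, nrow(x), ncol(x))
  for (e in seq_len(nrow(x))) {
    pred <- perceptron_predict(state, x[e, ],
                               mode = if (consolidated) "sampled"
                                      else "expected")
    contrib[e, ] <- (y[e] - pred) / 2 * x[e, ]
  }
  g <- colMeans(contrib)

  p_old <- state$p
  if (consolidated) {
    up <- abs(g) > cfg$g_lim & !state$frozen
    down <- abs(g) <= cfg$g_lim & !state$frozen
    p_new <- state$p
    p_new[up] <- pmin(p_new[up] + cfg$p_up, 1)
    p_new[down] <- pmax(p_new[down] - cfg$p_down, cfg$p_min)
    if (cfg$consolidation) {
      # freeze *at* the threshold: (1 - p) stays positive, so frozen
      # synapses keep a residual strength plasticity of 1 - p_freeze
      crossing <- p_new >= cfg$p_freeze & !state$frozen
      p_new[crossing] <- cfg$p_freeze
      state$frozen <- state$frozen | crossing
    }
    state$p <- p_new
  }
  eta_eff <- if (consolidated && cfg$consolidation) {
    cfg$eta0 * (1 - p_old)
  } else cfg$eta0
  wbar <- p_old * state$m + eta_eff * g
  state$m <- wbar / state$p
  state
}

#' Sequential pattern-memorisation experiment for the perceptron
#'
#' Trains on each task in turn (batches of `batch_size` with a fresh
#' shuffle per pass) and, after finishing each task, records the
#' expected-weight accuracy on every task, yielding the task x checkpoint
#' accuracy grid used to quantify retention.
#'
#' @param tasks A [generate_perceptron_tasks()] sequence.
#' @param variant Perceptron variant, as in [stochastic_perceptron()].
#' @param cfg A `meta_config`.
#' @param n_passes Passes through each task's data.
#' @param batch_size Update-averaging batch size.
#' @param eval_mode Prediction mode for evaluation.
#' @return A tibble of class `accuracy_matrix` with columns `checkpoint`
#'   (task just finished), `task`, `accuracy`, `variant`; the final state
#'   is attached as attribute `state`.
#' @export
run_lifelong_perceptron <- function(tasks,
                                    variant = c("stochastic_consolidated",
                                                "standard"),
                                    cfg = perceptron_config(),
                                    n_passes = 25, batch_size = 5,
                                    eval_mode = "expected") {
  variant <- match.arg(variant)
  dim <- ncol(tasks[[1]]$x)
  state <- stochastic_perceptron(dim, variant, p_min = cfg$p_min)
  rows <- list()
  for (k in seq_along(tasks)) {
    xk <- tasks[[k]]$x
    yk <- tasks[[k]]$y
    n <- nrow(xk)
    for (pass in seq_len(n_passes)) {
      ord <- sample(n)
      for (b in seq_len(ceiling(n / batch_size))) {
        sel <- ord[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        state <- perceptron_batch_update(state, xk[sel, , drop = FALSE],
                                         yk[sel], cfg)
      }
    }
    for (j in seq_along(tasks)) {
      preds <- apply(tasks[[j]]$x, 1, perceptron_predict, state = state,
                     mode = eval_mode)
      rows[[length(rows) + 1]] <- tibble::tibble(
        checkpoint = k, task = j, accuracy = mean(preds == tasks[[j]]$y),
        variant = variant)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "state") <- state
  class(out) <- c("accuracy_matrix", class(tibble::tibble()))
  out
}
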