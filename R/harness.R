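#' Train a network on a labelled dataset
#'
#' Plain mini-batch training with the full learning rule: every batch runs
#' [plasticity_step()] (update direction, probability rule, strength
#' update). Batch order and mask seeds are drawn from R's global RNG, so a
#' single `set.seed()` fixes the whole trajectory bit-exactly.
#'
#' @param net A `stoch_net`.
#' @param data Training [labelled_dataset()].
#' @param cfg A `meta_config`.
#' @param epochs Number of passes through the data.
#' @param batch_size Mini-batch size.
#' @param mode Gradient mode, `"sampled"` (through drawn masks) or
#'   `"expected"`.
#' @param p_dynamics If `FALSE`, release probabilities stay fixed
#'   (deterministic and fixed-release control variants).
#' @return A list of class `training_run`: the trained `net` and `log`, a
#'   tibble with per-epoch `loss`, `accuracy` (training, running mean over
#'   batches), `mean_p`, `frac_frozen`, `mean_abs_g`.
#' @export
train_network <- function(net, data, cfg, epochs = 10, batch_size = 100,
                          mode = "sampled", p_dynamics = TRUE) {
  data <- as_labelled_dataset(data)
  n <- nrow(data$x)
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    n_batches <- ceiling(n / batch_size)
    seeds <- vapply(seq_len(n_batches), function(i) kernel_seed(), numeric(1))
    loss <- acc <- absg <- 0
    for (b in seq_len(n_batches)) {
      sel <- ord[((b - 1) * batch_size + 1):min(b * batch_size, n)]
      st <- plasticity_step(net, data$x[sel, , drop = FALSE], data$y[sel],
                            cfg, mode = mode, seed = seeds[b],
                            p_dynamics = p_dynamics)
      net <- st$net
      loss <- loss + st$loss; acc <- acc + st$accuracy
      absg <- absg + st$mean_abs_g
    }
    log_rows[[ep]] <- tibble::tibble(
      epoch = ep, loss = loss / n_batches, accuracy = acc / n_batches,
      mean_p = mean(unlist(lapply(net$layers, `[[`,
                                  if (net$ghost) "p_ghost" else "p"))),
      frac_frozen = mean(unlist(lapply(net$layers, `[[`, "frozen"))),
      mean_abs_g = absg / n_batches)
  }
  structure(list(net = net, log = dplyr::bind_rows(log_rows)),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "<training_run> %d epochs | final loss %.4f acc %.3f mean_p %.3f\n",
    nrow(x$log), last$loss, last$accuracy, last$mean_p))
  invisible(x)
}

#' Train on a continuous task stream
#'
#' Walks the stream in its given order (optionally several times),
#' batching consecutive positions; no task-boundary information reaches
#' the learner.
#'
#' @param net A `stoch_net`.
#' @param stream A [make_continuous_sequence()] stream.
#' @param cfg A `meta_config`.
#' @param passes Number of passes over the stream.
#' @param batch_size Mini-batch size.
#' @return A `training_run` (one log row per pass).
#' @export
train_on_stream <- function(net, stream, cfg, passes = 1, batch_size = 100) {
  data <- labelled_dataset(stream$x, stream$y, stream$n_out)
  n <- nrow(data$x)
  log_rows <- vector("list", passes)
  for (pass in seq_len(passes)) {
    n_batches <- ceiling(n / batch_size)
    loss <- acc <- 0
    for (b in seq_len(n_batches)) {
      sel <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
      st <- plasticity_step(net, data$x[sel, , drop = FALSE], data$y[sel],
                            cfg, seed = kernel_seed())
      net <- st$net
      loss <- loss + st$loss; acc <- acc + st$accuracy
    }
    log_rows[[pass]] <- tibble::tibble(epoch = pass, loss = loss / n_batches,
                                       accuracy = acc / n_batches,
                                       mean_p = NA_real_,
                                       frac_frozen = NA_real_,
                                       mean_abs_g = NA_real_)
  }
  structure(list(net = net, log = dplyr::bind_rows(log_rows)),
            class = "training_run")
}

variant_setup <- function(variant, dim, hidden, n_out, cfg) {
  switch(variant,
    plastic_stochastic = list(
      net = stochastic_network(c(dim, hidden, n_out)),
      cfg = cfg, p_dynamics = TRUE),
    no_consolidation = list(
      net = stochastic_network(c(dim, hidden, n_out)),
      cfg = metaplasticity_config(cfg$p_up, cfg$p_down, cfg$g_lim, cfg$eta0,
                                  cfg$p_min, cfg$p_freeze, cfg$lambda_l2,
                                  consolidation = FALSE),
      p_dynamics = TRUE),
    ghost = list(
      net = stochastic_network(c(dim, hidden, n_out), ghost = TRUE),
      cfg = metaplasticity_config(cfg$p_up, cfg$p_down, cfg$g_lim, cfg$eta0,
                                  cfg$p_min, cfg$p_freeze, cfg$lambda_l2,
                                  consolidation = TRUE, ghost = TRUE),
      p_dynamics = TRUE),
    deterministic = list(
      net = stochastic_network(c(dim, hidden, n_out), p_init = 1),
      cfg = metaplasticity_config(cfg$p_up, cfg$p_down, cfg$g_lim, cfg$eta0,
                                  cfg$p_min, 1, cfg$lambda_l2,
                                  consolidation = FALSE),
      # with p = 1 the sampled and expected gradients coincide exactly;
      # the expected path skips the (all-ones) mask draws
      p_dynamics = FALSE, mode = "expected"),
    stop("unknown variant: ", variant))
}

#' Sequential-task lifelong-learning experiment
#'
#' Trains a freshly initialised network on the tasks of a sequence in
#' order and evaluates every task's held-out test set after finishing each
#' task. Variants: `"plastic_stochastic"` (full model: stochastic release,
#' probability dynamics, learning-rate modulation, freezing),
#' `"no_consolidation"` (probability dynamics but no modulation/freezing),
#' `"ghost"` (transmission fixed at p = 0.5; ghost probabilities evolve
#' and drive consolidation), `"deterministic"` (plain network, p = 1, no
#' dynamics). Initial strengths, batch orders, and mask seeds all derive
#' from R's global RNG with identical draw counts across variants, so
#' calling `set.seed(s)` before each variant yields a paired comparison
#' differing only in the ablated mechanism.
#'
#' @param tasks A `task_sequence`.
#' @param variant Model variant, see above.
#' @param cfg A `meta_config`; defaults to [lifelong_config()].
#' @param hidden Hidden-layer widths.
#' @param epochs_per_task Training epochs on each task.
#' @param batch_size Mini-batch size.
#' @param eval_mode,K Evaluation settings ([evaluate_predictions()]).
#' @return A list of class `lifelong_run`: `accuracy` (tibble of class
#'   `accuracy_matrix`: `checkpoint`, `task`, `accuracy`, `variant`),
#'   `p_histograms` (release-probability histogram per checkpoint,
#'   including checkpoint 0 before training), and the final `net`.
#' @export
train_lifelong_experiment <- function(tasks, variant = "plastic_stochastic",
                                      cfg = lifelong_config(),
                                      hidden = c(200, 200),
                                      epochs_per_task = 10, batch_size = 100,
                                      eval_mode = "sampled", K = 10) {
  if (!inherits(tasks, "task_sequence")) stop("expected a task_sequence")
  dim <- ncol(tasks$tasks[[1]]$train$x)
  setup <- variant_setup(variant, dim, hidden, tasks$n_out, cfg)
  net <- setup$net
  acc_rows <- list()
  hists <- list(dplyr::mutate(release_probability_histogram(net),
                              checkpoint = 0L))
  for (k in seq_len(tasks$n_tasks)) {
    run <- train_network(net, tasks$tasks[[k]]$train, setup$cfg,
                         epochs = epochs_per_task, batch_size = batch_size,
                         mode = if (is.null(setup$mode)) "sampled"
                                else setup$mode,
                         p_dynamics = setup$p_dynamics)
    net <- run$net
    for (j in seq_len(tasks$n_tasks)) {
      ev <- evaluate_predictions(net, tasks$tasks[[j]]$test,
                                 mode = eval_mode, K = K)
      acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
        checkpoint = k, task = j, accuracy = ev$accuracy, variant = variant)
    }
    hists[[k + 1]] <- dplyr::mutate(release_probability_histogram(net),
                                    checkpoint = k)
  }
  acc <- dplyr::bind_rows(acc_rows)
  class(acc) <- c("accuracy_matrix", class(tibble::tibble()))
  structure(list(accuracy = acc, p_histograms = dplyr::bind_rows(hists),
                 net = net, variant = variant),
            class = "lifelong_run")
}

#' @export
print.lifelong_run <- function(x, ...) {
  fin <- dplyr::filter(x$accuracy, .data$checkpoint == max(.data$checkpoint))
  cat(sprintf("<lifelong_run> %s | final mean accuracy %.3f over %d tasks\n",
              x$variant, mean(fin$accuracy), nrow(fin)))
  invisible(x)
}

#' Joint-training upper bound for a task sequence
#'
#' Trains one network on the union of all tasks' training sets
#' simultaneously, the conventional upper reference for sequential
#' learning.
#'
#' @inheritParams train_lifelong_experiment
#' @param epochs Total training epochs on the pooled data.
#' @return An `accuracy_matrix` tibble with one checkpoint.
#' @export
joint_training_baseline <- function(tasks, cfg = lifelong_config(),
                                    hidden = c(200, 200), epochs = 10,
                                    batch_size = 100,
                                    eval_mode = "sampled", K = 10) {
  dim <- ncol(tasks$tasks[[1]]$train$x)
  pooled <- labelled_dataset(
    do.call(rbind, lapply(tasks$tasks, function(t) t$train$x)),
    unlist(lapply(tasks$tasks, function(t) t$train$y)), tasks$n_out)
  net <- stochastic_network(c(dim, hidden, tasks$n_out))
  run <- train_network(net, pooled, cfg, epochs = epochs,
                       batch_size = batch_size)
  rows <- lapply(seq_len(tasks$n_tasks), function(j) {
    ev <- evaluate_predictions(run$net, tasks$tasks[[j]]$test,
                               mode = eval_mode, K = K)
    tibble::tibble(checkpoint = tasks$n_tasks, task = j,
                   accuracy = ev$accuracy, variant = "joint")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_matrix", class(tibble::tibble()))
  out
}

#' Energy/information trade-off experiment
#'
#' For each seed and each l2 strength `lambda`, trains the plastic
#' stochastic model and records the task-relevant mutual information
#' (sampled evaluation on the held-out set) against the synaptic energy.
#' Two controls share each seed's initial strengths: a fixed-release model
#' whose uniform release probability matches the plastic model's final
#' mean release probability for the same `lambda` (isolating presynaptic
#' plasticity), and a deterministic model with `p = 1` (isolating
#' stochasticity altogether). Neither control has probability dynamics.
#'
#' @param task A `synthetic_task` (or list with `train`/`test`).
#' @param lambda_grid l2 strengths to sweep.
#' @param seeds Integer seeds, one repetition each.
#' @param epochs Training epochs per run.
#' @param hidden Hidden-layer widths.
#' @param batch_size Mini-batch size.
#' @param cfg Base rule constants; defaults to [energy_config()].
#' @param K Mask draws for sampled evaluation.
#' @param p_init Initial release probability of the plastic model.
#' @return A tibble of class `info_energy` with one row per
#'   (variant, lambda, seed): `mutual_information` (bits), `energy`,
#'   `accuracy`, `mean_p`, `info_per_energy`.
#' @export
train_energy_experiment <- function(task,
                                    lambda_grid = c(0, 3e-4, 1e-3, 3e-3),
                                    seeds = 1:3, epochs = 50,
                                    hidden = c(200, 200), batch_size = 100,
                                    cfg = energy_config(), K = 10,
                                    p_init = 0.25) {
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  dim <- ncol(task$train$x)
  n_out <- task$train$n_classes
  rows <- list()
  measure <- function(net, variant, lambda, seed) {
    ev <- evaluate_predictions(net, task$test, mode = "sampled", K = K)
    mi <- mutual_information(ev$counts)
    en <- synaptic_energy(net)
    tibble::tibble(variant = variant, lambda = lambda, seed = seed,
                   mutual_information = mi, energy = en,
                   accuracy = ev$accuracy,
                   mean_p = mean(unlist(lapply(net$layers, `[[`, "p"))),
                   info_per_energy = mi / en)
  }
  for (seed in seeds) {
    set.seed(seed)
    init <- stochastic_network(c(dim, hidden, n_out), p_init = p_init)
    for (lambda in lambda_grid) {
      cfg_l <- metaplasticity_config(cfg$p_up, cfg$p_down, cfg$g_lim,
                                     cfg$eta0, cfg$p_min, cfg$p_freeze,
                                     lambda_l2 = lambda,
                                     consolidation = FALSE)
      run <- train_network(init, task$train, cfg_l, epochs = epochs,
                           batch_size = batch_size)
      plastic_row <- measure(run$net, "plastic_stochastic", lambda, seed)
      rows[[length(rows) + 1]] <- plastic_row

      fixed <- init
      for (l in seq_along(fixed$layers)) {
        fixed$layers[[l]]$p[] <- plastic_row$mean_p
      }
      fixed$p_min <- 0
      runf <- train_network(fixed, task$train, cfg_l, epochs = epochs,
                            batch_size = batch_size, p_dynamics = FALSE)
      rows[[length(rows) + 1]] <- measure(runf$net, "fixed_release",
                                          lambda, seed)

      det <- init
      for (l in seq_along(det$layers)) det$layers[[l]]$p[] <- 1
      rund <- train_network(det, task$train, cfg_l, epochs = epochs,
                            batch_size = batch_size, mode = "expected",
                            p_dynamics = FALSE)
      rows[[length(rows) + 1]] <- measure(rund$net, "deterministic",
                                          lambda, seed)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("info_energy", class(tibble::tibble()))
  out
}

#' Best information-per-energy ratio per variant
#'
#' Summarises an [train_energy_experiment()] table: per seed and variant
#' the best ratio over the lambda grid, then the mean and standard error
#' over seeds.
#'
#' @param points An `info_energy` tibble.
#' @return A tibble with `variant`, `best_ratio` (mean over seeds), `se`.
#' @export
best_info_per_energy <- function(points) {
  points |>
    dplyr::group_by(.data$variant, .data$seed) |>
    dplyr::summarise(best = max(.data$info_per_energy), .groups = "drop") |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(best_ratio = mean(.data$best),
                     se = sd(.data$best) / sqrt(dplyr::n()),
                     .groups = "drop")
}

#' Full analysis battery for a trained network
#'
#' Bundles every measurement on one trained network and dataset: synaptic
#' energy, accuracy and task-relevant mutual information, per-synapse
#' empirical Fisher information, paired lesion curves, neuron-level
#' sparsity, and the release-probability histogram.
#'
#' @param net A trained `stoch_net`.
#' @param data Held-out [labelled_dataset()].
#' @param p_important Importance threshold for the sparsity analysis.
#' @param fractions Lesion fractions.
#' @param sparsity_layer Hidden layer analysed for sparsity.
#' @param K Mask draws for sampled evaluation.
#' @return A list of class `analysis_suite` with `energy`, `evaluation`,
#'   `mutual_information`, `fisher`, `lesion`, `sparsity`, `p_histogram`.
#' @export
run_analysis_suite <- function(net, data, p_important = 0.9,
                               fractions = seq(0, 1, by = 0.125),
                               sparsity_layer = 1, K = 10) {
  ev <- evaluate_predictions(net, data, mode = "sampled", K = K)
  structure(list(
    energy = synaptic_energy(net),
    evaluation = ev,
    mutual_information = mutual_information(ev$counts),
    fisher = empirical_fisher(net, data),
    lesion = lesion_experiment(net, data, fractions = fractions, K = K),
    sparsity = sparsity_report(net, layer = sparsity_layer,
                               p_important = p_important),
    p_histogram = release_probability_histogram(net)),
    class = "analysis_suite")
}

#' @export
print.analysis_suite <- function(x, ...) {
  cat(sprintf(
    "<analysis_suite> energy %.2f | acc %.3f | MI %.3f bits | KS D %.3f\n",
    x$energy, x$evaluation$accuracy, x$mutual_information,
    x$sparsity$ks_statistic))
  invisible(x)
}

#' Write an analysis suite to CSV files and a JSON summary
#'
#' Curves and per-neuron tables go to CSV (`lesion.csv`, `neurons.csv`,
#' `p_histogram.csv`, `fisher.csv`); scalar measurements to
#' `summary.json`.
#'
#' @param suite An `analysis_suite`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_analysis_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(suite$lesion, file.path(dir, "lesion.csv"),
                   row.names = FALSE)
  utils::write.csv(suite$sparsity$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  utils::write.csv(suite$p_histogram, file.path(dir, "p_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(suite$fisher), file.path(dir, "fisher.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    energy = suite$energy,
    accuracy = suite$evaluation$accuracy,
    mutual_information_bits = suite$mutual_information,
    ks_statistic = suite$sparsity$ks_statistic,
    correlation_in_out = suite$sparsity$correlation_in_out,
    n_low = suite$sparsity$n_low, n_high = suite$sparsity$n_high),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
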