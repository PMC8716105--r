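# Harness tests run on a deliberately small task (40 dims, 4 classes) so
# each block trains in seconds; the full-scale behaviour is exercised by
# the acceptance suite.

small_task <- function(seed = 501) {
  tiny_task(seed = seed, n_train = 480, n_test = 120, dim = 40,
            relevant_dim = 16, n_classes = 4, noise_sd = 0.2)
}

test_that("training reduces the loss and logs the trajectory", {
  task <- small_task()
  set.seed(502)
  net <- stochastic_network(c(40, 30, 4))
  run <- train_network(net, task$train, energy_config(), epochs = 8,
                       batch_size = 10)
  expect_s3_class(run$log, "tbl_df")
  expect_equal(nrow(run$log), 8)
  expect_lt(run$log$loss[8], run$log$loss[1])
  ev <- evaluate_predictions(run$net, task$test, K = 5)
  expect_gt(ev$accuracy, 0.5)     # 4-class chance is 0.25
})

test_that("identical seeds give bit-identical training runs", {
  task <- small_task()
  run_once <- function() {
    set.seed(503)
    net <- stochastic_network(c(40, 20, 4))
    train_network(net, task$train, energy_config(), epochs = 2,
                  batch_size = 20)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$net$layers, r2$net$layers)
  expect_identical(r1$log, r2$log)
})

test_that("lifelong experiment produces a full accuracy matrix", {
  task <- small_task()
  seq2 <- make_split_tasks(task, n_tasks = 2)
  set.seed(504)
  run <- train_lifelong_experiment(seq2, "plastic_stochastic",
                                   cfg = lifelong_config(eta0 = 0.05),
                                   hidden = c(30), epochs_per_task = 6,
                                   batch_size = 10, K = 5)
  expect_s3_class(run$accuracy, "accuracy_matrix")
  expect_equal(nrow(run$accuracy), 4)     # 2 checkpoints x 2 tasks
  expect_true(all(run$accuracy$accuracy >= 0 & run$accuracy$accuracy <= 1))
  # p histogram includes the pre-training checkpoint: point mass at p_init
  h0 <- dplyr::filter(run$p_histograms, checkpoint == 0)
  expect_equal(sum(h0$count[h0$bin_mid > 0.2 & h0$bin_mid < 0.3]),
               sum(h0$count))
  # single task trained last is learned
  final <- dplyr::filter(run$accuracy, checkpoint == 2, task == 2)
  expect_gt(final$accuracy, 0.6)
})

test_that("ablation variants share initial weights under paired seeds", {
  task <- small_task()
  seq2 <- make_split_tasks(task, n_tasks = 2)
  nets <- lapply(c("plastic_stochastic", "ghost", "no_consolidation",
                   "deterministic"), function(v) {
    set.seed(505)
    stochsyn:::variant_setup(v, 40, c(30), 2, lifelong_config())$net
  })
  for (k in 2:4) {
    expect_identical(nets[[k]]$layers[[1]]$m, nets[[1]]$layers[[1]]$m)
  }
  # ghost variant transmits at 0.5 with a separate learned array
  ghost <- nets[[2]]
  expect_true(all(ghost$layers[[1]]$p == 0.5))
  expect_true(all(ghost$layers[[1]]$p_ghost == 0.25))
  # deterministic variant transmits deterministically
  expect_true(all(nets[[4]]$layers[[1]]$p == 1))
})

test_that("ghost dynamics move the ghost array, never the transmission p", {
  task <- small_task()
  seq2 <- make_split_tasks(task, n_tasks = 2)
  set.seed(506)
  run <- train_lifelong_experiment(seq2, "ghost",
                                   cfg = lifelong_config(eta0 = 0.05),
                                   hidden = c(20), epochs_per_task = 3,
                                   batch_size = 10, K = 3)
  expect_true(all(unlist(lapply(run$net$layers, `[[`, "p")) == 0.5))
  pg <- unlist(lapply(run$net$layers, `[[`, "p_ghost"))
  expect_gt(sd(pg), 0)             # ghost probabilities actually evolved
  expect_true(all(pg >= 0.25 & pg <= 1))
})

test_that("energy experiment emits the full variant x lambda x seed grid", {
  task <- small_task()
  pts <- train_energy_experiment(task, lambda_grid = c(0, 1e-3),
                                 seeds = 1:2, epochs = 4, hidden = c(20),
                                 batch_size = 10, K = 3)
  expect_s3_class(pts, "info_energy")
  expect_equal(nrow(pts), 3 * 2 * 2)
  expect_setequal(unique(pts$variant),
                  c("plastic_stochastic", "fixed_release", "deterministic"))
  expect_true(all(pts$energy > 0))
  expect_true(all(pts$mutual_information >= 0 &
                    pts$mutual_information <= 2 + 1e-9))
  # deterministic variant has p = 1: energy equals sum |m|
  # fixed-release variant matches the plastic model's mean p
  fr <- dplyr::filter(pts, variant == "fixed_release", lambda == 0, seed == 1)
  pl <- dplyr::filter(pts, variant == "plastic_stochastic", lambda == 0,
                      seed == 1)
  expect_equal(fr$mean_p, pl$mean_p, tolerance = 1e-12)

  best <- best_info_per_energy(pts)
  expect_equal(nrow(best), 3)
  expect_true(all(best$best_ratio > 0))
  expect_error(train_energy_experiment(task, lambda_grid = numeric(0)),
               "empty")
})

test_that("joint-training baseline evaluates every task once", {
  task <- small_task()
  seq2 <- make_split_tasks(task, n_tasks = 2)
  set.seed(507)
  jt <- joint_training_baseline(seq2, cfg = lifelong_config(eta0 = 0.05),
                                hidden = c(30), epochs = 6,
                                batch_size = 10, K = 5)
  expect_equal(nrow(jt), 2)
  expect_true(all(jt$variant == "joint"))
  expect_gt(mean(jt$accuracy), 0.5)
})

test_that("stream training consumes a continuous sequence", {
  task <- small_task()
  seqp <- withr::with_seed(508, make_permuted_tasks(task, n_tasks = 2))
  stream <- withr::with_seed(509, make_continuous_sequence(seqp, 0.2))
  set.seed(510)
  net <- stochastic_network(c(40, 20, 4))
  run <- train_on_stream(net, stream, lifelong_config(eta0 = 0.05),
                         passes = 1, batch_size = 10)
  expect_equal(nrow(run$log), 1)
  expect_true(is.finite(run$log$loss))
})

test_that("analysis suite bundles all measurements and serialises", {
  task <- small_task()
  set.seed(511)
  net <- stochastic_network(c(40, 30, 4))
  run <- train_network(net, task$train, energy_config(), epochs = 6,
                       batch_size = 10)
  suite <- withr::with_seed(512,
    run_analysis_suite(run$net, task$test, fractions = c(0, 0.5, 1),
                       K = 3))
  expect_s3_class(suite, "analysis_suite")
  expect_gt(suite$energy, 0)
  expect_gte(suite$mutual_information, 0)
  expect_equal(sort(unique(suite$lesion$ordering)),
               c("low_p_first", "random"))
  expect_true(all(unlist(suite$fisher$F) >= 0))

  dir <- withr::local_tempdir()
  write_analysis_suite(suite, dir)
  expect_true(all(file.exists(file.path(dir,
    c("lesion.csv", "neurons.csv", "p_histogram.csv", "fisher.csv",
      "summary.json")))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_named(js, c("energy", "accuracy", "mutual_information_bits",
                     "ks_statistic", "correlation_in_out", "n_low",
                     "n_high"), ignore.order = TRUE)
})

test_that("tidiers and plots cover the result types", {
  net <- tiny_net(sizes = c(6, 4, 3))
  td <- tidy(net)
  expect_equal(nrow(td), 6 * 4 + 4 * 3)
  expect_equal(td$wbar, td$p * td$m)
  g <- glance(net)
  expect_equal(g$n_synapses, 36)

  task <- small_task()
  ev <- evaluate_predictions(net_for <- withr::with_seed(513,
    stochastic_network(c(40, 10, 4))), task$test, K = 2, seed = 1)
  expect_equal(sum(tidy(ev)$count), ev$n)
  expect_equal(glance(ev)$accuracy, ev$accuracy)

  lc <- lesion_curve(net_for, task$test, fractions = c(0, 1), K = 2,
                     seed = 2)
  expect_s3_class(autoplot(lc), "ggplot")
  fe <- empirical_fisher(net_for, task$test, seed = 3)
  expect_equal(nrow(tidy(fe)), 40 * 10 + 10 * 4)
  expect_s3_class(plot_release_probabilities(net_for), "ggplot")
})
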