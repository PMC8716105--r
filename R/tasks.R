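#' Labelled classification dataset
#'
#' A thin container for an inputs matrix and integer labels in
#' `0, ..., n_classes - 1`.
#'
#' @param x Numeric matrix, examples in rows.
#' @param y Integer label vector.
#' @param n_classes Number of classes; inferred from `y` when missing.
#' @return A list of class `labelled_dataset` with `x`, `y`, `n_classes`.
#' @export
labelled_dataset <- function(x, y, n_classes = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("inputs and labels disagree in length")
  if (!all(is.finite(x))) stop("inputs must be finite")
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  if (any(y < 0L | y >= n_classes)) stop("labels must lie in [0, n_classes)")
  structure(list(x = x, y = y, n_classes = as.integer(n_classes)),
            class = "labelled_dataset")
}

as_labelled_dataset <- function(data) {
  if (inherits(data, "labelled_dataset")) return(data)
  if (is.list(data) && !is.null(data$x) && !is.null(data$y)) {
    return(labelled_dataset(data$x, data$y, data$n_classes))
  }
  stop("expected a labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d examples x %d dims, %d classes\n",
              nrow(x$x), ncol(x$x), x$n_classes))
  invisible(x)
}

#' Synthetic high-dimensional classification task
#'
#' Emulates image-classification inputs that are high-dimensional with high
#' entropy while the task-relevant information is just the class identity:
#' each class has a random high-contrast prototype (entries 0 or 1, like
#' pen strokes) supported on a small random subset of coordinates
#' (`relevant_dim` of `dim`); examples add Gaussian noise to the prototype
#' on those coordinates and carry pure high-variance Gaussian nuisance on
#' all others. Labels are exactly balanced, so `H(Y) = log2(n_classes)`
#' bits. Inputs are clipped into `[0, 1]`, and split 6:1 train:test by
#' default.
#'
#' Uses R's global RNG; `set.seed()` makes the task reproducible.
#'
#' @param n_train,n_test Example counts for the two splits.
#' @param n_classes Number of classes.
#' @param dim Input dimensionality.
#' @param relevant_dim Number of coordinates carrying class information.
#' @param noise_sd Gaussian noise s.d. on the relevant coordinates (before
#'   scaling); small values make the task linearly separable.
#' @return A list of class `synthetic_task`: `train` and `test`
#'   [labelled_dataset()]s, `prototypes` (n_classes x relevant_dim),
#'   `relevant_dims` (coordinate indices), `noise_sd`.
#' @export
generate_synthetic_classification <- function(n_train = 2400, n_test = 400,
                                              n_classes = 10, dim = 784,
                                              relevant_dim = 20,
                                              noise_sd = 0.3) {
  if (relevant_dim > dim) stop("`relevant_dim` must not exceed `dim`")
  if (n_classes < 2 || dim < 1 || relevant_dim < 1) {
    stop("invalid task dimensions")
  }
  n <- n_train + n_test
  rel <- sort(sample.int(dim, relevant_dim))
  prototypes <- matrix(sample(c(0, 1), n_classes * relevant_dim,
                              replace = TRUE), n_classes)
  y <- sample(rep_len(0:(n_classes - 1L), n))
  x <- matrix(rnorm(n * dim, mean = 0.5, sd = 0.5), n, dim)
  x[, rel] <- prototypes[y + 1L, , drop = FALSE] +
    matrix(rnorm(n * relevant_dim, sd = noise_sd), n)
  x <- pmin(pmax(x, 0), 1)
  idx <- seq_len(n_train)
  structure(list(train = labelled_dataset(x[idx, , drop = FALSE], y[idx],
                                          n_classes),
                 test = labelled_dataset(x[-idx, , drop = FALSE], y[-idx],
                                         n_classes),
                 prototypes = prototypes, relevant_dims = rel,
                 noise_sd = noise_sd),
            class = "synthetic_task")
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf(
    "<synthetic_task> %d classes, dim %d (%d relevant), %d train / %d test\n",
    x$train$n_classes, ncol(x$train$x), length(x$relevant_dims),
    nrow(x$train$x), nrow(x$test$x)))
  invisible(x)
}

new_task_sequence <- function(tasks, protocol, n_out) {
  structure(list(tasks = tasks, protocol = protocol,
                 n_tasks = length(tasks), n_out = as.integer(n_out)),
            class = "task_sequence")
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> protocol=%s, %d tasks, %d output classes\n",
              x$protocol, x$n_tasks, x$n_out))
  invisible(x)
}

#' Split a multi-class task into sequential binary parity tasks
#'
#' Task `k` contains only the examples of classes `2k` and `2k + 1`
#' (0-based), relabelled by parity: even source class -> 0, odd -> 1. The
#' learner sees a shared two-way output for all tasks and, at the end of
#' the sequence, should classify the parity of every class.
#'
#' @param task A `synthetic_task` (or list with `train`/`test`
#'   [labelled_dataset()]s).
#' @param n_tasks Number of binary tasks; the source task needs at least
#'   `2 * n_tasks` classes.
#' @return A `task_sequence` whose element `k` has `train`, `test`, and
#'   `classes` (the two source classes).
#' @export
make_split_tasks <- function(task, n_tasks = 5) {
  if (task$train$n_classes < 2 * n_tasks) {
    stop("need at least 2 * n_tasks source classes")
  }
  pick <- function(ds, classes) {
    keep <- ds$y %in% classes
    labelled_dataset(ds$x[keep, , drop = FALSE], ds$y[keep] %% 2L, 2L)
  }
  tasks <- lapply(seq_len(n_tasks) - 1L, function(k) {
    classes <- c(2L * k, 2L * k + 1L)
    list(train = pick(task$train, classes), test = pick(task$test, classes),
         classes = classes)
  })
  new_task_sequence(tasks, "split_parity", 2L)
}

#' Permuted sequential tasks
#'
#' Each task applies one fixed random permutation of the input coordinates
#' to the whole dataset (task 1 is the identity), producing a sequence of
#' equally difficult tasks with uncorrelated input statistics. All tasks
#' keep the original labels and share the full output layer.
#'
#' @param task A `synthetic_task`.
#' @param n_tasks Number of permuted tasks.
#' @return A `task_sequence`; each element carries its `permutation`.
#' @export
make_permuted_tasks <- function(task, n_tasks = 10) {
  d <- ncol(task$train$x)
  tasks <- lapply(seq_len(n_tasks), function(k) {
    perm <- if (k == 1) seq_len(d) else sample.int(d)
    list(train = labelled_dataset(task$train$x[, perm, drop = FALSE],
                                  task$train$y, task$train$n_classes),
         test = labelled_dataset(task$test$x[, perm, drop = FALSE],
                                 task$test$y, task$test$n_classes),
         permutation = perm)
  })
  new_task_sequence(tasks, "permuted", task$train$n_classes)
}

#' Continuous task stream with smooth transitions
#'
#' Serialises a task sequence into a single example stream in which
#' adjacent tasks blend: inside a transition window centred on each task
#' boundary (of width `transition_fraction` of a task segment), each
#' position draws from the incoming task with linearly increasing
#' probability, so mid-transition batches are an even mixture and no
#' abrupt task switch is visible to the learner. With
#' `transition_fraction = 0` the abrupt concatenation is recovered. The
#' total example count equals the sum of the tasks' training examples.
#'
#' @param tasks A `task_sequence`.
#' @param transition_fraction Window width as a fraction of a task
#'   segment, in `[0, 1)`.
#' @return A list of class `task_stream`: `x`, `y` (the stream, in order),
#'   `source_task` (evaluation metadata, never shown to the learner),
#'   `n_out`, and the per-task `test` sets.
#' @export
make_continuous_sequence <- function(tasks, transition_fraction = 0.2) {
  if (!inherits(tasks, "task_sequence")) stop("expected a task_sequence")
  if (tasks$n_tasks < 2) stop("need at least two tasks")
  if (transition_fraction < 0 || transition_fraction >= 1) {
    stop("`transition_fraction` must lie in [0, 1)")
  }
  lens <- vapply(tasks$tasks, function(t) nrow(t$train$x), numeric(1))
  starts <- c(0, cumsum(lens))
  total <- sum(lens)
  u <- seq_len(total) - 0.5                      # continuous stream position
  seg <- findInterval(u, starts)

  # Per position: probability of drawing from the task *after* the nearest
  # boundary rises linearly 0 -> 1 across a window of width
  # transition_fraction * segment length centred on that boundary; the
  # boundary itself sits at an even 50/50 mixture.
  src <- seg
  if (transition_fraction > 0) {
    for (t in seq_len(total)) {
      s <- seg[t]
      into <- u[t] - starts[s]
      w_here <- transition_fraction * lens[s]
      if (s < tasks$n_tasks && into > lens[s] - w_here / 2) {
        q <- (into - (lens[s] - w_here / 2)) / w_here  # 0 -> 0.5 at boundary
        if (runif(1) < q) src[t] <- s + 1L
      } else if (s > 1) {
        w_prev <- transition_fraction * lens[s - 1]
        if (into < w_prev / 2) {
          q <- 0.5 - into / w_prev               # prob of the outgoing task
          if (runif(1) < q) src[t] <- s - 1L
        }
      }
    }
  }

  # consume each task's shuffled example queue in stream order, recycling
  # if a pool is exhausted; with transition_fraction = 0 this reproduces
  # the abrupt concatenation of shuffled task blocks exactly
  queues <- lapply(lens, sample)
  qpos <- rep(1L, tasks$n_tasks)
  idx <- integer(total)
  for (t in seq_len(total)) {
    k <- src[t]
    if (qpos[k] > lens[k]) {
      queues[[k]] <- sample(lens[k])
      qpos[k] <- 1L
    }
    idx[t] <- queues[[k]][qpos[k]]
    qpos[k] <- qpos[k] + 1L
  }
  x <- matrix(0, total, ncol(tasks$tasks[[1]]$train$x))
  y <- integer(total)
  for (k in seq_len(tasks$n_tasks)) {
    rows <- which(src == k)
    if (length(rows)) {
      x[rows, ] <- tasks$tasks[[k]]$train$x[idx[rows], , drop = FALSE]
      y[rows] <- tasks$tasks[[k]]$train$y[idx[rows]]
    }
  }
  structure(list(x = x, y = y, source_task = src, n_out = tasks$n_out,
                 test = lapply(tasks$tasks, `[[`, "test")),
            class = "task_stream")
}

#' Random pattern-memorisation tasks for the perceptron
#'
#' Each task holds `n_patterns` patterns sampled uniformly from
#' `{-1, +1}^dim` with labels sampled uniformly from `{-1, +1}`,
#' independently across tasks.
#'
#' @param n_tasks,n_patterns,dim Task count, patterns per task, pattern
#'   dimension.
#' @return A list of class `perceptron_tasks`; each element has `x`
#'   (n_patterns x dim, entries +-1) and `y` (+-1).
#' @export
generate_perceptron_tasks <- function(n_tasks = 5, n_patterns = 100,
                                      dim = 1000) {
  tasks <- lapply(seq_len(n_tasks), function(k) {
    list(x = matrix(sample(c(-1, 1), n_patterns * dim, replace = TRUE),
                    n_patterns, dim),
         y = sample(c(-1, 1), n_patterns, replace = TRUE))
  })
  structure(tasks, class = "perceptron_tasks", pattern_dim = dim)
}

# ---- IDX (MNIST container format) reader/writer -------------------------

read_idx_header <- function(con, expect_dims) {
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  ndim <- bitwAnd(magic, 0xFF)
  dtype <- bitwAnd(bitwShiftR(magic, 8), 0xFF)
  if (bitwShiftR(magic, 16) != 0 || dtype != 0x08 || ndim != expect_dims) {
    stop("IDX magic number mismatch")
  }
  readBin(con, "integer", n = ndim, size = 4, endian = "big")
}

#' Read an IDX-format image/label pair
#'
#' Reads the MNIST container format (unsigned-byte IDX files): a
#' 3-dimensional image file and a 1-dimensional label file. Pixels are
#' scaled to `[0, 1]` and images flattened row-wise.
#'
#' @param images_path,labels_path Paths to the IDX image and label files.
#' @return A [labelled_dataset()].
#' @export
load_idx_images <- function(images_path, labels_path) {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, 3L)
  n <- dims[1]; npix <- dims[2] * dims[3]
  raw <- readBin(con, "integer", n = n * npix, size = 1, signed = FALSE)
  if (length(raw) < n * npix) stop("truncated IDX image file")
  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  ldims <- read_idx_header(lcon, 1L)
  if (ldims[1] != n) stop("image and label counts disagree")
  y <- readBin(lcon, "integer", n = n, size = 1, signed = FALSE)
  if (length(y) < n) stop("truncated IDX label file")
  x <- matrix(raw, nrow = n, ncol = npix, byrow = TRUE) / 255
  labelled_dataset(x, y, n_classes = max(y) + 1L)
}

#' Write an IDX-format image/label pair
#'
#' Inverse of [load_idx_images()], mainly for building fixtures: values in
#' `[0, 1]` are quantised to bytes.
#'
#' @param data A [labelled_dataset()] whose dimension is a perfect square
#'   or for which `rows`/`cols` are given.
#' @param images_path,labels_path Output paths.
#' @param rows,cols Image shape; default square.
#' @return `images_path`, invisibly.
#' @export
write_idx_images <- function(data, images_path, labels_path,
                             rows = NULL, cols = NULL) {
  data <- as_labelled_dataset(data)
  npix <- ncol(data$x)
  if (is.null(rows)) rows <- as.integer(round(sqrt(npix)))
  if (is.null(cols)) cols <- as.integer(npix / rows)
  if (rows * cols != npix) stop("image shape does not match dimension")
  n <- nrow(data$x)
  con <- file(images_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(as.integer(c(0x00000803, n, rows, cols)), con, size = 4,
           endian = "big")
  writeBin(as.raw(round(t(data$x) * 255)), con)
  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(as.integer(c(0x00000801, n)), lcon, size = 4, endian = "big")
  writeBin(as.raw(data$y), lcon)
  invisible(images_path)
}
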