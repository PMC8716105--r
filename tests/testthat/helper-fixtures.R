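# Small fixtures shared across test files. Everything is generated in code
# under fixed seeds; nothing is read from disk.

# A small, quickly learnable synthetic task (lower-dimensional than the
# package default, same structure).
tiny_task <- function(seed = 101, n_train = 400, n_test = 120, dim = 40,
                      relevant_dim = 12, n_classes = 4, noise_sd = 0.1) {
  withr::with_seed(seed,
    generate_synthetic_classification(n_train = n_train, n_test = n_test,
                                      n_classes = n_classes, dim = dim,
                                      relevant_dim = relevant_dim,
                                      noise_sd = noise_sd))
}

tiny_net <- function(seed = 7, sizes = c(6, 5, 3), p_init = 0.5) {
  withr::with_seed(seed, stochastic_network(sizes, p_init = p_init))
}

# Plain multilayer-perceptron reference implemented with explicit
# double-precision scalar loops (ascending-index accumulation, no BLAS, no
# extended-precision sums), independent of the package's kernels. Used as
# the oracle for the deterministic limit, where agreement is bit-for-bit.
ref_mlp_forward <- function(weights, x) {
  a <- x
  L <- length(weights)
  for (l in seq_len(L)) {
    w <- weights[[l]]
    z <- numeric(ncol(w))
    for (j in seq_len(ncol(w))) {
      s <- 0
      for (i in seq_len(nrow(w))) s <- s + w[i, j] * a[i]
      z[j] <- s
    }
    if (l < L) {
      a <- ifelse(z > 0, z, 0)
    } else {
      zmax <- z[1]
      for (j in seq_along(z)) if (z[j] > zmax) zmax <- z[j]
      e <- exp(z - zmax)
      tot <- 0
      for (j in seq_along(e)) tot <- tot + e[j]
      a <- e / tot
    }
  }
  a
}

# Batch-mean cross-entropy gradient of the reference MLP, accumulated in
# the same order as the package kernels (per example, per layer, per
# postsynaptic unit; final scaling by multiplication with 1/n).
ref_mlp_grad <- function(weights, X, y) {
  L <- length(weights)
  g <- lapply(weights, function(w) w * 0)
  n <- nrow(X)
  for (e in seq_len(n)) {
    a <- list(X[e, ])
    z <- list()
    for (l in seq_len(L)) {
      w <- weights[[l]]
      zl <- numeric(ncol(w))
      for (j in seq_len(ncol(w))) {
        s <- 0
        for (i in seq_len(nrow(w))) s <- s + w[i, j] * a[[l]][i]
        zl[j] <- s
      }
      z[[l]] <- zl
      a[[l + 1]] <- if (l < L) ifelse(zl > 0, zl, 0) else {
        ez <- exp(zl - max(zl))
        tot <- 0
        for (j in seq_along(ez)) tot <- tot + ez[j]
        ez / tot
      }
    }
    delta <- a[[L + 1]]
    delta[y[e] + 1] <- delta[y[e] + 1] - 1
    for (l in L:1) {
      da <- numeric(nrow(weights[[l]]))
      for (j in seq_len(ncol(weights[[l]]))) {
        g[[l]][, j] <- g[[l]][, j] + delta[j] * a[[l]]
        da <- da + weights[[l]][, j] * delta[j]
      }
      if (l > 1) delta <- ifelse(z[[l - 1]] > 0, da, 0)
    }
  }
  lapply(g, function(m) m * (1 / n))
}

# plug-in mutual information by direct summation over cells (oracle)
ref_mutual_information <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  py <- rowSums(p); pz <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) {
      total <- total + p[i, j] * log2(p[i, j] / (py[i] * pz[j]))
    }
  }
  total
}
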