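# Independent brute-force oracles used to cross-check the implementation.

# Pearson matrix by explicit double loop over the textbook formula.
oracle_pearson <- function(X) {
  n <- nrow(X)
  R <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- X[i, ]; xj <- X[j, ]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    R[i, j] <- num / den
  }
  R
}

# Local clustering coefficients by triple loop over neighbour pairs.
oracle_clustering <- function(A) {
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] != 0) links <- links + 1
    C[i] <- 2 * links / (k * (k - 1))
  }
  C
}

# Global efficiency via per-source breadth-first search.
oracle_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) stop("need >= 2 nodes")
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] != 0)) {
          if (dist[w] > d) { dist[w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    total <- total + sum(1 / dist[-s][is.finite(dist[-s])])
  }
  total / (n * (n - 1))
}

# Random symmetric adjacency with density p.
random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# Build a functional_network directly from an adjacency matrix.
net_from_adjacency <- function(A) {
  rownames(A) <- colnames(A) <- paste0("cell_", seq_len(nrow(A)))
  R <- ifelse(A != 0, 0.9, 0)
  diag(R) <- 1
  corr <- structure(list(R = R, n_samples = 100L, window = NULL,
                         constant_cells = character(0)),
                    class = "correlation_matrix")
  suppressWarnings(threshold_network(corr, R_th = 0.5))
}

# Small noiseless deterministic islet used by several files.
quiet_params <- function(n_cells = 8, seed = 11, noise_sd = 0,
                         bleach_linear = 0, bleach_exp_amp = 0, ...) {
  sim_params(n_cells = n_cells, seed = seed, noise_sd = noise_sd,
             common_noise_sd = 0, shared_amp = 0, field_amp = 0,
             bleach_linear = bleach_linear, bleach_exp_amp = bleach_exp_amp,
             nonbeta_fraction = 0, f0_range = c(100, 100), ...)
}

# The 9-islet default-condition study is expensive; compute it once per
# test run and share it across test files.
study_cache <- new.env(parent = emptyenv())
get_default_study <- function() {
  if (is.null(study_cache$study))
    study_cache$study <- run_study(n_islets = 9L, seed = 1L)
  study_cache$study
}
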