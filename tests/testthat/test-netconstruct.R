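ts_from <- function(...) {
  rows <- rbind(...)
  trace_set(seq(0, by = 2, length.out = ncol(rows)), rows, stage = "unit")
}

test_that("pearson_matrix reproduces hand-computed coefficients", {
  R <- pearson_matrix(ts_from(c(0, 1, 2), c(0, 1, 2)))$R
  expect_equal(R[1, 2], 1)
  R <- pearson_matrix(ts_from(c(0, 1, 2), c(2, 1, 0)))$R
  expect_equal(R[1, 2], -1)
  R <- pearson_matrix(ts_from(c(1, 2, 3, 4), c(1, 3, 2, 4)))$R
  expect_equal(R[1, 2], 0.8)
})

test_that("pearson_matrix flags constant traces and validates windows", {
  corr <- pearson_matrix(ts_from(c(1, 1, 1, 1), c(1, 3, 2, 4)))
  expect_equal(corr$R[1, 2], 0)
  expect_equal(diag(corr$R), c(1, 1), ignore_attr = TRUE)
  expect_identical(corr$constant_cells, "cell_1")
  expect_error(pearson_matrix(ts_from(c(1, 2), c(3, 4))), "3 frames")
})

test_that("pearson_matrix matches the brute-force double loop", {
  set.seed(77)
  for (rep in 1:25) {
    X <- matrix(rnorm(10 * 30), 10)
    got <- pearson_matrix(trace_set(seq(0, by = 2, length.out = 30), X,
                                    stage = "unit"))$R
    expect_equal(got, oracle_pearson(X), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("critical correlation inverts the t significance test", {
  # independent oracle: numerically solve 2*(1 - pt(t(R), df)) = p
  oracle <- function(n, p) {
    uniroot(function(r)
      2 * (1 - pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2)) - p,
      c(1e-6, 1 - 1e-9), tol = 1e-12)$root
  }
  expect_equal(critical_r(50, 0.001), oracle(50, 0.001), tolerance = 1e-9)
  expect_equal(round(critical_r(50, 0.001), 3), 0.451)
  expect_equal(round(critical_r(25, 0.001), 3), 0.618)
  # strictly decreasing in n, increasing in 1-p, vanishing for large n
  ns <- c(5, 10, 25, 50, 200, 1000)
  expect_true(all(diff(critical_r(ns, 0.001)) < 0))
  expect_true(critical_r(50, 0.01) < critical_r(50, 0.001))
  expect_lt(critical_r(1e6, 0.001), 0.004)
  expect_error(critical_r(2, 0.001), "n")
})

test_that("thresholding keeps strict exceedances and isolated nodes", {
  R <- matrix(0.8, 4, 4); diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("cell_", 1:4)
  corr <- structure(list(R = R, n_samples = 100L,
                         constant_cells = character(0)),
                    class = "correlation_matrix")
  net <- threshold_network(corr, 0.75)
  expect_equal(unname(net$degrees), rep(3, 4))

  expect_equal(igraph::ecount(threshold_network(corr, 0.8)$graph), 0)

  R3 <- diag(3)
  R3[1, 2] <- R3[2, 1] <- 0.9
  R3[1, 3] <- R3[3, 1] <- 0.7
  R3[2, 3] <- R3[3, 2] <- 0.76
  rownames(R3) <- colnames(R3) <- paste0("cell_", 1:3)
  corr3 <- structure(list(R = R3, n_samples = 100L,
                          constant_cells = character(0)),
                     class = "correlation_matrix")
  net3 <- threshold_network(corr3, 0.75)
  expect_equal(unname(net3$degrees), c(1, 2, 1))
  expect_error(threshold_network(corr3, -0.1), "positive")
  # sub-significant threshold warns
  corr_small <- corr3; corr_small$n_samples <- 10L
  expect_warning(threshold_network(corr_small, 0.75), "critical")
})

test_that("network metrics decrease monotonically in the threshold", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 40), 15) +
      rep(rnorm(40), each = 15) * runif(15)
    corr <- pearson_matrix(trace_set(seq(0, by = 2, length.out = 40), X,
                                     stage = "unit"))
    ths <- seq(0.05, 0.95, by = 0.05)
    stats <- t(vapply(ths, function(th) {
      net <- suppressWarnings(threshold_network(corr, th))
      c(edges = igraph::ecount(net$graph), k = mean(net$degrees),
        C = clustering_coefficients(net)$C_avg,
        E = global_efficiency(net))
    }, numeric(4)))
    for (cn in c("edges", "k", "E"))
      expect_true(all(diff(stats[, cn]) <= 1e-12))
    # clustering decreases as a trend, not pointwise
    expect_lt(cor(ths, stats[, "C"], method = "spearman"), 0)
  }
})

test_that("average correlation is the unordered off-diagonal mean", {
  R3 <- diag(3)
  R3[upper.tri(R3)] <- c(0.2, 0.4, 0.6)
  R3 <- pmax(R3, t(R3))
  corr <- structure(list(R = R3, n_samples = 50L,
                         constant_cells = character(0)),
                    class = "correlation_matrix")
  expect_equal(average_correlation(corr), 0.4)

  cc <- pearson_matrix(ts_from(c(1, 2, 3), c(2, 4, 6), c(0, 1, 2)))
  expect_equal(average_correlation(cc), 1)

  set.seed(3)
  X <- matrix(rnorm(30 * 200), 30)
  nullc <- pearson_matrix(trace_set(seq(0, by = 2, length.out = 200), X,
                                    stage = "unit"))
  expect_lt(abs(average_correlation(nullc)), 0.05)
})

test_that("sliding windows tile the recording as specified", {
  p <- sim_params(n_cells = 8, seed = 6)
  tr <- simulate_traces(generate_geometry(p), p)
  s1 <- sliding_metrics(tr, 100, 100, metrics = "R_avg")
  expect_equal(nrow(s1), 18)
  expect_equal(s1$t_center[1], 50)
  s2 <- sliding_metrics(tr, 100, 20, metrics = "R_avg")
  expect_equal(nrow(s2), 86)
  expect_error(sliding_metrics(tr, 4, 2), "3 frames")
  expect_error(sliding_metrics(tr, 100, 150), "step")
})

test_that("windowed average correlation peaks during the transients", {
  p <- sim_params(n_cells = 25, seed = 10)
  tr <- simulate_traces(generate_geometry(p), p)
  unit <- rescale_unit(f_over_f0(correct_bleaching(tr, p$schedule)))
  sl <- sliding_metrics(unit, 100, 100, metrics = "R_avg")
  in_win <- function(t, lo, hi) t >= lo & t < hi
  r_on <- max(sl$R_avg[in_win(sl$t_center, 300, 420)])
  r_off <- max(sl$R_avg[in_win(sl$t_center, 1080, 1200)])
  r_hg <- mean(sl$R_avg[in_win(sl$t_center, 600, 1000)])
  r_lg <- mean(sl$R_avg[in_win(sl$t_center, 0, 300) |
                          in_win(sl$t_center, 1400, 1800)])
  expect_gt(r_on, r_hg)
  expect_gt(r_off, r_hg)
  expect_gt(r_hg, r_lg)
})
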