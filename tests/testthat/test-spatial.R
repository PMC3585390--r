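geom_df <- function(x, y) data.frame(cell_id = seq_along(x), x_um = x,
                                     y_um = y)

corr_from_R <- function(R) {
  rownames(R) <- colnames(R) <- paste0("cell_", seq_len(nrow(R)))
  structure(list(R = R, n_samples = 100L, constant_cells = character(0)),
            class = "correlation_matrix")
}

sym <- function(n, vals) {
  R <- diag(n)
  R[upper.tri(R)] <- vals
  pmax(R, t(R))
}

test_that("pairwise distances are Euclidean and rigid-motion invariant", {
  D <- pairwise_distances(geom_df(c(0, 3), c(0, 4)))
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), c(0, 0), ignore_attr = TRUE)
  expect_equal(pairwise_distances(geom_df(c(1, 1), c(2, 2)))[1, 2], 0)

  set.seed(12)
  x <- runif(20, 0, 100); y <- runif(20, 0, 100)
  D1 <- pairwise_distances(geom_df(x, y))
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    brute[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  expect_equal(unname(D1), brute, tolerance = 1e-12)

  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 50
  yr <- sin(th) * x + cos(th) * y - 20
  expect_equal(pairwise_distances(geom_df(xr, yr)), D1, tolerance = 1e-9)
})

test_that("2D histograms conserve the pair count", {
  D <- pairwise_distances(geom_df(c(0, 10, 20), c(0, 0, 0)))
  corr <- corr_from_R(sym(3, c(0.5, 0.6, 0.7)))
  H <- hist2d_distance_correlation(D, corr, d_edges = c(0, 15, 30),
                                   r_edges = c(0, 0.55, 1))
  expect_equal(sum(H) + attr(H, "overflow"), 3)

  # all pairs collapse into a single bin
  H1 <- hist2d_distance_correlation(D, corr, d_edges = c(0, 100),
                                    r_edges = c(0, 1))
  expect_equal(sum(H1 == 3), 1)
  expect_equal(attr(H1, "overflow"), 0)

  # out-of-range pairs land in the overflow, preserving the total
  H2 <- hist2d_distance_correlation(D, corr, d_edges = c(0, 5),
                                    r_edges = c(0, 1))
  expect_equal(attr(H2, "overflow"), 3)
  expect_error(hist2d_distance_correlation(D, corr, d_edges = c(10, 0)),
               "increasing")
})

test_that("distance-binned correlation averages per bin", {
  D <- pairwise_distances(geom_df(c(0, 10, 100), c(0, 0, 0)))
  corr <- corr_from_R(sym(3, c(0.2, 0.8, 0.8)))
  # drop the third cell pairings into known bins
  out <- distance_binned_avg_correlation(
    D, corr_from_R(sym(3, c(0.2, 0.8, 0.8))), d_edges = c(0, 50, 150))
  expect_equal(out$R_avg, c(0.2, 0.8))
  expect_equal(out$n_pairs, c(1L, 2L))

  # constant correlations return the constant in every nonempty bin
  cc <- corr_from_R(sym(3, rep(0.42, 3)))
  out2 <- distance_binned_avg_correlation(D, cc, d_edges = c(0, 50, 150))
  expect_equal(out2$R_avg, c(0.42, 0.42))
  # empty bins are NA, not zero
  out3 <- distance_binned_avg_correlation(D, cc, d_edges = c(0, 5, 50, 150))
  expect_true(is.na(out3$R_avg[1]))
})

test_that("hub link lengths average edges incident to top-degree nodes", {
  # star K_{1,4}: hub at origin, spokes 10 um away
  g <- geom_df(c(0, 10, -10, 0, 0), c(0, 0, 0, 10, -10))
  D <- pairwise_distances(g)
  star <- sym(5, rep(0, 10))
  star[1, 2:5] <- star[2:5, 1] <- 0.9
  net <- threshold_network(corr_from_R(star), 0.75)
  expect_equal(hub_link_lengths(net, D, 0.2), 10)

  # complete graph with equal link lengths: hub selection is irrelevant
  tri <- geom_df(c(0, 10, 5), c(0, 0, 10 * sin(pi / 3)))
  Dtri <- pairwise_distances(tri)
  netc <- threshold_network(corr_from_R(sym(3, rep(0.9, 3))), 0.75)
  expect_equal(hub_link_lengths(netc, Dtri, 0.2), 10)
  # with every node a hub, the mean runs over all edges
  el <- igraph::as_edgelist(netc$graph, names = FALSE)
  expect_equal(hub_link_lengths(netc, Dtri, 1), mean(Dtri[el]))

  # degrees (4,2,2,1,1): the single top-20% node is node 1; enumerate
  R5 <- sym(5, rep(0, 10))
  edges <- list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3))
  for (e in edges) R5[e[1], e[2]] <- R5[e[2], e[1]] <- 0.9
  net5 <- threshold_network(corr_from_R(R5), 0.75)
  expect_equal(unname(net5$degrees), c(4, 2, 2, 1, 1))
  hub_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
  expect_equal(hub_link_lengths(net5, D, 0.2), mean(D[hub_edges]))

  edgeless <- threshold_network(corr_from_R(sym(5, rep(0, 10))), 0.75)
  expect_warning(res <- hub_link_lengths(edgeless, D), "no edges")
  expect_true(is.na(res))
})

test_that("clustering vs link length bins node-wise mean lengths", {
  # triangle with 10-um sides plus a remote 100-um pair
  x <- c(0, 10, 5, 200, 300)
  y <- c(0, 0, 10 * sin(pi / 3), 0, 0)
  g <- geom_df(x, y)
  D <- pairwise_distances(g)
  R5 <- sym(5, rep(0, 10))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5)))
    R5[e[1], e[2]] <- R5[e[2], e[1]] <- 0.9
  net <- threshold_network(corr_from_R(R5), 0.75)
  out <- clustering_vs_link_length(net, D, c_edges = seq(0, 1, 0.5))
  # C = 1 bin: the triangle nodes (sides ~10 um); C = 0 bin: the far pair
  expect_equal(out$mean_link_length_um[out$bin_lo == 0.5],
               mean(c(10, D[1, 3], D[2, 3])), tolerance = 0.5)
  expect_equal(out$mean_link_length_um[out$bin_lo == 0], 100)

  # uniform edge length: every nonempty bin reports that length
  sq <- geom_df(c(0, 10, 10, 0), c(0, 0, 10, 10))
  Dsq <- pairwise_distances(sq)
  ring <- sym(4, rep(0, 6))
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    ring[e[1], e[2]] <- ring[e[2], e[1]] <- 0.9
  netr <- threshold_network(corr_from_R(ring), 0.75)
  outr <- clustering_vs_link_length(netr, Dsq)
  vals <- outr$mean_link_length_um[!is.na(outr$mean_link_length_um)]
  expect_equal(vals, 10)
})

test_that("high-glucose simulations put short links on correlated pairs", {
  p <- sim_params(n_cells = 50, seed = 17)
  g <- generate_geometry(p)
  tr <- simulate_traces(g, p)
  unit <- rescale_unit(f_over_f0(correct_bleaching(tr, p$schedule)))
  beta <- names(attr(tr, "true_labels"))[attr(tr, "true_labels") == "beta"]
  unit <- trace_set(unit$times, unit$values[beta, ], stage = "unit")
  D <- pairwise_distances(g)
  hg_corr <- pearson_matrix(segment_regime(unit, p$schedule, "HG"))
  lg_corr <- pearson_matrix(segment_regime(unit, p$schedule, "LG1"))
  edges <- seq(0, 220, by = 20)

  hg_bin <- distance_binned_avg_correlation(D, hg_corr, edges)
  ok <- !is.na(hg_bin$R_avg)
  rho_hg <- cor(hg_bin$bin_center[ok], hg_bin$R_avg[ok], method = "spearman")
  expect_lt(rho_hg, -0.5)

  lg_bin <- distance_binned_avg_correlation(D, lg_corr, edges)
  okl <- !is.na(lg_bin$R_avg)
  rho_lg <- cor(lg_bin$bin_center[okl], lg_bin$R_avg[okl],
                method = "spearman")
  expect_lt(abs(rho_lg), abs(rho_hg))

  # 2D histogram: count-weighted mean R of nearest bin beats farthest
  H <- hist2d_distance_correlation(D, hg_corr, d_edges = edges,
                                   r_edges = seq(-1, 1, 0.05))
  rmid <- seq(-0.975, 0.975, by = 0.05)
  near <- which(rowSums(H) > 0)[1]
  far <- rev(which(rowSums(H) > 0))[1]
  expect_gt(sum(H[near, ] * rmid) / sum(H[near, ]),
            sum(H[far, ] * rmid) / sum(H[far, ]))
})
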