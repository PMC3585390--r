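#' Pairwise Euclidean distances between cell centroids
#'
#' @param geom a data frame with `cell_id`, `x_um`, `y_um` (e.g. from
#'   [generate_geometry()] or [read_fixture()]).
#' @return A symmetric matrix of distances in µm, dimnames `cell_<id>`.
#' @export
pairwise_distances <- function(geom) {
  if (!all(c("cell_id", "x_um", "y_um") %in% names(geom)))
    stop("geometry needs columns cell_id, x_um, y_um")
  if (any(!is.finite(geom$x_um)) || any(!is.finite(geom$y_um)))
    stop("positions must be finite")
  D <- as.matrix(stats::dist(cbind(geom$x_um, geom$y_um)))
  dimnames(D) <- list(paste0("cell_", geom$cell_id),
                      paste0("cell_", geom$cell_id))
  D
}

# align a distance matrix to the cell ids of a correlation matrix / network
align_distances <- function(D, ids) {
  if (!all(ids %in% rownames(D)))
    stop("distance matrix is missing cells present in the network")
  D[ids, ids, drop = FALSE]
}

#' 2D histogram of cell pairs over distance and correlation
#'
#' Counts the unordered off-diagonal cell pairs falling in each
#' (distance, correlation) bin — the joint view that reveals whether nearby
#' cells are better correlated than remote ones. Pairs outside the binned
#' ranges are accumulated in an overflow count (attribute `"overflow"`), so
#' the total including overflow always equals `N(N-1)/2`.
#'
#' @param dist distance matrix from [pairwise_distances()].
#' @param corr a [pearson_matrix()] result.
#' @param d_edges,r_edges monotone increasing bin edges for distance (µm)
#'   and correlation.
#' @return An integer matrix (distance bins x correlation bins) with
#'   attributes `"overflow"`, `"d_edges"`, `"r_edges"`.
#' @export
hist2d_distance_correlation <- function(dist, corr,
                                        d_edges = seq(0, 300, by = 10),
                                        r_edges = seq(-1, 1, by = 0.05)) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (is.unsorted(d_edges, strictly = TRUE) ||
      is.unsorted(r_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  D <- align_distances(dist, rownames(corr$R))
  pr <- upper_pairs(nrow(D))
  l <- D[pr]; r <- corr$R[pr]
  di <- findInterval(l, d_edges, rightmost.closed = TRUE)
  ri <- findInterval(r, r_edges, rightmost.closed = TRUE)
  nd <- length(d_edges) - 1L; nr <- length(r_edges) - 1L
  inside <- di >= 1L & di <= nd & ri >= 1L & ri <= nr
  H <- matrix(0L, nd, nr,
              dimnames = list(
                sprintf("[%g,%g)", d_edges[-length(d_edges)], d_edges[-1L]),
                sprintf("[%g,%g)", r_edges[-length(r_edges)], r_edges[-1L])))
  if (any(inside)) {
    tab <- table(factor(di[inside], levels = seq_len(nd)),
                 factor(ri[inside], levels = seq_len(nr)))
    H[] <- as.integer(tab)
  }
  attr(H, "overflow") <- sum(!inside)
  attr(H, "d_edges") <- d_edges
  attr(H, "r_edges") <- r_edges
  H
}

#' Distance-binned average correlation
#'
#' Mean `R_ij` over the cell pairs whose separation falls in each distance
#' bin. Empty bins are reported as `NA`, not zero.
#'
#' @param dist distance matrix from [pairwise_distances()].
#' @param corr a [pearson_matrix()] result.
#' @param d_edges monotone distance-bin edges in µm.
#' @return Data frame with `bin_lo`, `bin_hi`, `bin_center`, `R_avg`,
#'   `n_pairs`.
#' @export
distance_binned_avg_correlation <- function(dist, corr,
                                            d_edges = seq(0, 300, by = 10)) {
  stopifnot(inherits(corr, "correlation_matrix"))
  D <- align_distances(dist, rownames(corr$R))
  pr <- upper_pairs(nrow(D))
  l <- D[pr]; r <- corr$R[pr]
  nb <- length(d_edges) - 1L
  bi <- findInterval(l, d_edges, rightmost.closed = TRUE)
  out <- data.frame(bin_lo = d_edges[-length(d_edges)],
                    bin_hi = d_edges[-1L])
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out$R_avg <- vapply(seq_len(nb), function(b) {
    sel <- bi == b
    if (any(sel)) mean(r[sel]) else NA_real_
  }, numeric(1))
  out$n_pairs <- vapply(seq_len(nb), function(b) sum(bi == b), integer(1))
  out
}

#' Mean length of links incident to hub cells
#'
#' Selects the `ceiling(top_fraction * N)` most connected cells (ties broken
#' by cell id for determinism) and returns the mean Euclidean length of the
#' links with at least one endpoint among them, each link counted once.
#'
#' @param net a [threshold_network()] result.
#' @param dist distance matrix from [pairwise_distances()].
#' @param top_fraction fraction of nodes treated as hubs (default 0.2).
#' @return Mean hub link length in µm, or `NA` (with a warning) for an
#'   edgeless network.
#' @export
hub_link_lengths <- function(net, dist, top_fraction = 0.2) {
  stopifnot(inherits(net, "functional_network"))
  D <- align_distances(dist, net$cell_ids)
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  if (nrow(el) == 0L) {
    warning("network has no edges; hub link length undefined")
    return(NA_real_)
  }
  n <- length(net$cell_ids)
  ord <- order(-net$degrees, net$cell_ids)
  hubs <- ord[seq_len(ceiling(top_fraction * n))]
  keep <- el[, 1L] %in% hubs | el[, 2L] %in% hubs
  mean(D[el[keep, , drop = FALSE]])
}

#' Mean incident-link length as a function of local clustering
#'
#' For every connected cell, the mean length of its incident links is
#' computed; cells are then grouped into bins of their local clustering
#' coefficient `C_i` and each bin reports the mean of its cells' values.
#' Short links supporting high clustering indicate cliques of physically
#' adjacent cells.
#'
#' @param net a [threshold_network()] result.
#' @param dist distance matrix from [pairwise_distances()].
#' @param c_edges monotone bin edges for `C_i` (the last bin is closed so
#'   that `C_i = 1` is included).
#' @return Data frame with `bin_lo`, `bin_hi`, `bin_center`,
#'   `mean_link_length_um`, `n_cells`.
#' @export
clustering_vs_link_length <- function(net, dist,
                                      c_edges = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(net, "functional_network"))
  D <- align_distances(dist, net$cell_ids)
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  if (nrow(el) == 0L) stop("network needs at least one edge")
  C_i <- clustering_coefficients(net)$C_i
  lens <- D[el]
  n <- length(net$cell_ids)
  node_mean <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    inc <- el[, 1L] == v | el[, 2L] == v
    if (any(inc)) node_mean[v] <- mean(lens[inc])
  }
  connected <- !is.na(node_mean)
  bi <- findInterval(C_i, c_edges, rightmost.closed = TRUE)
  nb <- length(c_edges) - 1L
  out <- data.frame(bin_lo = c_edges[-length(c_edges)],
                    bin_hi = c_edges[-1L])
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out$mean_link_length_um <- vapply(seq_len(nb), function(b) {
    sel <- connected & bi == b
    if (any(sel)) mean(node_mean[sel]) else NA_real_
  }, numeric(1))
  out$n_cells <- vapply(seq_len(nb), function(b)
    sum(connected & bi == b), integer(1))
  out
}
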