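#' Pairwise Pearson correlation matrix over a time window
#'
#' Computes the cells-by-cells matrix of Pearson product-moment correlation
#' coefficients
#' \deqn{R_{ij} = \frac{\sum_t (x_i(t)-\bar x_i)(x_j(t)-\bar x_j)}
#'       {n\,\sigma_i \sigma_j}}
#' over the frames of `traces` (population and sample conventions cancel in
#' the ratio). `R = 0` means no linear relationship, `R = 1` completely
#' synchronous dynamics. Constant traces have undefined correlations; their
#' entries are recorded as 0 and the cells flagged, so one dead ROI cannot
#' abort an islet.
#'
#' @param traces a [trace_set()] (typically a [segment_regime()] slice).
#' @return An object of class `correlation_matrix`: list with `R` (symmetric
#'   matrix, unit diagonal), `n_samples`, `window` (if the slice carries
#'   one), and `constant_cells`.
#' @export
pearson_matrix <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  n <- ncol(traces$values)
  if (n < 3L) stop("correlation window must contain at least 3 frames")
  if (nrow(traces$values) < 2L) stop("need at least 2 cells")
  sds <- apply(traces$values, 1L, stats::sd)
  const <- sds == 0
  R <- suppressWarnings(stats::cor(t(traces$values)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  structure(list(R = R, n_samples = n,
                 window = attr(traces, "window"),
                 regime = attr(traces, "regime"),
                 constant_cells = cell_ids(traces)[const]),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d cells, n = %d frames\n",
              nrow(x$R), x$n_samples))
  if (length(x$constant_cells))
    cat("  constant (flagged) cells:",
        paste(x$constant_cells, collapse = ", "), "\n")
  invisible(x)
}

#' Critical correlation coefficient at a given significance level
#'
#' The significance of a Pearson coefficient is assessed with the t-test
#' \eqn{t = R\sqrt{(n-2)/(1-R^2)}} on `n - 2` degrees of freedom. Inverting
#' at the two-tailed critical t gives the smallest coefficient significant
#' at level `p` for a window of `n` compared frames:
#' \deqn{R_{crit} = t_c / \sqrt{n - 2 + t_c^2}.}
#' `R_crit` decreases monotonically in `n` and tends to 0 as `n` grows.
#'
#' @param n number of compared data points (frames), at least 3.
#' @param p two-tailed significance level in (0, 1); default 0.001.
#' @return The critical correlation coefficient.
#' @examples
#' critical_r(50, 0.001)  # ~0.451 for a 100-s window at 0.5 Hz
#' @export
critical_r <- function(n, p = 0.001) {
  if (any(n < 3)) stop("n must be >= 3")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  tc <- stats::qt(1 - p / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Threshold a correlation matrix into a functional network
#'
#' Two cells are functionally connected iff their correlation strictly
#' exceeds the positive threshold `R_th`; the result is a simple undirected
#' unweighted graph (edge weights retain `R_ij` for reporting). Isolated
#' nodes are kept. A warning is recorded if `R_th` lies below the critical
#' correlation at `p` for the window's sample count, i.e. if sub-significant
#' links could enter the graph.
#'
#' @param corr a [pearson_matrix()] result.
#' @param R_th positive correlation threshold (default 0.75).
#' @param p significance level used for the threshold check.
#' @return An object of class `functional_network`: list with `graph`
#'   (igraph), `R_th`, `cell_ids`, `degrees`, and `subsignificant` flag.
#' @export
threshold_network <- function(corr, R_th = 0.75, p = 0.001) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (R_th <= 0) stop("R_th must be positive")
  subsig <- FALSE
  rc <- critical_r(corr$n_samples, p)
  if (R_th < rc) {
    subsig <- TRUE
    warning(sprintf(
      "R_th = %.3g is below the critical correlation %.3g (n = %d, p = %g)",
      R_th, rc, corr$n_samples, p))
  }
  A <- corr$R > R_th
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::E(g)$weight <- corr$R[igraph::as_edgelist(g, names = FALSE)]
  structure(list(graph = g, R_th = R_th, cell_ids = rownames(corr$R),
                 degrees = igraph::degree(g), subsignificant = subsig),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(
    "functional_network: %d nodes, %d edges (R_th = %g, k_avg = %.2f)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$R_th,
    mean(x$degrees)))
  invisible(x)
}

#' Average pairwise correlation
#'
#' Mean of `R_ij` over all `N(N-1)/2` unordered off-diagonal pairs — a
#' single-parameter summary of the coherence of calcium dynamics in the
#' islet.
#'
#' @param corr a [pearson_matrix()] result.
#' @return Scalar `R_avg`.
#' @export
average_correlation <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (nrow(corr$R) < 2L) stop("need at least 2 cells")
  mean(corr$R[upper.tri(corr$R)])
}

#' Sliding-window network metrics
#'
#' Splits the recording into windows of length `window_s` advanced by
#' `step_s` (non-overlapping when `step_s == window_s`) and evaluates the
#' requested metrics on each window's correlation matrix and thresholded
#' network. Windows are half-open `[start, start + window_s)`; the series is
#' truncated at the end of the recording (no padding) and timestamps are
#' window centers.
#'
#' @param traces a [trace_set()].
#' @param window_s window length in seconds (>= 3 frames).
#' @param step_s step between window starts; must not exceed `window_s`.
#' @param R_th correlation threshold for the network metrics.
#' @param metrics subset of `c("R_avg", "k_avg", "C_avg", "E_glob")`.
#' @return A data frame with `t_center` and one column per metric.
#' @export
sliding_metrics <- function(traces, window_s, step_s = window_s,
                            R_th = 0.75,
                            metrics = c("R_avg", "k_avg", "C_avg",
                                        "E_glob")) {
  stopifnot(inherits(traces, "trace_set"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  dt <- 1 / traces$frame_rate_hz
  if (window_s < 3 * dt)
    stop("window_s must span at least 3 frames")
  if (step_s > window_s) stop("step_s must not exceed window_s")
  t0 <- traces$times[1L]
  t_end <- traces$times[length(traces$times)] + dt
  starts <- seq(t0, t_end - window_s, by = step_s)
  rows <- lapply(starts, function(s) {
    keep <- traces$times >= s & traces$times < s + window_s
    sl <- trace_set(traces$times[keep],
                    traces$values[, keep, drop = FALSE],
                    frame_rate_hz = traces$frame_rate_hz,
                    stage = traces$stage)
    corr <- pearson_matrix(sl)
    out <- c(t_center = s + window_s / 2)
    if ("R_avg" %in% metrics)
      out["R_avg"] <- average_correlation(corr)
    if (any(c("k_avg", "C_avg", "E_glob") %in% metrics)) {
      net <- suppressWarnings(threshold_network(corr, R_th))
      if ("k_avg" %in% metrics) out["k_avg"] <- mean(net$degrees)
      if ("C_avg" %in% metrics)
        out["C_avg"] <- clustering_coefficients(net)$C_avg
      if ("E_glob" %in% metrics) out["E_glob"] <- global_efficiency(net)
    }
    out
  })
  as.data.frame(do.call(rbind, rows))
}

#' Export a correlation matrix or network edge list as CSV
#'
#' @param corr a [pearson_matrix()] result.
#' @param net a [threshold_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(corr, path) {
  stopifnot(inherits(corr, "correlation_matrix"))
  df <- data.frame(cell_id = rownames(corr$R), corr$R, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
write_edgelist_csv <- function(net, path) {
  stopifnot(inherits(net, "functional_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  df <- data.frame(cell_i = el[, 1L], cell_j = el[, 2L],
                   R_ij = if (igraph::ecount(net$graph))
                     igraph::E(net$graph)$weight else numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
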