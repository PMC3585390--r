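# Accept either a functional_network or a bare igraph object.
as_graph <- function(net) {
  if (inherits(net, "functional_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a functional_network or an igraph graph")
}

#' Node clustering coefficients
#'
#' The clustering coefficient of node i is the number of existing links
#' between its neighbours divided by the number of possible links between
#' them, `C_i = 2 T_i / (k_i (k_i - 1))` with `T_i` the triangles through i.
#' Nodes of degree < 2 have `C_i = 0` (and are included in the average), so
#' `C_avg` stays defined on sparse low-glucose networks. `C_avg` measures
#' functional segregation.
#'
#' @param net a [threshold_network()] result or igraph graph.
#' @return List with `C_i` (named per-node vector) and `C_avg`.
#' @export
clustering_coefficients <- function(net) {
  g <- as_graph(net)
  C_i <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(C_i) <- igraph::V(g)$name
  list(C_i = C_i, C_avg = mean(C_i))
}

#' Global efficiency
#'
#' \deqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij},}
#' the mean inverse shortest-path length over ordered node pairs, with
#' disconnected pairs contributing `1/Inf = 0` (Latora-Marchiori form).
#' It is inversely related to the average shortest path length and measures
#' functional integration; a complete graph attains 1, an edgeless graph 0.
#'
#' @param net a [threshold_network()] result or igraph graph.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  D <- igraph::distances(g, weights = NA, algorithm = "unweighted")
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Random-graph reference metrics
#'
#' Averages the clustering coefficient and global efficiency over uniform
#' random graphs with exactly the same number of nodes and links (the
#' G(n, m) model, hence also the same average degree) as the network of
#' interest. This is the null model against which small-world-ness is
#' quantified.
#'
#' @param n_nodes,n_edges order and size of the reference ensemble.
#' @param n_realizations number of sampled graphs (default 100).
#' @param seed integer seed for reproducibility (optional).
#' @return List with `C_rand`, `E_rand`, their Monte-Carlo standard errors
#'   `se_C` and `se_E`, and `n_realizations`.
#' @export
random_reference <- function(n_nodes, n_edges, n_realizations = 100L,
                             seed = NULL) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_edges)
    stop(sprintf("infeasible edge count %d for %d nodes (max %d)",
                 n_edges, n_nodes, max_edges))
  if (n_realizations < 1L) stop("n_realizations must be >= 1")
  with_seed(seed, {
    Cs <- Es <- numeric(n_realizations)
    for (r in seq_len(n_realizations)) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      Cs[r] <- clustering_coefficients(g)$C_avg
      Es[r] <- global_efficiency(g)
    }
    list(C_rand = mean(Cs), E_rand = mean(Es),
         se_C = stats::sd(Cs) / sqrt(n_realizations),
         se_E = stats::sd(Es) / sqrt(n_realizations),
         n_realizations = n_realizations)
  })
}

#' Small-world-ness
#'
#' A network is small-world when it is simultaneously more clustered than a
#' matched random graph (`C_avg / C_rand >> 1`) while remaining comparably
#' integrated (`E_rand / E_glob ~ 1`). The single-parameter summary is
#' \deqn{S = \frac{C_{avg}/C_{rand}}{E_{rand}/E_{glob}},}
#' typically > 1 for small worlds.
#'
#' @param C_avg,E_glob clustering and efficiency of the network of interest.
#' @param C_rand,E_rand the random-reference values (see
#'   [random_reference()]).
#' @return List with `clustering_ratio` (`C_avg/C_rand`), `efficiency_ratio`
#'   (`E_rand/E_glob`), `S`, and a `defined` flag; a zero denominator yields
#'   `NA` ratios with `defined = FALSE` rather than infinities.
#' @export
small_worldness <- function(C_avg, E_glob, C_rand, E_rand) {
  if (C_rand <= 0 || E_glob <= 0 || E_rand <= 0)
    return(list(clustering_ratio = NA_real_, efficiency_ratio = NA_real_,
                S = NA_real_, defined = FALSE))
  small_worldness_from_ratios(C_avg / C_rand, E_rand / E_glob)
}

#' @rdname small_worldness
#' @param clustering_ratio,efficiency_ratio precomputed ratios
#'   `C_avg/C_rand` and `E_rand/E_glob`, e.g. from a published summary
#'   table.
#' @export
small_worldness_from_ratios <- function(clustering_ratio,
                                        efficiency_ratio) {
  if (!is.finite(clustering_ratio) || !is.finite(efficiency_ratio) ||
      efficiency_ratio <= 0)
    return(list(clustering_ratio = clustering_ratio,
                efficiency_ratio = efficiency_ratio,
                S = NA_real_, defined = FALSE))
  list(clustering_ratio = clustering_ratio,
       efficiency_ratio = efficiency_ratio,
       S = clustering_ratio / efficiency_ratio, defined = TRUE)
}

#' Cumulative degree distribution, optionally pooled across islets
#'
#' `G(k)` is the fraction of nodes with degree at least `k`; the cumulative
#' form tames statistical fluctuations in small networks. To pool islets of
#' different sizes, each islet's degrees are first normalized to its maximal
#' degree `k_max`, `G` is evaluated on a common normalized-degree grid, and
#' the pooled curve is the mean of the per-islet curves. Networks with
#' `k_max = 0` are excluded with a warning.
#'
#' @param nets a single network, a list of networks, or a (list of) numeric
#'   degree vector(s).
#' @param grid evaluation grid; defaults to `seq(0.05, 1, by = 0.05)` on the
#'   normalized scale, or the sorted unique degrees when `normalize = FALSE`.
#' @param normalize normalize each islet's degrees by its `k_max` (required
#'   for pooling more than one islet).
#' @return An object of class `degree_distribution`: list with `grid`, `G`
#'   (pooled curve), `per_islet` (matrix islets x grid), `n_islets`,
#'   `normalized`.
#' @export
cumulative_degree_distribution <- function(nets, grid = NULL,
                                           normalize = TRUE) {
  if (inherits(nets, "functional_network") || igraph::is_igraph(nets) ||
      is.numeric(nets))
    nets <- list(nets)
  degs <- lapply(nets, function(x)
    if (is.numeric(x)) x else as.numeric(igraph::degree(as_graph(x))))
  kmax <- vapply(degs, function(d) if (length(d)) max(d) else 0, numeric(1))
  keep <- kmax > 0
  if (!all(keep)) {
    warning(sprintf("%d islet(s) with k_max = 0 excluded", sum(!keep)))
    degs <- degs[keep]; kmax <- kmax[keep]
  }
  if (!length(degs)) stop("no non-empty networks to pool")
  if (!normalize && length(degs) > 1L)
    stop("pooling multiple islets requires normalize = TRUE")
  if (normalize) degs <- Map(function(d, m) d / m, degs, kmax)
  if (is.null(grid))
    grid <- if (normalize) seq(0.05, 1, by = 0.05)
    else sort(unique(degs[[1L]]))
  per <- t(vapply(degs, function(d)
    vapply(grid, function(k) mean(d >= k), numeric(1)), numeric(length(grid))))
  structure(list(grid = grid, G = colMeans(per), per_islet = per,
                 n_islets = length(degs), normalized = normalize),
            class = "degree_distribution")
}

#' Fit candidate models to a cumulative degree distribution
#'
#' Fits three decay models to `G` over the grid points with `G > 0`, by
#' least squares in log-G space (all three are linear there):
#' a power law `G = A x^(-alpha)`, an exponential `G = A e^(-x/kappa)`, and
#' an exponentially truncated power law `G = A x^(-alpha) e^(-x/kappa)`,
#' the signature of broad-scale networks. Goodness of fit is the coefficient
#' of determination r^2 on the fitted (log) scale; the best model maximizes
#' r^2.
#'
#' @param dist a [cumulative_degree_distribution()] result.
#' @return A data frame of class `degree_fits` with one row per model:
#'   `model`, `A`, `alpha`, `kappa`, `r2`, `best`.
#' @export
fit_degree_models <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  ok <- dist$G > 0 & dist$grid > 0
  if (sum(ok) < 5L)
    stop("need at least 5 grid points with G > 0")
  x <- dist$grid[ok]
  y <- log(dist$G[ok])
  fit1 <- function(formula_x) {
    fit <- tryCatch(stats::lm.fit(formula_x, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(coef = fit$coefficients,
         r2 = if (sst > 0) 1 - ssr / sst else as.numeric(ssr == 0))
  }
  pl <- fit1(cbind(1, log(x)))
  ex <- fit1(cbind(1, x))
  tp <- fit1(cbind(1, log(x), x))
  row <- function(model, f, a_idx = NA, k_idx = NA) {
    if (is.null(f))
      return(data.frame(model = model, A = NA_real_, alpha = NA_real_,
                        kappa = NA_real_, r2 = NA_real_))
    data.frame(model = model, A = exp(f$coef[1L]),
               alpha = if (is.na(a_idx)) NA_real_ else -f$coef[a_idx],
               kappa = if (is.na(k_idx)) NA_real_ else -1 / f$coef[k_idx],
               r2 = f$r2)
  }
  out <- rbind(row("power_law", pl, a_idx = 2L),
               row("exponential", ex, k_idx = 2L),
               row("truncated_power_law", tp, a_idx = 2L, k_idx = 3L))
  out$best <- FALSE
  if (any(is.finite(out$r2)))
    out$best[which.max(out$r2)] <- TRUE
  rownames(out) <- NULL
  class(out) <- c("degree_fits", "data.frame")
  out
}
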