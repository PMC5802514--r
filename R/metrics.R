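#' Global weighted graph metrics
#'
#' Computes the segregation and integration measures used in structural
#' covariance analysis, with the weighted definitions standard in brain
#' connectivity work:
#'
#' * transitivity: Onnela-style, `sum_i sum_{j!=h} (w'_ij w'_ih w'_jh)^(1/3) /
#'   sum_i k_i (k_i - 1)` with weights normalized by the maximum weight;
#' * clustering coefficient: mean over nodes of the nodal Onnela coefficient
#'   (nodes with degree < 2 contribute 0);
#' * modularity: best Newman Q over `modularity_runs` restarts of Louvain
#'   community detection on the weights, under a deterministic seed stream
#'   (Q over the first k restarts is non-decreasing in k);
#' * path length: mean shortest-path distance over connected ordered pairs,
#'   with edge lengths 1/weight (disconnected pairs excluded);
#' * n_components: number of connected components.
#'
#' @param g A [threshold_by_density()] network.
#' @param modularity_runs Louvain restarts (default 100).
#' @param seed Integer seed for the Louvain restart stream.
#' @return List of class `global_metrics`: `transitivity`,
#'   `clustering_coefficient`, `modularity`, `path_length`, `n_components`.
#' @export
global_metrics <- function(g, modularity_runs = 100L, seed = 1L) {
  W <- as_weight_matrix(g)
  if (all(W == 0)) stop("empty graph: no edges")
  tm <- cpp_triangle_metrics(W)
  lv <- cpp_louvain(W, as.integer(modularity_runs), as.numeric(seed))
  D <- cpp_apsp(W)
  off <- D[upper.tri(D)]
  finite <- is.finite(off)
  pl <- if (any(finite)) mean(off[finite]) else NA_real_
  comp <- components_from_distances(D)
  structure(list(transitivity = tm$transitivity,
                 clustering_coefficient = tm$clustering_coefficient,
                 modularity = lv$modularity,
                 path_length = pl,
                 n_components = comp),
            class = "global_metrics")
}

components_from_distances <- function(D) {
  n <- nrow(D)
  seen <- logical(n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      ncomp <- ncomp + 1L
      seen[is.finite(D[i, ])] <- TRUE
      seen[i] <- TRUE
    }
  }
  ncomp
}

#' Nodal hubness metrics
#'
#' Per-node centrality measures on a thresholded covariance network: degree
#' (incident edge count on the binarized graph), strength (sum of incident
#' weights), betweenness (fraction of shortest 1/w-distance paths through the
#' node, endpoints excluded, normalized by `(n-1)(n-2)/2`), closeness (the
#' reachable-scaled Wasserman-Faust form, `((r-1)/sum d) * (r-1)/(n-1)` with
#' `r` the size of the node's component), and `degree_rank` (1 = highest
#' degree; ties share the minimum rank).
#'
#' @param g A [threshold_by_density()] network.
#' @return Data frame of class `nodal_metrics` with one row per ROI.
#' @export
nodal_metrics <- function(g) {
  W <- as_weight_matrix(g)
  n <- nrow(W)
  degree <- as.integer(colSums(W > 0))
  strength <- colSums(W)
  btw <- as.numeric(cpp_betweenness(W))
  D <- cpp_apsp(W)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    fin <- is.finite(d)
    r <- sum(fin) + 1L
    if (r <= 1L) return(0)
    ((r - 1) / sum(d[fin])) * ((r - 1) / (n - 1))
  }, numeric(1))
  out <- data.frame(
    roi = colnames(W) %||% sprintf("roi_%03d", seq_len(n)),
    degree = degree, strength = strength,
    betweenness = btw, closeness = clo,
    degree_rank = as.integer(rank(-degree, ties.method = "min")),
    stringsAsFactors = FALSE)
  class(out) <- c("nodal_metrics", "data.frame")
  out
}

as_weight_matrix <- function(g) {
  if (inherits(g, "covariance_network")) {
    W <- g$weights
  } else if (is.matrix(g)) {
    W <- g
  } else stop("expected a covariance_network or a weight matrix")
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  if (!isSymmetric(unname(W))) stop("weight matrix must be symmetric")
  W
}
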