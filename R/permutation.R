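#' Permutation inference on group differences in network metrics
#'
#' Tests stress-minus-control differences in one or several network metrics
#' across a density grid by group-label permutation. For every permutation
#' (group labels shuffled over the pooled subjects, preserving group sizes)
#' both group networks are rebuilt from scratch — correlation, negative-edge
#' removal, density thresholding — at every grid density, and the metric
#' difference is recorded. One shared permutation schedule is used across all
#' densities and metrics within a run, so the per-density nulls and the AUC
#' null are mutually coherent and the correlation matrices are computed once
#' per permutation. Empirical two-tailed p-values use the +1-corrected
#' formula `(#\{|null| >= |observed|\} + 1) / (n_perm + 1)`, and aggregate
#' significance across the grid is assessed on the trapezoid area under the
#' signed difference curve (AUC) against the null AUCs from the same
#' schedule.
#'
#' @param v A [volume_table()].
#' @param grid A [density_grid()].
#' @param metrics Character vector from `transitivity`,
#'   `clustering_coefficient`, `modularity`, `path_length` (global) and
#'   `degree`, `strength`, `betweenness`, `closeness` (nodal; require
#'   `node`).
#' @param n_perm Number of permutations (study default 10,000).
#' @param seed Integer seed; the result is byte-reproducible under it.
#' @param node ROI label for nodal metrics.
#' @param roi_exclude ROI labels dropped before network construction.
#' @param modularity_runs Louvain restarts per network during permutation
#'   (default 5; raise for final single-network estimates).
#' @return For [permute_metrics()], a named list of class `permutation_set`
#'   (one `permutation_result` per metric). For [permute_metric()], a single
#'   `permutation_result` with fields `metric_name`, `node`, `densities`,
#'   `observed_diff`, `null_diffs`, `p_per_density`, `auc_observed`,
#'   `auc_p`, `n_perm`.
#' @export
permute_metrics <- function(v, grid = density_grid(), metrics = "modularity",
                            n_perm = 10000L, seed = 1L, node = NULL,
                            roi_exclude = character(),
                            modularity_runs = 5L) {
  stopifnot(inherits(v, "volume_table"))
  global_m <- c("transitivity", "clustering_coefficient", "modularity",
                "path_length")
  nodal_m <- c("degree", "strength", "betweenness", "closeness")
  bad <- setdiff(metrics, c(global_m, nodal_m))
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  keep <- setdiff(v$roi_labels, roi_exclude)
  if (length(keep) < 3L) stop("need >= 3 ROIs after exclusion")
  X <- v$volumes[, keep, drop = FALSE]
  node_idx <- NULL
  if (any(metrics %in% nodal_m)) {
    if (is.null(node)) stop("nodal metric requested without a node argument")
    node_idx <- match(node, keep)
    if (is.na(node_idx)) stop("unknown node label: ", node)
  }
  n <- nrow(X); nr <- ncol(X)
  n_stress <- sum(v$group == "stress")
  if (n_stress < 4L || n - n_stress < 4L) stop("both groups need >= 4 subjects")
  densities <- as.numeric(grid)
  nd <- length(densities)
  M <- nr * (nr - 1) / 2
  ks <- floor(densities * M + 0.5)
  if (ks[1L] < 1L) stop("grid lower bound yields an empty graph")

  seeds <- local_seed_split(seed, 2L)
  perm_idx <- with_seed(seeds[1L],
                        replicate(n_perm, sample.int(n, n_stress)))
  lseed <- with_seed(seeds[2L],
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       (n_perm + 1L) * 2L * nd),
                            nrow = n_perm + 1L))
  nm <- length(metrics)
  codes <- match(metrics, c("transitivity", "clustering_coefficient",
                            "modularity", "path_length", "degree",
                            "strength", "betweenness", "closeness"))
  assignments <- cbind(which(v$group == "stress"),
                       matrix(perm_idx, nrow = n_stress))
  diffs <- cpp_perm_engine(X, assignments, as.integer(ks),
                           as.integer(codes),
                           as.integer(node_idx %||% 1L),
                           as.integer(modularity_runs),
                           lseed * 1.0)
  observed <- diffs[1L, ]
  nulls <- diffs[-1L, , drop = FALSE]

  trapz <- function(y) {
    if (nd == 1L) return(y)
    sum(diff(densities) * (y[-nd] + y[-1L]) / 2)
  }
  results <- vector("list", nm)
  names(results) <- ifelse(metrics %in% nodal_m,
                           paste0(metrics, "[", node, "]"), metrics)
  for (mi in seq_len(nm)) {
    cols <- (mi - 1L) * nd + seq_len(nd)
    obs <- observed[cols]
    nul <- nulls[, cols, drop = FALSE]
    p_d <- vapply(seq_len(nd), function(di) {
      (sum(abs(nul[, di]) >= abs(obs[di])) + 1) / (n_perm + 1)
    }, numeric(1))
    auc_obs <- trapz(obs)
    auc_null <- apply(nul, 1L, trapz)
    auc_p <- (sum(abs(auc_null) >= abs(auc_obs)) + 1) / (n_perm + 1)
    results[[mi]] <- structure(
      list(metric_name = metrics[mi],
           node = if (metrics[mi] %in% nodal_m) node else NULL,
           densities = densities, observed_diff = obs, null_diffs = nul,
           p_per_density = p_d, auc_observed = auc_obs, auc_p = auc_p,
           n_perm = as.integer(n_perm)),
      class = "permutation_result")
  }
  structure(results, class = "permutation_set")
}

#' @rdname permute_metrics
#' @param metric A single metric name.
#' @export
permute_metric <- function(v, grid = density_grid(), metric = "modularity",
                           n_perm = 10000L, seed = 1L, node = NULL,
                           roi_exclude = character(), modularity_runs = 5L) {
  permute_metrics(v, grid, metric, n_perm, seed, node, roi_exclude,
                  modularity_runs)[[1L]]
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", x$metric_name,
      if (!is.null(x$node)) paste0("at node '", x$node, "'") else "",
      "\n  densities:", length(x$densities),
      "| n_perm:", x$n_perm,
      "| min p:", format.pval(min(x$p_per_density), digits = 3),
      "| AUC p:", format.pval(x$auc_p, digits = 3), "\n")
  invisible(x)
}

#' @export
print.permutation_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Flag nodes significant over consecutive densities
#'
#' Applies the a-priori nodal significance criterion: a node-metric result is
#' flagged when its per-density permutation p-value falls below `alpha` at
#' `min_consecutive` or more consecutive densities of the grid.
#'
#' @param results A `permutation_result`, or a (possibly named) list of them
#'   sharing a common density grid.
#' @param alpha Significance level (default 0.05).
#' @param min_consecutive Required run length of significant densities
#'   (default 2).
#' @return Named logical vector, one flag per result.
#' @export
node_significance_profile <- function(results, alpha = 0.05,
                                      min_consecutive = 2L) {
  if (inherits(results, "permutation_result")) results <- list(results)
  dens <- lapply(results, `[[`, "densities")
  if (length(results) > 1L &&
      !all(vapply(dens[-1L], identical, logical(1), dens[[1L]])))
    stop("all results must share one density grid")
  flags <- vapply(results, function(r) {
    sig <- r$p_per_density < alpha
    runs <- rle(sig)
    any(runs$values & runs$lengths >= min_consecutive)
  }, logical(1))
  nm <- names(results)
  if (!is.null(nm)) names(flags) <- nm
  flags
}
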