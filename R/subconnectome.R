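#' Compare a focal node's covariance neighborhood across groups
#'
#' Characterizes how a node's direct structural-covariance neighborhood
#' differs between the control and stress networks at a common density:
#' its degree rank within each group's network (1 = highest degree, ties
#' share the minimum rank) and the partition of its neighbors into those
#' common to both groups, those unique to the stress network, and those
#' unique to the control network.
#'
#' @param gc,gs Control and stress [threshold_by_density()] networks sharing
#'   ROI labels and density.
#' @param node Focal ROI label.
#' @return List of class `neighborhood_comparison` with fields `node`,
#'   `density`, `rank_control`, `rank_stress`, `common_neighbors`,
#'   `stress_only`, `control_only`.
#' @export
compare_neighborhood <- function(gc, gs, node) {
  stopifnot(inherits(gc, "covariance_network"),
            inherits(gs, "covariance_network"))
  if (!identical(gc$roi_labels, gs$roi_labels))
    stop("networks must share ROI labels")
  if (!isTRUE(all.equal(gc$density, gs$density)))
    stop("networks must share the same density")
  idx <- match(node, gc$roi_labels)
  if (is.na(idx)) stop("unknown node label: ", node)
  nb <- function(g) g$roi_labels[g$weights[, idx] > 0]
  nbc <- nb(gc); nbs <- nb(gs)
  rank_of <- function(g) {
    deg <- colSums(g$weights > 0)
    as.integer(rank(-deg, ties.method = "min")[idx])
  }
  structure(list(node = node, density = gc$density,
                 rank_control = rank_of(gc), rank_stress = rank_of(gs),
                 common_neighbors = sort(intersect(nbc, nbs)),
                 stress_only = sort(setdiff(nbs, nbc)),
                 control_only = sort(setdiff(nbc, nbs))),
            class = "neighborhood_comparison")
}

#' @export
print.neighborhood_comparison <- function(x, ...) {
  cat("neighborhood_comparison for '", x$node, "' at density ",
      format(x$density), ":\n", sep = "")
  cat("  degree rank: control ", x$rank_control, " -> stress ",
      x$rank_stress, "\n", sep = "")
  cat("  neighbors: ", length(x$common_neighbors), " common, ",
      length(x$stress_only), " stress-only, ",
      length(x$control_only), " control-only\n", sep = "")
  invisible(x)
}

#' Lowest density with a significant nodal group difference
#'
#' The default reporting density for subconnectome views: the smallest grid
#' density at which any of the supplied nodal permutation results falls
#' below `alpha`. Returns `NA` if none does.
#'
#' @param results A `permutation_result` or list of them on one grid.
#' @param alpha Significance level.
#' @return A density (numeric scalar) or `NA`.
#' @export
default_report_density <- function(results, alpha = 0.05) {
  if (inherits(results, "permutation_result")) results <- list(results)
  dens <- results[[1L]]$densities
  sig <- Reduce(`|`, lapply(results, function(r) r$p_per_density < alpha))
  if (!any(sig)) return(NA_real_)
  dens[which(sig)[1L]]
}
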