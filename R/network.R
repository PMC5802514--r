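#' Group-level structural covariance matrix
#'
#' Pearson correlation of every ROI pair across the subjects of one group.
#' Structural covariance is a group-level construct: each group yields one
#' ROI x ROI correlation matrix, not one network per subject.
#'
#' @param v A [volume_table()].
#' @param group `"control"` or `"stress"`.
#' @param roi_exclude ROI labels to drop before correlating (e.g. ventricles).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
build_covariance <- function(v, group = c("control", "stress"),
                             roi_exclude = character()) {
  stopifnot(inherits(v, "volume_table"))
  group <- match.arg(group)
  rows <- v$group == group
  if (sum(rows) < 4L) stop("group '", group, "' needs >= 4 subjects")
  miss <- setdiff(roi_exclude, v$roi_labels)
  if (length(miss)) stop("roi_exclude not in table: ",
                         paste(miss, collapse = ", "))
  keep <- setdiff(v$roi_labels, roi_exclude)
  x <- v$volumes[rows, keep, drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero within-group variance for ROI(s): ",
         paste(keep[sds == 0], collapse = ", "))
  stats::cor(x)
}

#' Discard negative correlations
#'
#' Sets negative entries (and the diagonal) to zero, leaving positive
#' correlations untouched. Discarded entries become structural zeros, i.e.
#' absent edges, not zero-weight edges.
#'
#' @param c Symmetric correlation matrix.
#' @return Nonnegative matrix with zero diagonal.
#' @export
discard_negatives <- function(c) {
  if (!isSymmetric(unname(c))) stop("input matrix must be symmetric")
  c[c < 0] <- 0
  diag(c) <- 0
  if (all(c == 0))
    warning("all correlations nonpositive: resulting graph is empty")
  c
}

#' Threshold a covariance matrix at a target edge density
#'
#' Keeps exactly `k = round(d * M)` largest-weight edges (half-up rounding;
#' `M = n(n-1)/2` possible edges), zeroing the rest while retaining the
#' surviving correlation values as edge weights. Ties at the cutoff are
#' broken deterministically by (-weight, i, j) lexicographic order, which
#' also makes edge sets nested across increasing densities.
#'
#' @param c Nonnegative symmetric matrix with zero diagonal (from
#'   [discard_negatives()]).
#' @param density Target edge density in (0, 1).
#' @param group Group label stored on the network.
#' @return An object of class `covariance_network` with fields `group`,
#'   `roi_labels`, `weights`, `density`, `retained_edges`.
#' @export
threshold_by_density <- function(c, density, group = "control") {
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  n <- nrow(c)
  labels <- colnames(c) %||% sprintf("roi_%03d", seq_len(n))
  M <- n * (n - 1) / 2
  k <- floor(density * M + 0.5)  # half-up rounding
  ut <- upper.tri(c)
  w <- c[ut]
  if (sum(w > 0) < k)
    stop(sprintf(
      "only %d positive correlations available; maximum achievable density is %.4f",
      sum(w > 0), sum(w > 0) / M))
  ij <- which(ut, arr.ind = TRUE)  # row < col, ordered by (j, i)
  ord <- order(-w, ij[, 1L], ij[, 2L])
  keep <- ord[seq_len(k)]
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  W[ij[keep, , drop = FALSE]] <- w[keep]
  W <- W + t(W)
  structure(list(group = group, roi_labels = labels, weights = W,
                 density = density, retained_edges = as.integer(k)),
            class = "covariance_network")
}

#' @export
print.covariance_network <- function(x, ...) {
  cat("covariance_network (", x$group, "): ", length(x$roi_labels),
      " ROIs, ", x$retained_edges, " edges at density ",
      format(x$density), "\n", sep = "")
  invisible(x)
}

#' Density grid for network thresholding
#'
#' @param lo,hi,step Bounds and increment of the density grid; defaults give
#'   the standard 21-point grid from 10% to 30% of the strongest connections
#'   in 1% steps.
#' @return Numeric vector of class `density_grid`, strictly increasing in
#'   (0, 1).
#' @export
density_grid <- function(lo = 0.10, hi = 0.30, step = 0.01) {
  if (step <= 0) stop("step must be positive")
  if (lo <= 0 || hi >= 1 || lo > hi)
    stop("need 0 < lo <= hi < 1")
  d <- seq(lo, hi, by = step)
  structure(round(d, 10), class = "density_grid")
}
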