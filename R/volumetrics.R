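#' Normalize regional volumes by total brain volume
#'
#' With `mode = "divide_by_total"` every ROI volume is divided by the
#' subject's `total_brain_volume` covariate (mm^3), yielding unitless volume
#' fractions; `mode = "none"` returns the table unchanged. A table can be
#' normalized only once: after normalization the stored totals no longer
#' match the volume scale, so a second call errors.
#'
#' @param v A [volume_table()].
#' @param mode `"none"` or `"divide_by_total"`.
#' @return A [volume_table()] (with `normalized = TRUE` when divided).
#' @export
normalize_volumes <- function(v, mode = c("none", "divide_by_total")) {
  stopifnot(inherits(v, "volume_table"))
  mode <- match.arg(mode)
  if (mode == "none") return(v)
  if (isTRUE(v$normalized))
    stop("volume table is already normalized; totals no longer apply")
  tot <- v$covariates$total_brain_volume
  if (is.null(tot)) stop("total_brain_volume covariate is required")
  bad <- which(!is.finite(tot) | tot <= 0)
  if (length(bad))
    stop("missing or nonpositive total_brain_volume for subject(s): ",
         paste(v$subject_id[bad], collapse = ", "))
  v$volumes <- v$volumes / tot
  v$normalized <- TRUE
  v
}

#' Per-ROI group comparison by general linear model with FDR control
#'
#' Fits `volume ~ group (+ covariates)` for every ROI, records the group
#' (stress - control) coefficient, its t-based p-value and the partial
#' variance it explains, adjusts p-values across ROIs by Benjamini-Hochberg,
#' and ranks ROIs by association strength |t| (1 = strongest).
#'
#' @param v A [volume_table()].
#' @param covariates Character vector of covariate column names to adjust for
#'   (default none).
#' @return A data frame of class `roi_stats_table` with columns `roi`,
#'   `effect_size`, `t`, `variance_explained`, `p`, `q`, `rank`.
#' @export
roi_group_glm <- function(v, covariates = character()) {
  stopifnot(inherits(v, "volume_table"))
  if (min(table(v$group)) < 3L) stop("both groups need >= 3 subjects")
  X <- stats::model.matrix(
    ~ group, data = data.frame(group = v$group))
  if (length(covariates)) {
    miss <- setdiff(covariates, names(v$covariates))
    if (length(miss)) stop("covariate(s) not found: ",
                           paste(miss, collapse = ", "))
    Z <- as.matrix(v$covariates[covariates])
    if (anyNA(Z)) stop("covariates contain missing values")
    X <- cbind(X, Z)
  }
  if (qr(X)$rank < ncol(X)) stop("collinear covariates in the design matrix")
  gcol <- 2L  # groupstress coefficient
  n <- nrow(X); df <- n - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)
  coefs <- H %*% v$volumes                       # p_design x n_roi
  resid <- v$volumes - X %*% coefs
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[gcol, gcol])
  tval <- coefs[gcol, ] / se
  tval[se == 0] <- 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  ve <- tval^2 / (tval^2 + df)
  out <- data.frame(roi = v$roi_labels,
                    effect_size = as.numeric(coefs[gcol, ]),
                    t = as.numeric(tval),
                    variance_explained = as.numeric(ve),
                    p = as.numeric(p), q = as.numeric(q),
                    rank = as.integer(rank(-abs(tval), ties.method = "first")),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_stats_table", "data.frame")
  out
}

#' Regress ROI volume on a behavioral score
#'
#' Simple per-ROI linear regression of volume on the supplied per-subject
#' score (typically behavioral PC1), across all subjects of both groups
#' pooled; returns r-squared and the slope p-value per ROI.
#'
#' @param v A [volume_table()].
#' @param scores Numeric per-subject score, aligned with (or named by)
#'   `v$subject_id`.
#' @return Data frame with columns `roi`, `r_squared`, `p`.
#' @export
volume_behavior_regression <- function(v, scores) {
  stopifnot(inherits(v, "volume_table"))
  if (!is.null(names(scores))) {
    if (!all(v$subject_id %in% names(scores)))
      stop("scores missing for some subjects")
    scores <- scores[v$subject_id]
  }
  if (length(scores) != length(v$subject_id))
    stop("one score per subject required")
  if (stats::sd(scores) == 0) stop("behavioral score is constant")
  n <- length(scores)
  xc <- scores - mean(scores)
  sxx <- sum(xc^2)
  yc <- sweep(v$volumes, 2L, colMeans(v$volumes), "-")
  beta <- colSums(xc * yc) / sxx
  ssr <- beta^2 * sxx
  sst <- colSums(yc^2)
  r2 <- ifelse(sst > 0, ssr / sst, 0)
  df <- n - 2L
  fstat <- ifelse(r2 < 1, r2 / (1 - r2) * df, Inf)
  p <- stats::pf(fstat, 1L, df, lower.tail = FALSE)
  data.frame(roi = v$roi_labels, r_squared = as.numeric(r2),
             p = as.numeric(p), stringsAsFactors = FALSE)
}

#' Enrichment of a-priori regions among top-ranked effects
#'
#' Tests whether a pre-selected ROI set is overrepresented among the `top_k`
#' strongest group associations, via a 2x2 chi-square test (membership in the
#' a-priori set x membership in the top k) without continuity correction.
#'
#' @param stats A `roi_stats_table` from [roi_group_glm()].
#' @param apriori_set Character vector of a-priori ROI labels.
#' @param top_k Number of top-ranked ROIs to consider.
#' @return A list with `chi2`, `p`, and the 2x2 `table`.
#' @export
apriori_enrichment <- function(stats, apriori_set, top_k = 20L) {
  stopifnot(inherits(stats, "roi_stats_table"))
  n_roi <- nrow(stats)
  if (length(apriori_set) == 0L) stop("a-priori set is empty (degenerate margin)")
  if (!all(apriori_set %in% stats$roi))
    stop("a-priori ROI(s) not in the stats table: ",
         paste(setdiff(apriori_set, stats$roi), collapse = ", "))
  if (top_k > n_roi) stop("top_k exceeds the number of ROIs")
  if (top_k == n_roi || length(apriori_set) == n_roi)
    stop("degenerate margin: top_k (or a-priori set) covers every ROI")
  in_top <- stats$rank <= top_k
  in_apriori <- stats$roi %in% apriori_set
  tab <- table(factor(in_apriori, c(TRUE, FALSE)),
               factor(in_top, c(TRUE, FALSE)),
               dnn = c("apriori", "top"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}

#' Two-sample test on total brain volume
#'
#' Student t-test (equal variances) of per-subject total brain volume
#' (the `total_brain_volume` covariate if present, else the sum of ROI
#' volumes) between stress and control groups.
#'
#' @param v A [volume_table()].
#' @return The two-sided p-value.
#' @export
total_brain_volume_test <- function(v) {
  stopifnot(inherits(v, "volume_table"))
  if (min(table(v$group)) < 2L) stop("both groups need >= 2 subjects")
  tot <- v$covariates$total_brain_volume %||% rowSums(v$volumes)
  stats::t.test(tot[v$group == "stress"], tot[v$group == "control"],
                var.equal = TRUE)$p.value
}
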