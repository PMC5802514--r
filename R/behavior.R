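#' Integrate a behavioral battery into one emotionality score
#'
#' Implements the z-score integration convention for multi-test behavioral
#' batteries: every variable is z-scored against the CONTROL group's mean and
#' SD, variables whose direction is `lower_is_more_emotional` are
#' sign-flipped so larger always means more emotional, z-scores are averaged
#' within each test, and the per-test means are averaged across tests into a
#' single per-subject emotionality z. Scoring against the control group makes
#' the control mean exactly zero and expresses stress effects in control-SD
#' units. The group difference is assessed by a two-sample t-test.
#'
#' @param b A [behavior_table()].
#' @return A list of class `emotionality_result` with `per_subject_z`
#'   (named numeric), `per_test_z` (subjects x tests matrix), and
#'   `group_difference_p`.
#' @export
emotionality_zscore <- function(b) {
  stopifnot(inherits(b, "behavior_table"))
  ctrl <- b$group == "control"
  if (!any(ctrl)) stop("control group is empty")
  if (anyNA(b$values)) stop("behavior table contains missing values")
  mu <- colMeans(b$values[ctrl, , drop = FALSE])
  sdv <- apply(b$values[ctrl, , drop = FALSE], 2L, stats::sd)
  bad <- which(!is.finite(sdv) | sdv == 0)
  if (length(bad))
    stop("zero control-group SD for variable(s): ",
         paste(colnames(b$values)[bad], collapse = ", "))
  z <- sweep(sweep(b$values, 2L, mu, "-"), 2L, sdv, "/")
  flip <- b$var_meta$direction == "lower_is_more_emotional"
  z[, flip] <- -z[, flip, drop = FALSE]
  tests <- unique(b$var_meta$test)
  per_test <- vapply(tests, function(tt) {
    rowMeans(z[, b$var_meta$test == tt, drop = FALSE])
  }, numeric(nrow(z)))
  per_test <- matrix(per_test, nrow = nrow(z),
                     dimnames = list(b$subject_id, tests))
  per_subject <- rowMeans(per_test)
  p <- if (sum(ctrl) >= 2 && sum(!ctrl) >= 2)
    stats::t.test(per_subject[!ctrl], per_subject[ctrl])$p.value else NA_real_
  structure(list(per_subject_z = per_subject, per_test_z = per_test,
                 group_difference_p = p),
            class = "emotionality_result")
}

#' @export
print.emotionality_result <- function(x, ...) {
  cat("emotionality_result:", length(x$per_subject_z), "subjects,",
      ncol(x$per_test_z), "tests; group difference p =",
      format.pval(x$group_difference_p, digits = 3), "\n")
  invisible(x)
}

#' Principal component analysis of the behavioral battery
#'
#' PCA of the standardized battery across ALL subjects pooled (both groups as
#' one sample). Each component's sign is oriented so the stress-group mean
#' score is at least the control-group mean, making the first component read
#' directly as a behavioral emotionality axis when a stress effect exists.
#' Explained-variance fractions are reported relative to the total variance
#' over all components (so they sum to 1 when every component is retained).
#'
#' @param b A [behavior_table()].
#' @param n_components Number of components to retain.
#' @return A list of class `pca_result` with `scores` (subjects x
#'   components), `loadings` (variables x components), and
#'   `explained_variance_fraction`.
#' @export
behavioral_pca <- function(b, n_components = 3L) {
  stopifnot(inherits(b, "behavior_table"))
  x <- b$values
  n <- nrow(x); p <- ncol(x)
  if (n < 2L || p < 2L) stop("need >= 2 subjects and >= 2 variables")
  if (anyNA(x)) stop("behavior table contains missing values")
  if (n_components > min(n - 1L, p))
    stop("n_components must be <= min(subjects - 1, variables) = ",
         min(n - 1L, p))
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  sv <- svd(xs)
  ev <- sv$d^2
  evf <- ev / sum(ev)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # orient: stress mean score >= control mean score on every component
  stress <- b$group == "stress"
  if (any(stress) && any(!stress)) {
    for (j in seq_len(k)) {
      if (mean(scores[stress, j]) < mean(scores[!stress, j])) {
        scores[, j] <- -scores[, j]
        loadings[, j] <- -loadings[, j]
      }
    }
  }
  dimnames(scores) <- list(b$subject_id, sprintf("PC%d", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf[seq_len(k)],
                 explained_variance_fraction_all = evf),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", ncol(x$scores), "components;",
      "variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}
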