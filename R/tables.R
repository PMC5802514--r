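#' Subject-by-ROI volume table
#'
#' The substrate of both the volumetric and covariance-network analyses: one
#' row per subject, a group label (`control`/`stress`), a numeric covariate
#' frame (e.g. `sex`, `total_brain_volume` in mm^3), and a strictly positive
#' subjects x ROIs volume matrix with unique ROI labels.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Factor or character with levels `control`, `stress`.
#' @param volumes Numeric matrix, subjects x ROIs, column names = ROI labels.
#' @param covariates Data frame of per-subject numeric covariates (may be
#'   empty).
#' @return An object of class `volume_table`.
#' @export
volume_table <- function(subject_id, group, volumes,
                         covariates = data.frame(row.names = subject_id)) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject IDs")
  group <- factor(as.character(group), levels = c("control", "stress"))
  if (anyNA(group)) stop("group labels must be 'control' or 'stress'")
  volumes <- as.matrix(volumes)
  if (!is.numeric(volumes)) stop("volumes must be numeric")
  if (nrow(volumes) != length(subject_id))
    stop("one volume row per subject required")
  if (is.null(colnames(volumes))) stop("volumes must carry ROI column names")
  if (anyDuplicated(colnames(volumes)))
    stop("duplicate ROI labels: ",
         paste(unique(colnames(volumes)[duplicated(colnames(volumes))]),
               collapse = ", "))
  if (anyNA(volumes)) stop("volumes contain missing values")
  if (any(volumes <= 0)) stop("all volumes must be strictly positive")
  rownames(volumes) <- subject_id
  structure(list(subject_id = subject_id, group = group, volumes = volumes,
                 roi_labels = colnames(volumes), covariates = covariates,
                 normalized = FALSE),
            class = "volume_table")
}

#' @export
print.volume_table <- function(x, ...) {
  cat("volume_table:", length(x$subject_id), "subjects (",
      sum(x$group == "control"), "control /", sum(x$group == "stress"),
      "stress ),", ncol(x$volumes), "ROIs",
      if (isTRUE(x$normalized)) "(normalized)" else "", "\n")
  invisible(x)
}

#' Subject-by-variable behavior table
#'
#' Holds a multi-test behavioral battery: a subjects x variables numeric
#' matrix plus per-variable metadata assigning each variable to one test and
#' a direction (`higher_is_more_emotional` or `lower_is_more_emotional`)
#' stating which way the variable points on the emotionality axis.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Factor/character with levels `control`, `stress`.
#' @param values Numeric matrix, subjects x variables, with column names.
#' @param var_meta Data frame with columns `variable`, `test`, `direction`.
#' @return An object of class `behavior_table`.
#' @export
behavior_table <- function(subject_id, group, values, var_meta) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject IDs")
  group <- factor(as.character(group), levels = c("control", "stress"))
  if (anyNA(group)) stop("group labels must be 'control' or 'stress'")
  values <- as.matrix(values)
  if (nrow(values) != length(subject_id))
    stop("one behavior row per subject required")
  if (is.null(colnames(values))) stop("values must carry variable names")
  stopifnot(all(c("variable", "test", "direction") %in% names(var_meta)))
  if (!identical(sort(var_meta$variable), sort(colnames(values))))
    stop("var_meta must describe exactly the variables in `values`")
  if (anyDuplicated(var_meta$variable))
    stop("every variable must be assigned to exactly one test")
  ok_dir <- c("higher_is_more_emotional", "lower_is_more_emotional")
  if (!all(var_meta$direction %in% ok_dir))
    stop("direction must be one of: ", paste(ok_dir, collapse = ", "))
  var_meta <- var_meta[match(colnames(values), var_meta$variable), , drop = FALSE]
  rownames(var_meta) <- NULL
  rownames(values) <- subject_id
  structure(list(subject_id = subject_id, group = group, values = values,
                 var_meta = var_meta),
            class = "behavior_table")
}

#' @export
print.behavior_table <- function(x, ...) {
  cat("behavior_table:", length(x$subject_id), "subjects,",
      ncol(x$values), "variables over",
      length(unique(x$var_meta$test)), "tests\n")
  invisible(x)
}
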