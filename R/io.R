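#' Read and write volume tables
#'
#' Tables interchange as tidy CSV (one row per subject: `subject_id`,
#' `group`, covariates, then one column per ROI) with an optional JSON
#' sidecar holding `roi_labels`, covariate names, the `normalized` flag and,
#' for synthetic cohorts, the full generating specification. Without a
#' sidecar, the columns `sex` and `total_brain_volume` are taken as
#' covariates and every other numeric column as an ROI.
#'
#' @param v A [volume_table()].
#' @param path CSV file path.
#' @param meta_path Sidecar JSON path (default: `path` with `.json`
#'   extension). Set `NULL` to skip when writing.
#' @param spec Optional [cohort_spec()] recorded in the sidecar.
#' @return `read_volume_table()` returns a [volume_table()];
#'   `write_volume_table()` returns `path` invisibly.
#' @export
write_volume_table <- function(v, path, meta_path = default_meta_path(path),
                               spec = NULL) {
  stopifnot(inherits(v, "volume_table"))
  df <- data.frame(subject_id = v$subject_id, group = as.character(v$group),
                   v$covariates, v$volumes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(table = "volume_table", roi_labels = v$roi_labels,
                 covariates = names(v$covariates),
                 normalized = isTRUE(v$normalized))
    if (!is.null(spec)) meta$cohort_spec <- unclass(spec)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume_table
#' @export
read_volume_table <- function(path, meta_path = default_meta_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  if (anyDuplicated(names(df)))
    stop("duplicated column(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  meta <- if (!is.null(meta_path) && file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  if (!is.null(meta)) {
    roi_cols <- meta$roi_labels
    cov_cols <- meta$covariates
    miss <- setdiff(roi_cols, names(df))
    if (length(miss)) stop("ROI column(s) missing from CSV: ",
                           paste(miss, collapse = ", "))
  } else {
    cov_cols <- intersect(c("sex", "total_brain_volume"), names(df))
    roi_cols <- setdiff(names(df), c("subject_id", "group", cov_cols))
  }
  vols <- df[roi_cols]
  nonnum <- names(vols)[!vapply(vols, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric volume column(s): ", paste(nonnum, collapse = ", "))
  vt <- volume_table(df$subject_id, df$group,
                     as.matrix(vols),
                     df[cov_cols])
  rownames(vt$covariates) <- vt$subject_id
  if (!is.null(meta) && isTRUE(meta$normalized)) vt$normalized <- TRUE
  vt
}

#' Read and write behavior tables
#'
#' CSV with columns `subject_id`, `group`, then one column per behavioral
#' variable; the JSON sidecar carries `var_meta` (variable, test,
#' direction). Without a sidecar each variable is treated as its own test
#' with direction `higher_is_more_emotional`.
#'
#' @param b A [behavior_table()].
#' @param path CSV file path.
#' @param meta_path Sidecar JSON path (default: `path` with `.json`).
#' @return `read_behavior_table()` returns a [behavior_table()];
#'   `write_behavior_table()` returns `path` invisibly.
#' @export
write_behavior_table <- function(b, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(b, "behavior_table"))
  df <- data.frame(subject_id = b$subject_id, group = as.character(b$group),
                   b$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(list(table = "behavior_table", var_meta = b$var_meta),
                         meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_behavior_table
#' @export
read_behavior_table <- function(path, meta_path = default_meta_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  var_cols <- setdiff(names(df), c("subject_id", "group"))
  meta <- if (!is.null(meta_path) && file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  var_meta <- if (!is.null(meta)) {
    as.data.frame(meta$var_meta, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = var_cols, test = var_cols,
               direction = "higher_is_more_emotional",
               stringsAsFactors = FALSE)
  }
  behavior_table(df$subject_id, df$group, as.matrix(df[var_cols]), var_meta)
}

default_meta_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Export a covariance network
#'
#' `write_edge_list()` writes the retained edges as CSV
#' (`i_label, j_label, weight`); `write_graphml()` exports the weighted
#' graph as GraphML for external visualization tools.
#'
#' @param g A [threshold_by_density()] network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "covariance_network"))
  el <- network_edges(g)
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

network_edges <- function(g) {
  W <- g$weights
  ij <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  data.frame(i_label = g$roi_labels[ij[, 1L]],
             j_label = g$roi_labels[ij[, 2L]],
             weight = W[ij], stringsAsFactors = FALSE)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "covariance_network"))
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                            weighted = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a two-group subconnectome GraphML bundle
#'
#' Writes one GraphML file per group with a per-edge `category` attribute in
#' `{common, stress_only, control_only}` marking whether each edge is shared
#' between the two networks or unique to one, for external rendering of
#' gained/lost covariance.
#'
#' @param gc,gs Control and stress networks on the same labels and density.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_subconnectome_bundle <- function(gc, gs, dir, prefix = "subconnectome") {
  stopifnot(inherits(gc, "covariance_network"),
            inherits(gs, "covariance_network"))
  if (!identical(gc$roi_labels, gs$roi_labels))
    stop("networks must share ROI labels")
  key <- function(el) paste(el$i_label, el$j_label, sep = "|")
  elc <- network_edges(gc); els <- network_edges(gs)
  common <- intersect(key(elc), key(els))
  paths <- character(2)
  for (gi in 1:2) {
    g <- list(gc, gs)[[gi]]
    el <- list(elc, els)[[gi]]
    cat_lab <- ifelse(key(el) %in% common, "common",
                      if (gi == 1L) "control_only" else "stress_only")
    ig <- igraph::graph_from_data_frame(
      cbind(el[c("i_label", "j_label")], weight = el$weight,
            category = cat_lab),
      directed = FALSE,
      vertices = data.frame(name = g$roi_labels))
    paths[gi] <- file.path(dir, sprintf("%s_%s.graphml", prefix, g$group))
    igraph::write_graph(ig, paths[gi], format = "graphml")
  }
  invisible(paths)
}
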