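#' Configure an end-to-end structural covariance analysis
#'
#' Builds a validated configuration for [run_pipeline()]. The
#' `species_preset` fills documented defaults: `"mouse"` uses raw volumes
#' (no normalization), no GLM covariates, and the 10-30% density grid;
#' `"human"` normalizes by total brain volume, adjusts for sex in the GLM,
#' and residualizes normalized volumes on sex before correlation. Any field
#' set explicitly overrides its preset value.
#'
#' @param volumes A [volume_table()] or path to a volume CSV.
#' @param behavior Optional [behavior_table()] or path.
#' @param species_preset `"mouse"`, `"human"`, or `"custom"`.
#' @param normalization `"none"` or `"divide_by_total"`.
#' @param covariates GLM covariate names.
#' @param residualize_covariates Covariates regressed out of volumes before
#'   network construction.
#' @param roi_exclude ROI labels excluded from networks (e.g. ventricles).
#' @param apriori A-priori ROI labels for the enrichment test (optional).
#' @param top_k Top-ranked set size for enrichment.
#' @param grid A [density_grid()].
#' @param metrics Global metrics to permutation-test.
#' @param focal_node ROI whose hubness and subconnectome are profiled.
#' @param nodal_metrics Nodal metrics tested for `focal_node`.
#' @param n_perm Permutations per test.
#' @param n_components Behavioral PCA components.
#' @param alpha,min_consecutive Nodal significance criterion (p < alpha at
#'   no fewer than `min_consecutive` consecutive densities).
#' @param modularity_runs Louvain restarts inside permutation tests.
#' @param seed Master seed.
#' @param out_dir Output directory for the result bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(volumes, behavior = NULL,
                            species_preset = c("custom", "mouse", "human"),
                            normalization = NULL, covariates = NULL,
                            residualize_covariates = NULL,
                            roi_exclude = character(), apriori = NULL,
                            top_k = 20L, grid = density_grid(),
                            metrics = c("modularity", "transitivity",
                                        "clustering_coefficient",
                                        "path_length"),
                            focal_node = "amygdala",
                            nodal_metrics = c("degree", "strength"),
                            n_perm = 1000L, n_components = 3L,
                            alpha = 0.05, min_consecutive = 2L,
                            modularity_runs = 5L, seed = 1L,
                            out_dir = tempfile("scovnet_run_")) {
  species_preset <- match.arg(species_preset)
  preset <- switch(species_preset,
    mouse = list(normalization = "none", covariates = character(),
                 residualize_covariates = character()),
    human = list(normalization = "divide_by_total", covariates = "sex",
                 residualize_covariates = "sex"),
    custom = list(normalization = "none", covariates = character(),
                  residualize_covariates = character()))
  cfg <- list(
    volumes = volumes, behavior = behavior, species_preset = species_preset,
    normalization = normalization %||% preset$normalization,
    covariates = covariates %||% preset$covariates,
    residualize_covariates = residualize_covariates %||%
      preset$residualize_covariates,
    roi_exclude = roi_exclude, apriori = apriori, top_k = as.integer(top_k),
    grid = grid, metrics = metrics, focal_node = focal_node,
    nodal_metrics = nodal_metrics, n_perm = as.integer(n_perm),
    n_components = as.integer(n_components), alpha = alpha,
    min_consecutive = as.integer(min_consecutive),
    modularity_runs = as.integer(modularity_runs),
    seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$volumes)) stop("config must name a volumes table or path")
  for (field in c("volumes", "behavior")) {
    x <- cfg[[field]]
    if (is.character(x) && !file.exists(x))
      stop(field, " file does not exist: ", x)
  }
  if (!cfg$normalization %in% c("none", "divide_by_total"))
    stop("normalization must be 'none' or 'divide_by_total'")
  if (cfg$n_perm < 1L) stop("n_perm must be >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Maps YAML keys one-to-one onto [pipeline_config()] arguments; `grid` may
#' be given as `{lo, hi, step}`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$grid))
    y$grid <- density_grid(y$grid$lo %||% 0.10, y$grid$hi %||% 0.30,
                           y$grid$step %||% 0.01)
  if (!is.null(y$roi_exclude)) y$roi_exclude <- as.character(y$roi_exclude)
  do.call(pipeline_config, y)
}

# regress covariates out of each ROI, preserving the ROI mean so volumes stay
# on their original (positive) scale
residualize_volumes <- function(v, covariates) {
  if (!length(covariates)) return(v)
  miss <- setdiff(covariates, names(v$covariates))
  if (length(miss)) stop("residualize covariate(s) not found: ",
                         paste(miss, collapse = ", "))
  Z <- cbind(1, as.matrix(v$covariates[covariates]))
  fit <- Z %*% qr.solve(crossprod(Z), crossprod(Z, v$volumes))
  res <- v$volumes - fit
  v$volumes <- sweep(res, 2L, colMeans(v$volumes), "+")
  if (any(v$volumes <= 0))
    stop("residualization produced nonpositive volumes")
  v
}

#' Run the full structural covariance pipeline
#'
#' Executes, in order: behavioral integration (emotionality z-score and PCA,
#' if a behavior table is configured), per-ROI volumetrics (normalization,
#' group GLM with FDR, total-volume test, volume-PC1 regression, a-priori
#' enrichment), per-group network construction over the density grid, global
#' and focal-node metrics, permutation inference with AUC aggregation, and
#' focal-node subconnectome comparison at the lowest density showing a nodal
#' group difference. All tables are written to `cfg$out_dir` as CSV plus a
#' machine-readable JSON manifest (configuration, seed, package version);
#' rerunning with the same configuration reproduces the bundle byte for
#' byte.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `pipeline_result` with the in-memory results and
#'   the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  say <- function(...) if (!quiet) message("[scovnet] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)

  v <- if (is.character(cfg$volumes)) read_volume_table(cfg$volumes) else cfg$volumes
  stopifnot(inherits(v, "volume_table"))
  b <- if (is.character(cfg$behavior)) read_behavior_table(cfg$behavior)
       else cfg$behavior

  # --- behavior ---
  pc1 <- NULL
  if (!is.null(b)) {
    say("behavior: emotionality z-score and PCA (",
        ncol(b$values), " variables)")
    res$emotionality <- emotionality_zscore(b)
    res$pca <- behavioral_pca(b, cfg$n_components)
    pc1 <- res$pca$scores[, 1L]
    utils::write.csv(
      data.frame(subject_id = b$subject_id, group = as.character(b$group),
                 emotionality_z = res$emotionality$per_subject_z,
                 res$pca$scores, check.names = FALSE),
      file.path(cfg$out_dir, "behavior_scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(variable = rownames(res$pca$loadings), res$pca$loadings,
                 check.names = FALSE),
      file.path(cfg$out_dir, "behavior_loadings.csv"), row.names = FALSE)
  }

  # --- volumetrics ---
  say("volumetrics: ", cfg$normalization, " normalization, GLM on ",
      ncol(v$volumes), " ROIs")
  vn <- normalize_volumes(v, cfg$normalization)
  res$roi_stats <- roi_group_glm(vn, cfg$covariates)
  res$total_volume_p <- total_brain_volume_test(v)
  utils::write.csv(res$roi_stats,
                   file.path(cfg$out_dir, "roi_stats.csv"), row.names = FALSE)
  if (!is.null(pc1)) {
    res$volume_pc1 <- volume_behavior_regression(vn, pc1)
    utils::write.csv(res$volume_pc1,
                     file.path(cfg$out_dir, "volume_pc1_regression.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cfg$apriori))
    res$enrichment <- apriori_enrichment(res$roi_stats, cfg$apriori, cfg$top_k)

  # --- networks over the density grid ---
  vnet <- residualize_volumes(vn, cfg$residualize_covariates)
  say("networks: correlation + thresholding at ", length(cfg$grid),
      " densities")
  corr <- lapply(c(control = "control", stress = "stress"), function(g) {
    discard_negatives(build_covariance(vnet, g, cfg$roi_exclude))
  })
  for (g in names(corr))
    utils::write.csv(corr[[g]],
                     file.path(cfg$out_dir, paste0("correlation_", g, ".csv")))
  nets <- lapply(names(corr), function(g) {
    lapply(as.numeric(cfg$grid), function(d)
      threshold_by_density(corr[[g]], d, group = g))
  })
  names(nets) <- names(corr)
  mseeds <- local_seed_split(cfg$seed + 1L, 2L * length(cfg$grid))
  gm <- do.call(rbind, lapply(seq_along(cfg$grid), function(di) {
    do.call(rbind, lapply(1:2, function(gi) {
      m <- global_metrics(nets[[gi]][[di]], modularity_runs = 100L,
                          seed = mseeds[(gi - 1L) * length(cfg$grid) + di])
      data.frame(group = names(nets)[gi], density = as.numeric(cfg$grid)[di],
                 as.data.frame(unclass(m)))
    }))
  }))
  res$global_metrics <- gm
  utils::write.csv(gm, file.path(cfg$out_dir, "global_metrics.csv"),
                   row.names = FALSE)

  # --- permutation inference ---
  say("permutation: ", cfg$n_perm, " permutations, metrics: ",
      paste(cfg$metrics, collapse = ", "))
  res$permutation <- permute_metrics(
    vnet, cfg$grid, cfg$metrics, n_perm = cfg$n_perm, seed = cfg$seed,
    roi_exclude = cfg$roi_exclude, modularity_runs = cfg$modularity_runs)
  res$nodal_permutation <- NULL
  if (!is.null(cfg$focal_node) &&
      cfg$focal_node %in% setdiff(v$roi_labels, cfg$roi_exclude)) {
    say("permutation: nodal metrics for '", cfg$focal_node, "'")
    res$nodal_permutation <- permute_metrics(
      vnet, cfg$grid, cfg$nodal_metrics, n_perm = cfg$n_perm,
      seed = cfg$seed, node = cfg$focal_node,
      roi_exclude = cfg$roi_exclude, modularity_runs = cfg$modularity_runs)
  }
  perm_rows <- function(set) do.call(rbind, lapply(set, function(r) {
    data.frame(metric = r$metric_name, node = r$node %||% NA_character_,
               density = r$densities, observed_diff = r$observed_diff,
               p = r$p_per_density, auc_observed = r$auc_observed,
               auc_p = r$auc_p)
  }))
  perm_tab <- rbind(perm_rows(res$permutation),
                    if (!is.null(res$nodal_permutation))
                      perm_rows(res$nodal_permutation))
  utils::write.csv(perm_tab, file.path(cfg$out_dir, "permutation_tests.csv"),
                   row.names = FALSE)

  # --- subconnectome ---
  flagged <- character()
  if (!is.null(res$nodal_permutation)) {
    flags <- node_significance_profile(res$nodal_permutation, cfg$alpha,
                                       cfg$min_consecutive)
    if (any(flags)) flagged <- names(flags)[flags]
    d_rep <- default_report_density(res$nodal_permutation, cfg$alpha)
    if (is.na(d_rep)) d_rep <- as.numeric(cfg$grid)[1L]
    di <- which.min(abs(as.numeric(cfg$grid) - d_rep))
    say("subconnectome: '", cfg$focal_node, "' at density ", d_rep)
    res$neighborhood <- compare_neighborhood(nets$control[[di]],
                                             nets$stress[[di]],
                                             cfg$focal_node)
    nb <- res$neighborhood
    utils::write.csv(
      data.frame(
        neighbor = c(nb$common_neighbors, nb$stress_only, nb$control_only),
        category = rep(c("common", "stress_only", "control_only"),
                       c(length(nb$common_neighbors), length(nb$stress_only),
                         length(nb$control_only)))),
      file.path(cfg$out_dir, "subconnectome_neighbors.csv"),
      row.names = FALSE)
    write_subconnectome_bundle(nets$control[[di]], nets$stress[[di]],
                               cfg$out_dir)
  }

  manifest <- list(
    package = "scovnet",
    version = as.character(utils::packageVersion("scovnet")),
    seed = cfg$seed, n_perm = cfg$n_perm,
    species_preset = cfg$species_preset,
    normalization = cfg$normalization,
    grid = as.numeric(cfg$grid),
    metrics = cfg$metrics, nodal_metrics = cfg$nodal_metrics,
    focal_node = cfg$focal_node,
    flagged_nodes = flagged,
    total_volume_p = res$total_volume_p,
    outputs = sort(list.files(cfg$out_dir)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (seed ", x$manifest$seed, "):\n", sep = "")
  cat("  outputs in ", x$config$out_dir, ":\n    ",
      paste(x$manifest$outputs, collapse = "\n    "), "\n", sep = "")
  invisible(x)
}
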