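# Brute-force oracles for the weighted graph metrics, independent of the
# package's C++ kernels: exhaustive simple-path enumeration for shortest
# paths (feasible for n <= 7), direct triple loops for triangle metrics, and
# a step-up loop for Benjamini-Hochberg.

random_weight_matrix <- function(n, p_edge = 0.6, seed = 1) {
  with_seed(seed, {
    W <- matrix(0, n, n)
    for (j in 2:n) for (i in 1:(j - 1)) {
      if (stats::runif(1) < p_edge) W[i, j] <- W[j, i] <- stats::runif(1, 0.05, 1)
    }
    dimnames(W) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    W
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# all simple paths between s and t as lists of node sequences
bf_all_paths <- function(W, s, t) {
  n <- nrow(W)
  paths <- list()
  walk <- function(path, visited) {
    u <- path[length(path)]
    if (u == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (v in seq_len(n)) {
      if (!visited[v] && W[u, v] > 0) {
        visited[v] <- TRUE
        walk(c(path, v), visited)
        visited[v] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n); visited[s] <- TRUE
  walk(s, visited)
  paths
}

bf_path_len <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

# exhaustive shortest-path structure: distances, counts, and per-node
# pass-through counts for betweenness
bf_shortest <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  sigma <- matrix(0, n, n)
  through <- array(0, c(n, n, n))  # s, t, interior node
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- bf_all_paths(W, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) bf_path_len(W, p), numeric(1))
    dmin <- min(lens)
    tol <- 1e-10 * (1 + dmin)
    short <- paths[abs(lens - dmin) <= tol]
    D[s, t] <- D[t, s] <- dmin
    sigma[s, t] <- sigma[t, s] <- length(short)
    for (p in short) {
      interior <- setdiff(p, c(s, t))
      through[s, t, interior] <- through[s, t, interior] + 1
    }
  }
  list(D = D, sigma = sigma, through = through)
}

bf_betweenness <- function(W) {
  n <- nrow(W)
  sp <- bf_shortest(W)
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (sp$sigma[s, t] > 0)
      bc <- bc + sp$through[s, t, ] / sp$sigma[s, t]
  }
  bc / ((n - 1) * (n - 2) / 2)
}

bf_path_length <- function(W) {
  D <- bf_shortest(W)$D
  off <- D[upper.tri(D)]
  fin <- is.finite(off)
  if (any(fin)) mean(off[fin]) else NA_real_
}

bf_closeness <- function(W) {
  n <- nrow(W)
  D <- bf_shortest(W)$D
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    fin <- is.finite(d)
    r <- sum(fin) + 1
    if (r <= 1) return(0)
    ((r - 1) / sum(d[fin])) * ((r - 1) / (n - 1))
  }, numeric(1))
}

bf_triangle_metrics <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  num <- den <- numeric(n)
  for (i in 1:n) {
    k <- sum(W[i, ] > 0)
    den[i] <- k * (k - 1)
    for (j in 1:n) for (h in 1:n) {
      if (j != h && j != i && h != i &&
          W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        num[i] <- num[i] + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    }
  }
  cc <- ifelse(den > 0, num / den, 0)
  list(transitivity = if (sum(den) > 0) sum(num) / sum(den) else 0,
       clustering_coefficient = mean(cc))
}

# Benjamini-Hochberg step-up, written as the literal procedure
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small cohort builders used across test files
small_null_spec <- function(seed, n_roi = 30L, n_per_group = 12L) {
  cohort_spec(
    n_control = n_per_group, n_stress = n_per_group, n_roi = n_roi,
    module_sizes = rep(n_roi %/% 3L, 3L) +
      c(n_roi - 3L * (n_roi %/% 3L), 0L, 0L),
    within_module_corr = 0.6, between_module_corr = 0.1,
    hub_roi = 1L, hub_gain = 0, demodularization = 1,
    volume_effect_size = 0, emotionality_effect_size = 0,
    n_behavior_tests = 2L, vars_per_test = c(3L, 3L),
    noise_sd = 0.5, seed = seed,
    roi_labels = sprintf("roi_%03d", seq_len(n_roi)))
}

small_effect_spec <- function(seed, hub_gain = 0.3, n_roi = 30L,
                              n_per_group = 12L) {
  cohort_spec(
    n_control = n_per_group, n_stress = n_per_group, n_roi = n_roi,
    module_sizes = rep(n_roi %/% 3L, 3L) +
      c(n_roi - 3L * (n_roi %/% 3L), 0L, 0L),
    within_module_corr = 0.6, between_module_corr = 0.1,
    hub_roi = n_roi,  # last module member
    hub_target_set = as.integer(seq(2L, n_roi - 10L, by = 3L)),
    hub_gain = hub_gain, demodularization = 0.7,
    volume_effect_size = 0, emotionality_effect_size = 0,
    n_behavior_tests = 2L, vars_per_test = c(3L, 3L),
    noise_sd = 0.5, seed = seed,
    roi_labels = sprintf("roi_%03d", seq_len(n_roi)))
}
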