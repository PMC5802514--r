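fake_perm_result <- function(p, densities = seq(0.1, 0.1 + 0.05 * (length(p) - 1),
                                                by = 0.05)) {
  structure(list(metric_name = "degree", node = "x", densities = densities,
                 observed_diff = rep(1, length(p)),
                 null_diffs = matrix(0, 10, length(p)),
                 p_per_density = p, auc_observed = 1, auc_p = 0.5,
                 n_perm = 10L),
            class = "permutation_result")
}

test_that("empirical p-values follow the +1-corrected two-tailed formula", {
  ch <- generate_cohort(small_effect_spec(6L, n_roi = 15L, n_per_group = 8L))
  res <- permute_metric(ch$volumes, density_grid(0.15, 0.25, 0.05),
                        "strength", n_perm = 99, seed = 2, node = "roi_015")
  for (di in seq_along(res$densities)) {
    expect_equal(res$p_per_density[di],
                 (sum(abs(res$null_diffs[, di]) >= abs(res$observed_diff[di])) + 1) /
                   (res$n_perm + 1))
  }
  expect_true(all(res$p_per_density >= 1 / (res$n_perm + 1)))
  expect_true(all(res$p_per_density <= 1))
  # AUC is the trapezoid area of the observed difference curve
  d <- res$densities
  y <- res$observed_diff
  expect_equal(res$auc_observed, sum(diff(d) * (y[-1] + y[-length(y)]) / 2))
  expect_equal(res$auc_p,
               (sum(abs(apply(res$null_diffs, 1, function(z)
                 sum(diff(d) * (z[-1] + z[-length(z)]) / 2))) >=
                   abs(res$auc_observed)) + 1) / (res$n_perm + 1))
})

test_that("a zero observed difference yields p = 1", {
  # stress group is an exact copy of the control subjects, so every metric
  # difference is exactly zero and |null| >= |observed| always holds
  vals <- with_seed(10, matrix(stats::rnorm(8 * 10) + 20, 8, 10))
  vals2 <- rbind(vals, vals)
  colnames(vals2) <- sprintf("r%02d", 1:10)
  v <- volume_table(sprintf("s%d", 1:16),
                    rep(c("control", "stress"), each = 8), vals2)
  res <- permute_metric(v, density_grid(0.2, 0.2, 0.01), "transitivity",
                        n_perm = 60, seed = 3)
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_per_density, 1)
})

test_that("results are byte-identical under a fixed seed", {
  ch <- generate_cohort(small_effect_spec(7L, n_roi = 15L, n_per_group = 8L))
  r1 <- permute_metrics(ch$volumes, density_grid(0.15, 0.25, 0.05),
                        c("modularity", "degree"), n_perm = 40, seed = 9,
                        node = "roi_015")
  r2 <- permute_metrics(ch$volumes, density_grid(0.15, 0.25, 0.05),
                        c("modularity", "degree"), n_perm = 40, seed = 9,
                        node = "roi_015")
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- permute_metrics(ch$volumes, density_grid(0.15, 0.25, 0.05),
                        c("modularity", "degree"), n_perm = 40, seed = 10,
                        node = "roi_015")
  expect_false(identical(r1$modularity$null_diffs, r3$modularity$null_diffs))
})

test_that("one permutation schedule is shared across metrics in a run", {
  ch <- generate_cohort(small_effect_spec(8L, n_roi = 15L, n_per_group = 8L))
  grid <- density_grid(0.15, 0.25, 0.05)
  combo <- permute_metrics(ch$volumes, grid, c("degree", "strength"),
                           n_perm = 30, seed = 4, node = "roi_015")
  solo <- permute_metric(ch$volumes, grid, "degree", n_perm = 30, seed = 4,
                         node = "roi_015")
  expect_equal(combo[["degree[roi_015]"]]$null_diffs, solo$null_diffs)
  expect_equal(combo[["degree[roi_015]"]]$observed_diff, solo$observed_diff)
})

test_that("invalid requests are rejected before computation", {
  ch <- generate_cohort(small_effect_spec(9L, n_roi = 15L, n_per_group = 8L))
  grid <- density_grid(0.15, 0.25, 0.05)
  expect_error(permute_metric(ch$volumes, grid, "smallworldness"), "unknown")
  expect_error(permute_metric(ch$volumes, grid, "degree"), "node")
  expect_error(permute_metric(ch$volumes, grid, "degree", node = "zz"), "zz")
  tiny <- ch$volumes
  tiny$group[1:14] <- "control"
  expect_error(permute_metric(tiny, grid, "modularity"), ">= 4 subjects")
})

test_that("excluded ROIs take no part in permutation networks", {
  ch <- generate_cohort(small_effect_spec(12L, n_roi = 15L, n_per_group = 8L))
  grid <- density_grid(0.2, 0.2, 0.01)
  r_with <- permute_metric(ch$volumes, grid, "modularity", n_perm = 20,
                           seed = 5)
  r_wo <- permute_metric(ch$volumes, grid, "modularity", n_perm = 20, seed = 5,
                         roi_exclude = c("roi_001", "roi_002", "roi_003"))
  expect_false(identical(r_with$observed_diff, r_wo$observed_diff))
  expect_error(permute_metric(ch$volumes, grid, "strength", n_perm = 5,
                              seed = 5, node = "roi_001",
                              roi_exclude = "roi_001"), "roi_001")
})

test_that("permutation p-values are calibrated on null cohorts", {
  rej <- vapply(1:100, function(s) {
    ch <- generate_cohort(small_null_spec(20000 + s, n_roi = 12L,
                                          n_per_group = 8L))
    res <- permute_metric(ch$volumes, density_grid(0.2, 0.2, 0.01),
                          "strength", n_perm = 60, seed = 300 + s,
                          node = "roi_001")
    res$p_per_density[1]
  }, numeric(1))
  expect_gte(mean(rej < 0.1), 0.03)
  expect_lte(mean(rej < 0.1), 0.20)
  expect_gt(mean(rej), 0.35)
  expect_lt(mean(rej), 0.65)
})

test_that("nodal significance needs a consecutive run of low p-values", {
  expect_false(node_significance_profile(fake_perm_result(rep(0.5, 5))))
  expect_true(node_significance_profile(
    fake_perm_result(c(0.5, 0.01, 0.02, 0.01, 0.6))))
  expect_false(node_significance_profile(
    fake_perm_result(c(0.01, 0.99, 0.01, 0.99, 0.01))))
  expect_true(node_significance_profile(
    fake_perm_result(c(0.01, 0.99, 0.01, 0.99, 0.01)), min_consecutive = 1L))
  flags <- node_significance_profile(
    list(a = fake_perm_result(c(0.01, 0.01, 0.5)),
         b = fake_perm_result(c(0.5, 0.5, 0.5))))
  expect_identical(flags, c(a = TRUE, b = FALSE))
  expect_error(node_significance_profile(
    list(fake_perm_result(rep(0.5, 3)),
         fake_perm_result(rep(0.5, 4)))), "density grid")
})

test_that("report density is the first with a significant nodal difference", {
  r1 <- fake_perm_result(c(0.5, 0.03, 0.01))
  r2 <- fake_perm_result(c(0.5, 0.5, 0.01))
  expect_equal(default_report_density(list(r1, r2)), r1$densities[2])
  expect_true(is.na(default_report_density(fake_perm_result(rep(0.5, 3)))))
})
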