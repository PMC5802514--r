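make_volumes <- function(vals, group, covariates = NULL) {
  vals <- as.matrix(vals)
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("r%d", seq_len(ncol(vals)))
  ids <- sprintf("s%d", seq_len(nrow(vals)))
  if (is.null(covariates)) covariates <- data.frame(row.names = ids)
  volume_table(ids, group, vals, covariates)
}

test_that("normalization divides by total brain volume exactly once", {
  v <- make_volumes(rbind(c(10, 30), c(20, 20), c(10, 10), c(30, 10)),
                    c("control", "control", "stress", "stress"),
                    data.frame(total_brain_volume = c(100, 100, 50, 50)))
  vn <- normalize_volumes(v, "divide_by_total")
  expect_equal(unname(vn$volumes[1, ]), c(0.1, 0.3))
  expect_identical(normalize_volumes(v, "none"), v)
  expect_error(normalize_volumes(vn, "divide_by_total"), "already normalized")
  v$covariates$total_brain_volume[2] <- -1
  expect_error(normalize_volumes(v, "divide_by_total"), "s2")
})

test_that("BH adjustment equals the hand-computed step-up procedure", {
  p <- c(0.01, 0.02, 0.04, 0.05)
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.05, 0.05))
  for (s in 1:20) {
    pv <- with_seed(s, stats::runif(sample(3:50, 1)))
    expect_equal(stats::p.adjust(pv, "BH"), bf_bh(pv))
  }
})

test_that("covariate-free ROI GLM reduces to the two-sample t-test", {
  v <- make_volumes(with_seed(4, matrix(stats::rexp(12 * 6) + 1, 12, 6)),
                    rep(c("control", "stress"), each = 6))
  st <- roi_group_glm(v)
  for (j in 1:6) {
    tt <- stats::t.test(v$volumes[7:12, j], v$volumes[1:6, j],
                        var.equal = TRUE)
    expect_equal(st$p[j], tt$p.value, tolerance = 1e-10)
    expect_equal(st$effect_size[j], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
  expect_true(all(st$q >= st$p))
  expect_setequal(st$rank, 1:6)
  o <- order(st$p)
  expect_true(all(diff(st$q[o]) >= -1e-12))
})

test_that("GLM degenerate inputs behave as expected", {
  x <- with_seed(1, matrix(stats::runif(6 * 4) + 1, 6, 4))
  v <- make_volumes(rbind(x, x), rep(c("control", "stress"), each = 6))
  st <- roi_group_glm(v)
  expect_equal(st$effect_size, rep(0, 4))
  expect_equal(st$p, rep(1, 4), tolerance = 1e-9)

  v2 <- make_volumes(rbind(x, x), rep(c("control", "stress"), each = 6),
                     data.frame(a = rep(1:6, 2), b = rep(1:6, 2) * 2))
  expect_error(roi_group_glm(v2, c("a", "b")), "collinear")
})

test_that("stress-affected ROIs rank among the strongest associations", {
  eff <- c("cingulate_area_32", "medial_orbital_cortex",
           "frontal_association_cortex", "dorsolateral_orbital_cortex")
  top20 <- vapply(1:100, function(s) {
    ch <- generate_cohort(mouse_default_spec(seed = 5000 + s))
    st <- roi_group_glm(ch$volumes)
    all(st$rank[match(eff, st$roi)] <= 20)
  }, logical(1))
  expect_gte(mean(top20), 0.85)
})

test_that("volume-behavior regression recovers r-squared", {
  pc1 <- with_seed(2, stats::rnorm(100))
  v <- make_volumes(cbind(5 + 2 * pc1, with_seed(3, stats::rnorm(100)) + 10),
                    rep(c("control", "stress"), 50))
  res <- volume_behavior_regression(v, pc1)
  expect_equal(res$r_squared[1], 1, tolerance = 1e-12)
  expect_lt(res$p[1], 1e-20)

  # null: independent volumes, r^2 near zero on average
  vals <- with_seed(5, matrix(stats::rnorm(1000 * 20) + 20, 1000, 20))
  vnull <- make_volumes(vals, rep(c("control", "stress"), 500))
  resnull <- volume_behavior_regression(vnull, with_seed(6, stats::rnorm(1000)))
  expect_lt(mean(resnull$r_squared), 0.01)

  # bivariate normal with correlation 0.6 -> r^2 -> 0.36
  n <- 2000L
  z <- with_seed(7, stats::rnorm(n))
  x <- 0.6 * z + sqrt(1 - 0.36) * with_seed(8, stats::rnorm(n))
  vr <- make_volumes(cbind(x + 20), rep(c("control", "stress"), n / 2))
  expect_equal(volume_behavior_regression(vr, z)$r_squared, 0.36,
               tolerance = 0.05)

  expect_error(volume_behavior_regression(vnull, rep(1, 1000)), "constant")
})

test_that("a-priori enrichment handles forced and degenerate tables", {
  p <- c(seq(0.001, 0.02, length.out = 20), seq(0.2, 0.99, length.out = 139))
  st <- structure(data.frame(roi = sprintf("r%03d", 1:159),
                             effect_size = 0, t = stats::qnorm(1 - p / 2),
                             variance_explained = 0, p = p,
                             q = stats::p.adjust(p, "BH"),
                             rank = seq_len(159)),
                  class = c("roi_stats_table", "data.frame"))
  # a-priori set identical to the top-20 set: chi-square hits its maximum,
  # which for a 2x2 table equals N
  en <- apriori_enrichment(st, sprintf("r%03d", 1:20), 20L)
  expect_equal(en$chi2, 159, tolerance = 1e-9)
  expect_lt(en$p, 1e-6)
  expect_error(apriori_enrichment(st, character(), 20L), "empty")
  expect_error(apriori_enrichment(st, sprintf("r%03d", 1:20), 159L),
               "degenerate")
  expect_error(apriori_enrichment(st, "nope", 20L), "not in the stats table")
})

test_that("enrichment p-values are near-uniform under the null", {
  ps <- vapply(1:200, function(s) {
    st <- structure(data.frame(roi = sprintf("r%02d", 1:60),
                               rank = with_seed(s, sample(60L))),
                    class = c("roi_stats_table", "data.frame"))
    apriori_enrichment(st, sprintf("r%02d", 1:12), 15L)$p
  }, numeric(1))
  # the 2x2 statistic is discrete, so check coarse uniformity summaries
  # rather than a KS distance
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.62)
  expect_lte(mean(ps < 0.05), 0.10)
})

test_that("total brain volume test behaves across regimes", {
  x <- with_seed(9, stats::runif(12, 10, 12))
  v_same <- make_volumes(cbind(c(x, x)), rep(c("control", "stress"), each = 12))
  expect_equal(total_brain_volume_test(v_same), 1, tolerance = 1e-9)

  v_shift <- make_volumes(cbind(c(x, x + 5 * stats::sd(x))),
                          rep(c("control", "stress"), each = 12))
  expect_lt(total_brain_volume_test(v_shift), 0.001)

  # calibration on null cohorts
  rej <- vapply(1:1000, function(s) {
    ch <- generate_cohort(small_null_spec(10000 + s, n_roi = 6L,
                                          n_per_group = 12L))
    total_brain_volume_test(ch$volumes) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
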