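#' Specify a synthetic two-group cohort
#'
#' A `cohort_spec` parameterizes the latent-factor generative model used by
#' [generate_cohort()]. Regional volumes follow a block (modular) correlation
#' structure: every ROI loads on one global factor (inter-module correlation
#' `between_module_corr`), on its module factor (raising within-module
#' correlation to `within_module_corr`), and on independent residual noise.
#' The stress group can differ from controls in three ways, each an
#' independent knob:
#'
#' * `demodularization` multiplies the within-module shared variance, so
#'   values below 1 attenuate module structure (global loss of covariance
#'   segregation);
#' * `hub_gain` adds a shared factor linking `hub_roi` to `hub_target_set`,
#'   raising those pairwise correlations by `hub_gain` (a focal gain in
#'   "hubness");
#' * `volume_effect_size` shifts mean volume on `volume_effect_rois` by that
#'   many per-ROI SDs, with the per-subject magnitude carried by the latent
#'   emotionality trait so that volume change and behavior are correlated.
#'
#' Behavioral variables load on a latent emotionality trait whose group mean
#' difference is `emotionality_effect_size` (in SD units); variables flagged
#' `lower_is_more_emotional` load negatively.
#'
#' @param n_control,n_stress Subjects per group.
#' @param n_roi Number of regions of interest.
#' @param module_sizes Integer vector summing to `n_roi`; one entry per module.
#' @param within_module_corr,between_module_corr Target Pearson correlations
#'   inside and across modules, in `[0, 1)`, with within >= between.
#' @param hub_roi Index of the focal (hub) ROI.
#' @param hub_target_set Indices of ROIs gaining covariance with the hub in
#'   the stress group (no duplicates).
#' @param hub_gain Added correlation between hub and targets, in `[0, 1)`.
#' @param demodularization Multiplier in `(0, 1]` on within-module shared
#'   variance in the stress group (1 = no change).
#' @param volume_effect_rois Indices of ROIs with a stress volume increase.
#' @param volume_effect_size Cohen's d of the group volume shift on those ROIs.
#' @param n_behavior_tests Number of behavioral tests in the battery.
#' @param vars_per_test Integer vector (length `n_behavior_tests`) of variables
#'   per test; the total is the battery size.
#' @param emotionality_effect_size Cohen's d of the group difference on the
#'   latent emotionality trait.
#' @param noise_sd Per-ROI volume SD in volume units (mm^3); baseline mean
#'   volumes are scaled so that mean/SD >= 10, keeping volumes positive.
#' @param seed Integer master seed; volume, behavior and latent-trait streams
#'   are split deterministically from it.
#' @param roi_labels Optional character vector of ROI names (defaults to
#'   generic labels with the hub labelled `"amygdala"`).
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [mouse_default_spec()], [human_default_spec()]
#' @export
cohort_spec <- function(n_control, n_stress, n_roi, module_sizes,
                        within_module_corr, between_module_corr,
                        hub_roi = 1L, hub_target_set = integer(),
                        hub_gain = 0, demodularization = 1,
                        volume_effect_rois = integer(), volume_effect_size = 0,
                        n_behavior_tests = 4L, vars_per_test = rep(3L, 4L),
                        emotionality_effect_size = 0,
                        noise_sd = 1, seed = 1L, roi_labels = NULL) {
  spec <- list(
    n_control = as.integer(n_control), n_stress = as.integer(n_stress),
    n_roi = as.integer(n_roi), module_sizes = as.integer(module_sizes),
    within_module_corr = within_module_corr,
    between_module_corr = between_module_corr,
    hub_roi = as.integer(hub_roi),
    hub_target_set = as.integer(hub_target_set),
    hub_gain = hub_gain, demodularization = demodularization,
    volume_effect_rois = as.integer(volume_effect_rois),
    volume_effect_size = volume_effect_size,
    n_behavior_tests = as.integer(n_behavior_tests),
    vars_per_test = as.integer(vars_per_test),
    emotionality_effect_size = emotionality_effect_size,
    noise_sd = noise_sd, seed = as.integer(seed))
  if (is.null(roi_labels)) {
    roi_labels <- sprintf("roi_%03d", seq_len(spec$n_roi))
    roi_labels[spec$hub_roi] <- "amygdala"
  }
  spec$roi_labels <- roi_labels
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_control >= 1L, spec$n_stress >= 1L, spec$n_roi >= 2L)
  if (sum(spec$module_sizes) != spec$n_roi)
    stop("module_sizes must sum to n_roi (", sum(spec$module_sizes),
         " != ", spec$n_roi, ")")
  if (any(spec$module_sizes < 1L)) stop("module_sizes must all be >= 1")
  a <- spec$within_module_corr; b <- spec$between_module_corr
  if (a < 0 || a >= 1) stop("within_module_corr must lie in [0, 1)")
  if (b < 0 || b >= 1) stop("between_module_corr must lie in [0, 1)")
  if (b > a)
    stop("implied covariance is not positive semi-definite: ",
         "between_module_corr exceeds within_module_corr")
  if (spec$hub_gain < 0 || spec$hub_gain >= 1) stop("hub_gain must lie in [0, 1)")
  if (spec$demodularization <= 0 || spec$demodularization > 1)
    stop("demodularization must lie in (0, 1]")
  idx_ok <- function(i) all(i >= 1L & i <= spec$n_roi)
  if (!idx_ok(spec$hub_roi) || !idx_ok(spec$hub_target_set) ||
      !idx_ok(spec$volume_effect_rois))
    stop("ROI indices out of range 1..n_roi")
  if (anyDuplicated(spec$hub_target_set))
    stop("hub_target_set contains duplicate indices")
  if (anyDuplicated(spec$volume_effect_rois))
    stop("volume_effect_rois contains duplicate indices")
  if (length(spec$vars_per_test) != spec$n_behavior_tests)
    stop("vars_per_test must have one entry per behavioral test")
  if (any(spec$vars_per_test < 1L)) stop("vars_per_test must all be >= 1")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  if (length(spec$roi_labels) != spec$n_roi ||
      anyDuplicated(spec$roi_labels))
    stop("roi_labels must be ", spec$n_roi, " unique names")
  # stress-group residual variance must stay nonnegative
  w_stress <- b + spec$demodularization * (a - b)
  if (1 - w_stress - spec$hub_gain < -1e-12)
    stop("implied covariance is not positive semi-definite: ",
         "hub_gain too large for the modular correlation level")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:", x$n_control, "control /", x$n_stress, "stress subjects,",
      x$n_roi, "ROIs in", length(x$module_sizes), "modules\n")
  cat("  corr within/between:", x$within_module_corr, "/",
      x$between_module_corr,
      "| hub gain:", x$hub_gain, "| demodularization:", x$demodularization, "\n")
  cat("  volume effect d =", x$volume_effect_size, "on",
      length(x$volume_effect_rois), "ROIs; emotionality d =",
      x$emotionality_effect_size, "over", sum(x$vars_per_test),
      "behavioral variables\n")
  invisible(x)
}

# module index per ROI
.module_of <- function(spec) rep(seq_along(spec$module_sizes), spec$module_sizes)

# loading of behavioral variables on the latent emotionality trait; chosen so
# a one-factor battery has its first principal component carry roughly a
# fifth of total variance, typical of multi-test rodent batteries
.behavior_loading <- 0.45

# within-group coupling of the stress volume effect to the latent trait, in
# effect-size units per trait SD; keeps the group mean shift exact while
# letting affected volumes track emotionality across subjects
.volume_trait_coupling <- 0.3

#' Implied structural correlation matrix of a cohort specification
#'
#' Returns the exact ROI-by-ROI correlation matrix implied by the
#' latent-factor model of a [cohort_spec()] for one group, against which the
#' sample covariance of generated cohorts converges as n grows.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"stress"`.
#' @return A symmetric `n_roi` x `n_roi` correlation matrix.
#' @export
implied_correlation <- function(spec, group = c("control", "stress")) {
  group <- match.arg(group)
  a <- spec$within_module_corr; b <- spec$between_module_corr
  w <- if (group == "stress") b + spec$demodularization * (a - b) else a
  mod <- .module_of(spec)
  R <- matrix(b, spec$n_roi, spec$n_roi)
  same <- outer(mod, mod, "==")
  R[same] <- w
  if (group == "stress" && spec$hub_gain > 0) {
    inv <- sort(unique(c(spec$hub_roi, spec$hub_target_set)))
    R[inv, inv] <- R[inv, inv] + spec$hub_gain
  }
  diag(R) <- 1
  dimnames(R) <- list(spec$roi_labels, spec$roi_labels)
  R
}

#' Generate a synthetic volume + behavior cohort
#'
#' Draws a two-group cohort from the latent-factor model described in
#' [cohort_spec()]. ROI volumes are Gaussian around baseline means scaled so
#' that mean/SD >= 10 (generation errors rather than clips if any volume is
#' nonpositive). Behavioral variables are affine-rescaled per variable so
#' that the z-scoring step genuinely has units to absorb. The volume,
#' behavior, and latent-trait random streams are split deterministically from
#' `spec$seed`, so regenerating either table is reproducible in isolation.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `volumes` (a `volume_table`) and `behavior`
#'   (a `behavior_table`).
#' @examples
#' cohort <- generate_cohort(mouse_default_spec())
#' dim(cohort$volumes$volumes)  # 24 x 155
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_control + spec$n_stress
  group <- factor(rep(c("control", "stress"), c(spec$n_control, spec$n_stress)),
                  levels = c("control", "stress"))
  is_stress <- group == "stress"
  subject_id <- sprintf("sub_%03d", seq_len(n))

  seeds <- local_seed_split(spec$seed, 4L)

  # latent emotionality trait (shared by volume coupling and behavior)
  ell <- with_seed(seeds[1L], {
    stats::rnorm(n) + spec$emotionality_effect_size * as.numeric(is_stress)
  })

  # subject covariates
  sex <- with_seed(seeds[2L], stats::rbinom(n, 1L, 0.5))

  # --- volumes ---
  a <- spec$within_module_corr; b <- spec$between_module_corr
  mod <- .module_of(spec)
  n_mod <- length(spec$module_sizes)
  involved <- sort(unique(c(spec$hub_roi, spec$hub_target_set)))
  z <- with_seed(seeds[3L], {
    g_fac <- stats::rnorm(n)
    f_fac <- matrix(stats::rnorm(n * n_mod), n, n_mod)
    h_fac <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * spec$n_roi), n, spec$n_roi)
    z <- matrix(0, n, spec$n_roi)
    for (grp in c("control", "stress")) {
      rows <- if (grp == "stress") which(is_stress) else which(!is_stress)
      w <- if (grp == "stress") b + spec$demodularization * (a - b) else a
      lam_g <- sqrt(b)
      lam_m <- sqrt(w - b)
      lam_h <- if (grp == "stress") sqrt(spec$hub_gain) else 0
      psi <- rep(1 - w, spec$n_roi)
      if (grp == "stress") psi[involved] <- psi[involved] - spec$hub_gain
      if (any(psi < -1e-12))
        stop("implied covariance is not positive semi-definite: hub_gain")
      psi <- pmax(psi, 0)
      for (j in seq_len(spec$n_roi)) {
        lh <- if (j %in% involved) lam_h else 0
        z[rows, j] <- lam_g * g_fac[rows] + lam_m * f_fac[rows, mod[j]] +
          lh * h_fac[rows] + sqrt(psi[j]) * eps[rows, j]
      }
    }
    z
  })

  mu <- spec$noise_sd * seq(12, 40, length.out = spec$n_roi)
  volumes <- sweep(z * spec$noise_sd, 2L, mu, "+")

  # stress volume effect: an exact group mean shift of d SD units plus a
  # within-group coupling to the latent emotionality trait, so that volume
  # change tracks emotionality across subjects without burying the group
  # effect in carrier noise
  if (length(spec$volume_effect_rois) && spec$volume_effect_size != 0) {
    d <- spec$volume_effect_size
    ell_centered <- ell - spec$emotionality_effect_size * as.numeric(is_stress)
    carrier <- as.numeric(is_stress) + .volume_trait_coupling * ell_centered
    volumes[, spec$volume_effect_rois] <-
      volumes[, spec$volume_effect_rois] + d * spec$noise_sd * carrier
  }

  if (any(volumes <= 0))
    stop("generated nonpositive volume; increase baseline mean / reduce noise_sd")
  dimnames(volumes) <- list(subject_id, spec$roi_labels)

  covariates <- data.frame(
    sex = sex,
    total_brain_volume = rowSums(volumes),
    row.names = subject_id)

  vt <- volume_table(subject_id, group, volumes, covariates)

  # --- behavior ---
  p <- sum(spec$vars_per_test)
  test_of <- rep(seq_len(spec$n_behavior_tests), spec$vars_per_test)
  test_names <- sprintf("test_%02d", seq_len(spec$n_behavior_tests))
  direction <- ifelse(seq_len(p) %% 3L == 0L,
                      "lower_is_more_emotional", "higher_is_more_emotional")
  sgn <- ifelse(direction == "lower_is_more_emotional", -1, 1)
  lam <- .behavior_loading
  values <- with_seed(seeds[4L], {
    eps <- matrix(stats::rnorm(n * p), n, p)
    raw <- outer(ell, sgn * lam) + sqrt(1 - lam^2) * eps
    scl <- seq(0.5, 3, length.out = p)
    ctr <- seq(-2, 10, length.out = p)
    sweep(sweep(raw, 2L, scl, "*"), 2L, ctr, "+")
  })
  var_names <- sprintf("%s_v%d", test_names[test_of],
                       unlist(lapply(spec$vars_per_test, seq_len)))
  dimnames(values) <- list(subject_id, var_names)
  var_meta <- data.frame(variable = var_names,
                         test = test_names[test_of],
                         direction = direction,
                         stringsAsFactors = FALSE)
  bt <- behavior_table(subject_id, group, values, var_meta)

  list(volumes = vt, behavior = bt)
}

#' Default cohort specifications for the two study designs
#'
#' `mouse_default_spec()` parameterizes a rodent unpredictable-chronic-mild-
#' stress design: 12 animals per group, 155 network ROIs in eight anatomical
#' modules, a 34-variable behavioral battery over eight tests, an amygdala
#' hub gaining covariance with 30 distributed targets, mild global
#' demodularization, and a volumetric increase in four corticolimbic ROIs
#' coupled to behavioral emotionality. `human_default_spec()` parameterizes a
#' childhood-trauma design: 237 low-trauma controls vs 299 high-trauma
#' subjects over 56 atlas ROIs, with a weaker focal amygdala gain and a
#' single-ROI volumetric effect, as appropriate for the larger sample.
#'
#' @param seed Master RNG seed stored in the spec.
#' @return A [cohort_spec()].
#' @export
mouse_default_spec <- function(seed = 1L) {
  # eight anatomical modules with strong within-module covariance; the
  # amygdala sits in the small subcortical module 8 and, under stress, gains
  # covariance with 30 targets scattered over the other modules; four
  # prefrontal a-priori ROIs carry the emotionality-coupled volume increase
  labs <- sprintf("roi_%03d", 1:155)
  labs[c(1, 2, 3, 5)] <- c("cingulate_area_32", "medial_orbital_cortex",
                           "frontal_association_cortex",
                           "dorsolateral_orbital_cortex")
  labs[148] <- "amygdala"
  cohort_spec(
    n_control = 12L, n_stress = 12L, n_roi = 155L,
    module_sizes = c(24L, 22L, 20L, 20L, 19L, 18L, 17L, 15L),
    within_module_corr = 0.7, between_module_corr = 0.05,
    hub_roi = 148L,
    hub_target_set = as.integer(round(seq(10L, 138L, length.out = 30L))),
    hub_gain = 0.3, demodularization = 0.7,
    volume_effect_rois = c(1L, 2L, 3L, 5L), volume_effect_size = 1.5,
    n_behavior_tests = 8L,
    vars_per_test = c(6L, 5L, 4L, 5L, 4L, 4L, 3L, 3L),
    emotionality_effect_size = 2,
    noise_sd = 0.4, seed = seed,
    roi_labels = labs)
}

#' @rdname mouse_default_spec
#' @export
human_default_spec <- function(seed = 1L) {
  labs <- sprintf("roi_%03d", 1:56)
  labs[20] <- "occipital_fusiform_gyrus"
  labs[52] <- "amygdala"
  cohort_spec(
    n_control = 237L, n_stress = 299L, n_roi = 56L,
    module_sizes = c(10L, 10L, 9L, 9L, 9L, 9L),
    within_module_corr = 0.5, between_module_corr = 0.05,
    hub_roi = 52L,
    hub_target_set = as.integer(round(seq(3L, 46L, length.out = 12L))),
    hub_gain = 0.15, demodularization = 0.85,
    volume_effect_rois = 20L, volume_effect_size = 0.4,
    n_behavior_tests = 5L,
    vars_per_test = c(5L, 5L, 4L, 3L, 3L),
    emotionality_effect_size = 0.8,
    noise_sd = 400, seed = seed,
    roi_labels = labs)
}
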