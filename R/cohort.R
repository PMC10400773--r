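#' Default per-group cognitive-scale parameters
#'
#' Group means and SDs (NC, MCI, AD) for the 13 cognitive scales, matching
#' the demographic table of the clinical cohort this package emulates,
#' together with the sign and magnitude of each scale's programmed coupling
#' to the latent ALPS index. IADL and the Trail Making Tests are
#' impairment-coded (higher = worse), hence negative coupling.
#'
#' @return Data frame with one row per scale.
#' @export
default_scale_params <- function() {
  df <- read.table(header = TRUE, text = "
scale  nc_mean nc_sd mci_mean mci_sd ad_mean ad_sd rho
MoCA_B   23.8  3.7   16.9  3.8    7.9  3.6   0.25
MMSE     27.0  2.2   24.2  2.9   14.9  5.8   0.24
IADL     15.2  2.6   16.7  2.9   24.1  6.4  -0.27
HVLT1    20.5  4.5   15.3  4.2    7.4  4.6   0.22
HVLT2     7.2  2.3    3.0  2.9    0.2  1.0   0.22
HVLT3     7.3  2.2    2.8  2.8    0.3  0.9   0.22
WMS       9.5  2.4    6.2  2.3    3.0  2.3   0.20
TMT_A    54.7 16.7   76.6 28.0  120.0 48.8  -0.20
TMT_B   139.6 44.4  180.1 51.5  211.7 50.3  -0.20
ROCFT1   25.2 13.3   23.9 12.6   15.1 12.9   0.18
ROCFT2   13.4  8.7    6.7  6.8    0.9  2.8   0.20
VFT      14.7  3.5   11.6  3.2    6.3  3.3   0.20
BNT      23.9  3.4   19.9  4.2   14.2  5.7   0.20
")
  df$scale <- as.character(df$scale)
  df
}

#' Synthetic cohort specification
#'
#' Parameters of the three-group (NC / MCI / AD) synthetic cohort
#' generator. Demographic and scale defaults reproduce the clinical
#' characteristics table of the emulated cohort (n = 111/120/69; e.g. NC
#' MMSE 27.0 +/- 2.2, AD MMSE 14.9 +/- 5.8; ages 68.6/72.0/74.0). ALPS
#' group means are not published for that cohort; the defaults (1.470 /
#' 1.375 / 1.280, SD 0.12) were derived so that the covariate-adjusted
#' group contrasts are detectable at the cohort's sample sizes and the
#' implied pairwise discriminabilities track the reported classification
#' performance (see the methods vignette for the derivation).
#'
#' @param n_per_group Named integer vector `c(NC=, MCI=, AD=)`, each >= 2.
#' @param age_mean,age_sd,edu_mean,edu_sd,wmh_mean,wmh_sd Per-group
#'   demographic parameters (vectors of 3, NC/MCI/AD order).
#' @param female_frac Per-group probability that a subject is female.
#' @param alps_mean,alps_sd Per-group latent ALPS mean and residual SD.
#' @param fa_mean,fa_sd Per-group ROI-mean FA parameters.
#' @param beta_age,beta_edu,beta_wmh Linear covariate effects on ALPS
#'   (units: index per year, per year, per Fazekas point), applied to
#'   covariates centered at `cov_center`.
#' @param cov_center Centering constants `c(age, edu, wmh)`.
#' @param rho_fa_alps Within-group correlation between FA and ALPS residuals.
#' @param hemi_sd SD of independent per-hemisphere measurement noise added
#'   to the left and right indices around the latent subject value.
#' @param scale_params Data frame as from [default_scale_params()].
#' @param batch_prop Batch assignment probabilities (sum to 1); defaults
#'   mirror the three-scanner composition of the emulated study
#'   (159/96/45 of 300).
#' @param batch_shift,batch_scale Per-batch additive location and residual
#'   scale effects on ALPS (first batch is the reference).
#' @param batch_shift_fa Per-batch additive location effects on FA.
#' @param seed Integer seed.
#' @return A `cohort_gen_spec` list.
#' @export
cohort_gen_spec <- function(
    n_per_group = c(NC = 111L, MCI = 120L, AD = 69L),
    age_mean = c(68.6, 72.0, 74.0), age_sd = c(7.5, 7.1, 8.5),
    edu_mean = c(12.2, 10.0, 9.4), edu_sd = c(3.6, 4.4, 5.2),
    wmh_mean = c(2.0, 2.5, 3.1), wmh_sd = c(1.5, 1.5, 1.6),
    female_frac = c(57 / 111, 68 / 120, 38 / 69),
    alps_mean = c(1.470, 1.375, 1.280), alps_sd = c(0.12, 0.12, 0.12),
    fa_mean = c(0.450, 0.440, 0.426), fa_sd = c(0.03, 0.03, 0.03),
    beta_age = -0.002, beta_edu = 0.002, beta_wmh = -0.01,
    cov_center = c(age = 71, edu = 10.5, wmh = 2.5),
    rho_fa_alps = 0.3, hemi_sd = 0.03,
    scale_params = default_scale_params(),
    batch_prop = c(159, 96, 45) / 300,
    batch_shift = c(0, 0.08, -0.06), batch_scale = c(1, 1.2, 0.9),
    batch_shift_fa = c(0, 0.012, -0.009),
    seed = 1L) {
  groups <- c("NC", "MCI", "AD")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (any(n_per_group < 2L)) stop("each n_per_group must be >= 2")
  if (any(c(age_sd, edu_sd, wmh_sd, alps_sd, fa_sd) <= 0))
    stop("all SDs must be > 0")
  if (any(unlist(scale_params[, c("nc_sd", "mci_sd", "ad_sd")]) <= 0))
    stop("all scale SDs must be > 0")
  if (abs(sum(batch_prop) - 1) > 1e-8) stop("batch proportions must sum to 1")
  if (any(abs(scale_params$rho) > 1)) stop("|rho| must be <= 1")
  if (length(batch_shift) != length(batch_prop) ||
      length(batch_scale) != length(batch_prop))
    stop("batch effect vectors must match batch_prop length")
  structure(as.list(environment()), class = "cohort_gen_spec")
}

#' Null-cohort specification
#'
#' All group means equal, all ALPS couplings and covariate effects zero, no
#' batch effects: every downstream test statistic is distributed under its
#' null, which is what the type-I-error and FDR-control simulations need.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @return A `cohort_gen_spec`.
#' @export
cohort_gen_spec_null <- function(n_per_group = c(NC = 50L, MCI = 50L, AD = 50L),
                                 seed = 1L) {
  sp <- default_scale_params()
  sp$mci_mean <- sp$ad_mean <- sp$nc_mean
  sp$mci_sd <- sp$ad_sd <- sp$nc_sd
  sp$rho <- 0
  cohort_gen_spec(
    n_per_group = n_per_group,
    age_mean = rep(70, 3), age_sd = rep(7.5, 3),
    edu_mean = rep(11, 3), edu_sd = rep(4, 3),
    wmh_mean = rep(2.5, 3), wmh_sd = rep(1.5, 3),
    female_frac = rep(0.5, 3),
    alps_mean = rep(1.4, 3), alps_sd = rep(0.12, 3),
    fa_mean = rep(0.44, 3), fa_sd = rep(0.03, 3),
    beta_age = 0, beta_edu = 0, beta_wmh = 0,
    rho_fa_alps = 0, scale_params = sp,
    batch_shift = c(0, 0, 0), batch_scale = c(1, 1, 1),
    batch_shift_fa = c(0, 0, 0),
    seed = seed)
}

#' Generate a synthetic three-group cohort
#'
#' One row per subject with demographics, Fazekas WMH score, 13 cognitive
#' scales, scanner batch, and the observed imaging features `L_ALPS`,
#' `R_ALPS`, `Bi_ALPS`, `FA_mean`. The generative model is linear-Gaussian:
#' a latent per-subject ALPS value is the group mean plus centered covariate
#' effects plus a residual; cognitive scores couple to that residual at the
#' programmed within-group (covariate-adjusted) correlations; batch effects
#' act as an additive shift plus a residual scale, the model ComBat assumes.
#' Ground-truth parameters and latent values are attached as the
#' `"ground_truth"` attribute (a sidecar, never written to CSV).
#'
#' @param spec A [cohort_gen_spec()].
#' @return Data frame of class `cohort_table`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  set.seed(spec$seed)
  groups <- c("NC", "MCI", "AD")
  n <- sum(spec$n_per_group)
  grp <- factor(rep(groups, times = spec$n_per_group[groups]), levels = groups)
  gi <- as.integer(grp)
  age <- rnorm(n, spec$age_mean[gi], spec$age_sd[gi])
  edu <- pmax(0, rnorm(n, spec$edu_mean[gi], spec$edu_sd[gi]))
  wmh <- pmin(6L, pmax(0L, as.integer(round(
    rnorm(n, spec$wmh_mean[gi], spec$wmh_sd[gi])))))
  sex <- ifelse(runif(n) < spec$female_frac[gi], "F", "M")
  batch <- sample(paste0("batch", seq_along(spec$batch_prop)), n,
                  replace = TRUE, prob = spec$batch_prop)
  bi <- as.integer(sub("batch", "", batch))

  z_eps <- rnorm(n)                       # standardized ALPS residual
  eps <- z_eps * spec$alps_sd[gi]
  systematic <- spec$alps_mean[gi] +
    spec$beta_age * (age - spec$cov_center[["age"]]) +
    spec$beta_edu * (edu - spec$cov_center[["edu"]]) +
    spec$beta_wmh * (wmh - spec$cov_center[["wmh"]])
  latent <- systematic + eps
  observed <- systematic + spec$batch_shift[bi] + spec$batch_scale[bi] * eps
  L <- observed + rnorm(n, 0, spec$hemi_sd)
  R <- observed + rnorm(n, 0, spec$hemi_sd)

  z_fa <- spec$rho_fa_alps * z_eps +
    sqrt(1 - spec$rho_fa_alps^2) * rnorm(n)
  fa <- spec$fa_mean[gi] + spec$batch_shift_fa[bi] +
    spec$batch_scale[bi] * spec$fa_sd[gi] * z_fa

  out <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)), group = grp, sex = sex,
    age = age, education = edu, WMH = wmh, batch = batch,
    stringsAsFactors = FALSE)
  sp <- spec$scale_params
  means <- as.matrix(sp[, c("nc_mean", "mci_mean", "ad_mean")])
  sds <- as.matrix(sp[, c("nc_sd", "mci_sd", "ad_sd")])
  for (k in seq_len(nrow(sp))) {
    rho <- sp$rho[k]
    out[[sp$scale[k]]] <- means[k, gi] +
      sds[k, gi] * (rho * z_eps + sqrt(1 - rho^2) * rnorm(n))
  }
  out$L_ALPS <- L
  out$R_ALPS <- R
  out$Bi_ALPS <- (L + R) / 2
  out$FA_mean <- fa
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "ground_truth") <- list(
    spec = spec, latent_alps = latent, systematic = systematic,
    residual_z = z_eps, batch_index = bi)
  out
}

#' Simulate paired test-retest sessions from variance components
#'
#' Each subject has a latent trait with variance `var_between`; each
#' session observes it with independent error of variance `var_within`
#' plus an optional systematic per-session offset. The population ICC(2,1)
#' with zero offsets is `var_between / (var_between + var_within)`.
#'
#' @param n Number of subjects.
#' @param var_between,var_within Variance components (> 0).
#' @param session_offset Length-2 additive session effects.
#' @param mean Grand mean.
#' @param seed Integer seed.
#' @return Data frame with columns `session1`, `session2`.
#' @export
simulate_sessions <- function(n, var_between = 3, var_within = 1,
                              session_offset = c(0, 0), mean = 0, seed = 1L) {
  stopifnot(n >= 2, var_between >= 0, var_within > 0)
  set.seed(as.integer(seed))
  subj <- rnorm(n, 0, sqrt(var_between))
  data.frame(
    session1 = mean + session_offset[1] + subj + rnorm(n, 0, sqrt(var_within)),
    session2 = mean + session_offset[2] + subj + rnorm(n, 0, sqrt(var_within)))
}
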