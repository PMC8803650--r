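#' Simulation configuration for synthetic cohorts
#'
#' Defaults reproduce the study conditions the analysis is designed for:
#' four groups — healthy controls (CON), polysubstance users with comorbid
#' alcohol use disorder (PSU), alcohol use disorder (AUD), opioid use
#' disorder (OUD) — with sizes 21/21/65/27, a control mean cortical
#' thickness of 2.52 mm with between-subject SD 0.07 mm, group-specific
#' ages, a weak negative age slope on thickness, total intracranial volume
#' around 1493 (106) cm^3, and Barratt impulsiveness (BIS-11) scores per
#' group. Group atrophy effects are planted at parcel granularity so ground
#' truth is unambiguous for recovery tests.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param baseline_mean_mm mean cortical thickness of controls (mm).
#' @param baseline_sd_mm between-subject SD of subject-average thickness
#'   (mm); the subject-level random intercept is calibrated so the control
#'   group's subject-mean SD matches this value after accounting for the
#'   age slope.
#' @param age_mean_sd named list of `c(mean, sd)` ages per group (years).
#' @param age_slope_mm_per_year change of thickness per year of age.
#' @param effect_table data.frame with columns `group`, `parcel_id`,
#'   `thinning_mm` (nonnegative mm removed on that parcel for that group).
#' @param noise_fwhm_mm spatial smoothness (FWHM) of the element-wise noise.
#' @param element_noise_sd_mm SD of the element-wise noise before smoothing.
#' @param tiv_mean_sd_cm3 `c(mean, sd)` of total intracranial volume.
#' @param behavioral_scores named list: score -> named list of `c(mean, sd)`
#'   per group.
#' @param latent_factor `NULL`, or `list(network_family =, sd_mm =)` adding
#'   a shared subject-level factor loading on one network family's parcels,
#'   giving structural covariance seed maps a recoverable target.
#' @return A `ctcov_sim_config` list.
#' @export
simulation_config <- function(
    group_sizes = c(CON = 21, PSU = 21, AUD = 65, OUD = 27),
    baseline_mean_mm = 2.52,
    baseline_sd_mm = 0.07,
    age_mean_sd = list(CON = c(45.3, 8.3), PSU = c(43.7, 11.1),
                       AUD = c(41.8, 9.5), OUD = c(45.6, 11.9)),
    age_slope_mm_per_year = -0.005,
    effect_table = NULL,
    noise_fwhm_mm = 12,
    element_noise_sd_mm = 0.25,
    tiv_mean_sd_cm3 = c(1493, 106),
    behavioral_scores = list(
      bis_total = list(CON = c(53.7, 7.9), PSU = c(74.3, 8.2),
                       AUD = c(65.5, 11.4), OUD = c(65.48, 10.1)),
      bis_attentional = list(CON = c(13.0, 3.0), PSU = c(19.8, 4.7),
                             AUD = c(18.0, 4.1), OUD = c(15.6, 3.3)),
      bis_motor = list(CON = c(19.9, 3.4), PSU = c(25.9, 3.8),
                       AUD = c(23.5, 4.6), OUD = c(23.9, 4.4)),
      bis_nonplanning = list(CON = c(20.8, 4.2), PSU = c(28.5, 3.9),
                             AUD = c(25.8, 5.1), OUD = c(26.0, 4.6))),
    latent_factor = NULL) {
  stopifnot(all(group_sizes >= 2), baseline_sd_mm >= 0,
            element_noise_sd_mm >= 0,
            all(names(group_sizes) %in% names(age_mean_sd)))
  if (!is.null(effect_table))
    stopifnot(all(c("group", "parcel_id", "thinning_mm") %in%
                    names(effect_table)),
              all(effect_table$thinning_mm >= 0))
  structure(list(group_sizes = group_sizes,
                 baseline_mean_mm = baseline_mean_mm,
                 baseline_sd_mm = baseline_sd_mm,
                 age_mean_sd = age_mean_sd,
                 age_slope_mm_per_year = age_slope_mm_per_year,
                 effect_table = effect_table,
                 noise_fwhm_mm = noise_fwhm_mm,
                 element_noise_sd_mm = element_noise_sd_mm,
                 tiv_mean_sd_cm3 = tiv_mean_sd_cm3,
                 behavioral_scores = behavioral_scores,
                 latent_factor = latent_factor),
            class = "ctcov_sim_config")
}

#' Simulate a cohort of thickness maps with covariates
#'
#' Thickness is baseline + age slope (relative to the cohort mean age) +
#' planted parcel-level group thinning + a subject-level global intercept +
#' spatially smoothed, per-subject mean-centered Gaussian noise. The global
#' intercept SD is calibrated so the SD of control subject-average thickness
#' equals `baseline_sd_mm`. Deterministic given `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @param domain the spatial domain.
#' @param parcellation parcellation used to place parcel-level effects.
#' @param rng_seed integer seed.
#' @return A `ctcov_cohort` list: `thickness` (subjects x elements matrix,
#'   mm), `covariates` (data.frame with subject_id, group, age, tiv and one
#'   column per behavioral score), `config`.
#' @export
simulate_cohort <- function(config, domain, parcellation, rng_seed = 1) {
  stopifnot(inherits(config, "ctcov_sim_config"),
            inherits(domain, "ctcov_domain"),
            inherits(parcellation, "ctcov_parcellation"))
  gs <- config$group_sizes
  if (!is.null(config$effect_table)) {
    if (!all(config$effect_table$group %in% names(gs)))
      stop("unknown group in effect_table")
    if (!all(config$effect_table$parcel_id %in%
               parcellation$parcels$parcel_id))
      stop("unknown parcel in effect_table")
  }
  n <- sum(gs)
  m <- domain$n_elements
  group <- rep(names(gs), gs)
  with_seed(rng_seed, {
    age <- numeric(n)
    for (g in names(gs)) {
      ms <- config$age_mean_sd[[g]]
      age[group == g] <- rnorm(gs[[g]], ms[1], ms[2])
    }
    tiv <- rnorm(n, config$tiv_mean_sd_cm3[1], config$tiv_mean_sd_cm3[2])
    scores <- lapply(config$behavioral_scores, function(sc) {
      out <- numeric(n)
      for (g in names(gs)) out[group == g] <- rnorm(gs[[g]], sc[[g]][1],
                                                    sc[[g]][2])
      out
    })
    # subject random intercept calibrated to the control subject-mean SD
    age_sd_con <- config$age_mean_sd[[1]][2]
    v_int <- config$baseline_sd_mm^2 -
      (config$age_slope_mm_per_year * age_sd_con)^2
    sd_int <- sqrt(max(v_int, 0))
    intercept <- rnorm(n, 0, sd_int)
    thick <- matrix(config$baseline_mean_mm +
                      config$age_slope_mm_per_year * (age - mean(age)) +
                      intercept,
                    nrow = n, ncol = m)
    if (config$element_noise_sd_mm > 0) {
      eps <- matrix(rnorm(n * m, 0, config$element_noise_sd_mm), m, n)
      eps <- smooth_field(eps, domain, fwhm_mm = config$noise_fwhm_mm)
      eps <- sweep(eps, 2, colMeans(eps)) # per-subject mean-centering
      thick <- thick + t(eps)
    }
    if (!is.null(config$effect_table)) {
      for (i in seq_len(nrow(config$effect_table))) {
        row <- config$effect_table[i, ]
        el <- parcels_to_elements(row$parcel_id, parcellation)
        sel <- group == row$group
        thick[sel, el] <- thick[sel, el] - row$thinning_mm
      }
    }
    if (!is.null(config$latent_factor)) {
      lf <- config$latent_factor
      pid <- parcellation$parcels$parcel_id[
        parcellation$parcels$network_family == lf$network_family]
      el <- parcels_to_elements(pid, parcellation)
      f <- rnorm(n, 0, lf$sd_mm)
      thick[, el] <- thick[, el] + f
    }
    thick <- pmax(thick, 0.05) # thickness strictly positive
    covs <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       group = group, age = age, tiv = tiv,
                       stringsAsFactors = FALSE)
    for (s in names(scores)) covs[[s]] <- scores[[s]]
    structure(list(thickness = thick, covariates = covs, config = config),
              class = "ctcov_cohort")
  })
}

#' @export
print.ctcov_cohort <- function(x, ...) {
  cat(sprintf("<ctcov_cohort> %d subjects x %d elements; groups: %s\n",
              nrow(x$thickness), ncol(x$thickness),
              paste(sprintf("%s=%d", names(table(x$covariates$group)),
                            table(x$covariates$group)), collapse = ", ")))
  invisible(x)
}

#' Simulate functional-connectivity template maps per network family
#'
#' For each network family, produces an element-wise connectivity map with
#' value about `within_network_level` on that family's parcels and about 0
#' elsewhere, plus i.i.d. Gaussian noise, clipped to [-1, 1]. These maps
#' stand in for seed-correlation maps derived from large resting-state
#' samples, and are the functional reference against which structural
#' covariance maps are scored for concordance.
#'
#' @param domain the spatial domain.
#' @param parcellation the parcellation carrying the network families.
#' @param within_network_level connectivity level inside the family's
#'   parcels, in (0, 1].
#' @param noise_sd SD of the additive noise (default 0.01).
#' @param rng_seed integer seed.
#' @return Named list (one per network family) of numeric element maps.
#' @export
simulate_functional_templates <- function(domain, parcellation,
                                          within_network_level = 0.6,
                                          noise_sd = 0.01, rng_seed = 1) {
  stopifnot(within_network_level > 0, within_network_level <= 1,
            noise_sd >= 0)
  fams <- unique(parcellation$parcels$network_family)
  m <- domain$n_elements
  with_seed(rng_seed, {
    out <- lapply(fams, function(fam) {
      pid <- parcellation$parcels$parcel_id[
        parcellation$parcels$network_family == fam]
      v <- numeric(m)
      v[parcels_to_elements(pid, parcellation)] <- within_network_level
      v <- v + rnorm(m, 0, noise_sd)
      pmin(pmax(v, -1), 1)
    })
    names(out) <- fams
    out
  })
}
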