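#' Configuration for synthetic plate-luminescence data
#'
#' Describes the ground truth and noise model of a simulated bioluminescence
#' inhibition experiment mirroring the two-timepoint microplate protocol:
#' each well is read at contact (t0) and after 5 min of exposure, negative
#' controls receive only sample diluent, and inhibition is recovered by
#' control normalisation.
#'
#' The generative model per well is
#' `lum_t0 ~ logNormal(baseline)`, `lum_t5 = lum_t0 * control_decay *
#' (1 - E/100) * exp(eps)`, `eps ~ N(0, noise_cv)`, with `E` the true effect.
#' Mixture rays respond along a logit curve whose slope is the numeric
#' composite slope of the concentration-addition prediction and whose EC50 is
#' `interaction_lambda * EC50_CA`: `lambda = 1` gives exact concentration
#' addition (MDR 1); under the assay's MDR mapping (predicted/observed),
#' `lambda > 1` produces MDR `1/lambda < 1`, read as synergism, and
#' `lambda < 1` MDR above 1, read as antagonism.
#'
#' @param true_curves Named list of per-substance [tox_curve()]s (ground
#'   truth; default the built-in reference curves).
#' @param rays Named list of [mixture_ray()]s (default the built-in reference
#'   rays).
#' @param interaction_lambda Positive interaction multiplier on the CA EC50
#'   (may be a named vector per ray).
#' @param replicates Wells per concentration (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   luminescence noise (default 0.05; 0 = noiseless).
#' @param control_decay Fraction of t0 luminescence retained by negative
#'   controls after 5 min (default 0.8).
#' @param baseline_lum_mean,baseline_lum_cv Mean and CV of the log-normal t0
#'   luminescence (defaults 2e5 counts, 0.1).
#' @param n_controls Negative-control wells per plate group (default 3).
#' @param single_n_points Points in each single-stressor concentration series
#'   (default 7, log-spaced between the true EC5 and EC95).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(true_curves = reference_curves(as_curves = TRUE),
                       rays = reference_rays(as_rays = TRUE),
                       interaction_lambda = 1,
                       replicates = 3,
                       noise_cv = 0.05,
                       control_decay = 0.8,
                       baseline_lum_mean = 2e5,
                       baseline_lum_cv = 0.1,
                       n_controls = 3,
                       single_n_points = 7,
                       seed = 1L) {
  stopifnot(all(interaction_lambda > 0), noise_cv >= 0,
            control_decay > 0, control_decay <= 1,
            replicates >= 1, baseline_lum_mean > 0, baseline_lum_cv >= 0,
            single_n_points >= 4)
  if (!is.null(rays)) {
    lam <- interaction_lambda
    if (is.null(names(lam))) lam <- stats::setNames(rep_len(lam, length(rays)),
                                                    names(rays))
    interaction_lambda <- lam
  }
  structure(list(true_curves = true_curves, rays = rays,
                 interaction_lambda = interaction_lambda,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 control_decay = control_decay,
                 baseline_lum_mean = baseline_lum_mean,
                 baseline_lum_cv = baseline_lum_cv,
                 n_controls = as.integer(n_controls),
                 single_n_points = as.integer(single_n_points),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal draws with a given arithmetic mean and CV
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

sim_wells <- function(config, group_id, ray_id, dilution, conc, unit, effect) {
  n <- length(effect)
  t0 <- rlnorm_cv(n, config$baseline_lum_mean, config$baseline_lum_cv)
  eps <- if (config$noise_cv == 0) rep(0, n) else stats::rnorm(n, 0, config$noise_cv)
  t5 <- t0 * config$control_decay * (1 - effect / 100) * exp(eps)
  data.frame(
    well_id = paste0(group_id, "_w", seq_len(n)),
    role = "sample", ray_id = ray_id,
    dilution_factor = dilution, concentration = conc, unit = unit,
    lum_t0 = t0, lum_t5 = pmax(t5, 0), stringsAsFactors = FALSE
  )
}

sim_controls <- function(config, group_id, ray_id) {
  n <- config$n_controls
  t0 <- rlnorm_cv(n, config$baseline_lum_mean, config$baseline_lum_cv)
  eps <- if (config$noise_cv == 0) rep(0, n) else stats::rnorm(n, 0, config$noise_cv)
  data.frame(
    well_id = paste0(group_id, "_nc", seq_len(n)),
    role = "negative_control", ray_id = ray_id,
    dilution_factor = 1, concentration = 0,
    unit = NA_character_,
    lum_t0 = t0, lum_t5 = t0 * config$control_decay * exp(eps),
    stringsAsFactors = FALSE
  )
}

#' Simulate single-stressor dilution plates
#'
#' One concentration series per substance in `config$true_curves`:
#' `single_n_points` log-spaced concentrations between the substance's true
#' EC5 and EC95 (in the curve's own unit), `replicates` wells each, plus
#' negative controls per substance group. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Plate data.frame (schema of [read_plate_csv()]).
#' @export
simulate_single_plates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- list()
  for (s in names(config$true_curves)) {
    cv <- config$true_curves[[s]]
    conc <- 10^seq(log10(ecx(cv, 5)), log10(ecx(cv, 95)),
                   length.out = config$single_n_points)
    eff <- logit_effect(cv, log10(conc))
    conc_all <- rep(conc, each = config$replicates)
    eff_all <- rep(eff, each = config$replicates)
    gid <- paste0(s, "_", seq_along(conc_all))
    wells <- sim_wells(config, gid, ray_id = s, dilution = 1,
                       conc = conc_all, unit = cv$unit, effect = eff_all)
    out[[length(out) + 1L]] <- rbind(wells, sim_controls(config, s, ray_id = s))
  }
  do.call(rbind, out)
}

# Composite slope of the CA prediction curve, from its EC25/EC75 chord in
# log10 space (matches the exact slope when all components share one slope).
ca_composite_slope <- function(ray, curves) {
  e25 <- ca_ecx(ray, curves, 25)
  e75 <- ca_ecx(ray, curves, 75)
  2 * log10(3) / (log10(e75) - log10(e25))
}

# True mixture curve of a simulated ray: logit with the CA composite slope,
# centred at lambda * EC50_CA.
true_mixture_curve <- function(config, ray_id) {
  ray <- config$rays[[ray_id]]
  lam <- config$interaction_lambda[[ray_id]]
  ca50 <- ca_ecx(ray, config$true_curves, 50)
  tox_curve(paste0("ray_", ray_id), ca_composite_slope(ray, config$true_curves),
            log10(lam * ca50), unit = "M")
}

#' Simulate mixture-ray dilution plates
#'
#' For each configured ray, wells along its dilution series with the true
#' effect drawn from the ray's true mixture curve (see [sim_config()]), plus
#' negative controls per ray. Concentrations are total molar.
#'
#' @param config A [sim_config()].
#' @return Plate data.frame (schema of [read_plate_csv()]).
#' @export
simulate_mixture_plates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  out <- list()
  for (id in names(config$rays)) {
    ray <- config$rays[[id]]
    truth <- true_mixture_curve(config, id)
    series <- dilution_series(ray)
    conc <- rep(series$total_M, each = config$replicates)
    dil <- rep(series$dilution_factor, each = config$replicates)
    eff <- logit_effect(truth, log10(conc))
    gid <- paste0("ray", id, "_", seq_along(conc))
    wells <- sim_wells(config, gid, ray_id = id, dilution = dil,
                       conc = conc, unit = "M", effect = eff)
    out[[length(out) + 1L]] <- rbind(wells, sim_controls(config, paste0("ray", id),
                                                         ray_id = id))
  }
  do.call(rbind, out)
}

#' Ground-truth table of a simulation configuration
#'
#' One row per substance (true single-stressor EC50) and per ray (CA EC50,
#' interaction lambda, true mixture EC50 `lambda * EC50_CA`, and the
#' composite slope of the true mixture curve), for parameter-recovery
#' assertions. All EC50s in mol/L.
#'
#' @param config A [sim_config()].
#' @return Data.frame with columns `id`, `kind`, `ec50_M`, `lambda`, `slope`.
#' @export
simulation_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  singles <- do.call(rbind, lapply(names(config$true_curves), function(s) {
    cv <- config$true_curves[[s]]
    cvM <- if (cv$unit == "M") cv else as_molar_curve(cv)
    data.frame(id = s, kind = "single", ec50_M = 10^cvM$log_xc,
               lambda = NA_real_, slope = cv$p, stringsAsFactors = FALSE)
  }))
  rays <- NULL
  if (!is.null(config$rays)) {
    rays <- do.call(rbind, lapply(names(config$rays), function(id) {
      truth <- true_mixture_curve(config, id)
      data.frame(id = id, kind = "mixture", ec50_M = 10^truth$log_xc,
                 lambda = config$interaction_lambda[[id]], slope = truth$p,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(singles, rays)
}
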