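#' Model deviation ratio (MDR)
#'
#' Quotient of the model-predicted and observed EC50 of a mixture ray. Two
#' conventions are supported because both occur in published tables:
#' `"predicted_over_observed"` (the default, matching the textual definition)
#' and `"observed_over_predicted"` (its reciprocal). The convention is
#' recorded as an attribute of the result.
#'
#' @param ec50_predicted,ec50_observed Positive effect concentrations (same
#'   unit).
#' @param convention Ratio orientation.
#' @return Positive MDR value(s), with attribute `convention`.
#' @export
#' @examples
#' mdr(8.73e-2, 4.19e-3)  # 20.83
mdr <- function(ec50_predicted, ec50_observed,
                convention = c("predicted_over_observed",
                               "observed_over_predicted")) {
  convention <- match.arg(convention)
  if (any(ec50_predicted <= 0) || any(ec50_observed <= 0)) {
    stop("EC50 values must be positive", call. = FALSE)
  }
  out <- if (convention == "predicted_over_observed") {
    ec50_predicted / ec50_observed
  } else {
    ec50_observed / ec50_predicted
  }
  attr(out, "convention") <- convention
  out
}

#' Relative deviation of a predicted EC50
#'
#' `100 * |predicted - observed| / observed`, in percent. Scale-invariant:
#' rescaling both EC50s by the same factor leaves it unchanged.
#'
#' @inheritParams mdr
#' @return Nonnegative percent deviation.
#' @export
relative_deviation <- function(ec50_predicted, ec50_observed) {
  if (any(ec50_observed <= 0)) {
    stop("observed EC50 must be positive", call. = FALSE)
  }
  100 * abs(ec50_predicted - ec50_observed) / ec50_observed
}

#' Classify mixture behaviour from an MDR value
#'
#' Applies the assay's MDR mapping — values above unity alert to antagonism,
#' below unity to synergism, unity itself to additive behaviour — with a
#' configurable tolerance band around 1 inside which behaviour is called
#' additive. The MDR is taken under the predicted/observed convention. Band
#' edges belong to the non-additive classes (an MDR sitting exactly on the
#' band boundary is already an alert).
#'
#' Note this mapping follows the source assay's stated reading of the MDR and
#' is the reverse of the Belden convention common elsewhere in mixture
#' toxicology; adjust `band` (or swap labels downstream) if the other reading
#' is wanted.
#'
#' @param mdr_value Positive MDR value(s) (predicted/observed).
#' @param band Length-2 numeric `(low, high)` additive band, default
#'   `c(0.5, 2)`.
#' @return Character vector: `"synergistic"` (`mdr <= low`), `"additive"`
#'   (`low < mdr < high`) or `"antagonistic"` (`mdr >= high`).
#' @export
classify_behavior <- function(mdr_value, band = c(0.5, 2)) {
  stopifnot(length(band) == 2L, band[1L] > 0, band[2L] > band[1L])
  if (any(mdr_value <= 0)) stop("MDR must be positive", call. = FALSE)
  ifelse(mdr_value <= band[1L], "synergistic",
         ifelse(mdr_value >= band[2L], "antagonistic", "additive"))
}

#' RMSE and mean absolute error of predicted inhibition
#'
#' Error summary on the inhibition fraction scale (0-1): root-mean-squared
#' error as a fraction and mean absolute error in percent.
#'
#' @param predicted,observed Equal-length vectors of inhibition fractions.
#' @return Named vector `c(rmse = ..., mae_pct = ...)`.
#' @export
error_summary <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed)) {
    stop("predicted and observed must be nonempty and of equal length",
         call. = FALSE)
  }
  d <- predicted - observed
  c(rmse = sqrt(mean(d^2)), mae_pct = 100 * mean(abs(d)))
}

#' Pearson product-moment correlation
#'
#' Sample Pearson correlation of two vectors, with explicit validation of the
#' degenerate cases (fewer than two points, zero variance).
#'
#' @param xs,ys Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 2L) {
    stop("need at least two paired observations", call. = FALSE)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(xs, ys)
}

#' Recommended water-quality limits for Atlantic salmon RAS
#'
#' The built-in recommended limit concentrations of the five stressors for
#' Atlantic salmon farming in recirculating aquaculture systems, in mg/L.
#' Where the recommendation is a range, the lower bound acts as the warning
#' threshold and the upper bound as the alarm threshold; single-valued limits
#' serve as both.
#'
#' @return Data.frame with columns `substance`, `warning_mg_L`, `alarm_mg_L`.
#' @export
water_limits <- function() {
  data.frame(
    substance    = c("nitrite", "ammonia", "copper", "aluminum", "zinc"),
    warning_mg_L = c(0.1, 0.030, 0.0006, 0.015, 0.053),
    alarm_mg_L   = c(0.1, 0.146, 0.030, 0.020, 0.053),
    stringsAsFactors = FALSE
  )
}

#' Check measured concentrations against water-quality limits
#'
#' Per-substance early-warning status: `"ok"` below the warning threshold,
#' `"warning"` at or above it, `"alarm"` at or above the alarm threshold.
#' Thresholds are inclusive. Molar inputs are converted to mg/L through the
#' substance registry before comparison.
#'
#' @param substance Character vector of substance names.
#' @param concentration Measured concentrations.
#' @param unit Unit of the measurements: `"mg/L"`, `"mM"` or `"M"` (scalar or
#'   per-measurement).
#' @param limits Limit table, by default [water_limits()].
#' @return Data.frame with `substance`, `concentration_mg_L`, `status`, and
#'   the triggering threshold (`threshold_mg_L`, `NA` when ok).
#' @export
#' @examples
#' limit_alert(c("nitrite", "zinc"), c(0.05, 9e-4), unit = c("mg/L", "mM"))
limit_alert <- function(substance, concentration, unit = "mg/L",
                        limits = water_limits()) {
  stopifnot(length(substance) == length(concentration))
  unit <- rep_len(unit, length(substance))
  key <- normalize_substance(substance)
  idx <- match(key, normalize_substance(limits$substance))
  if (anyNA(idx)) {
    stop("no limit configured for: ",
         paste(unique(substance[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mgL <- vapply(seq_along(substance), function(i) {
    switch(unit[i],
           "mg/L" = concentration[i],
           "mM"   = molar_to_mass(concentration[i] / 1000, substance[i]),
           "M"    = molar_to_mass(concentration[i], substance[i]),
           stop("unknown unit: ", unit[i], call. = FALSE))
  }, numeric(1))
  warn <- limits$warning_mg_L[idx]
  alarm <- limits$alarm_mg_L[idx]
  status <- ifelse(mgL >= alarm, "alarm",
                   ifelse(mgL >= warn, "warning", "ok"))
  data.frame(
    substance = key,
    concentration_mg_L = mgL,
    status = status,
    threshold_mg_L = ifelse(status == "alarm", alarm,
                            ifelse(status == "warning", warn, NA_real_)),
    stringsAsFactors = FALSE
  )
}

#' Evaluate LCA and LIA predictions for mixture rays
#'
#' End-to-end evaluation of one or more rays against observed inhibition
#' data: fits the observed four-parameter logit curve of each ray (observed
#' EC50), builds the LCA and LIA linearised models, pushes the raw CA/IA EC50
#' through them, and summarises MDR, relative deviation and behaviour class.
#'
#' @param observed Data.frame with columns `ray_id`, `total_concentration_M`
#'   and `inhibition_pct` (one row per well/dilution).
#' @param rays Named list of [mixture_ray()]s (names = ray ids).
#' @param curves Named list of per-substance [tox_curve()]s.
#' @param models Which linearised models to evaluate.
#' @param mdr_convention Convention for the reported MDR column.
#' @param band Additive band for [classify_behavior()] (applied to the
#'   predicted/observed MDR regardless of the reported convention).
#' @param effect_pct Effect level evaluated (default 50).
#' @return Data.frame of class `ray_evaluation`: one row per ray x model with
#'   `b0`, `b1`, `pearson_r`, `ec50_pred_M`, `ec50_obs_M`, `mdr`,
#'   `deviation_pct`, `behavior`.
#' @export
evaluate_rays <- function(observed, rays, curves,
                          models = c("LCA", "LIA"),
                          mdr_convention = "predicted_over_observed",
                          band = c(0.5, 2), effect_pct = 50) {
  models <- match.arg(models, several.ok = TRUE)
  need <- c("ray_id", "total_concentration_M", "inhibition_pct")
  if (!all(need %in% names(observed))) {
    stop("observed must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(as.character(observed$ray_id))
  missing <- setdiff(ids, names(rays))
  if (length(missing) > 0L) {
    stop("observed data references unknown ray(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (id in ids) {
    obs <- observed[observed$ray_id == id, , drop = FALSE]
    ofit <- fit_logit(log10(obs$total_concentration_M), obs$inhibition_pct,
                      unit = "M", subject = paste0("ray_", id))
    ec50_obs <- 10^ofit$log_xc
    for (mk in models) {
      lin <- linearize(obs$total_concentration_M, obs$inhibition_pct,
                       rays[[id]], curves,
                       predictor = if (mk == "LCA") "CA" else "IA")
      ec50_pred <- model_ec50(lin, rays[[id]], curves, effect_pct)
      m <- as.numeric(mdr(ec50_pred, ec50_obs, mdr_convention))
      rows[[length(rows) + 1L]] <- data.frame(
        ray_id = id, model = mk,
        b0 = lin$b0, b1 = lin$b1, pearson_r = lin$pearson_r,
        ec50_pred_M = ec50_pred, ec50_obs_M = ec50_obs,
        mdr = m,
        deviation_pct = relative_deviation(ec50_pred, ec50_obs),
        behavior = classify_behavior(ec50_pred / ec50_obs, band),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mdr_convention") <- mdr_convention
  class(out) <- c("ray_evaluation", class(out))
  out
}

#' Evaluate simulated or measured mixture plates
#'
#' Convenience wrapper: converts raw plate luminescence to inhibition with
#' [plate_inhibition()] and runs [evaluate_rays()].
#'
#' @param plate Plate data.frame (mixture wells must carry `ray_id` and total
#'   molar `concentration` with unit `"M"`).
#' @inheritParams evaluate_rays
#' @return See [evaluate_rays()].
#' @export
evaluate_plates <- function(plate, rays, curves, ...) {
  inh <- plate_inhibition(plate)
  inh <- inh[!is.na(inh$ray_id) & inh$ray_id != "", , drop = FALSE]
  observed <- data.frame(ray_id = inh$ray_id,
                         total_concentration_M = inh$concentration,
                         inhibition_pct = inh$inhibition_pct,
                         stringsAsFactors = FALSE)
  evaluate_rays(observed, rays, curves, ...)
}
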