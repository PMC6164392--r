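#' Construct a four-parameter logit dose-response curve
#'
#' The curve model is the four-parameter log-logistic ("logit") in log10
#' concentration space,
#' \deqn{y = A_L + \frac{A_H - A_L}{1 + 10^{\,p\,(\log_{10} x_c - \log_{10} x)}}}
#' where `y` is percent inhibition of bioluminescence, `x` the concentration,
#' `x_c` the central concentration (EC50 when `A_L = 0, A_H = 100`), `p` the
#' slope and `A_L`, `A_H` the lower and upper inhibition limits.
#'
#' @param subject Stressor name or mixture-ray id the curve describes.
#' @param p Slope (nonzero; positive for inhibition increasing with
#'   concentration).
#' @param log_xc log10 of the central concentration, in `unit`.
#' @param AL,AH Lower and upper inhibition limits in percent (`AH > AL`).
#' @param unit Concentration unit of `x_c`: `"mg/L"`, `"mM"` or `"M"`.
#' @return An object of class `tox_curve`.
#' @seealso [logit_effect()], [ecx()], [fit_logit()]
#' @export
#' @examples
#' ammonia <- tox_curve("ammonia", p = 3.741, log_xc = -0.24315)
#' logit_effect(ammonia, log_xc(ammonia))  # 50 at the centre
tox_curve <- function(subject, p, log_xc, AL = 0, AH = 100, unit = "mg/L") {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(log_xc), length(log_xc) == 1L, is.finite(log_xc))
  if (p == 0) stop("slope p must be nonzero", call. = FALSE)
  if (!is.finite(AL) || !is.finite(AH) || AH <= AL) {
    stop("limits must satisfy AH > AL", call. = FALSE)
  }
  unit <- match.arg(unit, c("mg/L", "mM", "M"))
  structure(
    list(subject = as.character(subject), p = p, log_xc = log_xc,
         AL = AL, AH = AH, unit = unit),
    class = "tox_curve"
  )
}

#' @rdname tox_curve
#' @param x A `tox_curve`.
#' @export
log_xc <- function(x) {
  stopifnot(inherits(x, "tox_curve"))
  x$log_xc
}

#' @export
print.tox_curve <- function(x, ...) {
  cat("Four-parameter logit dose-response curve:", x$subject, "\n")
  cat(sprintf("  slope p = %.5g, log10(xc) = %.5g (%s), limits [%g, %g] %%\n",
              x$p, x$log_xc, x$unit, x$AL, x$AH))
  cat(sprintf("  EC50 = %.4g %s\n", 10^x$log_xc, x$unit))
  invisible(x)
}

#' @export
coef.tox_curve <- function(object, ...) {
  c(p = object$p, log_xc = object$log_xc, AL = object$AL, AH = object$AH)
}

#' Evaluate a logit dose-response curve
#'
#' Predicted percent inhibition at the given log10 concentration(s), in the
#' curve's own unit. Strictly increasing in concentration for `p > 0`,
#' approaching `AL` as concentration tends to 0 and `AH` as it grows.
#'
#' @param curve A [tox_curve()].
#' @param log10_concentration Numeric vector of log10 concentrations
#'   (`-Inf` allowed, giving the zero-dose limit).
#' @return Percent inhibition, same length as `log10_concentration`.
#' @export
logit_effect <- function(curve, log10_concentration) {
  stopifnot(inherits(curve, "tox_curve"))
  expo <- curve$p * (curve$log_xc - log10_concentration)
  # zero dose: exponent +/-Inf depending on sign of p
  eff <- curve$AL + (curve$AH - curve$AL) / (1 + 10^expo)
  eff[is.infinite(log10_concentration) & log10_concentration < 0] <-
    if (curve$p > 0) curve$AL else curve$AH
  eff
}

#' Effect concentration (ECx) of a logit curve
#'
#' Inverts the curve to the concentration giving `effect_pct` percent
#' inhibition:
#' \deqn{\log_{10} EC_x = \log_{10} x_c + \frac{\log_{10}(E / (100 - E))}{p}}
#' for curves normalised to limits (0, 100); for free limits the effect is
#' rescaled into `(AL, AH)` first. `ecx(curve, 50)` equals `10^log_xc`.
#'
#' @param curve A [tox_curve()].
#' @param effect_pct Effect level(s) in percent, strictly inside `(AL, AH)`
#'   (i.e. `(0, 100)` for the default limits).
#' @return Concentration(s) in the curve's unit.
#' @export
ecx <- function(curve, effect_pct) {
  stopifnot(inherits(curve, "tox_curve"))
  f <- (effect_pct - curve$AL) / (curve$AH - curve$AL)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    stop("effect_pct must lie strictly between the curve limits (",
         curve$AL, ", ", curve$AH, ")", call. = FALSE)
  }
  10^(curve$log_xc + log10(f / (1 - f)) / curve$p)
}

#' Convert a curve to molar concentration units
#'
#' Rescaling a log-logistic curve to a new concentration unit only shifts its
#' log-centre; the slope and limits are unchanged. Curves in mg/L require the
#' substance's molar mass (looked up in the registry by the curve's subject
#' unless `substance` is given).
#'
#' @param curve A [tox_curve()].
#' @param substance Substance used for the mg/L -> M conversion; defaults to
#'   the curve's subject.
#' @param registry Substance registry.
#' @return A `tox_curve` in unit `"M"`.
#' @export
as_molar_curve <- function(curve, substance = curve$subject,
                           registry = substance_registry()) {
  stopifnot(inherits(curve, "tox_curve"))
  shift <- switch(curve$unit,
    "M"    = 0,
    "mM"   = -3,
    "mg/L" = -log10(1000 * molar_mass(substance, registry))
  )
  out <- curve
  out$log_xc <- curve$log_xc + shift
  out$unit <- "M"
  out
}

#' Inhibition from paired-timepoint luminescence
#'
#' Percent inhibition by control-normalised decrease of bioluminescence over
#' the 5-minute exposure, accounting for the initial luminescence of each
#' well:
#' \deqn{I = 100 \left(1 - \frac{L_5 / L_0}{C_5 / C_0}\right)}
#' where `L` is the sample well and `C` the negative control. Values can be
#' negative (luminescence stimulation / hormesis); they are returned
#' unclipped.
#'
#' @param lum_t0,lum_t5 Sample luminescence at contact and after 5 min.
#' @param control_t0,control_t5 Negative-control luminescence at the same
#'   timepoints.
#' @return Percent inhibition (vectorised over the sample readings).
#' @export
#' @examples
#' inhibition_from_luminescence(100, 40, 100, 80)  # 50
inhibition_from_luminescence <- function(lum_t0, lum_t5, control_t0, control_t5) {
  if (any(lum_t0 <= 0) || any(control_t0 <= 0)) {
    stop("invalid reading: luminescence at t0 must be positive", call. = FALSE)
  }
  if (any(lum_t5 < 0) || any(control_t5 < 0)) {
    stop("invalid reading: luminescence cannot be negative", call. = FALSE)
  }
  if (any(control_t5 == 0)) {
    stop("degenerate control: zero luminescence at t5", call. = FALSE)
  }
  100 * (1 - (lum_t5 / lum_t0) / (control_t5 / control_t0))
}

#' Compute well inhibition for a whole plate
#'
#' Normalises every `sample` well of a plate table against the mean
#' luminescence ratio of that plate's negative controls, grouped by `ray_id`
#' when present (each ray / single-stressor series carries its own controls).
#'
#' @param plate Plate data.frame with columns `well_id`, `role`, `ray_id`,
#'   `dilution_factor`, `concentration`, `unit`, `lum_t0`, `lum_t5`
#'   (see [read_plate_csv()]).
#' @return The sample rows with an added `inhibition_pct` column and a
#'   `stimulation` flag (`TRUE` where inhibition is negative).
#' @export
plate_inhibition <- function(plate) {
  required <- c("role", "lum_t0", "lum_t5")
  if (!all(required %in% names(plate))) {
    stop("plate table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!any(plate$role == "negative_control")) {
    stop("plate has no negative_control wells", call. = FALSE)
  }
  grp <- if ("ray_id" %in% names(plate)) as.character(plate$ray_id) else ""
  grp[is.na(grp)] <- ""
  samples <- plate[plate$role == "sample", , drop = FALSE]
  sgrp <- grp[plate$role == "sample"]
  inhib <- vapply(seq_len(nrow(samples)), function(i) {
    ctrl <- plate[plate$role == "negative_control" & grp == sgrp[i], , drop = FALSE]
    if (nrow(ctrl) == 0L) {  # fall back to plate-wide controls
      ctrl <- plate[plate$role == "negative_control", , drop = FALSE]
    }
    ratio <- mean(ctrl$lum_t5 / ctrl$lum_t0)
    inhibition_from_luminescence(samples$lum_t0[i], samples$lum_t5[i],
                                 1, ratio)
  }, numeric(1))
  samples$inhibition_pct <- inhib
  samples$stimulation <- inhib < 0
  samples
}

#' Reference single-stressor dose-response curves
#'
#' The published logit parameters of the five stressors against
#' *Aliivibrio fischeri* (slope, log10 centre in mg/L, limits fixed at 0/100)
#' together with the published molar EC50. Note the documented anomaly: for
#' zinc and copper the published molar EC50 column is cross-swapped with
#' respect to the logit parameters (each row's parameters reproduce the
#' other's EC50).
#'
#' @param as_curves If `TRUE` return a named list of [tox_curve()] objects
#'   (in mg/L); otherwise a data.frame mirroring the published table.
#' @return Data.frame with columns `subject_id`, `ec50_M`, `p`, `log_xc`,
#'   `AL`, `AH`, `unit`, or a list of curves.
#' @export
reference_curves <- function(as_curves = FALSE) {
  tab <- data.frame(
    subject_id = c("nitrite", "ammonia", "zinc", "aluminum", "copper"),
    ec50_M     = c(3.66e-6, 3.35e-5, 5.83e-6, 4.41e-7, 1.22e-6),
    p          = c(0.26432, 3.741, 2.88562, 2.00837, 8.05861),
    log_xc     = c(-0.77343, -0.24315, -1.09769, -1.92469, -0.431),
    AL         = 0, AH = 100, unit = "mg/L",
    stringsAsFactors = FALSE
  )
  if (!as_curves) return(tab)
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    tox_curve(tab$subject_id[i], tab$p[i], tab$log_xc[i],
              tab$AL[i], tab$AH[i], tab$unit[i])
  })
  names(curves) <- tab$subject_id
  curves
}
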