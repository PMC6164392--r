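#' Parse scientific-notation numbers, including typeset forms
#'
#' Accepts ordinary R numerics ("3.66E-06") as well as the typeset variant
#' found in published tables ("3.66 × 10−6", with multiplication
#' sign, unicode minus and optional superscripts stripped by text
#' extraction).
#'
#' @param x Character vector.
#' @return Numeric vector (`NA` for unparseable entries).
#' @export
parse_scientific <- function(x) {
  x <- as.character(x)
  x <- gsub("−", "-", x)                     # unicode minus
  x <- gsub("\\s*[×x]\\s*10\\^?", "e", x)    # "a x 10^b" -> "aeb"
  x <- gsub("[\\^\\s%]", "", x, perl = TRUE)
  suppressWarnings(as.numeric(x))
}

plate_columns <- c("well_id", "role", "ray_id", "dilution_factor",
                   "concentration", "unit", "lum_t0", "lum_t5")

#' Read and write plate-luminescence CSV tables
#'
#' Plate tables carry one row per well: `well_id`, `role` (`sample`,
#' `negative_control`, `positive_control`), optional `ray_id`, the
#' `dilution_factor` (1 = undiluted), the nominal `concentration` with its
#' `unit` (`mg/L`, `mM` or `M`), and paired luminescence readings `lum_t0`
#' (at contact) and `lum_t5` (after 5 min). UTF-8, '.' decimal separator,
#' header required; numbers in either plain or typeset scientific notation.
#'
#' @param path File path.
#' @param plate Plate data.frame to write.
#' @return `read_plate_csv()`: a validated plate data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L) stop("parse error: empty plate CSV: ", path, call. = FALSE)
  missing <- setdiff(plate_columns, names(df))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("dilution_factor", "concentration", "lum_t0", "lum_t5")) {
    if (!is.numeric(df[[col]])) df[[col]] <- parse_scientific(df[[col]])
  }
  bad <- which(!df$role %in% c("sample", "negative_control", "positive_control"))
  if (length(bad) > 0L) {
    stop("parse error in ", path, ": invalid role at data line ", bad[1L],
         call. = FALSE)
  }
  if (any(df$dilution_factor < 1, na.rm = TRUE)) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  has_conc <- !is.na(df$concentration) & df$concentration > 0
  if (any(has_conc & (is.na(df$unit) | df$unit == ""))) {
    stop("unit must be declared wherever a concentration is present",
         call. = FALSE)
  }
  df
}

#' @rdname read_plate_csv
#' @export
write_plate_csv <- function(plate, path) {
  missing <- setdiff(plate_columns, names(plate))
  if (length(missing) > 0L) {
    stop("plate table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(plate[, plate_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write fitted-curve CSV tables
#'
#' Curve tables mirror the published parameter layout: one row per subject
#' with `subject_id`, slope `p`, `log_xc`, limits `AL`, `AH` and the
#' concentration `unit`.
#'
#' @param path File path.
#' @param curves Either a data.frame with the columns above or a (named) list
#'   of [tox_curve()]s.
#' @param as_curves If `TRUE`, return a named list of [tox_curve()]s.
#' @return Data.frame or list of curves.
#' @export
read_curve_csv <- function(path, as_curves = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("subject_id", "p", "log_xc", "AL", "AH", "unit")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("p", "log_xc", "AL", "AH")) {
    if (!is.numeric(df[[col]])) df[[col]] <- parse_scientific(df[[col]])
  }
  if (!as_curves) return(df)
  out <- lapply(seq_len(nrow(df)), function(i) {
    tox_curve(df$subject_id[i], df$p[i], df$log_xc[i], df$AL[i], df$AH[i],
              df$unit[i])
  })
  names(out) <- df$subject_id
  out
}

#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curves, path) {
  if (!is.data.frame(curves)) {
    curves <- do.call(rbind, lapply(curves, function(cv) {
      data.frame(subject_id = cv$subject, p = cv$p, log_xc = cv$log_xc,
                 AL = cv$AL, AH = cv$AH, unit = cv$unit,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(curves, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write mixture-ray composition CSV tables
#'
#' Ray tables carry one row per ray x component: `ray_id`, `substance`,
#' `top_concentration_mM`. An optional `printed_total_mM` column, when
#' present, is validated against the recomputed component sum (1% relative
#' tolerance, matching 3-significant-figure rounding).
#'
#' @param path File path.
#' @param rays Data.frame in the above layout or a list of [mixture_ray()]s.
#' @param as_rays If `TRUE` return a named list of [mixture_ray()]s.
#' @param dilution_factors Dilution series attached to constructed rays.
#' @return Data.frame or list of rays.
#' @export
read_ray_csv <- function(path, as_rays = FALSE,
                         dilution_factors = c(1, 2, 4, 8, 16, 32, 64)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("ray_id", "substance", "top_concentration_mM")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$top_concentration_mM)) {
    df$top_concentration_mM <- parse_scientific(df$top_concentration_mM)
  }
  df$ray_id <- as.character(df$ray_id)
  if ("printed_total_mM" %in% names(df)) {
    if (!is.numeric(df$printed_total_mM)) {
      df$printed_total_mM <- parse_scientific(df$printed_total_mM)
    }
    for (id in unique(df$ray_id)) {
      sub <- df[df$ray_id == id, ]
      tot <- sum(sub$top_concentration_mM)
      printed <- sub$printed_total_mM[1L]
      if (is.finite(printed) && abs(tot - printed) / printed > 0.01) {
        stop("ray ", id, ": component sum ", signif(tot, 4),
             " mM disagrees with declared total ", printed, " mM", call. = FALSE)
      }
    }
  }
  if (!as_rays) return(df)
  out <- lapply(unique(df$ray_id), function(id) {
    sub <- df[df$ray_id == id, ]
    mixture_ray(id, sub$substance, sub$top_concentration_mM, unit = "mM",
                dilution_factors = dilution_factors)
  })
  names(out) <- unique(df$ray_id)
  out
}

#' @rdname read_ray_csv
#' @export
write_ray_csv <- function(rays, path) {
  if (!is.data.frame(rays)) {
    rays <- do.call(rbind, lapply(rays, function(r) {
      data.frame(ray_id = r$ray_id,
                 substance = r$components$substance,
                 top_concentration_mM = r$components$top_M * 1000,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(rays, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a ray-evaluation table
#'
#' Persists the output of [evaluate_rays()] (`ray_id`, `model`,
#' `ec50_pred_M`, `ec50_obs_M`, `mdr`, `deviation_pct`, `behavior`, plus the
#' regression columns) as CSV with "E"-notation numbers.
#'
#' @param evaluation A `ray_evaluation` data.frame.
#' @param path File path.
#' @export
write_evaluation_csv <- function(evaluation, path) {
  utils::write.csv(as.data.frame(evaluation), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit dose-response curves for every subject on a plate
#'
#' Orchestration for single-stressor plates: computes well inhibition with
#' [plate_inhibition()], groups sample wells by subject (`ray_id` column),
#' fits a four-parameter logit curve per subject with [fit_logit()], and
#' returns the curve table plus a per-subject fit report.
#'
#' @param plate Plate data.frame or path to a plate CSV.
#' @param fix_limits As in [fit_logit()].
#' @param stim_floor As in [fit_logit()].
#' @return List with `curves` (named list of fits), `table` (curve CSV
#'   layout) and `report` (per-subject n, exclusions, RMSE).
#' @export
fit_plate_curves <- function(plate, fix_limits = c(0, 100), stim_floor = -10) {
  if (is.character(plate)) plate <- read_plate_csv(plate)
  inh <- plate_inhibition(plate)
  subjects <- unique(inh$ray_id)
  fits <- list(); report <- list()
  for (s in subjects) {
    sub <- inh[inh$ray_id == s & !is.na(inh$concentration) &
                 inh$concentration > 0, , drop = FALSE]
    fit <- fit_logit(log10(sub$concentration), sub$inhibition_pct,
                     fix_limits = fix_limits, unit = sub$unit[1L],
                     subject = s, stim_floor = stim_floor)
    fits[[s]] <- fit
    report[[s]] <- data.frame(subject_id = s, n_used = fit$n_used,
                              n_excluded = fit$n_excluded,
                              n_stimulation = fit$n_flagged_stimulation,
                              rmse = sqrt(mean(fit$residuals^2)),
                              stringsAsFactors = FALSE)
  }
  list(curves = fits,
       table = do.call(rbind, lapply(fits, function(cv) {
         data.frame(subject_id = cv$subject, p = cv$p, log_xc = cv$log_xc,
                    AL = cv$AL, AH = cv$AH, unit = cv$unit,
                    stringsAsFactors = FALSE)
       })),
       report = do.call(rbind, report))
}

#' Check a measurements table against the water-quality limits
#'
#' Orchestration for the early-warning check: reads a measurements table
#' (columns `substance`, `concentration`, `unit`) and returns the
#' [limit_alert()] report.
#'
#' @param measurements Data.frame or CSV path.
#' @param limits Limit table, by default [water_limits()].
#' @return Alert data.frame from [limit_alert()].
#' @export
check_water_limits <- function(measurements, limits = water_limits()) {
  if (is.character(measurements)) {
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE,
                                    encoding = "UTF-8")
  }
  need <- c("substance", "concentration", "unit")
  missing <- setdiff(need, names(measurements))
  if (length(missing) > 0L) {
    stop("measurements must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(measurements$concentration)) {
    measurements$concentration <- parse_scientific(measurements$concentration)
  }
  limit_alert(measurements$substance, measurements$concentration,
              measurements$unit, limits)
}
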