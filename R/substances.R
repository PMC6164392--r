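#' Built-in substance registry
#'
#' The five fish-health stressors studied in the bioluminescence assay, with
#' the molar masses used to convert between mass (mg/L) and molar (M)
#' concentrations: nitrite ion (NO2-), un-ionized ammonia (NH3-N), copper,
#' aluminum and zinc. Molar masses are standard atomic/formula weights in
#' g/mol.
#'
#' @return A data.frame with columns `substance` and `molar_mass` (g/mol).
#' @export
#' @examples
#' substance_registry()
substance_registry <- function() {
  data.frame(
    substance  = c("nitrite", "ammonia", "copper", "aluminum", "zinc"),
    molar_mass = c(46.005, 17.031, 63.546, 26.982, 65.38),
    stringsAsFactors = FALSE
  )
}

# Canonicalise user-facing substance labels ("Un-ionized ammonia",
# "Nitrite (NO2-)", ...) onto registry keys.
normalize_substance <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- sub("\\s*\\(.*\\)$", "", key)
  key[key %in% c("un-ionized ammonia", "unionized ammonia", "nh3", "nh3-n")] <- "ammonia"
  key[key %in% c("no2", "no2-", "nitrite ion")] <- "nitrite"
  key[key %in% c("cu")] <- "copper"
  key[key %in% c("al", "aluminium")] <- "aluminum"
  key[key %in% c("zn")] <- "zinc"
  key
}

#' Molar mass of a registered substance
#'
#' @param substance Substance name (case-insensitive; common synonyms such as
#'   "un-ionized ammonia" or "NO2-" are recognised).
#' @param registry Registry data.frame, by default [substance_registry()].
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(substance, registry = substance_registry()) {
  key <- normalize_substance(substance)
  idx <- match(key, registry$substance)
  if (anyNA(idx)) {
    stop("unknown substance(s): ",
         paste(unique(substance[is.na(idx)]), collapse = ", "),
         " (not in registry)", call. = FALSE)
  }
  registry$molar_mass[idx]
}

#' Convert between mass and molar concentration
#'
#' `mass_to_molar()` converts mg/L to mol/L (M); `molar_to_mass()` is the
#' exact inverse. Conversions go through the substance registry, e.g.
#' nitrite 0.1 mg/L is 2.17e-6 M (2.17e-3 mM).
#'
#' @param mg_per_L Concentration in mg/L (nonnegative).
#' @param molar Concentration in mol/L.
#' @param substance Substance name resolvable in the registry.
#' @param registry Registry data.frame.
#' @return Numeric vector of converted concentrations.
#' @export
mass_to_molar <- function(mg_per_L, substance, registry = substance_registry()) {
  if (any(mg_per_L < 0, na.rm = TRUE)) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  mg_per_L / 1000 / molar_mass(substance, registry)
}

#' @rdname mass_to_molar
#' @export
molar_to_mass <- function(molar, substance, registry = substance_registry()) {
  if (any(molar < 0, na.rm = TRUE)) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  molar * 1000 * molar_mass(substance, registry)
}
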