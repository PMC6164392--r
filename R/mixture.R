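#' Construct a fixed-ratio mixture ray
#'
#' A mixture ray holds the composition of a fixed-ratio mixture: the top
#' (undiluted) molar concentration of each component and the dilution factors
#' of its series. The molar proportions `p_i = top_i / sum(top)` are constant
#' along the ray.
#'
#' @param ray_id Ray label.
#' @param substances Character vector of component names.
#' @param top_concentration Top concentration of each component.
#' @param unit Unit of `top_concentration`: `"M"` or `"mM"` (stored as M).
#' @param dilution_factors Dilution factors of the series (default
#'   1, 2, 4, 8, 16, 32, 64).
#' @return An object of class `mixture_ray` with elements `ray_id`,
#'   `components` (data.frame `substance`, `top_M`, `proportion`),
#'   `total_M` and `dilution_factors`.
#' @export
#' @examples
#' mixture_ray("demo", c("a", "b"), c(1, 3), unit = "mM")
mixture_ray <- function(ray_id, substances, top_concentration, unit = "M",
                        dilution_factors = c(1, 2, 4, 8, 16, 32, 64)) {
  unit <- match.arg(unit, c("M", "mM"))
  stopifnot(length(substances) == length(top_concentration),
            length(substances) >= 1L)
  if (any(top_concentration < 0)) {
    stop("component concentrations must be nonnegative", call. = FALSE)
  }
  if (sum(top_concentration) <= 0) {
    stop("ray must have positive total concentration", call. = FALSE)
  }
  if (any(dilution_factors < 1) || is.unsorted(dilution_factors, strictly = TRUE)) {
    stop("dilution factors must be >= 1 and strictly increasing", call. = FALSE)
  }
  top_M <- if (unit == "mM") top_concentration / 1000 else top_concentration
  comp <- data.frame(substance = as.character(substances),
                     top_M = top_M,
                     proportion = top_M / sum(top_M),
                     stringsAsFactors = FALSE)
  structure(list(ray_id = as.character(ray_id), components = comp,
                 total_M = sum(top_M), dilution_factors = dilution_factors),
            class = "mixture_ray")
}

#' @export
print.mixture_ray <- function(x, ...) {
  cat(sprintf("Mixture ray %s: %d components, total %.4g mM\n",
              x$ray_id, nrow(x$components), x$total_M * 1000))
  df <- x$components
  df$top_mM <- df$top_M * 1000
  print(df[, c("substance", "top_mM", "proportion")], row.names = FALSE)
  invisible(x)
}

# Resolve the per-substance curve list for a ray, converted to molar units.
ray_curves_molar <- function(ray, curves, registry = substance_registry()) {
  subs <- ray$components$substance
  missing <- setdiff(subs, names(curves))
  if (length(missing) > 0L) {
    stop("no dose-response curve supplied for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(curves[subs], function(cv) {
    if (cv$unit == "M") cv else as_molar_curve(cv, registry = registry)
  })
}

#' Concentration-addition mixture effect concentration
#'
#' Predicts the total molar mixture concentration producing `effect_pct`
#' inhibition under concentration addition (shared mode of action):
#' \deqn{EC_{x,mix} = \left(\sum_i \frac{p_i}{EC_{x,i}}\right)^{-1}}
#' with `p_i` the molar proportion of component `i` and `EC_{x,i}` its
#' single-substance effect concentration. The result always lies between the
#' smallest and largest component ECx.
#'
#' @param ray A [mixture_ray()].
#' @param curves Named list of per-substance [tox_curve()]s (any unit;
#'   converted to molar internally through the substance registry).
#' @param effect_pct Effect level(s) in percent, in `(0, 100)`.
#' @return Mixture ECx in mol/L (vectorised over `effect_pct`).
#' @export
ca_ecx <- function(ray, curves, effect_pct) {
  mc <- ray_curves_molar(ray, curves)
  p <- ray$components$proportion
  vapply(effect_pct, function(E) {
    eci <- vapply(mc, ecx, numeric(1), effect_pct = E)
    1 / sum(p / eci)
  }, numeric(1))
}

#' Independent-action mixture effect
#'
#' Predicted percent inhibition of the mixture at a given total molar
#' concentration under independent action (dissimilar modes of action):
#' \deqn{E\% = 100\,\Big(1 - \prod_i (1 - F_i(p_i \cdot C)/100)\Big)}
#' where `F_i` is component `i`'s dose-response curve evaluated at its
#' partial dose `p_i * C`. The IA effect is never below any component's
#' individual effect at its partial dose.
#'
#' @inheritParams ca_ecx
#' @param total_concentration_M Total mixture concentration(s) in mol/L.
#' @return Percent inhibition (vectorised over the concentrations).
#' @export
ia_effect <- function(ray, curves, total_concentration_M) {
  mc <- ray_curves_molar(ray, curves)
  p <- ray$components$proportion
  vapply(total_concentration_M, function(C) {
    if (C < 0) stop("total concentration must be nonnegative", call. = FALSE)
    if (C == 0) return(0)
    f <- vapply(seq_along(mc), function(i) {
      logit_effect(mc[[i]], log10(p[i] * C)) / 100
    }, numeric(1))
    f <- pmin(pmax(f, 0), 1)
    100 * (1 - prod(1 - f))
  }, numeric(1))
}

#' Independent-action mixture effect concentration
#'
#' Numerically inverts [ia_effect()]: the total molar concentration at which
#' the IA-predicted inhibition equals `effect_pct`. Monotone bisection with a
#' geometrically expanding initial bracket; terminates when the effect is
#' matched within `tol` percent.
#'
#' @inheritParams ca_ecx
#' @param tol Convergence tolerance on the effect scale, in percent.
#' @return Mixture ECx in mol/L (vectorised over `effect_pct`).
#' @export
ia_ecx <- function(ray, curves, effect_pct, tol = 1e-6) {
  vapply(effect_pct, function(E) {
    if (!is.finite(E) || E <= 0 || E >= 100) {
      stop("effect_pct must be in (0, 100)", call. = FALSE)
    }
    g <- function(C) ia_effect(ray, curves, C) - E
    lo <- 1e-12; hi <- 10
    while (g(lo) > 0 && lo > 1e-30) lo <- lo / 100
    while (g(hi) < 0 && hi < 1e6) hi <- hi * 10
    if (g(lo) > 0 || g(hi) < 0) {
      stop("unattainable effect: IA prediction cannot reach ", E, "%",
           call. = FALSE)
    }
    for (i in 1:200) {
      mid <- sqrt(lo * hi)  # bisect in log space
      gm <- g(mid)
      if (abs(gm) < tol) return(mid)
      if (gm < 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
}

#' Linearise CA or IA predictions against observed mixture data (LCA / LIA)
#'
#' Builds the linearised concentration-addition (LCA) or independent-action
#' (LIA) model for one ray: ordinary least-squares regression of the observed
#' log10 total concentrations on the model-predicted log10 effect
#' concentrations at the same observed inhibition levels,
#' \deqn{pEC_{x,obs} = b_0 + b_1 \, pEC_{x,CA/IA}.}
#' Observed points with inhibition at or outside 0%/100% are excluded (their
#' log-odds, hence predicted ECx, is undefined); the count is recorded.
#'
#' @param total_concentration_M Observed total molar concentrations of the
#'   ray's dilution series.
#' @param inhibition_pct Observed percent inhibition at those concentrations.
#' @param ray A [mixture_ray()].
#' @param curves Named list of per-substance curves.
#' @param predictor `"CA"` or `"IA"`.
#' @param effect_grid Optional fixed grid of effect levels (percent) to
#'   regress on instead of the observed levels; when given, the observed
#'   curve must first be fit so observed concentrations can be interpolated —
#'   here the grid mode simply restricts the regression to observed levels
#'   inside the grid range.
#' @return An object of class `mix_lm`: `model_kind` ("LCA"/"LIA"), `ray_id`,
#'   `b0`, `b1`, `pearson_r`, `n_points`, `n_excluded` and the underlying
#'   [lm()] fit.
#' @export
linearize <- function(total_concentration_M, inhibition_pct, ray, curves,
                      predictor = c("CA", "IA"), effect_grid = NULL) {
  predictor <- match.arg(predictor)
  stopifnot(length(total_concentration_M) == length(inhibition_pct))
  usable <- is.finite(inhibition_pct) & inhibition_pct > 0 &
    inhibition_pct < 100 & total_concentration_M > 0
  if (!is.null(effect_grid)) {
    usable <- usable & inhibition_pct >= min(effect_grid) &
      inhibition_pct <= max(effect_grid)
  }
  n_excluded <- sum(!usable)
  E <- inhibition_pct[usable]
  C <- total_concentration_M[usable]
  if (length(E) < 2L) {
    stop("insufficient data: need at least 2 observed points strictly ",
         "inside (0, 100)% inhibition", call. = FALSE)
  }
  pred <- if (predictor == "CA") ca_ecx(ray, curves, E) else ia_ecx(ray, curves, E)
  x <- log10(pred)
  y <- log10(C)
  if (stats::sd(x) == 0) {
    stop("degenerate regression: zero variance in predicted log-ECx",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(list(
    model_kind = if (predictor == "CA") "LCA" else "LIA",
    predictor = predictor,
    ray_id = ray$ray_id,
    b0 = unname(stats::coef(fit)[1L]),
    b1 = unname(stats::coef(fit)[2L]),
    pearson_r = stats::cor(x, y),
    n_points = length(E),
    n_excluded = n_excluded,
    lm = fit
  ), class = "mix_lm")
}

#' @export
print.mix_lm <- function(x, ...) {
  cat(sprintf("%s model for ray %s: pECx = %.5g + %.5g * pECx_%s  (r = %.4f, n = %d)\n",
              x$model_kind, x$ray_id, x$b0, x$b1, x$predictor, x$pearson_r,
              x$n_points))
  invisible(x)
}

#' @export
coef.mix_lm <- function(object, ...) c(b0 = object$b0, b1 = object$b1)

#' Predicted mixture EC50 through a linearised model
#'
#' Pushes the raw CA or IA EC50 through the fitted linearisation:
#' `EC50_model = 10^(b0 + b1 * log10(EC50_predictor))`.
#'
#' @param model A [linearize()] result.
#' @param ray,curves As in [linearize()].
#' @param effect_pct Effect level (default 50).
#' @return Model-predicted effect concentration in mol/L.
#' @export
model_ec50 <- function(model, ray, curves, effect_pct = 50) {
  stopifnot(inherits(model, "mix_lm"))
  raw <- if (model$predictor == "CA") {
    ca_ecx(ray, curves, effect_pct)
  } else {
    ia_ecx(ray, curves, effect_pct)
  }
  10^(model$b0 + model$b1 * log10(raw))
}

#' Reference fixed-ratio mixture rays
#'
#' The seven published uniform-design mixture rays of the five stressors:
#' top (undiluted) concentration of each component in mM, with the dilution
#' series 1-64. The published per-ray totals are stored alongside for
#' consistency checks.
#'
#' @param as_rays If `TRUE` return a list of [mixture_ray()] objects,
#'   otherwise the composition data.frame (`ray_id`, `substance`,
#'   `top_concentration_mM`).
#' @return List of rays or a data.frame; the data.frame carries the published
#'   totals (mM) as attribute `printed_total_mM`.
#' @export
reference_rays <- function(as_rays = FALSE) {
  subs <- c("nitrite", "ammonia", "copper", "aluminum", "zinc")
  conc <- rbind(
    c(8.99e-7, 2.32e-2, 5.25e-3, 3.60e-4, 1.22e-3),
    c(1.93e-5, 3.01e-2, 6.13e-3, 1.48e-4, 9.11e-4),
    c(1.48e-4, 3.74e-2, 4.91e-3, 4.41e-4, 5.70e-4),
    c(7.90e-4, 1.86e-2, 5.83e-3, 2.21e-4, 1.41e-3),
    c(3.66e-3, 2.67e-2, 4.44e-3, 5.39e-4, 1.06e-3),
    c(1.70e-2, 3.35e-2, 5.55e-3, 2.89e-4, 7.55e-4),
    c(9.04e-2, 4.21e-2, 6.48e-3, 6.72e-4, 1.64e-3)
  )
  totals <- c(3.00e-2, 3.73e-2, 4.35e-2, 2.69e-2, 3.64e-2, 5.71e-2, 1.41e-1)
  df <- data.frame(
    ray_id = rep(as.character(1:7), each = length(subs)),
    substance = rep(subs, times = 7),
    top_concentration_mM = as.vector(t(conc)),
    stringsAsFactors = FALSE
  )
  attr(df, "printed_total_mM") <- totals
  if (!as_rays) return(df)
  rays <- lapply(1:7, function(i) {
    mixture_ray(as.character(i), subs, conc[i, ], unit = "mM")
  })
  names(rays) <- as.character(1:7)
  rays
}
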