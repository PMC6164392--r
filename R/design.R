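#' Uniform design table by good lattice points
#'
#' Constructs a uniform design U_n(n^s): `n_runs` runs for `n_factors`
#' factors, each factor taking every level 1..n exactly once. Column `j` uses
#' lattice generator `h_j` (the j-th integer in 1..n-1 coprime with n):
#' `level[i, j] = ((i * h_j - 1) mod n) + 1`. For prime `n` there are `n - 1`
#' valid generators.
#'
#' @param n_runs Number of runs (levels per factor).
#' @param n_factors Number of factors; at most the number of integers in
#'   1..n-1 coprime with `n_runs`.
#' @return An object of class `uniform_design`: list with `levels`
#'   (`n_runs x n_factors` integer matrix), `generators`, `n_runs`,
#'   `n_factors`.
#' @export
#' @examples
#' uniform_design(7, 6)
uniform_design <- function(n_runs, n_factors) {
  stopifnot(n_runs >= 2, n_factors >= 1)
  h_all <- which(vapply(seq_len(n_runs - 1),
                        function(h) gcd(h, n_runs) == 1L, logical(1)))
  if (n_factors > length(h_all)) {
    stop("capacity error: only ", length(h_all),
         " coprime generators available for n_runs = ", n_runs, call. = FALSE)
  }
  h <- h_all[seq_len(n_factors)]
  i <- seq_len(n_runs)
  levels <- outer(i, h, function(i, h) ((i * h - 1L) %% n_runs) + 1L)
  storage.mode(levels) <- "integer"
  colnames(levels) <- paste0("f", seq_len(n_factors))
  rownames(levels) <- paste0("run", i)
  structure(list(levels = levels, generators = h,
                 n_runs = n_runs, n_factors = n_factors),
            class = "uniform_design")
}

gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  as.integer(a)
}

#' @export
print.uniform_design <- function(x, ...) {
  cat(sprintf("Uniform design U_%d(%d^%d), generators: %s\n",
              x$n_runs, x$n_runs, x$n_factors,
              paste(x$generators, collapse = ", ")))
  print(x$levels)
  invisible(x)
}

#' Log-odds-equispaced effect level grid
#'
#' Default effect levels for mapping design levels onto effect
#' concentrations: `n` levels whose logit transforms are equally spaced
#' between `lo` and `hi` percent (default EC5..EC95).
#'
#' @param n Number of levels.
#' @param lo,hi Smallest and largest effect level in percent.
#' @return Numeric vector of effect percentages, increasing.
#' @export
effect_level_grid <- function(n, lo = 5, hi = 95) {
  stopifnot(n >= 1, lo > 0, hi < 100, hi > lo)
  lg <- function(E) log10(E / (100 - E))
  z <- seq(lg(lo), lg(hi), length.out = n)
  100 * 10^z / (1 + 10^z)
}

#' Build fixed-ratio mixture rays from a uniform design
#'
#' Maps each design level onto an effect level, then sets component `i`'s top
#' concentration in run `r` to its single-substance effect concentration at
#' `effect_levels[levels[r, i]]` (converted to molar units). One mixture ray
#' per design run; per component, every effect level is used exactly once
#' across runs.
#'
#' @param design A [uniform_design()]; its first `length(curves)` columns are
#'   used, in input curve order (use `shuffle_seed` for a random assignment).
#' @param curves Named list of per-substance [tox_curve()]s.
#' @param effect_levels Vector of `n_runs` effect percentages (default the
#'   log-odds-equispaced EC5..EC95 grid).
#' @param dilution_factors Dilution series attached to each ray.
#' @param shuffle_seed Optional seed for a random column-to-component
#'   assignment.
#' @return Named list of [mixture_ray()]s (`"1"`, `"2"`, ...).
#' @export
rays_from_design <- function(design, curves,
                             effect_levels = effect_level_grid(design$n_runs),
                             dilution_factors = c(1, 2, 4, 8, 16, 32, 64),
                             shuffle_seed = NULL) {
  stopifnot(inherits(design, "uniform_design"))
  k <- length(curves)
  if (k > design$n_factors) {
    stop("design has fewer factors than components", call. = FALSE)
  }
  if (length(effect_levels) != design$n_runs) {
    stop("need one effect level per design level (", design$n_runs, ")",
         call. = FALSE)
  }
  if (any(effect_levels <= 0) || any(effect_levels >= 100)) {
    stop("effect levels must be in (0, 100)", call. = FALSE)
  }
  cols <- seq_len(k)
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    cols <- sample(seq_len(design$n_factors), k)
  }
  mc <- lapply(names(curves), function(s) {
    cv <- curves[[s]]
    if (cv$unit == "M") cv else as_molar_curve(cv)
  })
  names(mc) <- names(curves)
  rays <- lapply(seq_len(design$n_runs), function(r) {
    top <- vapply(seq_len(k), function(i) {
      ecx(mc[[i]], effect_levels[design$levels[r, cols[i]]])
    }, numeric(1))
    mixture_ray(as.character(r), names(curves), top, unit = "M",
                dilution_factors = dilution_factors)
  })
  names(rays) <- as.character(seq_len(design$n_runs))
  rays
}

#' Dilution series of a mixture ray
#'
#' Expands a ray into its dilution series: total and per-component
#' concentrations at each dilution factor. Proportions are invariant along
#' the series (fixed-ratio design).
#'
#' @param ray A [mixture_ray()].
#' @param factors Dilution factors (>= 1, strictly increasing); defaults to
#'   the ray's own.
#' @return Data.frame with `dilution_factor`, `total_M`, and one
#'   concentration column per component (molar).
#' @export
dilution_series <- function(ray, factors = ray$dilution_factors) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (any(factors < 1) || is.unsorted(factors, strictly = TRUE)) {
    stop("dilution factors must be >= 1 and strictly increasing", call. = FALSE)
  }
  comp <- ray$components
  out <- data.frame(dilution_factor = factors,
                    total_M = ray$total_M / factors)
  for (i in seq_len(nrow(comp))) {
    out[[comp$substance[i]]] <- comp$top_M[i] / factors
  }
  out
}
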