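test_that("concentration addition reduces to known closed forms", {
  cvs <- list(a = tox_curve("a", 2, -5, unit = "M"),
              b = tox_curve("b", 3, -4, unit = "M"))
  # single-component "mixture" is the identity
  solo <- mixture_ray("solo", "a", 1e-5, unit = "M")
  expect_equal(ca_ecx(solo, cvs, 30), ecx(cvs$a, 30), tolerance = 1e-12)
  # identical component ECx -> same mixture ECx
  twin <- list(a = cvs$a, b = tox_curve("b", 5, -5, unit = "M"))
  ray5050 <- mixture_ray("tw", c("a", "b"), c(1e-5, 1e-5), unit = "M")
  expect_equal(ca_ecx(ray5050, twin, 50), 1e-5, tolerance = 1e-12)
})

test_that("CA on a reference ray matches an independent summation oracle", {
  curves <- reference_curves(as_curves = TRUE)
  rays <- reference_rays(as_rays = TRUE)
  ray1 <- rays[["1"]]
  # spreadsheet-style oracle: explicit per-component EC50 and harmonic sum
  tab <- reference_curves()
  ec50_M <- 10^tab$log_xc / 1000 / vapply(tab$subject_id, molar_mass, numeric(1))
  names(ec50_M) <- tab$subject_id
  p <- ray1$components$proportion
  names(p) <- ray1$components$substance
  oracle <- 1 / sum(p[names(ec50_M)] / ec50_M)
  expect_equal(ca_ecx(ray1, curves, 50), oracle, tolerance = 1e-12)
})

test_that("CA is bracketed by component ECx and sham-combination invariant", {
  curves <- reference_curves(as_curves = TRUE)
  rays <- reference_rays(as_rays = TRUE)
  for (id in names(rays)) {
    ray <- rays[[id]]
    mcurves <- lapply(curves[ray$components$substance], as_molar_curve)
    for (E in c(10, 50, 90)) {
      eci <- vapply(mcurves, ecx, numeric(1), effect_pct = E)
      mix <- ca_ecx(ray, curves, E)
      expect_gte(mix, min(eci))
      expect_lte(mix, max(eci))
    }
  }
  # splitting one component into two identical pseudo-components changes nothing
  cvs <- list(a = tox_curve("a", 2, -5, unit = "M"),
              b = tox_curve("b", 3, -4, unit = "M"))
  whole <- mixture_ray("w", c("a", "b"), c(2e-5, 1e-5), unit = "M")
  cvs_split <- c(cvs, list(a2 = cvs$a))
  split <- mixture_ray("s", c("a", "a2", "b"), c(1e-5, 1e-5, 1e-5), unit = "M")
  for (E in c(5, 50, 95)) {
    expect_equal(ca_ecx(split, cvs_split, E), ca_ecx(whole, cvs, E),
                 tolerance = 1e-12)
  }
})

test_that("independent action composes survival fractions", {
  cvs <- list(a = tox_curve("a", 2, -5, unit = "M"),
              b = tox_curve("b", 2, -5, unit = "M"))
  ray <- mixture_ray("ia", c("a", "b"), c(1e-5, 1e-5), unit = "M")
  expect_equal(ia_effect(ray, cvs, 0), 0)
  # both partial doses at their EC50 -> 1 - 0.5 * 0.5 = 75%
  expect_equal(ia_effect(ray, cvs, 2e-5), 75, tolerance = 1e-9)
  # single component: IA equals that component's own curve
  solo <- mixture_ray("solo", "a", 1e-5, unit = "M")
  conc <- 10^seq(-7, -3, length.out = 9)
  expect_equal(ia_effect(solo, cvs, conc),
               logit_effect(cvs$a, log10(conc)), tolerance = 1e-9)
})

test_that("IA effect dominates every component's individual effect", {
  curves <- reference_curves(as_curves = TRUE)
  ray <- reference_rays(as_rays = TRUE)[["3"]]
  mcurves <- lapply(curves[ray$components$substance], as_molar_curve)
  p <- ray$components$proportion
  for (C in 10^seq(-8, -2, length.out = 7)) {
    tot <- ia_effect(ray, curves, C)
    single <- vapply(seq_along(mcurves), function(i) {
      logit_effect(mcurves[[i]], log10(p[i] * C))
    }, numeric(1))
    expect_gte(tot + 1e-9, max(single))
  }
  # monotone nondecreasing in total concentration
  conc <- 10^seq(-9, -1, length.out = 30)
  expect_true(all(diff(ia_effect(ray, curves, conc)) >= 0))
})

test_that("ia_ecx inverts ia_effect and matches an independent bisection oracle", {
  curves <- reference_curves(as_curves = TRUE)
  rays <- reference_rays(as_rays = TRUE)
  for (id in c("1", "4", "7")) {
    for (E in c(5, 35, 50, 80)) {
      ec <- ia_ecx(rays[[id]], curves, E)
      expect_equal(ia_effect(rays[[id]], curves, ec), E, tolerance = 1e-6)
    }
  }
  # independent oracle: uniroot on the survival-product formula written inline
  cvs <- list(a = tox_curve("a", 2, -5, unit = "M"),
              b = tox_curve("b", 4, -4.5, unit = "M"))
  ray <- mixture_ray("sym", c("a", "b"), c(1e-5, 1e-5), unit = "M")
  oracle <- uniroot(function(C) {
    fa <- 1 / (1 + 10^(2 * (-5 - log10(0.5 * C))))
    fb <- 1 / (1 + 10^(4 * (-4.5 - log10(0.5 * C))))
    100 * (1 - (1 - fa) * (1 - fb)) - 50
  }, c(1e-12, 1), tol = 1e-15)$root
  expect_equal(ia_ecx(ray, cvs, 50), oracle, tolerance = 1e-6)
  # single-component inversion identity
  solo <- mixture_ray("solo", "a", 1e-5, unit = "M")
  expect_equal(ia_ecx(solo, cvs, 30), ecx(cvs$a, 30), tolerance = 1e-6)
})

test_that("effects above the IA asymptote raise an unattainable-effect error", {
  truncated <- list(a = tox_curve("a", 2, -5, AL = 0, AH = 80, unit = "M"))
  solo <- mixture_ray("solo", "a", 1e-5, unit = "M")
  expect_error(ia_ecx(solo, truncated, 99.9999), "unattainable effect")
})

test_that("CA and IA coincide for a one-component mixture", {
  cvs <- list(a = tox_curve("a", 1.7, -5.2, unit = "M"))
  solo <- mixture_ray("solo", "a", 1e-5, unit = "M")
  for (E in c(10, 50, 90)) {
    expect_equal(ca_ecx(solo, cvs, E), ia_ecx(solo, cvs, E), tolerance = 1e-6)
  }
})

test_that("linearize recovers exact and affine relations", {
  hm <- homogeneous_mixture()
  E <- c(10, 25, 40, 55, 70, 85)
  conc <- ca_ecx(hm$ray, hm$curves, E)
  # observed data exactly on the CA prediction -> identity regression
  lin <- linearize(conc, E, hm$ray, hm$curves, predictor = "CA")
  expect_equal(lin$b0, 0, tolerance = 1e-9)
  expect_equal(lin$b1, 1, tolerance = 1e-9)
  expect_equal(lin$pearson_r, 1, tolerance = 1e-9)
  # constructed affine displacement: observed = 10^(0.5) * predicted^1.2
  lin2 <- linearize(10^(0.5 + 1.2 * log10(conc)), E, hm$ray, hm$curves, "CA")
  expect_equal(lin2$b0, 0.5, tolerance = 1e-9)
  expect_equal(lin2$b1, 1.2, tolerance = 1e-9)
  # exclusion of 0/100% points, insufficient-data and degenerate errors
  expect_error(linearize(conc[1:2], c(0, 100), hm$ray, hm$curves, "CA"),
               "insufficient data")
  expect_error(linearize(conc[1], E[1], hm$ray, hm$curves, "CA"),
               "insufficient data")
  lin3 <- linearize(c(conc, 1e-9), c(E, 0), hm$ray, hm$curves, "CA")
  expect_equal(lin3$n_points, 6L)
  expect_equal(lin3$n_excluded, 1L)
})

test_that("model_ec50 applies the linear correction on the log scale", {
  hm <- homogeneous_mixture()
  E <- c(10, 30, 50, 70, 90)
  conc <- ca_ecx(hm$ray, hm$curves, E)
  ca50 <- ca_ecx(hm$ray, hm$curves, 50)
  lin <- linearize(conc, E, hm$ray, hm$curves, "CA")
  expect_equal(model_ec50(lin, hm$ray, hm$curves), ca50, tolerance = 1e-9)
  # a pure log-shift doubles the EC50
  lin$b0 <- log10(2); lin$b1 <- 1
  expect_equal(model_ec50(lin, hm$ray, hm$curves), 2 * ca50, tolerance = 1e-9)
})

test_that("LCA pipeline recovers the true mixture EC50 on additive data", {
  # recovery error is dominated by errors-in-variables attenuation (the
  # predicted log-ECx regressor is built from noisy observed inhibition), so
  # accuracy is bounded by the assay noise rather than the replicate count
  hm <- homogeneous_mixture()
  truth <- ca_ecx(hm$ray, hm$curves, 50)
  med_err <- function(noise_cv, grid) {
    errs <- vapply(1:200, function(i) {
      cfg <- sim_config(true_curves = hm$curves, rays = list(hom = hm$ray),
                        interaction_lambda = 1, noise_cv = noise_cv,
                        replicates = 3, seed = 5000L + i)
      plate <- simulate_mixture_plates(cfg)
      inh <- plate_inhibition(plate)
      lin <- linearize(inh$concentration, inh$inhibition_pct, hm$ray,
                       hm$curves, "CA", effect_grid = grid)
      abs(model_ec50(lin, hm$ray, hm$curves) / truth - 1)
    }, numeric(1))
    median(errs)
  }
  # at the assay's 5% luminescence noise
  expect_lt(med_err(0.05, NULL), 0.10)
  # tighter noise with the 5-95% fixed-grid trim converges further
  expect_lt(med_err(0.02, seq(5, 95, 5)), 0.05)
})
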