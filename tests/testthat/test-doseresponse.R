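test_that("inhibition is the control-normalised luminescence decrease", {
  # sample behaves exactly like the control -> no inhibition
  expect_equal(inhibition_from_luminescence(100, 80, 100, 80), 0)
  # total quenching -> 100%
  expect_equal(inhibition_from_luminescence(200, 0, 100, 90), 100)
  # sample ratio half the control ratio -> 50%
  expect_equal(inhibition_from_luminescence(100, 40, 100, 80), 50)
  # stimulation is returned negative, unclipped
  expect_lt(inhibition_from_luminescence(100, 90, 100, 80), 0)

  expect_error(inhibition_from_luminescence(0, 10, 100, 80), "invalid reading")
  expect_error(inhibition_from_luminescence(100, 10, 0, 80), "invalid reading")
  expect_error(inhibition_from_luminescence(100, 10, 100, 0), "degenerate control")
})

test_that("logit_effect matches direct evaluation of the four-parameter form", {
  am <- ammonia_curve()
  # half response at the centre for any curve
  expect_equal(logit_effect(am, log_xc(am)), 50)
  cv2 <- tox_curve("free", 1.5, 0.3, AL = 5, AH = 95)
  expect_equal(logit_effect(cv2, 0.3), 50)
  # independent arithmetic: 100 / (1 + 10^(-3.741 * log10(2)))
  expect_equal(logit_effect(am, log10(2) + log_xc(am)),
               100 / (1 + 10^(-3.741 * log10(2))), tolerance = 1e-12)
  expect_equal(logit_effect(am, log10(2) + log_xc(am)), 93.04, tolerance = 1e-4)
  # asymptotes
  nitrite <- tox_curve("nitrite", 0.26432, -0.77343)
  expect_equal(logit_effect(nitrite, 1e6), 100, tolerance = 1e-6)
  expect_equal(logit_effect(nitrite, -Inf), 0)
})

test_that("ecx inverts the curve (round trip) and EC50 is the centre", {
  am <- ammonia_curve()
  expect_equal(ecx(am, 50), 10^log_xc(am))
  # EC10 by independent arithmetic
  expect_equal(ecx(am, 10), 10^(-0.24315 + log10(10 / 90) / 3.741),
               tolerance = 1e-12)
  expect_equal(ecx(am, 10), 0.3177, tolerance = 1e-3)
  # round-trip property over many curves and effect levels
  set.seed(42)
  for (i in 1:20) {
    cv <- tox_curve("rt", p = runif(1, 0.2, 9) * sample(c(-1, 1), 1),
                    log_xc = runif(1, -3, 3))
    for (E in c(0.5, 5, 27, 50, 73, 95, 99.5)) {
      expect_equal(logit_effect(cv, log10(ecx(cv, E))), E, tolerance = 1e-9)
    }
  }
  # rescaled limits round-trip too
  cv <- tox_curve("free", 2, -1, AL = 5, AH = 95)
  expect_equal(logit_effect(cv, log10(ecx(cv, 40))), 40, tolerance = 1e-9)
  expect_error(ecx(am, 0), "strictly between")
  expect_error(ecx(am, 100), "strictly between")
})

test_that("logit_effect is strictly monotone in concentration for p > 0", {
  set.seed(7)
  for (i in 1:10) {
    cv <- tox_curve("mono", p = runif(1, 0.1, 10), log_xc = runif(1, -2, 2))
    # stay clear of the numerically saturated tails
    x <- cv$log_xc + sort(runif(25, -10 / cv$p, 10 / cv$p))
    expect_true(all(diff(logit_effect(cv, x)) > 0))
  }
})

test_that("mass/molar conversion reproduces published molar limits", {
  expect_equal(mass_to_molar(0, "zinc"), 0)
  # nitrite 0.1 mg/L -> 2.17e-3 mM; zinc 0.053 mg/L -> 8.11e-4 mM
  expect_equal(mass_to_molar(0.1, "nitrite") * 1000, 2.17e-3, tolerance = 0.01)
  expect_equal(mass_to_molar(0.053, "zinc") * 1000, 8.11e-4, tolerance = 0.01)
  # exact round trip
  x <- c(0.01, 0.5, 7)
  expect_equal(molar_to_mass(mass_to_molar(x, "copper"), "copper"), x)
  expect_error(mass_to_molar(1, "plutonium"), "unknown substance")
  # synonyms resolve
  expect_equal(molar_mass("Un-ionized ammonia"), 17.031)
})

test_that("plate_inhibition normalises sample wells against their controls", {
  plate <- data.frame(
    well_id = c("s1", "s2", "nc1", "nc2"),
    role = c("sample", "sample", "negative_control", "negative_control"),
    ray_id = "r1", dilution_factor = 1,
    concentration = c(1, 2, 0, 0), unit = "mM",
    lum_t0 = c(100, 200, 100, 150),
    lum_t5 = c(40, 80, 80, 120)
  )
  out <- plate_inhibition(plate)
  expect_equal(out$inhibition_pct, c(50, 50))
  expect_false(any(out$stimulation))
  expect_error(plate_inhibition(plate[plate$role == "sample", ]),
               "no negative_control")
})
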