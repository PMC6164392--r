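test_that("mdr honours both conventions and their reciprocity", {
  expect_equal(as.numeric(mdr(2e-3, 2e-3)), 1)
  expect_equal(as.numeric(mdr(8.73e-2, 4.19e-3)), 20.83, tolerance = 1e-3)
  expect_equal(as.numeric(mdr(2.59e-3, 1.76e-2)), 0.147, tolerance = 1e-2)
  expect_equal(attr(mdr(1, 2), "convention"), "predicted_over_observed")
  # reciprocity property
  set.seed(3)
  for (i in 1:20) {
    a <- 10^runif(1, -8, 0); b <- 10^runif(1, -8, 0)
    expect_equal(as.numeric(mdr(a, b)) *
                   as.numeric(mdr(a, b, "observed_over_predicted")), 1,
                 tolerance = 1e-12)
  }
  expect_error(mdr(-1, 2), "positive")
  expect_error(mdr(1, 0), "positive")
})

test_that("relative deviation matches published worked examples and is scale-free", {
  expect_equal(relative_deviation(5e-3, 5e-3), 0)
  expect_equal(relative_deviation(2.16e-1, 5.76e-2), 275.1, tolerance = 1e-3)
  expect_equal(relative_deviation(3.82e-3, 4.87e-2), 92.2, tolerance = 1e-3)
  set.seed(4)
  for (i in 1:20) {
    a <- 10^runif(1, -6, 0); b <- 10^runif(1, -6, 0); s <- 10^runif(1, -3, 3)
    expect_equal(relative_deviation(s * a, s * b), relative_deviation(a, b),
                 tolerance = 1e-9)
  }
  expect_error(relative_deviation(1, 0), "positive")
})

test_that("behaviour classification follows the assay's MDR mapping", {
  expect_equal(classify_behavior(1), "additive")
  expect_equal(classify_behavior(13.93), "antagonistic")
  expect_equal(classify_behavior(0.15), "synergistic")
  # monotone with exactly two thresholds; band edges are alerts
  m <- c(0.01, 0.5, 0.51, 1, 1.99, 2, 100)
  expect_equal(classify_behavior(m),
               c("synergistic", "synergistic", "additive", "additive",
                 "additive", "antagonistic", "antagonistic"))
  # configurable band
  expect_equal(classify_behavior(3, band = c(0.2, 5)), "additive")
  expect_error(classify_behavior(-1), "positive")
})

test_that("error summary works on the inhibition fraction scale", {
  expect_equal(error_summary(c(0.3, 0.7), c(0.3, 0.7)),
               c(rmse = 0, mae_pct = 0))
  expect_equal(error_summary(c(0.5, 0.5), c(0.4, 0.6)),
               c(rmse = 0.1, mae_pct = 10))
  expect_equal(error_summary(0.2, 0.5), c(rmse = 0.3, mae_pct = 30))
  expect_error(error_summary(c(0.1, 0.2), 0.1), "equal length")
  expect_error(error_summary(numeric(0), numeric(0)), "nonempty")
})

test_that("pearson_r computes the product-moment correlation with guards", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  # hand computation: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_error(pearson_r(1, 1), "at least two")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
})

test_that("limit alerts fire at the recommended thresholds, unit-converted", {
  out <- limit_alert(
    c("nitrite", "aluminum", "zinc", "copper"),
    c(0.05, 0.015, 9.0e-4, 5e-4),
    unit = c("mg/L", "mg/L", "mM", "mM")
  )
  expect_equal(out$status, c("ok", "warning", "alarm", "alarm"))
  # warning threshold is inclusive and cited
  expect_equal(out$threshold_mg_L[2], 0.015)
  # zinc 9e-4 mM converts above the 0.053 mg/L (8.11e-4 mM) limit
  expect_gt(out$concentration_mg_L[3], 0.053)
  expect_error(limit_alert("mercury", 1), "no limit configured")
})

test_that("evaluate_rays produces one evaluated row per ray and model", {
  hm <- homogeneous_mixture()
  cfg <- sim_config(true_curves = hm$curves, rays = list(hom = hm$ray),
                    interaction_lambda = 1, noise_cv = 0, replicates = 2,
                    seed = 77)
  plate <- simulate_mixture_plates(cfg)
  ev <- evaluate_plates(plate, list(hom = hm$ray), hm$curves)
  expect_s3_class(ev, "ray_evaluation")
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$model, c("LCA", "LIA"))
  # additive homogeneous mixture: LCA identity regression and MDR 1
  lca <- ev[ev$model == "LCA", ]
  expect_equal(lca$b1, 1, tolerance = 1e-6)
  expect_equal(lca$b0, 0, tolerance = 1e-5)
  expect_equal(lca$mdr, 1, tolerance = 1e-3)
  expect_equal(lca$behavior, "additive")
  # unknown ray ids are a configuration error
  obs <- data.frame(ray_id = "ghost", total_concentration_M = 1e-5,
                    inhibition_pct = 50)
  expect_error(evaluate_rays(obs, list(hom = hm$ray), hm$curves),
               "unknown ray")
})
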