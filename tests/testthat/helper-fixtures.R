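# Shared fixtures built in code.

ammonia_curve <- function() tox_curve("ammonia", p = 3.741, log_xc = -0.24315)

# A two-component mixture whose components share one slope: the CA prediction
# of such a mixture is exactly a logit with that slope, so full-pipeline
# closure properties hold to optimizer tolerance.
homogeneous_mixture <- function(p = 2) {
  curves <- list(a = tox_curve("a", p, log_xc = -5, unit = "M"),
                 b = tox_curve("b", p, log_xc = -4, unit = "M"))
  # top ~8x the CA EC50 so the 1..64 dilution series straddles the transition
  ray <- mixture_ray("hom", c("a", "b"), c(7.3e-5, 7.3e-5), unit = "M")
  list(curves = curves, ray = ray)
}

# Noiseless inhibition points generated from a curve.
curve_points <- function(curve, n = 12, lo = 5, hi = 95) {
  x <- seq(log10(ecx(curve, lo)), log10(ecx(curve, hi)), length.out = n)
  list(x = x, y = logit_effect(curve, x))
}
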