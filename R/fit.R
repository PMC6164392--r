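#' Fit a four-parameter logit dose-response curve
#'
#' Least-squares fit of the log-logistic inhibition model
#' `y = AL + (AH - AL) / (1 + 10^(p * (log_xc - x)))` with `x` the log10
#' concentration and `y` percent inhibition. By default the limits are fixed
#' at `(0, 100)` and only the slope `p` and centre `log_xc` are estimated;
#' pass `fix_limits = NULL` to free all four parameters.
#'
#' Initialisation: `log_xc` starts at the observed point nearest 50% effect
#' and `p` at the slope of a straight-line fit to logit-transformed interior
#' points; `p` is box-bounded to `[-50, 50]`. Optimisation is
#' Levenberg-Marquardt (via \pkg{minpack.lm}). Observed inhibition below
#' `stim_floor` (strong stimulation) is excluded from the fit and counted;
#' negative values above the floor are kept.
#'
#' @param x For the default method, numeric vector of log10 concentrations;
#'   for the formula method, a formula `inhibition ~ log10_concentration`.
#' @param y Percent inhibition at each `x`.
#' @param fix_limits Length-2 numeric `(AL, AH)` to hold the limits fixed
#'   (default `c(0, 100)`), or `NULL` to estimate them.
#' @param unit Concentration unit carried as curve metadata.
#' @param subject Label for the fitted curve.
#' @param stim_floor Inhibition floor in percent below which points are
#'   excluded as strong stimulation (default -10).
#' @param data Data frame for the formula method.
#' @param ... Passed between methods.
#' @return An object of class `c("logit_fit", "tox_curve")`: the fitted curve
#'   plus `residuals`, `fitted`, `vcov`, `df.residual`, `sigma`, `n_used`,
#'   `n_excluded` and the data used. Supports [coef()], [predict()] (with
#'   95% confidence bands), [residuals()], [plot()], [summary()] and
#'   [simulate()].
#' @export
#' @examples
#' true <- tox_curve("ammonia", 3.741, -0.24315)
#' x <- seq(-1, 0.6, length.out = 12)
#' fit <- fit_logit(x, logit_effect(true, x))
#' coef(fit)
fit_logit <- function(x, ...) UseMethod("fit_logit")

#' @rdname fit_logit
#' @export
fit_logit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L) stop("formula must be inhibition ~ log10_concentration",
                           call. = FALSE)
  fit_logit.default(mf[[2L]], mf[[1L]], ...)
}

#' @rdname fit_logit
#' @export
fit_logit.default <- function(x, y, fix_limits = c(0, 100), unit = "mg/L",
                              subject = "fit", stim_floor = -10, ...) {
  ok <- is.finite(x) & is.finite(y)
  flagged <- ok & y < stim_floor
  keep <- ok & !flagged
  n_excluded <- sum(!keep)
  x0 <- x[keep]; y0 <- y[keep]
  if (length(x0) < 4L) {
    stop("need at least 4 usable points to fit a dose-response curve",
         call. = FALSE)
  }
  if (stats::sd(y0) == 0) {
    stop("degenerate data: all inhibition values identical", call. = FALSE)
  }

  free_limits <- is.null(fix_limits)
  AL0 <- if (free_limits) min(y0) else fix_limits[1L]
  AH0 <- if (free_limits) max(y0) else fix_limits[2L]
  if (!free_limits && AH0 <= AL0) stop("fix_limits must satisfy AH > AL",
                                       call. = FALSE)

  # starting values: centre at the point nearest half-effect, slope from a
  # straight-line fit to the logit transform of interior points
  mid <- (AL0 + AH0) / 2
  xc0 <- x0[which.min(abs(y0 - mid))]
  span <- AH0 - AL0
  f <- pmin(pmax((y0 - AL0) / span, 0.01), 0.99)
  z <- log10(f / (1 - f))
  p0 <- tryCatch(unname(stats::coef(stats::lm(z ~ x0))[2L]),
                 error = function(e) NA_real_)
  if (!is.finite(p0) || p0 == 0) {
    p0 <- if (stats::cor(x0, y0) >= 0) 1 else -1
  }
  p0 <- min(max(p0, -50), 50)

  dat <- data.frame(x = x0, y = y0)
  if (free_limits) {
    form <- y ~ AL + (AH - AL) / (1 + 10^(p * (xc - x)))
    starts <- list(list(p = p0, xc = xc0, AL = AL0, AH = AH0))
    lower <- c(-50, -Inf, -100, -100)
    upper <- c(50, Inf, 300, 300)
  } else {
    form <- substitute(y ~ AL0 + (AH0 - AL0) / (1 + 10^(p * (xc - x))),
                       list(AL0 = AL0, AH0 = AH0))
    # multi-start fallback grid for weakly informative data
    sgn <- if (p0 >= 0) 1 else -1
    starts <- c(list(list(p = p0, xc = xc0)),
                unlist(lapply(c(0.5, 1, 2, 4, 8) * sgn, function(pp) {
                  lapply(stats::quantile(x0, c(0.25, 0.5, 0.75, 1),
                                         names = FALSE),
                         function(xx) list(p = pp, xc = xx))
                }), recursive = FALSE))
    lower <- c(-50, -Inf)
    upper <- c(50, Inf)
  }
  fit <- NULL
  last_err <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(form), data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("dose-response fit did not converge: ", last_err, call. = FALSE)
  }
  cf <- stats::coef(fit)
  AL <- if (free_limits) cf[["AL"]] else AL0
  AH <- if (free_limits) cf[["AH"]] else AH0
  if (AH <= AL) stop("dose-response fit degenerate: AH <= AL", call. = FALSE)

  out <- tox_curve(subject, cf[["p"]], cf[["xc"]], AL, AH, unit)
  out$free_limits <- free_limits
  out$data <- dat
  out$fitted <- stats::fitted(fit)
  out$residuals <- stats::resid(fit)
  out$df.residual <- stats::df.residual(fit)
  out$sigma <- summary(fit)$sigma
  out$vcov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  out$n_used <- length(x0)
  out$n_excluded <- n_excluded
  out$n_flagged_stimulation <- sum(flagged)
  class(out) <- c("logit_fit", "tox_curve")
  out
}

#' @export
print.logit_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  fitted on %d points (%d excluded), residual sd %.3g\n",
              x$n_used, x$n_excluded, x$sigma))
  invisible(x)
}

#' @export
residuals.logit_fit <- function(object, ...) object$residuals

# Gradient of the mean response wrt the free parameters, for delta-method
# confidence bands.
logit_fit_gradient <- function(object, x) {
  p <- object$p; xc <- object$log_xc; AL <- object$AL; AH <- object$AH
  u <- 10^(p * (xc - x))
  denom <- (1 + u)^2
  dp <- -(AH - AL) * u * log(10) * (xc - x) / denom
  dxc <- -(AH - AL) * u * log(10) * p / denom
  g <- cbind(p = dp, xc = dxc)
  if (isTRUE(object$free_limits)) {
    g <- cbind(g, AL = 1 - 1 / (1 + u), AH = 1 / (1 + u))
  }
  g
}

#' Predict from a fitted dose-response curve
#'
#' @param object A [fit_logit()] result.
#' @param newdata Numeric vector of log10 concentrations, or a data.frame
#'   with a `log10_concentration` (or `x`) column; defaults to the fitted
#'   points.
#' @param interval `"none"` or `"confidence"` for a 95% confidence band of
#'   the mean response (delta method on the parameter covariance).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Vector of predicted inhibition, or a data.frame with `fit`,
#'   `lwr`, `upr`.
#' @export
predict.logit_fit <- function(object, newdata = NULL,
                              interval = c("none", "confidence"),
                              level = 0.95, ...) {
  interval <- match.arg(interval)
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    col <- intersect(c("log10_concentration", "x"), names(newdata))[1L]
    if (is.na(col)) stop("newdata needs a log10_concentration column",
                         call. = FALSE)
    newdata[[col]]
  } else {
    as.numeric(newdata)
  }
  fitv <- logit_effect(object, x)
  if (interval == "none") return(fitv)
  if (is.null(object$vcov)) stop("no covariance available for this fit",
                                 call. = FALSE)
  g <- logit_fit_gradient(object, x)
  se <- sqrt(pmax(rowSums((g %*% object$vcov) * g), 0))
  tq <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  data.frame(fit = fitv, lwr = fitv - tq * se, upr = fitv + tq * se)
}

#' @export
summary.logit_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else NULL
  out <- list(curve = object,
              coef = coef(object),
              se = se,
              ec50 = 10^object$log_xc,
              unit = object$unit,
              sigma = object$sigma,
              rmse = sqrt(mean(object$residuals^2)),
              n_used = object$n_used,
              n_excluded = object$n_excluded)
  class(out) <- "summary.logit_fit"
  out
}

#' @export
print.summary.logit_fit <- function(x, ...) {
  print(x$curve)
  if (!is.null(x$se)) {
    cat(sprintf("  se(p) = %.3g, se(log_xc) = %.3g\n", x$se[1L], x$se[2L]))
  }
  cat(sprintf("  RMSE = %.4g %%, n = %d (excluded %d)\n",
              x$rmse, x$n_used, x$n_excluded))
  invisible(x)
}

#' @export
plot.logit_fit <- function(x, band = TRUE, n_grid = 200, ...) {
  xr <- range(x$data$x)
  xs <- seq(xr[1L] - 0.2, xr[2L] + 0.2, length.out = n_grid)
  pr <- if (band && !is.null(x$vcov)) {
    predict(x, xs, interval = "confidence")
  } else {
    data.frame(fit = logit_effect(x, xs))
  }
  graphics::plot(x$data$x, x$data$y,
                 xlab = sprintf("log10 concentration (%s)", x$unit),
                 ylab = "Inhibition (%)",
                 main = x$subject, ...)
  graphics::lines(xs, pr$fit, col = "red")
  if (!is.null(pr$lwr)) {
    graphics::lines(xs, pr$lwr, lty = 2)
    graphics::lines(xs, pr$upr, lty = 2)
  }
  invisible(x)
}

#' Simulate inhibition data from a fitted curve
#'
#' Draws new responses at the fitted design points: the fitted mean plus
#' Gaussian residual noise at the estimated residual standard deviation.
#'
#' @param object A [fit_logit()] result.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data.frame with one column per simulation.
#' @export
simulate.logit_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- logit_effect(object, object$data$x)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "log10_concentration") <- object$data$x
  out
}
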