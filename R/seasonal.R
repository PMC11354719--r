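#' Exponential-cubic seasonal abundance model
#'
#' Within-year mosquito abundance is modeled as an "exponential cubic"
#' trend on day-of-year `t`: the expected daily abundance is
#' `exp(b0 + b1 * t + b2 * t^2)`, with observation noise from either a
#' negative-binomial family (trap counts, dispersion `theta`) or a
#' log-normal family (aerial densities, log-scale SD `sigma`).
#'
#' Objects of this class are returned by [fit_seasonal_nb()] and
#' [fit_seasonal_lognormal()], or built directly for simulation studies.
#'
#' @param beta Numeric length-3 coefficient vector `(b0, b1, b2)`.
#' @param family `"negative_binomial"` or `"lognormal"`.
#' @param theta NB dispersion (variance = `mu + mu^2 / theta`); required for
#'   the negative-binomial family.
#' @param sigma Log-scale residual SD; required for the log-normal family.
#' @param season Integer day-of-year bounds covered by the model (default
#'   days 121-300, a May-October trapping season).
#' @return An object of class `seasonal_model`.
#' @examples
#' m <- seasonal_model(c(-17.4, 0.21, -5e-4), "negative_binomial", theta = 5)
#' predict(m, t = c(150, 210, 270))
#' @export
seasonal_model <- function(beta,
                           family = c("negative_binomial", "lognormal"),
                           theta = NULL, sigma = NULL,
                           season = c(121L, 300L)) {
  family <- match.arg(family)
  if (length(beta) != 3L || any(!is.finite(beta))) {
    stop("'beta' must be three finite coefficients (b0, b1, b2)")
  }
  if (family == "negative_binomial") {
    if (is.null(theta) || !is.finite(theta) || theta <= 0) {
      stop("negative-binomial family needs a positive 'theta'")
    }
  } else {
    if (is.null(sigma) || !is.finite(sigma) || sigma < 0) {
      stop("log-normal family needs a non-negative 'sigma'")
    }
  }
  structure(
    list(beta = as.numeric(beta), family = family, theta = theta,
         sigma = sigma, season = as.integer(season)),
    class = "seasonal_model"
  )
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat("Exponential-cubic seasonal abundance model\n")
  cat(sprintf("  mean(t) = exp(%.4g %+.4g t %+.4g t^2)\n",
              x$beta[1], x$beta[2], x$beta[3]))
  if (x$family == "negative_binomial") {
    cat(sprintf("  family: negative binomial, theta = %.4g\n", x$theta))
  } else {
    cat(sprintf("  family: log-normal, sigma = %.4g\n", x$sigma))
  }
  cat(sprintf("  season: days %d-%d\n", x$season[1], x$season[2]))
  invisible(x)
}

#' @export
coef.seasonal_model <- function(object, ...) {
  stats::setNames(object$beta, c("b0", "b1", "b2"))
}

#' @rdname seasonal_model
#' @param object,x A `seasonal_model`.
#' @param t Day-of-year vector (defaults to the model's season).
#' @param ... Unused.
#' @export
predict.seasonal_model <- function(object, t = NULL, ...) {
  t <- t %||% seq(object$season[1], object$season[2])
  exp(object$beta[1] + object$beta[2] * t + object$beta[3] * t^2)
}

# Fit on a centered day axis for numerical stability, then map the
# coefficients back to the raw day-of-year parameterisation (exact
# transform of the quadratic).
uncenter_quadratic <- function(b, center) {
  c(b[1] - b[2] * center + b[3] * center^2,
    b[2] - 2 * b[3] * center,
    b[3])
}

#' Fit the seasonal trend to daily trap counts
#'
#' Negative-binomial regression (log link) of daily counts on day-of-year
#' and its square, via [MASS::glm.nb]. Days are centered internally for a
#' well-conditioned design; reported coefficients are on the raw
#' day-of-year scale. Zero counts are ordinary observations of the NB
#' family and are retained.
#'
#' @param counts Non-negative integer daily counts.
#' @param t Day-of-year for each count.
#' @return A [seasonal_model()] with the estimated dispersion; the fit
#'   object is attached as attribute `fit` and convergence problems are
#'   reported via `converged`.
#' @export
fit_seasonal_nb <- function(counts, t) {
  if (length(counts) != length(t)) stop("length mismatch")
  if (length(counts) < 10L) stop("need at least 10 observations")
  if (any(counts < 0)) stop("counts must be non-negative")
  center <- mean(t)
  tc <- t - center
  dat <- data.frame(y = counts, tc = tc, tc2 = tc^2)
  fit <- withCallingHandlers(
    MASS::glm.nb(y ~ tc + tc2, data = dat),
    warning = function(w) {
      if (grepl("iteration limit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) warning("negative-binomial fit did not converge")
  m <- seasonal_model(uncenter_quadratic(unname(stats::coef(fit)), center),
                      "negative_binomial", theta = fit$theta,
                      season = c(min(t), max(t)))
  m$converged <- isTRUE(fit$converged)
  attr(m, "fit") <- fit
  m
}

#' Fit the seasonal trend to daily aerial densities
#'
#' Ordinary least squares of log-transformed densities on day-of-year and
#' its square (the log transform renders the errors homoscedastic). Days
#' with zero density carry no information on the log scale and are dropped
#' by default; alternatively a small offset can be added.
#'
#' @param densities Positive daily densities (zeros handled per
#'   `zero_handling`).
#' @param t Day-of-year for each density.
#' @param zero_handling `"drop"` (default) or `"offset"`; the offset is
#'   half the smallest positive density.
#' @return A [seasonal_model()] with log-normal family and residual SD
#'   `sigma`; the `lm` fit is attached as attribute `fit`.
#' @export
fit_seasonal_lognormal <- function(densities, t,
                                   zero_handling = c("drop", "offset")) {
  if (length(densities) != length(t)) stop("length mismatch")
  zero_handling <- match.arg(zero_handling)
  if (any(densities < 0)) stop("densities must be non-negative")
  if (all(densities == 0)) stop("all densities are zero; nothing to fit")
  if (any(densities == 0)) {
    if (zero_handling == "drop") {
      keep <- densities > 0
      densities <- densities[keep]; t <- t[keep]
    } else {
      densities <- densities + min(densities[densities > 0]) / 2
    }
  }
  if (length(densities) < 10L) stop("need at least 10 positive observations")
  center <- mean(t)
  tc <- t - center
  fit <- stats::lm(log(densities) ~ tc + I(tc^2))
  m <- seasonal_model(uncenter_quadratic(unname(stats::coef(fit)), center),
                      "lognormal", sigma = summary(fit)$sigma,
                      season = c(min(t), max(t)))
  m$converged <- TRUE
  attr(m, "fit") <- fit
  m
}

#' Simulate one season of daily observations
#'
#' Draws a daily series from the model's error family around the (possibly
#' rescaled) seasonal mean `scale * exp(b0 + b1 t + b2 t^2)`. For the
#' negative-binomial family the draws are integer counts with mean exactly
#' the seasonal curve; for the log-normal family the curve is the median of
#' the draws.
#'
#' @param model A [seasonal_model()].
#' @param scale Multiplier applied to the seasonal curve (e.g. 1.05 for a
#'   5% abundance increase).
#' @param t Day-of-year grid (defaults to the model's season).
#' @param seed Optional integer seed.
#' @param n Number of independent seasons to draw.
#' @return If `n = 1` a numeric vector over `t`; otherwise a
#'   `length(t) x n` matrix with one season per column.
#' @export
simulate_year <- function(model, scale = 1, t = NULL, seed = NULL, n = 1L) {
  if (!inherits(model, "seasonal_model")) {
    stop("'model' must be a seasonal_model")
  }
  stopifnot_scalar(scale, "scale", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  t <- t %||% seq(model$season[1], model$season[2])
  mu <- scale * predict(model, t = t)
  draw <- if (model$family == "negative_binomial") {
    stats::rnbinom(length(t) * n, mu = mu, size = model$theta)
  } else if (model$sigma > 0) {
    stats::rlnorm(length(t) * n, meanlog = log(mu), sdlog = model$sigma)
  } else {
    rep(mu, n)
  }
  if (n == 1L) draw else matrix(draw, nrow = length(t), ncol = n)
}

#' @rdname simulate_year
#' @param object A `seasonal_model`.
#' @param nsim Number of seasons.
#' @param ... Passed on to [simulate_year()] (`scale`, `t`).
#' @export
simulate.seasonal_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_year(object, seed = seed, n = nsim, ...)
}

#' Simulate a dated season of daily abundance
#'
#' Convenience wrapper producing a daily ledger for a season: the
#' day-of-year, the expected abundance from the exponential-cubic curve,
#' and a realized draw from the model's error family.
#'
#' @param model A [seasonal_model()].
#' @param days Number of days (defaults to the model's full season).
#' @param seed Optional integer seed.
#' @return Data frame with columns `t`, `expected`, `count`.
#' @export
simulate_season <- function(model, days = NULL, seed = NULL) {
  t0 <- model$season[1]
  t <- if (is.null(days)) seq(model$season[1], model$season[2]) else {
    if (days < 1) stop("'days' must be >= 1")
    seq(t0, t0 + days - 1L)
  }
  data.frame(
    t = t,
    expected = predict(model, t = t),
    count = simulate_year(model, t = t, seed = seed)
  )
}
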