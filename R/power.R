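#' Multi-device precision experiment
#'
#' Measures how precisely a monitoring network detects a 5% change in
#' overall seasonal abundance. For each device count `d`, the experiment
#' draws `d` independent simulated seasons from the fitted model and `d`
#' from the same model with its seasonal curve multiplied by `effect`
#' (default 1.05), sums total annual abundance within each arm, and records
#' the proportional difference `(S_scaled - S_base) / S_base`. Repeating
#' this `n_comparisons` times per device count yields a distribution of
#' differences centered at the true effect (0.05), whose spread narrows as
#' more devices are pooled -- by a factor `1/sqrt(d)` for independent
#' devices.
#'
#' The baseline-arm total is used as the denominator so the statistic
#' equals the true effect exactly in the noise-free limit. The spread
#' metric is the interdecile range, robust to the skew of count noise.
#'
#' @param model A [seasonal_model()].
#' @param device_counts Integer device counts to compare (default
#'   `c(1, 2, 4, 8, 16)`).
#' @param n_comparisons Comparisons per device count (default 10000).
#' @param effect Multiplicative abundance change to detect (default 1.05,
#'   i.e. a 5% increase; the true proportional difference is
#'   `effect - 1`).
#' @param seed Optional integer seed.
#' @return An object of class `power_sim_result`: list with
#'   `device_counts`, `differences` (matrix, `n_comparisons` x counts),
#'   `center` (mean difference per count), `spread` (interdecile range per
#'   count), `true_effect`.
#' @export
precision_experiment <- function(model, device_counts = c(1, 2, 4, 8, 16),
                                 n_comparisons = 10000, effect = 1.05,
                                 seed = NULL) {
  if (any(device_counts < 1)) stop("device counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(model$season[1], model$season[2])
  diffs <- matrix(NA_real_, n_comparisons, length(device_counts),
                  dimnames = list(NULL, paste0("d", device_counts)))
  block <- 2000L
  for (j in seq_along(device_counts)) {
    d <- device_counts[j]
    done <- 0L
    while (done < n_comparisons) {
      m <- min(block, n_comparisons - done)
      base <- colSums(simulate_year(model, scale = 1, t = t, n = m * d))
      scal <- colSums(simulate_year(model, scale = effect, t = t, n = m * d))
      s_base <- colSums(matrix(base, nrow = d))
      s_scal <- colSums(matrix(scal, nrow = d))
      diffs[done + seq_len(m), j] <- (s_scal - s_base) / s_base
      done <- done + m
    }
  }
  structure(
    list(device_counts = device_counts, differences = diffs,
         center = colMeans(diffs),
         spread = apply(diffs, 2L, function(x) {
           unname(diff(stats::quantile(x, c(0.1, 0.9))))
         }),
         true_effect = effect - 1),
    class = "power_sim_result"
  )
}

#' @export
print.power_sim_result <- function(x, ...) {
  cat(sprintf(
    "Precision experiment: %d comparisons per device count (true effect %+.3g)\n",
    nrow(x$differences), x$true_effect))
  out <- data.frame(devices = x$device_counts, center = x$center,
                    interdecile = x$spread)
  print(out, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.power_sim_result <- function(x, ...) {
  graphics::plot(x$device_counts, x$spread, log = "xy", type = "b",
                 xlab = "devices", ylab = "interdecile range of difference",
                 main = "Precision vs device count", ...)
  invisible(x)
}

#' Device-equivalence factor between two instrument types
#'
#' The number `k` of devices of type B needed to match the precision of a
#' single device of type A: solves `spread_b(k) = spread_a(1)` by linear
#' interpolation of log spread against log device count (spread scales as
#' `1/sqrt(d)` for independent devices, i.e. a straight line of slope -1/2
#' in this space). When no crossing lies inside B's simulated range the
#' nearest endpoint is returned as a bound, flagged in the `bound`
#' attribute.
#'
#' @param result_a,result_b [precision_experiment()] results for the two
#'   device types; `result_a` must include a single-device arm.
#' @return Equivalence factor `k` (devices of B per device of A), with
#'   attribute `bound` (`NA`, `"lower"` or `"upper"`).
#' @export
device_equivalence <- function(result_a, result_b) {
  if (!1 %in% result_a$device_counts) {
    stop("'result_a' must include a single-device arm")
  }
  target <- log(result_a$spread[which(result_a$device_counts == 1)])
  ld <- log(result_b$device_counts)
  ls <- log(result_b$spread)
  ord <- order(ld)
  ld <- ld[ord]; ls <- ls[ord]  # ls decreases along ld for independent devices
  bound <- NA_character_
  if (target > ls[1]) {
    # B at its smallest simulated count is already more precise than one A.
    k <- exp(ld[1])
    bound <- "k_at_most"
  } else if (target < ls[length(ls)]) {
    # even B's largest simulated network is less precise than one A.
    k <- exp(ld[length(ld)])
    bound <- "k_at_least"
  } else {
    k <- exp(stats::approx(ls, ld, xout = target, ties = mean)$y)
  }
  structure(unname(k), bound = bound)
}
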