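#' Fit a protein half-life from a translation shut-off time course
#'
#' Estimates the first-order decay rate of a protein after synthesis
#' shut-off by ordinary least squares of `log(intensity)` on time with a
#' free intercept (the intercept absorbs loading error at time 0). The
#' half-life is `t1/2 = ln(2) / k` with `k = -slope`. When the fitted slope
#' is non-negative the protein is flagged `"stable"` and `t1/2 = Inf`.
#'
#' Given a [decay_timecourse()], the replicates are first normalized to
#' their own time-0 intensity ([normalize_timecourse()]) and averaged
#' ([average_replicates()]); the fit is on the averaged curve. With
#' `per_replicate = TRUE` each replicate is fitted separately as well and
#' the mean and sd of the per-replicate half-lives are reported alongside.
#' A fit in which more than 30% of the points were floored (see
#' [normalize_timecourse()]) is flagged `"low_confidence"`.
#'
#' @param x a [decay_timecourse()], or a numeric vector of times (minutes)
#'   when `values` is given.
#' @param ... passed between methods.
#' @return An object of class `halflife_fit` with elements `t_half`
#'   (minutes), `k` (1/min), `r_squared`, `n_replicates`, `times`,
#'   `normalized_mean`, `normalized_sd`, `flags`, `coefficients`,
#'   `per_replicate` (data.frame or NULL) and `condition_label`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @export
#' @examples
#' tc <- decay_timecourse(seq(0, 60, 10), 100 * 2^(-seq(0, 60, 10) / 26))
#' fit_half_life(tc)
fit_half_life <- function(x, ...) UseMethod("fit_half_life")

# log-linear OLS core; values must be positive
halflife_loglin <- function(times, values) {
  if (length(times) < 3) stop("need at least 3 time points")
  if (length(values) != length(times)) stop("times and values differ in length")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and > 0 (apply the flooring rule first)")
  ly <- log(values)
  fit <- stats::lm(ly ~ times)
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  stable <- slope >= 0
  k <- if (stable) 0 else -slope
  list(k = k, t_half = if (stable) Inf else log(2) / k,
       r_squared = r2, stable = stable,
       coefficients = c(log_intercept = unname(stats::coef(fit)[1]),
                        slope = slope),
       residuals = unname(stats::residuals(fit)),
       fitted_log = unname(stats::fitted(fit)))
}

new_halflife_fit <- function(core, times, mean_norm, sd_norm, n_replicates,
                             flags, per_replicate, condition_label, call) {
  structure(
    list(t_half = core$t_half, k = core$k, r_squared = core$r_squared,
         n_replicates = as.integer(n_replicates),
         times = times, normalized_mean = mean_norm, normalized_sd = sd_norm,
         flags = flags, coefficients = core$coefficients,
         log_residuals = core$residuals,
         per_replicate = per_replicate,
         condition_label = condition_label, call = call),
    class = "halflife_fit")
}

#' @rdname fit_half_life
#' @param values normalized mean intensities (fractions of time 0), same
#'   length as the time vector; default-method interface.
#' @export
fit_half_life.default <- function(x, values, ...) {
  core <- halflife_loglin(as.numeric(x), as.numeric(values))
  flags <- character(0)
  if (core$stable) flags <- "stable"
  new_halflife_fit(core, as.numeric(x), as.numeric(values),
                   rep(NA_real_, length(x)), 1L, flags, NULL, "",
                   match.call())
}

#' @rdname fit_half_life
#' @param per_replicate also fit each replicate separately and report the
#'   mean and sd of the per-replicate half-lives.
#' @param floor_frac passed to [normalize_timecourse()].
#' @param low_confidence_frac flag the fit `"low_confidence"` when more
#'   than this fraction of intensity values was floored; default 0.3.
#' @export
fit_half_life.decay_timecourse <- function(x, per_replicate = FALSE,
                                           floor_frac = 1e-6,
                                           low_confidence_frac = 0.3, ...) {
  tc <- if (x$normalized) x else normalize_timecourse(x, floor_frac)
  avg <- suppressWarnings(average_replicates(tc))
  core <- halflife_loglin(avg$time_min, avg$mean)
  flags <- character(0)
  if (core$stable) flags <- c(flags, "stable")
  if (tc$n_floored / length(tc$intensities) > low_confidence_frac)
    flags <- c(flags, "low_confidence")
  per <- NULL
  if (per_replicate) {
    per <- do.call(rbind, lapply(seq_len(ncol(tc$intensities)), function(j) {
      cj <- halflife_loglin(tc$times, tc$intensities[, j])
      data.frame(replicate = colnames(tc$intensities)[j],
                 t_half = cj$t_half, k = cj$k, r_squared = cj$r_squared,
                 stringsAsFactors = FALSE)
    }))
  }
  new_halflife_fit(core, avg$time_min, avg$mean, avg$sd,
                   ncol(tc$intensities), flags, per, tc$condition_label,
                   match.call())
}

#' @export
print.halflife_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Protein half-life fit%s (log-linear OLS on %d time points, %d replicate%s)\n",
              if (nzchar(x$condition_label)) paste0(" '", x$condition_label, "'") else "",
              length(x$times), x$n_replicates, if (x$n_replicates > 1) "s" else ""))
  if (is.infinite(x$t_half))
    cat("  t1/2 = Inf (stable: no net decay detected)\n")
  else
    cat(sprintf("  t1/2 = %s min  (k = %s /min, r^2 = %s)\n",
                format(x$t_half, digits = digits),
                format(x$k, digits = digits),
                format(x$r_squared, digits = digits)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.halflife_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.halflife_fit")
}

#' @export
print.summary.halflife_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\n  time_min  mean_fraction  sd\n")
  for (i in seq_along(f$times))
    cat(sprintf("  %8g  %13.4g  %.4g\n", f$times[i], f$normalized_mean[i],
                f$normalized_sd[i]))
  if (!is.null(f$per_replicate)) {
    finite <- is.finite(f$per_replicate$t_half)
    cat(sprintf("\n  per-replicate t1/2: mean %.4g min, sd %.4g (n = %d)\n",
                mean(f$per_replicate$t_half[finite]),
                stats::sd(f$per_replicate$t_half[finite]),
                nrow(f$per_replicate)))
  }
  invisible(x)
}

#' @export
coef.halflife_fit <- function(object, ...) {
  c(object$coefficients["log_intercept"], decay_rate_k = object$k,
    t_half = object$t_half)
}

#' @export
predict.halflife_fit <- function(object, times = object$times, ...) {
  b <- object$coefficients
  exp(b[["log_intercept"]] + b[["slope"]] * as.numeric(times))
}

#' @export
fitted.halflife_fit <- function(object, ...) predict(object)

#' @export
residuals.halflife_fit <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  if (type == "log") object$log_residuals
  else object$normalized_mean - fitted(object)
}

#' Plot a half-life fit
#'
#' Mean normalized intensity with replicate-sd error bars on a log y axis,
#' with the fitted exponential overlaid.
#'
#' @param x a `halflife_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.halflife_fit <- function(x, ...) {
  ylim <- range(c(pmax(x$normalized_mean - x$normalized_sd, 1e-4, na.rm = TRUE),
                  x$normalized_mean + ifelse(is.na(x$normalized_sd), 0, x$normalized_sd),
                  1), na.rm = TRUE)
  graphics::plot(x$times, x$normalized_mean, log = "y", ylim = ylim,
                 xlab = "time after shut-off (min)",
                 ylab = "fraction of initial protein",
                 main = if (nzchar(x$condition_label)) x$condition_label else "half-life fit",
                 pch = 19, ...)
  ok <- !is.na(x$normalized_sd) & x$normalized_sd > 1e-8 * x$normalized_mean
  if (any(ok))
    graphics::arrows(x$times[ok], pmax(x$normalized_mean[ok] - x$normalized_sd[ok], 1e-4),
                     x$times[ok], x$normalized_mean[ok] + x$normalized_sd[ok],
                     angle = 90, code = 3, length = 0.04)
  tt <- seq(min(x$times), max(x$times), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  if (is.finite(x$t_half))
    graphics::legend("topright", bty = "n",
                     legend = sprintf("t1/2 = %.3g min", x$t_half))
  invisible(x)
}

#' Simulate new shut-off time courses from a fitted half-life
#'
#' Draws seeded synthetic decay time courses with the fitted half-life on
#' the fitted time grid (see [simulate_decay()]), e.g. for parametric
#' bootstrap checks of the estimator.
#'
#' @param object a `halflife_fit` with finite half-life.
#' @param nsim number of time courses.
#' @param seed integer seed (required).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param ... unused.
#' @return A list of [decay_timecourse()] objects.
#' @export
simulate.halflife_fit <- function(object, nsim = 1, seed = NULL,
                                  noise_cv = 0.1, ...) {
  if (!is.finite(object$t_half)) stop("cannot simulate from a stable (infinite half-life) fit")
  if (is.null(seed)) stop("'seed' is required")
  lapply(seq_len(nsim), function(i)
    simulate_decay(t_half = object$t_half, times = object$times,
                   n_replicates = object$n_replicates, noise_cv = noise_cv,
                   seed = seed + i - 1L,
                   condition_label = object$condition_label))
}
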