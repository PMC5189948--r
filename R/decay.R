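#' Translation shut-off decay time course
#'
#' Band-intensity measurements of a protein after protein synthesis is
#' blocked (chloramphenicol addition at time 0). All replicates share one
#' time grid; intensities are in arbitrary densitometry units.
#'
#' @param times minutes since chloramphenicol addition; non-negative,
#'   strictly increasing, first point 0.
#' @param intensities numeric matrix (rows = time points, columns =
#'   replicates) or a vector for a single replicate; all values >= 0 and
#'   every replicate positive at time 0.
#' @param condition_label text label (e.g. "EtOH_4pct").
#' @param stress_pre_treatment_min minutes of stress pre-incubation before
#'   the shut-off; metadata only (e.g. 5).
#'
#' @return Object of class `decay_timecourse`: list with `times`,
#'   `intensities` (matrix), `condition_label`, `stress_pre_treatment_min`,
#'   `normalized` (logical), `n_floored` (integer).
#' @export
#' @examples
#' decay_timecourse(c(0, 10, 20), c(100, 50, 25))
decay_timecourse <- function(times, intensities, condition_label = "",
                             stress_pre_treatment_min = NA_real_) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(times < 0) || any(diff(times) <= 0))
    stop("'times' must be non-negative and strictly increasing")
  if (times[1] != 0) stop("the first time point must be 0 (shut-off)")
  if (is.vector(intensities)) intensities <- matrix(as.numeric(intensities), ncol = 1)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(times))
    stop("'intensities' must have one row per time point")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0")
  bad0 <- which(intensities[1, ] <= 0)
  if (length(bad0))
    stop(sprintf("replicate%s %s ha%s non-positive intensity at time 0",
                 if (length(bad0) > 1) "s" else "",
                 paste(bad0, collapse = ", "),
                 if (length(bad0) > 1) "ve" else "s"))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("rep", seq_len(ncol(intensities)))
  structure(list(times = times, intensities = intensities,
                 condition_label = as.character(condition_label)[1],
                 stress_pre_treatment_min = stress_pre_treatment_min,
                 normalized = FALSE, n_floored = 0L),
            class = "decay_timecourse")
}

#' @export
print.decay_timecourse <- function(x, ...) {
  cat(sprintf("Decay time course '%s': %d time points (0-%g min), %d replicate%s%s%s\n",
              x$condition_label, length(x$times), max(x$times),
              ncol(x$intensities), if (ncol(x$intensities) > 1) "s" else "",
              if (x$normalized) ", normalized" else "",
              if (x$n_floored > 0) sprintf(", %d floored value(s)", x$n_floored) else ""))
  invisible(x)
}

#' Normalize a decay time course to its time-0 intensity
#'
#' Divides each replicate by its own time-0 intensity so every replicate
#' starts at exactly 1 (fraction of initial protein). Zero intensities at
#' later time points would make the log-linear fit undefined, so values at
#' or below `floor_frac` of the time-0 intensity (i.e. below densitometry
#' detection) are floored to `floor_frac` and counted in `n_floored`
#' rather than dropped.
#'
#' @param tc a [decay_timecourse()].
#' @param floor_frac floor, as a fraction of the time-0 intensity, applied
#'   to non-positive values at t > 0; default 1e-6.
#' @return The normalized `decay_timecourse` (`normalized = TRUE`).
#' @export
normalize_timecourse <- function(tc, floor_frac = 1e-6) {
  if (!inherits(tc, "decay_timecourse")) stop("'tc' must be a decay_timecourse")
  norm <- sweep(tc$intensities, 2, tc$intensities[1, ], "/")
  floored <- norm <= floor_frac
  floored[1, ] <- FALSE
  norm[floored] <- floor_frac
  tc$intensities <- norm
  tc$normalized <- TRUE
  tc$n_floored <- tc$n_floored + sum(floored)
  tc
}

#' Average replicates of a normalized decay time course
#'
#' Pointwise arithmetic mean and sample standard deviation (n - 1
#' denominator) across replicates. With a single replicate the sd is
#' reported as 0 with a warning.
#'
#' @param tc a normalized [decay_timecourse()] (see
#'   [normalize_timecourse()]).
#' @return A data.frame with columns `time_min`, `mean`, `sd`.
#' @export
average_replicates <- function(tc) {
  if (!inherits(tc, "decay_timecourse")) stop("'tc' must be a decay_timecourse")
  if (!tc$normalized) stop("normalize the time course first (normalize_timecourse)")
  nr <- ncol(tc$intensities)
  if (nr == 1L) {
    warning("single replicate: standard deviation reported as 0")
    s <- rep(0, length(tc$times))
  } else {
    s <- apply(tc$intensities, 1, stats::sd)
  }
  data.frame(time_min = tc$times,
             mean = rowMeans(tc$intensities),
             sd = s)
}
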