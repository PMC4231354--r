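# DNA-DNA relatedness from renaturation kinetics, and G+C content from
# thermal melting curves.
#
# In the spectrophotometric renaturation assay, sheared single-stranded
# DNA of organisms A and B, and an equal mixture of the two, re-anneal at
# the optimal renaturation temperature while A260 is recorded. The decline
# rates Va, Vb and Vm (absorbance units per minute) give the relatedness
# percentage by the De Ley formula
#     100 * (4*Vm - Va - Vb) / (2 * sqrt(Va * Vb)).
# The printed form of this expression is typographically ambiguous; the
# standard De Ley (1970) grouping above is used and documented.

#' An absorbance-vs-time renaturation series
#'
#' @param time Times in minutes, strictly increasing.
#' @param a260 Absorbance at 260 nm at each time.
#' @param label `"A"`, `"B"` or `"mix"`.
#' @return An object of class `absorbance_series`.
#' @export
absorbance_series <- function(time, a260, label = "A") {
  time <- as.numeric(time); a260 <- as.numeric(a260)
  if (length(time) != length(a260) || anyNA(time) || anyNA(a260))
    abort("time and a260 must be equal-length numeric vectors", "invalid_input")
  if (is.unsorted(time, strictly = TRUE))
    abort("times must be strictly increasing", "invalid_input")
  structure(list(time = time, a260 = a260, label = label),
            class = "absorbance_series")
}

#' Renaturation rate from an absorbance decline
#'
#' The rate V is minus the ordinary least-squares slope of A260 against
#' time over the window `(exclude_before, window_end]`. The first minutes
#' of the recording are excluded because the cuvette temperature is still
#' stabilising there; the default exclusion is 3 minutes.
#'
#' @param series An [absorbance_series].
#' @param exclude_before Minutes excluded at the start (strict lower
#'   bound; default 3).
#' @param window_end End of the regression window in minutes (inclusive);
#'   defaults to the last recorded time.
#' @return The rate V in absorbance units per minute (positive for a
#'   declining series).
#' @examples
#' s <- absorbance_series(0:21, 1 - 0.01 * (0:21))
#' renaturation_rate(s)  # 0.01
#' @export
renaturation_rate <- function(series, exclude_before = 3,
                              window_end = max(series$time)) {
  stopifnot(inherits(series, "absorbance_series"))
  keep <- series$time > exclude_before & series$time <= window_end
  if (sum(keep) < 2L)
    abort(sprintf("fewer than 2 usable points in (%g, %g]",
                  exclude_before, window_end), "insufficient_data")
  fit <- stats::lm.fit(cbind(1, series$time[keep]),
                       series$a260[keep])
  -unname(fit$coefficients[2])
}

#' De Ley reassociation percentage from three renaturation rates
#'
#' `100 * (4*Vm - Va - Vb) / (2 * sqrt(Va * Vb))`. The value is symmetric
#' in Va and Vb and invariant to a common rescaling of all three rates.
#' On noisy input it can exceed 100 or fall below 0; it is reported
#' unclamped, with a flag attribute, because silent truncation would hide
#' assay problems.
#'
#' @param Va,Vb,Vm Positive renaturation rates for organism A, organism B
#'   and the equal mixture.
#' @return Percentage relatedness (unclamped). Values outside `[0, 100]`
#'   carry attribute `flag = "outside [0, 100]"`.
#' @examples
#' reassociation_percent(1, 4, 1.5)  # 25
#' @export
reassociation_percent <- function(Va, Vb, Vm) {
  if (!all(is.finite(c(Va, Vb, Vm))) || Va <= 0 || Vb <= 0 || Vm <= 0)
    abort("Va, Vb and Vm must all be positive", "invalid_input")
  pct <- 100 * (4 * Vm - Va - Vb) / (2 * sqrt(Va * Vb))
  eps <- 1e-8  # do not flag floating-point dust at the boundaries
  if (pct < -eps || pct > 100 + eps) attr(pct, "flag") <- "outside [0, 100]"
  pct
}

#' DNA-DNA relatedness from three renaturation series
#'
#' Computes, for each reading timepoint (default 21 and 24 minutes), the
#' three rates over the window `(exclude_before, timepoint]` and the De
#' Ley percentage, and reports their mean.
#'
#' @param seriesA,seriesB,seriesMix [absorbance_series] for organism A,
#'   organism B and the equal mixture.
#' @param timepoints Reading times in minutes.
#' @param exclude_before Initial minutes excluded from every rate fit.
#' @return An object of class `ddh_result`: `percent_relatedness` (the
#'   mean), `per_timepoint` (named vector), `timepoints_used`, `rates`
#'   (per-timepoint Va/Vb/Vm), `flags`.
#' @export
ddh <- function(seriesA, seriesB, seriesMix, timepoints = c(21, 24),
                exclude_before = 3) {
  if (missing(seriesA) || missing(seriesB) || missing(seriesMix) ||
      is.null(seriesA) || is.null(seriesB) || is.null(seriesMix))
    abort("ddh requires all three series (A, B, mix)", "invalid_input")
  per <- numeric(length(timepoints))
  rates <- vector("list", length(timepoints))
  flags <- character(0)
  for (i in seq_along(timepoints)) {
    tp <- timepoints[i]
    Va <- renaturation_rate(seriesA, exclude_before, tp)
    Vb <- renaturation_rate(seriesB, exclude_before, tp)
    Vm <- renaturation_rate(seriesMix, exclude_before, tp)
    pct <- reassociation_percent(Va, Vb, Vm)
    if (!is.null(attr(pct, "flag")))
      flags <- c(flags, sprintf("t=%g min: %s", tp, attr(pct, "flag")))
    per[i] <- as.numeric(pct)
    rates[[i]] <- c(Va = Va, Vb = Vb, Vm = Vm)
  }
  names(per) <- paste0("t", timepoints)
  names(rates) <- paste0("t", timepoints)
  structure(list(percent_relatedness = mean(per), per_timepoint = per,
                 timepoints_used = timepoints, rates = rates, flags = flags),
            class = "ddh_result")
}

#' @export
print.ddh_result <- function(x, ...) {
  cat(sprintf("DNA-DNA relatedness: %.1f%% (mean over readings at %s min)\n",
              x$percent_relatedness,
              paste(x$timepoints_used, collapse = ", ")))
  cat("  per timepoint:",
      paste(sprintf("%s = %.1f%%", names(x$per_timepoint), x$per_timepoint),
            collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' A DNA thermal melting curve
#'
#' @param temperature Temperatures in degrees C, strictly increasing.
#' @param a260 Absorbance at 260 nm.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, a260) {
  temperature <- as.numeric(temperature); a260 <- as.numeric(a260)
  if (length(temperature) != length(a260) || anyNA(temperature) || anyNA(a260))
    abort("temperature and a260 must be equal-length numerics", "invalid_input")
  if (is.unsorted(temperature, strictly = TRUE))
    abort("temperatures must be strictly increasing", "invalid_input")
  structure(list(temperature = temperature, a260 = a260),
            class = "melting_curve")
}

#' Melting midpoint (Tm) of a hyperchromic rise
#'
#' Tm is the temperature at which the absorbance has completed half of its
#' total rise, linearly interpolated between the flanking recorded points.
#' A curve with no rise (flat or declining) has no melting transition and
#' raises a `no_transition` condition.
#'
#' @param curve A [melting_curve].
#' @return Tm in degrees C.
#' @export
tm_from_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  a <- curve$a260; tt <- curve$temperature
  lo <- min(a); hi <- max(a)
  if (hi - lo <= 1e-12 * max(abs(hi), 1))
    abort("curve is flat: no hyperchromic rise", "no_transition")
  half <- (lo + hi) / 2
  i <- which(a >= half)[1]
  if (i == 1L)
    abort("curve starts above its half-rise: no transition recorded",
          "no_transition")
  # linear interpolation across the crossing
  tt[i - 1] + (half - a[i - 1]) / (a[i] - a[i - 1]) * (tt[i] - tt[i - 1])
}

#' G+C content from a melting midpoint
#'
#' Applies a linear Tm-to-G+C calibration `gc = a * Tm + b`. The
#' calibration depends on the solvent and instrument and is therefore a
#' configuration, not a constant; the shipped default `(2.44, -169.1)` is
#' the classical 1xSSC relation GC = 2.44 (Tm - 69.3).
#'
#' @param Tm Melting midpoint in degrees C.
#' @param coefficients Numeric `c(a, b)` of the linear calibration.
#' @return A list of class `gc_estimate`: `Tm`, `gc_percent`,
#'   `coefficients`.
#' @examples
#' gc_from_tm(94.4)$gc_percent  # about 61.2
#' @export
gc_from_tm <- function(Tm, coefficients = c(2.44, -169.1)) {
  if (!is.numeric(coefficients) || length(coefficients) != 2L)
    abort("coefficients must be numeric c(a, b)", "invalid_input")
  gc <- coefficients[1] * Tm + coefficients[2]
  if (gc < 0 || gc > 100)
    abort(sprintf("calibration gives G+C = %.1f%%, outside [0, 100]", gc),
          "invalid_input")
  structure(list(Tm = Tm, gc_percent = gc, coefficients = coefficients),
            class = "gc_estimate")
}
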