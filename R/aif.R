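#' Arterial input function container
#'
#' An AIF is the plasma contrast-agent concentration curve \eqn{C_p(t)} that
#' drives the tracer-kinetic models. Stored as a simple list with a time base
#' in seconds and concentrations in mM.
#'
#' @param times Numeric vector of sample times in seconds, non-negative and
#'   strictly increasing.
#' @param cp Numeric vector of plasma concentrations in mM, same length as
#'   `times`, non-negative.
#' @return An object of class `dce_aif` with elements `times` and `cp`.
#' @export
aif <- function(times, cp) {
  stopifnot(is.numeric(times), is.numeric(cp))
  if (length(times) == 0L) stop("AIF time base must be non-empty")
  if (length(times) != length(cp)) stop("times and cp must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(cp))) stop("AIF values must be finite")
  if (any(diff(times) <= 0)) stop("AIF times must be strictly increasing")
  if (min(times) < 0) stop("AIF times must be non-negative")
  if (any(cp < -1e-12)) stop("plasma concentration must be non-negative")
  structure(list(times = as.numeric(times), cp = pmax(as.numeric(cp), 0)),
            class = "dce_aif")
}

#' Synthesize a population-shaped arterial input function
#'
#' Models the first-pass bolus as a linear ramp from contrast arrival (`onset`)
#' to the peak, followed by bi-exponential washout (a fast distribution phase
#' and a slow clearance phase). The curve is identically zero before the bolus
#' arrives and is continuous at the peak.
#'
#' @param timebase Numeric vector of sample times, seconds.
#' @param onset Bolus-arrival time, seconds; must lie inside the time base.
#' @param peak_amplitude Peak plasma concentration, mM (>= 0).
#' @param decay_rates Length-2 numeric, fast and slow washout rate constants
#'   in 1/s; both > 0.
#' @param rise_time Ramp duration from onset to peak, seconds (default 8 s,
#'   a typical first-pass upslope at clinical injection rates).
#' @param frac_fast Weight of the fast washout component in (0, 1).
#' @return A [aif()] object.
#' @examples
#' a <- generate_aif(seq(0, 300, by = 2), onset = 30, peak_amplitude = 6)
#' max(a$cp)
#' @export
generate_aif <- function(timebase, onset = 30, peak_amplitude = 6,
                         decay_rates = c(0.03, 0.0015), rise_time = 8,
                         frac_fast = 0.6) {
  if (length(timebase) == 0L) stop("empty timebase")
  if (peak_amplitude < 0) stop("peak_amplitude must be non-negative")
  if (onset < min(timebase) || onset > max(timebase))
    stop("onset must lie within the timebase")
  stopifnot(length(decay_rates) == 2L, all(decay_rates > 0), rise_time > 0,
            frac_fast > 0, frac_fast < 1)
  t <- as.numeric(timebase)
  tp <- onset + rise_time
  cp <- numeric(length(t))
  ramp <- t > onset & t <= tp
  cp[ramp] <- peak_amplitude * (t[ramp] - onset) / rise_time
  wash <- t > tp
  dt <- t[wash] - tp
  cp[wash] <- peak_amplitude *
    (frac_fast * exp(-decay_rates[1] * dt) +
       (1 - frac_fast) * exp(-decay_rates[2] * dt))
  aif(t, cp)
}

#' Closed-form time integral of the synthetic AIF
#'
#' Analytic antiderivative of the ramp + bi-exponential form on
#' `[min(timebase), t_end]`; used as an independent check on numerical
#' integration of the sampled curve.
#'
#' @inheritParams generate_aif
#' @param t_end Upper integration limit, seconds.
#' @return Integral of cp dt in mM*s.
#' @export
aif_integral <- function(t_end, onset = 30, peak_amplitude = 6,
                         decay_rates = c(0.03, 0.0015), rise_time = 8,
                         frac_fast = 0.6) {
  tp <- onset + rise_time
  if (t_end <= onset) return(0)
  ramp_part <- if (t_end >= tp) {
    peak_amplitude * rise_time / 2
  } else {
    peak_amplitude * (t_end - onset)^2 / (2 * rise_time)
  }
  wash_part <- 0
  if (t_end > tp) {
    d <- t_end - tp
    k1 <- decay_rates[1]; k2 <- decay_rates[2]
    wash_part <- peak_amplitude *
      (frac_fast * (1 - exp(-k1 * d)) / k1 +
         (1 - frac_fast) * (1 - exp(-k2 * d)) / k2)
  }
  ramp_part + wash_part
}

#' Write / read an AIF as a two-column CSV (time_s, cp_mM)
#'
#' @param x A [aif()] object.
#' @param path Output CSV path.
#' @return `write_aif` returns `path` invisibly; `read_aif` returns a
#'   [aif()] object.
#' @export
write_aif <- function(x, path) {
  stopifnot(inherits(x, "dce_aif"))
  utils::write.csv(data.frame(time_s = x$times, cp_mM = x$cp), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  d <- utils::read.csv(path)
  aif(d$time_s, d$cp_mM)
}
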