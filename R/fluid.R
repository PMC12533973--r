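#' Blood rheological properties
#'
#' Newtonian blood model used throughout: dynamic viscosity in centipoise and
#' bulk density in g/cc. Defaults are the standard whole-blood values (4.0 cP,
#' 1.06 g/cc).
#'
#' @param viscosity dynamic viscosity, cP.
#' @param density bulk density, g/cc.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 4.0, density = 1.06) {
  stopifnot(is.numeric(viscosity), viscosity > 0, is.numeric(density), density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' Periodic aortic inflow waveform
#'
#' Builds a pulsatile inlet flow pulse `Q(t)` on a uniform grid over one
#' cardiac cycle. The shape is an offset half-sine systolic pulse: flow sits at
#' `diastolic_level` times the mean through diastole and rises as a half sine
#' over the systolic fraction of the cycle. The discrete grid values are
#' rescaled so the cycle mean equals `mean_flow` exactly.
#'
#' @param period cardiac cycle duration, s.
#' @param mean_flow cycle-averaged flow (cardiac output), mL/s.
#' @param systole_fraction fraction of the cycle occupied by the systolic pulse.
#' @param diastolic_level diastolic flow as a fraction of the mean.
#' @param dt time grid spacing, s.
#' @return object of class `cardiac_waveform` with fields `period`,
#'   `mean_flow`, `t` (grid, s) and `q` (flow, mL/s).
#' @export
cardiac_waveform <- function(period = 0.83, mean_flow = 79,
                             systole_fraction = 0.36, diastolic_level = 0.25,
                             dt = 1e-3) {
  stopifnot(period > 0, mean_flow > 0,
            systole_fraction > 0, systole_fraction < 1,
            diastolic_level >= 0, diastolic_level < 1)
  nt <- round(period / dt)
  t <- (seq_len(nt) - 1) * dt
  tau <- t / period
  a <- diastolic_level
  b <- (1 - a) * pi / (2 * systole_fraction)
  shape <- ifelse(tau < systole_fraction,
                  a + b * sin(pi * tau / systole_fraction), a)
  q <- shape * mean_flow / mean(shape)
  structure(list(period = period, mean_flow = mean_flow, t = t, q = q, dt = dt),
            class = "cardiac_waveform")
}

#' Flow at arbitrary time from a waveform (periodic linear interpolation)
#' @param wf a `cardiac_waveform`.
#' @param time time(s), s; interpreted modulo the period.
#' @return flow, mL/s.
#' @export
waveform_flow <- function(wf, time) {
  tt <- time %% wf$period
  n <- length(wf$q)
  i0 <- floor(tt / wf$dt)
  frac <- tt / wf$dt - i0
  i0 <- (i0 %% n) + 1
  i1 <- (i0 %% n) + 1
  wf$q[i0] * (1 - frac) + wf$q[i1] * frac
}
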