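#' Derive central aortic pressure targets from brachial cuff pressures
#'
#' Diastolic pressure is taken as constant along the arterial tree, so the
#' aortic diastolic target equals the brachial measurement. The aortic
#' systolic target is obtained from the brachial pressures with the linear
#' transfer `Psa = 0.83*Psb + 0.15*Pdb`. The weighted mean pressure is
#' `Pmean = 0.4*Psa + 0.6*Pda`, the usual diastole-weighted estimate of the
#' time-averaged arterial pressure.
#'
#' @param psb brachial systolic pressure (mmHg).
#' @param pdb brachial diastolic pressure (mmHg).
#' @param round_psa logical; if `TRUE` (default) the integer-rounded systolic
#'   target is used when forming the mean pressure, so that reported mean
#'   pressures match integer-precision clinical tables. The full-precision
#'   systolic value is always retained in the `psa` field.
#' @param transfer numeric length-2: coefficients of `Psb` and `Pdb` in the
#'   systolic transfer (default `c(0.83, 0.15)`).
#' @param mean_weights numeric length-2: weights of systolic and diastolic
#'   pressure in the mean (default `c(0.4, 0.6)`).
#'
#' @return an object of class `pressure_targets`: a list with fields `psb`,
#'   `pdb`, `psa` (full precision), `psa_presentation` (integer-rounded),
#'   `pda`, `ppulse`, `pmean` (all mmHg).
#' @export
#' @examples
#' derive_central_pressures(117, 72)
derive_central_pressures <- function(psb, pdb, round_psa = TRUE,
                                     transfer = c(0.83, 0.15),
                                     mean_weights = c(0.4, 0.6)) {
  stopifnot(is.numeric(psb), is.numeric(pdb), length(psb) == 1L,
            length(pdb) == 1L, is.finite(psb), is.finite(pdb))
  if (pdb <= 0) stop("brachial diastolic pressure must be positive")
  if (psb <= pdb) stop("brachial systolic must exceed diastolic (no pulse)")
  stopifnot(length(transfer) == 2L, length(mean_weights) == 2L,
            abs(sum(mean_weights) - 1) < 1e-12)

  psa <- transfer[1] * psb + transfer[2] * pdb
  psa_pres <- round(psa)
  pda <- pdb
  psa_for_mean <- if (round_psa) psa_pres else psa
  pmean <- mean_weights[1] * psa_for_mean + mean_weights[2] * pda

  structure(list(
    psb = psb, pdb = pdb,
    psa = psa, psa_presentation = psa_pres,
    pda = pda,
    ppulse = psa_for_mean - pda,
    pmean = pmean
  ), class = "pressure_targets")
}

#' @export
print.pressure_targets <- function(x, ...) {
  cat("Central pressure targets (mmHg)\n")
  cat(sprintf("  brachial: %g / %g\n", x$psb, x$pdb))
  cat(sprintf("  aortic systolic:  %.2f (reported %d)\n",
              x$psa, as.integer(x$psa_presentation)))
  cat(sprintf("  aortic diastolic: %.2f\n", x$pda))
  cat(sprintf("  pulse: %.2f   mean: %.2f\n", x$ppulse, x$pmean))
  invisible(x)
}

#' Resample a sparse inlet flow waveform onto a 1 ms periodic grid
#'
#' Takes sparse (time, flow) measurements covering one cardiac cycle (as
#' extracted from 4D-flow MRI at the ascending aorta) and produces a smooth
#' periodic waveform with 1 ms increments using shape-preserving monotone
#' piecewise-cubic interpolation. Monotone interpolation is used rather than
#' an unconstrained cubic spline so the resampled waveform cannot overshoot
#' the measurements (e.g. producing spurious negative flow in diastole).
#'
#' Periodicity is enforced by appending the first sample at `t = period`
#' before interpolation; the returned grid carries a final sample exactly at
#' the period so that the first and last values agree.
#'
#' @param samples a data.frame or list with numeric fields `t` (s) and `Q`
#'   (ml/s), at least 8 points spanning one cycle.
#' @param heart_rate heart rate in beats per minute; the cardiac period is
#'   `60/heart_rate` s.
#' @param dt output grid spacing in seconds (default 1e-3).
#' @return an object of class `flow_waveform`: list with fields `t`, `Q`,
#'   `period`, `qmean`, and `q_fun` (a periodic interpolant `function(t)`).
#' @export
resample_inlet_waveform <- function(samples, heart_rate, dt = 1e-3) {
  t <- as.numeric(samples$t)
  Q <- as.numeric(samples$Q)
  if (length(t) < 8L) stop("need at least 8 samples covering one cycle")
  if (length(t) != length(Q)) stop("t and Q lengths differ")
  if (any(!is.finite(t)) || any(!is.finite(Q))) stop("non-finite samples")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (heart_rate <= 0) stop("heart rate must be positive")

  period <- 60 / heart_rate
  span <- max(t) - min(t)
  if (span < 0.9 * period)
    stop(sprintf("samples span %.3f s, less than 90%% of the %.3f s period",
                 span, period))

  t0 <- t - min(t)
  keep <- t0 < period - 1e-12
  t0 <- t0[keep]; Q0 <- Q[keep]
  # close the cycle: the waveform drives a periodic ODE
  tc <- c(t0, period)
  Qc <- c(Q0, Q0[1])

  f <- stats::splinefun(tc, Qc, method = "monoH.FC")
  grid <- seq(0, period - dt / 2, by = dt)
  tg <- c(grid, period)
  Qg <- f(tg)

  rng <- range(Qc)
  tol <- 0.05 * max(diff(rng), 1e-12)
  # monotone interpolation guarantees this; clamp guards rounding only
  Qg <- pmin(pmax(Qg, rng[1] - tol), rng[2] + tol)

  q_fun <- make_periodic_fun(tg, Qg, period)
  qmean <- trapz(tg, Qg) / period

  structure(list(t = tg, Q = Qg, period = period, qmean = qmean,
                 q_fun = q_fun),
            class = "flow_waveform")
}

#' Construct a flow_waveform from an already-dense periodic trace
#'
#' Used by the synthetic-physiology generator; the trace must start at t = 0
#' and its last sample is taken to close the cycle at t = period.
#' @param t time grid (s), starting at 0, last point at the period.
#' @param Q flow values (ml/s), `Q[1] == Q[length(Q)]` within rounding.
#' @param period cardiac period (s).
#' @return a `flow_waveform` object.
#' @keywords internal
#' @export
flow_waveform <- function(t, Q, period) {
  stopifnot(length(t) == length(Q), t[1] == 0,
            abs(t[length(t)] - period) < 1e-9)
  q_fun <- make_periodic_fun(t, Q, period)
  structure(list(t = t, Q = Q, period = period,
                 qmean = trapz(t, Q) / period, q_fun = q_fun),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "Flow waveform: period %.4f s, %d samples, mean %.2f ml/s, peak %.1f ml/s\n",
    x$period, length(x$t), x$qmean, max(x$Q)))
  invisible(x)
}

make_periodic_fun <- function(t, Q, period) {
  f <- stats::approxfun(t, Q, rule = 2)
  function(tt) f(tt %% period)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Total mean supra-aortic flow from inlet and descending-aorta plane flows
#'
#' Flow measurements in the narrow supra-aortic branches carry high
#' uncertainty, so the total supra-aortic flow is inferred by mass balance:
#' the mean inlet flow minus the average of the mean flows measured at four
#' descending-aorta analysis planes.
#'
#' @param qinlet_mean mean inlet flow (ml/s).
#' @param qda numeric vector of 4 descending-aorta plane mean flows (ml/s).
#' @return total supra-aortic mean flow (ml/s).
#' @export
#' @examples
#' supra_aortic_flow(82.73, rep(44.44, 4))
supra_aortic_flow <- function(qinlet_mean, qda) {
  stopifnot(length(qinlet_mean) == 1L, length(qda) == 4L)
  if (qinlet_mean <= 0 || any(qda <= 0)) stop("flows must be positive")
  qda_mean <- mean(qda)
  if (qda_mean > qinlet_mean)
    stop("mean descending-aorta flow exceeds inlet flow: non-physical")
  qinlet_mean - qda_mean
}

#' Split supra-aortic flow between branches by diastolic area
#'
#' The total supra-aortic flow is divided proportionally to each branch's
#' diastolic cross-sectional area. The shares sum to the total exactly.
#'
#' @param qsa total supra-aortic mean flow (ml/s).
#' @param areas named numeric vector of per-branch diastolic areas (any
#'   consistent unit).
#' @return named numeric vector of per-branch mean-flow targets (ml/s).
#' @export
split_flow_by_area <- function(qsa, areas) {
  if (length(areas) == 0L) stop("empty area list")
  if (any(areas <= 0)) stop("areas must be positive")
  if (qsa < 0) stop("supra-aortic flow must be non-negative")
  qsa * areas / sum(areas)
}

#' Total outlet resistance from mean pressure and mean flow
#'
#' Each outlet's total (proximal + distal) Windkessel resistance is fixed by
#' the mean pressure/flow balance `Rtot = Pmean / Qmean`.
#'
#' @param pmean mean aortic pressure (mmHg).
#' @param qi outlet mean flow (ml/s).
#' @return total resistance (mmHg/(ml/s)).
#' @export
#' @examples
#' total_outlet_resistance(86.4, 44.44)
total_outlet_resistance <- function(pmean, qi) {
  stopifnot(is.numeric(pmean), is.numeric(qi))
  if (any(qi <= 0)) stop("outlet mean flow must be positive")
  if (any(pmean <= 0)) stop("mean pressure must be positive")
  pmean / qi
}

#' Assemble the full calibration flow-target set
#'
#' Combines the mean inlet flow, the four descending-aorta plane flows and
#' the supra-aortic branch areas into per-outlet mean-flow targets: the three
#' supra-aortic branches split the inferred supra-aortic flow by area, and
#' the terminal outlet (abdominal aorta) receives the descending-aorta mean.
#'
#' @param qinlet_mean mean inlet flow (ml/s).
#' @param qda four descending-aorta plane mean flows (ml/s).
#' @param sa_areas named areas of the supra-aortic branches (typically
#'   `c(BT=, LCC=, LSA=)`).
#' @param terminal_id name of the terminal outlet (default `"AbAo"`).
#' @return object of class `flow_targets`: list with `qinlet_mean`, `qda`,
#'   `qsa`, and `targets` (named per-outlet mean flows, supra-aortic branches
#'   first then the terminal outlet).
#' @export
flow_targets <- function(qinlet_mean, qda, sa_areas, terminal_id = "AbAo") {
  qsa <- supra_aortic_flow(qinlet_mean, qda)
  qi <- split_flow_by_area(qsa, sa_areas)
  qterm <- qinlet_mean - qsa
  targets <- c(qi, stats::setNames(qterm, terminal_id))
  structure(list(qinlet_mean = qinlet_mean, qda = qda, qsa = qsa,
                 targets = targets),
            class = "flow_targets")
}

#' @export
print.flow_targets <- function(x, ...) {
  cat(sprintf("Flow targets (ml/s): inlet %.2f, supra-aortic %.2f\n",
              x$qinlet_mean, x$qsa))
  print(round(x$targets, 2))
  invisible(x)
}

#' Read an inlet flow waveform CSV
#'
#' Expects a header and two columns `time_s,flow_ml_s`.
#' @param path CSV file path.
#' @return data.frame with fields `t` (s) and `Q` (ml/s).
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "flow_ml_s") %in% names(d)))
    stop("waveform CSV must have columns time_s,flow_ml_s")
  data.frame(t = d$time_s, Q = d$flow_ml_s)
}

#' Write an inlet flow waveform CSV
#' @param w a `flow_waveform`.
#' @param path output path.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$t, flow_ml_s = w$Q), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
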