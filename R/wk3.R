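#' Three-element Windkessel parameter set
#'
#' Proximal resistance in series with a parallel capacitance /
#' distal-resistance pair, the standard lumped model of the vasculature
#' downstream of one outlet.
#'
#' @param Rp proximal resistance (mmHg/(ml/s)).
#' @param Rd distal resistance (mmHg/(ml/s)).
#' @param C capacitance (ml/mmHg).
#' @param id outlet identifier.
#' @return object of class `wk3_params`.
#' @export
wk3_params <- function(Rp, Rd, C, id = "outlet") {
  stopifnot(Rp > 0, Rd > 0, C > 0)
  structure(list(Rp = Rp, Rd = Rd, C = C, id = id), class = "wk3_params")
}

#' Whole-system single-Windkessel analogue
#'
#' @param Rptot total proximal resistance (mmHg/(ml/s)).
#' @param Rdtot total distal resistance (mmHg/(ml/s)).
#' @param Ctot total arterial compliance (ml/mmHg).
#' @return object of class `system_wk3`.
#' @export
system_wk3 <- function(Rptot, Rdtot, Ctot) {
  stopifnot(Rptot > 0, Rdtot > 0, Ctot > 0)
  structure(list(Rptot = Rptot, Rdtot = Rdtot, Ctot = Ctot),
            class = "system_wk3")
}

as_wk3 <- function(x) {
  if (inherits(x, "wk3_params")) return(x)
  if (inherits(x, "system_wk3"))
    return(wk3_params(x$Rptot, x$Rdtot, x$Ctot, id = "system"))
  stop("expected wk3_params or system_wk3")
}

#' Solve a single three-element Windkessel driven by a flow waveform
#'
#' Integrates the Windkessel ODE `C dPc/dt = Q - Pc/Rd` with inlet pressure
#' `Pin = Pc + Q*Rp`, cycle by cycle from an initial capacitor pressure,
#' until periodic convergence (systolic and diastolic inlet pressures change
#' by less than `conv_tol` between consecutive cycles) or `n_cycles` is
#' reached. Uses backward-differentiation (BDF) stiff integration.
#'
#' @param wk3 a `wk3_params` or `system_wk3`.
#' @param Q a `flow_waveform` (periodic).
#' @param n_cycles maximum cycles (default 20).
#' @param p0 initial capacitor pressure (mmHg, default 70).
#' @param conv_tol periodic-convergence tolerance (default 0.01 = 1%).
#' @param dt output grid spacing (s).
#' @return object of class `sim_result_0d` (see [solve_network()]), with a
#'   single outlet flow trace `q_out` equal to `Pc/Rd`.
#' @export
solve_single_wk3 <- function(wk3, Q, n_cycles = 20, p0 = 70,
                             conv_tol = 0.01, dt = 1e-3) {
  wk3 <- as_wk3(wk3)
  if (!inherits(Q, "flow_waveform")) stop("Q must be a periodic flow_waveform")
  period <- Q$period
  qf <- Q$q_fun
  tg <- unique(c(seq(0, period - dt / 2, by = dt), period))

  rhs <- function(t, y, parms) {
    q <- qf(t)
    list((q - y[1] / wk3$Rd) / wk3$C)
  }

  y <- c(Pc = p0)
  percycle <- NULL
  converged <- FALSE
  cycles <- 0L
  last <- NULL
  for (cyc in seq_len(n_cycles)) {
    sol <- deSolve::ode(y, tg, rhs, parms = NULL, method = "bdf",
                        rtol = 1e-8, atol = 1e-8)
    pc <- sol[, "Pc"]
    qin <- qf(tg)
    pin <- pc + qin * wk3$Rp
    ext <- c(psys = max(pin), pdias = min(pin))
    percycle <- rbind(percycle, ext)
    y <- c(Pc = unname(pc[length(pc)]))
    cycles <- cyc
    last <- list(t = tg, p_inlet = pin, pc = pc, qin = qin)
    if (cyc > 1L) {
      prev <- percycle[cyc - 1L, ]
      if (all(abs(ext - prev) / abs(prev) < conv_tol)) {
        converged <- TRUE
        break
      }
    }
  }

  q_out <- matrix(last$pc / wk3$Rd, ncol = 1,
                  dimnames = list(NULL, wk3$id))
  new_sim_result(t = last$t, p_inlet = last$p_inlet, q_out = q_out,
                 percycle = percycle, cycles = cycles,
                 converged = converged, qin = last$qin, period = period)
}

new_sim_result <- function(t, p_inlet, q_out, percycle, cycles, converged,
                           qin, period, state = NULL, q_units = NULL) {
  n <- length(t)
  w <- diff(t)
  tm <- function(y) sum(w * (y[-1] + y[-n]) / 2) / period
  qout_mean <- apply(q_out, 2, tm)
  qin_mean <- tm(qin)
  mass_err <- abs(qin_mean - sum(qout_mean)) / abs(qin_mean)
  structure(list(
    t = t, p_inlet = p_inlet, q_out = q_out, qin = qin,
    psys = max(p_inlet), pdias = min(p_inlet),
    pmean = tm(p_inlet),
    qin_mean = qin_mean, qout_mean = qout_mean,
    mass_balance_error = mass_err,
    percycle = percycle, cycles = cycles, converged = converged,
    period = period, state = state, q_units = q_units
  ), class = "sim_result_0d")
}

#' @export
print.sim_result_0d <- function(x, ...) {
  cat(sprintf(
    "0D solution: %d cycle(s), %s; inlet %.1f/%.1f mmHg (mean %.1f)\n",
    x$cycles, if (x$converged) "periodic" else "NOT converged",
    x$psys, x$pdias, x$pmean))
  cat(sprintf("  mean inflow %.2f ml/s; outlet means: %s; mass error %.2f%%\n",
              x$qin_mean,
              paste(sprintf("%s %.2f", names(x$qout_mean), x$qout_mean),
                    collapse = ", "),
              100 * x$mass_balance_error))
  invisible(x)
}

#' Closed-form input impedance of a three-element Windkessel
#'
#' `Z(w) = Rp + Rd / (1 + i*w*Rd*C)` at angular frequency `w`. Used as the
#' analytic oracle for the numeric solver under single-frequency forcing.
#'
#' @param omega angular frequency (rad/s).
#' @param wk3 `wk3_params`.
#' @return complex impedance (mmHg/(ml/s)).
#' @export
wk3_impedance <- function(omega, wk3) {
  wk3 <- as_wk3(wk3)
  wk3$Rp + wk3$Rd / (1 + 1i * omega * wk3$Rd * wk3$C)
}

#' Tune a whole-system single Windkessel to the pressure targets
#'
#' Determines total arterial compliance (and total resistance) such that the
#' single-Windkessel analogue of the full arterial system, driven by the
#' inlet waveform, shows the target systolic and diastolic pressures at its
#' inlet. The total resistance is initialised from the mean-pressure balance
#' `Rtot = Pmean/Qmean` with a fixed proximal share (default 5%), the
#' compliance is found by a bounded root-find on the pulse-pressure error,
#' and an outer pass re-scales `Rtot` against the weighted-mean residual.
#' Matching the weighted mean (`0.4*Psys + 0.6*Pdias`) and the pulse
#' pressure is algebraically equivalent to matching both targets.
#'
#' @param Q `flow_waveform`.
#' @param targets `pressure_targets`.
#' @param tol relative tolerance on systolic and diastolic pressure
#'   (default 0.005 = 0.5%).
#' @param rp_frac proximal share of the total resistance (default 0.05).
#' @param c_bounds search interval for `Ctot` (ml/mmHg).
#' @param max_passes maximum outer resistance-refinement passes.
#' @param conv_tol periodic-convergence tolerance passed to the solver.
#' @return a `system_wk3` with attributes `achieved` (named psys/pdias),
#'   `iterations` (data.frame log) and `converged` (logical).
#' @export
tune_system_wk3 <- function(Q, targets, tol = 0.005, rp_frac = 0.05,
                            c_bounds = c(1e-3, 50), max_passes = 4,
                            conv_tol = 0.005) {
  stopifnot(inherits(Q, "flow_waveform"), inherits(targets, "pressure_targets"))
  if (Q$qmean <= 0) stop("mean inlet flow must be positive")
  psa_t <- targets$pmean + 0.6 * targets$ppulse
  pda_t <- targets$pmean - 0.4 * targets$ppulse
  rtot <- targets$pmean / Q$qmean

  simulate <- function(rtot, ctot) {
    wk <- wk3_params(rp_frac * rtot, (1 - rp_frac) * rtot, ctot,
                     id = "system")
    solve_single_wk3(wk, Q, n_cycles = 30, p0 = pda_t,
                     conv_tol = conv_tol)
  }

  log <- NULL
  ctot <- NA_real_
  for (pass in seq_len(max_passes)) {
    f <- function(logc) {
      s <- simulate(rtot, 10^logc)
      (s$psys - s$pdias) - targets$ppulse
    }
    lo <- log10(c_bounds[1]); hi <- log10(c_bounds[2])
    # pulse pressure decreases monotonically with compliance
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-4)
    ctot <- 10^root$root
    s <- simulate(rtot, ctot)
    err_s <- (s$psys - psa_t) / psa_t
    err_d <- (s$pdias - pda_t) / pda_t
    log <- rbind(log, data.frame(pass = pass, rtot = rtot, ctot = ctot,
                                 psys = s$psys, pdias = s$pdias,
                                 err_sys = err_s, err_dias = err_d))
    if (abs(err_s) < tol && abs(err_d) < tol) {
      out <- system_wk3(rp_frac * rtot, (1 - rp_frac) * rtot, ctot)
      attr(out, "achieved") <- c(psys = s$psys, pdias = s$pdias)
      attr(out, "iterations") <- log
      attr(out, "converged") <- TRUE
      return(out)
    }
    pw <- 0.4 * s$psys + 0.6 * s$pdias
    rtot <- rtot * targets$pmean / pw
  }
  warning(sprintf(
    "system Windkessel tuning did not reach %.2f%% tolerance; residuals %.3f%%/%.3f%%",
    100 * tol, 100 * log$err_sys[nrow(log)], 100 * log$err_dias[nrow(log)]))
  out <- system_wk3(rp_frac * rtot, (1 - rp_frac) * rtot, ctot)
  attr(out, "achieved") <- c(psys = log$psys[nrow(log)],
                             pdias = log$pdias[nrow(log)])
  attr(out, "iterations") <- log
  attr(out, "converged") <- FALSE
  out
}

#' Initial proximal resistance from characteristic impedance
#'
#' `Rp = rho * PWV / A`, the characteristic impedance of the branch vessel,
#' converted to clinical units. Minimises non-physical wave reflection at
#' the outlet.
#'
#' @param rho blood density (kg/m^3).
#' @param pwv pulse wave velocity (m/s).
#' @param abranch branch outlet cross-sectional area (m^2).
#' @param rtot optional total outlet resistance (mmHg/(ml/s)); when given,
#'   `Rp` is clipped below `0.95*rtot` with a warning if necessary.
#' @return proximal resistance (mmHg/(ml/s)).
#' @export
initial_rp <- function(rho, pwv, abranch, rtot = NULL) {
  if (rho <= 0 || pwv <= 0 || abranch <= 0) stop("inputs must be positive")
  rp <- resistance_si_to_clinical(rho * pwv / abranch)
  if (!is.null(rtot) && rp >= 0.95 * rtot) {
    warning(sprintf(
      "characteristic impedance %.3f exceeds feasible bound; clipped to %.3f",
      rp, 0.95 * rtot))
    rp <- 0.95 * rtot
  }
  rp
}

#' Distribute peripheral compliance between outlets
#'
#' Each outlet's Windkessel capacitance is its mean-flow-proportional share
#' of the peripheral compliance, `Ci = (Qi/Qinlet) * Cper`. Under the
#' `"residual"` rule the terminal outlet receives whatever remains after the
#' supra-aortic branches take their shares (identical to the proportional
#' share when the flow targets are mass-consistent, but robust to rounding).
#'
#' @param cper peripheral compliance `Ctot - sum(CVi)` (ml/mmHg, >= 0).
#' @param qmeans named per-outlet mean flows (ml/s).
#' @param qsi_mean mean inlet flow (ml/s).
#' @param terminal_id name of the terminal outlet (receives the residual
#'   under the `"residual"` rule); default the last element.
#' @param rule `"residual"` (default) or `"proportional"`.
#' @return named per-outlet capacitances (ml/mmHg).
#' @export
wk3_capacitances <- function(cper, qmeans, qsi_mean,
                             terminal_id = names(qmeans)[length(qmeans)],
                             rule = c("residual", "proportional")) {
  rule <- match.arg(rule)
  if (cper < 0) stop("peripheral compliance must be non-negative")
  if (sum(qmeans) > qsi_mean * (1 + 1e-9))
    stop("outlet mean flows exceed inlet mean flow")
  ci <- cper * qmeans / qsi_mean
  if (rule == "residual" && terminal_id %in% names(qmeans)) {
    others <- setdiff(names(qmeans), terminal_id)
    ci[terminal_id] <- cper - sum(ci[others])
  }
  ci
}
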