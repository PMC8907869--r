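#' Assemble the 0D lumped-parameter network of the aorta
#'
#' The modelled (3D CFD) domain is represented as an ordered series chain of
#' RLC units — each with viscous resistance `R`, blood inertance `L` and
#' wall volume-compliance `CV` — with three-element Windkessel outlets
#' attached after named units and one terminal Windkessel closing the chain.
#' The rigid variant removes the `CV` capacitor states and lumps branch-free
#' stretches of the chain, which is the exact limit of zero wall compliance.
#'
#' @param segments list of [segment_props()] objects, in chain order
#'   (default layout: ascending aorta, two arch units, six descending
#'   units).
#' @param wk3s named list of [wk3_params()] — one per outlet.
#' @param topology list with `attach`: named character vector mapping each
#'   non-terminal outlet id to the segment id after which it branches, and
#'   `terminal`: the outlet id closing the chain.
#' @param compliant logical; `FALSE` removes the segment capacitors.
#' @return object of class `network_0d`.
#' @export
build_network <- function(segments, wk3s, topology, compliant = TRUE) {
  ids <- vapply(segments, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids")
  onames <- names(wk3s)
  if (is.null(onames) || anyDuplicated(onames)) stop("duplicate or unnamed outlet ids")
  if (!topology$terminal %in% onames)
    stop("terminal outlet not among the Windkessel set")
  branch_ids <- setdiff(onames, topology$terminal)
  if (!setequal(names(topology$attach), branch_ids))
    stop("topology attach map must cover exactly the non-terminal outlets")
  if (!all(topology$attach %in% ids))
    stop("disconnected topology: attach points name unknown segments")

  n <- length(segments)
  R <- vapply(segments, function(s) s$R, numeric(1))
  L <- vapply(segments, function(s) s$L, numeric(1))
  CV <- vapply(segments, function(s) s$CV, numeric(1))
  if (!compliant) CV[] <- 0

  attach_idx <- stats::setNames(match(topology$attach, ids),
                                names(topology$attach))
  outlet_node <- c(attach_idx,
                   stats::setNames(n, topology$terminal))
  outlet_node <- outlet_node[onames]

  structure(list(
    segments = segments, seg_ids = ids, n = n,
    R = R, L = L, CV = CV,
    wk3s = wk3s, outlet_ids = onames, outlet_node = outlet_node,
    terminal = topology$terminal, topology = topology,
    compliant = compliant && any(CV > 0)
  ), class = "network_0d")
}

#' @export
print.network_0d <- function(x, ...) {
  cat(sprintf("0D network: %d RLC units (%s), outlets: %s (terminal %s)\n",
              x$n, if (x$compliant) "compliant" else "rigid",
              paste(x$outlet_ids, collapse = ", "), x$terminal))
  invisible(x)
}

#' Per-outlet Windkessel parameter table of a network
#' @param net `network_0d`.
#' @return data.frame with columns `outlet`, `Rp`, `Rd`, `C`, `Rtot`.
#' @export
wk3_table <- function(net) {
  do.call(rbind, lapply(net$outlet_ids, function(id) {
    w <- net$wk3s[[id]]
    data.frame(outlet = id, Rp = w$Rp, Rd = w$Rd, C = w$C,
               Rtot = w$Rp + w$Rd)
  }))
}

# ---- solver internals -------------------------------------------------------

# Compliant formulation states: node pressures P[1..n], unit flows Q[2..n],
# outlet Windkessel pressures Pc[1..m]. Unit 1 carries the prescribed inlet
# flow; inlet pressure is reconstructed as P1 + R1*Qin + L1*dQin/dt.
rhs_compliant <- function(net, qf, dqf) {
  n <- net$n
  m <- length(net$outlet_ids)
  CV <- pmax(net$CV, 1e-9)  # floor keeps mixed rigid/compliant chains well-posed
  R <- net$R; L <- net$L
  Rp <- vapply(net$wk3s, function(w) w$Rp, numeric(1))
  Rd <- vapply(net$wk3s, function(w) w$Rd, numeric(1))
  Cw <- vapply(net$wk3s, function(w) w$C, numeric(1))
  node <- net$outlet_node

  function(t, y, parms) {
    P <- y[1:n]
    Qf <- if (n > 1) y[(n + 1):(2 * n - 1)] else numeric(0)
    Pc <- y[(2 * n):(2 * n - 1 + m)]
    qin <- qf(t)

    qb_out <- (P[node] - Pc) / Rp          # flow into each outlet WK3
    qb_node <- numeric(n)
    for (k in seq_len(m)) qb_node[node[k]] <- qb_node[node[k]] + qb_out[k]

    inflow <- c(qin, Qf)                   # flow entering node i through unit i
    outflow <- c(Qf, 0)                    # flow leaving node i into unit i+1
    dP <- (inflow - outflow - qb_node) / CV
    dQ <- if (n > 1)
      (P[1:(n - 1)] - P[2:n] - R[2:n] * Qf) / L[2:n]
    else numeric(0)
    dPc <- (qb_out - Pc / Rd) / Cw
    list(c(dP, dQ, dPc))
  }
}

compliant_init <- function(net, p0) {
  n <- net$n
  m <- length(net$outlet_ids)
  c(rep(p0, n), rep(0, max(n - 1, 0)), rep(p0, m))
}

compliant_extract <- function(net, sol, qf, dqf, tg) {
  n <- net$n
  m <- length(net$outlet_ids)
  P <- sol[, 2:(n + 1), drop = FALSE]
  Pc <- sol[, (2 * n + 1):(2 * n + m), drop = FALSE]
  qin <- qf(tg)
  pin <- P[, 1] + net$R[1] * qin + net$L[1] * dqf(tg)
  Rp <- vapply(net$wk3s, function(w) w$Rp, numeric(1))
  node <- net$outlet_node
  q_out <- sapply(seq_len(m), function(k) (P[, node[k]] - Pc[, k]) / Rp[k])
  colnames(q_out) <- net$outlet_ids
  q_units <- cbind(qin, if (n > 1) sol[, (n + 2):(2 * n), drop = FALSE])
  colnames(q_units) <- net$seg_ids
  list(pin = pin, q_out = q_out, qin = qin, q_units = q_units)
}

# Rigid formulation: branch-free stretches of the chain are lumped; states
# are the stretch flows (except the first, which carries the prescribed
# inlet flow) and the outlet Windkessel pressures. Node pressures follow
# algebraically from flow balance through the proximal resistances.
rigid_layout <- function(net) {
  nodes <- sort(unique(net$outlet_node))   # chain indices carrying outlets
  if (nodes[length(nodes)] != net$n)
    stop("terminal outlet must close the chain")
  m <- length(nodes)
  bounds <- c(0, nodes)
  Rs <- Ls <- numeric(m)
  for (k in seq_len(m)) {
    span <- (bounds[k] + 1):bounds[k + 1]
    Rs[k] <- sum(net$R[span]); Ls[k] <- sum(net$L[span])
  }
  per_node <- lapply(nodes, function(nd) which(net$outlet_node == nd))
  list(nodes = nodes, m = m, Rs = Rs, Ls = Ls, per_node = per_node)
}

rhs_rigid <- function(net, lay, qf, dqf) {
  m <- lay$m
  no <- length(net$outlet_ids)
  Rp <- vapply(net$wk3s, function(w) w$Rp, numeric(1))
  Rd <- vapply(net$wk3s, function(w) w$Rd, numeric(1))
  Cw <- vapply(net$wk3s, function(w) w$C, numeric(1))

  node_pressures <- function(Qs, Pc) {
    # Qs: flow entering node k (length m); outflow into next stretch
    Pn <- numeric(m)
    for (k in seq_len(m)) {
      idx <- lay$per_node[[k]]
      out_next <- if (k < m) Qs[k + 1] else 0
      Pn[k] <- (Qs[k] - out_next + sum(Pc[idx] / Rp[idx])) /
        sum(1 / Rp[idx])
    }
    Pn
  }

  function(t, y, parms) {
    qin <- qf(t)
    Qst <- if (m > 1) y[1:(m - 1)] else numeric(0)
    Pc <- y[m:(m - 1 + no)]
    Qs <- c(qin, Qst)
    Pn <- node_pressures(Qs, Pc)
    dQ <- if (m > 1) {
      (Pn[1:(m - 1)] - Pn[2:m] - lay$Rs[2:m] * Qst) / lay$Ls[2:m]
    } else numeric(0)
    node_of <- match(net$outlet_node, lay$nodes)
    qb <- (Pn[node_of] - Pc) / Rp
    dPc <- (qb - Pc / Rd) / Cw
    list(c(dQ, dPc))
  }
}

rigid_init <- function(net, lay, p0) {
  c(rep(0, max(lay$m - 1, 0)), rep(p0, length(net$outlet_ids)))
}

rigid_extract <- function(net, lay, sol, qf, dqf, tg) {
  m <- lay$m
  no <- length(net$outlet_ids)
  Rp <- vapply(net$wk3s, function(w) w$Rp, numeric(1))
  qin <- qf(tg)
  Qst <- if (m > 1) sol[, 2:m, drop = FALSE] else NULL
  Pc <- sol[, (m + 1):(m + no), drop = FALSE]
  npts <- length(tg)
  Pn <- matrix(0, npts, m)
  for (k in seq_len(m)) {
    idx <- lay$per_node[[k]]
    Qk <- if (k == 1) qin else Qst[, k - 1]
    out_next <- if (k < m) Qst[, k] else 0
    num <- Qk - out_next
    for (j in idx) num <- num + Pc[, j] / Rp[j]
    Pn[, k] <- num / sum(1 / Rp[idx])
  }
  pin <- Pn[, 1] + lay$Rs[1] * qin + lay$Ls[1] * dqf(tg)
  node_of <- match(net$outlet_node, lay$nodes)
  q_out <- sapply(seq_len(no), function(j) (Pn[, node_of[j]] - Pc[, j]) / Rp[j])
  colnames(q_out) <- net$outlet_ids
  # flow through unit i equals its stretch's flow (no storage in between)
  stretch_of <- findInterval(seq_len(net$n) - 1L, lay$nodes) + 1L
  q_units <- cbind(qin, Qst)[, stretch_of, drop = FALSE]
  colnames(q_units) <- net$seg_ids
  list(pin = pin, q_out = q_out, qin = qin, q_units = q_units)
}

#' Solve a 0D network to periodic convergence
#'
#' Integrates the network ODE system with the stiff backward-differentiation
#' (BDF) method on a fixed 1 ms reporting grid, cycle by cycle, until the
#' per-cycle inlet systolic and diastolic pressures both change by less than
#' `conv_tol` (default 1%) between consecutive cycles, or `max_cycles` is
#' reached. All capacitor pressures start at `p0` and all inductor flows at
#' zero — a physiological diastolic state that converges quickly.
#'
#' @param net `network_0d`.
#' @param Q `flow_waveform` applied at the inlet.
#' @param dt reporting grid spacing (s, default 1e-3).
#' @param max_cycles maximum cardiac cycles (default 20).
#' @param conv_tol periodic-convergence tolerance (default 0.01).
#' @param p0 initial pressure state (mmHg); defaults to 70.
#' @return `sim_result_0d`: last-cycle traces (`t`, `p_inlet`, `q_out`),
#'   per-cycle extremes (`percycle`), `cycles`, `converged`, cycle-mean
#'   flows and the periodic mass-balance error.
#' @export
solve_network <- function(net, Q, dt = 1e-3, max_cycles = 20,
                          conv_tol = 0.01, p0 = 70) {
  stopifnot(inherits(net, "network_0d"), inherits(Q, "flow_waveform"))
  period <- Q$period
  qf <- Q$q_fun
  dqf <- waveform_derivative(Q)
  tg <- unique(c(seq(0, period - dt / 2, by = dt), period))

  if (net$compliant) {
    rhs <- rhs_compliant(net, qf, dqf)
    y <- compliant_init(net, p0)
    extract <- function(sol) compliant_extract(net, sol, qf, dqf, tg)
  } else {
    lay <- rigid_layout(net)
    rhs <- rhs_rigid(net, lay, qf, dqf)
    y <- rigid_init(net, lay, p0)
    extract <- function(sol) rigid_extract(net, lay, sol, qf, dqf, tg)
  }

  percycle <- NULL
  converged <- FALSE
  cycles <- 0L
  tr <- NULL
  for (cyc in seq_len(max_cycles)) {
    sol <- deSolve::ode(y, tg, rhs, parms = NULL, method = "bdf",
                        rtol = 1e-7, atol = 1e-7)
    if (any(!is.finite(sol)))
      stop("0D integration diverged (non-finite state); check parameters")
    y <- sol[nrow(sol), -1]
    tr <- extract(sol)
    ext <- c(psys = max(tr$pin), pdias = min(tr$pin))
    percycle <- rbind(percycle, ext)
    cycles <- cyc
    if (cyc > 1L) {
      prev <- percycle[cyc - 1L, ]
      if (all(abs(ext - prev) / abs(prev) < conv_tol)) {
        converged <- TRUE
        break
      }
    }
  }

  new_sim_result(t = tg, p_inlet = tr$pin, q_out = tr$q_out,
                 percycle = percycle, cycles = cycles, converged = converged,
                 qin = tr$qin, period = period, state = y,
                 q_units = tr$q_units)
}

waveform_derivative <- function(Q) {
  t <- Q$t; q <- Q$Q; period <- Q$period
  n <- length(t)
  # centred differences with periodic wrap (first and last samples coincide)
  tm <- c(t[n - 1] - period, t[1:(n - 1)])
  qm <- c(q[n - 1], q[1:(n - 1)])
  tp <- c(t[2:n], period + t[2])
  qp <- c(q[2:n], q[2])
  dq <- (qp - qm) / (tp - tm)
  f <- stats::approxfun(t, dq, rule = 2)
  function(tt) f(tt %% period)
}

#' Tune the network's proximal resistances to the pressure targets
#'
#' Each outlet's total resistance `Rp + Rd` is fixed by the mean balance and
#' is never altered, so the per-outlet mean flows stay pinned throughout
#' tuning. Two shape knobs remain: a single scalar multiplier applied to
#' every outlet's initial characteristic-impedance estimate of `Rp` (with
#' `Rd` recomputed as the remainder), which sets the systolic peak, and a
#' common scale factor on the outlet Windkessel capacitances, which sets
#' the pulse width and hence the diastolic level. The multiplier is found
#' by a secant iteration on the systolic error inside an outer fixed-point
#' on the pulse-pressure ratio. If the starting network is already on
#' target it is returned unchanged.
#'
#' @param net `network_0d` whose Windkessel `Rp+Rd` totals are already set.
#' @param Q inlet `flow_waveform`.
#' @param targets `pressure_targets`.
#' @param tol relative pressure tolerance (default 0.005).
#' @param mult_bounds feasible interval for the `Rp` multiplier.
#' @param max_outer maximum outer compliance-scale iterations.
#' @param tune_c logical; `FALSE` freezes the outlet capacitances (used when
#'   a variant must retain another calibration's C column) so only the
#'   proximal-resistance multiplier is tuned.
#' @param conv_tol periodic-convergence tolerance for inner solves.
#' @param max_cycles per-solve cycle cap.
#' @return the tuned `network_0d`, with attributes `achieved` (psys, pdias,
#'   per-outlet mean flows), `iterations` (log data.frame), `converged`
#'   (logical) and `result` (the final `sim_result_0d`).
#' @export
tune_network <- function(net, Q, targets, tol = 0.005,
                         mult_bounds = c(0.02, 40), max_outer = 8,
                         tune_c = TRUE, conv_tol = 0.005, max_cycles = 30) {
  stopifnot(inherits(net, "network_0d"), inherits(Q, "flow_waveform"),
            inherits(targets, "pressure_targets"))
  psa_t <- targets$pmean + 0.6 * targets$ppulse
  pda_t <- targets$pmean - 0.4 * targets$ppulse
  ppulse_t <- psa_t - pda_t

  rtot <- vapply(net$wk3s, function(w) w$Rp + w$Rd, numeric(1))
  rp0 <- vapply(net$wk3s, function(w) w$Rp, numeric(1))
  c0 <- vapply(net$wk3s, function(w) w$C, numeric(1))

  apply_pars <- function(m, cs) {
    net2 <- net
    rp <- pmin(pmax(m * rp0, 1e-6), 0.95 * rtot)
    for (k in seq_along(net$outlet_ids)) {
      id <- net$outlet_ids[k]
      net2$wk3s[[id]]$Rp <- rp[k]
      net2$wk3s[[id]]$Rd <- rtot[k] - rp[k]
      net2$wk3s[[id]]$C <- cs * c0[k]
    }
    net2
  }

  log <- NULL
  evalp <- function(m, cs) {
    s <- solve_network(apply_pars(m, cs), Q, conv_tol = conv_tol,
                       max_cycles = max_cycles)
    log <<- rbind(log, data.frame(mult = m, c_scale = cs,
                                  psys = s$psys, pdias = s$pdias))
    s
  }

  s0 <- evalp(1, 1)
  if (abs(s0$psys - psa_t) / psa_t < tol &&
      abs(s0$pdias - pda_t) / pda_t < tol) {
    attr(net, "achieved") <- c(psys = s0$psys, pdias = s0$pdias,
                               s0$qout_mean)
    attr(net, "iterations") <- log
    attr(net, "converged") <- TRUE
    attr(net, "result") <- s0
    return(net)
  }

  clipm <- function(m) min(max(m, mult_bounds[1]), mult_bounds[2])
  # inner: secant on the systolic error; psys grows with the proximal share
  tune_sys <- function(m_start, cs, s_start = NULL) {
    m1 <- clipm(m_start)
    s1 <- if (is.null(s_start)) evalp(m1, cs) else s_start
    e1 <- s1$psys - psa_t
    if (abs(e1) / psa_t < tol / 2) return(list(m = m1, s = s1))
    m2 <- clipm(m1 * if (e1 > 0) 0.7 else 1.4)
    s2 <- evalp(m2, cs)
    for (it in seq_len(10)) {
      e2 <- s2$psys - psa_t
      if (abs(e2) / psa_t < tol / 2) break
      denom <- e2 - e1
      m3 <- if (abs(denom) < 1e-12) m2 else m2 - e2 * (m2 - m1) / denom
      m3 <- clipm(if (!is.finite(m3) || m3 <= 0) m2 / 2 else m3)
      m1 <- m2; e1 <- e2; m2 <- m3
      s2 <- evalp(m2, cs)
    }
    list(m = m2, s = s2)
  }

  m <- 1; cs <- 1
  fit <- tune_sys(m, cs, s_start = s0)
  if (tune_c) {
    for (outer in seq_len(max_outer)) {
      m <- fit$m; s <- fit$s
      ok <- abs(s$psys - psa_t) / psa_t < tol &&
        abs(s$pdias - pda_t) / pda_t < tol
      if (ok) break
      # compliance scales inversely with the pulse pressure
      cs <- cs * (s$psys - s$pdias) / ppulse_t
      fit <- tune_sys(m, cs)
    }
  }

  net2 <- apply_pars(fit$m, cs)
  s <- fit$s
  ok <- abs(s$psys - psa_t) / psa_t < tol &&
    abs(s$pdias - pda_t) / pda_t < tol
  if (!ok)
    warning(sprintf(
      "network tuning residuals: systolic %.2f%%, diastolic %.2f%%",
      100 * (s$psys - psa_t) / psa_t, 100 * (s$pdias - pda_t) / pda_t))
  attr(net2, "achieved") <- c(psys = s$psys, pdias = s$pdias, s$qout_mean)
  attr(net2, "iterations") <- log
  attr(net2, "converged") <- ok
  attr(net2, "result") <- s
  net2
}
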