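#' Generate a physiological inlet flow waveform
#'
#' A smooth systolic ejection pulse (squared half-sine, which is C1 at both
#' ends) carrying the prescribed stroke volume, with an optional gentle
#' mid-diastolic bump, sampled on a 1 ms grid. The cycle integral equals the
#' stroke volume to within 0.1% by construction (the waveform is rescaled
#' analytically), and the waveform is non-negative. Optional multiplicative
#' low-order harmonic noise (seeded) perturbs the shape without changing
#' the stroke volume.
#'
#' @param hr heart rate (bpm).
#' @param sv stroke volume (ml).
#' @param eject_frac systolic ejection duration as a fraction of the cycle
#'   (default 0.34, i.e. ~0.3 s at 68 bpm).
#' @param tail_sv_frac fraction of the stroke volume carried by the
#'   diastolic bump (default 0.03).
#' @param noise relative amplitude of the harmonic shape noise (default 0).
#' @param seed RNG seed for the noise phases.
#' @param dt grid spacing (s).
#' @return a [flow_waveform()].
#' @export
#' @examples
#' w <- make_inlet_waveform(68, 73)
#' w$qmean  # = 73 * 68/60
make_inlet_waveform <- function(hr, sv, eject_frac = 0.34,
                                tail_sv_frac = 0.03, noise = 0, seed = 1,
                                dt = 1e-3) {
  stopifnot(hr > 0, sv >= 0, eject_frac > 0, eject_frac < 1,
            tail_sv_frac >= 0, tail_sv_frac < 0.5)
  period <- 60 / hr
  te <- eject_frac * period
  tg <- unique(c(seq(0, period - dt / 2, by = dt), period))
  if (sv == 0) return(flow_waveform(tg, rep(0, length(tg)), period))

  sys_sv <- sv * (1 - tail_sv_frac)
  qpk <- 2 * sys_sv / te                      # integral of sin^2 pulse = qpk*te/2
  q <- ifelse(tg <= te, qpk * sin(pi * tg / te)^2, 0)

  if (tail_sv_frac > 0) {
    t0 <- te + 0.25 * (period - te)
    tw <- 0.4 * (period - te)
    inb <- tg > t0 & tg < t0 + tw
    bump <- numeric(length(tg))
    bump[inb] <- sin(pi * (tg[inb] - t0) / tw)^2
    q <- q + bump * (sv * tail_sv_frac) / (tw / 2)
  }

  if (noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- noise * stats::runif(3, 0.3, 1)
    eps <- rowSums(sapply(1:3, function(k)
      amp[k] * sin(2 * pi * k * tg / period + ph[k])))
    q <- q * pmax(1 + eps, 0)
  }

  # exact stroke volume after any shaping
  w <- flow_waveform(tg, q, period)
  scale <- sv / (w$qmean * period)
  flow_waveform(tg, q * scale, period)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a cine-MRI-like luminal area waveform
#'
#' Produces one cardiac cycle of cross-sectional area with a prescribed
#' ground-truth distensibility: the pulsatile area change is exactly
#' `dA = D * Amin * Ppulse` at zero noise, so the distensibility estimator
#' inverts the generator exactly. Optional Gaussian noise emulates
#' segmentation uncertainty (a few percent of the diastolic area).
#'
#' @param amin diastolic area (mm^2).
#' @param d_true ground-truth distensibility (1/mmHg).
#' @param ppulse pulse pressure (mmHg).
#' @param hr heart rate (bpm).
#' @param phase_lag delay of the area pulse behind cycle start (s).
#' @param noise Gaussian noise standard deviation as a fraction of `amin`.
#' @param seed RNG seed.
#' @param dt sampling interval (s); default 1 ms. Use 0.038 to mimic the
#'   native cine-MRI frame interval.
#' @return an [area_waveform()].
#' @export
make_area_waveform <- function(amin, d_true, ppulse, hr = 68,
                               phase_lag = 0.05, noise = 0, seed = 1,
                               dt = 1e-3) {
  stopifnot(amin > 0, d_true >= 0, ppulse > 0, hr > 0)
  period <- 60 / hr
  ts <- 0.45 * period                       # systolic distension window
  tg <- sort(unique(c(seq(0, period, by = dt), phase_lag + ts / 2)))
  tg <- tg[tg <= period]
  da <- d_true * amin * ppulse
  tt <- (tg - phase_lag) %% period
  s <- ifelse(tt < ts, sin(pi * tt / ts)^2, 0)
  A <- amin + da * s
  if (noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    A <- pmax(A + stats::rnorm(length(A), 0, noise * amin), 0.1 * amin)
  }
  area_waveform(tg, A)
}

#' Generate a labelled cylinder surface mesh
#'
#' An axis-aligned (z) open cylinder of the given radius and length,
#' triangulated as `n_axial + 1` rings of `n_circ` nodes, with outward
#' radial normals, axial region bands, ring metadata for slice-based area
#' evaluation, and the first/last rings flagged as fixed inlet/outlet
#' boundary rings.
#'
#' @param radius tube radius (m).
#' @param length axial length (m).
#' @param n_circ nodes per ring (>= 8; >= 32 for percent-level slice-area
#'   accuracy).
#' @param n_axial axial elements.
#' @param regions character vector of band labels applied as equal axial
#'   bands (default single region `"wall"`).
#' @return a [surface_mesh()].
#' @export
make_cylinder_mesh <- function(radius, length, n_circ = 48, n_axial = 24,
                               regions = "wall") {
  stopifnot(radius > 0, length > 0, n_circ >= 8, n_axial >= 1,
            length(regions) >= 1)
  th <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  nr <- n_axial + 1
  z <- length * (seq_len(nr) - 1) / n_axial
  nodes <- cbind(radius * cos(rep(th, nr)),
                 radius * sin(rep(th, nr)),
                 rep(z, each = n_circ))
  normals <- cbind(cos(rep(th, nr)), sin(rep(th, nr)), 0)

  nreg <- length(regions)
  band <- pmin(floor(rep(z, each = n_circ) / length * nreg) + 1L, nreg)
  region <- regions[band]

  faces <- cylinder_faces(n_circ, n_axial)
  rings <- lapply(seq_len(nr), function(j) (j - 1L) * n_circ + seq_len(n_circ))
  surface_mesh(nodes, faces, normals, region,
               boundary_rings = list(inlet = rings[[1]],
                                     outlet = rings[[nr]]),
               rings = rings)
}

cylinder_faces <- function(n_circ, n_axial) {
  f <- matrix(0L, 2 * n_circ * n_axial, 3)
  r <- 1L
  for (j in seq_len(n_axial)) {
    base0 <- (j - 1L) * n_circ
    base1 <- j * n_circ
    for (i in seq_len(n_circ)) {
      ip <- if (i == n_circ) 1L else i + 1L
      a <- base0 + i; b <- base0 + ip; c2 <- base1 + i; d <- base1 + ip
      # wound so face normals point radially outward (+z axis, CCW rings)
      f[r, ] <- c(a, b, d); r <- r + 1L
      f[r, ] <- c(a, d, c2); r <- r + 1L
    }
  }
  f
}

#' Generate a labelled torus-segment (bent tube) surface mesh
#'
#' A tube of radius `tube_radius` bent along a circular centreline of
#' radius `centre_radius` spanning `span` radians (default a half-turn,
#' an idealised aortic arch). Normals point outward from the local
#' centreline point; end rings are flagged as boundary rings.
#'
#' @param tube_radius tube (lumen) radius (m).
#' @param centre_radius centreline bend radius (m).
#' @param span arc angle (rad).
#' @param n_circ nodes per ring.
#' @param n_axial rings minus one along the arc.
#' @param regions axial band labels as in [make_cylinder_mesh()].
#' @return a [surface_mesh()].
#' @export
make_torus_mesh <- function(tube_radius, centre_radius, span = pi,
                            n_circ = 48, n_axial = 24, regions = "wall") {
  stopifnot(tube_radius > 0, centre_radius > tube_radius, span > 0,
            n_circ >= 8, n_axial >= 1)
  nr <- n_axial + 1
  phi <- span * (seq_len(nr) - 1) / n_axial
  th <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  nodes <- matrix(0, nr * n_circ, 3)
  normals <- matrix(0, nr * n_circ, 3)
  for (j in seq_len(nr)) {
    er <- c(cos(phi[j]), sin(phi[j]), 0)     # radial direction of centreline
    ez <- c(0, 0, 1)
    ctr <- centre_radius * er
    idx <- (j - 1L) * n_circ + seq_len(n_circ)
    dir <- outer(cos(th), er) + outer(sin(th), ez)
    nodes[idx, ] <- matrix(ctr, n_circ, 3, byrow = TRUE) + tube_radius * dir
    normals[idx, ] <- dir
  }
  nreg <- length(regions)
  band <- pmin(floor(rep(phi, each = n_circ) / span * nreg) + 1L, nreg)
  faces <- cylinder_faces(n_circ, n_axial)
  rings <- lapply(seq_len(nr), function(j) (j - 1L) * n_circ + seq_len(n_circ))
  surface_mesh(nodes, faces, normals, regions[band],
               boundary_rings = list(inlet = rings[[1]],
                                     outlet = rings[[nr]]),
               rings = rings)
}

#' Default virtual-patient profile
#'
#' Measurement set of a healthy adult: heart rate 68 bpm, brachial pressures
#' 117/72 mmHg, per-outlet mean-flow targets 18.34/8.11/11.84/44.44 ml/s
#' (brachiocephalic trunk BT, left common carotid LCC, left subclavian LSA,
#' abdominal aorta AbAo), which fix the stroke volume at 73 ml. Supra-aortic
#' outlet areas are proportional to the flow targets (the area-proportional
#' split is then exact); segment geometry and regional distensibilities are
#' physiological values for a young thoracic aorta giving ~5-12% area
#' pulsation.
#'
#' @return named list understood by [make_virtual_patient()].
#' @export
default_patient_profile <- function() {
  flows <- c(BT = 18.34, LCC = 8.11, LSA = 11.84, AbAo = 44.44)
  qin <- sum(flows)
  sa <- flows[c("BT", "LCC", "LSA")]
  sa_areas_mm2 <- sa * 6.27            # BT ~115 mm2 (d ~12 mm)
  list(
    hr = 68, psb = 117, pdb = 72,
    outlet_flows = flows,
    sv = qin * 60 / 68,
    sa_areas_mm2 = sa_areas_mm2,
    terminal_diameter_mm = 20,
    eject_frac = 0.34,
    # nine-unit chain: ascending aorta, two arch units, six descending units
    segments = data.frame(
      id = c("AA", "arch1", "arch2", paste0("DA", 1:6)),
      region = c("AA", "arch", "arch", rep("DA", 6)),
      length_m = c(0.060, 0.025, 0.025, rep(0.035, 6)),
      area_m2 = c(6.2e-4, 5.5e-4, 5.5e-4, rep(4.0e-4, 6))
    ),
    # regional ground-truth distensibility (1/mmHg) and diastolic areas (mm2)
    region_D_mmhg = c(AA = 3.2e-3, arch = 2.8e-3, DA = 2.4e-3),
    region_amin_mm2 = c(AA = 620, arch = 550, DA = 400),
    attach = c(BT = "AA", LCC = "arch1", LSA = "arch2"),
    terminal = "AbAo",
    rho = 1056
  )
}

#' Generate a self-consistent virtual patient
#'
#' Builds the complete synthetic measurement bundle the calibration
#' pipeline consumes: inlet flow waveform, per-region cine-MRI-like area
#' waveforms, segment/branch geometry, a labelled lumen surface mesh, plus
#' a ground-truth record (true distensibilities and outlet mean flows) for
#' parameter-recovery testing. The inlet mean flow equals the sum of the
#' ground-truth outlet flows by construction.
#'
#' @param profile a profile list, see [default_patient_profile()].
#' @param seed RNG seed for any stochastic elements.
#' @param noise relative measurement noise applied to the waveforms
#'   (default 0: noise-free ground truth).
#' @return object of class `virtual_patient`.
#' @export
make_virtual_patient <- function(profile = default_patient_profile(),
                                 seed = 1, noise = 0) {
  pr <- profile
  targets <- derive_central_pressures(pr$psb, pr$pdb)
  waveform <- make_inlet_waveform(pr$hr, pr$sv, eject_frac = pr$eject_frac,
                                  noise = noise, seed = seed)

  area_waves <- lapply(names(pr$region_D_mmhg), function(rg)
    make_area_waveform(pr$region_amin_mm2[[rg]], pr$region_D_mmhg[[rg]],
                       targets$ppulse, hr = pr$hr, noise = noise,
                       seed = seed + match(rg, names(pr$region_D_mmhg))))
  names(area_waves) <- names(pr$region_D_mmhg)

  seg <- pr$segments
  seg$volume_ml <- seg$area_m2 * seg$length_m * 1e6
  seg$D_mmhg <- pr$region_D_mmhg[seg$region]

  sa_areas_m2 <- pr$sa_areas_mm2 * 1e-6
  branches <- data.frame(
    id = c(names(sa_areas_m2), pr$terminal),
    attach_to = c(pr$attach[names(sa_areas_m2)], tail(seg$id, 1)),
    area_m2 = c(unname(sa_areas_m2),
                pi / 4 * (pr$terminal_diameter_mm * 1e-3)^2)
  )
  branches$diameter_mm <- sqrt(4 * branches$area_m2 / pi) * 1e3

  # mesh: three axial bands matching the cine-MRI regions, radius from the
  # mean regional diastolic area
  rmean <- sqrt(mean(pr$region_amin_mm2) * 1e-6 / pi)
  mesh <- make_cylinder_mesh(rmean, 0.18, n_circ = 48, n_axial = 24,
                             regions = names(pr$region_D_mmhg))

  qda <- rep(pr$outlet_flows[[pr$terminal]], 4)

  structure(list(
    profile = pr, hr = pr$hr, psb = pr$psb, pdb = pr$pdb,
    waveform = waveform, area_waves = area_waves,
    segments = seg, branches = branches, qda = qda, mesh = mesh,
    truth = list(D_mmhg = pr$region_D_mmhg,
                 outlet_flows = pr$outlet_flows,
                 qinlet_mean = sum(pr$outlet_flows),
                 sv = pr$sv)
  ), class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf(
    "Virtual patient: HR %g bpm, BP %g/%g mmHg, SV %.1f ml, %d segments\n",
    x$hr, x$psb, x$pdb, x$truth$sv, nrow(x$segments)))
  invisible(x)
}

#' Write a virtual-patient bundle to a directory
#'
#' Emits `waveform.csv`, `areas.csv`, `geometry.yaml`, `mesh.vtk` and
#' `truth.json`.
#' @param vp `virtual_patient`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_patient_dir <- function(vp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_waveform_csv(vp$waveform, file.path(dir, "waveform.csv"))
  write_area_csv(vp$area_waves, file.path(dir, "areas.csv"))
  geom <- list(
    heart_rate_bpm = vp$hr,
    brachial_pressures_mmhg = c(vp$psb, vp$pdb),
    qda_ml_s = as.numeric(vp$qda),
    segments = lapply(seq_len(nrow(vp$segments)), function(i)
      as.list(vp$segments[i, ])),
    branches = lapply(seq_len(nrow(vp$branches)), function(i)
      as.list(vp$branches[i, ]))
  )
  yaml::write_yaml(geom, file.path(dir, "geometry.yaml"))
  write_mesh_vtk(vp$mesh, file.path(dir, "mesh.vtk"))
  jsonlite::write_json(vp$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
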