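#' Area waveform container
#'
#' A luminal cross-sectional area trace over one cardiac cycle, as measured
#' by cine-MRI on a transverse plane. Diastolic (minimum) and systolic
#' (maximum) areas and the pulsatile area change are derived on construction.
#'
#' @param t time samples (s).
#' @param A area samples (mm^2), all positive.
#' @return object of class `area_waveform`: list with `t`, `A`, `amin`,
#'   `amax`, `da` (mm^2).
#' @export
area_waveform <- function(t, A) {
  stopifnot(length(t) == length(A), all(is.finite(A)))
  if (any(A <= 0)) stop("areas must be positive")
  structure(list(t = t, A = A, amin = min(A), amax = max(A),
                 da = max(A) - min(A)),
            class = "area_waveform")
}

#' Local area distensibility from a cine-MRI area waveform
#'
#' Distensibility is the fractional area change per unit pulse pressure,
#' `D = dA / (Amin * Ppulse)`, with `dA` the maximum area change across the
#' cycle and `Amin` the diastolic area.
#'
#' @param w an `area_waveform` (or list with `amin` and `da`).
#' @param ppulse pulse pressure (mmHg).
#' @return distensibility (1/mmHg). A flat trace gives 0 with a warning
#'   (rigid region).
#' @export
distensibility_from_area <- function(w, ppulse) {
  if (ppulse <= 0) stop("pulse pressure must be positive")
  if (is.null(w$amin) || is.null(w$da)) stop("not an area waveform")
  if (w$amin <= 0) stop("diastolic area must be positive")
  if (w$da <= 0) {
    warning("flat area trace: distensibility 0 (rigid region)")
    return(0)
  }
  w$da / (w$amin * ppulse)
}

#' Branch distensibility from diameter via the empirical pulse-wave-velocity
#' relation
#'
#' Supra-aortic branches are usually too small to resolve with cine-MRI, so
#' their distensibility is estimated from the empirical diameter relation
#' `PWV = 13.3 * d^-0.3` (d in mm, PWV in m/s) combined with the
#' Bramwell-Hill form `D = 1/(rho * PWV^2)`.
#'
#' @param di branch diameter (mm).
#' @param rho blood density (kg/m^3, default 1056).
#' @param pwv_coef,pwv_exp constants of the empirical relation
#'   (defaults 13.3 and -0.3).
#' @return object of class `branch_props`: list with `di` (mm), `pwv` (m/s),
#'   `D_pa` (1/Pa) and `D_mmhg` (1/mmHg).
#' @export
#' @examples
#' branch_distensibility(8)
branch_distensibility <- function(di, rho = 1056,
                                  pwv_coef = 13.3, pwv_exp = -0.3) {
  if (any(di <= 0)) stop("diameter must be positive")
  pwv <- pwv_coef * di^pwv_exp
  D_pa <- 1 / (rho * pwv^2)
  structure(list(di = di, pwv = pwv, D_pa = D_pa,
                 D_mmhg = distensibility_pa_to_mmhg(D_pa)),
            class = "branch_props")
}

#' Blood inertance of a large-artery segment
#'
#' `L = (4/3) * rho * l / A`, the standard large-artery inertance for a
#' segment of length `l` and cross-sectional area `A`. The 4/3 factor
#' accounts for the non-flat velocity profile.
#'
#' @param li segment length (m).
#' @param ai cross-sectional area (m^2).
#' @param rho blood density (kg/m^3, default 1056).
#' @return list with `L_si` (Pa s^2/m^3) and `L_clinical` (mmHg/(ml/s^2)).
#' @export
inductance <- function(li, ai, rho = 1056) {
  if (ai <= 0) stop("area must be positive")
  if (li < 0) stop("length must be non-negative")
  L_si <- (4 / 3) * rho * li / ai
  list(L_si = L_si, L_clinical = inductance_si_to_clinical(L_si))
}

#' Volume compliance of a segment
#'
#' `CV = D * V`: distensibility times segment volume.
#'
#' @param di distensibility (1/mmHg).
#' @param vi segment volume (ml).
#' @return volume compliance (ml/mmHg).
#' @export
volume_compliance <- function(di, vi) {
  if (di < 0 || vi < 0) stop("inputs must be non-negative")
  di * vi
}

#' Poiseuille estimate of segment viscous resistance
#'
#' A fully-developed laminar (Poiseuille) estimate
#' `R = 8*pi*mu*l / A^2` used as the default viscous resistance of a 0D
#' segment. In a calibration against 3D CFD this value would normally be
#' replaced by the pressure loss from a steady simulation; a per-segment
#' `override` takes precedence when supplied.
#'
#' @param li segment length (m).
#' @param ai cross-sectional area (m^2).
#' @param mu_eff effective dynamic viscosity (Pa s, default 3.5e-3).
#' @param override optional externally computed resistance
#'   (mmHg/(ml/s)); returned unchanged when not `NULL`.
#' @return list with `R_si` (Pa s/m^3) and `R_clinical` (mmHg/(ml/s)).
#' @export
segment_resistance_estimate <- function(li, ai, mu_eff = 3.5e-3,
                                        override = NULL) {
  if (!is.null(override)) {
    return(list(R_si = resistance_clinical_to_si(override),
                R_clinical = override))
  }
  if (ai <= 0) stop("area must be positive")
  if (li < 0 || mu_eff <= 0) stop("invalid geometry or viscosity")
  R_si <- 8 * pi * mu_eff * li / ai^2
  list(R_si = R_si, R_clinical = resistance_si_to_clinical(R_si))
}

#' Carreau-Yasuda fluid property set
#'
#' Default constants are literature values for healthy human blood; the
#' zero- and infinite-shear viscosities bracket the shear-thinning range.
#'
#' @param rho density (kg/m^3).
#' @param mu0 zero-shear viscosity (Pa s).
#' @param muInf infinite-shear viscosity (Pa s).
#' @param lambda relaxation time (s).
#' @param a Yasuda transition exponent.
#' @param n power-law index.
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1056, mu0 = 0.16, muInf = 3.5e-3,
                        lambda = 8.2, a = 0.64, n = 0.2128) {
  if (!(mu0 > muInf && muInf > 0)) stop("require mu0 > muInf > 0")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(rho = rho, mu0 = mu0, muInf = muInf,
                 lambda = lambda, a = a, n = n),
            class = "fluid_props")
}

#' Carreau-Yasuda apparent viscosity
#'
#' `mu(g) = muInf + (mu0 - muInf) * (1 + (lambda*g)^a)^((n-1)/a)` with shear
#' rate `g`. Recovers `mu0` at zero shear and `muInf` asymptotically.
#'
#' @param gamma_dot shear rate (1/s), non-negative; vectorised.
#' @param fp a `fluid_props` object.
#' @return apparent viscosity (Pa s).
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, fp = fluid_props()) {
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  fp$muInf + (fp$mu0 - fp$muInf) *
    (1 + (fp$lambda * gamma_dot)^fp$a)^((fp$n - 1) / fp$a)
}

#' Turbulence-onset check via peak and critical Reynolds numbers
#'
#' Computes the peak Reynolds number `Re_peak = rho * U * Dh / mu_eff` with
#' the effective viscosity evaluated at a nominal shear rate (default
#' `U/Dh`), and a critical Reynolds number from a configurable
#' pulsatile-flow correlation `Re_crit = K * alpha^m` on the Womersley
#' number `alpha = (Dh/2) * sqrt(2*pi*f*rho/mu_eff)`. The flow is flagged
#' turbulent when `Re_peak` strictly exceeds `Re_crit`.
#'
#' @param u_peak peak velocity (m/s).
#' @param dh hydraulic diameter (m).
#' @param fp `fluid_props`.
#' @param freq_hz cardiac frequency (Hz) for the Womersley number.
#' @param crit_coef,crit_exp constants of the critical-Re correlation
#'   (defaults 250 and 1: `Re_crit = 250 * alpha`, a standard pulsatile
#'   correlation form; constants are injected, not hard-coded science).
#' @param nominal_shear optional shear rate (1/s) at which to evaluate the
#'   effective viscosity; default `u_peak / dh`.
#' @return object of class `flow_regime_report`: list with `re_peak`,
#'   `re_crit`, `alpha`, `mu_eff`, `turbulent`.
#' @export
turbulence_onset_check <- function(u_peak, dh, fp = fluid_props(),
                                   freq_hz = 68 / 60,
                                   crit_coef = 250, crit_exp = 1,
                                   nominal_shear = NULL) {
  if (u_peak <= 0 || dh <= 0 || freq_hz <= 0) stop("inputs must be positive")
  if (is.null(nominal_shear)) nominal_shear <- u_peak / dh
  mu_eff <- carreau_yasuda_viscosity(nominal_shear, fp)
  re_peak <- fp$rho * u_peak * dh / mu_eff
  alpha <- (dh / 2) * sqrt(2 * pi * freq_hz * fp$rho / mu_eff)
  re_crit <- crit_coef * alpha^crit_exp
  structure(list(re_peak = re_peak, re_crit = re_crit, alpha = alpha,
                 mu_eff = mu_eff, turbulent = re_peak > re_crit),
            class = "flow_regime_report")
}

#' @export
print.flow_regime_report <- function(x, ...) {
  cat(sprintf("Re_peak = %.0f, Re_crit = %.0f (alpha %.1f): %s\n",
              x$re_peak, x$re_crit, x$alpha,
              if (x$turbulent) "turbulence onset expected" else "laminar"))
  invisible(x)
}

#' Build the property table of one 0D segment
#'
#' Combines geometry with the constitutive relations: inertance from the
#' large-artery formula, volume compliance `CV = D*V` with distensibility
#' from the segment's area waveform, and viscous resistance from the
#' Poiseuille estimate unless overridden.
#'
#' @param id segment identifier.
#' @param length_m segment length (m).
#' @param area_m2 representative (diastolic) cross-sectional area (m^2).
#' @param volume_ml luminal volume (ml).
#' @param D_mmhg distensibility (1/mmHg).
#' @param rho blood density (kg/m^3).
#' @param mu_eff effective viscosity (Pa s).
#' @param R_override optional measured resistance (mmHg/(ml/s)).
#' @return object of class `segment_props`: list with clinical-unit `R`,
#'   `L`, `CV` plus the geometric fields.
#' @export
segment_props <- function(id, length_m, area_m2, volume_ml, D_mmhg,
                          rho = 1056, mu_eff = 3.5e-3, R_override = NULL) {
  stopifnot(length_m > 0, area_m2 > 0, volume_ml > 0, D_mmhg >= 0)
  L <- inductance(length_m, area_m2, rho)$L_clinical
  R <- segment_resistance_estimate(length_m, area_m2, mu_eff,
                                   override = R_override)$R_clinical
  CV <- volume_compliance(D_mmhg, volume_ml)
  structure(list(id = id, length_m = length_m, area_m2 = area_m2,
                 volume_ml = volume_ml, D_mmhg = D_mmhg,
                 R = R, L = L, CV = CV),
            class = "segment_props")
}

#' Read per-region area waveforms from CSV
#'
#' Accepts either a long-format CSV with columns `region,time_s,area_mm2`
#' or a single-region file `time_s,area_mm2`.
#' @param path CSV path.
#' @param region region name used when the file has no `region` column.
#' @return named list of `area_waveform` objects.
#' @export
read_area_csv <- function(path, region = "region1") {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "area_mm2") %in% names(d)))
    stop("area CSV must have columns time_s,area_mm2 (and optionally region)")
  if (!"region" %in% names(d)) d$region <- region
  out <- lapply(split(d, d$region),
                function(g) area_waveform(g$time_s, g$area_mm2))
  out[unique(d$region)]
}

#' Write per-region area waveforms to a long-format CSV
#' @param waves named list of `area_waveform`.
#' @param path output path.
#' @export
write_area_csv <- function(waves, path) {
  rows <- do.call(rbind, lapply(names(waves), function(nm) {
    w <- waves[[nm]]
    data.frame(region = nm, time_s = w$t, area_mm2 = w$A)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
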