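# Shared fixtures, computed lazily and memoised so the expensive closed-loop
# calibrations run once per test session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, force(expr), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

fx_patient <- function() memo("vp", make_virtual_patient(seed = 42))

fx_cal_compliant <- function() memo("cal_c", suppressWarnings(
  calibrate_patient(fx_patient(), "compliant")))

fx_cal_rigid <- function() memo("cal_r", {
  cal <- fx_cal_compliant()
  suppressWarnings(calibrate_patient(
    fx_patient(), "rigid", ctot = cal$system,
    fixed_c = stats::setNames(cal$wk3$C, cal$wk3$outlet)))
})

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# printed reference Windkessel table (compliant and rigid variants)
ref_wk3 <- list(
  compliant = data.frame(
    outlet = c("BT", "LCC", "LSA", "AbAo"),
    R1 = c(0.4872, 0.9744, 0.9179, 0.1154),
    R2 = c(4.2231, 9.7188, 6.3783, 1.8281),
    C  = c(0.3818, 0.1682, 0.2465, 0.5702)),
  rigid = data.frame(
    outlet = c("BT", "LCC", "LSA", "AbAo"),
    R1 = c(0.1500, 0.2500, 0.2500, 0.0750),
    R2 = c(4.5600, 10.4430, 7.0460, 1.8690),
    C  = c(0.3818, 0.1682, 0.2465, 0.5702))
)

ref_flows <- c(BT = 18.34, LCC = 8.11, LSA = 11.84, AbAo = 44.44)
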