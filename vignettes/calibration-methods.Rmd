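---
title: "Calibrating 0D haemodynamic models and compliant-wall fields from MRI measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating 0D haemodynamic models and compliant-wall fields from MRI measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortacal)
```

## The problem

Patient-specific CFD of the thoracic aorta stands or falls with its boundary
conditions. Outlet pressures are usually imposed through three-element
Windkessel (WK3) models — a proximal resistance $R_p$ in series with a
parallel distal resistance $R_d$ and capacitance $C$ — and wall motion, when
it is modelled at all, needs a calibrated stiffness distribution. Neither
the WK3 parameters nor the wall stiffness can be measured directly; they
must be inferred from routinely measurable quantities: a brachial cuff
pressure, an inlet flow waveform from 4D-flow MRI, and luminal
cross-sectional area waveforms from cine-MRI.

`aortacal` implements that inference chain as a reusable toolkit:

1. **Targets** — central aortic pressure targets from the brachial cuff,
   per-outlet mean-flow targets from the measured flows and branch areas.
2. **Vessel mechanics** — distensibility, compliance, inertance and
   resistance of each vessel segment from geometry and area waveforms.
3. **0D network** — a lumped-parameter (RLC + WK3) model of the aorta,
   solved to periodic convergence with a stiff BDF integrator, and tuned
   iteratively until the pressure targets appear at its inlet.
4. **Wall stiffness field** — a per-node stiffness coefficient on the lumen
   surface mesh for moving-boundary (pressure-proportional wall
   displacement) CFD, smoothed across region boundaries.

The 3D Navier–Stokes solve itself is deliberately out of scope: the package
produces the calibrated parameter tables, traces and fields that such a
solver consumes.

## Pressure and flow targets

Diastolic pressure is nearly constant along the arterial tree, so the aortic
diastolic target equals the brachial measurement, $P_{da} = P_{db}$. Central
systolic pressure is lower than the brachial value; we use the linear
transfer

$$P_{sa} = 0.83\,P_{sb} + 0.15\,P_{db},$$

keeping full precision internally and rounding only for presentation
(117/72 mmHg maps to a 107.91 → 108 mmHg systolic target). The mean
pressure uses the standard diastole-weighted estimate
$\bar P = 0.4\,P_{sa} + 0.6\,P_{da}$. Whether the rounded or the raw
systolic value enters $\bar P$ is exposed as `round_psa` (default: rounded,
so reported means match integer-precision clinical tables; the difference
is below 0.05%).

Flow measurements in the narrow supra-aortic branches carry large
voxel-size uncertainties, so the total supra-aortic flow is inferred by
mass balance from the mean inlet flow and the average of four
descending-aorta plane measurements,
$\bar Q_{SA} = \bar Q_{inlet} - \tfrac14\sum_{i=1}^4 \bar Q_{DA_i}$,
and divided between the brachiocephalic trunk (BT), left common carotid
(LCC) and left subclavian (LSA) arteries in proportion to their diastolic
cross-sectional areas. Each outlet's total resistance then follows from the
mean balance $R_{tot,i} = \bar P / \bar Q_i$.

The inlet waveform is resampled to a 1 ms periodic grid with
shape-preserving monotone piecewise-cubic interpolation
(`splinefun(method = "monoH.FC")`). An unconstrained cubic spline can
overshoot sparse systolic samples and produce spurious negative diastolic
flow; the monotone interpolant cannot, which is why it was chosen. The
first sample is appended at $t = T$ before interpolation so the waveform
closes exactly — it drives a periodic ODE.

## Vessel mechanics

Distensibility of each imaged region comes directly from the area waveform,

$$D_i = \frac{\Delta A_i}{A_{min,i}\, P_{pulse}},$$

with $\Delta A_i$ the peak systolic area change and $A_{min,i}$ the
diastolic area. Segment volume compliance is $C_{V,i} = D_i V_i$ and blood
inertance uses the large-artery expression $L_i = \tfrac43 \rho l_i / A_i$.
The representative area $A_i$ is the diastolic area by default (the choice
— diastolic, mean or mid-segment — is configurable; at ~5–12% area
pulsation it moves $L_i$ by a few percent at most).

Branches too small for cine-MRI get their distensibility from the empirical
pulse-wave-velocity relation $PWV = 13.3\, d_i^{-0.3}$ (diameter in mm, PWV
in m/s — the unit reading that lands in the physiological 4.8–9.6 m/s range
across 3–30 mm vessels) combined with the Bramwell–Hill form
$D = 1/(\rho\, PWV^2)$.

Segment viscous resistances are, in the source workflow, extracted from a
steady 3D CFD solve of the actual geometry. That solve is out of scope
here, so the package defaults to a Poiseuille estimate
$R_i = 8\pi\mu l_i/A_i^2$ with an explicit per-segment override hook for
externally computed values. None of the calibration results depend on this
default: mean flows are pinned by the outlet $R_{tot}$ targets, and the
aortic segment resistances are three orders of magnitude smaller than the
outlet resistances.

Blood rheology is available as a Carreau–Yasuda viscosity
$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,[1+(\lambda\dot\gamma)^a]^{(n-1)/a}$
with literature default constants, and a Reynolds-number turbulence-onset
check whose critical-Re correlation constants are injected rather than
hard-coded (the published critical values depend on definitions that vary
between references; the utility makes the comparison, not the constants).

## The 0D network and its tuning

The modelled aortic domain is an ordered chain of nine RLC units
(ascending aorta, two arch units, six descending units by default; the
layout and attachment points are configurable), with WK3 outlets for
BT/LCC/LSA taking off after the first three units and a terminal WK3
(abdominal aorta) closing the chain. States are the unit (capacitor)
pressures, the inter-unit inductor flows and the outlet WK3 pressures; the
inlet unit carries the prescribed flow waveform, and inlet pressure is
reconstructed as $P_1 + R_1 Q_{in} + L_1 \dot Q_{in}$. The rigid variant
removes the volume-compliance capacitors; branch-free stretches of the
chain then carry a common flow and are lumped exactly, avoiding the
differential-algebraic system that naive capacitor removal would create.

Integration uses `deSolve`'s backward-differentiation method on a fixed
1 ms reporting grid, cycle by cycle, until the per-cycle inlet systolic and
diastolic pressures both change by less than 1% — the same periodic
convergence rule used for the 3D simulations the calibration feeds. All
capacitor pressures start at the diastolic target and inductor flows at
zero, a physiological state from which the default patient converges in
3–5 cycles. At convergence the cycle-mean inflow matches the summed
cycle-mean outflows to well under 0.5% (capacitors store no net volume over
a period); the solver reports this mass-balance error.

Tuning proceeds in two stages:

**Stage 1 — total compliance.** A single WK3 analogue of the whole system
is driven by the inlet waveform. Total resistance starts from the mean
balance $\bar P/\bar Q$ with a 5% proximal share; total compliance is found
by a bounded root-find on the pulse-pressure error (pulse pressure is
monotone decreasing in compliance, so the bracket is safe); an outer pass
rescales the total resistance against the weighted-mean residual. Matching
the weighted mean $0.4 P_{sys} + 0.6 P_{dia}$ and the pulse pressure is
algebraically equivalent to matching both targets, which is why the outer
pass converges in 2–3 iterations.

**Stage 2 — network tuning.** The peripheral compliance
$C_{per} = C_{tot} - \sum C_{V,i}$ is distributed between outlets in
proportion to their mean flows (the terminal outlet takes the residual —
identical to its proportional share when the flow targets are
mass-consistent). Initial proximal resistances come from the characteristic
impedance $R_p = \rho\,PWV/A_{branch}$, clipped below the outlet total.
Tuning then adjusts one scalar multiplier on all $R_p$ (with
$R_d = R_{tot} - R_p$ recomputed, so every outlet's total — and hence every
mean flow — is preserved *exactly*) by a secant iteration on the systolic
error, inside an outer fixed-point on a common outlet-capacitance scale
factor that sets the pulse width and hence the diastolic level.

The outer compliance knob deserves a note, because a single-knob design
(tune $R_p$, let diastole follow) looks sufficient on paper: the outlet
totals pin the *time-mean* inlet pressure, and one might expect the
diastolic value to land once systole is matched. It does not — the
time-mean of a realistic pressure waveform differs from the 0.4/0.6
weighted estimate of its extremes by 1–2%, and with systole pinned, that
entire discrepancy lands on the diastolic value (2.4% high on the default
patient). Scaling the outlet capacitances is the smallest additional
mechanism that closes the loop without touching the resistance totals.
After tuning, the default patient shows 108.0/72.2 mmHg against 108/72
targets, with mean outlet flows within 0.15% of their targets.

The rigid variant reuses the compliant outlet capacitances unchanged (the
reporting convention for the two parameter sets shares one C row) and
re-tunes only the resistive split. With the chain's volume storage removed
but the same outlet capacitances, its diastolic pressure settles ~1.8% low
— reported honestly by the convergence flag rather than absorbed by
re-tuning C.

One reference value is deliberately not reproduced: the published terminal
(abdominal) capacitance is not consistent with the flow-proportional rule
that generates the supra-aortic values (their ratios match the flow ratios;
the terminal one does not), and the source does not state how it was set.
The package applies the stated rule and exposes it (`rule = "residual"` /
`"proportional"`) rather than forcing agreement.

### Compliant vs rigid distal flow

In the lumped network, wall compliance *attenuates and delays* the distal
flow pulse: each descending-aorta unit's peak flow is lower in the
compliant variant than in the rigid one, because the chain capacitors store
systolic volume. Reports comparing 3D compliant/rigid simulations against
flow measurements describe the opposite ordering at descending-aorta
planes (compliant over-predicting the measured peak, rigid
under-predicting). A uniform lumped chain cannot produce that distal
amplification — it would require wave-reflection effects of a tapered,
distally stiffening vasculature that sit outside a nine-unit 0D
abstraction. The package asserts the attenuation behaviour as its tested
invariant and documents the discrepancy rather than tuning toward an
ordering the model class cannot express.

## The moving-boundary stiffness field

The wall law displaces each lumen-surface node along its outward normal in
proportion to the local transmural pressure:

$$\delta_n = \frac{p_n - p_{ext}}{K_n}\,\hat n_n,
\qquad K_n = \frac{2\sqrt{\pi A_n}}{C_{A,i}},$$

with $p_{ext}$ set to the diastolic pressure, $A_n$ the lumen
cross-sectional area at the node and $C_{A,i} = D_i A_{min,i}$ the region's
area compliance. The form of $K_n$ is exactly the coefficient that makes a
cylinder reproduce its measured area compliance: for a tube of area $A$,
$\mathrm{d}A = 2\sqrt{\pi A}\,\mathrm{d}r$, so a uniform load
$\Delta p$ yields $\Delta A = C_A\,\Delta p$ to first order in
$\delta r/r$. The package verifies this identity on generated cylinders:
at ~5% systolic area pulsation the recovered area change matches
$D\,A_{min}\,P_{pulse}$ within 1.5%. The identity is first-order — the
quadratic geometric term contributes a relative error of about
$\delta r/2r$, so at the extreme of 10% area pulsation a one-shot
displacement overshoots by ~2.4% regardless of implementation. This is a
property of the linearised wall law itself, documented here so users do not
mistake it for a numerical defect.

$A_n$ defaults to the region's diastolic area (the same quantity the
stiffness is calibrated against, per cine-MRI plane); per-node geometric
slicing of the mesh's cross-sectional rings is available behind
`area_method = "slice"`.

Nodes on the inlet/outlet boundary rings are stiffened by a factor of
$10^3$ (configurable) so the boundary does not dilate; their displacement
under uniform load is then $10^{-3}$ of the interior's. Five
neighbour-averaging smoothing passes (uniform one-ring Laplacian, boundary
rings frozen) remove the stiffness discontinuities between calibration
regions; averaging obeys the discrete maximum principle, so smoothing can
never create stiffness values outside the input range. Smoothing acts on
$K$ itself by default; smoothing the compliance $1/K$ instead is available
as `on = "compliance"`.

## The synthetic physiology generator

No measurement data ship with the package; every test input is generated.
The default virtual patient mirrors a healthy-adult measurement set: heart
rate 68 bpm, brachial pressures 117/72 mmHg, and per-outlet mean-flow
targets of 18.34 (BT), 8.11 (LCC), 11.84 (LSA) and 44.44 (AbAo) ml/s, which
fix the stroke volume at 73 ml. Supra-aortic outlet areas are proportional
to the flow targets, so the area split reproduces them exactly; segment
geometry (nine units, ~0.28 m of aorta) and regional distensibilities
(3.2/2.8/2.4 × 10⁻³ mmHg⁻¹ for ascending/arch/descending) are
physiological values for a young thoracic aorta giving 5–12% area
pulsation.

The inlet waveform is a squared half-sine ejection pulse (C¹ at both ends)
over 34% of the cycle with a small mid-diastolic bump, rescaled
analytically so the cycle integral equals the stroke volume exactly. Area
waveforms place their peak on the sampling grid so the distensibility
estimator inverts the generator exactly at zero noise. Optional seeded
noise (harmonic shape perturbations for flow, Gaussian area noise at the
few-percent scale typical of segmentation uncertainty) is off by default:
the reference conditions are noise-free ground truth.

What the generator does *not* emulate: measured waveforms' beat-to-beat
variability, intercostal flow loss along the descending aorta (the four
plane flows are identical by construction), non-circular lumen
cross-sections, and any imaging artefact. Passing the recovery tests
therefore demonstrates the correctness of the inference chain, not
robustness to real measurement error — the `noise` arguments exist for
users to probe the latter.

## Numerical choices and problem sizes

* ODE integration: `deSolve::ode(method = "bdf")`, `rtol = atol = 1e-7`
  (network) / `1e-8` (single WK3); fixed 1 ms reporting grid.
* Periodic convergence: <1% change in per-cycle systolic and diastolic
  inlet pressure; tuning solves use a tighter 0.5% so tuned-in residuals
  are not convergence noise.
* Root finds: `stats::uniroot` on a log-compliance bracket
  [10⁻³, 50] ml/mmHg; secant iteration for the proximal-resistance
  multiplier, clipped to [0.02, 40] times the characteristic-impedance
  estimate.
* Pressure tolerance for both tuning stages: 0.5% (relative).
* Meshes in tests: 48–64 nodes per ring, 10–24 axial rings (600–1600
  nodes) — enough for sub-percent polygonal slice-area accuracy with
  seconds-scale runtimes. The full calibration of the default patient
  takes ~20 s per variant on one core.

## Worked example

```{r example, eval = FALSE}
vp <- make_virtual_patient(seed = 1)
cal <- calibrate_patient(vp, mode = "compliant")
cal
#> Calibration (compliant): inlet 108.0/72.2 mmHg (targets 108/72)
#> Windkessel table:
#>  outlet      Rp    Rd      C   Rtot
#>      BT 0.28446 4.427 0.3973  4.711
#>     LCC 0.72704 9.926 0.1757 10.654
#>     LSA 0.47052 6.827 0.2565  7.297
#>    AbAo 0.08955 1.855 0.9628  1.944
```

Every number above is produced at run time by the tuning loop; the
Windkessel totals per outlet equal $\bar P/\bar Q_i$ to machine precision
before and after tuning.

## Known limitations

* The 0D topology is a series chain with branch take-offs — adequate for
  the aorta, not for general arterial graphs (no loops, single inlet).
* The wall law is one-shot and linear: no load stepping, no bending
  stiffness, no longitudinal wall motion, and the first-order area error
  noted above.
* Windkessel tuning assumes pulse pressure decreases monotonically with
  compliance and systole grows with the proximal share — true across the
  physiological range, untested far outside it.
* Mesh I/O covers legacy ASCII VTK polydata and ASCII STL only, and the
  VTK reader targets files this package writes (plus a sidecar
  node-to-region CSV for unlabelled surfaces).
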