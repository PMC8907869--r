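# aortacal

MRI-informed calibration of lumped-parameter haemodynamics and
compliant-wall fields for patient-specific aortic CFD.

Cardiovascular CFD groups impose three-element Windkessel (WK3) outlet
boundary conditions and, increasingly, moving-boundary wall motion on
their aortic simulations. Neither the WK3 parameters nor the wall
stiffness can be measured directly. `aortacal` derives them from routine
measurements — a brachial cuff pressure, an inlet flow waveform from
4D-flow MRI, cine-MRI luminal area waveforms and branch geometry — by:

1. **Targets**: central aortic pressures via the transfer
   `Psa = 0.83·Psb + 0.15·Pdb`, `Pda = Pdb`; per-outlet mean-flow targets
   from the inlet/descending-aorta mass balance with an area-proportional
   supra-aortic split; outlet resistance totals `Rtot = P̄/Q̄` with
   `P̄ = 0.4·Psa + 0.6·Pda`.
2. **Vessel mechanics**: distensibility `D = ΔA/(Amin·Ppulse)` from area
   waveforms; branch distensibility via `PWV = 13.3·d^-0.3` and
   `D = 1/(ρ·PWV²)`; inertance `L = (4/3)ρl/A`; volume compliance
   `CV = D·V`; Carreau–Yasuda rheology and a Reynolds turbulence-onset
   check.
3. **0D network**: a nine-unit RLC chain of the aorta with WK3 outlets,
   integrated with a stiff BDF method to periodic convergence (<1%
   cycle-to-cycle change) and tuned — total compliance on a single-WK3
   system analogue, then proximal resistances (and the outlet-capacitance
   scale) on the full network — until the pressure targets appear at the
   inlet, with every outlet's `Rp + Rd` held exactly at its mean-balance
   value. A rigid variant removes the chain capacitors and re-tunes the
   resistive split only.
4. **Wall stiffness field**: per-node `K = 2√(πA)/CA` on a labelled lumen
   surface mesh, with area compliance `CA = D·Amin` per cine-MRI region,
   fixed (stiffened) inlet/outlet rings, five neighbour-averaging
   smoothing passes, and the pressure-proportional displacement operator
   `δ = (p − pext)/K · n̂`.

A synthetic-physiology module generates complete, self-consistent virtual
patients (waveforms, geometry, labelled cylinder/torus meshes, ground-truth
record) so the whole chain is testable without any deposited data. The 3D
flow solve itself is out of scope — the package produces the calibrated
tables, traces and fields a 3D solver consumes.

## Worked example

```r
library(aortacal)

vp  <- make_virtual_patient(seed = 1)   # HR 68 bpm, BP 117/72, SV 73 ml
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

Reading the output: the tuned 0D model shows 108.0/72.2 mmHg at its inlet
against the 108/72 targets derived from the 117/72 brachial cuff. Each
outlet's `Rtot` column equals `P̄/Q̄` for its mean-flow target (e.g.
86.4/18.34 = 4.711 for the brachiocephalic trunk), a constraint the tuning
never violates, so the mean outlet flows match their targets within 0.15%.
`Rp`/`Rd`/`C` are the calibrated Windkessel parameters in mmHg/(ml/s) and
ml/mmHg. Running `calibrate_patient(vp, "rigid", ...)` afterwards produces
the companion parameter set with the identical C column and a softer
resistive split.

`run_calibration(list(mode = "both", out_dir = "out"))` executes the whole
workflow and writes the Windkessel table (CSV), target reports (JSON),
last-cycle pressure/flow traces (CSV) and the smoothed stiffness field
(CSV + legacy ASCII VTK).

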