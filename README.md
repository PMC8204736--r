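# resp2kit

Partial atomic charges for fixed-charge force fields, derived by
two-stage restrained electrostatic-potential (RESP) fitting with a
tunable gas/aqueous polarity mix — plus the evaluation machinery for the
non-bonded model built on top of them.

## Who this is for

Force-field developers and simulation practitioners who need
reproducible partial charges for small organic molecules (H/C/N/O
chemistry: alcohols, amines, nitriles, ethers, alkanes, small ions) and
a transparent, scriptable implementation of the surrounding
bookkeeping: Merz–Singh–Kollman (MSK) surface grids, symmetry-aware
two-stage restrained fitting, charge mixing, Lennard-Jones (LJ) typing,
regularized property objectives and liquid-property estimators. Quantum
chemistry and molecular dynamics are *not* run by this package — ESP
grids and trajectory summaries come in as data, and a synthetic
point-charge ESP generator is included so every fitting operation can be
validated end-to-end without a QM engine.

## The method

Two independent multi-conformer RESP fits are performed, one against
gas-phase ESPs and one against aqueous-phase (implicit solvent,
ε = 78.39) ESPs, and combined per atom with a mixing parameter δ:

    q_i = (1 − δ) q_i^gas + δ q_i^aqueous

Each fit minimizes, over all conformers with equal weight,

    Σ_c Σ_p ( V_c(p) − Σ_i q_i / |p − r_ci| )²  +  a Σ_i ( √(q_i² + b²) − b )

subject to the total-charge constraint and symmetry equalities, on MSK
shells at 1.6/1.8/2.0 Bondi radii with 2.4 points/Å². Stage 1 fits all
charges with a weak hyperbolic restraint (a₁ = 0.005 e/a₀²); stage 2
enforces chemical symmetry and refits only apolar C–H groups under a
stronger restraint (a₂ = 0.01 e/a₀²), with everything else frozen.
δ = 0 gives gas-like, δ = 1 aqueous-like charges; the default δ = 0.6
is the value supported by condensed-phase benchmarking of this model
family.

The evaluation side implements the ten-parameter, five-LJ-type (C, N, O,
polar H, nonpolar H) objective: physical parameters are scaled by prior
widths (0.4184 kJ/mol for ε, 1.0 Å for r_min/2), property deviations are
unit-removed by d_HOV = 0.3 kJ/mol and d_density = 30 kg/m³, a Tikhonov
term w_reg |k|² with w_reg = 10 anchors the search, and a
derivative-free optimizer stops when the step size falls below 0.01 or
the objective improves by less than 1.0. Estimators compute heats of
vaporization (⟨U_gas⟩ − ⟨U_liq⟩/n + RT), densities (nM/(N_A⟨V⟩)) and
dielectric constants (from box-dipole fluctuations) from per-frame
trajectory summaries, and error metrics (MUE, mean relative error vs a
baseline) compare models against experiment.

See `vignettes/charge-derivation-methods.Rmd` for the full account of
the model, conventions and limitations.

## Worked example

Fit δ-mixed charges for the built-in methanol fixture (two O–H rotamers,
synthetic ESPs from hidden reference charges):

```r
library(resp2kit)

fx  <- mock_fixture("methanol")
gas <- lapply(fx$conformers, synthesize_esp, model = fx$model, phase = "gas")
aq  <- lapply(fx$conformers, synthesize_esp, model = fx$model, phase = "aqueous")

model <- resp2(fx$molecule, fx$conformers, gas, aq, delta = 0.6)
summary(model)
```

```
RESP2 fit of 'methanol', delta = 0.6
 atom element class    lj_type   q_gas q_aqueous q_mixed
    1       C     0          C  0.0032    0.0067  0.0053
    2       O     3          O -0.5687   -0.6845 -0.6382
    3       H     1 H_nonpolar  0.0703    0.0838  0.0784
    4       H     1 H_nonpolar  0.0703    0.0838  0.0784
    5       H     1 H_nonpolar  0.0703    0.0838  0.0784
    6       H     2    H_polar  0.3546    0.4265  0.3977
Dipole (conformer 1): gas 2.036 D, aqueous 2.449 D, mixed 2.284 D
```

Reading the output: the three methyl hydrogens share one symmetry class,
so stage 2 has equalized their charges exactly; the O and hydroxyl-H
charges are frozen at their stage-1 values; every column sums to the net
charge (0). The aqueous fit is more polar than the gas fit (here by
construction: the generator polarizes the hidden charges by λ = 1.2, and
the fitted dipoles recover that 2.449/2.036 ≈ 1.2 ratio), and the mixed
column interpolates 40 % gas / 60 % aqueous. The restraint pulls weakly
determined charges toward zero — that is why `q_gas` for the buried
carbon is 0.003 rather than the generating 0.12; rerun with
`settings = fit_settings(stage1_restraint = 0, stage2_restraint = 0)` to
recover the generating charges to < 1e-6 e.

`coef(model, delta = 0.5)` re-mixes without refitting;
`predict(model, points)` evaluates the fitted ESP; `residuals(model)`
gives per-grid ESP misfits; `write_charge_json()` / `write_mol2_charges()`
export the result. A command-line wrapper with `grid`, `mockqm`, `fit`,
`mix`, `eval` and `optimize` subcommands is in `inst/cli/resp2.R`.

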