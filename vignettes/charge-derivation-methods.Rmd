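---
title: "Methods: restrained ESP charge derivation with gas/aqueous mixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restrained ESP charge derivation with gas/aqueous mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resp2kit)
```

## The problem

Fixed-charge force fields assign each atom a partial charge that does not
respond to its environment. Charges fitted to the gas-phase electrostatic
potential (ESP) of a molecule underestimate the polarity a molecule takes
on in a condensed phase, while charges fitted against an implicit-solvent
ESP overestimate it for gas-like environments. `resp2kit` implements a
charge-derivation scheme that fits two separate restrained-ESP (RESP)
charge sets — one to gas-phase ESPs, one to aqueous-phase ESPs (in
production workflows obtained with an implicit solvent of dielectric
constant 78.39) — and interpolates between them with a single polarity
parameter $\delta$:

$$q_i = (1-\delta)\, q_i^{\mathrm{gas}} + \delta\, q_i^{\mathrm{aqueous}}.$$

$\delta = 0$ gives gas-like charges, $\delta = 1$ aqueous-like charges and
$\delta = 0.5$ the per-atom mean; the package default is $\delta = 0.6$,
the value supported by condensed-phase benchmarking of this family of
models. Mixing is affine per atom, so the molecular net charge is
conserved for every $\delta$ and the procedure applies to ions unchanged.

The package also ships the machinery used to *evaluate* a non-bonded
model built from such charges: a five-type Lennard-Jones (LJ)
parameterization, a Tikhonov-regularized property objective,
liquid-property estimators operating on trajectory summaries, error
metrics, and a derivative-free optimization driver. Quantum chemistry and
molecular dynamics themselves are out of scope: ESPs enter as data
(or from the synthetic generator below), trajectories as per-frame
summaries.

## Surface grids

ESP fitting points are generated on Merz–Singh–Kollman (MSK) shells:
fused-sphere surfaces at 1.6, 1.8 and 2.0 times the Bondi van der Waals
radius of each atom (0.2 $R_i$ layer spacing), populated at an areal
density of 2.4 points/Å² per layer. A candidate point on atom $i$'s
sphere at scale $s$ is kept only if it lies at distance $\ge s R_j$ from
every other atom $j$ — exclusion is evaluated per layer at that layer's
own scale, the standard MSK convention.

Two choices here are the package's own:

* **Point placement.** Only the areal density is prescribed, not the
  placement. We use a deterministic golden-angle spiral of
  $n = \mathrm{round}(2.4 \cdot 4\pi r^2)$ points per sphere, which gives
  near-uniform coverage and bit-reproducible grids.
* **Molecule-fixed frame.** Spiral directions are expressed in an
  orthonormal frame built from the first three non-collinear atoms, so a
  rigid motion of the conformer moves every grid point identically
  (pointwise equivariance, tested to $10^{-8}$). For a single atom or a
  perfectly linear molecule no such frame exists and the spiral falls
  back to laboratory axes; the grid is still valid, but only
  set-equivariant under rotations about the degenerate axes.

Internally molecules are in Å and grids in Bohr
(1 Bohr = 0.52917721067 Å), with potentials in Hartree/e — the
quantum-chemistry file conventions.

## The restrained fit

For conformers $c$ with grids $\{p\}$ and reference potentials $V$, the
solver minimizes

$$\sum_c \sum_p \Big(V_c(p) - \sum_i \frac{q_i}{|p - r_{ci}|}\Big)^2
  + a \sum_{i \in \mathcal{R}} \left(\sqrt{q_i^2 + b^2} - b\right)$$

subject to $\sum_i q_i = Q$, optional equality groups and optional frozen
charges. All conformers enter with equal weight — every grid point
contributes one least-squares row, so duplicating a conformer's grid
doubles its weight and conformer order is irrelevant. The hyperbolic
restraint is handled by the classic fixed point: the normal equations
carry a diagonal $a/\sqrt{q_i^2 + b^2}$ refreshed from the previous
iterate, starting from the unrestrained constrained solution, until the
largest charge update falls below $10^{-10}$ e. Equality groups are
applied exactly by collapsing design-matrix columns (never as penalties),
and the total-charge constraint enters as a Lagrange row.

Numerical choices and defaults:

* restraint strengths $a_1 = 0.005$ and $a_2 = 0.01$ e/$a_0^2$ for the
  two stages, centered at zero;
* hyperbola tightness $b = 0.1$ e, inherited from the original RESP
  formulation (only the strengths are prescribed for this scheme);
* hydrogens are excluded from the restraint set by default, the original
  RESP convention; `restrain_hydrogens = TRUE` exposes the other reading;
* the reduced KKT system is solved by QR; rank deficiency after
  constraint reduction is an error rather than a silent minimum-norm
  solution;
* degenerate inputs (grids without values or phase tags, mixed phases,
  infeasible frozen/total-charge combinations, fewer points than free
  parameters) are rejected up front.

**Two-stage protocol.** Stage 1 fits all charges independently under
$a_1$. Stage 2 enforces chemical symmetry and refits only the apolar
parts under $a_2$: the refit set is the carbons bearing at least one
nonpolar hydrogen together with those hydrogens; every other atom is
frozen at its stage-1 value. "Refit-set symmetry" means the topological
equivalence classes restricted to the refit set. The scheme itself does
not enumerate the refit set; ours is the original two-stage RESP
convention. Molecules with no apolar C–H group (water, ammonia) skip
stage 2.

**Equivalence detection.** Chemical equivalence is computed by iterative
neighborhood color refinement seeded by (element, degree), run to a fixed
point with lexicographic tie-breaking. This is deterministic, invariant
under atom relabeling, and never finer than the graph-automorphism
orbits; the test suite verifies it *equals* brute-force orbits on all
built-in fixtures. Its known limitation is that it ignores geometry, so
stereoheterotopic atoms that are graph-equivalent share a class — the
correct behavior for charge fitting of the molecules in scope.

**Polar hydrogens** are hydrogens bonded to N or O (the bond-graph
reading of the SMARTS pattern `[#1:1]-[#7,#8]`); together with C, N, O
and nonpolar H they define the five LJ types.

## The synthetic-ESP generator

`mock_fixture()` and `synthesize_esp()` stand in for the quantum-chemistry
stage so the entire pipeline can be validated exactly:

* reference charges are hidden in the fixture; grid values are the
  Coulomb superposition $V(p) = \sum_i q_i / |p - r_i|$ in atomic units;
* the aqueous phase is emulated by scaling about the mean,
  $q_i' = \lambda q_i + (1-\lambda) Q/N$ with $\lambda = 1.2$ by default,
  which preserves the net charge exactly for ions and scales a neutral
  molecule's dipole by exactly $\lambda$ — the simplest model with the
  qualitative property that aqueous charges are more polar;
* optional Gaussian noise of width `noise_sigma` (default 0) with a
  named, recorded seed.

Because the generator is a pure point-charge model, a noiseless grid
makes the generating charges the *exact* global minimizer of the
unrestrained fit: recovery to $<10^{-6}$ e per atom is a sharp
end-to-end correctness oracle, which the suite checks on all seven
fixtures (water, methanol, methane, ethane, ammonia, acetonitrile,
methylammonium; idealized geometries with standard bond lengths and
angles, two O–H rotamers for methanol). What this deliberately does
*not* emulate: real ESPs contain higher multipole structure,
basis-set/solvent-model artifacts and grid-placement sensitivity, so
exact recovery on the mock generator demonstrates the correctness of the
solver, not the chemical accuracy of any particular charge set.

### What the restraint does to recovery

With the production restraints the fitted charges are *not* expected to
equal the generating charges: the hyperbolic restraint pulls every
restrained atom toward zero with force $\approx a\,q/\sqrt{q^2+b^2}$, and
for atoms whose ESP signature is weak the data term cannot resist it.
The effect is largest for buried atoms — the methane carbon, whose
point-charge field is octupolar only, moves by $\sim$0.4 e — and is
precisely the documented purpose of the restraint: charges on buried
atoms are otherwise ill-determined. Users validating against the mock
generator should therefore use zero restraints for recovery checks and
the production restraints for production charges. The acceptance report
states both numbers.

## The evaluation objective

Physical LJ parameters $K$ (well depth $\epsilon$ in kJ/mol and
$r_{\min}/2$ in Å for each of the five types, ten parameters) are mapped
to mathematical parameters $k_i = (K_i - K_i^0)/t_i$ with prior widths
$t = 0.4184$ kJ/mol for $\epsilon$ and $1.0$ Å for $r_{\min}/2$. The
objective is

$$L(k) = \sum_m \sum_p \frac{\big(y_p^m(k) - y_{p,\mathrm{ref}}^m\big)^2}{d_p^2}
  + w_{\mathrm{reg}} |k|^2,$$

with $w_{\mathrm{reg}} = 10$ and unit-removal scales $d_{\mathrm{HOV}} =
0.3$ kJ/mol and $d_{\mathrm{density}} = 30$ kg/m³. Scales for dielectric
constants and hydration free energies are not standardized and must be
supplied by the user. Property predictions come through a provider
interface; the package ships (a) trajectory-summary estimators and (b)
analytic surrogates for optimizer testing — MD itself is out of scope,
and hydration free energies enter only as externally supplied numbers to
the error metrics.

Estimators (per-frame summaries in kJ/mol, nm³, e·nm):

* heat of vaporization
  $\mathrm{HOV} = \langle U_{\mathrm{gas}}\rangle -
  \langle U_{\mathrm{liq}}\rangle/n + RT$ with
  $R = 0.0083145$ kJ/(mol K);
* density $\rho = n M / (N_A \langle V\rangle)$ in SI units;
* dielectric constant from box-dipole fluctuations,
  $\varepsilon = 1 + (\langle M\!\cdot\!M\rangle - \langle M\rangle\!\cdot\!
  \langle M\rangle) / (3\varepsilon_0 \langle V\rangle k_B T) \ge 1$.

Error metrics are the per-property mean unsigned error
$E_j = \frac{1}{N_d}\sum_i |x_{ij}^{\mathrm{model}} -
x_{ij}^{\mathrm{expt}}|$ and the mean relative error against a baseline
model, $E = \frac{1}{N_P}\sum_j (E_j - E_j^{\mathrm{base}})/
E_j^{\mathrm{base}}$ (conventionally over $N_P = 4$ properties:
densities, HOV, dielectric constants, hydration free energies).

**Optimizer.** The reference workflow's optimizer is not specified beyond
its stopping behavior, and surrogate providers need not be
differentiable, so `optimize_objective()` is a deterministic
derivative-free compass search in $k$-space: poll $\pm$step along each
coordinate, accept the best improvement (accepted-step objective values
never increase), halve the step on failure. It stops when the step size
falls below 0.01, when an accepted step improves the objective by less
than 1.0, or at the iteration cap; the two thresholds are the published
stopping rules and are exposed as arguments because the coarse objective
threshold (1.0 against $w_{\mathrm{reg}}|k|^2 = 10|k|^2$) already fires
at $|k| \approx 0.3$ — tests of the "regularizer returns $k$ to zero"
property use a tighter objective tolerance. Starting at a minimum
terminates without accepting any step. The search reproduces the stated
termination behavior, not the trajectory of any particular production
optimizer.

## Problem sizes used in the tests

The validation suite runs entirely on the synthetic generator: seven
fixtures of 3–8 atoms, one or two conformers each, full-density MSK
grids of roughly 700–2600 points per phase — large enough that every fit
is overdetermined by two orders of magnitude, and small enough that the
whole suite (including a $10^5$-frame dielectric fluctuation check and
100-table metric oracles) runs in well under a minute. The methods are
dimension-independent; nothing in the implementation assumes these sizes.

## Known limitations

* Equivalence classes are topological; geometric symmetry breaking
  (e.g. stereoheterotopic protons) is intentionally ignored.
* Pointwise grid equivariance degenerates to set-equivariance for linear
  and single-atom systems (frame ambiguity).
* Whether production RESP implementations restrain hydrogens, their
  exact $b$, and whether stage 2 re-enforces symmetry outside the refit
  set vary; the defaults here follow the original RESP conventions and
  flags expose the alternatives.
* Conformer weighting is uniform (no Boltzmann weights), matching the
  reference protocol.
* The CLI's `optimize` subcommand drives the shipped analytic surrogate
  provider; wiring a simulation-backed provider is the caller's
  responsibility via `objective_spec()`.
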