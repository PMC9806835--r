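---
title: "Conformer mixtures and benchmark proton affinities: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer mixtures and benchmark proton affinities: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protaff)
```

## The problem

The proton affinity (PA) of a base B is the enthalpy change of the
gas-phase reaction BH⁺ → B + H⁺, and the gas-phase basicity (GB) is
the corresponding Gibbs free-energy change. For a conformationally
flexible molecule like cysteine neither species is a single structure:
at 298 K the neutral amino acid and each of its protonated forms
(amino-, carbonyl- and thiol-protonated) are equilibrium mixtures of
several low-lying conformers. `protaff` packages the entire workflow
that sits between electronic-structure output and the final PA/GB
numbers: systematic conformer generation, deduplication, focal-point
energy assembly, rigid-rotor/harmonic-oscillator (RRHO)
thermochemistry, and Boltzmann-mixture averaging.

## Torsional enumeration and its symmetry reductions

Starting structures come from rotating each internal-rotation group
(amino, carboxyl, hydroxyl, thiol, side chain) on a grid, by default
60°, so each free torsion contributes `360/60 = 6` values and five of
them give 6⁵ = 7776 starts. Two reductions are built into
`torsion_spec()`:

* a **local symmetry period**: a protonated amino group is C3v, its
  torsion repeats every 120°, contributing `120/step` points (6⁴ × 2 =
  2592 starts for the amino-protonated species);
* a **mirror flag**: a planar `{C(OH)2}` group is C2v, making half the
  joint grid redundant; the grid is halved once (6⁶/2 = 23 328 for the
  carbonyl-protonated species, which gains one extra hydroxyl torsion).

`enumerate_grid()` reports the closed-form count and `grid_points()`
materialises the lexicographic angle tuples; the identity between the
two is property-tested over random step/period combinations.

## Deduplication and stationary-point filtering

Optimised endpoints are fingerprinted by two numbers: the energy
relative to the current set minimum and the largest rotational
constant A. Two structures are *the same* conformer only when both
agree — |ΔΔE| < 0.01 kcal/mol **and** |ΔA| ≤ 3 × 10⁻⁴ cm⁻¹ (the
defaults; both tunable). The published criterion states when two
structures are *different* ("and/or"); same-iff-both-below is the only
reading under which "different" is well defined, so that is what
`deduplicate()` implements. Chains of near-duplicates are resolved by
transitive closure (union-find) with the lowest-energy member as the
cluster representative, and the pass repeats on representatives until
a fixed point, making the operation idempotent. An independent
all-pairs threshold-graph oracle (igraph components) backs this in the
test suite.

Minima are separated from transition states only by harmonic
frequencies: `filter_minima()` keeps exactly the entries with zero
imaginary modes and refuses entries whose mode counts were never
computed — silence is not consent here, because a missing frequency
job is the most common silent failure in large sweeps.

Grid sweeps also produce structures that are no longer the target
molecule. `classify_byproduct()` decides from bond topology alone
(covalent-radius cutoff, default scale 1.2): more fragments than the
reference is *broken* (detached SH₂/OH₂/NH₃-type unit), a new small
ring is *cyclized*, a changed hydrogen/heavy-group attachment map with
intact connectivity is *rearranged*. Energy gaps are deliberately not
used — for protonated species the gap between target conformers and
byproducts closes, so topology is the only reliable separator.

## Protonation-site construction

`attach_proton()` builds starting guesses by placing one hydrogen at a
trial bond length (1.02 Å N–H, 0.98 Å O–H, 1.35 Å S–H) along the
site's lone-pair direction, in two variants per site: the amino
variants differ by a 60° rotation about the C–N axis, the
hydroxyl/thiol variants by a 90° azimuthal rotation (perpendicular
H–X–H planes), and the carbonyl variants by cis–trans placement
relative to the other C–O bond. These are *seeds* for downstream
optimisation; chemical accuracy of the placement is neither needed nor
claimed.

## Focal-point composite energies

The benchmark electronic energy of each conformer is assembled
additively from ledger columns (all kcal/mol):

* post-(T) corrections in a small basis: δT = CCSDT − CCSD(T) and
  δ(Q) = CCSDT(Q) − CCSDT;
* core correlation: Δ_core = all-electron − frozen-core;
* scalar relativity: Δ_rel = Douglas–Kroll − non-relativistic;
* ΔE_e = ΔE(CCSD(T)-F12b/cc-pVQZ-F12) + Δ_core + Δ_rel + δT + δ(Q),
  and ΔH₀ = ΔE_e + Δ_ZPE, both exact sums.

Ledgers are either *relative* (conformer I at zero — the form tables
are printed in) or *absolute* (hartree input converted with
627.509474 kcal/mol). Relative outputs are re-zeroed on the lowest
composite energy, which cannot change any energy difference. When the
package validates against printed tables it allows 0.015 kcal/mol,
absorbing per-column rounding (a row of values printed to 2 decimals
can mis-sum by one unit in the last digit).

A diagnostic, `geometry_effect()`, reports the energy difference
between the coupled-cluster energies at the cheap-method and at the
coupled-cluster geometries; in the packaged cysteine tables it averages
0.02 kcal/mol for amino-protonated but 0.55 kcal/mol for
thiol-protonated conformers (mean over the nine non-reference rows —
the reference row is identically zero by construction).

## RRHO thermochemistry

`rrho_state()` uses the standard ideal-gas expressions: translation
contributes 5/2 RT and the Sackur–Tetrode entropy; rotation 3/2 RT and
the classical asymmetric-top entropy with symmetry number 1 (the
species handled here are C1) and electronic degeneracy 1 (closed
shell); each harmonic mode its Bose-factor enthalpy and entropy, with
the zero-point energy reported separately so H(0 K) reduces to the
ZPE. No frequency scaling is applied, and anharmonic or hindered-rotor
refinements are out of scope by design — the low-frequency torsional
modes are therefore the dominant uncertainty in the 298 K thermal
corrections, which is inherent to plain RRHO.

Choices a user may care about:

* standard state 1 bar (`pressure = 1e5` Pa). The proton enthalpy
  5/2 RT = 1.48 kcal/mol at 298.15 K is pressure-independent; the
  proton entropy at 1 bar is 26.04 cal mol⁻¹ K⁻¹. Both are fixed by
  physics, not fitted.
* the bare proton mass (1.00727646627 u) is used for H⁺, not the H
  standard atomic weight.
* all constants are CODATA 2018, shared through `pa_constants` so
  every module (and every test oracle) agrees; 1 cm⁻¹ =
  2.859144 × 10⁻³ kcal/mol; masses are IUPAC standard atomic weights.
* `G = H − T·S` holds exactly (to 10⁻¹² kcal/mol) for every emitted
  state; this is asserted, not assumed.

## Boltzmann mixtures

Populations follow `x_i ∝ exp(−ΔG°_i/RT)` from the 298.15 K relative
free energies. Mixture enthalpies are population-weighted means. For
the mixture free energy two conventions exist:

* the population-weighted mean ⟨ΔG⟩, and
* the ensemble form −RT ln Σ exp(−ΔG_i/RT) = ⟨ΔG⟩ + RT Σ x ln x,
  which includes the configurational (mixing) term and is never above
  the weighted mean.

The source tables do not state which convention their mixture rows
use, so both were computed against the published N-site basicity:
the weighted mean gives 208.65 kcal/mol, the ensemble form
208.18 kcal/mol against a published 208.21. The ensemble form is
adopted, and the discriminating computation is kept as a regression
test so the convention cannot silently drift. One further convention
follows the same logic: the 0 K mixture enthalpy averages use the
298.15 K populations (a single population set per species), which
reproduces the published 0 K mixture PA within the 0.05 kcal/mol
input-rounding tolerance.

`site_pa_gb()` combines the two species:

```
PA_mix(T) = PA_anchor(T) + ⟨ΔH(T)⟩_B − ⟨ΔH(T)⟩_BH⁺
GB_mix    = GB_anchor + G_mix,B − G_mix,BH⁺
```

anchored on the lowest-conformer pair. With a single conformer per
species every shift vanishes — the single-conformer reduction is one
of the package's invariant tests.

```{r example}
neutral <- cysteine_benchmark_table("neutral")
n_prot <- cysteine_benchmark_table("N")
res <- site_pa_gb(neutral, n_prot,
                  anchor = list(pa_0k = 214.49, pa_298k = 215.79,
                                gb_298k = 208.44),
                  site = "N")
res
glance(res)
```

## The synthetic backend: what it emulates and what it does not

Real conformer searches run through electronic-structure programs the
package cannot (and should not) ship. Two synthetic components stand
in for them, as first-class tested code:

* **`toy_pes()`** — an analytic, 2π-periodic Fourier surface over the
  torsion angles with optional pairwise couplings. It reproduces the
  *funnelling* phenomenology of real landscapes (many grid starts
  drain into few minima; saddles with exactly one imaginary mode sit
  between wells) while keeping every property checkable: gradients are
  analytic, all minima are enumerable by dense scanning
  (`toy_minima_scan()`, the test oracle), and the Hessian has a closed
  form. Optimisation runs in torsion space (BFGS with the analytic
  gradient, gradient norm < 10⁻⁶ kcal/mol/rad; idempotent at
  convergence). "Frequencies" are central-difference Hessian
  eigenvalues (step 0.5°) mapped to nominal wavenumbers by a fixed
  scale of 500 — they order stationary points correctly but are **not
  physical**. The default surface has 3 × 2 wells with stationary
  points deliberately shifted off the 60° grid.
* **`generate_ledger()`** — seeded synthetic correction ledgers with
  the magnitude structure of real benchmark tables: relative energies
  over a few kcal/mol, corrections of order 0.01–0.1 kcal/mol, and
  ZPE corrections whose sign regime depends on the protonation site
  (varying sign for N, negative ≈ −0.47 for O, positive ≈ +0.79
  kcal/mol for S — the published per-site averages).

What passing the synthetic tests shows: the bookkeeping, the
combinatorics, the clustering, the assembly algebra and the mixture
statistics are correct. What it does not show: anything about a real
potential-energy surface. In particular the published conformer
inventories of cysteine (85 neutral; 21/64/37 protonated) require
ab initio surfaces and are deliberately not reproduction targets; the
packaged tables are transcriptions used as *inputs*, and the packaged
seed geometry and torsion definitions are synthetic stand-ins, labelled
as such.

## Numerical choices and degenerate inputs

* Dihedral convention: right-handed atan2 form; angles in (−180°,
  180°]; rotating a torsion by +θ increases its measured dihedral by
  +θ regardless of which side of the bond the moving set lies on.
* Linear geometries: flagged, the two finite rotational constants
  returned, A undefined — linear species cannot use the A-based
  deduplication fingerprint.
* Non-convergence in a grid sweep is data (kept with
  `converged = FALSE`), never an abort: occurrence statistics count
  only converged starts.
* Conformer assignment during a sweep clusters endpoints by energy
  (< 0.01 kcal/mol) and torus distance between angle tuples (< 15° by
  default) — the angle criterion replaces the A-constant fingerprint,
  which has no meaning on the toy surface.
* Report CSVs print doubles at 17 significant digits and are re-read
  with the base parser, so write→read round trips are bit-exact.
* Empty torsion sets enumerate to a single grid point (the seed);
  empty ledgers and empty free-energy vectors are explicit errors.

## Problem sizes

The shipped tests run the toy searches on two-torsion grids (36 and
144 starts) against 2°-resolution scan oracles, deduplication on 100
random entries against the graph oracle, and the full mixture
calculations on the 10-conformer packaged tables; the complete suite
takes well under a minute on a single core.

## Known limitations

* RRHO only: no anharmonicity, no hindered-rotor treatment, no
  quasi-RRHO damping of low frequencies.
* Byproduct classification is topological; it cannot distinguish
  stereochemical rearrangements that preserve the attachment map.
* `attach_proton()` requires the site's functional group to be
  detectable from connectivity at the default cutoff scale.
* The toy backend's wavenumbers are nominal; thermodynamic quantities
  derived from them exercise code paths, not chemistry.
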