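---
title: "Methods: desk-scale modelling and electroanalysis for e-MIP sensor design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale modelling and electroanalysis for e-MIP sensor design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An electropolymerized molecularly imprinted polymer (e-MIP) sensor is built
by polymerizing a functional monomer (here ortho-phenylenediamine, o-PD)
around a template analyte (here the synthetic cathinone MDPV) directly on an
electrode. Washing out the template leaves cavities whose geometry and
interaction pattern were moulded by the *pre-polymerization complex*: the
template plus the monomers of its first solvation shell in the
polymerization solution. Rational design therefore asks two computational
questions — what do those complexes look like, and how strongly do they bind
the template — and a set of electroanalytical ones once the sensor exists:
how sensitive is it (calibration slope, detection limit), how resistive is
the film (impedance), and how thick is it (polymerization charge).

`emip` implements that whole chain at desk scale: a rigid-body Metropolis
Monte Carlo sampler in the constant-NPT ensemble, first-shell cavity
extraction with population statistics and a two-stage energy funnel,
classification of tabulated QTAIM bond-critical-point (BCP) interactions
with Espinosa binding energies, and the electroanalytical computations.

## The molecular model

Molecules are **rigid bodies**: interaction sites with fixed body-frame
coordinates, a Lennard-Jones diameter $\sigma$ (Å), well depth $\epsilon$
(kcal/mol) and fixed partial charge $q$ (e). Torsional flexibility is
deliberately not modelled; a rigid template/monomer/water system keeps
every downstream statistic exercisable while removing intramolecular
terms entirely. The intermolecular energy of a molecule pair is

$$U_{AB} = \sum_{i \in A}\sum_{j \in B}
  4\epsilon_{ij}\!\left[\left(\frac{\sigma_{ij}}{r_{ij}}\right)^{12}
  - \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
  + \frac{C\, q_i q_j}{r_{ij}},$$

with geometric-mean combining rules for both $\sigma$ and $\epsilon$,
$C = 332.06371$ kcal mol$^{-1}$ Å e$^{-2}$, and minimum-image distances in
an orthorhombic periodic box. The cutoff is **molecule-based**: a pair
interacts if and only if the minimum-image distance between the two
centres of geometry is within the cutoff, so whole-molecule interactions
switch together and cavity energies never see split molecules. Within an
included pair the LJ term is shifted by its value at the cutoff;
electrostatics use a straight cutoff at the same molecular distance — a
documented approximation appropriate for desk-scale boxes, where lattice
sums would be overkill for the statistics being tested. The unit system
is fixed throughout: Å, kcal/mol, K, atm, elementary charges,
$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$.

## NPT Metropolis sampling

`metropolis_step()` proposes, with probability `volume_move_frequency`, a
volume move uniform in $\ln V$ (accepted with
$\min\{1, e^{-\beta[\Delta U + P\Delta V] + (N+1)\ln(V'/V)}\}$,
coordinates scaled through molecule centres — the $(N+1)$ Jacobian is the
standard formulation for ln-V moves), and otherwise a uniformly chosen
molecule receives a random translation (uniform in a cube) or rotation
(uniform axis, bounded angle), accepted with
$\min\{1, e^{-\beta\Delta U}\}$. A volume move that would push the cutoff
past half the smallest box edge is auto-rejected and logged. Move
amplitudes default to values giving 30–50 % acceptance in dense toy
boxes; `volume_move_frequency = 0` supports fixed-box sampling.

Energy bookkeeping is incremental (only the moved molecule's
interactions are recomputed) and is validated against full recomputation:
drift after $10^5$ moves is below $10^{-8}$ kcal/mol. Correctness of the
sampler itself is checked against two independent oracles: the
closed-form ideal-gas NPT average $\langle V\rangle = (N+1)k_BT/P$
(within 2 % at $N = 50$, $2\times10^5$ steps) and the radial distribution
of an LJ dimer in a fixed box against numerical quadrature of
$r^2 e^{-\beta U(r)}$ (Kolmogorov–Smirnov distance < 0.02 at $10^5$
recorded samples). For the dimer check the chain is thinned (one recorded
sample every 4 moves) purely to decorrelate samples; the target
distribution is unaffected.

`run_simulation()` runs `n_parallel_runs` logically independent chains
with seeds derived deterministically from the master seed, recording one
frame every `snapshot_stride` production steps:
`n_parallel_runs * floor(n_production / snapshot_stride)` frames. Two
chains of 154 000 production steps at stride 500 — the protocol scale the
cavity statistics are built on — give exactly 616 frames. Whether a
"step" counts one attempted move or one sweep is left abstract: the
stride arithmetic, and hence the frame count, is identical either way.

The layered start (`build_layered_initial()`) places monomers on a
jittered lattice in the lower half of the box, solvent in the upper
half, and the single template at the centre of the dividing plane.
Lattice spacing and jitter guarantee no two sites of different molecules
are closer than $0.85\,\sigma_{ij}$. The default packing density is
0.35 g/cm³, not the ~1.0 of a real aqueous solution: the coarse-grained
beads (up to $\sigma = 4.5$ Å) cannot pack to liquid-water density on a
non-overlapping lattice, and the initial density is only a construction
convenience — NPT sampling relaxes the volume afterwards.

## Cavity extraction, funnel and statistics

A monomer belongs to the template's **first solvation shell** when its
minimum site–site minimum-image distance to the template is at most the
shell cutoff. The field's convention bounds the first shell by the first
minimum of the contact-distance distribution; `shell_cutoff_from_rdf()`
implements exactly that (histogram, moving-average smoothing, first
local minimum after the first peak, parabolic refinement) and errors on
monotone or structureless histograms rather than guessing. A fixed
default of 4.0 Å is available when the trajectory is too short for a
stable histogram.

Extracted cavities are grouped by monomer count and pushed through a
coarse-to-fine funnel that mirrors a semi-empirical-then-DFT selection
hierarchy with classical stand-ins (quantum engines are out of scope
here, by design):

1. every member is relaxed by greedy rigid-body coordinate descent
   (per-molecule axis translations/rotations, only energy-lowering moves,
   step halving) to a **stage-1** tolerance of $10^{-2}$ kcal/mol per
   cycle; within each group, members within 10 kcal/mol of the group
   minimum survive;
2. survivors are re-relaxed to a **stage-2** tolerance of $10^{-4}$;
   those within 5 kcal/mol of the overall minimum survive and are
   rescored with a single-point energy.

Both cuts are inclusive (`<=`) — threshold semantics must be fixed to be
testable. The wording of the protocol applies the first cut *per group*
and the second *from the most stable one*; we read the latter as the
global minimum over survivors, and implement per-group at stage 1,
global at stage 2. Ties for "most stable" break towards fewer monomers,
then the earlier provenance step, so reports are deterministic.

Binding energies are $E(\text{complex}) - E(\text{template}) -
\sum E(\text{monomer})$; with rigid molecules the isolated terms vanish,
so the value equals the total intermolecular energy of the isolated
complex (no cutoff, no periodicity). Stabilizing energies are negative;
reports also print $|E|$, since stability discussions usually quote
magnitudes.

Population statistics (`population_report()`) are fractions of all
extracted cavities per monomer-count group; interval queries
(`population_share()`) sum member fractions. The packaged preset
`mdpv_population_counts()` — 616 cavities split 80/126/140/114/88/68
over sizes 18–23 — is *authored to match the printed full-scale
population statistics* (20.5 % / 22.7 % / 18.5 % for 19/20/21 monomers,
61.7 % combined); it is a worked-example fixture, not a re-simulation,
and the package never claims to reproduce the full OPLS-parametrized
sampling behind those numbers.

## QTAIM tables and Espinosa energies

The AIM module consumes *tabulated* BCP properties (CSV, atomic units);
wavefunctions and BCP searches are out of scope. A contact is classified
non-covalent when $\nabla^2\rho > 0$ and $|H|$ is close to zero;
"close" defaults to $|H| \le 0.005$ a.u., a typical QTAIM practice
threshold made explicit (and configurable) so the rule is testable.
Negative-Laplacian rows are covalent; a positive Laplacian with
substantial $|H|$ is flagged ambiguous rather than forced into either
class. Espinosa binding energies are $BE = V(r)/2$, converted at
627.5095 kcal/mol per hartree with sign preserved — individual
closed-shell contacts are weak, and it is their *number* that stabilizes
the template in a cavity, which is why the per-cavity summary reports
the count alongside the summed energy.

## Electroanalysis

**SWV peaks.** The baseline is a straight line through the current
minima flanking the search window (minimum of the first and last third);
the peak is the interior maximum of the corrected current, with the peak
potential refined by 3-point parabolic interpolation. A trace with no
interior maximum reports "not detected" — the behaviour of
non-responding interferents in selectivity panels. The linear-flanking
baseline is the simplest defensible rule; nothing in the protocol
prescribes one.

**Calibration.** Ordinary least squares; detection limits follow the
ICH-style rules LOD = 3.3 s / slope and LOQ = 10 s / slope, with s the
intercept standard error by default or a supplied blank SD. No published
replicate data exist to validate a specific LOD value, so the package
asserts the *estimator* (exact recovery on noiseless data; Monte Carlo
mean LOD within 2 % of 3.3 s/slope over 1000 synthetic replicates), not
any particular printed number.

**EIS.** The fitted circuit is $R_s + (R_{ct} \parallel CPE)$ — the
described Nyquist feature is a single depressed semicircle whose
diameter is the charge-transfer resistance; no Warburg element is
included. Fitting is complex nonlinear least squares with modulus
weighting $\sum|Z_{obs}-Z_{model}|^2/|Z_{obs}|^2$ (the standard choice
when $|Z|$ spans decades), on bounded parameters via
Levenberg–Marquardt; parameters pinned at bounds (e.g. $R_{ct}$ for a
pure resistor) are flagged, and asymptotic standard errors come from the
Jacobian.

**Film thickness.** $h = qM/(\rho A n F)$, returned in nm. The number of
electrons per monomer is *not* defaulted — it is not a settled constant
for o-PD electropolymerization — so callers must state it. The
polymerization charge comes from a baseline-corrected trapezoidal
integral of CV current over the anodic window divided by the scan rate,
summed over cycles.

Concentrations are stored in mol/L with explicit unit documentation;
where source material mixes mol/L and mmol/L the package takes no side
and the recipe-ratio helper (`monomer_template_ratio()`) works on any
single consistent unit.

## Synthetic data: what it emulates and what it does not

`make_toy_system()` builds a coarse-grained stand-in: a net +1 template
(a protonated analyte salt) with three H-bond acceptor sites and a
cationic amine buried behind a bulky core bead (sterically hindered, as
the real tertiary amine is in its shell), a neutral two-donor monomer,
and a neutral LJ-sphere solvent. Donor/acceptor contacts are modelled as
deep LJ wells (ε 1.5–1.7 kcal/mol) with modest charges, calibrated once
so the head-on donor–acceptor scan minimum sits at 2.89 Å, inside the
2.8–3.2 Å band typical of N–H···O hydrogen bonds. The single-site
solvent has no dipole: it provides packing and a hydrophobic driving
force but no competing H-bonds, one reason desk-scale shell statistics
are not comparable to the full-scale study.

Every generator (`gen_cavity_count_fixture()`, `gen_calibration()`,
`gen_eis()`, `gen_bcp_table()`) is deterministic given its seed and
emits its ground truth as an attribute plus a `.truth.csv` sidecar, so
tests validate against recorded truth instead of re-deriving it. The
cavity-count generator *constructs* frames with exactly the requested
shell membership (placing monomers against template sites and decoys far
outside, then verifying by running the extractor) — passing tests
demonstrate the correctness of extraction, grouping and reporting, not
that the toy force field reproduces real shell-size distributions.

## Validation problem sizes

The test suite exercises: ideal-gas NPT at $N = 50$ over $2\times10^5$
steps; the LJ-dimer distribution at $10^5$ recorded samples; energy
bookkeeping over $10^5$ moves at $N = 12$; shell extraction against a
brute-force double loop on 100 random frames; the full 616-frame
population fixture; 100-seed EIS recovery and 1000-replicate calibration
Monte Carlo. These sizes give stable statistics at interactive runtimes;
the sampler accepts full-scale inputs (one template, 601 monomers, 5000
solvent molecules) and the layered builder is tested at that scale, but
full-scale production sampling is outside the test suite's scope.

## Known limitations

- Rigid molecules: no torsional relaxation of template or monomers.
- Straight-cutoff electrostatics; no Ewald summation. Net-charged
  template plus cutoff electrostatics means absolute energies carry a
  systematic truncation component; funnel decisions compare energies of
  same-composition cavities, which cancels most of it.
- The classical relax-and-rescore funnel preserves the *topology* of a
  semi-empirical/DFT hierarchy, not its energetics; no quantum-level
  quantity is reproduced, and published full-scale numbers (shell-size
  ranges, funnel survivor counts from real energies, formation energies,
  charge-transfer resistances, detection limits, film thicknesses) are
  not asserted by any test.
- Greedy coordinate descent finds local minima only — appropriate for
  tightening an extracted geometry, not for global search.
- The SWV baseline and the RDF-minimum shell rule are simple documented
  conventions; other reasonable choices shift absolute values slightly.
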