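---
title: "Boost potentials and free-energy landscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boost potentials and free-energy landscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdpmf)
```

## The accelerated-MD boost potential

Accelerated molecular dynamics (aMD) enhances conformational sampling by
raising the potential-energy surface wherever it falls below a reference
energy $E$. The modified potential is

$$V^*(r) = V(r) + \Delta V(r), \qquad
\Delta V(r) = \begin{cases}
\dfrac{(E - V(r))^2}{\alpha + E - V(r)} & V(r) < E,\\[4pt]
0 & V(r) \ge E,
\end{cases}$$

with acceleration factor $\alpha > 0$. The form has the properties that
make it useful: $\Delta V \ge 0$, the boosted energy never crosses the
reference ($V^* < E$ whenever $V < E$), the boost and its first
derivative vanish continuously at $V = E$, and the landscape flattens
progressively as $\alpha$ decreases while $V^* \to V$ as
$\alpha \to \infty$ (the conventional-MD limit). Forces on the modified
surface are the unbiased forces scaled by

$$\frac{dV^*}{dV} = \frac{\alpha^2}{(\alpha + E - V)^2} \in (0, 1],$$

which `force_scale_factor()` implements analytically. The boundary
$V = E$ is assigned to the unboosted branch; both branches agree there,
so the choice is cosmetic, but it is fixed so that bit-exact tests are
well defined.

In dual-boost aMD a dihedral-term boost and a total-energy boost act
together. The composition order is: dihedral boost first, then the
total boost applied to the already-dihedral-boosted total energy — the
convention of the dual-boost implementations this recipe comes from.
`compute_amd_parameters()` derives the four parameters from short
conventional-MD averages:

$$E_\mathrm{dihed} = (1+\lambda) V_\mathrm{dihed,avg}, \quad
\alpha_\mathrm{dihed} = \lambda V_\mathrm{dihed,avg}/5, \quad
E_\mathrm{total} = V_\mathrm{total,avg} + 0.2\,N_\mathrm{atoms}, \quad
\alpha_\mathrm{total} = 0.2\,N_\mathrm{atoms},$$

with $\lambda = 0.3$ the recommended acceleration for membrane-protein
systems. The dihedral divisor 5 is part of the recipe, not a tuning
knob; it is only exposed as an advanced argument for methodological
experiments.

## The Langevin toy engine

The simulator integrates underdamped Langevin dynamics with the BAOAB
splitting at unit mass. BAOAB was chosen because its configurational
sampling error is small at usable timesteps, which is exactly what PMF
validation needs. Defaults are a timestep of 0.01 reduced time units
and friction 1.0; temperature enters through
$k_BT = 0.0019872041\,T$ kcal/mol, so 300 K gives the familiar
$k_BT \approx 0.596$ kcal/mol and toy energies read directly in
kcal/mol.

With a boost active the engine runs on $V^*$: forces are scaled by
`force_scale_factor()` evaluated at the instantaneous potential, and
the per-frame $\Delta V$ is stored with each saved frame (not every
step) for later reweighting. Toy potentials have no meaningful
dihedral/total split, so the engine applies a single (total) boost; a
`boost_parameters` object is accepted and its total term used.

Randomness comes from R's RNG — one normal deviate per degree of
freedom per step — so a `set.seed()`-style seed in the configuration
makes runs bit-reproducible, and the compiled (Rcpp) and pure-R
integration paths replay the identical stream. Potentials built by the
package constructors carry a compiled-kernel tag; user-supplied
closures fall back to the pure-R loop.

The analytic reference is `analytic_pmf()`, which integrates the
Boltzmann weight per bin by composite Simpson quadrature (33 points per
bin by default; the harmonic and double-well checks in the test suite
bound the quadrature error well below 10^-6 kcal/mol at that setting).

## PMF estimation conventions

`pmf_1d()`/`pmf_2d()` are histogram estimators:
$F_i = -k_BT \log P_i$ with $P_i$ the (optionally weighted) fraction of
frames in bin $i$. Conventions, fixed once so that every downstream
comparison is reproducible:

* **Zero.** The minimum over defined bins is shifted to exactly 0 for
  every profile, 1D and 2D.
* **Empty bins** have undefined (`NA`) free energy — never a clipped
  cap. Comparisons and sweeps operate on commonly defined bins only.
* **Anchoring.** Bins are anchored at 0 for distances and at -180° for
  dihedrals, so different bin sizes share an origin.
* **Periodicity.** Dihedral axes wrap on (-180°, 180°]; bin sizes must
  divide 360 (3, 5, 6, 9, 10, 12, 15 all do, covering the usual sweep
  and the 6° 2D grid). Sizes that do not divide the period are
  rejected rather than silently tiling unevenly.
* **Temperature.** 300 K unless stated; the simulation temperature
  behind published landscapes is not always restated alongside them,
  so the default is recorded in every profile's metadata.
* Error bars are deliberately out of the core contract; per-bin counts
  are exposed so callers can bootstrap.

### Reweighting

`exponential_weights()` implements the exact Boltzmann-factor
reweighting $w_i \propto e^{\Delta V_i/k_BT}$ with max-shifted
exponentials, so a 500 kcal/mol boost is handled without overflow.
`cumulant_reweight()` implements the expansion of
$\log\langle e^{\beta\Delta V}\rangle$ per bin to first or second
order: $F_i^{rw} = F_i - [\langle\Delta V\rangle_i +
\tfrac{\beta}{2}\mathrm{Var}(\Delta V)_i]$. For Gaussian per-bin boost
distributions the order-2 expansion is exact
($\log\langle e^{\beta x}\rangle = \beta\mu + \beta^2\sigma^2/2$), and
the test suite verifies the two estimators agree within 0.1 kcal/mol
when $\sigma \le k_BT$. For broad or heavy-tailed boost distributions —
the regime large solvated systems actually produce — the estimators
legitimately diverge; the suite checks the divergence has the expected
direction rather than pretending it away. Orders above 2 amplify noise
and are refused.

### The bin-size precision sweep

Recomputing a PMF at several bin sizes and checking that the profiles
coincide is the standard precision diagnostic: poor sampling shows up
as large variation across bin sizes. Two design points deserve
explanation.

First, *how profiles of different bin sizes are compared.* A naive
piecewise-constant comparison at the finest profile's bin centers is
dominated by discretization parallax on steep walls: where the PMF
rises at slope $s$, a bin of width $w$ reads low by
$k_BT\log\left(\sinh(a)/a\right)$ with $a = sw/2k_BT$ — about 0.2–0.3
kcal/mol for $s \approx 3.5$ kcal/mol/Å at $w = 0.5$ Å — even with
perfect sampling, which would make the diagnostic condemn converged
data. `bin_size_sweep()` therefore compares profiles as curves (linear
interpolation through defined bin centers, the way multi-bin-size
profiles are overlaid in practice), evaluated at the finest profile's
centers.

Second, *where they are compared.* Log-counts of bins holding a
handful of frames are noise; the sweep restricts the comparison to
bins that every profile resolves with at least `min_count` frames
(default 200, the same well-sampled convention the sampling-oracle
tests use: at 200 counts the per-bin statistical error is
$\sim k_BT/\sqrt{200} \approx 0.04$ kcal/mol). If no bin qualifies —
a genuinely undersampled series — the sweep falls back to all commonly
defined bins and flags the report `low_sampling`, which preserves the
diagnostic's direction: undersampled series still show large
deviations.

### Locating minima

`pmf_minima()` reads well positions off a profile the way one reads
them off a plotted landscape: local minima over well-sampled bins,
filtered by topographic prominence (the rise to the lowest saddle
separating a minimum from any deeper one, default 0.15 kcal/mol — two
standard errors at the default count threshold), then refined by a
quadratic fit across the well bottom. The fit window grows until the
profile has risen by min(0.5 kcal/mol, 90% of the prominence) or
starts descending into a neighbouring basin, so broad flat wells are
averaged over many bins while shallow wells are not polluted by their
saddle. In 2D, candidate cells must additionally be local minima over
their 8-neighbourhood (periodic-aware), which prevents the shoulder of
a deep basin from outranking a genuinely separate shallow one.

## The synthetic generators

The generators define the study conditions for everything the package
cannot rerun (microsecond trajectories of a membrane-embedded
receptor), and their defaults are fixed, not tuned per test.

`synth_ionic_lock_series()` draws i.i.d. frames from a three-component
Gaussian mixture emulating a converged ionic-lock distance
distribution: a closed salt-bridge well at 4.6 Å, a second contact
conformation at 6.4 Å, and a broad open basin at 14.2 Å. Weights
(0.6180, 0.2186, 0.1634) and widths (0.55, 0.45, 1.8 Å) place the
basin free energies at 0, 0.5 and 1.5 kcal/mol at 300 K: the open
basin's ~1.5 kcal/mol offset and breadth match the published apo-state
landscape, the second well is shallower than the first (it is the less
populated of the two contact states), and the contact-well widths are
chosen so the two minima remain distinct (prominence ≈ 0.3 kcal/mol)
with wall slopes moderate enough that the multi-bin-size profiles of a
converged sample coincide — both properties the published landscapes
display.

`synth_toggle_series()` draws a correlated (χ1, χ2) pair from three
clusters at (-75°, 40°), (-165°, 40°) and (-160°, -100°) — the
inactive, intermediate and active rotamers of the conserved toggle-
switch tryptophan — with per-axis spread 12° (a typical rotamer-well
width) and weights on the 0/2/3 kcal/mol depth ladder of the published
2D landscape.

What the generators deliberately do **not** emulate: time correlation
(frames are i.i.d., so error bars on real, correlated trajectories
would be larger at equal length), the coupling between boost magnitude
and configuration that real dual-boost runs produce (reweighting tests
inject controlled Gaussian or heavy-tailed boost noise instead), and
any coupling between the reaction coordinates and the rest of the
receptor. Passing tests therefore demonstrate estimator correctness
under known ground truth, not the convergence of any particular
molecular simulation.

The bundled structure fixture `m2_motifs_synthetic.pdb` is synthetic
coordinates, not an experimental model: the five key receptor residues
(Arg121, Tyr206, Glu382, Trp400, Tyr440) built from ideal residue
geometry and placed to reproduce the published inter-residue geometry
of the antagonist-bound receptor — Tyr206 OH–Tyr440 OH 12.6 Å, ionic
lock Cζ–Cδ 4.6 Å, toggle-switch χ1/χ2 = -75°/40°. It exercises the
full PDB → selection → distance/dihedral pipeline without any
download.

## Geometry conventions

Dihedrals follow the community sign convention (the one MD analysis
packages and torsion tables share); the test suite pins it against an
independent geometry oracle and against rigid-motion invariance and
mirror antisymmetry. χ1/χ2 for tryptophan are N–CA–CB–CG and
CA–CB–CG–CD1; the CD1-versus-CD2 branch ambiguity of χ2 is resolved to
CD1, the convention of the rotamer literature (choosing CD2 would
shift χ2 by ~180° and relabel the wells). "Charge centers" of the
ionic-lock residues are the conventional single atoms (Arg Cζ, Glu
Cδ), not charge-weighted averages. Coordinates are Å throughout; PDB
residue numbering is used verbatim (generic residue-position labels
are display metadata only). Multi-model files contribute model 1;
altloc A or blank is retained.

## Problem sizes

The validation runs use problem sizes chosen from the statistics they
must support, and they are deliberate package choices: the double-well
sampling and flattening/recovery checks integrate 4×10⁷ steps (saving
every 40th). A Kramers estimate at barrier 4 kcal/mol and
$k_BT = 0.596$ gives ≈ 0.004 barrier crossings per time unit, so this
length yields several hundred crossings and a well-to-well statistical
error near 0.04 kcal/mol — comfortably inside the 0.2 kcal/mol check —
whereas a run ten times shorter would leave the check noise-limited.
Synthetic landscape analyses use 10⁵ (1D) and 2.5×10⁵ (2D) frames, at
which the deepest cells of the shallowest well still hold ~60 frames.

## Known limitations

* Trajectories serialize to lossless TSV plus JSON manifests; no
  binary container format is provided.
* The sweep's `min_count` convention means the diagnostic says nothing
  about bins rarer than the threshold; that is intentional.
* Exponential reweighting of genuinely broad boost distributions is
  noise-dominated no matter the estimator; the package exposes both
  estimators and their disagreement rather than a fix.
* No multi-window combination (WHAM-style), metadynamics, or
  replica-exchange variants; the scope is single-trajectory energetic
  reweighting.
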