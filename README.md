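# amdpmf

Desk-scale toolkit for **accelerated molecular dynamics (aMD)**
enhanced sampling and **potential-of-mean-force (PMF)** analysis,
aimed at people who study conformational free-energy landscapes —
GPCR activation in particular — and want the aMD mathematics, the
reweighting estimators and the PMF precision diagnostics as small,
testable, scriptable pieces rather than buried inside an MD engine.

## What it implements

aMD flattens the energy landscape by adding a non-negative boost
wherever the potential falls below a reference energy *E*:

    V*(r) = V(r) + ΔV(r),   ΔV = (E − V)² / (α + E − V)   for V < E,
    ΔV = 0 otherwise,

with acceleration factor α; forces on the boosted surface are scaled
by dV*/dV = α²/(α + E − V)². The package provides:

* **Boost mathematics** (`boost_potential`, `boosted_energy`,
  `force_scale_factor`, `dual_boost_energy`) and the dual-boost
  parameter recipe for membrane-protein-scale systems
  (`compute_amd_parameters`, λ = 0.3 default).
* **A Langevin toy engine** (`langevin_simulate`, compiled BAOAB
  integrator, optional boost, bit-reproducible seeds) with analytic
  Boltzmann references (`analytic_pmf`) on double-well and 2D
  multi-well surfaces.
* **Reaction-coordinate extraction** from PDB structures and
  trajectory frames (`read_pdb`, `atom_distance`, `dihedral_angle`,
  `trp_chi_selections`, `extract_rc_series`): ionic-lock style
  atom-pair distances and side-chain χ1/χ2 dihedrals.
* **PMF estimation** in 1D and 2D (`pmf_1d`, `pmf_2d`), multi-bin-size
  precision sweeps (`bin_size_sweep`), exponential Boltzmann
  reweighting (`exponential_weights`) and cumulant-expansion
  reweighting (`cumulant_reweight`), plus minima location
  (`pmf_minima`) and profile comparison (`compare_profiles`).
* **Synthetic generators** (`synth_ionic_lock_series`,
  `synth_toggle_series`) emulating the multi-well ionic-lock and
  toggle-switch landscapes, so every analysis stage is testable
  without any trajectory downloads.

The methods vignette (`vignettes/amdpmf-methods.Rmd`) documents the
estimator conventions, the design decisions and their rationale.

## Worked example

Derive dual-boost parameters from short conventional-MD averages, run
a boosted double-well simulation, and recover the unbiased landscape
by reweighting:

```r
library(amdpmf)

compute_amd_parameters(
  energy_averages(v_dihed_avg = 1000, v_total_avg = -150000,
                  n_atoms = 50000),
  lambda_accel = 0.3)
#> Dual-boost aMD parameters (lambda = 0.3 )
#>   dihedral: E = 1300, alpha = 60 kcal/mol
#>   total:    E = -140000, alpha = 10000 kcal/mol

dw   <- make_double_well(barrier_height = 4, well_separation = 1)
traj <- langevin_simulate(dw, sim_config(n_steps = 2e6, save_stride = 20,
                                         rng_seed = 42,
                                         boost = boost_spec(E = 5, alpha = 5)))
rc      <- trajectory_rc(traj)
pmf_raw <- pmf_1d(rc, bin_size = 0.05)
pmf_rw  <- pmf_1d(rc, bin_size = 0.05, weights = exponential_weights(rc))
ref     <- analytic_pmf(dw, thermo_state(300), pmf_raw$edges)

round(c(raw = pmf_evaluate(pmf_raw, 0), reweighted = pmf_evaluate(pmf_rw, 0),
        analytic = pmf_evaluate(ref, 0)), 2)
#>        raw reweighted   analytic
#>       1.66       3.98       3.98
```

The raw boosted-run profile shows the flattened barrier (1.66
kcal/mol); exponential reweighting by e^{ΔV/k_BT} recovers the
analytic 3.98 kcal/mol barrier.

The precision protocol on a synthetic ionic-lock landscape:

```r
ion <- synth_ionic_lock_series(1e5, rng_seed = 1)
sw  <- bin_size_sweep(ion, sizes = seq(0.1, 0.5, by = 0.1))
sw
#> Bin-size sweep over {0.1, 0.2, 0.3, 0.4, 0.5}: max pairwise deviation
#> 0.1676 kcal/mol
m <- pmf_minima(sw$profiles[[3]])
round(as.numeric(m), 2)          # wells at 4.61, 6.45, 14.22 A
round(attr(m, "free_energy"), 2) # depths  0, 0.5, 1.45 kcal/mol
```

A deviation well under 0.2 kcal/mol across the five bin sizes marks
converged sampling; the three recovered wells sit at the closed
(4.6 Å), second contact (6.4 Å) and broad open (14.2 Å, ~1.5 kcal/mol)
basins of the ionic-lock coordinate.

## Command line

A thin script wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "amdpmf", package = "amdpmf"))')" \
  simulate --config sim.json --out-dir out --seed 7
```

Subcommands `simulate`, `rc`, `pmf` and `fixtures` take a
schema-validated JSON configuration; every output carries the
configuration hash, and fixed seeds give byte-identical reruns.

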