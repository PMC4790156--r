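# confcount

Conformer counting free energies from discretized configurational space.

## The problem

Free energy differences between macrostates of a flexible molecule are usually
read off a converged MD trajectory from relative populations,
`ΔF = −kT ln(N_snap^B / N_snap^A)`. That estimator needs the full dynamical
sampling that produced the populations. An alternative is to discretize
configurational space into explicit *conformers* — joint assignments of
torsional states (three 120° arcs per dihedral) over a chosen torsion subset —
and count how many conformers are thermally occupied in each macrostate:

```
ΔF_conf = −kT ln(N_conf^B / N_conf^A)
```

This is exact precisely when the occupied conformers have an **invariant
statistical weight distribution (ISWD)** across configurational space, so that
average conformer weights cancel between macrostates. `confcount` is a toolkit
for testing whether a conformer definition has that property:

* **Discretization** — canonical angle wrapping, torsional-state assignment
  with configurable boundaries, mixed-radix conformer encoding, and occupied
  counts by sort + run-count (`wrap_angle`, `assign_torsional_states`,
  `encode_conformers`, `count_unique`).
* **Macrostates** — fixed-width windows on order-parameter dihedrals (18° by
  default; 43 dihedrals × 20 windows = 860 macrostates), with per-window
  snapshot and conformer counts (`build_macrostates`,
  `count_conformers_per_macrostate`).
* **ISWD diagnostics** — the per-pair deviation `δΔF = ΔF_snap − ΔF_conf` over
  all macrostate pairs, its |·| CPD and area-under-curve summaries, the
  `−ln N_snap` vs `−ln N_conf` scaling fit, and the convergence trend over
  nested trajectory subsets (`pairwise_ddF`, `cpd`, `scaling_data`,
  `convergence_trend`).
* **Entropy** — the exact split `S_conf = k ln N_conf − k·D_KL(P‖uniform)`,
  the grouped decomposition `S_total = S_conf + ⟨S_intra⟩`, the pairwise
  `δΔS` statistic, and an entropy–enthalpy compensation check
  (`conformational_entropy`, `kl_to_uniform`, `pairwise_ddS`, `eec_check`).
* **Exactly solvable synthetic systems** — a double-well potential (the
  canonical counterexample to uniform discretization), factorized and coupled
  multi-torsion Boltzmann lattices with full enumeration, and a generator that
  realizes ISWD exactly at the conformer level (`sample_double_well`,
  `torsion_system`, `sample_torsion_system`, `exact_entropy_report`,
  `sample_iswd_trajectory`). Every estimator has a brute-force oracle; no
  external trajectory data are required anywhere.

It is aimed at people analyzing MD trajectories of flexible molecules (lipids,
ligands, side chains) who want count-based free energies and entropies with an
explicit, testable validity criterion. All energies are in kT, entropies in k,
with β = 1 throughout.

## Worked example

The double well shows why uniform discretization can fail. Two equal-width
wells separated by a 12 kT barrier, with well B sitting ΔU = 2 kT above well A;
a uniform 100-cell grid on the coordinate plays the role of the conformer
definition, and the two wells are the macrostate pair (oriented into the deep
well):

```r
library(confcount)
spec <- double_well_spec(delta_U = 2, well_width = 0.35, barrier_height = 12)
samples <- sample_double_well(spec, 1e6, seed = 1)
dw <- double_well_iswd(samples, n_cells = 100)
cat(sprintf("dF_snap = %.4f kT, dF_conf = %.4f kT, ddF = %.4f kT\n",
            dw$dF_snap, dw$dF_conf, dw$ddF))
#> dF_snap = -2.0037 kT, dF_conf = -0.0000 kT, ddF = -2.0037 kT
```

The population estimator recovers −ΔU, but both wells occupy exactly 35 cells,
so the conformer-count estimator is blind to the energy gap no matter how fine
the grid: `δΔF → −ΔU`, a provable ISWD violation.

On the exact-ISWD generator the trend diagnostic separates a sufficiently fine
definition from a coarse one over nested subsets (AUCs share one abscissa
range; larger AUC = smaller deviations):

```r
s <- sample_iswd_trajectory(2e5, seed = 1)
defs <- list(conformer_definition(1:27, name = "fine"),
             conformer_definition(1:6, name = "coarse"))
convergence_trend(s$trajectory, defs, fractions = c(0.1, 0.5, 1.0),
                  order_params = 1L, window_width = 24)
#> <convergence_trend> AUC over [0, 6.114374]
#>  definition fraction n_snap n_pairs      auc
#>        fine      0.1  20000      78 6.114374
#>      coarse      0.1  20000      78 4.789604
#>        fine      0.5 100000      78 6.114374
#>      coarse      0.5 100000      78 3.945259
#>        fine      1.0 200000      78 6.114374
#>      coarse      1.0 200000      78 3.608507
#> classification: fine: shrinking; coarse: broadening
```

The fine definition keeps one snapshot per conformer (deviations at their
minimum at every size), while the coarse definition's occupied counts saturate
progressively and its deviations grow with trajectory size — the signature of
conformers without ISWD.

Entropy–enthalpy compensation is an identity of the decomposition, checked here
on a system engineered so two macrostates have equal Boltzmann weight but
different internal ruggedness:

```r
site1 <- rep(3, 40); site1[1:2] <- 0; site1[21:22] <- c(-log(1.5), log(2))
set.seed(11); sys <- torsion_system(rbind(site1, runif(40, -1, 1)))
eec_check(sys, macrostate_selector(1, -180, -162),
          macrostate_selector(1, 0, 18), conformer_definition(2L, name = "t2"))
#> <eec_report> (kT / k units, T = 1)
#>   dU -0.13081 | d<S_intra> -0.13081 | dS_conf +0.00000 | dS_Boltz +0.00000
#>   dF_exact -0.00000 | dF_conf -0.00000 | EEC residual -1.110e-16 | closure +1.110e-16
```

The enthalpy change is exactly cancelled by the intra-conformer entropy change:
ΔF depends only on conformer counts.

## Command line

A thin wrapper over the same functions ships at `inst/cli/confcount` with
subcommands `simulate | discretize | ddf | dds | scaling | report`, reading and
writing TSV tables with provenance headers (seed, invocation hash). Example:

```sh
Rscript inst/cli/confcount simulate --system popc --n 10000 --seed 1 --out traj.tsv
Rscript inst/cli/confcount report --input traj.tsv \
    --defs "fine:1,2,3,4,5,6,7,8,9,10,11,12;coarse:1,2" \
    --fractions 0.1,0.5,1.0 --order-params 1 --out report.tsv
```

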