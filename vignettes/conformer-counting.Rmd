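---
title: "Conformer counting free energies: model, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer counting free energies: model, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcount)
```

## The model

For two macrostates $A$ and $B$ visited by a converged, Boltzmann-distributed
set of snapshots, the population estimator of their free energy difference is

$$\Delta F_{snap} = -k_B T \,\ln\frac{N_{snap}^B}{N_{snap}^A},$$

where $N_{snap}^X$ is the number of snapshots observed in $X$. Each snapshot
can be viewed as a representative of an implicit microscopic volume of
configurational space — a *conformer* — and in a converged sample all of these
implicit conformers carry the same statistical weight. This motivates replacing
implicit conformers with *explicit* ones: discretize every selected torsion
into three 120° arcs (*torsional states*) and call each joint assignment of
states over a chosen torsion subset a conformer. If the thermally accessible
explicit conformers also have an (approximately) invariant statistical weight
distribution — ISWD — then the average conformer weights cancel between
macrostates and

$$\Delta F_{conf} = -k_B T \,\ln\frac{N_{conf}^B}{N_{conf}^A},$$

with $N_{conf}^X$ the number of *occupied* conformers in $X$. The per-pair
deviation

$$\delta\Delta F = \Delta F_{snap} - \Delta F_{conf}$$

is the operational ISWD diagnostic: computed over all unordered pairs of
observed macrostates, its distribution concentrates at zero exactly insofar as
the conformer definition realizes ISWD. Everything in this package is expressed
in $k_B T$ (free energies, energies) and $k_B$ (entropies) with $\beta = 1$, so
temperature never appears as a free parameter.

Macrostates are windows on order-parameter dihedrals: each selected dihedral is
partitioned into fixed-width windows (18° by default, hence 20 windows per
dihedral), every snapshot falls in exactly one window per order parameter, and
windows of different order parameters may overlap. With 43 order parameters
this gives 860 macrostates and $\binom{860}{2} = 369{,}370$ pairs, which
`build_macrostates()` and `pairwise_ddF()` reproduce in seconds.

## Entropy decomposition and compensation

Take occupied conformers as basic states. With $P_i$ the weight of conformer
$i$ within a macrostate, the conformational entropy
$S_{conf} = -k \sum_i P_i \ln P_i$ splits exactly as

$$S_{conf} = k \ln N_{conf} - k\, D_{KL}(P \,\|\, U),$$

a Boltzmann (ideal-gas) term from the occupied count minus the Kullback–Leibler
divergence of the actual weights from uniformity (`conformational_entropy()`,
`kl_to_uniform()`; the identity is tested to $10^{-12}$ relative). Dividing
further inside each conformer gives the grouped decomposition
$S_{total} = S_{conf} + \langle S_{intra}\rangle$, verified on enumerable
systems against the direct microstate Shannon entropy to $10^{-10}$ relative
(`exact_entropy_report()`).

The pairwise entropy deviation $\delta\Delta S = \Delta S_{conf} -
\Delta S_{Boltz} = -k\,\Delta D_{KL}$ mirrors $\delta\Delta F$: under ISWD the
KL deviations cancel between macrostates. Note that
$\Delta F_{conf} = -T\,\Delta S_{Boltz}$ is an identity (both are the same log
count ratio), whereas $\delta\Delta F = -T\,\delta\Delta S$ is *not* an
identity for arbitrary empirical counts: it holds exactly precisely when
$\sum_i c_i \ln c_i / N_{snap}$ (over conformer occupancies $c_i$) is equal in
the two macrostates — trivially in the one-snapshot-per-conformer limit, and
nontrivially on matched-count constructions such as occupancies $\{2,2\}$ vs
$\{4,1,1,1,1\}$, where both sides equal $\ln(5/4) \approx 0.2231$. The test
suite asserts exactly these cases rather than pretending to a general identity.

In the canonical ensemble $\Delta F = \Delta U - T\,\Delta S_{total}$ holds
exactly on enumerable systems (`eec_check()` verifies it to $10^{-10}$
relative). Substituting the decomposition,

$$\Delta F - \Delta F_{conf} =
  \Delta U - T\,\Delta\langle S_{intra}\rangle - T(\Delta S_{conf} -
  \Delta S_{Boltz}),$$

so whenever conformer counting is exact the enthalpy change is compensated by
the average intra-conformer entropy change (plus the KL term): entropy–enthalpy
compensation is the local, in-conformer face of ISWD. `eec_check()` reports
this residual. A nontrivial exact case ships in the tests: two equal-weight
windows of a torsion profile, one flat and one alternating between
$-\ln 1.5$ and $+\ln 2$ (so the window's Boltzmann mass is unchanged), give
$\Delta U = -0.1308\,kT \ne 0$ with a residual at machine precision.

## Synthetic systems and what they do (not) emulate

**Double well** (`double_well_spec()`, `sample_double_well()`): a 1-D
piecewise-constant potential with equal-width wells separated by a high
barrier; sampling is exact inverse-CDF. It is the minimal counterexample to
naive discretization: any uniform cell grid occupies equally many cells in both
wells, so $\Delta F_{conf} = 0$ identically while $\Delta F_{snap} \to
\Delta U$ — the deviation converges to $-\Delta U$ for the pair oriented into
the deep well (`double_well_iswd()`), recovered within $0.05\,kT$ at $10^6$
samples in the tests. Quadrature over $e^{-U(x)}$ provides the independent
oracle.

**Torsion lattice** (`torsion_system()`, `popc_like_system()`): $D$ torsions on
a `grid_size` microstate grid with per-torsion site energies and optional
nearest-neighbour coupling. Without coupling the joint distribution factorizes,
so exact marginals and macrostate weights are available at any $D$; with
coupling, full enumeration (capped at $10^7$ microstates) provides exact
weights, entropies and mean energies. The lipid-like default (12 torsions,
three Gaussian rotameric basins at $-60/60/180°$ with seeded random depths in
$[1, 4]\,kT$, width 25°) mimics the basin structure that motivates 3-state
discretization. Samplers: exact factorized draws, or single-site Metropolis
(burn-in $10 \cdot D \cdot \mathrm{grid\_size}$ sweeps, thinning $D$ sweeps,
recorded in provenance; defaults chosen for reproducibility, not tuning).

**Exact-ISWD generator** (`sample_iswd_trajectory()`): a conformer-level model
in which ISWD holds by construction — every accessible conformer has the same
weight and window $k$ of the order parameter owns
$M_k = \lceil m_1 e^{-\lambda(k-1)} \rceil$ of them, so macrostate weights span
$\lambda \,(n_{windows}-1)\,kT$ (11.2 kT at the defaults). A factorized lattice
cannot play this role: its occupied conformer counts do not scale with
macrostate weight, which is the defining ISWD property. The defaults keep the
accessible space ($m_1 = 2\times10^{12}$ over $3^{26}$ cells) orders of
magnitude above any desk-scale trajectory, so the full-resolution definition
remains in the one-snapshot-per-conformer regime at every subset size —
mirroring the regime of real lipid analyses, where $3^{43}$ cells dwarf
$3.4\times10^{7}$ snapshots.

What passing tests on these systems show: the estimators, identities and
diagnostics are implemented correctly, with exact oracles. What they do not
show: that any particular real molecule admits a 3-state conformer definition
with ISWD — real torsions are correlated, basins are not aligned with fixed
arcs, and potential energy varies within conformers. The synthetic generators
deliberately isolate each mechanism (weight ladders, saturation, ruggedness)
rather than reproducing all of them at once.

## The convergence-trend diagnostic

`convergence_trend()` implements the qualitative test: over nested time-ordered
prefixes of a trajectory (e.g. fractions 0.1/0.5/1.0), compute the CPD of
$|\delta\Delta F|$ and its area under the curve (AUC) on one shared abscissa
range — larger AUC means smaller deviations. For an (approximately) ISWD
definition the deviations shrink as data accumulate ("shrinking": AUC
non-decreasing); for conformers with widely varying weights the deviations grow
toward their converged values ("broadening": AUC decreasing). Two design
choices matter here:

* **Common macrostates.** The pair ensemble is restricted to macrostates
  already observed in the smallest subset. Macrostates that only appear in
  larger subsets would change the composition of the ensemble between sizes
  (late-appearing rare windows contribute many small rare–rare deviations),
  confounding the trend's direction; with the restriction, the same quantity
  is tracked at every size. This matches the setting where all windows are
  occupied in every trajectory set.
* **What "coarse" means.** The broadening signature is driven by progressive
  saturation: as snapshots accumulate, occupied-count ratios compress toward 1
  while population ratios do not move. A definition whose counts are already
  saturated at the smallest size (e.g. a single torsion, one conformer per
  window) shows only noise; the package's acceptance checks therefore use a
  6-torsion coarse definition ($3^5$ cells per window) against the
  27-torsion fine one on the exact-ISWD generator, which broadens and shrinks
  respectively, robustly across seeds.

## Numerical and convention choices

* **Angles** live on $(-180°, 180°]$ with $-180°$ mapped to $+180°$; state
  boundaries are cuts canonicalized to $[-180°, 180°)$ because each cut is the
  *included* left edge of its half-open arc — deterministic, order-free
  tie-breaking for angles exactly on a boundary. Default cuts
  $\{-180°, -60°, 60°\}$ (the gauche−/anti-adjacent trisection) and the
  $+60°$-shifted alternative are both configurable; no adaptive or
  energy-weighted placement is attempted (equal arcs are the point of the
  method when nothing better is known a priori).
* **Windows** are anchored at $-180°$; widths must divide 360°. Empty windows
  are retained but flagged unobserved and excluded from pairwise analyses
  (the free energy of an unvisited macrostate is undefined).
* **Conformer ids** are mixed-radix base-3 integers (least-significant-first)
  for subsets up to 33 torsions — the largest size at which $3^k$ is exactly
  representable in a double — and packed state strings beyond that; both sort
  and compare exactly, and counting occupied conformers is sort + run-count,
  never an allocation over the $3^k$ id space.
* **Pair orientation** is fixed (lower macrostate index = start state) so all
  signed quantities are reproducible; every pairwise statistic is antisymmetric
  under swapping, which the tests exercise.
* **CPD/AUC**: the empirical CDF of $|\delta\Delta F|$ is integrated exactly as
  a step function over a caller-fixed range shared by all compared conditions;
  AUCs from different ranges are not comparable. Classification tolerance for
  the trend is $10^{-6}$ of the range, so AUC changes far below the curve scale
  count as ties.
* **Entropies** are computed over occupied conformers only; zero weights
  contribute nothing ($p\ln p \to 0$), and weight vectors must be normalized to
  $10^{-9}$. $\langle S_{intra}\rangle$ is only defined where microstates can
  be enumerated (synthetic systems); trajectory reports mark it unavailable
  rather than estimating it.
* **Determinism**: every sampler takes an explicit integer seed and restores
  the caller's RNG state; identical `(spec, n, seed)` give identical samples,
  and the command-line `simulate` writes byte-identical tables on repeat runs.

## Problem sizes

The test suite and the acceptance script run the double well at $10^6$
samples, the oracle-equivalence comparison at $10^5$ samples on a
$3 \times 60$-bin factorized lattice, enumeration checks on $12^3$ coupled
microstates, and the convergence trend at $10^6$ snapshots with 15 windows of
24° (a width that divides the 120° arcs, so windows never straddle a state
boundary and the ISWD construction stays exact). These sizes put every
stochastic check comfortably past its asymptotic regime while keeping the
whole suite under a minute of compute for the deterministic parts and a few
tens of seconds for the sampled parts.

## Limitations

* The package evaluates conformer definitions against trajectories or exact
  synthetic systems; it does not search for good definitions, and it does not
  implement stochastic conformer counting (sequential Monte Carlo with
  importance sampling) for end-point free energy estimation.
* Macrostates are dihedral windows only — no kinetic or clustering-based
  lumping.
* The MD-format adapter reads PDB/DCD via bio3d when available and computes
  dihedrals from atom quadruples; the core consumes plain dihedral tables, so
  the adapter is optional by design.
* Absolute entropies of real molecules are out of reach on principle (the
  classical density of states is defined up to a factor); all reported
  quantities are differences.
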