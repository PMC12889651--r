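---
title: "Pose-stability ranking with the c(t) reversible-work estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-stability ranking with the c(t) reversible-work estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmd)
```

## The idea

Docking scores are good at carving a large library into plausible and
implausible binders but poor at ranking the plausible ones among
themselves, while converged free-energy calculations are accurate but far
too expensive for triage. Pose-stability metadynamics sits between the
two: bias a ligand's RMSD from its docked pose with well-tempered
metadynamics and ask how hard the pose resists displacement. The scalar
this package builds everything around is the reversible-work estimator

$$
c(t) \;=\; \frac{1}{\beta}\,\log
\frac{\int ds\; e^{\frac{\gamma}{\gamma-1}\,\beta V(s,t)}}
     {\int ds\; e^{\frac{1}{\gamma-1}\,\beta V(s,t)}},
$$

where $s$ is the biased collective variable, $V(s,t)$ the accumulated
bias, and $\gamma$ the well-tempered bias factor. Writing the ratio as a
weighted average of $e^{\beta V}$ shows that $\min_s V \le c(t) \le
\max_s V$: $c(t)$ is a smooth, integral measure of how much tempered bias
the trajectory has had to pile up. A ligand that stays pinned near its
pose forces the bias to grow deep in one place and $c(t)$ rises steeply; a
ligand that slides away lets the hills spread thinly and $c(t)$ stays low.
The stability score of a pose is the **minimum over a few short,
independent replicas of the terminal $c(t)$** — the most pessimistic
replica decides, which is what makes the score conservative. No fitting,
no convergence requirement: the score is read off the HILLS log that any
metadynamics engine already writes.

Crucially, the runs must be *short*. The score discriminates while stable
poses are still resisting the bias; once every well has been filled and
escaped, continued deposition raises the bias everywhere roughly
uniformly, and the constant-shift covariance of $c(t)$ (a uniform offset
$\Delta$ in $V$ shifts $c(t)$ by exactly $\Delta$) means the depth signal
is progressively buried under a common, uninformative offset. We return
to this when choosing the toy run length.

## The toy model

Production use of this protocol runs on protein–ligand systems in an MD
engine; this package instead ships a desk-scale analog so the whole
pipeline is exercisable and testable end to end. The analog keeps exactly
the features the estimator sees:

* the CV is a 1D displacement-like coordinate, non-negative like an RMSD,
  propagated by overdamped Euler–Maruyama Langevin dynamics with a
  reflecting boundary at $s = 0$ (no inertia — only CV statistics matter
  at this scale);
* the pose is a Gaussian well at $s = 0$ whose **depth is the single
  latent parameter standing in for pose stability**, with a half-harmonic
  wall bounding the accessible range the way an RMSD restraint does;
* hills are deposited every `pace` steps at the current CV value with the
  standard well-tempered height rule
  $w = w_0 e^{-V/((\gamma-1)kT)}$, and logged in the single-CV PLUMED
  HILLS dialect (kJ/mol in files, kT internally, converted with the
  temperature in `thermo_params()`).

What the toy model does *not* emulate: real ligand chemistry, solvent and
membrane environments, multi-dimensional escape pathways, rotational
alignment subtleties of a real RMSD, and force-field errors. Passing
tests therefore demonstrate that the estimator, the scoring rule and the
enrichment statistics behave as specified — not that the protocol will
enrich any particular real target.

On the RMSD itself: `rmsd()` is the plain displacement root-mean-square
with no rotational/translational superposition. The pose-metadynamics
lineage defines the CV in the receptor frame, where the docked reference
already fixes the orientation; since the alignment protocol is not part
of this package's contract, the simplest reading is implemented and
documented.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| $\gamma$ (bias factor) | 10 | — | conventional well-tempered choice; tempering strong enough to converge, weak enough to push |
| $w_0$ (hill height) | 1.2 | kJ/mol | conventional production value (≈ 0.48 kT at 300 K) |
| $\sigma$ (hill width) | 0.02 | CV units | matches the fine hill widths used on RMSD-like CVs |
| pace | 500 | steps | one hill every 0.5 toy time units |
| $dt$ | 0.001 | toy time | stable for the steepest default well ($k_{\mathrm{eff}}\,dt \ll 2$) |
| friction | 1 | 1/time | sets the diffusion constant $kT/\xi = 1$ |
| `n_steps` | 5e4 | steps | 100 hills/replica; see below |
| replicas | 3 | — | a few short independent runs; the minimum decides |
| well width | 0.1 | CV units | excursions in the bound state ≈ 0.03–0.05, several hill widths |
| wall position / stiffness | 1.0 / 100 | CV / kT·CV⁻² | bounds the escaped state like an RMSD restraint |

**Run length.** The run-length default was set by a pilot scan of
terminal $c(t)$ against well depth (0–11 kT, the generator's range). The
terminal value is monotone in depth at every length, but with 1000
hills/replica the tempered bias saturates the whole accessible range and
all depths converge to within a kT of each other — the common-offset
regime described above. Contrast is strongest around 100 hills, while
deep wells are still actively resisting; 5e4 steps (100 hills at pace
500) is therefore the default. This mirrors the protocol's own design
premise: it ranks stability precisely because the runs are short and
non-converged.

**Synthetic screens.** `gen_library()` draws binder depths from a
truncated-at-zero normal with mean 8 kT and non-binders from mean 2 kT
(sd 1), a separation large enough to be recovered but noisy enough that
replicas disagree; the default 5 binders vs 27 non-binders matches a
realistic ~16% triage hit rate. Replica seeds are `seed_base + replica`,
with `seed_base` derived deterministically from the library seed, so a
screen is bit-reproducible end to end.

## Numerical choices

* **Quadrature.** $c(t)$ uses the trapezoid rule on a uniform grid over
  $[0,\ \mathrm{wall} + 3\sigma_{\max}]$ with 1000 points — the biased
  CV's accessible range; the integration domain is configurable because
  nothing in the estimator fixes it. Both integrals are computed in log
  space (per-integrand maximum subtracted before exponentiating), so the
  estimator is finite for $\beta V$ of several hundred per node. Doubling
  the node count moves $c(t)$ by less than 1e-4 kT on all test fixtures.
* **Edge truncation.** Hills are plain Gaussians; no reflected images are
  added at $s = 0$. Bias mass that a hill near the boundary carries below
  $s = 0$ is deliberately outside the quadrature domain; `ct_value()`
  warns when any hill center is within $3\sigma$ of a grid edge
  (suppressible where, as in the screen pipeline, the pile-up against the
  reflecting boundary is expected).
* **Monotonicity.** $V(s,t)$ is pointwise non-decreasing in $t$ and this
  is asserted; $c(t)$ itself is *not* asserted monotone — pointwise bias
  growth does not force it for arbitrary hill placements, though
  simulator-generated series are observed to rise steadily.
* **Engine.** The per-step Langevin/deposition loop is compiled (Rcpp).
  The engine keeps the running bias and its derivative tabulated on a
  fine grid (5 nodes per $\sigma$, linear interpolation) and adds each
  new hill over a $\pm 6\sigma$ window (relative truncation error
  $< 2\times10^{-8}$); the HILLS-based estimators (`bias_value()`,
  `ct_value()`) always use exact Gaussian sums. Noise comes from an
  internal mt19937-64/Box–Muller stream seeded from `dyn_params$seed`, so
  trajectories are bit-reproducible across platforms and independent of
  R's RNG state.
* **Ties and determinism.** All rankings order by score descending, then
  ligand id, then (inside subsample replicates) replicate index, so every
  enrichment number is reproducible. The EF selection contains
  $\lceil xx\% \cdot N\rceil$ ligands while the denominator keeps the
  exact fractional $xx\% \cdot N$, which makes $EF_{100} = 1$ an exact
  identity rather than an approximation.
* **Terminal evaluation.** The per-replica readout is $c(t)$ at the final
  deposition time (not a minimum over time within a run, which would be
  degenerate since $c(0)=0$ for every run, and not a terminal-window
  average, which the protocol does not define). An empty replica scores
  0, the estimator's floor.

## Enrichment statistics

`ef_at()` implements the enrichment factor normalised by the library hit
rate; `bedroc()` implements the Truchon–Bailly Boltzmann-enhanced
discrimination of ROC, whose $\alpha$ sets how sharply early ranks are
weighted ($\alpha = 20$ concentrates on roughly the top 8%). Benchmark
libraries with generous hit rates are brought to realistic triage
conditions by `subsample_enrichment()`: repeatedly draw $k$ binders with
replacement (duplicates kept as independent rows — with-replacement
sampling implies them), keep all non-binders, and summarise EF/BEDROC
across repeats with percentile 2.5/97.5 intervals. pKi-labelled datasets
are classified with a deliberately stringent rule — non-binder below pKi
5, binder above 6, the ambiguous band excluded.

## Problem sizes in the shipped checks

The test-suite and acceptance computations run complete screens at the
default conditions: 5 + 27 ligands × 3 replicas × 5e4 steps, five seeds
for the separated and null screens, plus one 50-ligand library for the
depth–score association; all together they complete in well under a
minute on one core. These sizes were chosen as the smallest at which the
screen-level statistics are meaningful.

## Known limitations

* The null-calibration band for a 5-seed mean EF30 on a 5/27 screen is
  narrow relative to the estimator's own sampling error (per-seed EF30 is
  hypergeometric with sd ≈ 0.65 under the null): individual 5-seed runs
  scatter around the expected 1.04 by ±0.3. Calibration over many seeds
  is demonstrably clean (mean 1.08 ± 0.07 over 100 seeds).
* The toy landscape has a single escape channel; real poses can fail
  sideways into alternate poses, which the 1D model cannot represent.
* `read_hills()` parses the single-CV HILLS dialect only; multi-CV or
  grid-stored bias files are out of scope.
* Scores are comparable across ligands only when runs share thermostat,
  metadynamics parameters and run length — the package enforces this
  within a screen but cannot across hand-assembled HILLS files.
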