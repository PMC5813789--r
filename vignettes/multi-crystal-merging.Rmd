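---
title: "Multi-crystal dataset management: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-crystal dataset management: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Modern macromolecular data collection often yields many partial rotation
sweeps from many crystals instead of one complete dataset from one crystal.
Assembling a complete dataset out of such sweeps only works if the
contributing crystals are *isomorphous* — same lattice, same packing — and
if systematic errors (scale and overall B-factor differences between
sweeps, radiation damage late in each sweep) are modelled or excluded.
`mxmerge` implements the whole management loop: screen sweeps for cell
isomorphism, cluster them, scale and merge any candidate combination, score
it with the standard merging statistics, and refine it by discarding whole
datasets or sweep tails.

# Cell isomorphism: the aLCV metric

Hierarchical clustering needs a distance, but cluster-tree heights are
dimensionless and hard to interpret physically.  The absolute linear cell
variation (aLCV) provides the physical number: for two unit cells, compare
the corresponding diagonals of the three principal faces.  Each diagonal
depends simultaneously on its two spanning edges *and* the angle between
them, so the three differences `delta_a`, `delta_b`, `delta_c` (in Å)
absorb length and angle variation at once, and

```
aLCV = max(delta_a, delta_b, delta_c)
```

For a group of cells, the aLCV is the maximum over all pairs
(`group_alcv()`), so it reads as "the worst linear cell disagreement, in Å,
anywhere in this group".

Two geometric conventions exist, because every parallelogram face has two
diagonals (`|u + v|` and `|u - v|`).  We use `|u + v|` by default and
expose the other through the `convention` argument of `face_diagonals()`
and `pair_alcv()`.  For right angles the two coincide, so all orthorhombic
behaviour is convention-free.  Cells are compared as given — consistently
indexed input is assumed (upstream data processing guarantees this in
practice), and no Niggli or standard-setting reduction is attempted; a
warning is emitted when datasets in one analysis declare different space
groups.

# Symmetry-aware descriptors and clustering

Crystal symmetry fixes some cell parameters, so the clustering descriptors
are the *free* parameters of the crystal system: all six for triclinic,
(a, b, c, β) for monoclinic, (a, b, c) for orthorhombic, (a, c) for
tetragonal, trigonal and hexagonal, and a alone for cubic.  Descriptor
columns are divided by their means by default (`scaling = "mean"`), making
lengths and angles dimensionless and comparably weighted; this is a
documented choice, as is the linkage: Ward linkage on Euclidean distances
(`stats::hclust`, method `ward.D2`), with complete and average linkage as
options.  Ward gives compact, balanced clusters, which matches how
isomorphism groups behave in cell space.

Every internal node of the resulting dendrogram is annotated with the
group aLCV of its member cells, and nodes are numbered 1..N−1 in order of
increasing merge height, ties broken by member count and then by sorted
member ids, so cluster numbers are reproducible across runs and machines.

Outlier triage, usually done by eye on the dendrogram, is automated by an
explicit rule: a dataset is flagged when the smallest cluster containing it
already exceeds an aLCV threshold (in Å).  There is no default threshold;
the caller must choose one, because a sensible value depends on resolution
and cell size (2 Å is a reasonable level for cells of 30–120 Å merged at
3–4 Å).

# Scaling and merging

Observed intensities from sweep *j* are modelled as

```
I_obs = g_j(s) * <I_h>,   g_j(s) = k_j * exp(-2 * B_j * s^2),  s = 1/(2d)
```

with one scale `k_j > 0` and one isotropic decay `B_j` (Å²) per dataset,
and the gauge fixed by the reference dataset at exactly (k, B) = (1, 0).
`fit_scales()` minimises the inverse-variance weighted least-squares
residual by alternating

1. the closed-form update of the merged means `<I_h>` given the scales, and
2. a per-dataset weighted log-linear regression of `log(I/<I>)` on `s²`
   for (k, B), followed by a closed-form refinement of k given B; a
   candidate update is accepted only if it lowers that dataset's share of
   the residual, so the objective is non-increasing by construction.

Iteration stops when the relative residual change drops below `1e-8` or
after 200 iterations.  The per-dataset (k, B) model is a deliberate
simplification of smooth per-image scaling used by full-featured scaling
programs; it is the right level for dataset-selection decisions, which is
what this package automates.

Merging maps observations to the asymmetric unit — canonical representative:
the lexicographically greatest index triple of the orbit under the point
group plus Friedel inversion, a convention chosen purely for determinism —
and combines them by inverse-variance weighted mean (plain mean by flag).
Negative intensities are kept; the R-statistic denominators use the raw
intensity sums, as the printed formulas imply.  Friedel mates are merged;
anomalous bookkeeping is out of scope.

## Merging statistics

Over uniques measured at least twice: `Rmerge`, the multiplicity-corrected
`Rmeas` (factor `sqrt(n/(n-1))`) and the precision estimate `Rpim` (factor
`sqrt(1/(n-1))`), so `Rpim <= Rmerge <= Rmeas` always.  Completeness counts
observed uniques inside the theoretically possible set (enumerated from the
mean cell, the space group's systematic absences, and the resolution
cutoff); multiplicity is observations per unique.  CC1/2 correlates the
means of two half-sets; the halves are assigned deterministically by
alternation after sorting each unique's observations by dataset and batch,
so results are reproducible without a random split (a seed-free, documented
choice).  Mn(I/sd) is the mean merged I over its merged sigma.

Two resolution estimates are reported from the 10-shell (equal reciprocal
volume in 1/d³) table: the d where shell CC1/2 crosses 0.3 and where shell
Mn(I/sd) crosses 2, linearly interpolated between shell midpoints walking
from low to high resolution, and clamped at the applied cutoff.  If the
statistic already fails in the first shell the first midpoint is reported
(no extrapolation beyond the data); if it never fails, the cutoff itself.

Degenerate inputs are handled explicitly: if no unique is measured twice,
the R statistics and CC1/2 are `NA` (undefined), never numbers.

# Filtering and pruning

`filtering_variant()` greedily discards whole datasets: each round
re-scales and re-merges without each remaining dataset in turn and commits
the single removal with the lowest trial Rmeas, provided completeness stays
at or above the threshold.  `pruning_variant()` does the same with the
trailing `chunk` images (default 5; 1 recovers per-image pruning) of each
dataset, visiting datasets cyclically so none is pruned twice before all
have been tried, and never pruning a sweep below `chunk + 1` images.

A trial counts as an improvement only if it lowers Rmeas by more than the
`min_improvement` fraction (default 0.05).  The margin matters: trial Rmeas
values fluctuate at the percent level from sampling alone, because removing
data re-partitions which uniques enter the sums, and those fluctuations are
symmetric around zero.  A plain strict-descent rule would therefore commit
on chance improvements about half the time and slowly strip clean data.
Genuine non-isomorphism or radiation-damage effects are tens of percent in
Rmeas, well clear of the margin; `min_improvement = 0` restores plain
strict descent for callers who want it.  Committed Rmeas decreases at every
step, completeness never falls below the threshold after a commit, and the
audit trail records every trial of every round so any result can be
replayed exactly (`replay_combination()`).

Two related design choices: every round evaluates *all* single
removals/prunes (exhaustive per-round search, not a heuristic subset), and
the two stopping conditions — completeness floor reached, no admissible
improvement left — bind in whichever order occurs first.  The minimum
surviving set in filtering is 2 datasets.  The default completeness floor
for the variants is 95%, consistent with the working rule that completeness
should stay around or above 90% for useful maps; the resolution-cut
workflow (try a cutoff, fall back on Rmeas deterioration) is left to the
user, not automated.

# Pre-clustering by conditions

Cells can agree while crystals differ (growth condition, cryo protocol,
dehydration, heavy atom).  `group_by_conditions()` partitions datasets by
the exact combination of the five metadata codes (BC, CC, DH, CO, HA)
before any cell-based clustering.  Serial numbers follow first appearance
in the input — the ordering is otherwise arbitrary — so programmatic
look-ups should go by key, not by serial.

# The campaign simulator

`simulate_campaign()` generates the statistical structure the method
assumes, with full ground truth:

* isomorphism groups as cell centres offset by `group_offset` (Å, default 2)
  with within-group Gaussian jitter on the free parameters
  (`jitter_length` 0.2 Å, `jitter_angle` 0.1°);
* true intensities drawn from an exponential distribution (acentric Wilson
  statistics) with unit-free mean `mean_intensity` = 100; no centric
  correction — adequate for statistical testing of merging behaviour;
* partial sweeps as per-batch random subsets of the unique list (`coverage`
  per batch); a deterministic `"wedge"` option yields contiguous index
  blocks for reproducing complete-vs-partial triage;
* per-dataset true scales k in [0.5, 2] and B in [0, 10] Å²;
* radiation damage on selected datasets as B growth per image (`beta`,
  Å²/image) plus a fractional drift `delta` per image applied to a seeded
  random half of the reflections — a *systematic*, not purely random,
  late-batch bias, which is what makes tail pruning detectable;
* noise `sigma² = sigma0² + alpha·I` with the sigma reported alongside, and
  a positive floor on reported sigmas so noise-free configurations remain
  representable.

The defaults describe a modest orthorhombic (P2221) protein-complex
campaign merged at 4 Å.  What the simulator does **not** emulate: diffraction
geometry (spot shape, partiality fractions, absorption), anomalous signal,
non-isomorphism of *content* at equal cell, and smooth per-image scale
variation.  Passing tests therefore demonstrate the statistical and
algorithmic correctness of the pipeline, not detector-level realism.

A subtlety worth knowing when designing experiments on synthetic data: with
heterogeneous true (k, B), weaker datasets are genuinely noisier (the noise
model acts on the observed scale), so filtering and pruning can *correctly*
discard their data even without planted damage.  Tests that isolate planted
effects therefore hold quality homogeneous (`scale_range = c(1, 1)`,
`b_range = c(0, 0)`) so that the planted perturbation is the only
systematic difference.

# Numerical and scale choices

* Scaling convergence: relative residual change `1e-8`, 200 iterations;
  deterministic.
* ASU representative and cluster numbering tie-breaks are lexicographic,
  for bit-reproducibility.
* Shells: 10 by default, equal reciprocal volume; per-dataset crude
  resolution triage uses 20 shells and a mean I/sigma floor of 1.5 (the
  estimator is deliberately crude: a per-sweep triage number).
* Supported space groups: P1, P21, C2, P222, P2221, P212121, P4, P43212 —
  hard-coded operator tables covering the common macromolecular groups;
  extending the registry is one table entry, and group closure is verified
  by the test suite.
* Test and demo problem sizes are chosen for the laptop scale: cells around
  30–40 Å, 6–8 Å data for structural checks and 2.5 Å complete sweeps for
  the scale-recovery study, which keeps the whole suite around a minute
  while leaving every statistical property measurable.

# Known limitations

* The per-dataset (k, B) scaling model cannot absorb within-sweep scale
  variation; the pruning variant compensates only for monotone late-sweep
  damage.
* No reindexing/cell reduction: datasets must be consistently indexed.
* Completeness denominators assume the mean cell of the merged datasets;
  for strongly non-isomorphous inputs (which the workflow is designed to
  reject) this denominator is itself fuzzy.
* The outlier rule flags leaves by their first merge only; pathological
  topologies (two tight but mutually distant groups) need the dendrogram,
  not just the flag list — which is why analysis mode always writes the
  rendered tree.
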