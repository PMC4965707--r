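---
title: "Assembling optical restriction maps with omsweep: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling optical restriction maps with omsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omsweep)
```

This vignette is the package's own account of the science it implements:
the error model behind Rmap simulation and alignment, the assembly and
sweep algorithms, the parameters that matter and why their defaults are
what they are, and what the simulation-based tests do and do not
demonstrate about real instrument data.

## The data and its noise

A nanochannel optical-mapping experiment reports each DNA molecule as an
*Rmap*: a measured length and an ordered vector of fluorescent label
positions, nominally the recognition sites of one or two nicking
endonucleases. Three noise processes separate the observation from the
underlying genomic restriction pattern:

* **False-positive labels** (`fp_per_100kbp`): labels at non-site
  positions, from spurious nicks and imaging artifacts. Modeled as a
  homogeneous Poisson process along the molecule, in labels per 100 kbp.
* **False-negative labels** (`fn_rate`): true sites left unlabeled by
  enzyme inefficiency. Modeled as independent site dropout with
  probability `fn_rate`.
* **Sizing error** (`sizing_sd_bp_per_kbp`): the measured distance between
  adjacent labels differs from truth by an error whose standard deviation
  grows with the interval — an interval of `g` kbp receives zero-mean
  Gaussian noise with sd `g * sizing_sd_bp_per_kbp`. A global
  `stretch_factor` covers uniform over/under-stretching.

Both the simulator (`error_profile()`) and the aligner (`align_params()`)
speak exactly this vocabulary. That symmetry is the point of a
trial-and-error sweep: the aligner's parameters are *assumptions* about the
data, and the sweep asks which assumptions produce the best assembly.

## The simulator

`simulate_molecules()` draws molecules from uniformly random intervals of a
reference map, in random orientation, until the requested fold coverage is
reached. Molecule lengths follow a truncated exponential
(`length_model()`): a hard minimum (the instrument reporting threshold)
plus an exponential tail. The defaults — 100 kbp minimum, 163 kbp mean —
give a length-weighted N50 near 165 kbp, the figure typical of
high-molecular-weight plant DNA runs; the true instrument length
distribution is not published, so the model claims only the long-tail
shape. Sizing noise is applied per inter-label gap and clamped (a gap never
shrinks below 10 % of its true size) so label order is preserved without
rejection sampling. Two enzymes are handled upstream: `digest_sequence()`
merges motif hits from both strands and both motifs into one label channel,
as simultaneous dual nicking produces a single label population. Chimeric
molecules (two unrelated intervals imaged as one) exist on real instruments
but default to `chimera_rate = 0`; they can be enabled for robustness
studies.

The simulator emits a *truth sidecar* — per-molecule origin interval and
orientation, per-label provenance (reference site index or FP flag) —
which downstream tests use as an oracle that needs no alignment.

Defaults for the simulated study conditions are `fp_per_100kbp = 1`,
`fn_rate = 0.10`, `sizing_sd_bp_per_kbp = 30` (≈3 % interval CV), within
the platform vendor's recommended operating envelope (FP below 1.5 per
100 kbp, FN below 0.15) and consistent with nanochannel sizing precision.

## Pairwise alignment and its score

`align_pair()` performs ends-free (overlap) dynamic programming over the
two label sequences, in both orientations of the second map (reverse =
reflect its labels through its length; only `b` is ever reversed). The
score is a log-likelihood ratio of the error model against chance. A
matched interval pair with gaps `g_a, g_b`, skipping `k_a, k_b` labels
since the previous match, contributes

```
R  −  (g_a − g_b)² / (2σ²)  −  (k_a + k_b) · P
```

* `σ² = (s/1000)² (g_a² + g_b²)`: both maps carry interval-proportional
  sizing noise, so the discrepancy variance is the **sum** of the two
  variances. (Aligning against a noiseless reference this slightly
  overstates σ; the cost is a marginally flatter penalty, not a bias.)
* `P = −log p_err`, where `p_err` is the probability a given label is
  erroneous — a false positive (FP density relative to the assumed true
  site density, `site_density_per_100kbp`, default 10) or an unlabeled
  partner site (`fn_rate`).
* `R = −log p_chance`, the log-odds against two labels co-locating within
  sizing error by chance, computed at the typical site spacing.

The DP bounds skipped labels per side between consecutive matches
(`max_skip`, default 3) — an explicit accuracy/speed knob. Two quantities
are tracked per cell: the best chain of any length (extension may prefer a
fresh single match over continuing a bad chain) and the best chain of at
least two pairs, which is what may be reported; an alignment needs ≥ 2
matched pairs to exist. Ties break deterministically: more matched pairs,
then smaller absolute offset, then forward orientation — determinism is
load-bearing for the sweep-equivalence guarantees.

### Significance

`alignment_pvalue()` shuffles the inter-label gaps of `b`, realigns each
shuffle, and reports the smoothed empirical tail probability
`(1 + #{null ≥ obs}) / (reps + 1)`. Assembly-scale significance thresholds
(10⁻⁴ … 10⁻¹²) lie far below the resolution of any affordable permutation
count, so when the observed score exceeds every null score the default
method extrapolates with a Gumbel upper tail moment-fitted to the null
scores — the classical extreme-value form for maxima of many dependent
comparisons. Tail extrapolation is honest only when the null has real
spread: pairs with few labels produce concentrated, quasi-discrete null
distributions for which a fitted tail can understate the true tail by
orders of magnitude. The assembly pipeline therefore imposes a minimum
candidate-edge score (`null_score_min = 8` in `sweep_options()`, roughly
four cleanly matched intervals) before any permutation test is run; below
it a pair is treated as non-significant. This is simultaneously an evidence
floor and the main speed lever of all-pairs alignment, and truth-sidecar
experiments at 20× / 1 Mbp and 50× / 2 Mbp show it removing all
chance-edge false joins. `align_params()` itself defaults the floor to 0 so
that interactive pairwise use always yields a p-value.

Confidence is `−log₁₀ p` (`confidence()` / `pvalue_from_confidence()`).

## Assembly: sort, split, all pairs, overlap-layout-consensus

The unrefined assembly pipeline has four steps.

1. **Sort** (`sort_molecules()`): stable descending length, ties by id.
2. **Split** (`split_molecules()`): round-robin over the sorted order into
   `n_chunks` chunks, keeping totals within one molecule of each other.
   Chunking exists for operational parallelism; the retained overlap set is
   provably chunking-invariant because each pair is aligned exactly once
   with a permutation stream seeded from `(seed, id_a, id_b)`.
3. **All pairs** (`all_pairs_overlaps()`): every unordered pair, both
   orientations; alignments passing the significance threshold are
   retained.
4. **Layout + consensus** (`assemble_olc()`): greedy best-edge-first (by
   p-value) union-find merging, each component carrying affine coordinate
   transforms (`pos → s·pos + t`, `s ∈ {±1}`); an edge whose implied
   placement contradicts an existing one by more than
   `placement_tolerance_bp` (default 2000) or by orientation is rejected.
   Consensus labels are single-linkage clusters of member labels within
   `merge_radius_bp` (default 1500): position = cluster mean, occurrence =
   contributing molecules, coverage = spanning molecules. Contig frames are
   anchored to the longest member (kept forward) and contig ids are
   assigned in descending length. Molecules with no accepted edge are
   singletons; the singleton denominator is the *post-filter* molecule
   count (the pre-filter convention is equally defensible, but post-filter
   measures what the assembler was actually given).

The two layout tolerances are not swept and have no published reference
values; 2000 bp tolerates the offset drift that accumulates across a
molecule of sizing noise, and 1500 bp merges labels that the ~1 kbp optical
resolution cannot separate while staying below the typical ~9 kbp site
spacing.

## The sweep: step keys and reuse

Five parameters are swept: overlap significance threshold, FP density, FN
proportion, minimum molecule length, minimum labels per molecule. The core
observation is that each pipeline step *computes* with only a subset of
them; the rest merely filter its output, so a run at the most lenient
filter values dominates every stringent descendant:

| step      | computation depends on | filter-only            |
|-----------|------------------------|------------------------|
| sort      | —                      | min length, min labels |
| split     | —                      | min length, min labels |
| pairwise  | FP, FN                 | min length, min labels, threshold |
| assembly  | all five               | —                      |

`project_step_key()` projects a combination onto a step: computation
parameters pass through, filter-only parameters are replaced by the grid's
lenient dominators (largest threshold, smallest minimums). `plan_sweep()`
deduplicates the projections into a DAG — for a `5×3×3×3×3` grid, 405
assemblies need only one sort, one split and nine pairwise steps.
`run_sweep()` executes each node once, caching results keyed by a content
hash of the step key, the input molecules, the shared options, and the
package version — so a cache can never be silently reused across datasets
or code versions, and a tampered entry is detected and recomputed with a
warning. Each assembly node re-filters molecules and alignments down to its
own stringent values before layout.

The correctness contract — memoized output field-identical to naive
per-combination execution — holds because pair scores depend only on the
two molecules involved, and per-pair seeding makes p-values independent of
evaluation order. The test suite asserts this equality assembly-by-assembly
and also that warming the cache reduces executed steps to zero.

## Quality metrics

* **Contiguity**: total length, N50 (length at which the descending
  cumulative sum first reaches half the total — the dominant convention;
  ties and alternatives exist, hence it is documented), longest contig.
* **Internal consistency**: mean label depth (mean per-label occurrence)
  and the non-singleton proportion.
* **Accuracy**: each contig aligned to the reference; confidence
  `= −log₁₀ p`; the aggregate is the *contig-length-weighted* mean over
  contigs that align. The weighting basis is a genuine open choice
  (alignment length and molecule support are alternatives); contig length
  is used because it weights the map by the fraction of assembled sequence
  it vouches for. Unaligned contigs are excluded from the mean and counted
  separately rather than contributing zero, which would conflate "wrong"
  with "short".

Contig-vs-reference alignment uses its own error model
(`consensus_align_params()`: sizing 60 bp/kbp, spurious-label density
5/100 kbp, FN 0.15, `max_skip` 5). Consensus label positions are cluster
means over molecules placed by noisy pairwise offsets, so adjacent labels
carry several hundred base pairs of quasi-independent drift, and unmerged
false-positive clusters appear at well above the raw-molecule FP rate;
molecule-level parameters demonstrably under-match long chains on
truth-verified near-perfect contigs.

`dataset_stats()` aggregates per-flow-cell run statistics
(quantity-weighted means of molecule N50 and label density, total Gbp,
implied fold coverage rounded to an integer); the package ships the
nineteen-run *Gossypium raimondii* collection table as a fixture.

## Numerical and degenerate-input choices

* Positions are continuous bp written at 0.1 bp precision; round trips are
  stable to that precision. Labels exactly at a molecule end are legal
  (`(0, length]`).
* An empty assembly yields zero contiguity metrics and depth 0 by
  convention, not NA, so sweep tables stay numeric.
* Score ties in the DP break toward more matched pairs, then smaller
  |offset|, then forward orientation; equal-score floating-point
  comparisons use a 10⁻¹² slack.
* The smoothed permutation p-value never reaches 0; Gumbel extrapolation is
  clamped to `[1e-300, 1/(reps+1)]`.
* Cache hashes include the package version, trading spurious cache misses
  across upgrades for immunity to stale reuse.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at deliberately desk-sized
conditions: unit tests simulate 0.2–0.5 Mbp references at 6–20× with
shorter molecules (30–90 kbp mean) so each all-pairs pass stays in seconds;
the headline reassembly check runs the full stated conditions — a 2 Mbp
reference at 50× with the default 163/100 kbp length model, FP 1.0 and FN
0.10 — and requires ≥ 90 % reference-site recall with zero false joins,
verified against the truth sidecar. The memoization-equivalence check uses
200 molecules with a 60 kbp mean length so that its six full all-pairs
passes (two memoized pairwise nodes plus four naive runs) remain cheap; the
reuse algebra being tested is independent of molecule size.

## What the simulations do and do not show

The simulator reproduces the error structure the assembler reasons about —
FP/FN labels, interval-proportional sizing noise, orientation, a long-tail
length distribution — so passing tests demonstrate the *algorithms* are
correct under their own model assumptions. Real instrument data violates
those assumptions in known ways the simulator does not emulate by default:
fragile-site breakage correlated with label positions, optical resolution
limits that merge close labels, chimeric joins, non-Gaussian stretch within
flow cells, and density-dependent enzyme inhibition. Consequently,
simulation results say nothing about the *parameter values* that best fit
any particular instrument run — which is exactly why the sweep machinery
exists — and accuracy on real data should always be judged against an
independent reference. A further known limitation: assemblies of repetitive
genomes can exceed the true genome size by double-placing repeat copies;
nothing in the unrefined pipeline collapses them (refinement is explicitly
out of scope).
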