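---
title: "Classifying rheostat and toggle positions from parallel mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying rheostat and toggle positions from parallel mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoscan)
```

## The measurement model

The package analyses site-saturation mutagenesis performed in parallel
across protein homologs, with function read out as transcription repression
in Miller units. Three reference levels anchor every profile:

* the **parent** activity of the un-mutated starting protein;
* the **DEL control** — reporter activity with no repressor at all, the
  floor ("MIN") of detectable repression (note the inverted axis: *higher*
  Miller units mean *weaker* repression, so DEL is numerically the top of
  the scale);
* the **growth threshold** (13 Miller units for the *lac* system): below
  it, any repression change measurably alters growth, which makes changes
  that cross it biologically "catastrophic".

Because replicate scatter is multiplicative over the four decades the assay
spans, every comparison uses ratios, and the one distinguishability rule
used everywhere is the dual **change criterion**: two measurements differ
when their means are more than 2-fold apart *and* their `mean ± sd`
intervals are disjoint (`is_changed()`). Repression is read in the
homolog's *active* condition — without effector for inducible repressors,
with effector for co-repressible ones — and each homolog's context records
which.

## The behavior classifier

`classify_position()` rank-orders the substitutions of one
(homolog, position) profile and applies, in order:

1. **Insufficient-data gate.** Fewer than 5 scored substitutions gives
   `#`. The scans typically yielded 8–12 substitutions per position; 5 is
   deliberately below that so a thin profile is marked rather than guessed.
2. **Dead gate.** If every variant is indistinguishable from DEL (the
   change criterion against the DEL control fails), the position scores
   `x` — no substitution retains measurable repression.
3. **Neutral gates.** A substitution is *neutral* when it is within 2-fold
   of the parent or not a change by the dual criterion. We fold the dual
   criterion into the neutral test because "within 2-fold" is itself
   defined through that criterion — a nominally 2.3-fold shift whose error
   bars overlap the parent's is not a change. All neutral gives `N`; all
   within the ~5-fold band gives `n`.
4. **Cluster detection.** Log10 activities are split wherever adjacent
   values are ≥ 0.7 log10 units apart (0.7 ≈ log10 5, just beyond the
   near-neutral band, so two "levels" must be separated by more than any
   plausible within-level scatter). Exactly two occupied levels — one
   parent-like, one at MIN, nothing between — is a toggle `T`; exactly
   three well-separated levels is the three-state code `3`.
5. **Hybrids.** Three or more variants at MIN with a rheostatic remainder
   give `R+T` (remainder span > 2 orders) or `r+T`; a neutral majority
   with at least two changed, non-MIN variants gives `N+r`.
6. **Span measurement.** Otherwise the profile is a rheostat candidate:
   `span = log10(max/min)` over the variant activities. `R` requires
   span > 2 *and* progressivity — no single adjacent gap may exceed 0.62
   of the span, so one outlier cannot fake a continuum. Wide but
   gap-dominated spans, and spans between ~9-fold and 2 orders, score `r`;
   spans in the ~5–9-fold window score the borderline code `n/r`.

All thresholds live in `behavior_config()` and are overridable. The
procedure is deterministic, invariant to the order of input rows, and
invariant under a common rescaling of all activities (only ratios enter).
Zero activities are clamped to half the smallest positive activity in the
dataset before ratios are formed, since the assay bottoms out rather than
reaching zero.

```{r classify-example}
# a hand-made rheostat: progressive values from enhanced to near-DEL
classify_position(c(0.1, 0.4, 1.5, 6, 25, 120), rep(0, 6),
                  parent_mean = 1, parent_sd = 0, del_mean = 200,
                  del_sd = 0)
```

## Sequence entropies and the two-tier separation

Conservation is quantified per alignment column as the gap-inclusive
Shannon entropy `H = −Σ f_i ln f_i` over 21 symbols (20 amino acids + gap),
in nats: 0 for perfect conservation, ln 21 ≈ 3.04 at the uniform maximum.
Ambiguity letters are counted as gap after a warning. Sequences are
unweighted; no redundancy filtering is applied.

The two-tier analysis restricts the family to the sequences carrying a
co-evolving motif (`subset_by_motif()`, e.g. the YPAL motif Tyr47, Pro49,
Ala53, Leu56 for the LacI/GalR linker) and recomputes entropies on that
subset. On the full family almost everything looks nonconserved, and on a
narrow ortholog subfamily almost everything looks conserved; the motif
subset is the "just right" set in which toggle positions score H < 0.1 and
rheostat positions H ≥ 0.6 (`tier_separation()`; ties at the rheostat cut
are rheostat candidates, matching the ≥ phrasing of the calibration, where
position 50 sits exactly at 0.60). The subset keeps the parent alignment's
column map: columns are positional, so entropies of nested sets stay
comparable even if the reference sequence is dropped.

```{r tiers}
linker_entropies() |>
  dplyr::transmute(position, mutated, entropy = ypal_seqs) |>
  tier_separation() |>
  dplyr::count(tier)
```

## Outcome codes and scale screens

`assign_outcome_codes()` cross-tabulates each (position, amino acid) across
homologs against the motif-subset frequencies: `A` (absent from the MSA yet
tolerated, fold ≥ 0.5, in ≥ 2 homologs), `P1` / `P2` (present in the MSA
yet pushing a tight-parent homolog above the growth threshold / to the DEL
floor), `D` (disparate: fold-changes spanning ≥ 2 orders across homologs,
or enhancing in one and at MIN in another), `L` (absent, tolerated only in
the designated reference homolog), `-` (fewer than two homologs carry it).
"Near or better than parent" is operationalized as fold ≥ 0.5 — the 2-fold
equivalence band is the only closeness criterion the assay defines —
and "absent" means raw frequency exactly 0. Codes are sets, not mutually
exclusive (cells like `P2D` are expected), except `A` versus `P1`/`P2`,
which split on zero versus non-zero frequency.

`scale_screen()` computes, per (homolog, position, scale), the tie-corrected
Spearman correlation between a physico-chemical scale value and log10
activity (undefined below 4 substitutions or for constant scales);
`scale_screen_summary()` reports, per scale, the fraction of cells with
|ρ| ≥ 0.8. The bundled `amino_acid_scales()` are standard literature
scales — Kyte–Doolittle hydropathy, free-residue accessible surface area,
Pace–Scholtz helix propensity, Zamyatnin volume — of the same kinds used in
the original screens.

## The synthetic generator

`simulate_dataset()` draws a full variant table with ground truth, so every
stage is testable without laboratory data. Its defaults *are* the study
conditions: the 14 mutagenized parents with their published repression
values (using the tightened point-mutant parents for TreR and AscG, as the
scans did, and excluding the 320-Miller LGhP parent whose changes were
undetectable), 12 positions, 10 substitutions per position (the scans
yielded 8–12), 4 replicates, lognormal replicate noise with cv 0.2 (chosen
to make simulated sd bands comparable to the published parent sds), and 30
planted allostery-altering variants among the ~1700 (matching the ~30
observed). The DEL control is set to 750 Miller units, a representative
no-repressor reporter activity.

Per-class true activities:

* **R / r** — stratified log-uniform over
  `[parent/10^(span/2), parent·10^(span/2)]`, upper-clipped at DEL. One
  draw per equal log-width stratum keeps the marginal distribution
  log-uniform while guaranteeing that the realized range covers at least
  `(n−2)/n` of the nominal span and that no adjacent gap exceeds `2/n` of
  it — so a nominal 3-order rheostat always realizes > 2 orders and is
  never gap-dominated, making zero-noise recovery of class R deterministic
  rather than merely high-probability. Log-uniform sampling is the weakest
  distributional assumption consistent with a progressive multi-decade
  series; real rheostat outcomes need not be uniform, which is one reason
  the benchmark does not certify real-data accuracy.
* **T** — a parent-level / DEL-level mixture (abolished fraction 0.5 by
  default) with nothing between; **3** — parent, geometric midpoint, DEL.
* **N** — lognormal offsets (σ = 0.08 log10) truncated to ±0.25, inside
  the 2-fold band; **n** — stratified over the 5-fold band, which
  guarantees excursions beyond 2-fold; **x** — everything at DEL.

Measurements average `n_replicates` lognormal draws
(`σ² = ln(1 + cv²)`, mean-preserving), so `noise_cv = 0` reproduces true
values exactly. `simulate_msa()` plants a motif in a Bernoulli fraction of
sequences (non-carriers never draw a complete motif, so subset membership
equals ground truth), draws family columns from symmetric Dirichlet
compositions (entropy rises with the concentration parameter), and embeds a
low-diversity subfamily inside the motif carriers, giving the nested
family ⊃ motif ⊃ subfamily structure with non-increasing entropies.

What the generator does **not** emulate: epistatic re-ordering of amino
acid preferences between positions, codon-level mutagenesis bias (an
anti-Met toggle exists but is off by default), assay-specific floor/ceiling
compression, and any correlation between a substitution's physico-chemical
properties and its activity. Passing recovery benchmarks therefore
demonstrates correctness of the decision procedure under the stated noise
model, not classifier performance on real scans.

## Numerical choices and edge cases

* Ratios of zero activities: clamped (half the smallest positive value);
  `fold_change()` errors only if everything is zero.
* Duplicate clones merge by geometric mean with root-mean-square sds;
  pairs differing > 2-fold are flagged (`merge_flagged`), not dropped.
* Percentages round half-up (`enhancement_percent()`), which reproduces
  all twelve published enhancement percentages from their printed counts;
  base R's round-half-even does not.
* Tier ties: entropy exactly at the rheostat cut is a rheostat candidate;
  exactly at the toggle cut is intermediate.
* Insertion-coded position labels (e.g. "61a") are opaque ordered strings;
  no arithmetic is ever done on positions.
* Variants flagged `excluded` (e.g. no activity in either pull-down assay)
  stay in files and round-trips but never enter classification.

## Benchmark sizes and known limitations

The shipped tests and the acceptance script use the default benchmark (14
homologs × 12 positions × 10 substitutions ≈ 3 700 measurement rows, MSAs
of 150–500 sequences), which the package's own Monte-Carlo (30 seeds) puts
at recovery accuracy ≥ 0.97 at default noise — the regression gate is 0.95.
The residual errors are neutral positions drifting into the near-neutral
band `n` when a measured fold-change crosses 2-fold with disjoint sds.

Limitations: the classifier cannot distinguish a true three-state position
from a toggle when the parent represses within ~25-fold of DEL (the
geometric midpoint is then closer than one cluster gap); `r`-class spans
near the 5-fold boundary are intrinsically ambiguous against `n` (the
calibration itself writes "~5-fold"); and code `L` depends on which homolog
is designated the reference. Structural rationalization of codes and
alignment construction are out of scope — the package consumes an existing
alignment.
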