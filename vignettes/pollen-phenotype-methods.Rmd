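---
title: "Methods: pollen phenotype statistics for infrageneric germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen phenotype statistics for infrageneric germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenphen)
```

## The problem

Crabapple (*Malus*) collections — and congeneric germplasm collections in
general — mix a few dozen wild species with a much larger number of
cultivars whose parentage is often partly or wholly unrecorded. Pollen
grains carry taxon-specific morphology, so replicated scanning-electron-
microscope measurements of a handful of grain traits are a cheap
phenotype for probing relatedness. `pollenphen` implements the
statistical layer of such a study: it takes a replicated trait table
(taxon x replicate x trait), taxonomy metadata (rank, and for species an
ordinal section I–V from most ancient to most advanced), and breeding
routes (progeny with up to two parents, possibly `unknown` or
`untested`), and computes uniformity/distinctness verdicts, a two-level
phenotype clustering, pedigree-aware aggregation scores, and ordinal
trend correlations.

Seven traits are measured: polar axis `P`, equatorial diameter `E`, the
half-polar diameter `Eprime` (E′), equatorial-view area `S` (all μm or
μm²), ridge width `RW` and furrow width `FW` of the striate exine (μm),
and perforation density `PD` (holes per μm²). Three shape ratios are
derived: P/E, P/E′, E′/E. An aberrant pollen rate `AP` — the fraction of
grains deviating from the taxon's typical morphology — is a population
fraction and is stored once per taxon rather than per replicate. `S` is
treated as an independently measured trait (it is read off the
micrograph), never recomputed from P and E.

## Uniformity and distinctness

For taxon *i* with replicate mean $\bar{X}_i$ and sample standard
deviation $S_i$ (always the $n-1$ denominator; which denominator the
convention intends is rarely stated, so we fix the sample one
throughout), the **intraspecific uniformity** of a trait is

$$\overline{c.v.} = \frac{1}{n}\sum_{i=1}^{n} S_i / \bar{X}_i ,$$

the unweighted mean of within-taxon coefficients of variation. A trait
with $\overline{c.v.} \le 15\%$ is stable within taxa. Taxa with a zero
trait mean (imperforate taxa have `PD` exactly 0) have no defined CV;
they are excluded from the average and their count is reported — adding
them as 0 would reward degenerate invariance, and as ∞ would be
meaningless.

The **interspecific distinctness** of a trait is
$c.v. = S'/\bar{X}'$, the coefficient of variation of the per-taxon
means; $c.v. \ge 15\%$ marks a trait that discriminates among taxa. A
one-way ANOVA of replicate values across taxa accompanies the statistic.
Verdict comparisons use a $10^{-12}$ epsilon so that an exactly-boundary
value (e.g. $\overline{c.v.} = 0.15$ from round numbers) is classified
by its mathematical value, not by floating-point representation.

Size and shape classes follow Erdtman's catalogue: medium pollen spans
25.1–50 μm of polar axis (both ends inclusive, so the printed boundary
values classify as medium); P/E in [1.14, 1.33) is subprolate,
[1.33, 2.00] prolate, above 2.00 perprolate. Ratios below 1.14 are
flagged `out_of_range` rather than raising an error, since a single
deformed taxon should not abort a batch run.

## Tukey letters

Group comparisons (per-trait across cluster groups, or across taxa) use
one-way ANOVA followed by Tukey HSD. The pairwise p-matrix is summarized
as a compact letter display by the insert-and-absorb algorithm: start
with one letter shared by all groups; for each significant pair still
sharing a letter, duplicate that letter column and strike one member
from each copy; absorb columns whose membership is a subset of
another's. The construction guarantees both directions of the contract —
two groups share no letter exactly when their Tukey p-value is below α —
and the test suite checks this exhaustively for every significance
pattern with up to six groups. Groups are ordered by descending mean
(ties broken lexicographically) before letters are assigned, so "a"
attaches to the largest mean. If the residual variance is numerically
zero the ANOVA is degenerate: equal-mean groups get p = 1, distinct-mean
groups p = 0.

## Clustering and the two-level cut

Taxa are clustered on six features: `P`, `E`, `E′/E`, `RW`, `FW`, `PD`.
P/E, P/E′ and S are omitted as near-functions of the included features.
Features are per-taxon means, z-scored across taxa; with units spanning
μm² (hundreds) to μm (hundredths), unstandardized Euclidean distances
would be dominated by `S`-scale traits, so standardization is not
optional. Default linkage is Ward's minimum-variance criterion on
Euclidean distances (heights on the distance scale); UPGMA and complete
linkage are selectable. The linkage choice is a genuinely open design
point — agglomeration method is rarely reported in morphometric studies
— and Ward is the default because it favours the compact, evenly
shaped groups that per-group trait summaries assume.

The tree is cut at `k_top` (default 4) groups labelled A…D by ascending
size — the largest group always takes the last letter, matching the
heavily skewed group sizes typical of cultivar-dominated collections —
and the largest group's own subtree is then re-cut into `k_sub`
(default 3) subgroups labelled D1…D3, again by ascending size. Cutting
the subtree (rather than taking a global six-group cut) preserves the
nested reading "the largest group divides into three". Labels are
presentation; the partition is the contract, and the suite checks
invariance of the partition under taxon relabeling.

## Pedigree scores

**Family aggregation**: a progeny counts as aggregated when its cluster
label equals that of at least one clustered parent ("at least one"
matches how such tables are scored in the breeding literature; an
all-parents rule is available). At four-group level subgroup labels are
collapsed to their group; at six-group level they are compared directly
— so four-group aggregation can never fall below six-group aggregation.
Progeny with no clustered parent are excluded from the denominator and
reported.

**Perforation-density progression**: a progeny progresses when its PD
exceeds that of at least one comparator parent. `unknown` (unnamed) and
`untested` (named but unmeasured) parents are distinct states: both are
dropped in `exclude_unknown` mode, and both auto-succeed as comparators
in `assume_lower` mode, which treats missing ancestors as low-PD — the
direction the macroevolutionary record suggests. `assume_lower` can
therefore never score below `exclude_unknown`.

**Section aggregation** uses modal-label membership: each section's
modal cluster label is found and the share of species sitting in their
section's modal label is reported, at group and subgroup resolution.
Modal ties are resolved permissively and flagged. The counting rule
behind published section-aggregation figures is typically unstated;
modal membership is the simplest rule that reproduces the published
shares on the packaged assignment table.

**Hybridization frequency** divides the number of routes in which a
species appears as a parent by the total number of routes (not by
parent slots), keeping the scale comparable across tables with many
unknown second parents. Bands: high ≥ 0.20, medium ≥ 0.05, low below.

## Trend correlations

Trends are Pearson correlations of per-taxon trait means against an
ordinal coding — section value 1–5 for species, or rank (species = 1,
cultivar = 2) for the whole collection — with two-sided p-values on
$n-2$ degrees of freedom. With binary coding this is the point-biserial
correlation, and the suite asserts its p-value equals a pooled-variance
two-sample t-test to $10^{-10}$. Correlations are computed on taxon
means, not replicates: replicates share a taxon and would
pseudo-replicate the test. Raw p-values are reported by default (the
conventional presentation); Holm adjustment is available via
`trend_summary(..., adjust = "holm")`.

## The synthetic generator

Raw replicated measurements for collections like this are rarely
deposited, so the generator is a first-class module: every downstream
stage is tested against data with known structure.

* **Species** get sections I–V cyclically and trait means drawn
  uniformly within published-range defaults (P 29.44–52.35 μm,
  E 20.95–29.64 μm, S 560.25–1108.89 μm², RW 0.13–0.25 μm,
  FW 0.04–0.28 μm, PD 0–11.18 μm⁻²). `E` is drawn conditionally on `P`
  so the P/E shape ratio stays inside 1.22–2.21, and `E′` is `E` times a
  ratio in 0.80–0.87 — drawing the three independently would produce
  grains wider than long or E′ > E, which no real grain shows. A
  configurable share of species (default 0.327) is imperforate
  (PD exactly 0). `section_size_slope` (default −0.8 μm per section
  step) adds a weak large-to-small size drift from ancient to advanced
  sections, applied to P, E and S only — size is the only trait for
  which a section-ordered trend is posited.
* **Cultivars** draw two distinct species parents (the second slot
  `unknown` with probability 0.35, near the share of one-parent routes
  in published tables); trait means are the `w`-weighted midparent
  (w = 0.5) plus relative Gaussian noise. The noise sd is *relative*
  (default 5% of the midparent value): traits span four orders of
  magnitude in their units, so a single absolute sd would be meaningless
  across traits. PD is additionally multiplied by a drift factor
  (default 1.2), emulating the low-to-high perforation progression
  across generations; the drift is multiplicative because progression is
  judged by ratio-style comparison to parents. Cultivar `E′` tracks the
  realized `E` through the inherited E′/E ratio (with half-sized
  relative noise, clamped below 1) for the same geometric reason as
  above.
* **Replicates** are Normal(mean, cv·mean) truncated at zero, 30 per
  taxon and trait; default CVs are 0.10 for P, E, E′, S, RW and 0.20 for
  FW, PD — the two regimes on which the uniformity verdicts split.
  Truncation at zero (rather than a log-normal) is simpler and
  essentially bias-free at cv ≤ 0.25; at much higher cv it would bias
  means upward, which the documentation flags rather than corrects.
  No distributional family for within-taxon variation is established in
  the literature; normality is an explicit assumption here. Aberrant
  rates are uniform on [0, 0.956].

Determinism: each stage reseeds from a deterministic function of the
single config seed, so identical configs give byte-identical output and
adding cultivars does not perturb the species draws.

What the generator does *not* emulate: measurement error correlated
across traits within a grain, aberrant-grain morphology classes,
non-normal replicate noise, and genuinely clustered (rather than
uniform) species means. Passing tests on synthetic data therefore
demonstrate the statistics are computed correctly and are well
calibrated under the stated model — not that real collections satisfy
that model.

## Packaged fixtures

`inst/extdata/family_routes_synthetic.csv` transcribes a published
28-cultivar route table. Thirteen rows print full routes and cluster
labels and are transcribed verbatim; the other fifteen rows publish only
their four per-row indicator outcomes (aggregated at four/six-group
level; PD progression under both missing-parent policies), so those
rows' parent identities, labels and all PD values are synthetic
reconstructions chosen to be consistent with every printed indicator and
with cross-row reuse of the same parent species (flagged by the
`reconstructed` column). On this table the package recomputes the four
published percentages — 92.86%, 67.86%, 96.43%, 53.57% — from the row
ingredients, not from the indicator columns. One source-table quirk is
preserved as printed: the same parent species appears with different
labels in different rows (D2 in most rows, D3 in one); per-row labels
are authoritative. The published summary text also rounds the four-group
figure differently in one place (92.60 vs 92.86); the table value is
treated as canonical.

`inst/extdata/section_assignments_synthetic.csv` is a synthetic
23-species assignment table consistent with the published narrative of
how five sections distribute over cluster groups; on it the
modal-membership score reproduces 82.6% (group) and 52.2% (subgroup).

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations everywhere.
* Ratio convention: per-taxon ratios default to ratio-of-means;
  mean-of-ratios (pairing replicates by index) is exposed, and the two
  provably coincide for constant replicates.
* Replicate counts: the design expects 30; ≥ 2 is accepted with a
  warning, 1 is an error (no sample sd).
* Groups of size 1 in summaries report a missing sd rather than
  failing; ANOVA-degenerate (zero-variance) comparisons fall back to
  exact-equality p-values.
* Empty pedigrees load with a warning; score functions refuse to emit a
  percentage with an empty denominator rather than returning NaN.
* Problem sizes used in the test-suite simulations (e.g. 50 taxa × 30
  replicates for CV recovery, 1000 replicates for test-size
  calibration, 100 seeded family simulations) are the package's chosen
  trade-off between Monte-Carlo error and runtime.

## Known limitations

* The clustering linkage actually used in any given published study is
  usually unknowable; conclusions that depend on the tree shape should
  be checked across `ward`, `upgma` and `complete`.
* Hybridization frequencies depend on the route list supplied; the
  package does not attempt to reconstruct unpublished route tables, and
  literature frequencies for concordance checks are user-supplied.
* Ordinal trend tests treat section order as an interval scale, as is
  conventional; no phylogenetic correction is attempted.
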