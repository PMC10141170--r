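---
title: "Methods: from ASV counts to community metabolic restructuring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ASV counts to community metabolic restructuring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomod)
```

`glycomod` analyses in vitro glycan-supplementation experiments: pooled
fecal communities grown on a defined medium with a single added substrate,
profiled by 16S rRNA amplicon sequencing, and compared against
unsupplemented control cultures. This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, the
design choices made where more than one reading was defensible, and what
the synthetic-data tests do and do not demonstrate about real data.

## Multi-taxonomy assignment

The V3–V4 amplicon rarely separates closely related species, so forcing a
single species label on every ASV fabricates precision. Instead, with *M*
the best alignment identity of an ASV against the reference set, all
references with identity strictly greater than

$$t = M - \frac{1 - M}{4}$$

are admitted as co-assignments, and the reference(s) achieving *M* itself
are always included — without that inclusion an ASV whose best identity sits
exactly at the threshold would receive an empty assignment. The window
narrows as the best hit improves and closes entirely at *M = 1*: a perfect
match tolerates no ambiguity.

Numerical choices:

* identities are rounded to 6 decimal places before comparison. Tabular
  alignment outputs carry 2–3 decimals; without rounding, float noise can
  split genuinely tied hits across the strict threshold.
* the multi-name is the *sorted*, de-duplicated `"/"`-join of member
  species labels. Sorting is what makes phylotype names usable as set
  elements in the overlap analysis: the same species group always produces
  the same string.
* members are de-duplicated by full lineage, so two reference records of
  the same species never appear twice.
* ASVs with no alignment hits are retained under the phylotype
  `"unclassified"`, participate in diversity and modulation statistics,
  and are excluded from phenotype prediction (they cannot be mapped to
  genomes). No global identity floor is applied below which hits are
  discarded; the window rule is the only filter.

An ASV's counts go whole and undivided to one phylotype. Splitting counts
across members would presume a resolution the marker gene does not have;
keeping the group as the unit (as unresolved species groups) makes collapse
exactly count-conserving, which the tests assert to the integer.

## Copy-number renormalization

Ribosomal RNA operon copy number varies from 1 to about 15 across gut
bacteria, inflating read counts of high-copy taxa. The package builds a
per-rank lookup: for each rank (species up to domain) and label, the mean
copy number over all reference records carrying that label, plus a global
mean. A lineage is estimated at the most specific rank with an entry,
walking species → domain; specificity-first is the standard usage for this
kind of hierarchical table, and the global mean guarantees the estimate
always exists. Multi-taxonomy phylotypes take the unweighted mean over
members — under the admission rule all members are equally plausible
sources, so there is no defensible weighting.

Renormalization happens *after* collapse, at the phylotype level, because
the phylotype is the analysis unit in every downstream statistic. The
operation is scale-free (multiplying all copy numbers by a constant changes
nothing) and each sample re-closes to 1 within 1e-9, both asserted as
properties.

## Community phenotype index

A binary phenotype matrix (BPM) scores each reference genome 0/1 per
phenotype: pathway calls are taken as annotated, and a CAZyme family is 1
iff the genome encodes at least one member enzyme. The vocabulary spans 7
fermentation products, 11 vitamin/cofactor pathways, and 170 GH + 33 PL
families by default.

A phylotype's value for a phenotype is the unweighted mean of BPM entries
over all genomes of all its member species; fractional values express
strain- or member-level disagreement. The community phenotype index of a
sample is then

$$\mathrm{CPI} = \sum_t a_t\, v_t \in [0, 1],$$

with abundances $a_t$ re-closed over the genome-mappable phylotypes. The
mappable fraction is reported per sample; silently treating unmapped taxa
as phenotype-negative would bias every CPI downward, which is why they are
dropped with renormalization instead. For binary taxon values the CPI
coincides with the summed relative abundance of phenotype-positive taxa,
so "representation of producers" and CPI are the same quantity in that
case — this is the implemented reading.

CPI is linear in abundance (a 50/50 pooled sample has the mean CPI of its
parts) and moving mass from a negative to a positive taxon strictly raises
it; both are asserted as properties.

## Modulation scoring and statistics

For each treatment and phylotype, the replicate-mean relative abundance is
compared with control and classified on a five-fold cutoff: `increased`
when the ratio is ≥ 5, `reduced` when ≤ 1/5, `unchanged` otherwise. Both
bounds are inclusive — the cutoff phrase and the stricter caption wording
differ on the boundary case, and an inclusive rule is deterministic and
symmetric (swapping the roles of treatment and control exactly exchanges
`increased` and `reduced`, asserted as a property). Replicate means rather
than pooled counts feed the ratio, matching the averaged-abundance
description of the comparison.

Zeros receive a pseudovalue of 0.5 counts (half a read, configurable)
before conversion to relative abundance, so fold ratios are always
defined; affected phylotypes carry a `used_pseudo` flag because a ratio
against half a read deserves caution.

Significance uses an exact double-tailed Mann–Whitney U test by full
enumeration: all $\binom{n_1+n_2}{n_1}$ assignments of the pooled
mid-ranks, two-sided p = min(1, 2 · one-sided tail), tails including the
observed value. Enumeration conditions on the observed tie pattern, which
is the correct permutation null for tied data; above 10 observations per
group the test falls back to the tie-corrected normal approximation with a
notice. With 6 vs 6 replicates the p-value floors at 2/924 ≈ 0.002 and
with 5 vs 5 at 2/252 ≈ 0.008 — the values that dominate small-replicate
screens of this design. A Welch t-test and a chi-squared test (no
continuity correction) are provided for the same comparisons. No
multiple-testing correction is applied at the default α = 0.05: the design
is a hypothesis-driven screen with very small n, and the discrete exact
test is already conservative (below). p-values print at 3 decimals; full
precision is kept internally.

### Calibration of a discrete exact test

An exact enumeration test cannot spend the full nominal level. For
tie-free groups of six, the achievable one-sided tail probabilities near
0.025 jump from 19/924 to 30/924, so the true rejection probability at
nominal 0.05 is $2 \times 19/924 \approx 0.041$, and heavy ties (rare taxa
with zeros in most replicates) push it further down — to exactly 0 for
fully tied data. A null simulation should therefore *not* be expected to
reject at 5% of tests; it should reject at the test's *attainable size*,
which `mw_attained_size()` computes from the same enumeration, per test,
conditioning on the observed tie pattern. The package's null-calibration
test asserts two things over pooled null simulations: the empirical
rejection fraction shows no inflation beyond the 99% binomial upper bound
at the nominal level, and it agrees with the summed attainable sizes
within 99% Poisson-binomial bounds. That pair of checks is the meaningful
two-sided calibration statement for a discrete test; a literal two-sided
band around the nominal 0.05 would fail for any correctly implemented
exact test, conservatively, by construction.

## Overlap f-scores

Responder sets contain the phylotypes significantly *increased* by a
treatment (p < α and treatment mean above control); matching across
treatments is by exact display name, multi-names included. A
decreased-direction mode exists but is off by default — co-suppression
mixes compositional artefacts with genuine exclusion and is not the
question the overlap statistic was designed for. For sets A and B,

$$o = |A \cap B|, \quad s = |A| + |B|, \quad f = 100\,o/s \le 50,$$

with equality only for identical non-empty sets. When both sets are empty,
f is reported as missing rather than 0: "no responders at all" and
"responders with no overlap" are different findings. For planted responder
sets of equal size with overlap fraction *q*, the expected f is 50·*q*,
which is what the calibration tests assert at sampling depth.

## The synthetic world

The generator mirrors the study design it stands in for: technical replicates
(default 6, range 4–6) sharing one underlying composition, sequencing
depth 1e5 reads per sample (the order of magnitude of a typical
post-QC amplicon library), a log-normal baseline community (σ = 1.5,
giving the few-dominant-families skew of real fecal cultures), integer
16S copy numbers in [1, 15] correlated within genus, genus-correlated
phenotype content (Beta-distributed genus priors, per-species draws, 3%
flip noise), and alignment hit tables whose decoys are planted either
strictly inside the admission window (true multi-taxonomy members) or
strictly below the threshold (never members). Replicate counts are
multinomial draws; a Dirichlet overdispersion parameter exists for
biological-replicate scenarios and defaults to 0 (technical replicates).

Planted fold changes (default 10-fold increases, 12 responders per
treatment) are drawn from a mid-abundance window, baseline relative
abundance 8e-4 to 5e-3. The window is dictated by closure algebra: if the
planted mass share is $m$, every null taxon's relative abundance shrinks
by $1 + (f-1)m$ and each planted taxon's observed fold is
$f / (1 + (f-1)m)$. The default window keeps $m$ a few percent, so planted
10-fold effects are observed at ~8–9 fold (comfortably above the 5-fold
cutoff, and with control counts of 80–500 reads the exact test reaches its
floor), while null taxa shrink by far less than 5-fold. Planting on very
rare taxa would make effects undetectable at the design depth; planting on
dominant taxa would drag every null taxon past the cutoff. Both regimes
are real phenomena, but they test the sequencing design, not the code.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: read-level error, chimeras and denoising
(the pipeline starts at ASV level); compositional correlation structure
between taxa beyond closure; biological replicate variance (unless
Dirichlet overdispersion is switched on); reference databases with absent
or misannotated lineages; primer and amplification bias.

Test problem sizes are deliberately modest — worlds of 250–400 species,
20 seeds for the recovery and calibration experiments — chosen so the full
suite exercises every stage end to end in a couple of minutes while the
binomial bounds asserted remain tight enough to be informative.

## Known limitations

* All inferences are relative-abundance inferences; the pipeline never
  estimates absolute biomass, and closure effects are interpreted, not
  removed (no CLR/ALR transform, no rarefaction — by design, out of
  scope).
* CPI treats annotation as ground truth: a pathway call error in the
  reference propagates linearly into every sample's index.
* The exact test's conservatism means real but marginal effects at n = 4
  replicates (p floor 2/70 ≈ 0.029) are only barely detectable, and at
  n = 3 undetectable at α = 0.05 (floor 0.1); the design parameters, not
  the implementation, set that limit.
* Multi-taxonomy names are exact-match keys: a taxon resolved cleanly
  under one treatment and ambiguously under another counts as different
  phylotypes in the overlap analysis. This mirrors the unit-of-analysis
  choice and is flagged rather than fixed.
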