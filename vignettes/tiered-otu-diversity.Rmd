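---
title: "Tiered OTU clustering and diversity estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered OTU clustering and diversity estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otutiers)
```

## The problem

Amplicon surveys of the 16S rRNA gene detect far more microbial diversity
than culture collections describe, especially in under-studied domains
such as the *Archaea*. Given a large pool of denoised OTU sequences from
many independent surveys — each sequence labelled with the samples it was
observed in and its abundance — `otutiers` organises that pool into
nested "molecular taxa": species-level clusters (SOTUs) at 97% identity,
genus-level clusters (GOTUs) at 93%, and family-level clusters (FOTUs)
at 89%, and then asks the downstream questions those tiers make
answerable: how many molecular species are defensibly present (a
conservative lower bound), which environments contribute the most unseen
diversity (novelty scores and rarefaction), and how well the clusters are
corroborated by an independent, metagenome-derived sequence collection
(occupancy-stratified match rates).

Everything is exercised end to end on synthetic communities with known
ground truth; no external database is required.

## The identity kernel

Every module rests on one definition of percent identity between two
gap-free sequences. Surveys target different, only partially overlapping
gene regions, so a global alignment would punish honest non-overlap. We
use a semi-global (overlap) alignment: match +1, mismatch −1, gap −1 per
position, with terminal gaps free. Identity is the fraction of matching
columns among the aligned columns, excluding the unaligned terminal
overhangs; a short sequence contained exactly in a longer one scores

```{r}
pairwise_identity("ACGT", "TTACGTTT")
```

IUPAC ambiguity codes match only on exact symbol equality — ambiguity is
treated as difference, which is the conservative choice for clustering.

Ties need care. Many distant pairs have multiple maximal-score
alignments whose identities differ. Choosing among them by traceback
direction preference (diagonal, then up, then left) turns out to be
asymmetric: `identity(a, b)` and `identity(b, a)` can disagree for
dissimilar pairs. We therefore resolve ties by a total order on additive
quantities — highest score, then most matches, then fewest columns. Each
component accumulates per alignment column, so the lexicographic optimum
can be computed cell-wise in the dynamic program, and each component is
invariant under swapping the sequences, which makes the reported
identity symmetric by construction. On near-identical pairs (the regime
where thresholds act) the chosen alignment coincides with the plain
diagonal one. The test suite checks the kernel against an exhaustive
enumeration of all alignments on short strings.

## Greedy centroid clustering and the tiers

Clustering follows the greedy centroid convention of the standard
amplicon tools: records are processed in order of decreasing abundance
(ties: longer first, then smaller id) and each joins the *first* centroid
at or above the threshold, else founds a new cluster. A `match = "best"`
variant is available; "first" is the default because it is what the
cited tool family does. The internal sort makes the result invariant to
input file order.

Genus and family tiers cluster the *centroids* of the level below, each
carrying its cluster's total abundance and sample union. Centroid
propagation guarantees strict nesting (every SOTU in exactly one GOTU,
every GOTU in exactly one FOTU), which the alternative — re-clustering
all sequences at 93% and 89% — does not.

One consequence worth knowing: under read noise, occasional noisy reads
found their own small clusters, and their centroids can fall just below
the genus threshold against the centroid they would ideally join, so
noisy communities recover slightly more GOTUs/FOTUs than planted. On
noise-free input recovery is exact (see the parameter-recovery test).
This is also why purely similarity-based clustering fragments curated
taxa; `taxon_fragmentation()` quantifies that effect and explains why
family-level cluster counts overestimate true family counts.

## Threshold calibration

`intra_taxon_identities()` computes, for a labelled reference set, the
pairwise identities of sequence pairs sharing a rank but *not* sharing
any lower rank — each distribution then characterises exactly one rank
boundary rather than mixing depths. The recommended threshold per rank
is the rounded median; monotonicity (species ≥ genus ≥ family) is
enforced and a violation raises an error, since it signals mislabelled
references. `mirror_check()` compares a distribution computed on full
sequences with one computed on an extracted sub-region (default
tolerance: 2 percentage points of median difference) — the check that
justifies analysing a sub-region at all.

## Region extraction and dereplication

Aligned inputs are trimmed to a 1-based inclusive column window and
gaps are collapsed. A record must carry at least
`min_informative_bases` non-gap characters inside the window to be kept
(boundary `>=`; the default specification is columns 10300–25300 with
244 bases, the count of *E. coli* bases in that window). Ambiguity codes
count as informative: the filter measures information quantity, not
quality, and no further quality filter is applied. Dereplication is
exact full-length string equality — the conservative reading — with
summed abundance, unioned sample sets, and the highest-abundance
(then lexicographically smallest) input id as representative.

## Reference replacement

Records whose best reference hit exceeds 98% identity (strictly) have
their sequence replaced by the curated reference; provenance is kept and
records replaced by the same reference merge. References matched by no
record are appended as single-count records carrying the `"refdb"`
pseudo-sample, representing biodiversity absent from the survey. In
`run_pipeline()` replacement runs *after* region extraction, in region
coordinate space: producing new alignments for replaced sequences would
require the external aligner, which this package deliberately does not
wrap, so the reference set handed to the pipeline must cover the same
region as the reads.

## Estimators

**Conservative lower bound.** For each (sample, GOTU) pair only the
highest-abundance SOTU in that sample is counted (ties: smallest SOTU
id); the bound is the number of distinct SOTUs selected. Co-occurring
same-genus SOTUs in one sample are treated as potential noise, so the
count is deliberately conservative; it is always bracketed by the
occupied-GOTU count and the SOTU count.

**Rarefaction and d_sotu.** Samples are accumulated in `R` seeded random
orders (default `R = 10`, seed 42) and distinct-SOTU counts averaged.
`d_sotu`, the expected number of new SOTUs contributed by one more
sample, is estimated as the mean final-sample increment over the
permutations — the direct empirical reading of "expected novel SOTUs
from one additional sample"; equivalently S(n) − E[S(n−1)]. The curve's
endpoint is permutation-invariant and the worked example
`{s1: {A,B}, s2: {B,C}}` gives exactly `d_sotu = 1`.

**Novelty scores.** Per environment: the number of distinct clusters at
each level observed in that environment's samples, divided by the
environment's sample count. Clusters are counted toward every
environment they occur in rather than uniquely assigned, so the three
scores per environment inherit the nesting inequality
(SOTU ≥ GOTU ≥ FOTU). All three levels are reported separately.

**Environment assignment.** Two votes per cluster: the environment of
the single highest-abundance member occurrence, and the majority
environment over all occurrences (ties: alphabetical, for determinism).

**Taxon summaries.** Per named taxon: sequence and cluster counts plus
`sotu_rate` = #SOTUs/#sequences. The direction of this ratio is a
documented choice: a rate near 1 means nearly every sequence founds its
own molecular species.

## Verification against a second collection

`match_rates()` computes each SOTU representative's best-hit identity
against the target collection once, then thresholds it at 99/97/93/89 —
monotone non-decreasing matched counts by construction. Rows are the
occupancy classes (singleton/doubleton/tripleton/moreton = 1/2/3/≥4
distinct samples) plus a Total row equal to the column-wise sum.
Percentages are formatted by truncation, not rounding — one decimal
below 1%, integer otherwise — because that is the convention the
published table this logic reproduces demonstrably uses (61.94% prints
as 61%); naive rounding fails the reproduction check.

## The synthetic community generator

The generator is first-class, tested code; its defaults are the study
conditions, not knobs.

*Taxonomy.* A random 250 bp root; family ancestors at 10 substitutions
from it; genus ancestors at 5 from their family; species ancestors at 4
from their genus; and two reference strains per species at 3 and 4
substitutions from the species ancestor. Substitution-only evolution
keeps pairwise distances additive down the tree (substitution-set
overlap can only raise identity, never lower it), so the emitted strain
pairs land just above each band edge: within-species ≈ 97.2% (the
asymmetric 3/4 strain depths make the pair distance odd, so the median
rounds to 97), within-genus ≈ 93.6–94.4%, within-family ≈ 89.6–90.4%,
cross-family ≈ 82%. Band membership is verified with the package's own
identity kernel and violating broods are resampled (at most 100 tries).
Calibration on such a set recovers thresholds of (97, 94, 90) — within
the ±1 the discreteness of a 250 bp grid allows around (97, 93, 89).
Reads are emitted from strain 1, the canonical species sequence, so
sibling species stay separated by at least 6 substitutions at the
species threshold.

*Sampling.* Each species draws a Dirichlet environment-affinity vector
(concentration 0.3: specialised species); a sample of environment *e*
detects a species with probability 1 − exp(−0.6 · affinity), which
spreads species occupancy over one to several samples and populates all
four occupancy classes. A configurable fraction of species is planted as
exact single-sample singletons (planting, not sampling — the count is
deterministic). Per-occurrence abundances are lognormal (meanlog 1,
sdlog 1), rounded up to ≥1; reads carry per-base substitution noise
(default 0.005). Any species the sampling missed entirely receives one
occurrence so the planted truth stays recoverable. An aligned view with
a fixed shared gap-column pattern plus the matching region specification
exercises the trimming stage.

*Metagenome target set.* Each observed species enters with a coverage
probability that grows with its occupancy class (defaults 0.05 / 0.3 /
0.35 / 0.6), emulating the over-representation of cosmopolitan species
in metagenome collections, with light noise (0.003) so best hits land
near but not at 100%.

*What the generator does not emulate:* indels and chimeras, PCR primer
bias, 16S secondary-structure constraints, and realistic taxon-abundance
skew across taxa. Passing tests therefore demonstrate correctness of the
pipeline's logic under a controlled substitution model, not performance
on real surveys.

## Numerical and design choices

* All threshold comparisons use `>=` with a 1e-9 guard against binary
  floating-point wobble in ratios like 245/250; the replacement rule is
  strictly `> 98`.
* Deterministic tie-breaks everywhere: clustering order (abundance,
  length, id), best-hit ties by smallest reference id, lower-bound ties
  by smallest SOTU id, majority-environment ties alphabetically.
* All randomness flows from explicit seeds; the three generator stages
  derive their streams from `seed`, `seed + 1`, `seed + 2` so that
  regenerating any stage is reproducible in isolation.
* Problem sizes in the test suite (communities of 10×3×4 species at
  250 bp, 30 samples, 20 gradient replicates) were chosen as the
  smallest sizes at which every occupancy class is well populated and
  binomial noise cannot blur the planted structure.

## Known limitations

* Greedy "first match" clustering is order-dependent by design (the
  internal sort fixes the order); it is not a globally optimal
  partition, and noisy reads can inflate higher-tier counts (see above).
* The identity kernel is quadratic per pair with no k-mer prescreening;
  it is meant for desk-scale analyses, not million-sequence searches.
* Reference replacement in region space assumes the reference set covers
  the analysis region.
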