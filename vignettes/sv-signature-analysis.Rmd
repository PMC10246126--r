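---
title: "Somatic SV signature analysis with svsig: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic SV signature analysis with svsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svsig)
```

# Overview

`svsig` analyzes somatic structural variation (SV) in whole-genome tumor
cohorts: consensus calling across SV callers, partition of junctions into
clustered-complex, non-clustered-complex and simple events, a
49-subcategory simple-SV catalog, NMF signature extraction with a
deterministic final assignment, matched-randomization genomic-feature
tests, and hotspot / mutation / homology / survival cohort statistics.
This vignette documents the models and the decisions behind them: what each
stage assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and where the implementation deliberately
simplifies.

# Data model and conventions

Internally every junction is a pair of oriented breakends on 1-based
coordinates. The orientation of a breakend records the direction of the
retained (joined) segment: `+` extends leftward from the position, `-`
rightward. This fixes the type/orientation correspondence — DEL = (-,+),
DUP = (+,-), head-to-head inversion = (-,-), tail-to-tail inversion =
(+,+); translocations span two chromosomes with a free orientation pair.
BEDPE input (0-based, half-open) is converted on read (`pos = start + 1`);
the VCF writer emits breakend (BND) mate pairs whose bracket notation
follows the same convention, so BEDPE → internal → VCF → internal is the
identity. Caller vocabularies that report a single `INV` type are
reconciled through orientation pairs, which is why the two inversion
orientations are kept as distinct types throughout.

# Consensus calling

Two calls from *different* callers are considered the same junction when
both breakpoints lie on the same chromosomes with identical orientations
and each positional difference is at most `match_distance` (default 10 bp,
read as ≤ 10). Matching builds a graph over one sample's calls with edges
for this predicate and takes connected components; components containing at
least `min_callers` (2) distinct callers are emitted, with the
highest-support member as representative (ties: caller priority
meerkat > manta > delly, then genome order). Within-caller duplicates
collapse first, keeping the higher-support call, so self-matches can never
bridge two otherwise distinct junctions. The graph formulation is
equivalent to exhaustive all-pairs component enumeration — the test suite
checks this on a thousand fuzzed callsets against an independent union-find
oracle.

Caller-level filters precede matching: calls with a breakend off the
canonical chromosomes are dropped, and Delly-style calls shorter than
500 bp need at least 4 combined read pairs + split reads (other callers are
exempt — the filter addresses one caller's known short-deletion noise
mode). After matching, deletions whose two breakends both lie within 3 bp
of exon–intron boundaries of the *same* gene are removed: such junctions
are the fingerprint of reverse-transcribed mRNA (cDNA) contamination
aligned across introns. Finally, a junction is flagged CNV-validated when
both breakends fall strictly within 1 kb of the nearest CNV segment
breakpoint of the same sample; the flag annotates quality but removes
nothing, since balanced SVs legitimately lack CNV support. Whether 1 kb is
strict or inclusive is not observable at our precision; we chose strict and
expose it in `consensus_config()`.

# Event classification

Junctions are grouped per sample by single-linkage agglomeration: two
junctions link when, on some shared chromosome, the gap between their
footprints (the interval between a junction's breakends; points for
translocation breakends) is smaller than expected under uniform placement —
`P(gap) ≈ 2·gap/L` is compared against `p_cluster` (default `1e-3`),
Bonferroni-adjusted by the number of junction pairs in the sample.
Overlapping footprints always link. This is a deliberately simplified
surrogate for published likelihood-based rearrangement clustering; it is
*not* a reproduction of those algorithms, and the package presents it as
its own documented rule.

An event is **clustered-complex** when it has ≥ `min_clustered_junctions`
(6) junctions and its breakpoint density exceeds the sample background by
`density_factor` (5×). Clustered events receive one of six labels from an
explicit decision tree over the copy-number footprint:

1. maximum copy number ≥ 8 on a circularizable junction set → **ecDNA**;
2. ≥ 50 % of a ≥ 10 Mb footprint lost → **Large loss** (gained →
   **Large gain**);
3. two-state copy-number oscillation (top two states cover ≥ 70 % of
   segments and the minor state holds ≥ 25 % of the footprint length) →
   **Micronuclei**, or **Chr bridge** when a terminal chromosome window
   is lost (telomere-loss evidence of a broken chromatin bridge);
4. otherwise **Hourglass** (concentrated breakpoints, little copy change).

The minor-state length condition separates genuine oscillation from
sporadic small losses: after merging adjacent equal-copy segments *any*
profile alternates between states, so a segment-count oscillation fraction
alone is uninformative. These thresholds are package defaults, exposed in
`event_config()`, and are a rule-based stand-in for the published
clustering-based classifier — label semantics are comparable, exact
boundaries are not.

Non-clustered multi-junction events are labeled from their junction-chain
topology. Breakends of different junctions pair either directly (opposite
orientations within `pair_distance` = 1 kb — a balanced join) or through a
*bridge* (facing breakends up to 10 Mb apart whose intervening segment is
copy-gained). A closed or near-closed chain of ≥ 3 junctions across ≥ 2
chromosomes built from balanced joins is **chromoplexy**; a closed cycle
routed through ≥ 1 gained bridge is a **templated-insertion cycle**;
everything else is **complex unclear**. Two-junction events whose members
form a reciprocal inversion/translocation pair are classed *simple* — they
are consumed as a single reciprocal SV by the catalog.

# The 49-subcategory catalog and the nine signatures

Simple SVs are typed first: an h2h + t2t inversion pair with all four
breakends mutually pairable (≤ 1 kb) is one reciprocal inversion; a lone
inversion with breakends ≤ 5 kb apart is a fold-back inversion (the
breakage–fusion–bridge hallmark); remaining lone inversions are unbalanced;
translocation pairs with pairable ends and opposite orientations are one
reciprocal translocation; lone translocations are unbalanced. Reciprocal
pairs count once.

Classification then proceeds fragile-site first (a deletion or tandem
duplication with a breakend inside a fragile-site interval goes to the
corresponding fragile-site category; "either breakend" is the default,
switchable to "both"), then by size bin. The schema ships as a TSV resource
with 1 + 1 + 18 + 18 + 3 + 5 + 1 + 1 + 1 = 49 subcategories. The exact
18 + 18 deletion/duplication bin edges and the 3/5 inversion bins are not
recoverable from the published description; our defaults are log-spaced
edges constrained to pass through the cut-points the final signatures need
(1 kb, 5 kb and 10 Mb for deletions; 1 Mb, 2.5 Mb and 10 Mb for tandem
duplications; 50 kb and 5 Mb for unbalanced inversions; 5 Mb for reciprocal
inversions). Bin edges are configuration data, not code.

The deterministic final assignment maps every subcategory to one of nine
signatures: deletions < 1 kb → Del0, 1–5 kb → Del1, 5 kb–10 Mb and both
fragile-site categories → Del2; tandem duplications ≤ 10 Mb → TD, except
1–2.5 Mb duplications with both breakends in the configured BRAF region →
BRAF fusion (the KIAA1549–BRAF fusion signature); fold-back and unbalanced
inversions → Unbal inv; deletions/duplications > 10 Mb and inversions
> 5 Mb → Large mixed; reciprocal inversions and translocations → Recip;
unbalanced translocations → Unbal tra. Unbalanced inversions below 50 kb
are not covered by the published wording; we assign them to Unbal inv so
the rule set is total.

# NMF extraction and rank selection

`nmf_extract()` factorizes the samples × 49 catalog (transposed internally)
by multiplicative updates under the KL divergence, the natural objective
for Poisson-distributed counts; the update loop is asserted non-increasing
in the tests. For each candidate rank, `n_restarts` fits run on
Poisson-resampled catalogs; the 40 % worst-converged restarts are discarded
(stuck local optima would contaminate the stability estimate), the pooled
signature vectors are clustered by k-means in cosine geometry, and
stability is the mean silhouette. The chosen rank is the largest candidate
that is both stable (silhouette ≥ 0.8) and *useful*: its mean resampled
reconstruction error must improve on the next smaller candidate by more
than `rank_penalty × (categories + samples)` KL units per added component.
The second condition is AIC-flavored: an extra component carries roughly
`categories + samples` free parameters, and on data already explained at a
lower rank a stable split buys only the improvement those parameters absorb
from noise. With the default `rank_penalty = 2`, noiseless low-rank
catalogs resolve to their true rank and 500-sample catalogs with nine
planted signatures recover rank 9 with matched cosine similarity above
0.99 (the acceptance script recomputes this). Convergence: relative
objective change below `1e-8`, at most 10,000 iterations (tests and the
acceptance script use smaller caps, 400–1,500 iterations, which the
convergence criterion reaches on their problem sizes).

The NMF is exploratory; the *deterministic* assignment above is what drives
hotspots, mutation tests and survival, so those results do not depend on
factorization seeds.

# Genomic-feature tests

For each observed SV, four random SVs of the same chromosome(s), span and
type are placed uniformly over feasible positions (translocation breakends
are redrawn per chromosome). Observed and random breakends are scored per
feature: interval tracks by log(distance + 1) in the track's units (kb for
non-B DNA, repeats, CpG islands and TAD boundaries; Mb for centromeres and
telomeres; 0 inside an interval), signal tracks by their annotated value,
GC content by the G+C fraction in a ±50 bp window when sequence is
available. Scores are min–max rescaled to [0, 1] over the pooled
observed + random sample — the KS statistic is invariant to this monotone
rescaling, so the pooled-vs-global choice is cosmetic — and compared by a
two-sided two-sample Kolmogorov–Smirnov test; direction is the sign of the
median shift; Benjamini–Hochberg FDR is applied over the whole
signature × feature grid at 0.1. The default manifest names 31 features
(1 GC + 7 non-B DNA + 8 repeat classes + centromere + telomere + CpG + TAD
+ 10 histone marks + 1 replication timing). Randomization samples uniformly
per chromosome; mappability or blacklist masking is not applied.

# Cohort statistics

Hotspots: 1 Mb non-overlapping bins tiling each chromosome from position 1
(final partial bin kept); per signature and bin, the count of *distinct*
samples with ≥ 1 breakpoint — repeated hits of one sample in one bin count
once. Mutation tests: within each tumor type, hypermutated samples
excluded, genes mutated in ≥ 5 % of the type's samples are tested against
each signature's presence with a two-sided Fisher exact test (the standard
sum-of-smaller-probability convention) and BH FDR < 0.1. Homology spectra
bin junctions into insertion > 10 bp, insertion 1–10 bp, blunt, and 1/2/3/4
and 5+ bp microhomology (insertions take precedence; junctions with no
annotation are excluded), the axis along which end-joining (blunt/short
homology), alternative end joining (2–5 bp+) and replication-based
mechanisms (long insertions) separate. Survival: within one tumor type,
clustered-complex signatures are compared by a multi-group log-rank test
over {each single signature, Mixed, None} and simple signatures by
two-group presence/absence log-rank; percentages in cohort summaries are
half-up rounded to one decimal.

# The synthetic-data generator

`simulate_cohort()` draws, deterministically from one seed (per-sample
substreams derived by counter-style splitting, so enlarging the cohort
never perturbs earlier samples):

* a genome model (default eight chromosomes, 80–240 Mb, ~1.2 Gb total)
  with centromeres, telomeres, fragile sites, toy gene/exon models and a
  3 Mb BRAF-fusion window;
* per-sample SV counts per process from a tumor-type × process activity
  matrix whose defaults mirror the qualitative cohort biology the package
  targets (high-grade gliomas rich in most processes; low-grade astrocytic
  tumors dominated by BRAF-fusion duplications; DNETs essentially
  TD-only; choroid plexus papillomas empty). Simple-SV sizes are
  log-normal within per-signature ranges chosen to make the nine classes
  separable; breakpoint homology/insertion lengths follow per-signature
  distributions (2 bp microhomology modes for TD/Recip/BRAF fusion, long
  insertions for amplification-associated processes, blunt/1 bp
  otherwise);
* clustered events (8–20 junctions) with one of six copy-number footprint
  patterns (oscillating two-state with or without telomere loss, stepwise
  loss, large gain, cyclic high amplification, sporadic-loss hourglass);
  chromoplexy as balanced translocation cycles over 3–5 chromosomes;
  templated-insertion cycles with a gained template segment. Processes
  avoid each other's territory (50 kb margin) so that ground-truth event
  membership is well defined;
* CNV segment profiles implied by the copy-altering SVs, with boundary
  jitter (sd 50 bp, clamped at 400 bp — inside the 1 kb validation
  distance);
* three caller views with per-caller sensitivity (defaults 0.75 / 0.90 /
  0.65), breakpoint jitter (sd 2 / 1 / 3 bp), support-count distributions
  and caller-specific false positives that are never shared between
  callers — hence consensus precision 1.0 *by construction* on synthetic
  data, and recall equal to the at-least-two-of-three binomial
  expectation;
* sample metadata: sex, mutation sets whose rates couple to processes
  (TP53 with clustered events, H3F3A with templated insertions),
  rare hypermutators, and exponential survival with a configurable hazard
  ratio (default 3) for carriers of one signature.

The generator emulates cohort *structure*, not sequence realism: no reads,
no breakpoint sequence context, no mappability structure, uniform breakpoint
placement within processes. Passing tests on synthetic data therefore
demonstrate the correctness of the pipeline's logic and statistics under
its stated assumptions — not the biological fidelity of any particular
threshold on real tumor genomes, where caller errors correlate and
breakpoints are far from uniform.

Default cohort sizes follow the real cohort layout (744 samples over 15
tumor types). The test suite and acceptance script run scaled-down but
structurally identical designs — cohorts of 40–60 samples on a four-
chromosome 180 Mb genome, 500 Monte-Carlo null cohorts of 9 × 200
breakpoints for the KS/FDR calibration, 500-sample catalogs for NMF
recovery, and 1,000 fuzzed callsets of up to 50 calls for the
consensus-oracle equivalence — sizes chosen so the checks are statistically
informative on a single core.

# Numerical choices and degenerate inputs

* Ties in consensus representatives break by caller priority then genome
  order; matching is order-independent.
* `ks_association_test()` returns D = 0, p = 1 on constant pooled scores;
  `cohort_summary()` returns zeros for empty cohorts instead of dividing
  by zero; samples without CNV data classify clustered events to a
  configurable fallback label ("Hourglass") with a warning and never fail.
* All randomized components (simulator, randomizer, NMF) consume explicit
  seeds; the simulator's per-sample substreams keep outputs byte-identical
  across repeated runs.
* Interval distance queries use a sorted `findInterval` sweep, exact for
  merged interval sets, chosen for the Monte-Carlo hot path.

# Known limitations

* The clustered/non-clustered classifiers are documented surrogates for
  published clustering tools; label boundaries (amplification ≥ 8, loss
  fraction ≥ 0.5, 10 Mb footprint, 70 % / 25 % oscillation rules) are
  package defaults, not reproductions.
* Size-bin edges within the Del0/Del1/Del2/TD ranges are conventional
  (log-spaced) choices; only the signature cut-points are anchored.
* The feature panel's tracks are user-supplied (or simulated); the package
  does not download public annotation resources.
* Multi-template insertion cycles whose templates exceed the clustering
  linkage scale may split across events; the default generator uses
  single-template cycles.
* Fisher tests are two-sided by the sum-of-smaller-probability convention;
  one-sided alternatives are available through the underlying
  `fisher.test` if a directional hypothesis is warranted.
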