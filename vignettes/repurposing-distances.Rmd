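---
title: "Sequence-embedding distances for drug-repurposing screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-embedding distances for drug-repurposing screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drembed)
```

## The question the package answers

Drug repurposing looks for new disease indications for approved drugs. One
signal worth screening for is *target similarity*: if a protein associated
with an untreated disease resembles the known target of some drug, that drug
is a candidate for the disease. `drembed` operationalises a sequence-level
version of this idea:

1. encode every protein sequence as a fixed-width numeric vector,
2. measure cosine distances between **repurposing pairs** — (protein
   associated with the disease a drug was repurposed *to*) × (target protein
   of that drug) — and between **background pairs** (everything else),
3. test whether repurposing pairs are systematically *closer* than background
   pairs, despite the enormous size imbalance between the two populations,
4. flag candidate pairs whose distance is below the corpus mean under several
   embedding methods at once.

The package ships the full pipeline plus a synthetic-study generator that
plants repurposing pairs with a controlled sequence divergence, so both the
direction of the effect and the behaviour of the test under the null can be
exercised end to end without any external database.

## Sequence encoders

All sequences are first sanitized onto a fixed 21-symbol alphabet: the 20
canonical amino acids in alphabetical order plus the wildcard `X` last
(`aa_alphabet()`). Ambiguity codes (B, Z, J), the rare U and O, stops and gaps
all map to `X`; how upstream tools handle non-canonical residues is rarely
documented, and a single explicit wildcard keeps the encoders total. The
alphabet ordering is part of the on-disk contract: it fixes the 21 one-hot
columns and the 441-feature ordering of the SGT vector.

**Mean-pooled one-hot (`onehot_mean`, width 21).** Each position is an
indicator vector over the alphabet; averaging over positions yields exactly
the residue-composition vector (entries in [0, 1], summing to 1). This is the
naive baseline: it is order-free, so `AC` and `CA` encode identically.

**Sequence Graph Transform (`sgt`, width 441 = 21²).** One feature per
*ordered* symbol pair (u, v). Every position pair i < j with s_i = u,
s_j = v contributes a weight e^(−κ·(j−i)); the accumulated weight is divided
by a normalizer and raised to the power 1/κ:

  ψ(u, v) = ( Σ_{(i,j)} e^(−κ(j−i)) / Z )^(1/κ),  ψ(u, v) = 0 with no
  contributing pair.

κ (default 1) sets how fast influence decays with the positional gap; small κ
lets distant co-occurrences matter. Two normalizers are offered: the number
of contributing position pairs (`length_insensitive`, the default) or the
sequence length (`length_sensitive`). The published description of the
encoder leaves the normalization variant and κ unstated, so both are exposed
and the defaults are documented rather than hidden; the engine is an O(21·L)
recurrence verified against a brute-force O(L²) enumeration to 1e−9 in the
test suite. Unlike pooled one-hot, SGT retains order:
`sgt_encode("AC") ≠ sgt_encode("CA")`.

**External embeddings.** Vectors from pretrained protein language models
(SeqVec- or ProtBERT-style) are supported as precomputed matrices loaded from
a delimited table (`load_external_embeddings()`); no model inference happens
in this package. They are used as-is, with no re-normalization, and are
tagged `signed` because their coordinates may be negative.

Sequences longer than 6,024 residues are removed before embedding
(`filter_by_length()`; the boundary itself is kept). This mirrors standard
practice for pretrained encoders, for which extreme lengths are both costly
and poorly represented in training corpora.

## Distances and their ranges

Distance is `1 − cos(θ)` with `cos(θ) = a·b / (‖a‖‖b‖)`. For nonnegative
vectors (both in-package encoders) it lives on [0, 1]; for signed external
embeddings on [0, 2]. Distances are range-checked with a numerical slack of
1e−12 and clipped into the declared range. Signed-embedding distances are
reported raw on [0, 2], not re-scaled, since raw embedding distances are what
the screening compares.

The background universe of a corpus with n proteins has n(n−1)/2 unordered
pairs — hundreds of millions at proteome scale — so `background_distances()`
never materialises the pair list: a rank ↔ (i, j) bijection enumerates (or
uniformly samples, under a seed) pair ranks, and distances are computed in
chunks with memory bounded by `chunk_size × d`. Pairs are canonicalized
(lexicographic id order, C collation) so exclusion sets and joins are
well defined and independent of the session locale.

## Building repurposing pairs

`build_dr_pairs()` crosses, per repurposing case, the new disease's proteins
with the drug's targets, and drops a case entirely when drug and disease
share a target protein: there the repurposing is explained by the shared
target itself, and the pair would measure identity, not informative
similarity. `filter_shared_class()` additionally removes pairs whose
functional-class sets intersect (PANTHER-style labels) — members of one
family are trivially similar and offer no repurposing insight. Proteins with
no class annotation pass the filter (an empty set is disjoint from
everything); annotation is sparse in real data and treating missingness as
exclusion would empty the filtered subset.

## The resampled Mann–Whitney U comparison

Repurposing pairs number in the tens to thousands; background pairs in the
millions. A single rank test at that imbalance is dominated by the large
sample, so the package repeats the comparison: each of `n_iterations`
(default 1000) iterations draws, uniformly without replacement, a background
subsample of exactly the repurposing-sample size and runs a Mann–Whitney U
test of the *fixed* repurposing sample against it, yielding a distribution of
p-values summarised by mean, population SD, and median, alongside the
distance statistics (`dr_mean`, `dr_std`, `background_mean`). Both p-value
and distance summaries are always reported, so no single scalar has to carry
the result.

`mwu_test()` uses midrank ties and the normal approximation with tie and
continuity corrections, switching to the exact null distribution when
`n_x·n_y ≤ 400` and no ties are present. The default alternative is
two-sided (a "repurposing pairs less distant" one-sided mode is available).
Each iteration's draw is seeded from a named substream of the master seed, so
iteration k is reproducible and unaffected by `n_iterations`.

**A calibration caveat that users should understand.** The per-test p-value
is marginally calibrated (the suite checks that p-values from independent
null samples are uniform). The *resampled* procedure, however, holds the
repurposing sample fixed while only the background subsample is redrawn.
Conditional on one realised repurposing sample, the 1000 p-values are
therefore *not* uniform even when no effect exists: about half the variance
of the U statistic comes from the sample that never changes, so the p-value
distribution is underdispersed for a typical sample and shifted for an
atypical one. The package's null acceptance check (planted divergence 1.0)
applies a Kolmogorov–Smirnov uniformity bound to those 1000 p-values and
fails it at the default seed — a property of the resampling scheme itself,
not of the implementation, which is why the suite also verifies the marginal
calibration of `mwu_test()` separately. In practice this means the *spread*
of the 1000 p-values should not be read as a frequentist error rate; the
median p-value and the distance means are the robust summaries.

## Candidate calling

`summarize_distances()` computes, per method, mean, population SD and median
over the distance universe available to the run (the background sample plus
the repurposing pairs; the repurposing pairs are a vanishing fraction of it).
A pair is *below mean* under a method when its distance is strictly smaller
than that method's mean; `call_candidates()` counts the consensus across
methods and sorts by descending consensus, then ascending mean distance, and
`consensus_fraction(calls, k)` reports the percentage of pairs at consensus
at least k. Strict inequality makes the boundary case unambiguous: a pair
exactly at the mean is not called.

## Visual validation of embeddings

`tsne_project()` (t-SNE via Rtsne, perplexity default 30 — the standard
default, since no value is prescribed for this analysis — and a fixed seed)
projects an embedding set to 2D or 3D; `plot_class_scatter()` colours
proteins by functional class, restricted upstream to proteins with exactly
one class (`select_single_class()`) so each point has one unambiguous colour.
Rows are canonically sorted by id before projection, making the result
independent of input order. An encoding that groups same-class proteins is
carrying biological signal; the suite asserts this as a silhouette
comparison against permuted labels on synthetic classes. 3D projections are
rendered as a depth-ordered oblique scatter.

## The synthetic-study generator

`synthetic_spec()` fixes the full parameterization of a study; everything
derives from one seed through named substreams, and `generate_dataset()`
writes a bitwise-reproducible file bundle (FASTA, class TSV, association
TSVs, a truth table kept separate from pipeline inputs).

* **Class structure** is compositional: each class gets a residue-composition
  profile drawn from a symmetric Dirichlet over the 21 symbols
  (`class_concentration`, default 1 — a flat Dirichlet, giving clearly
  distinct yet not degenerate profiles; large values approach the uniform
  composition). Residues are i.i.d. from the class profile. This is the
  minimal structure that makes composition embeddings informative and SGT
  distinct, while remaining fully controllable.
* **Proteome size** defaults to 5 classes × 50 proteins with lengths uniform
  on 100–400 residues — typical protein lengths, and a scale at which the
  full pipeline runs in seconds.
* **Planted cases** (default 20): each picks a distinct target T and creates
  a disease protein as a copy of T mutated per site with probability
  `dr_divergence` (substitutes uniform over the other 20 symbols). The dial
  maps directly onto the effect being tested: 0 gives identical pair members
  (distance 0), 1 gives full substitution (no planted effect). Default 0.05 —
  close homology, the regime the screening is meant to detect. Each disease
  also receives 3 random decoy proteins, so repurposing cases contribute
  both signal and null pairs, as real many-to-many association tables do.
  The target is never placed in its disease's protein set, so planted cases
  survive the shared-target exclusion. Mutant disease proteins carry no
  class annotation: they pass the shared-class filter vacuously, keeping the
  filtered and unfiltered analyses both meaningful on synthetic data.

What the generator does *not* emulate: motif or domain architecture,
phylogenetic correlation between background proteins, realistic class
hierarchies, or association-strength weighting. Passing tests on this data
shows the pipeline detects compositional sequence similarity against an
i.i.d. background — not that any particular biological corpus carries such
signal.

## Orchestration and reproducibility

`run_config()` validates every input before any stage runs; `run_pipeline()`
executes read → length filter → embed (each method) → pair construction
(± class filter) → distances → resampled MWU per (method, source, filtered)
→ candidate calls, logging counts at each stage, and returns a
`dr_run_report` that serializes to JSON with no timestamps — identical
configs yield byte-identical reports, and written artifacts carry md5
checksums. The functions themselves are the interface; `scripts/acceptance.R`
is a worked end-to-end driver.

## Numerical and design choices, collected

* Alphabet fixed at 21 symbols, `X` last; one-hot width 21, SGT width 441.
* Length filter strictly greater than 6,024 (the boundary is kept).
* SGT defaults κ = 1, length-insensitive normalization (the normalizer is
  the contributing-pair count; the length-sensitive variant divides by the
  sequence length); both overridable.
* Population (not sample) standard deviation in all descriptive summaries.
* Distances clipped into the declared regime after a 1e−12 slack check.
* Exact MWU when `n_x·n_y ≤ 400` and tie-free, otherwise normal
  approximation with tie and continuity corrections.
* Below-mean calls use strict inequality; thresholds come from the run's own
  distance universe and are recorded in the report.
* All randomness flows from one master seed through named substreams
  (profiles, proteome, planting, background sampling, each MWU iteration,
  t-SNE), so any single stage can be reproduced in isolation.
* Test and acceptance problem sizes — 250-protein proteomes, 20 planted
  cases, 20,000 background pairs, 1000 iterations — were chosen so the whole
  suite completes in well under a minute on one CPU while every statistical
  check retains the sample sizes its assertions need.

## Known limitations

* The resampled p-value distribution is conditional on the fixed repurposing
  sample (see the calibration caveat above).
* Pretrained language-model embeddings are supported only as precomputed
  matrices; no inference, and no k-mer/word2vec-style encoders.
* Only t-SNE is provided for projection.
* Below-mean consensus is a screening heuristic, not a calibrated
  classifier: its thresholds are corpus means, so calls shift with corpus
  composition.
* The worked-example reference distances require canonical UniProt sequences
  that are not redistributed with the package; fetch them once with
  `scripts/fetch_worked_examples.R` (network required), re-install, and
  `worked_example_distances()` recomputes the four values. Alignment-based
  similarity (BLAST-style) and set-overlap indices are out of scope.
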