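---
title: "Methods: ortholog sets, lineage-unique residues and thresholded differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog sets, lineage-unique residues and thresholded differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscan)
library(dplyr)
```

# The problem

Comparative transcriptomics of a long-lived focal species — the worked
examples in this package concern the bowhead whale, screened against a
panel of other mammals and vertebrates — asks three questions that this
package answers with small, testable procedures:

1. **Which sequences are comparable?** One representative coding
   sequence per gene is chosen (the *reference ORF*), matched across
   species by *reciprocal best hit*, and the resulting ortholog sets
   are cleaned by two refinement filters.
2. **Where has the focal lineage changed radically?** Alignment
   columns are scanned for residues whose chemical class is unique to
   the focal species.
3. **Which genes are differentially expressed?** A one-vs-rest
   contrast on TMM-normalised counts is thresholded jointly on effect
   size, false-discovery rate and posterior odds.

Every stage is driven by a seed-deterministic synthetic-data generator
so that each rule can be verified against planted ground truth at desk
scale.

# Reference ORFs

`find_orfs()` enumerates every complete ORF (`ATG` to the next in-frame
stop) in all six frames. `select_reference_orf()` keeps the **longest
transcript** of a gene — transcript length, not ORF length, picks the
representative — and takes the longest complete ORF within it. The
emitted coding sequence always satisfies four invariants: length
divisible by three, leading `ATG`, terminal stop, no internal stop.

Numerical and policy choices, made explicit because conventions differ
between tools:

* Coordinates are 0-based half-open internally; reported reference
  positions are 1-based.
* Only `ATG` counts as a start; the standard genetic code (table 1) is
  used throughout, matching the vertebrate scope of the pipeline.
* Any codon containing `N` is neither start nor stop and translates to
  `X`.
* Ties are resolved by a total order — equal transcript lengths go to
  the lexicographically smaller transcript id; equal ORF lengths to the
  smaller start coordinate, then the `+` strand — so selection is
  invariant to input order.
* The default minimum protein length (100 residues) is a configurable
  convention, not an inference from any upstream study.
* No coding-potential model is applied; selection is purely
  length-and-validity based.

# Ortholog sets by reciprocal best hit

`reciprocal_best_pairs()` declares a pair when a reference gene and a
species' transcript are each other's highest-scoring match.
`declare_ortholog_sets()` marks a gene *complete* when a pair exists in
every panel species, and `refine_ortholog_set()` applies two filters:

* **start/stop filter** — at least 80% of member sequences carry both a
  start and a stop codon (boundary inclusive: 8 of 10 passes);
* **length filter** — every member lies within ±50% of the median
  member length in nucleotides, bounds inclusive, with the median of an
  even count taken as the mean of the two central values.

Similarity can come from two interchangeable sources: the built-in
deterministic aligner (`score_pair()`), or an ingested 12-column
tabular hit file (`read_tabular_hits()`, ranked by bit score). The
decision rules downstream are identical for either source. The built-in
scorer uses global Needleman–Wunsch with BLOSUM62 for proteins, and
ends-free *overlap* alignment (match +2, mismatch −3) for nucleotides —
ends-free because a coding sequence matched against a transcript with
UTRs should not pay for the UTR overhangs, which is exactly the
behaviour of the seed-and-extend search engines this scorer stands in
for. Gap costs are affine (opening 10, extension 4) in both modes. Ties
in best-hit ranking go to the lexicographically smaller subject id.

`assign_reference_protein()` implements the annotation-assignment rule
used upstream of the residue scan: the best hit is accepted only with
E-value ≤ 1e-5 (when available), identity strictly above 50% and query
coverage strictly above 75%.

The pipeline is strictly one-to-one: no paralogy handling, no
many-to-many groups, and no reimplementation of heuristic seeding.

# Lineage-unique residues

`scan_alignment()` classifies the 20 standard residues into four
chemical groups — acidic `{E,D}`, basic `{K,H,R}`, cysteine `{C}` and
*other* (the remaining 14) — and calls a column when the focal
species' group is absent from every informative residue of all other
species. The rule is symmetric across all four groups. Each call is
reported with:

* a 1-based position in the **reference species' ungapped protein**
  (the convention used when sites are reported against a human
  protein), and
* a compact change string such as `STQ174R`: the other species'
  distinct residues, the position, then the focal residue.

Open policy points were settled as follows:

* **Gaps and `X` among non-focal species are ignored**; a column stays
  eligible while at least `min_informative_others` informative residues
  remain (default 30, chosen for panels of ~60+ heterogeneous genomes
  where some species are always missing). A focal gap or `X` skips the
  column. A stricter `treat_x = "disqualify"` policy is available.
* **Change-string ordering**: distinct other-residues are ordered by
  descending frequency among informative others, ties alphabetical.
  This is a deterministic convention of this package, chosen because
  frequency ordering is defensible and reproducible; it is not claimed
  to be the convention of any published table.
* Exactly one focal row enters the scan; if several focal assemblies
  exist, consensus or selection happens upstream.

`neutral_fp_simulation()` characterises the scanner's chance-call
behaviour by evolving independent columns along a tree with no planted
cross-group events and scanning them exactly as production alignments;
it reports the per-column rate with an exact binomial interval. It
makes no attempt to reproduce any empirical false-positive figure
derived from real alignment panels, which depend on alignment error
and lineage sampling that a neutral simulation does not model.

# Differential expression under the triple threshold

The stage follows the standard count pipeline: `tmm_factors()`
(trimmed mean of M-values: 30% two-sided trim on per-gene log-ratios,
5% on abundance, precision-weighted, factors rescaled to geometric
mean 1; delegated to edgeR's reference implementation of the
algorithm), `log_cpm()` with the usual pseudocounts
(`log2((y + 0.5)/(N·f + 1)·1e6)`), a two-group moderated t contrast
(`group_contrast()`: pooled variance shrunk towards a prior with
`d0 = 4` prior degrees of freedom by default), Benjamini–Hochberg
step-up adjustment, and the flagging rule

> flagged ⇔ |log2FC| ≥ 2 **and** adjusted P ≤ 0.05 **and** B ≥ 2.945,

where B is a natural-log posterior odds; `b_threshold_from_probability()`
shows that 2.945 is exactly the smallest three-decimal log-odds whose
sigmoid reaches 95% (`ln 19 = 2.9444…`).

Because a full empirical-Bayes hierarchy (voom weights, moderated-t
hyperparameter estimation) is deliberately out of scope, the B column
is either supplied externally (as when re-filtering published result
tables) or computed by `approximate_b()`, a clearly-labelled
two-component posterior-odds statistic on the moderated t (prior
proportion 0.01, variance inflation 16 under the alternative). The
approximation preserves the decision rule — strong effects get large
positive B, null genes negative B — without claiming to reproduce any
particular fit. Published B values are used only through the threshold
decision, never to reverse-engineer hyperparameters.

`term_enrichment()` computes fold enrichment
(`(k/n) / (K/N)`) and a one-sided Fisher's exact P per term over a flat
term-to-gene mapping; no ontology structure is modelled, matching how
flat enrichment tables are usually presented.

A numerical caution on BH adjustment: the step-up transform is *not*
idempotent — re-adjusting already-adjusted values inflates them again
by `m/rank` (e.g. `(0.1, 0.5) → (0.2, 0.5) → (0.4, 0.5)`). Adjusted
P-values should therefore be computed once, from raw P-values.

# The synthetic-data generator

The generator exists to make every rule falsifiable, not to model
evolution realistically:

* `evolve_cds()` proposes per-site nucleotide substitutions with
  probability `1 − exp(−b·r)` per branch (branch length `b` in expected
  substitutions per site, rate multiplier `r`) and replaces uniformly;
  with `preserve_frame = TRUE`, proposals creating an internal stop or
  destroying the start/stop are rejected, so codon invariants hold on
  every leaf. No GTR/dN/dS codon model and no indels are simulated.
* `make_transcripts()` wraps coding sequences in uniform-length UTRs
  (default 20–150 nt, long enough to exercise ORF search without
  dominating runtime) and applies per-transcript corruptions — start
  codon destroyed, stop codon mutated to a sense codon, truncation to a
  fraction of the CDS — recording which transcripts remain ORF-valid.
  An in-frame stop is placed at the 5'-UTR/CDS junction so that no
  chance upstream `ATG` can silently extend the embedded ORF; without
  it, recoverability of the planted truth would be probabilistic.
* `plant_unique_substitution()` inverts the scanner's rule: it places a
  focal residue from a chosen group and guarantees (homogenising the
  background column when needed, and recording that) that no other
  species carries that group, emitting a truth record the scanner must
  recover.
* `simulate_counts()` draws negative-binomial counts with expected
  value `library_size · abundance · 2^effect` (effect applied to focal
  samples), gamma-distributed gene abundances, and a single dispersion.
  The NB choice is a test-harness convention — nothing is inferred
  about the distribution of any real dataset.
* **Randomness**: one root seed; every gene/species/branch stream is
  derived by stable string hashing (`derive_seed()`), so adding a gene
  never perturbs the draws of another, and all outputs are pure
  functions of (inputs, seed).

Because the generator omits alignment error, indels, paralogy,
sequencing noise and library-composition effects, green tests certify
the *decision rules* — boundaries, tie-breaks, sensitivity on planted
truth — not performance on real data.

# Problem sizes used in the checks

The bundled verification suite runs at desk scale, chosen so each
property is measured with comfortable margins: 1,000 random 68-species
columns for the scanner-versus-oracle identity; 50 planted
substitutions across 20 twelve-species alignments (sensitivity 1.0
required, with within-group-only background so any extra call is a
failure); 20×20 toy proteomes for reciprocal-best-hit equivalence
against an independent affine-gap DP implementation; a 50-gene fixture
for TMM (1e-9 agreement) and 1,000 random vectors for BH; and 100
simulation seeds for the power property (planted |log2FC| = 5,
dispersion 0.01, 4 vs 4 samples, ≥95% of planted genes flagged; a null
simulation at vanishing dispersion must flag essentially nothing).

# Known limitations

* The built-in scorer is exact dynamic programming: appropriate for
  desk-scale panels, not for transcriptome-scale all-vs-all search —
  use the tabular ingest path for external search results there.
* `approximate_b()` is a decision-rule surrogate, not an
  empirical-Bayes fit; B values from a full hierarchical model should
  be supplied when available.
* The four-group model deliberately collapses physicochemistry into
  four classes; no radical/conservative scoring beyond group
  membership is attempted, and no structural interpretation of calls
  is offered.
* The one-vs-rest contrast treats species as replicates within groups;
  phylogenetic non-independence is not modelled.
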