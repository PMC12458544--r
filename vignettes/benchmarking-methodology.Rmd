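---
title: "Benchmarking peptide-TCR binder predictors: methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking peptide-TCR binder predictors: methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbench)
```

## The evaluation problem

A peptide-TCR binding predictor takes a peptide (an MHC-presented
antigen fragment) and the CDR3 loop of a T-cell receptor chain and
returns a binding score. Experimental data provide almost exclusively
*positive* pairs, so how a benchmark manufactures negatives, and what
question it then asks of the model, largely determines the numbers it
reports. `tcrbench` implements two complementary protocols:

1. **Balanced classification.** For each peptide an equal number of
   non-binding TCRs is drawn, and ROC-AUC / PR-AUC are computed on the
   balanced set. Negatives come from one of two strategies:
   *background-drawing* (uniform draws from a large unrelated
   repertoire, excluding the peptide's known binders) or *reshuffling*
   (permuting the TCR column across the known positive pairs, rejecting
   any permutation that recreates a positive). Because one balanced
   subset is a tiny, high-variance sample of the negative space, the
   protocol repeats the draw over many folds (default 100) with fixed
   positives; the fold seed is `xor(master_seed, fold_id)`, which makes
   fold composition reproducible byte-for-byte.
2. **Virtual screening.** Each peptide is scored against an entire
   repertoire and the question becomes one of *early enrichment*: how
   many of the true binders surface in the top ranks of the full
   ranking. This avoids negative-subsampling bias altogether and is
   closer to how such a model would actually be used to nominate
   candidate TCRs.

Peptides are stratified by the number of known binders into
**majority** (at least 100), **few-shot** (5-100) and **zero-shot**
(fewer than 5) tasks, since generalization behaves very differently in
the three regimes. The 100-binder boundary belongs to the majority
group by default; `group_thresholds(majority_min = 101)` flips it.
Exactly five binders is few-shot.

## Early-enrichment metrics

For one screen, let `N` be the library size, `n` the number of true
binders, and `r_i` their 1-based positions in the descending-score
ranking, with normalized ranks `R_i = (r_i - 1)/(N - 1)`. The default
BEDROC variant (`"relative"`) is

$$\mathrm{BEDROC}_\alpha \;=\; \frac{\alpha}{1-e^{-\alpha}} \cdot
  \frac{1}{n}\sum_{i=1}^{n} e^{-\alpha R_i},$$

an exponentially weighted enrichment whose expectation under a uniform
random ranking is ~1 (for `N >> 1`, since
$E[e^{-\alpha R}] = (1-e^{-\alpha})/\alpha$) and whose maximum, with
every binder at the very top, approaches $\alpha/(1-e^{-\alpha})$ —
about 20 at the default $\alpha = 20$. Read it as a fold enrichment
over random. The classical Truchon-Bayly formulation, bounded to
[0, 1], is available as `variant = "truchon_bayly"`; the two are never
substituted for one another silently. At $\alpha = 20$ the weight
function $e^{-\alpha R}$ places roughly 18% of its mass on the top 1%
of ranks and ~80% within the top 8%, so $\alpha$ should be raised if
only the extreme head of the ranking matters.

Alongside BEDROC the screening evaluator reports enrichment curves
(cumulative fraction of binders recovered vs fraction of the list
examined), hit rates (fraction of a peptide's binders in the top `k`)
and success rates. "Success rate" has no unique definition in the
literature; this package adopts the virtual-screening convention —
the fraction of query peptides with at least one true binder in the
top `k` — and labels it as an interpretation. Ties in scores are
broken by library position, a fixed deterministic policy shared by the
ranking and the PR-AUC prefix order.

ROC-AUC is computed by the rank-sum (Mann-Whitney) identity with ties
counted one half; PR-AUC is step-wise average precision. Both are
cross-checked in the test suite against brute-force enumeration
oracles. A subtlety worth knowing: under a random ranking the
*expectation* of average precision is slightly above the positive
prevalence at finite `n`/`N` (about 0.0059 vs 0.005 at `n = 50`,
`N = 10{,}000`); the calibration tests therefore compare against the
exact permutation-null expectation rather than the asymptotic value.

## Negative-sampling strategies and what they measure

Reshuffled negatives reuse TCRs that are genuine binders *of some
peptide*, so a model that has memorized "this TCR appears with positive
labels" is punished with false positives; background negatives are
overwhelmingly irrelevant sequences, which such a model rejects easily.
The package ships a `tcr_memorization` reference scorer that
operationalizes exactly this failure mode, and the acceptance suite
verifies the expected signature: inflated false-positive rate and
near-random ROC-AUC under reshuffling, near-perfect discrimination
under background-drawing. Conversely, reshuffling can mislabel genuinely
cross-reactive binders as negatives; background-drawing cannot exclude
unknown cross-reactive TCRs either. Neither bias is "solved" here —
the framework makes the two strategies cheap to run side by side so the
gap itself becomes an observable.

## Screening library construction

Each peptide is screened against the background repertoire augmented
with that peptide's own query binders (deduplicated), so every screen
contains its full truth set and `N` is essentially the repertoire
size. The alternative — pooling *all* tasks' binders into one shared
library — was rejected as the default because, on synthetic data,
another peptide's planted binder can match a query motif by chance and
silently break the exact ground-truth guarantee that the oracle-ceiling
tests rely on (and on real data it conflates "non-binder" with
"binder of another peptide", which is precisely the cross-reactivity
ambiguity discussed above). `screen_all(per_task_library = FALSE)`
restores the pooled behaviour. Scores are materialized for one peptide
at a time and immediately reduced to binder ranks; chunked scoring
(default chunk 10,000) guarantees identical rankings for any chunk
size, so the same contract scales from toy fixtures to repertoires of
tens of millions of sequences without retaining `N x peptides` scores.

## The synthetic generator

`generate_dataset()` emulates the structure the real benchmarks have:
a multi-peptide positive table with heavy-tailed binder counts spanning
all three groups (defaults: 5 majority peptides with 100-150 binders,
15 few-shot with 5-99, 10 zero-shot with 1-4), plus a large disjoint
background repertoire (default 10,000 sequences; lengths 12-20 for
CDR3s, 8-15 for peptides). Each peptide carries a hidden length-5
motif; binder CDR3s embed the motif with at most one substitution, and
the ground-truth affinity of any pair is the best sliding-window match
fraction between CDR3 and motif, so a pair is a binder iff affinity
reaches `(motif_length - motif_mismatch)/motif_length = 0.8`.

Two deliberate artificialities make the truth *exact* rather than
probabilistic. First, every motif contains `motif_mismatch + 1`
tryptophan anchors while background sequences are drawn from the
19-letter alphabet without W: no background sequence can ever reach the
binder threshold, so labels regenerate perfectly from the affinity
function and the repertoire is provably disjoint from every binder
set. Second, the affinity is a transparent Hamming-style motif match
rather than a learned landscape. Consequently, passing tests
demonstrate that the *evaluation machinery* is correct and calibrated
— they say nothing about how hard real TCR data are, where motifs
overlap, cross-reactivity is real, and negatives are never certain.
V/J-recombination realism is out of scope by design.

For paired-chain fixtures (`chains = "alphabeta"`) each peptide gets an
independent motif per chain, so both chains carry signal and
late-fusion averaging (`fuse_alpha_beta()`, the element-wise mean) can
be tested meaningfully against the single-chain baselines.

Synthetic scorers close the loop: `oracle` (true affinity — the
ceiling), `noisy_oracle` (affinity plus deterministic pseudo-Gaussian
noise; the noise dial demonstrably degrades ROC-AUC monotonically),
`random` (the calibration null) and `tcr_memorization` (described
above). All are pure functions of (seed, peptide, TCR) via a keyed
string hash, which is what makes chunked screening bit-reproducible
even for the "stochastic" scorers.

## Numerical and design choices

* **Seeds.** Every stochastic step takes an explicit integer seed and
  restores the RNG state afterwards (`withr::with_seed`), so library
  users never get their session RNG silently advanced. Fold seeds
  derive from the master seed by XOR with the fold id.
* **Reshuffling algorithm.** Up to 20 whole permutations are tried;
  the best is then repaired by greedy pairwise swaps, and only
  irreparable collisions (possible when one peptide dominates the
  positive table) are dropped with a warning. The TCR multiset of the
  positives is preserved up to those drops.
* **Classification threshold.** Confusion counts use a fixed 0.5
  threshold on scores normalized to [0, 1]; scorers producing values
  outside that range are min-max normalized per fold. AUCs are
  rank-based and unaffected by the normalization.
* **Group-level BEDROC** is the mean of per-peptide screen BEDROCs;
  `pooled_bedroc = TRUE` additionally reports the pooled-ranks variant
  since the aggregation convention differs between studies.
* **Quality-control defaults** in the curation module (amino-acid
  alphabet, CDR3 length >= 8) are a labelled reconstruction of common
  practice, not a canonical rule set; every rule is configurable and
  reported with per-rule removal counts.
* **Degenerate inputs** fail loudly: BEDROC is undefined for screens
  with no binders or `N = 1`; reshuffling is undefined with a single
  peptide; background draws error with required-vs-available counts
  when the repertoire is too small.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
so the full suite completes in a few minutes on one CPU: BEDROC
fidelity on 1,000 random instances up to `N = 100{,}000`; calibration
on a 10,000-sequence library with 50 binders over 2,000 random
screens; the negative-sampling-gap experiment on 20 peptides against a
100,000-sequence repertoire across 10 generator seeds; 100-fold
balance checks on a 1,000-sequence repertoire. The same code paths
scale to repertoire sizes limited only by memory for one score vector
per peptide (`O(N)` doubles) because of the streaming chunk contract.

## Known limitations

* The generator's exact-truth construction (reserved anchor letter)
  means synthetic backgrounds are slightly less diverse than real
  repertoires; calibration results transfer, difficulty estimates do
  not.
* Reshuffling with very few distinct peptides may not admit a full
  derangement; the implementation then returns fewer negatives than
  positives with a warning rather than fabricating pairs.
* The framework evaluates scorers; it trains nothing. Retraining-style
  protocols are represented by the peptide-level fold split
  (`make_peptide_folds()`) and by accepting one score table per
  retrained model.
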