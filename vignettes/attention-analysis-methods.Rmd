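---
title: "Methods: attention analysis of an RBP-binding sequence classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention analysis of an RBP-binding sequence classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpattn)
```

## The problem and the model

Enhanced CLIP (eCLIP) experiments yield, per RNA-binding protein (RBP),
genomic peaks that can be rendered as fixed-length bound sequences —
101 nt with the read peak at the center — alongside matched unbound
negatives from the same transcripts. `rbpattn` treats binding prediction as
binary sequence classification with a transformer encoder over overlapping
k-mer tokens, and treats the trained encoder's attention weights as the
object of scientific interest: which heads specialize for transcript-region
context, for secondary-structure states, and for binding motifs.

The encoder is a standard pre-LN-free (post-layer-norm) BERT-style stack:
token ids (five special tokens, then the `4^k` k-mers in lexicographic
order) are embedded, summed with learned positional embeddings, layer
normalized, and passed through `n_layers` blocks of multi-head scaled
dot-product self-attention plus a ReLU feed-forward sublayer, each with a
residual connection and layer norm. The final-layer `CLS` vector passes a
tanh pooler and a logistic head. Training minimizes binary cross-entropy
with Adam (decoupled weight decay on matrices, linear warmup then linear
decay). Both forward and backward passes are implemented in the package in
plain matrix arithmetic; gradients are verified against numerical
differentiation in the test suite. Everything is deterministic given the
seeds in `encoder_config()` and `training_settings()`.

Two geometries matter:

* the *reference* scale, 12 layers × 12 heads × 768 hidden — constructible,
  and the scale at which head grids have 144 cells;
* the *desk* scale used by every test and example, 2 × 2 × 32, which trains
  in about a minute on 1,280 101-nt sequences on one CPU.

The published hyperparameters of the original fine-tuning runs are not
reproduced here; optimizer settings are ordinary fine-tuning defaults
(peak learning rate 2e-3 for the desk scale, batch 32, 10% warmup) and are
recorded in every trained provider. They are configuration, not science.

## Dataset preparation rules

`clean_sequences()` removes records with non-ACGTU characters (unannotated
genome content) and within-class duplicate sequences; cleaning is
idempotent and cross-class duplicates are kept, since positives and
negatives are distinct observations. `sample_dataset()` caps each class at
15,000 (undersized classes are kept whole; an optional
cluster-representative id list supports externally computed redundancy
reduction). `split_dataset()` partitions 64/16/20 into train/eval/test with
largest-remainder rounding, stratified by label — stratification is this
package's choice, guaranteeing balanced test sets; the non-training set
(`build_non_training()`) is everything outside train and eval and is the
substrate for attention analyses.

## Attention statistics

For one head, attention is a row-stochastic `(L+2) × (L+2)` matrix; rows
are upper-layer tokens (the attender), columns lower-layer tokens. The
sequence-level statistic `s_α(f)` divides the mean total attention received
by the `CLS` column in property-positive sequences by the same mean in
property-negative sequences. The numerator's inner sum deliberately runs
over all `L + 2` rows including `CLS` and `SEP`. The default background is
the property-negative group; a whole-dataset background is exposed as an
option (`background = "all"`) and off by default, because the ratio against
the complement is the sharper contrast and is the reading consistent with
the indicator-weighted denominator. Degenerate indicators (all 0 or all 1)
raise an error rather than returning a ratio that means nothing.

The token-level statistic `t_α(g)` is the fraction of attention mass
landing on property-carrying tokens, with `CLS`/`SEP` excluded from both
axes. Under uniform attention it reduces exactly to the token frequency of
the property, and across mutually exclusive exhaustive labels it sums to 1
per head — both are asserted in the tests, along with agreement to naive
triple-loop references at 1e-10.

For the per-token "raw attention" used in structure curves we sum the
column of a token over sequence-token rows (attention *received*). A
literal row-sum reading would be identically 1 after normalization and
carry no information, so the received-attention reading is the only
meaningful one; it is implemented as such.

Head-specialization is the coefficient of variation (sample sd / mean, in
percent) over the head grid; it is scale-invariant, so it compares models
whose absolute attention levels differ. Kendall's tau-b (tie-corrected)
compares two grids; constant grids raise an error instead of returning 0.
`attention_structure_curve()` pools raw token attention, drops values above
the 99.5th percentile (linear-interpolation quantile; "within the
percentile" read as ≤ the percentile value) because the upper tail is
sparse, bins the rest into equal-width bins (count-balanced binning would
be a trivial variant), and reports per-bin property probabilities with a
dispersion estimated from random equal splits of the sequences (3 by
default).

## Loop-type labels

Dot-bracket structures are parsed with a stack (pseudoknots and extended
alphabets rejected — the consumed structures are MEA predictions, which are
nested). Each position gets one of six states: paired → `S`; unpaired
before the first / after the last paired base → `F` / `T`; an unpaired run
inside a loop closed by exactly one pair → `H` (hairpin; minimum 3 by
construction of the inputs), by exactly two pairs → `I` (internal loops and
bulges), by three or more → `M`. Two conventions had to be fixed where the
six-letter alphabet is silent: exterior unpaired runs *between* stems at
the outermost level are labeled `M` (junction semantics — the closest of
the six states; there is no exterior-loop letter), and a structure with no
pairs at all is all `F`. Both are documented choices, asserted in tests,
and cross-checked against an independently written brute-force classifier
on random structures. A token carries a structure property when any of its
k nucleotides does; this indicator is monotone in the labeled set.

## Motif extraction

Per positive test sequence, attention from the `CLS` row to each sequence
token is accumulated (summed) over all final-layer heads. Maximal runs of
tokens strictly above the per-sequence mean profile form candidate regions
— the threshold is not printed anywhere authoritative, and the per-sequence
mean is the convention of the upstream nucleotide-BERT motif utility this
pipeline adapts. A token run `[a, b]` covers nucleotides `[a, b + k)`;
spans under 6 nt are discarded and spans over 10 nt are truncated to the
10-nt window of highest summed attention (leftmost on ties; truncation
rather than extension keeps candidates inside the attended region).
Candidates are tested for enrichment in positives with the upper-tail
hypergeometric law on per-sequence presence/absence counts (p < 0.005
keeps), then greedily merged: best ungapped offset alignment, merge when
matches ≥ 70% of the shorter length (both knobs config-exposed), instances
pooled, the most-instantiated member's consensus representing the motif.
Aligned instances yield position frequency matrices and MEME-format output.

## The synthetic-data generator

`simulate_rbp_dataset()` emulates the benchmark geometry: 101-nt sequences,
positives carrying a consensus motif (default 7 nt, exact copies unless a
per-position mutation rate is set) implanted so its center falls within
±10 nt of the sequence center — mirroring peak-centered reads — in 90% of
positives by default. The 0.9 default reflects that most but not all bound
reads contain the consensus; it also sets the Bayes ceiling for AUROC at
1 − 0.1/2 = 0.95, since motif-free positives are indistinguishable from
negatives by construction. Negatives (and positive backbones) are i.i.d.
uniform A/C/G/T; a Markov background is deliberately not the default, so
test outcomes are attributable to the implanted signal. Region flags are
independent Bernoulli draws per region type with per-class rates — they
emulate annotation flags but are *not* derivable from the sequence, so they
exercise indicator plumbing, not model learning; when a sequence-derived
property is needed (the specialization contrast), motif presence itself is
the property.

Structures are generated by random pair insertion into free intervals with
a minimum 3-nt hairpin gap and a 70% helix-stacking move, which keeps
structures well-formed and non-crossing, guarantees legal hairpins, and
makes the expected paired fraction track the `stem_density` parameter (to
within the feasibility limits near 1) — no folding engine is reimplemented,
and real dot-brackets can be supplied instead. `simulate_attention()`
draws attention rows from a uniform simplex and plants specializations by
multiplying the `CLS` column (sequence-level) or property-token columns
(token-level) by `1 + effect` before renormalizing; effect 0 is exactly the
null. These tensors are the oracle fixtures for the head statistics.

What passing on these synthetics does *not* show: robustness to
composition bias, to crosslink-site artifacts, to correlated
region/structure/label confounding, or to motif families rather than a
single consensus. The generator is a contract checker, not an eCLIP
simulator.

## Numerical and design notes

* Attention rows sum to 1 within 1e-5 by contract (softmax makes them
  exact to rounding); padding never enters any analysis because tensors
  are extracted at each sequence's true length.
* The hypergeometric implementation is `stats::phyper`; the test oracle
  sums the pmf in exact integer arithmetic (all binomials for N ≤ 30 are
  exact in doubles).
* AUROC is the tie-corrected rank statistic, checked against brute-force
  pair enumeration and pROC.
* Head-grid argmax ties break toward the lowest layer, then lowest head;
  reports use 1-based (layer, head) naming.
* Attention archives are RDS files (plus a long-format TSV export); the
  analyses run identically from an archive with no live model.
* Replicate counts are parameters: the structure-curve dispersion uses 3
  subsets, the specialization contrast 5 seeds, by default.

## Problem sizes used by the test suite

The suite trains the 2 × 2 × 32 encoder on 1,280 training sequences (from
1,000 + 1,000 at the default split) for the motif-recovery and AUROC
checks, and five 300 + 300 replicates for 8 epochs for the specialization
contrast — by which point the tiny model is genuinely fine-tuned (held-out
AUROC ≈ 0.92–0.96) rather than marginally perturbed, which is the regime
the contrast is about. Oracle-agreement checks use 100 random 3-sequence,
5-token instances. These sizes are the package's chosen desk scale: small
enough to run anywhere, large enough that every assertion measures signal
rather than noise.

## Known limitations

The encoder trains from random initialization in all tests; importing
externally pretrained nucleotide-BERT weights is supported through the
documented checkpoint name mapping but not exercised against real
checkpoints here. Pseudoknotted structures are rejected, not flattened.
The motif merger is greedy and ungapped; families of gapped or highly
degenerate motifs will fragment. The synthetic generator's independence
assumptions are stated above. Full-scale (12 × 12 × 768) training is
architecturally supported but not practical in plain R; the package's
claims at that scale are limited to construction and analysis of supplied
attention tensors.
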