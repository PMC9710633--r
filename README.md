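# rbpattn

Prediction and attention-based interpretation of RNA–protein binding from
sequence.

RNA-binding proteins (RBPs) recognize short sequence and structure features
on their target transcripts. Given eCLIP-style data — fixed-length RNA
sequences labeled bound (peak-centered positives) or unbound (matched
negatives) — `rbpattn` trains a k-mer-tokenized transformer-encoder
classifier and then asks *what the model learned* by reading its attention
weights. The package is aimed at computational biologists who want the whole
loop — data preparation, training, attention analysis, motif extraction —
runnable at desk scale on a single CPU, with a synthetic-data module that
generates every input the pipeline needs.

## The model and the statistics

A sequence of length `n` is tokenized into `L = n − k + 1` overlapping
k-mers (default `k = 3`) flanked by `CLS` and `SEP`; the final-layer `CLS`
vector feeds a logistic head that scores binding probability, evaluated by
AUROC. Each attention head emits row-normalized weights `α[i, j]` (upper
token `i` attends to lower token `j`, rows summing to 1). Two head-level
statistics drive the interpretation:

- **Relative attention to CLS** for a sequence-level property `f` (e.g.
  "overlaps a 3′UTR"):

      s_α(f) = mean over f=1 sequences of Σ_i α[i, CLS]
               ───────────────────────────────────────────
               mean over f=0 sequences of Σ_i α[i, CLS]

- **Attention ratio** for a token-level property `g` (e.g. "token touches a
  hairpin-loop base", from six-state loop labels F/T/I/H/M/S of a
  dot-bracket structure):

      t_α(g) = Σ_n Σ_i Σ_j g(n,j) α[i,j] / Σ_n Σ_i Σ_j α[i,j]

  summed over sequence tokens only.

Across the layers × heads grid (144 heads at the full 12 × 12 scale) the
coefficient of variation of `s_α` measures head specialization, Kendall's
tau-b compares specialization patterns between models, and per-head
attention-versus-structure-probability curves (99.5-percentile filtered)
localize what a head responds to. Motifs are extracted by accumulating
final-layer CLS attention per token, taking 6–10 nt high-attention regions
from positive test sequences as candidates, keeping those enriched in
positives (hypergeometric p < 0.005), and merging similar candidates by
ungapped pairwise alignment into position frequency matrices.

## Worked example

```r
library(rbpattn)

spec  <- synthetic_spec(n_pos = 1000, n_neg = 1000, seed = 11)  # 101-nt reads
sim   <- simulate_rbp_dataset(spec)                 # motif TGCATGG near center
split <- split_dataset(sim$set, seed = 11)          # 64/16/20
vocab <- build_vocabulary(3)
tok   <- lapply(sim$set$sequence, tokenize, vocab = vocab)
y     <- as.integer(sim$set$label == "positive")

tr <- split$partition == "train"; te <- split$partition == "test"
prov <- train_classifier(tok[tr], y[tr],
                         config = encoder_config(seed = 11),     # 2x2x32
                         settings = training_settings(epochs = 4, seed = 11))
evaluate_auroc(predict_binding(prov, tok[te]), y[te])
#> [1] 0.934775

pos <- te & y == 1; neg <- te & y == 0
ds  <- attention_dataset(extract_attention(prov, tok[pos]), tok[pos])
res <- extract_motifs(ds, sim$set$sequence[neg])
res$motifs[[1]]$consensus ; res$motifs[[1]]$p_value
#> [1] "TGCATGG"
#> [1] 1.051058e-92
```

The tiny 2-layer model reaches AUROC ≈ 0.93 on held-out data (the ceiling is
0.95 because 10% of positives carry no motif), and the top extracted motif
is exactly the implanted consensus, enriched at p ≈ 1e-92.

A command-line front end covering `simulate`, `prepare`, `train`,
`predict`, `analyze-regions`, `analyze-structure`, `extract-motifs` and
`report` is installed at `exec/rbpattn` (see `rbpattn_cli()`).

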