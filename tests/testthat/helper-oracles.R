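# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms (triple loops, brute-force pair
# enumeration, exact integer arithmetic) and share no code with R/.

# Eq-style sequence-level relative attention: naive loops over sequences and
# rows. tensors: list of (layers, heads, T, T) arrays; f: 0/1 per sequence.
oracle_relative_attention <- function(tensors, f, layer, head) {
  cls <- numeric(length(tensors))
  for (n in seq_along(tensors)) {
    a <- tensors[[n]]
    s <- 0
    for (i in seq_len(dim(a)[3])) s <- s + a[layer, head, i, 1]
    cls[n] <- s
  }
  mean(cls[f == 1]) / mean(cls[f == 0])
}

# Token-level attention ratio: naive triple loop, sequence tokens only.
oracle_attention_ratio <- function(tensors, g, layer, head) {
  num <- 0; den <- 0
  for (n in seq_along(tensors)) {
    a <- tensors[[n]]
    L <- dim(a)[3] - 2
    for (i in seq_len(L)) for (j in seq_len(L)) {
      w <- a[layer, head, i + 1, j + 1]
      den <- den + w
      if (g[[n]][j] == 1) num <- num + w
    }
  }
  num / den
}

# Attention received per token: naive double loop.
oracle_raw_token_attention <- function(tensor, layer, head) {
  L <- dim(tensor)[3] - 2
  out <- numeric(L)
  for (j in seq_len(L)) for (i in seq_len(L))
    out[j] <- out[j] + tensor[layer, head, i + 1, j + 1]
  out
}

# CLS-attention profile: naive loop over final-layer heads.
oracle_cls_profile <- function(tensor) {
  d <- dim(tensor)
  L <- d[3] - 2
  out <- numeric(L)
  for (h in seq_len(d[2])) for (j in seq_len(L))
    out[j] <- out[j] + tensor[d[1], h, 1, j + 1]
  out
}

# Upper-tail hypergeometric probability by exact pmf summation. All binomial
# coefficients involved are integers below 2^53 for N <= 30, so the sum is
# exact in double arithmetic.
oracle_hyper_upper <- function(x, K, N, n) {
  lo <- max(x, 0, n - (N - K))
  hi <- min(K, n)
  if (lo > hi) return(0)
  s <- 0
  for (i in lo:hi) s <- s + choose(K, i) * choose(N - K, n - i)
  s / choose(N, n)
}

# Kendall tau-b by exhaustive pair enumeration.
oracle_kendall <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; Ta <- 0; Tb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- sign(a[j] - a[i]); db <- sign(b[j] - b[i])
    if (da == 0 && db == 0) next
    if (da == 0) Ta <- Ta + 1
    else if (db == 0) Tb <- Tb + 1
    else if (da == db) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Ta) * (C + D + Tb))
}

# AUROC by brute-force positive/negative pair comparison.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Per-base brute-force interval overlap (0-based half-open coordinates).
oracle_overlaps <- function(chrom, start, end, strand, ann) {
  for (r in seq_len(nrow(ann))) {
    if (ann$chrom[r] != chrom) next
    if (ann$strand[r] %in% c("+", "-") && strand %in% c("+", "-") &&
        ann$strand[r] != strand) next
    for (b in seq(start, end - 1)) {
      if (b >= ann$start[r] && b < ann$end[r]) return(1L)
    }
  }
  0L
}

# Independent loop-type classifier: brute-force enclosing-pair search per
# unpaired position (no stacks, no parent bookkeeping).
oracle_loop_labels <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") open <- c(open, i)
    if (ch[i] == ")") {
      partner[i] <- open[length(open)]
      partner[open[length(open)]] <- i
      open <- open[-length(open)]
    }
  }
  pairs <- cbind(p = which(ch == "("), q = partner[which(ch == "(")])
  lab <- rep(NA_character_, n)
  lab[!is.na(partner)] <- "S"
  if (nrow(pairs) == 0) return(paste(rep("F", n), collapse = ""))
  encl <- function(i) {
    cand <- pairs[pairs[, 1] < i & pairs[, 2] > i, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand[which.max(cand[, 1]), ]
  }
  # top-level child pairs of pair (p, q): pairs inside with no pair between
  n_children <- function(p, q) {
    inside <- pairs[pairs[, 1] > p & pairs[, 2] < q, , drop = FALSE]
    cnt <- 0
    for (r in seq_len(nrow(inside))) {
      a <- inside[r, 1]; b <- inside[r, 2]
      outer_exists <- any(inside[, 1] < a & inside[, 2] > b)
      if (!outer_exists) cnt <- cnt + 1
    }
    cnt
  }
  for (i in which(is.na(lab))) {
    e <- encl(i)
    if (is.null(e)) {
      before <- any(pairs[, 2] < i)
      after <- any(pairs[, 1] > i)
      lab[i] <- if (!before) "F" else if (!after) "T" else "M"
    } else {
      closing <- 1 + n_children(e[1], e[2])
      lab[i] <- if (closing == 1) "H" else if (closing == 2) "I" else "M"
    }
  }
  paste(lab, collapse = "")
}

# Small random attention dataset (valid row-normalized tensors) for oracle
# comparisons. Returns list(tensors, tokenized, f, g).
make_random_attention <- function(N = 3, L = 5, n_layers = 2, n_heads = 2,
                                  seed = 1) {
  set.seed(seed)
  T_ <- L + 2
  vocab <- build_vocabulary(3)
  tokenized <- lapply(seq_len(N), function(i)
    tokenize(paste(sample(c("A", "C", "G", "T"), L + 2, TRUE),
                   collapse = ""), vocab))
  tensors <- lapply(seq_len(N), function(i) {
    a <- array(rexp(n_layers * n_heads * T_ * T_), c(n_layers, n_heads, T_, T_))
    for (l in seq_len(n_layers)) for (h in seq_len(n_heads)) {
      m <- matrix(a[l, h, , ], T_, T_)
      a[l, h, , ] <- m / rowSums(m)
    }
    a
  })
  f <- c(1, rep(0, N - 1))
  if (N > 1) f[seq_len(max(1, floor(N / 2)))] <- 1
  g <- replicate(N, rbinom(L, 1, 0.5), simplify = FALSE)
  list(tensors = tensors, tokenized = tokenized, f = f, g = g)
}

# Tiny trained-model fixture shared by model tests: short sequences with a
# planted 5-mer so training converges in a few seconds.
make_tiny_training_problem <- function(n = 60, len = 21, motif = "GGTAC",
                                       seed = 4) {
  spec <- synthetic_spec(n_pos = n / 2, n_neg = n / 2, seq_len = len,
                         motif = motif, implant_rate = 1,
                         implant_halfwidth = 4, seed = seed)
  sim <- simulate_rbp_dataset(spec)
  set.seed(seed)
  perm <- sample(nrow(sim$set))  # interleave classes for index-based splits
  sim$set <- sim$set[perm, ]
  vocab <- build_vocabulary(3)
  list(tok = lapply(sim$set$sequence, tokenize, vocab = vocab),
       y = as.integer(sim$set$label == "positive"),
       set = sim$set, vocab = vocab)
}
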