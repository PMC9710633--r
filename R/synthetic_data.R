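#' Specification of a synthetic RBP-binding dataset
#'
#' Describes the geometry the generated data emulates: fixed-length
#' sequences (101 nt, the eCLIP peak window with the read peak at the
#' center), a consensus binding motif implanted near the center of most
#' positives, background sequences for negatives, and per-region-type
#' Bernoulli flag rates.
#'
#' @param n_pos,n_neg class sizes.
#' @param seq_len sequence length in nucleotides (default 101).
#' @param motif consensus string implanted into positives (default a 7-nt
#'   consensus).
#' @param mutation_rate per-position probability that an implanted motif base
#'   is replaced by a random base.
#' @param implant_rate fraction of positive sequences carrying the motif
#'   (default 0.9: most, but not all, bound sequences carry the consensus).
#' @param implant_halfwidth the motif center is drawn uniformly within this
#'   many nucleotides of the sequence center (default 10).
#' @param background base probabilities for A, C, G, T (default uniform).
#' @param region_rates named list of per-region-type Bernoulli rates, each a
#'   `c(pos =, neg =)` pair; defaults are label-independent.
#' @param stem_density expected paired fraction for generated structures.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 1000L, n_neg = 1000L, seq_len = 101L,
                           motif = "TGCATGG", mutation_rate = 0,
                           implant_rate = 0.9, implant_halfwidth = 10L,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           region_rates = list(
                             five_prime_utr = c(pos = 0.1, neg = 0.1),
                             three_prime_utr = c(pos = 0.3, neg = 0.3),
                             intron = c(pos = 0.5, neg = 0.5),
                             cds = c(pos = 0.3, neg = 0.3)),
                           stem_density = 0.5, seed = 1L) {
  stopifnot(implant_rate >= 0, implant_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            nchar(motif) <= seq_len, stem_density >= 0, stem_density <= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seq_len = as.integer(seq_len), motif = toupper(motif),
                 mutation_rate = mutation_rate, implant_rate = implant_rate,
                 implant_halfwidth = as.integer(implant_halfwidth),
                 background = background / sum(background),
                 region_rates = region_rates, stem_density = stem_density,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_sequences <- function(n, len, background) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(bases, len, replace = TRUE, prob = background),
          collapse = ""), character(1))
}

#' Simulate an RBP-binding sequence dataset
#'
#' Positives are background sequences of length `seq_len` with the consensus
#' motif implanted (after per-position mutation) at a uniform position whose
#' center lies within `implant_halfwidth` of the sequence center, in
#' `implant_rate` of them; negatives are pure background. Region-type flags
#' are drawn from the per-class Bernoulli rates. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `set` (data.frame `id`, `sequence`, `label`),
#'   `region_flags` (data.frame of 0/1 flags per region type, rows aligned
#'   with `set`), and `motif_start` (0-based implant position per sequence,
#'   NA when absent).
#' @export
simulate_rbp_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- nchar(spec$motif)
  half_lo <- floor((spec$seq_len - 1) / 2) - spec$implant_halfwidth
  lo <- max(0L, half_lo - floor(w / 2))
  hi <- min(spec$seq_len - w,
            floor((spec$seq_len - 1) / 2) + spec$implant_halfwidth -
              floor(w / 2))
  if (hi < lo) stop("motif does not fit inside the implant window")
  local_rng(spec$seed)
  n <- spec$n_pos + spec$n_neg
  seqs <- random_sequences(n, spec$seq_len, spec$background)
  label <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  motif_start <- rep(NA_integer_, n)
  bases <- c("A", "C", "G", "T")
  carry <- which(stats::runif(spec$n_pos) < spec$implant_rate)
  for (i in carry) {
    m <- strsplit(spec$motif, "")[[1L]]
    mut <- stats::runif(w) < spec$mutation_rate
    if (any(mut))
      m[mut] <- sample(bases, sum(mut), replace = TRUE)
    pos <- if (hi > lo) sample(lo:hi, 1L) else lo
    substr(seqs[i], pos + 1L, pos + w) <- paste(m, collapse = "")
    motif_start[i] <- pos
  }
  flags <- lapply(spec$region_rates, function(r)
    as.integer(stats::runif(n) <
                 ifelse(label == "positive", r[["pos"]], r[["neg"]])))
  list(set = data.frame(id = sprintf("seq%05d", seq_len(n)),
                        sequence = seqs, label = label,
                        stringsAsFactors = FALSE),
       region_flags = as.data.frame(flags),
       motif_start = motif_start)
}

#' Simulate well-formed dot-bracket secondary structures
#'
#' Generates non-crossing structures by repeatedly inserting base pairs into
#' randomly chosen free intervals until the target paired fraction is
#' reached; every insertion keeps at least 3 nucleotides between a pair's
#' ends, so each hairpin loop has >= 3 unpaired bases. The expected paired
#' fraction approximates `stem_density` (up to the 2-nucleotide granularity
#' of a pair and feasibility near 1). Deterministic given the seed.
#'
#' @param sequences character vector (only lengths are used).
#' @param stem_density target paired fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return data.frame `id`, `sequence`, `dot_bracket`.
#' @export
simulate_structures <- function(sequences, stem_density = 0.5, seed = 1L) {
  stopifnot(stem_density >= 0, stem_density <= 1)
  local_rng(seed)
  db <- vapply(sequences, function(s) {
    n <- nchar(s)
    target_pairs <- round(stem_density * n / 2)
    ch <- rep(".", n)
    free <- list(c(1L, n))
    pairs <- 0L
    while (pairs < target_pairs) {
      ok <- vapply(free, function(iv) iv[2L] - iv[1L] >= 4L, logical(1))
      if (!any(ok)) break
      lens <- vapply(free[ok], function(iv) iv[2L] - iv[1L] + 1L, integer(1))
      pick <- which(ok)[sample.int(sum(ok), 1L, prob = lens)]
      iv <- free[[pick]]
      if (stats::runif(1) < 0.7) {
        # stack onto the interval bounds: grows helices without fragmenting
        # the free space, which is what lets high target densities be reached
        i <- iv[1L]; j <- iv[2L]
      } else {
        i <- iv[1L] + sample.int(iv[2L] - 4L - iv[1L] + 1L, 1L) - 1L
        j <- (i + 4L) + sample.int(iv[2L] - (i + 4L) + 1L, 1L) - 1L
      }
      ch[i] <- "("; ch[j] <- ")"
      pairs <- pairs + 1L
      free[[pick]] <- NULL
      if (i - 1L >= iv[1L]) free[[length(free) + 1L]] <- c(iv[1L], i - 1L)
      if (j - 1L >= i + 1L) free[[length(free) + 1L]] <- c(i + 1L, j - 1L)
      if (iv[2L] >= j + 1L) free[[length(free) + 1L]] <- c(j + 1L, iv[2L])
    }
    paste(ch, collapse = "")
  }, character(1))
  data.frame(id = if (!is.null(names(sequences))) names(sequences) else
               sprintf("structure%05d", seq_along(sequences)),
             sequence = unname(sequences), dot_bracket = unname(db),
             stringsAsFactors = FALSE)
}

#' Specification of planted attention tensors
#'
#' @param n_layers,n_heads attention grid shape.
#' @param L sequence tokens per sequence.
#' @param N number of sequences.
#' @param planted list of planted specializations; each a list with `layer`,
#'   `head`, `level` (`"sequence"` or `"token"`), `effect` (>= 0; 0 means no
#'   planting).
#' @param seed RNG seed.
#' @return a `planted_attention_spec` list.
#' @export
planted_attention_spec <- function(n_layers = 2L, n_heads = 2L, L = 20L,
                                   N = 30L, planted = list(), seed = 1L) {
  for (p in planted) {
    stopifnot(p$layer >= 1, p$layer <= n_layers,
              p$head >= 1, p$head <= n_heads, p$effect >= 0,
              p$level %in% c("sequence", "token"))
  }
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), L = as.integer(L),
                 N = as.integer(N), planted = planted,
                 seed = as.integer(seed)),
            class = "planted_attention_spec")
}

#' Simulate attention tensors with planted head specializations
#'
#' Unplanted heads draw every row of the attention matrix from a symmetric
#' Dirichlet (uniform simplex) distribution. A token-level planted head
#' multiplies the columns of property-flagged tokens by `1 + effect` before
#' renormalizing its rows; a sequence-level planted head multiplies the CLS
#' column by `1 + effect` for property-positive sequences. Rows always
#' renormalize to 1.
#'
#' @param spec a [planted_attention_spec()].
#' @param f sequence-level 0/1 indicator of length N (generated Bernoulli(0.5)
#'   when NULL and a sequence-level head is planted).
#' @param g list of token-level 0/1 vectors of length L (generated
#'   Bernoulli(0.5) when NULL and a token-level head is planted).
#' @return an [attention_dataset()] carrying `f` and `g`.
#' @export
simulate_attention <- function(spec, f = NULL, g = NULL) {
  stopifnot(inherits(spec, "planted_attention_spec"))
  local_rng(spec$seed)
  N <- spec$N; L <- spec$L; T_ <- L + 2L
  if (is.null(f)) f <- stats::rbinom(N, 1L, 0.5)
  if (is.null(g)) g <- replicate(N, stats::rbinom(L, 1L, 0.5),
                                 simplify = FALSE)
  if (length(f) != N) stop("f length must equal N")
  if (length(g) != N || any(lengths(g) != L))
    stop("g must hold N vectors of length L")
  vocab <- build_vocabulary(3L)
  tokenized <- lapply(random_sequences(N, L + 2L, rep(0.25, 4)), tokenize,
                      vocab = vocab)
  tensors <- vector("list", N)
  for (n in seq_len(N)) {
    a <- array(stats::rexp(spec$n_layers * spec$n_heads * T_ * T_),
               c(spec$n_layers, spec$n_heads, T_, T_))
    for (p in spec$planted) {
      boost <- 1 + p$effect
      if (p$level == "token") {
        cols <- which(g[[n]] == 1L) + 1L
        if (length(cols))
          a[p$layer, p$head, , cols] <- a[p$layer, p$head, , cols] * boost
      } else if (f[n] == 1L) {
        a[p$layer, p$head, , 1L] <- a[p$layer, p$head, , 1L] * boost
      }
    }
    # renormalize each (layer, head) row
    for (l in seq_len(spec$n_layers)) for (h in seq_len(spec$n_heads)) {
      m <- matrix(a[l, h, , ], T_, T_)
      a[l, h, , ] <- m / rowSums(m)
    }
    tensors[[n]] <- a
  }
  attention_dataset(tensors, tokenized, f = f, g = g)
}
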