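test_that("CLS profile accumulates final-layer heads over sequence tokens", {
  one <- array(1 / 5, c(1, 1, 5, 5))
  expect_equal(cls_attention_profile(one), rep(0.2, 3))
  two <- array(1 / 5, c(1, 2, 5, 5))
  expect_equal(cls_attention_profile(two), rep(0.4, 3))
  for (seed in 1:5) {
    r <- make_random_attention(N = 1, L = 6, n_layers = 3, n_heads = 2,
                               seed = seed)
    expect_equal(cls_attention_profile(r$tensors[[1]]),
                 oracle_cls_profile(r$tensors[[1]]), tolerance = 1e-12)
  }
})

test_that("high-attention regions obey the length and threshold rules", {
  # uniform profile: nothing strictly above the mean
  expect_identical(nrow(find_high_attention_regions(rep(0.3, 10), 3)), 0L)
  # 4 consecutive above-mean 3-mer tokens -> one 6-nt span
  p <- c(1, 1, 9, 9, 9, 9, 1, 1, 1, 1)
  r <- find_high_attention_regions(p, 3)
  expect_identical(nrow(r), 1L)
  expect_identical(unname(r[1, "end"] - r[1, "start"]), 6L)
  expect_identical(unname(r[1, ]), c(2L, 8L))
  # isolated above-mean token -> 3-nt span, below min length, discarded
  iso <- c(1, 1, 9, 1, 1, 1, 1, 1, 1, 1)
  expect_identical(nrow(find_high_attention_regions(iso, 3)), 0L)
  # long runs are truncated to the best max_len window (leftmost on ties)
  long <- c(rep(10, 12), rep(1, 8))
  long[3] <- 20
  rl <- find_high_attention_regions(long, 3, max_len = 10)
  expect_identical(unname(rl[1, "end"] - rl[1, "start"]), 10L)
  expect_true(rl[1, "start"] <= 2 && rl[1, "end"] >= 5)  # window holds peak
  # bounds property on random profiles
  set.seed(9)
  for (trial in 1:20) {
    prof <- rexp(30)
    rr <- find_high_attention_regions(prof, 3)
    if (nrow(rr)) {
      len <- rr[, "end"] - rr[, "start"]
      expect_true(all(len >= 6 & len <= 10))
      expect_true(all(rr[, "start"] >= 0 & rr[, "end"] <= 32))
    }
  }
})

test_that("hypergeometric enrichment matches the exact integer pmf", {
  pos <- c("AAAA", "CCCC", "GGGG"); neg <- c("TTTT", "ACAC", "GTGT")
  expect_identical(hypergeometric_enrichment("AATT", pos, neg)$p_value, 1)
  both <- hypergeometric_enrichment("A", c("AA", "CA"), c("TA", "GA"))
  expect_identical(both$p_value, 1)  # present everywhere: x is forced
  # 10+10 sequences, candidate in exactly 5, all positive
  pos10 <- c(paste0("TTT", "GATTACA", "TTT"), rep("TTTTTTTTTTTTT", 5),
             rep(paste0("AAA", "GATTACA", "AAA"), 4))
  neg10 <- rep("CCCCCCCCCCCCC", 10)
  r <- hypergeometric_enrichment("GATTACA", pos10, neg10)
  expect_identical(r$pos_count, 5L)
  expect_equal(r$p_value, choose(15, 5) / choose(20, 10), tolerance = 1e-12)
  expect_error(hypergeometric_enrichment("", pos, neg), "empty")
  expect_error(hypergeometric_enrichment("AA", character(0), neg), "non-empty")
})

test_that("upper-tail p-values agree with pmf summation for all N <= 30", {
  for (N in 2:30) {
    for (K in 0:N) {
      for (n in 1:(N - 1)) {
        for (x in unique(c(0, 1, K %/% 2, K, min(K, n)))) {
          expect_equal(
            phyper(x - 1, K, N - K, n, lower.tail = FALSE),
            oracle_hyper_upper(x, K, N, n), tolerance = 1e-12,
            label = sprintf("N=%d K=%d n=%d x=%d", N, K, n, x))
        }
      }
    }
  }
})

test_that("p-value is monotone non-increasing in the positive count", {
  N <- 24; K <- 9; n <- 12
  ps <- vapply(0:K, function(x)
    phyper(x - 1, K, N - K, n, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("candidate merging pools instances at matching offsets", {
  cand <- function(cons, n) list(
    consensus = cons,
    instances = data.frame(sequence = seq_len(n), start = 0,
                           end = nchar(cons)),
    pos_count = n, neg_count = 0L, p_value = 1e-5)
  twin <- merge_motif_candidates(list(cand("GATTAC", 3), cand("GATTAC", 2)))
  expect_length(twin, 1L)
  expect_identical(twin[[1]]$n_instances, 5L)
  apart <- merge_motif_candidates(list(cand("TTTTTT", 3), cand("AGAGAG", 2)))
  expect_length(apart, 2L)
  expect_identical(apart[[1]]$consensus, "TTTTTT")  # sorted by instances
  near <- merge_motif_candidates(list(cand("GAAGAA", 3), cand("AAGAAG", 2)))
  expect_length(near, 1L)                            # 5/6 match at offset 1
  expect_identical(near[[1]]$consensus, "GAAGAA")
  al <- rbpattn:::best_offset_alignment("GAAGAA", "AAGAAG")
  expect_identical(al$matches, 5L)
})

test_that("PFMs conserve instance counts per column", {
  pfm <- build_pfm(c("AAA", "AAA"))
  expect_identical(pfm["A", ], c(2L, 2L, 2L))
  expect_identical(sum(pfm[c("C", "G", "T"), ]), 0L)
  mix <- build_pfm(c("AAA", "CCC"))
  expect_true(all(colSums(mix) == 2L))
  expect_identical(mix["A", ], c(1L, 1L, 1L))
  many <- build_pfm(rep(c("ACGTAC", "ACGTTT"), 5))
  expect_true(all(colSums(many) == 10L))
  expect_error(build_pfm(c("AAA", "AAAA")), "width mismatch")
  expect_error(build_pfm(character(0)), "no instances")
})

test_that("implanted motifs are recovered end to end from CLS attention", {
  # the stated recovery benchmark: 7-nt consensus in 80% of positives, none
  # of the negatives; tiny encoder trained from scratch
  spec <- synthetic_spec(n_pos = 1000, n_neg = 1000, implant_rate = 0.8,
                         seed = 17)
  sim <- simulate_rbp_dataset(spec)
  split <- split_dataset(sim$set, seed = 17)
  vocab <- build_vocabulary(3)
  tok <- lapply(sim$set$sequence, tokenize, vocab = vocab)
  y <- as.integer(sim$set$label == "positive")
  tr <- split$partition == "train"
  prov <- train_classifier(tok[tr], y[tr],
                           config = encoder_config(seed = 17),
                           settings = training_settings(epochs = 3,
                                                        seed = 17))
  te_pos <- split$partition == "test" & y == 1
  te_neg <- split$partition == "test" & y == 0
  ds <- attention_dataset(extract_attention(prov, tok[te_pos]), tok[te_pos])
  res <- extract_motifs(ds, sim$set$sequence[te_neg])
  expect_gt(length(res$motifs), 0)
  top <- res$motifs[[1]]
  al <- rbpattn:::best_offset_alignment(spec$motif, top$consensus)
  expect_gte(al$matches, 5)
  expect_lt(top$p_value, 0.005)
  # PFM consistency of the top motif
  expect_true(all(colSums(top$pfm) == length(top$aligned_instances)))
})

test_that("MEME output is well-formed", {
  mo <- list(list(consensus = "GATTACA", p_value = 1e-6,
                  pfm = build_pfm(rep("GATTACA", 4))))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(mo, f)
  lines <- readLines(f)
  expect_identical(lines[1], "MEME version 4")
  expect_true(any(grepl("^MOTIF GATTACA", lines)))
  probs <- lines[grepl("^ ", lines)]
  expect_length(probs, 7L)
  expect_true(all(abs(vapply(strsplit(trimws(probs), " +"),
                             function(x) sum(as.numeric(x)),
                             numeric(1)) - 1) < 1e-5))
})
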