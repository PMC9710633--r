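uniform_tensor <- function(T_, n_layers = 1, n_heads = 1) {
  array(1 / T_, c(n_layers, n_heads, T_, T_))
}

# dataset with hand-set CLS columns: per-sequence CLS sums fixed exactly
cls_sum_dataset <- function(sums, f, L = 2) {
  T_ <- L + 2
  vocab <- build_vocabulary(3)
  tokenized <- lapply(seq_along(sums), function(i)
    tokenize(strrep("A", L + 2), vocab))
  tensors <- lapply(sums, function(s) {
    a <- array(0, c(1, 1, T_, T_))
    m <- matrix(0, T_, T_)
    m[, 1] <- s / T_
    m[, 2] <- 1 - s / T_
    a[1, 1, , ] <- m
    a
  })
  attention_dataset(tensors, tokenized, f = f)
}

test_that("attention into CLS sums the CLS column over all rows", {
  expect_identical(attention_to_cls(uniform_tensor(4), 1, 1), 1)
  z <- uniform_tensor(4); z[1, 1, , 1] <- 0
  expect_identical(attention_to_cls(z, 1, 1), 0)
  hand <- array(0, c(1, 1, 3, 3))
  hand[1, 1, , ] <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.8, 0.1),
                          c(0.25, 0.5, 0.25))
  expect_identical(attention_to_cls(hand, 1, 1), 0.85)
  expect_error(attention_to_cls(hand, 2, 1), "out of range")
})

test_that("relative attention to CLS is the ratio of group means", {
  same <- cls_sum_dataset(c(0.5, 0.5, 0.5), f = c(1, 1, 0))
  expect_equal(relative_attention_cls(same, 1, 1), 1)
  forced <- cls_sum_dataset(c(0.2, 0.4, 0.1), f = c(1, 1, 0))
  expect_equal(relative_attention_cls(forced, 1, 1), 3)
  # all-sequence background option
  expect_equal(relative_attention_cls(forced, 1, 1, background = "all"),
               0.3 / mean(c(0.2, 0.4, 0.1)))
  expect_error(relative_attention_cls(
    cls_sum_dataset(c(0.2, 0.4), f = c(1, 1)), 1, 1), "constant")
})

test_that("swapping the indicator inverts the ratio (reciprocality)", {
  for (seed in 1:5) {
    r <- make_random_attention(N = 4, L = 5, seed = seed)
    ds1 <- attention_dataset(r$tensors, r$tokenized, f = r$f)
    ds2 <- attention_dataset(r$tensors, r$tokenized, f = 1 - r$f)
    for (l in 1:2) for (h in 1:2)
      expect_equal(relative_attention_cls(ds1, l, h) *
                     relative_attention_cls(ds2, l, h), 1,
                   tolerance = 1e-12)
  }
})

test_that("attention ratio hits its analytic limits", {
  r <- make_random_attention(N = 3, L = 6, seed = 2)
  ones <- lapply(r$tokenized, function(t) rep(1L, t$L))
  zeros <- lapply(r$tokenized, function(t) rep(0L, t$L))
  ds1 <- attention_dataset(r$tensors, r$tokenized, g = ones)
  ds0 <- attention_dataset(r$tensors, r$tokenized, g = zeros)
  expect_equal(attention_ratio(ds1, 1, 1), 1)
  expect_equal(attention_ratio(ds0, 2, 2), 0)
  # uniform attention reduces t_alpha to the token frequency of g
  L <- 6; T_ <- L + 2
  uni <- lapply(1:3, function(i) uniform_tensor(T_, 2, 2))
  half <- lapply(r$tokenized, function(t) rep(c(1L, 0L), t$L / 2))
  dsu <- attention_dataset(uni, r$tokenized, g = half)
  expect_identical(attention_ratio(dsu, 1, 2), 0.5)
  rand_g <- attention_dataset(uni, r$tokenized, g = r$g)
  expect_equal(attention_ratio(rand_g, 2, 1), mean(unlist(r$g)),
               tolerance = 1e-12)
})

test_that("exclusive exhaustive token labels have ratios summing to 1", {
  r <- make_random_attention(N = 3, L = 5, seed = 4)
  lab <- lapply(r$tokenized, function(t) sample(3, t$L, replace = TRUE))
  tot <- 0
  for (v in 1:3) {
    g <- lapply(lab, function(x) as.integer(x == v))
    tot <- tot + attention_ratio(
      attention_dataset(r$tensors, r$tokenized, g = g), 2, 1)
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("both head statistics match naive triple-loop references", {
  for (seed in 1:20) {
    r <- make_random_attention(N = 3, L = 5, seed = seed)
    ds <- attention_dataset(r$tensors, r$tokenized, f = r$f, g = r$g)
    for (l in 1:2) for (h in 1:2) {
      expect_equal(relative_attention_cls(ds, l, h),
                   oracle_relative_attention(r$tensors, r$f, l, h),
                   tolerance = 1e-10)
      expect_equal(attention_ratio(ds, l, h),
                   oracle_attention_ratio(r$tensors, r$g, l, h),
                   tolerance = 1e-10)
    }
  }
})

test_that("specialization CV is the sample-sd/mean in percent, scale-free", {
  expect_identical(specialization_cv(matrix(2, 3, 4)), 0)
  expect_equal(specialization_cv(matrix(c(1, 2, 3), 1)), 50)
  g <- matrix(runif(12, 1, 2), 3, 4)
  expect_equal(specialization_cv(g), specialization_cv(7.3 * g),
               tolerance = 1e-12)
  expect_error(specialization_cv(matrix(c(-1, 1), 1)), "zero-mean")
})

test_that("head similarity is Kendall tau-b with tie handling", {
  g <- matrix(c(4, 1, 3, 2), 2, 2)
  expect_equal(head_similarity(g, g), 1)
  expect_equal(head_similarity(g, -g), -1)
  a <- c(1, 2, 2, 3); b <- c(1, 3, 2, 4)
  expect_equal(head_similarity(matrix(a, 2), matrix(b, 2)),
               oracle_kendall(a, b), tolerance = 1e-12)
  set.seed(3)
  for (trial in 1:10) {
    x <- sample(5, 9, TRUE); y <- sample(5, 9, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(head_similarity(matrix(x, 3), matrix(y, 3)),
                 oracle_kendall(x, y), tolerance = 1e-12)
  }
  expect_error(head_similarity(matrix(1, 2, 2), g), "constant")
  expect_error(head_similarity(matrix(1:6, 2, 3), g), "shape")
})

test_that("max-head selection breaks ties toward the lowest layer then head", {
  g <- matrix(0, 8, 12)
  g[3, 5] <- 2
  expect_identical(unname(select_max_head(g)), c(3L, 5L))
  g[7, 1] <- 2
  expect_identical(unname(select_max_head(g)), c(3L, 5L))
  expect_identical(unname(select_max_head(matrix(1, 4, 4))), c(1L, 1L))
})

test_that("raw token attention is the received column sum over sequence rows", {
  u <- uniform_tensor(4)
  expect_equal(raw_token_attention(u, 1, 1), c(0.5, 0.5))
  z <- uniform_tensor(4); z[1, 1, , 3] <- 0
  expect_equal(raw_token_attention(z, 1, 1), c(0.5, 0))
  for (seed in 1:5) {
    r <- make_random_attention(N = 1, L = 7, seed = seed)
    for (l in 1:2) for (h in 1:2)
      expect_equal(raw_token_attention(r$tensors[[1]], l, h),
                   oracle_raw_token_attention(r$tensors[[1]], l, h),
                   tolerance = 1e-12)
  }
})

test_that("attention-structure curve tracks the planted coupling", {
  # under independence every bin probability stays near the background
  null_spec <- planted_attention_spec(n_layers = 1, n_heads = 2, L = 30,
                                      N = 120, seed = 21)
  ds0 <- simulate_attention(null_spec)
  cur0 <- attention_structure_curve(ds0, 1, 1, n_bins = 8, seed = 1)
  bg <- attr(cur0, "background")
  ok <- !is.na(cur0$probability) & cur0$n_tokens > 20
  expect_true(all(abs(cur0$probability[ok] - bg) <= 3 * pmax(cur0$sd[ok], 0.02)))
  # g identically 1
  ds1 <- simulate_attention(planted_attention_spec(1, 1, L = 20, N = 40,
                                                   seed = 3),
                            g = replicate(40, rep(1L, 20), simplify = FALSE))
  cur1 <- attention_structure_curve(ds1, 1, 1, n_bins = 5, seed = 1)
  expect_true(all(cur1$probability[!is.na(cur1$probability)] == 1))
  expect_identical(attr(cur1, "background"), 1)
  # planted positive coupling: probability rises with the attention bin
  pl <- planted_attention_spec(1, 2, L = 30, N = 150,
                               planted = list(list(layer = 1, head = 2,
                                                   level = "token",
                                                   effect = 4)),
                               seed = 8)
  dsp <- simulate_attention(pl)
  curp <- attention_structure_curve(dsp, 1, 2, n_bins = 8, seed = 1)
  keep <- !is.na(curp$probability) & curp$n_tokens > 10
  expect_gt(cor(seq_len(nrow(curp))[keep], curp$probability[keep],
                method = "spearman"), 0)
  # bins hold every retained token: at most 0.5% dropped by the filter
  total <- sum(vapply(dsp$tokenized, function(t) t$L, integer(1)))
  expect_lte(sum(curp$n_tokens), total)
  expect_gte(sum(curp$n_tokens), floor(0.995 * total))
  vocab5 <- build_vocabulary(3)
  tok5 <- lapply(1:3, function(i) tokenize(strrep("A", 7), vocab5))
  flat <- attention_dataset(lapply(1:3, function(i) uniform_tensor(7)), tok5,
                            g = replicate(3, rep(1L, 5), simplify = FALSE))
  expect_error(attention_structure_curve(flat, 1, 1, n_bins = 5, seed = 1),
               "too few")
})
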