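#' Bundle attention tensors with tokenizations and property indicators
#'
#' The common input of all attention analyses: aligned lists of per-sequence
#' attention tensors (from [extract_attention()] or an archive) and
#' tokenizations, plus optional property indicators — a sequence-level binary
#' flag `f` (one value per sequence) and/or token-level binary flags `g` (one
#' 0/1 vector of length L per sequence, sequence tokens only).
#'
#' @param tensors list of `(n_layers, n_heads, L+2, L+2)` arrays.
#' @param tokenized list of `tokenized_seq`, same length.
#' @param f optional numeric/integer 0/1 vector, one per sequence.
#' @param g optional list of 0/1 vectors, `g[[n]]` of length `L_n`.
#' @return an `attention_dataset`.
#' @export
attention_dataset <- function(tensors, tokenized, f = NULL, g = NULL) {
  N <- length(tensors)
  if (N < 1L) stop("attention dataset must hold at least one sequence")
  if (length(tokenized) != N)
    stop("tensors and tokenized lists differ in length")
  for (n in seq_len(N)) {
    d <- dim(tensors[[n]])
    if (length(d) != 4L || d[3L] != d[4L] ||
        d[3L] != tokenized[[n]]$L + 2L)
      stop("tensor ", n, " shape does not match its tokenization")
  }
  if (!is.null(f)) {
    if (length(f) != N) stop("f must have one value per sequence")
    if (!all(f %in% c(0, 1))) stop("f must be binary 0/1")
  }
  if (!is.null(g)) {
    if (length(g) != N) stop("g must have one vector per sequence")
    for (n in seq_len(N)) {
      if (length(g[[n]]) != tokenized[[n]]$L)
        stop("g[[", n, "]] must cover the L sequence tokens")
      if (!all(g[[n]] %in% c(0, 1))) stop("g must be binary 0/1")
    }
  }
  structure(list(tensors = tensors, tokenized = tokenized, f = f, g = g),
            class = "attention_dataset")
}

#' @export
print.attention_dataset <- function(x, ...) {
  d <- dim(x$tensors[[1L]])
  cat(sprintf("<attention_dataset> N=%d sequences, %d layers x %d heads%s%s\n",
              length(x$tensors), d[1L], d[2L],
              if (!is.null(x$f)) ", f" else "",
              if (!is.null(x$g)) ", g" else ""))
  invisible(x)
}

check_head <- function(tensor, layer, head) {
  d <- dim(tensor)
  if (layer < 1L || layer > d[1L] || head < 1L || head > d[2L])
    stop(sprintf("head index out of range: layer %d head %d for %d x %d grid",
                 layer, head, d[1L], d[2L]))
}

#' Total attention into the CLS token
#'
#' For one head, sums the CLS-column entry over all L+2 upper-token rows
#' (CLS and SEP rows included): the inner sum of the sequence-level relative
#' attention statistic.
#'
#' @param tensor a `(n_layers, n_heads, L+2, L+2)` attention array.
#' @param layer,head 1-based head coordinates.
#' @return scalar, total attention received by CLS.
#' @export
attention_to_cls <- function(tensor, layer, head) {
  check_head(tensor, layer, head)
  sum(tensor[layer, head, , 1L])
}

#' Relative attention to CLS for a sequence-level property
#'
#' The head-level statistic s_alpha(f): the mean total CLS attention over
#' property-positive sequences divided by the same mean over the background
#' group. The default background is the property-negative sequences; setting
#' `background = "all"` divides by the mean over all sequences instead.
#'
#' @param dataset an [attention_dataset()] with `f`.
#' @param layer,head 1-based head coordinates.
#' @param background `"complement"` (f = 0 sequences; default) or `"all"`.
#' @return the ratio s_alpha(f) (positive scalar).
#' @export
relative_attention_cls <- function(dataset, layer, head,
                                   background = c("complement", "all")) {
  background <- match.arg(background)
  f <- dataset$f
  if (is.null(f)) stop("dataset carries no sequence-level indicator f")
  if (all(f == 1) || all(f == 0))
    stop("property constant, ratio undefined")
  cls <- vapply(dataset$tensors, attention_to_cls, numeric(1),
                layer = layer, head = head)
  num <- mean(cls[f == 1])
  den <- if (background == "complement") mean(cls[f == 0]) else mean(cls)
  if (den == 0) stop("zero attention to CLS in the background group")
  num / den
}

#' Attention ratio for a token-level property
#'
#' The head-level statistic t_alpha(g): the fraction of all sequence-token to
#' sequence-token attention mass that lands on tokens carrying the property.
#' CLS and SEP rows and columns are excluded.
#'
#' @param dataset an [attention_dataset()] with `g`.
#' @param layer,head 1-based head coordinates.
#' @return t_alpha(g) in `[0, 1]`.
#' @export
attention_ratio <- function(dataset, layer, head) {
  if (is.null(dataset$g)) stop("dataset carries no token-level indicator g")
  num <- 0; den <- 0
  for (n in seq_along(dataset$tensors)) {
    check_head(dataset$tensors[[n]], layer, head)
    L <- dataset$tokenized[[n]]$L
    sub <- dataset$tensors[[n]][layer, head, 2L:(L + 1L), 2L:(L + 1L)]
    recv <- colSums(matrix(sub, L, L))
    num <- num + sum(recv * dataset$g[[n]])
    den <- den + sum(recv)
  }
  num / den
}

#' Head grid of relative CLS attention
#'
#' Computes [relative_attention_cls()] for every head, yielding the
#' layers x heads grid (144 cells for the 12 x 12 configuration) that the
#' specialization and similarity statistics consume.
#'
#' @inheritParams relative_attention_cls
#' @return numeric matrix `n_layers x n_heads`.
#' @export
head_grid_cls <- function(dataset, background = c("complement", "all")) {
  background <- match.arg(background)
  d <- dim(dataset$tensors[[1L]])
  outer_grid(d[1L], d[2L], function(l, h)
    relative_attention_cls(dataset, l, h, background))
}

#' Head grid of token-level attention ratios
#'
#' @inheritParams attention_ratio
#' @return numeric matrix `n_layers x n_heads` of t_alpha(g).
#' @export
head_grid_ratio <- function(dataset) {
  d <- dim(dataset$tensors[[1L]])
  outer_grid(d[1L], d[2L], function(l, h) attention_ratio(dataset, l, h))
}

outer_grid <- function(nl, nh, fun) {
  m <- matrix(NA_real_, nl, nh)
  for (l in seq_len(nl)) for (h in seq_len(nh)) m[l, h] <- fun(l, h)
  m
}

#' Head-specialization coefficient of variation
#'
#' Sample standard deviation of a head grid divided by its mean, in percent:
#' the degree to which heads specialize for a property.
#'
#' @param grid a layers x heads numeric matrix.
#' @return CV in percent.
#' @export
specialization_cv <- function(grid) {
  mu <- mean(grid)
  if (mu == 0) stop("zero-mean head grid, CV undefined")
  100 * stats::sd(as.vector(grid)) / mu
}

#' Rank similarity of two head grids
#'
#' Kendall's rank correlation (tau-b, tie-corrected) over the flattened head
#' values; used to compare head-specialization patterns between models.
#'
#' @param grid_a,grid_b equal-shape numeric matrices.
#' @return tau in `[-1, 1]`.
#' @export
head_similarity <- function(grid_a, grid_b) {
  if (!identical(dim(grid_a), dim(grid_b)))
    stop("head grids differ in shape")
  a <- as.vector(grid_a); b <- as.vector(grid_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant head grid")
  stats::cor(a, b, method = "kendall")
}

#' Select the head with the strongest statistic
#'
#' Argmax over a head grid; ties broken by lowest layer, then lowest head
#' index. Coordinates are 1-based to match head naming such as "head 7-12".
#'
#' @param grid a layers x heads numeric matrix.
#' @return integer vector `c(layer, head)`.
#' @export
select_max_head <- function(grid) {
  if (length(grid) == 0L) stop("empty head grid")
  best <- which(grid == max(grid), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
  c(layer = best[1L, 1L], head = best[1L, 2L])
}

#' Raw attention received per sequence token
#'
#' For one head, the total attention each lower-layer sequence token j
#' receives from all sequence-token rows i (CLS/SEP excluded on both axes).
#'
#' @param tensor a `(n_layers, n_heads, L+2, L+2)` attention array.
#' @param layer,head 1-based head coordinates.
#' @param L number of sequence tokens.
#' @return numeric vector of length `L`.
#' @export
raw_token_attention <- function(tensor, layer, head, L = dim(tensor)[3L] - 2L) {
  check_head(tensor, layer, head)
  sub <- tensor[layer, head, 2L:(L + 1L), 2L:(L + 1L)]
  colSums(matrix(sub, L, L))
}

#' Attention-versus-structure probability curve
#'
#' Pools [raw_token_attention()] values over all sequences of a dataset,
#' drops tokens above the given attention percentile (attention values are
#' sparse in the upper tail), bins the remainder into equal-width attention
#' bins, and reports per bin the probability that a token carries the
#' token-level property `g`. Dispersion per bin is the standard deviation of
#' that probability across random equal splits of the sequences.
#'
#' @param dataset an [attention_dataset()] with `g`.
#' @param layer,head 1-based head coordinates.
#' @param n_bins number of equal-width attention bins.
#' @param percentile upper percentile filter (tokens with attention above
#'   this percentile of the pooled values are dropped); default 99.5.
#' @param n_subsets number of random sequence splits for the dispersion
#'   estimate.
#' @param seed RNG seed for the splits.
#' @return data.frame with columns `bin_low`, `bin_high`, `n_tokens`,
#'   `probability`, `sd`; attribute `background` holds the dataset-wide token
#'   frequency of the property over retained tokens.
#' @export
attention_structure_curve <- function(dataset, layer, head, n_bins = 10L,
                                      percentile = 99.5, n_subsets = 3L,
                                      seed = 1L) {
  if (is.null(dataset$g)) stop("dataset carries no token-level indicator g")
  N <- length(dataset$tensors)
  att <- lapply(seq_len(N), function(n)
    raw_token_attention(dataset$tensors[[n]], layer, head,
                        dataset$tokenized[[n]]$L))
  seq_of <- rep(seq_len(N), lengths(att))
  a <- unlist(att, use.names = FALSE)
  gflat <- unlist(dataset$g, use.names = FALSE)
  cutoff <- stats::quantile(a, percentile / 100, names = FALSE)
  keep <- a <= cutoff
  a <- a[keep]; gflat <- gflat[keep]; seq_of <- seq_of[keep]
  if (length(unique(a)) < n_bins)
    stop("too few distinct attention values after filtering")
  edges <- seq(min(a), max(a), length.out = n_bins + 1L)
  bin <- findInterval(a, edges, rightmost.closed = TRUE, all.inside = TRUE)
  prob_by_bin <- function(sel) {
    vapply(seq_len(n_bins), function(b) {
      idx <- sel & bin == b
      if (any(idx)) mean(gflat[idx]) else NA_real_
    }, numeric(1))
  }
  probability <- prob_by_bin(rep(TRUE, length(a)))
  n_tokens <- tabulate(bin, nbins = n_bins)
  local_rng(seed)
  grp <- sample(rep_len(seq_len(n_subsets), N))
  sub_probs <- vapply(seq_len(n_subsets), function(s)
    prob_by_bin(seq_of %in% which(grp == s)), numeric(n_bins))
  disp <- apply(matrix(sub_probs, n_bins, n_subsets), 1L,
                stats::sd, na.rm = TRUE)
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                    n_tokens = n_tokens, probability = probability, sd = disp)
  attr(out, "background") <- mean(gflat)
  out
}
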