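#' Clean a labeled sequence set
#'
#' Applies the two dataset-construction cleaning rules: records whose
#' sequence contains a character outside A/C/G/T/U (e.g. N from unannotated
#' genome regions) are dropped, and duplicate sequence strings within a label
#' class are dropped after their first occurrence. Order is otherwise
#' preserved and the operation is idempotent. Cross-class duplicates are kept.
#'
#' @param raw data.frame with columns `id`, `sequence`, `label`.
#' @return the cleaned data.frame (possibly empty).
#' @export
clean_sequences <- function(raw) {
  if (nrow(raw) == 0L) return(raw)
  s <- toupper(raw$sequence)
  keep <- !grepl("[^ACGTU]", s)
  out <- raw[keep, , drop = FALSE]
  s <- s[keep]
  dup <- duplicated(paste(out$label, chartr("U", "T", s), sep = "\r"))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample a fixed number of sequences per label class
#'
#' Uniform sampling without replacement of up to `n_per_class` records per
#' class; classes with fewer records are retained in full. Deterministic for
#' a given seed.
#'
#' @param clean cleaned data.frame (`id`, `sequence`, `label`).
#' @param n_per_class cap per label class (default 15000, the standard
#'   benchmark cap).
#' @param seed integer RNG seed.
#' @param representatives optional character vector of sequence ids to
#'   restrict sampling to, e.g. cluster representatives from an external
#'   redundancy-reduction run (sequence-similarity clustering itself is not
#'   performed here).
#' @return the sampled data.frame, original order preserved within class.
#' @export
sample_dataset <- function(clean, n_per_class = 15000L, seed = 1L,
                           representatives = NULL) {
  if (!is.null(representatives))
    clean <- clean[clean$id %in% representatives, , drop = FALSE]
  if (n_per_class == 0L || nrow(clean) == 0L)
    return(clean[0L, , drop = FALSE])
  rng <- local_rng(seed)
  keep <- unlist(lapply(split(seq_len(nrow(clean)), clean$label), function(idx) {
    if (length(idx) <= n_per_class) idx else sort(sample(idx, n_per_class))
  }), use.names = FALSE)
  out <- clean[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a sequence set into train / eval / test partitions
#'
#' Stratified by label class; within each class the records are partitioned
#' 64% / 16% / 20% with largest-remainder rounding of fractional counts.
#' Deterministic for a given seed.
#'
#' @param sampled data.frame (`id`, `sequence`, `label`), non-empty.
#' @param seed integer RNG seed.
#' @param fractions train/eval/test fractions summing to 1.
#' @return data.frame with columns `id`, `label`, `partition` (factor with
#'   levels train, eval, test); attribute `seed` records the seed.
#' @export
split_dataset <- function(sampled, seed = 1L,
                          fractions = c(train = 0.64, eval = 0.16, test = 0.20)) {
  if (nrow(sampled) == 0L) stop("cannot split an empty set")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  rng <- local_rng(seed)
  parts <- names(fractions)
  assign <- character(nrow(sampled))
  for (idx in split(seq_len(nrow(sampled)), sampled$label)) {
    m <- length(idx)
    counts <- largest_remainder(fractions * m)
    lab <- rep(parts, counts)
    assign[idx] <- lab[sample.int(m)]
  }
  out <- data.frame(id = sampled$id, label = sampled$label,
                    partition = factor(assign, levels = parts),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "fractions") <- fractions
  out
}

# Integer apportionment: floor everything, then hand out the remaining units
# to the largest fractional remainders (ties to the earlier entry).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- sum(x) - sum(fl)
  n_extra <- round(rem)
  if (n_extra > 0) {
    ord <- order(-(x - fl), seq_along(x))
    fl[ord[seq_len(n_extra)]] <- fl[ord[seq_len(n_extra)]] + 1
  }
  as.integer(fl)
}

#' Assemble the non-training set
#'
#' The substrate for attention analyses: every cleaned record that is in
#' neither the train nor the eval partition. Test-partition records are
#' included, as are records that were never sampled.
#'
#' @param full_clean the full cleaned data.frame.
#' @param split a [split_dataset()] assignment whose ids all occur in
#'   `full_clean`.
#' @return data.frame subset of `full_clean`.
#' @export
build_non_training <- function(full_clean, split) {
  unknown <- setdiff(split$id, full_clean$id)
  if (length(unknown))
    stop("split refers to unknown ids, e.g. ", unknown[1L])
  held <- split$id[split$partition %in% c("train", "eval")]
  out <- full_clean[!full_clean$id %in% held, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All seeded entry points funnel through here so the seeding policy is
# uniform (Mersenne-Twister, Rejection sampling).
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
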