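#' CLS-attention profile of a sequence
#'
#' Accumulates, over all heads of the final layer, the attention weight from
#' the CLS row to each sequence token (CLS/SEP columns excluded): the
#' per-token signal the motif-extraction pipeline scans for high-attention
#' regions.
#'
#' @param tensor a `(n_layers, n_heads, L+2, L+2)` attention array.
#' @return numeric vector of length `L`.
#' @export
cls_attention_profile <- function(tensor) {
  d <- dim(tensor)
  if (length(d) != 4L || d[1L] < 1L) stop("tensor must have at least 1 layer")
  L <- d[3L] - 2L
  final <- tensor[d[1L], , 1L, 2L:(L + 1L)]
  if (d[2L] == 1L) final <- matrix(final, nrow = 1L)
  colSums(final)
}

#' Detect high-attention nucleotide regions
#'
#' Finds maximal runs of consecutive sequence tokens whose profile value is
#' strictly above the per-sequence mean, converts each token run to its
#' covered nucleotide span, discards spans shorter than `min_len`, and
#' truncates spans longer than `max_len` to the `max_len` window with the
#' highest summed token attention (leftmost on ties).
#'
#' @param profile a [cls_attention_profile()] row (length L).
#' @param k k-mer size of the tokenization.
#' @param min_len,max_len allowed nucleotide span lengths (defaults 6 and 10).
#' @return integer matrix with columns `start`, `end` (0-based half-open
#'   nucleotide coordinates); zero rows when no region qualifies.
#' @export
find_high_attention_regions <- function(profile, k, min_len = 6L,
                                        max_len = 10L) {
  if (length(profile) == 0L) stop("empty attention profile")
  k <- as.integer(k); min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  above <- profile > mean(profile)
  out <- matrix(integer(0), 0L, 2L,
                dimnames = list(NULL, c("start", "end")))
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (run in which(r$values)) {
    a <- starts[run]; b <- ends[run]          # 1-based token run
    span_len <- (b - a + 1L) + k - 1L
    if (span_len < min_len) next
    if (span_len > max_len) {
      w <- max_len - k + 1L                   # tokens per max_len window
      sums <- vapply(a:(b - w + 1L), function(s)
        sum(profile[s:(s + w - 1L)]), numeric(1))
      a <- (a:(b - w + 1L))[which.max(sums)]  # which.max is leftmost on ties
      b <- a + w - 1L
    }
    out <- rbind(out, c(as.integer(a) - 1L, as.integer(b) - 1L + k))
  }
  out
}

#' Hypergeometric enrichment of a candidate motif in positive sequences
#'
#' With N = total sequences, K = sequences containing at least one exact
#' occurrence of the candidate, n = number of positive sequences and x =
#' positive sequences containing it, returns P(X >= x) under the
#' hypergeometric law. Candidates pass the filter when p < cutoff
#' (0.005 by default in the pipeline).
#'
#' @param candidate nucleotide string (non-empty).
#' @param positives,negatives character vectors of sequences (both
#'   non-empty).
#' @return named list with `p_value`, `pos_count` (x), `neg_count`,
#'   `total_count` (K).
#' @export
hypergeometric_enrichment <- function(candidate, positives, negatives) {
  if (!nzchar(candidate)) stop("empty candidate string")
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both sequence sets must be non-empty")
  x <- sum(grepl(candidate, positives, fixed = TRUE))
  neg <- sum(grepl(candidate, negatives, fixed = TRUE))
  K <- x + neg
  N <- length(positives) + length(negatives)
  n <- length(positives)
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, pos_count = x, neg_count = neg, total_count = K)
}

# Best ungapped offset alignment of two strings. offset = start of s2
# relative to start of s1 (may be negative). Returns the offset maximizing
# the number of matching positions in the overlap (smallest offset on ties).
best_offset_alignment <- function(s1, s2) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  m <- length(a); n <- length(b)
  best <- list(matches = -1L, offset = 0L)
  for (o in (-(n - 1L)):(m - 1L)) {
    i1 <- max(1L, 1L + o); i2 <- min(m, n + o)
    if (i2 < i1) next
    matches <- sum(a[i1:i2] == b[(i1:i2) - o])
    if (matches > best$matches) best <- list(matches = matches, offset = o)
  }
  best
}

#' Merge similar motif candidates
#'
#' Greedy agglomeration of enriched candidates: candidates are visited in
#' decreasing order of instance count and joined to the first existing motif
#' whose representative consensus aligns (best ungapped offset) with at least
#' `identity` matching positions relative to the shorter length; otherwise
#' they found a new motif. A merged motif pools all member instances; its
#' consensus is the member with the most instances. Output is sorted by
#' pooled instance count, descending.
#'
#' @param candidates list of candidate objects as produced by
#'   [extract_motifs()] internals: each a list with `consensus`, `instances`
#'   (data.frame `sequence`, `start`, `end`), `pos_count`, `neg_count`,
#'   `p_value`.
#' @param identity minimum fraction of matching positions (default 0.7).
#' @return list of merged motifs; each adds `members` (consensus strings),
#'   `offsets` (member start relative to the representative) and
#'   `n_instances`.
#' @export
merge_motif_candidates <- function(candidates, identity = 0.7) {
  if (length(candidates) == 0L) return(list())
  ord <- order(-vapply(candidates, function(c) nrow(c$instances), integer(1)))
  clusters <- list()
  for (ci in ord) {
    cand <- candidates[[ci]]
    placed <- FALSE
    for (j in seq_along(clusters)) {
      rep_c <- clusters[[j]]$consensus
      al <- best_offset_alignment(rep_c, cand$consensus)
      need <- identity * min(nchar(rep_c), nchar(cand$consensus))
      if (al$matches >= need) {
        cl <- clusters[[j]]
        cl$members <- c(cl$members, cand$consensus)
        cl$offsets <- c(cl$offsets, al$offset)
        cl$instances <- rbind(cl$instances, cand$instances)
        clusters[[j]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cand$members <- cand$consensus
      cand$offsets <- 0L
      clusters[[length(clusters) + 1L]] <- cand
    }
  }
  for (j in seq_along(clusters))
    clusters[[j]]$n_instances <- nrow(clusters[[j]]$instances)
  clusters[order(-vapply(clusters, `[[`, integer(1), "n_instances"))]
}

#' Build a position frequency matrix
#'
#' @param instances character vector of aligned, equal-width nucleotide
#'   strings.
#' @return integer matrix 4 x width (rows A, C, G, T); every column sums to
#'   the number of instances.
#' @export
build_pfm <- function(instances) {
  if (length(instances) == 0L) stop("no instances")
  w <- unique(nchar(instances))
  if (length(w) != 1L) stop("instance width mismatch: ",
                            paste(w, collapse = ", "))
  chars <- do.call(rbind, strsplit(instances, ""))
  pfm <- vapply(seq_len(w), function(j)
    c(A = sum(chars[, j] == "A"), C = sum(chars[, j] == "C"),
      G = sum(chars[, j] == "G"), T = sum(chars[, j] == "T")),
    integer(4))
  pfm
}

#' Attention-driven motif extraction pipeline
#'
#' End-to-end procedure: per positive sequence, accumulate final-layer CLS
#' attention into a profile, detect 6-10 nt high-attention regions, treat the
#' covered subsequences as motif candidates, keep candidates enriched in the
#' positive set (hypergeometric p < `p_cutoff`), merge similar candidates by
#' ungapped pairwise alignment, and report merged motifs with position
#' frequency matrices, sorted by instance count.
#'
#' @param dataset an [attention_dataset()] over the positive sequences (test
#'   partition); profiles are computed from its tensors and candidate
#'   subsequences from its tokenized sequences.
#' @param negatives character vector of negative sequences (enrichment
#'   contrast only).
#' @param p_cutoff hypergeometric cutoff (default 0.005).
#' @param min_len,max_len candidate length bounds in nucleotides.
#' @param identity merge identity threshold (default 0.7).
#' @return list with `motifs` (merged motif list; each with `pfm`) and
#'   `candidates` (per-candidate report data.frame: consensus, n_instances,
#'   pos_count, neg_count, p_value, kept).
#' @export
extract_motifs <- function(dataset, negatives, p_cutoff = 0.005,
                           min_len = 6L, max_len = 10L, identity = 0.7) {
  stopifnot(inherits(dataset, "attention_dataset"))
  positives <- vapply(dataset$tokenized, `[[`, character(1), "sequence")
  k <- dataset$tokenized[[1L]]$k
  # gather candidate subsequences
  occ <- list()
  for (n in seq_along(dataset$tensors)) {
    prof <- cls_attention_profile(dataset$tensors[[n]])
    regions <- find_high_attention_regions(prof, k, min_len, max_len)
    for (r in seq_len(nrow(regions))) {
      s <- substr(positives[n], regions[r, 1L] + 1L, regions[r, 2L])
      occ[[length(occ) + 1L]] <- data.frame(
        consensus = s, sequence = n,
        start = regions[r, 1L], end = regions[r, 2L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(occ) == 0L)
    return(list(motifs = list(),
                candidates = data.frame(consensus = character(),
                                        n_instances = integer(),
                                        pos_count = integer(),
                                        neg_count = integer(),
                                        p_value = numeric(),
                                        kept = logical())))
  occ <- do.call(rbind, occ)
  cands <- lapply(split(occ, occ$consensus), function(df) {
    enr <- hypergeometric_enrichment(df$consensus[1L], positives, negatives)
    list(consensus = df$consensus[1L],
         instances = df[, c("sequence", "start", "end")],
         pos_count = enr$pos_count, neg_count = enr$neg_count,
         p_value = enr$p_value)
  })
  report <- data.frame(
    consensus = vapply(cands, `[[`, character(1), "consensus"),
    n_instances = vapply(cands, function(c) nrow(c$instances), integer(1)),
    pos_count = vapply(cands, `[[`, integer(1), "pos_count"),
    neg_count = vapply(cands, `[[`, integer(1), "neg_count"),
    p_value = vapply(cands, `[[`, numeric(1), "p_value"),
    row.names = NULL, stringsAsFactors = FALSE)
  report$kept <- report$p_value < p_cutoff
  kept <- cands[report$kept]
  motifs <- merge_motif_candidates(unname(kept), identity = identity)
  # PFM per merged motif: align member instances onto the representative
  # window and keep those fully inside their sequence
  for (j in seq_along(motifs)) {
    mo <- motifs[[j]]
    w <- nchar(mo$consensus)
    inst <- character(0)
    for (mi in seq_along(mo$members)) {
      mseqs <- mo$instances[mo$instances$end - mo$instances$start ==
                              nchar(mo$members[mi]) &
                            vapply(seq_len(nrow(mo$instances)), function(r)
                              substr(positives[mo$instances$sequence[r]],
                                     mo$instances$start[r] + 1L,
                                     mo$instances$end[r]) == mo$members[mi],
                              logical(1)), , drop = FALSE]
      for (r in seq_len(nrow(mseqs))) {
        a <- mseqs$start[r] - mo$offsets[mi]  # representative window start
        s <- positives[mseqs$sequence[r]]
        if (a >= 0L && a + w <= nchar(s))
          inst <- c(inst, substr(s, a + 1L, a + w))
      }
    }
    if (length(inst)) motifs[[j]]$pfm <- build_pfm(inst)
    motifs[[j]]$aligned_instances <- inst
  }
  list(motifs = motifs, candidates = report[order(report$p_value), ])
}

#' Write motifs in MEME minimal format
#'
#' @param motifs merged motif list from [extract_motifs()] (elements need a
#'   `pfm` and `consensus`).
#' @param path output file.
#' @param background background base frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (mo in motifs) {
    if (is.null(mo$pfm)) next
    nsites <- sum(mo$pfm[, 1L])
    ppm <- sweep(mo$pfm, 2L, colSums(mo$pfm), "/")
    writeLines(c(sprintf("MOTIF %s", mo$consensus),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
                         ncol(ppm), nsites, mo$p_value)), con)
    for (j in seq_len(ncol(ppm)))
      writeLines(sprintf(" %8.6f %8.6f %8.6f %8.6f",
                         ppm[1L, j], ppm[2L, j], ppm[3L, j], ppm[4L, j]), con)
    writeLines("", con)
  }
  invisible(path)
}
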