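#' Rank transcript isoforms and return the most prominent one
#'
#' Selects the representative isoform of a gene the way transcript-region
#' annotation pipelines do: by APPRIS category first (principal before
#' alternative, lower number preferred), then transcript support level (TSL,
#' lower preferred, missing treated as worst), then transcript length (longer
#' preferred). Remaining ties are broken by transcript id string order.
#'
#' @param records data.frame with columns `transcript_id`, `appris` (e.g.
#'   `"principal1"`, `"alternative2"`, or NA), `tsl` (integer or NA) and
#'   `length` (nucleotides, > 0).
#' @return the winning `transcript_id` (single string).
#' @export
rank_isoforms <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot rank an empty isoform list")
  if (any(records$length <= 0)) stop("transcript length must be positive")
  ar <- appris_rank(records$appris)
  tsl <- suppressWarnings(as.numeric(records$tsl))
  tsl[is.na(tsl)] <- Inf
  ord <- order(ar, tsl, -records$length, records$transcript_id)
  records$transcript_id[ord[1L]]
}

# APPRIS tags to a numeric rank: principal1 < ... < principal5 <
# alternative1 < alternative2 < anything else/missing.
appris_rank <- function(tag) {
  tag <- tolower(as.character(tag))
  num <- suppressWarnings(as.numeric(sub("^[a-z:]*", "", tag)))
  num[is.na(num)] <- 9
  rank <- rep(Inf, length(tag))
  rank[grepl("^principal", tag)] <- num[grepl("^principal", tag)]
  rank[grepl("^alternative", tag)] <- 10 + num[grepl("^alternative", tag)]
  rank
}

#' Sequence-level region-type indicator
#'
#' Flags a genomic interval as carrying a transcript-region property (5'UTR,
#' 3'UTR, intron, CDS) when it overlaps at least one annotated nucleotide of
#' that region type on the same chromosome and strand. Strandless annotation
#' rows (`*`) match both strands. Coordinates are 0-based half-open.
#'
#' @param chrom,start,end,strand the sequence interval (vectors recycle).
#' @param annotation a [GenomicRanges::GRanges] with metadata column
#'   `region_type`, e.g. from [read_bed()].
#' @param region_type which region type to test; one of `"five_prime_utr"`,
#'   `"three_prime_utr"`, `"intron"`, `"cds"`.
#' @return integer vector of 0/1 flags, one per input interval.
#' @export
region_indicator <- function(chrom, start, end, strand, annotation,
                             region_type) {
  if (any(start >= end)) stop("malformed interval: start >= end")
  region_type <- match.arg(region_type,
    c("five_prime_utr", "three_prime_utr", "intron", "cds"))
  ann <- annotation[annotation$region_type == region_type]
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand)
  # seqlevel mismatch between query and annotation is expected (unseen
  # chromosomes simply score 0), so the combine warning is silenced
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(q, ann, minoverlap = 1L))
  as.integer(hits > 0L)
}

#' Parse a dot-bracket secondary structure
#'
#' @param dot_bracket string over `.`, `(`, `)`; balanced and non-crossing
#'   (pseudoknots and extended bracket alphabets are rejected).
#' @return integer vector of length `nchar(dot_bracket)`: the 1-based partner
#'   of each position, or NA if unpaired.
#' @export
parse_dot_bracket <- function(dot_bracket) {
  ch <- strsplit(dot_bracket, "")[[1L]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid structure character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced dot-bracket: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket: unmatched '(' at position ", stack[1L])
  partner
}

#' Classify loop types of a secondary structure
#'
#' Assigns each nucleotide one of six structural states: `S` (stem, any paired
#' base), `F` (dangling start: unpaired before the first paired base), `T`
#' (dangling end: unpaired after the last paired base), `H` (hairpin loop:
#' unpaired region whose loop is closed by exactly one pair), `I` (internal
#' loop or bulge: loop closed by exactly two pairs) and `M` (multibranched
#' loop: closed by three or more pairs). Unpaired stretches between stems at
#' the outermost level are labeled `M` (junction semantics; the six-letter
#' alphabet has no exterior-loop state). A structure with no pairs is labeled
#' all `F`.
#'
#' @param dot_bracket a valid dot-bracket string.
#' @return single string of per-nucleotide labels over `F,T,I,H,M,S`.
#' @export
classify_loop_types <- function(dot_bracket) {
  ch <- strsplit(dot_bracket, "")[[1L]]
  n <- length(ch)
  partner <- parse_dot_bracket(dot_bracket)
  labels <- rep(NA_character_, n)
  paired <- !is.na(partner)
  labels[paired] <- "S"
  if (!any(paired)) return(paste(rep("F", n), collapse = ""))

  # parent[i]: position of the innermost '(' enclosing position i (NA at top
  # level). For an open bracket, its own parent is the enclosing open bracket.
  parent <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      parent[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      stack <- stack[-length(stack)]
    } else {
      parent[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
    }
  }
  # children per open bracket: pairs whose parent is that bracket
  opens <- which(ch == "(")
  n_children <- integer(n)
  has_parent <- opens[!is.na(parent[opens])]
  if (length(has_parent)) {
    tb <- table(parent[has_parent])
    n_children[as.integer(names(tb))] <- as.integer(tb)
  }

  first_pair <- min(which(paired)); last_pair <- max(which(paired))
  un <- which(!paired)
  for (i in un) {
    if (i < first_pair) { labels[i] <- "F"; next }
    if (i > last_pair)  { labels[i] <- "T"; next }
    p <- parent[i]
    if (is.na(p)) { labels[i] <- "M"; next }  # exterior between stems
    closing <- 1L + n_children[p]
    labels[i] <- if (closing == 1L) "H" else if (closing == 2L) "I" else "M"
  }
  paste(labels, collapse = "")
}

#' Token-level property indicator from per-nucleotide labels
#'
#' A sequence token is flagged 1 when any nucleotide in its span carries the
#' property label. CLS/SEP are never part of the output.
#'
#' @param tokenized a `tokenized_seq`.
#' @param nucleotide_labels per-base label string, same length as the
#'   tokenized sequence (e.g. from [classify_loop_types()]).
#' @param property the label value of interest (single character).
#' @return integer vector of 0/1 flags of length `L` (sequence tokens only).
#' @export
token_property_indicator <- function(tokenized, nucleotide_labels, property) {
  stopifnot(inherits(tokenized, "tokenized_seq"))
  n <- nchar(tokenized$sequence)
  if (nchar(nucleotide_labels) != n)
    stop(sprintf("label string length %d != sequence length %d",
                 nchar(nucleotide_labels), n))
  lab <- strsplit(nucleotide_labels, "")[[1L]]
  hit <- lab == property
  k <- tokenized$k
  vapply(seq_len(tokenized$L), function(j) {
    as.integer(any(hit[j:(j + k - 1L)]))
  }, integer(1))
}

#' Token-level indicators for all six loop types
#'
#' Convenience wrapper around [token_property_indicator()] returning one 0/1
#' column per structural state.
#'
#' @param tokenized a `tokenized_seq`.
#' @param nucleotide_labels per-base label string over `F,T,I,H,M,S`.
#' @return integer matrix `L x 6` with columns F, T, I, H, M, S.
#' @export
loop_token_indicators <- function(tokenized, nucleotide_labels) {
  states <- c("F", "T", "I", "H", "M", "S")
  m <- vapply(states, function(s)
    token_property_indicator(tokenized, nucleotide_labels, s),
    integer(tokenized$L))
  if (tokenized$L == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, states))
  m
}
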