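#' k-mer vocabulary for nucleotide language models
#'
#' Enumerates the full token vocabulary used by the encoder: five special
#' tokens (PAD, UNK, CLS, SEP, MASK, in that fixed order so token-id files are
#' reproducible byte-for-byte) followed by all `4^k` k-mers over A/C/G/T in
#' lexicographic order. Token ids are 0-based.
#'
#' @param k k-mer size; supported range is 3 to 6.
#' @return An object of class `kmer_vocab` with elements `k`, `tokens`
#'   (character vector of length `4^k + 5`) and `id` (named integer vector
#'   mapping token string to 0-based id).
#' @examples
#' v <- build_vocabulary(3)
#' length(v$tokens)  # 69
#' @export
build_vocabulary <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  if (k < 3L || k > 6L)
    stop("k out of supported range: must be between 3 and 6, got ", k)
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), k))
  kmers <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  tokens <- c("PAD", "UNK", "CLS", "SEP", "MASK", kmers)
  id <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(k = k, tokens = tokens, id = id), class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k=%d, %d tokens (5 special + %d k-mers)\n",
              x$k, length(x$tokens), length(x$tokens) - 5L))
  invisible(x)
}

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and maps U to T. Any remaining character outside A/C/G/T is an
#' error naming the first offending position; ambiguity codes are expected to
#' be removed upstream by [clean_sequences()].
#'
#' @param sequence a single nucleotide string.
#' @return normalized string over A/C/G/T.
#' @export
normalize_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  s
}

#' Tokenize a sequence into overlapping k-mers with CLS/SEP
#'
#' Renders a nucleotide sequence as the token stream the encoder consumes:
#' CLS, then all `L = nchar(sequence) - k + 1` overlapping k-mers left to
#' right, then SEP. U is mapped to T and case is folded before tokenization.
#'
#' @param sequence nucleotide string of length >= k over A/C/G/T/U (any case).
#' @param vocab a [build_vocabulary()] result.
#' @return An object of class `tokenized_seq` with elements `sequence`
#'   (normalized), `k`, `tokens` (character, including CLS/SEP), `token_ids`
#'   (0-based integer ids) and `L` (number of sequence tokens).
#' @examples
#' ts <- tokenize("ACGTAC", build_vocabulary(3))
#' ts$tokens  # CLS ACG CGT GTA TAC SEP
#' @export
tokenize <- function(sequence, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  s <- normalize_sequence(sequence)
  k <- vocab$k
  n <- nchar(s)
  if (n < k)
    stop(sprintf("sequence length %d is shorter than k = %d", n, k))
  L <- n - k + 1L
  starts <- seq_len(L)
  kmers <- substring(s, starts, starts + k - 1L)
  tokens <- c("CLS", kmers, "SEP")
  ids <- unname(vocab$id[tokens])
  structure(list(sequence = s, k = k, tokens = tokens,
                 token_ids = as.integer(ids), L = L),
            class = "tokenized_seq")
}

#' @export
print.tokenized_seq <- function(x, ...) {
  cat(sprintf("<tokenized_seq> %d nt, k=%d, L=%d (+CLS/SEP)\n",
              nchar(x$sequence), x$k, x$L))
  invisible(x)
}

#' Nucleotide span covered by a sequence token
#'
#' Maps a 0-based sequence-token index (CLS/SEP excluded) back to the 0-based
#' half-open nucleotide interval it covers on the input sequence.
#'
#' @param token_index 0-based index in `0..L-1`.
#' @param k k-mer size.
#' @param L number of sequence tokens, used for range checking (optional).
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
token_span <- function(token_index, k, L = NULL) {
  if (any(token_index < 0L)) stop("token_index out of range (negative)")
  if (!is.null(L) && any(token_index >= L))
    stop("token_index out of range: must be < L = ", L)
  cbind(start = as.integer(token_index), end = as.integer(token_index + k))
}

#' Reconstruct the nucleotide sequence from a tokenization
#'
#' Concatenates the first token with the last nucleotide of each subsequent
#' sequence token; inverse of [tokenize()].
#'
#' @param tokenized a `tokenized_seq`.
#' @return the nucleotide string.
#' @export
detokenize <- function(tokenized) {
  stopifnot(inherits(tokenized, "tokenized_seq"))
  kmers <- tokenized$tokens[c(-1L, -length(tokenized$tokens))]
  if (length(kmers) == 1L) return(kmers)
  paste0(kmers[1L], paste(substring(kmers[-1L], tokenized$k, tokenized$k),
                          collapse = ""))
}

#' Write tokenized sequences as a TSV of token ids
#'
#' One row per sequence: id, sequence length, space-separated 0-based token
#' ids (including CLS/SEP).
#'
#' @param tokenized_list named list of `tokenized_seq` objects (names become
#'   sequence ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_token_ids <- function(tokenized_list, path) {
  ids <- names(tokenized_list)
  if (is.null(ids)) ids <- paste0("seq", seq_along(tokenized_list))
  rows <- vapply(seq_along(tokenized_list), function(i) {
    ts <- tokenized_list[[i]]
    paste(ids[i], nchar(ts$sequence),
          paste(ts$token_ids, collapse = " "), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
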