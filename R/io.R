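#' Read a labeled FASTA file
#'
#' Headers follow the `>id|label` convention (label optional; anything after
#' the first `|` is the label). Returns a labeled sequence set: a data.frame
#' with columns `id`, `sequence`, `label`.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `sequence`, `label` (label is
#'   `"unlabeled"` when the header carries none), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  hdr <- names(x)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1L)
  label <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "unlabeled",
                  character(1))
  data.frame(id = id, sequence = as.character(x), label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a labeled sequence set as FASTA
#'
#' @param set data.frame with columns `id`, `sequence` and optionally `label`
#'   (written into the header as `>id|label`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  hdr <- if (!is.null(set$label)) paste(set$id, set$label, sep = "|") else set$id
  writeLines(paste0(">", hdr, "\n", set$sequence), path, sep = "\n")
  invisible(path)
}

#' Read region annotations from a BED file
#'
#' BED intervals are 0-based half-open. Column 4 carries the region-type tag
#' (one of `five_prime_utr`, `three_prime_utr`, `intron`, `cds`); column 6,
#' when present, the strand. Rows without a strand column (or with `.`) match
#' both strands.
#'
#' @param path BED file (3 to 6 whitespace-separated columns, no header).
#' @return a [GenomicRanges::GRanges] with metadata column `region_type`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  if (ncol(tab) < 4L) stop("BED file must have at least 4 columns")
  start <- suppressWarnings(as.numeric(tab[[2L]]))
  end <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(start) || anyNA(end) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop("non-integer coordinates in BED file")
  if (any(start >= end))
    stop("malformed BED interval: start >= end at row ",
         which(start >= end)[1L])
  strand <- if (ncol(tab) >= 6L) tab[[6L]] else rep(".", nrow(tab))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = start + 1, end = end),  # BED -> 1-based
    strand = strand)
  gr$region_type <- tab[[4L]]
  gr
}

#' Read Vienna-format secondary structures
#'
#' Plain-text records of the form: a `>id` header line (optional), a sequence
#' line, and a dot-bracket line of the same length.
#'
#' @param path Vienna file.
#' @return data.frame with columns `id`, `sequence`, `dot_bracket`.
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ids <- character(); seqs <- character(); dbs <- character()
  i <- 1L; auto <- 0L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- sub("^>", "", lines[i]); i <- i + 1L
    } else {
      auto <- auto + 1L; id <- paste0("structure", auto)
    }
    if (i + 1L > length(lines)) stop("truncated Vienna record for ", id)
    seq <- lines[i]; db <- lines[i + 1L]
    db <- sub("\\s.*$", "", db)  # strip trailing free-energy annotation
    if (nchar(db) != nchar(seq))
      stop("dot-bracket length differs from sequence length for ", id)
    ids <- c(ids, id); seqs <- c(seqs, seq); dbs <- c(dbs, db)
    i <- i + 2L
  }
  data.frame(id = ids, sequence = seqs, dot_bracket = dbs,
             stringsAsFactors = FALSE)
}

#' Write Vienna-format secondary structures
#'
#' @param structures data.frame with columns `id`, `sequence`, `dot_bracket`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(structures, path) {
  writeLines(paste0(">", structures$id, "\n", structures$sequence, "\n",
                    structures$dot_bracket), path)
  invisible(path)
}

#' Save an attention archive
#'
#' Serializes a list of per-sequence attention tensors (4-d arrays indexed
#' layer x head x token x token) together with their tokenizations so that the
#' attention analyses can run with no live model. The archive is an RDS file;
#' use [export_attention_tsv()] for a plain-text long-format dump.
#'
#' @param dataset an `attention_dataset` (see [attention_dataset()]).
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_attention_archive <- function(dataset, path) {
  stopifnot(inherits(dataset, "attention_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' Load an attention archive written by [write_attention_archive()]
#'
#' @param path `.rds` archive.
#' @return an `attention_dataset`.
#' @export
read_attention_archive <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "attention_dataset")) stop("not an attention archive: ", path)
  x
}

#' Export attention tensors as long-format TSV
#'
#' Columns: sequence index, layer, head, from-token i, to-token j (all
#' 1-based), attention weight. Intended for interoperability and small
#' tensors; quadratic in sequence length.
#'
#' @param dataset an `attention_dataset`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_attention_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "attention_dataset"))
  rows <- lapply(seq_along(dataset$tensors), function(n) {
    a <- dataset$tensors[[n]]
    d <- dim(a)
    idx <- expand.grid(layer = seq_len(d[1]), head = seq_len(d[2]),
                       i = seq_len(d[3]), j = seq_len(d[4]))
    data.frame(sequence = n, idx, alpha = as.vector(a))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a head grid as TSV
#'
#' @param grid a layers x heads matrix (a head grid).
#' @param path output TSV with columns layer, head (1-based), value.
#' @return `path`, invisibly.
#' @export
write_head_grid <- function(grid, path) {
  df <- data.frame(layer = as.vector(row(grid)), head = as.vector(col(grid)),
                   value = as.vector(grid))
  df <- df[order(df$layer, df$head), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
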