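#' Encode nucleotide sequences in SOLiD di-base color space
#'
#' Each color encodes the transition between two adjacent bases, anchored
#' at a known primer base: an identical pair gives color 0, an A/C or G/T
#' pair gives 1, an A/G or C/T pair gives 2, and a complementary pair
#' (A/T or C/G) gives 3. Color `i` of the output is the transition between
#' base `i-1` and base `i` of the input, with the primer base standing in
#' as "base 0".
#'
#' @param bases Character vector of uppercase A/C/G/T sequences.
#' @param primer_base Single base (or vector recycled to `length(bases)`),
#'   one of A, C, G, T.
#' @return Character vector of color strings over `0123`, one color per
#'   input base.
#' @examples
#' encode_colorspace("ACGT", "A")   # "0131"
#' decode_colorspace("T", "3000")   # "AAAA"
#' @export
encode_colorspace <- function(bases, primer_base) {
  .check_bases(bases)
  p <- .check_primer(primer_base, length(bases))
  cpp_encode_colors(bases, p)
}

#' Decode SOLiD color strings back to nucleotide sequences
#'
#' Inverse of [encode_colorspace()]: `decode_colorspace(p, encode_colorspace(s, p))`
#' recovers `s` for every sequence and primer base.
#'
#' @param primer_base Single base (or vector), one of A, C, G, T.
#' @param colors Character vector of nonempty color strings over `0123`.
#'   A `.` missing-call character is rejected with an error.
#' @return Character vector of decoded base sequences.
#' @export
decode_colorspace <- function(primer_base, colors) {
  .check_colors(colors)
  p <- .check_primer(primer_base, length(colors))
  cpp_decode_colors(colors, p)
}

.base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.check_primer <- function(primer_base, n) {
  if (!all(primer_base %in% names(.base_codes)))
    stop("primer_base must be one of A, C, G, T", call. = FALSE)
  rep_len(unname(.base_codes[primer_base]), n)
}

.check_bases <- function(bases) {
  if (length(bases) == 0) return(invisible(bases))
  if (any(!nzchar(bases)))
    stop("empty base sequence", call. = FALSE)
  bad <- regexpr("[^ACGT]", bases)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "invalid character '%s' at position %d of sequence %d (only uppercase A/C/G/T allowed)",
      substr(bases[i], bad[i], bad[i]), bad[i], i), call. = FALSE)
  }
  invisible(bases)
}

.check_colors <- function(colors) {
  if (length(colors) == 0) return(invisible(colors))
  if (any(!nzchar(colors)))
    stop("empty color string", call. = FALSE)
  bad <- regexpr("[^0-3]", colors)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    ch <- substr(colors[i], bad[i], bad[i])
    extra <- if (ch == ".") " (missing color calls are rejected, not imputed)" else ""
    stop(sprintf("invalid color character '%s' at position %d of read %d%s",
                 ch, bad[i], i, extra), call. = FALSE)
  }
  invisible(colors)
}

#' Construct and validate a set of color-space reads
#'
#' A color-read set is a data frame with columns `read_id`, `primer`
#' (single base), `colors` (string over `0123`) and `quals` (list column
#' of non-negative integer Phred-like values, one per color). Qualities
#' are carried for format fidelity but take no part in alignment.
#'
#' @param read_id Character vector of unique read identifiers.
#' @param primer Primer base per read (recycled).
#' @param colors Color strings, one per read.
#' @param quals List of integer vectors, one value per color; a single
#'   integer is recycled across all colors of all reads.
#' @return A validated `data.frame` of class `color_read_set`.
#' @export
color_reads <- function(read_id, primer, colors, quals = 30L) {
  .check_colors(colors)
  primer <- rep_len(primer, length(colors))
  .check_primer(primer, length(colors))
  if (anyDuplicated(read_id))
    stop("duplicate read ids", call. = FALSE)
  nc <- nchar(colors)
  if (!is.list(quals)) quals <- lapply(nc, function(n) rep_len(as.integer(quals), n))
  if (length(quals) != length(colors))
    stop("quals must have one entry per read", call. = FALSE)
  qlen <- lengths(quals)
  if (any(qlen != nc))
    stop(sprintf("read %d has %d colors but %d quality values",
                 which(qlen != nc)[1], nc[which(qlen != nc)[1]],
                 qlen[which(qlen != nc)[1]]), call. = FALSE)
  if (any(unlist(quals, use.names = FALSE) < 0))
    stop("quality values must be >= 0", call. = FALSE)
  out <- data.frame(read_id = as.character(read_id), primer = primer,
                    colors = colors, stringsAsFactors = FALSE)
  out$quals <- quals
  class(out) <- c("color_read_set", "data.frame")
  out
}

#' Read and write csfasta/qual files
#'
#' `read_csfasta()` parses the SOLiD csfasta text format (header lines
#' `>id`, sequence lines consisting of the primer base followed by color
#' digits) together with an optional paired `.qual` file holding one
#' space-separated integer per color under matching ids.
#'
#' @param csfasta Path to a csfasta file.
#' @param qual Optional path to the paired qual file.
#' @return A `color_read_set` data frame (see [color_reads()]).
#' @export
read_csfasta <- function(csfasta, qual = NULL) {
  lines <- readLines(csfasta)
  lines <- lines[!grepl("^#", lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no reads in ", csfasta, call. = FALSE)
  if (!all(hdr == rep(c(TRUE, FALSE), length.out = length(hdr))))
    stop("malformed csfasta: expected alternating header/sequence lines",
         call. = FALSE)
  ids <- sub("^>", "", lines[hdr])
  seqs <- lines[!hdr]
  primer <- substr(seqs, 1, 1)
  colors <- substr(seqs, 2, nchar(seqs))
  quals <- 30L
  if (!is.null(qual)) {
    qlines <- readLines(qual)
    qlines <- qlines[!grepl("^#", qlines)]
    qhdr <- grepl("^>", qlines)
    qids <- sub("^>", "", qlines[qhdr])
    if (!identical(qids, ids))
      stop("qual file ids do not match csfasta ids", call. = FALSE)
    quals <- lapply(strsplit(trimws(qlines[!qhdr]), "\\s+"), as.integer)
  }
  color_reads(ids, primer, colors, quals)
}

#' @rdname read_csfasta
#' @param reads A `color_read_set`.
#' @param path Output csfasta path.
#' @param qual_path Optional output qual path.
#' @export
write_csfasta <- function(reads, path, qual_path = NULL) {
  stopifnot(inherits(reads, "color_read_set"))
  out <- character(2 * nrow(reads))
  out[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
  out[c(FALSE, TRUE)] <- paste0(reads$primer, reads$colors)
  writeLines(out, path)
  if (!is.null(qual_path)) {
    qout <- character(2 * nrow(reads))
    qout[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
    qout[c(FALSE, TRUE)] <- vapply(reads$quals, paste, "", collapse = " ")
    writeLines(qout, qual_path)
  }
  invisible(path)
}

#' Read/write nucleotide FASTA as named character vectors
#'
#' Thin wrappers around Biostrings FASTA I/O; sequences are validated to
#' be nonempty uppercase A/C/G/T (ambiguity codes rejected).
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  .check_bases(seqs)
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of A/C/G/T sequences.
#' @export
write_fasta <- function(seqs, path) {
  .check_bases(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
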