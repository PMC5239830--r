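#' Build the 3'-end trimming ladder
#'
#' Reads are mapped full-length first; reads that fail are progressively
#' trimmed at the 3' end and remapped, which resolves short inserts that
#' run through into adapter sequence. The canonical ladder for 50-nt
#' reads trims in 11 steps of 4, 3 and 2 nt down to the 19-nt
#' size-selection floor: lengths 50, 46, 43, 40, 37, 34, 31, 28, 25, 23,
#' 21, 19. For other length pairs the schedule uses the fewest steps with
#' sizes in {4, 3, 2}, larger sizes first.
#'
#' @param initial_length Untrimmed read length (nt).
#' @param min_length Shortest aligned length; must be >= 19, the floor
#'   imposed by library size selection.
#' @param steps Optional explicit step sizes (each in {4, 3, 2}) summing
#'   to `initial_length - min_length`, overriding the default rule.
#' @return A `trim_schedule`: list with `initial_length`, `min_length`,
#'   `steps` and the descending `lengths` ladder (first entry untrimmed).
#' @examples
#' make_trim_schedule(50, 19)$steps  # the 11-step default
#' make_trim_schedule(23, 19)$steps  # 4
#' @export
make_trim_schedule <- function(initial_length, min_length = 19L,
                               steps = NULL) {
  initial_length <- as.integer(initial_length)
  min_length <- as.integer(min_length)
  if (min_length < 19)
    stop("min_length must be >= 19 nt (library size-selection floor)",
         call. = FALSE)
  if (initial_length < min_length)
    stop("initial_length must be >= min_length", call. = FALSE)
  d <- initial_length - min_length
  if (is.null(steps)) {
    if (d == 0) {
      steps <- integer(0)
    } else if (initial_length == 50L && min_length == 19L) {
      steps <- c(4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L)
    } else if (d == 1) {
      stop("no schedule with step sizes in {4,3,2} reaches ",
           min_length, " from ", initial_length, call. = FALSE)
    } else {
      n <- ceiling(d / 4)   # n steps from {2,3,4} cover any total in [2n, 4n]
      rem <- d - 2 * n      # extra to spread over 2-nt base steps
      k4 <- rem %/% 2
      k3 <- rem %% 2
      steps <- c(rep(4L, k4), rep(3L, k3), rep(2L, n - k4 - k3))
    }
  }
  steps <- as.integer(steps)
  if (!all(steps %in% c(4L, 3L, 2L)))
    stop("step sizes must be 4, 3 or 2 nt", call. = FALSE)
  if (sum(steps) != d)
    stop("steps must sum to initial_length - min_length", call. = FALSE)
  lengths <- c(initial_length, initial_length - cumsum(steps))
  structure(list(initial_length = initial_length, min_length = min_length,
                 steps = steps, lengths = as.integer(lengths)),
            class = "trim_schedule")
}

#' Alignment parameters
#'
#' @param max_mismatches Maximum mismatches per placement (color
#'   mismatches for color-space reads, where one base substitution shows
#'   up as two adjacent color mismatches). Default 2.
#' @param k Maximum placements reported per read: 1 (class contribution
#'   mode) or 2 (abundance quantification mode).
#' @return An `align_params` list.
#' @export
align_params <- function(max_mismatches = 2L, k = 1L) {
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2", call. = FALSE)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 k = as.integer(k)),
            class = "align_params")
}

# lexicographic rank of reference ids, C-locale, for deterministic
# tie-breaking
.ref_rank <- function(ids) {
  r <- integer(length(ids))
  r[order(ids, method = "radix")] <- seq_along(ids)
  r
}

.empty_records <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             position = integer(0), strand = character(0),
             aligned_length = integer(0), mismatches = integer(0),
             trim_step = integer(0), stringsAsFactors = FALSE)
}

#' Align a library of reads against one reference tier
#'
#' Each read is first placed full-length on both strands with at most
#' `max_mismatches` mismatches; reads with no placement are trimmed per
#' the schedule and retried, stopping at the first ladder length that
#' yields a placement (deeper trims are never attempted once a read is
#' placed). At most `k` placements per read are reported, ranked by
#' fewest mismatches, then longest aligned length, then lowest reference
#' id (lexicographic), then lowest position, with the + strand before
#' the - strand. Color-space reads are compared in color space against
#' the color-encoded reference, the first color against the primer
#' transition. Reads shorter than `min_length` get a `too_short` status
#' rather than an error.
#'
#' @param reads A `color_read_set` (see [color_reads()]) or a named
#'   character vector of nucleotide sequences.
#' @param tier A `reference_tier`.
#' @param params [align_params()].
#' @param schedule [make_trim_schedule()]; defaults to the ladder from
#'   the longest read length down to 19 nt.
#' @return List of class `alignment_result` with elements `records`
#'   (data frame: read_id, ref_id, position (1-based, fully closed
#'   convention), strand, aligned_length, mismatches, trim_step),
#'   `unaligned` and `too_short` (character vectors of read ids).
#' @export
align_library <- function(reads, tier, params = align_params(),
                          schedule = NULL) {
  stopifnot(inherits(tier, "reference_tier"))
  colorspace <- inherits(reads, "color_read_set")
  if (colorspace) {
    ids <- reads$read_id
    qry <- reads$colors
    primers <- unname(.base_codes[reads$primer])
  } else {
    qry <- unname(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(qry))
    primers <- rep(0L, length(qry))
    .check_bases(qry)
  }
  if (is.null(schedule)) {
    maxlen <- if (length(qry)) max(nchar(qry)) else 19L
    schedule <- make_trim_schedule(max(maxlen, 19L), 19L)
  }
  stopifnot(inherits(schedule, "trim_schedule"))
  if (length(qry) == 0)
    return(structure(list(records = .empty_records(),
                          unaligned = character(0),
                          too_short = character(0)),
                     class = "alignment_result"))
  ref_ids <- names(tier$seqs)
  res <- cpp_align_library(unname(tier$seqs), .ref_rank(ref_ids),
                           qry, primers, colorspace,
                           schedule$lengths, schedule$min_length,
                           params$max_mismatches, params$k)
  records <- data.frame(
    read_id = ids[res$read],
    ref_id = ref_ids[res$ref],
    position = res$pos,
    strand = c("+", "-")[res$strand + 1L],
    aligned_length = res$len,
    mismatches = res$mm,
    trim_step = res$step,
    stringsAsFactors = FALSE)
  structure(list(records = records,
                 unaligned = ids[res$status == 1L],
                 too_short = ids[res$status == 2L]),
            class = "alignment_result")
}

#' @rdname align_library
#' @param read A single read: one-row `color_read_set`, a list with
#'   `colors` and `primer`, or a nucleotide string.
#' @return `align_read()`: the records data frame for that read (empty
#'   when unaligned), with a `status` attribute of `aligned`,
#'   `unaligned` or `too_short`.
#' @export
align_read <- function(read, tier, params = align_params(),
                       schedule = NULL) {
  if (is.list(read) && !is.data.frame(read) && !is.null(read$colors)) {
    read <- color_reads(if (is.null(read$read_id)) "read1" else read$read_id,
                        read$primer, read$colors)
  } else if (is.character(read)) {
    if (is.null(names(read))) names(read) <- "read1"
  }
  res <- align_library(read, tier, params, schedule)
  status <- if (nrow(res$records)) "aligned"
            else if (length(res$too_short)) "too_short" else "unaligned"
  structure(res$records, status = status)
}

#' Write alignments as SAM
#'
#' Minimal SAM output: mandatory fields plus `NM` (mismatches), `XT`
#' (trim step) and, for color-space reads, `CS` (original color string).
#' Trimmed reads are reported at their aligned length; unaligned reads
#' are emitted with the unmapped flag.
#'
#' @param result An `alignment_result`.
#' @param reads The read set that produced it.
#' @param tier The `reference_tier` aligned against.
#' @param path Output path.
#' @export
write_sam <- function(result, reads, tier, path) {
  colorspace <- inherits(reads, "color_read_set")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(tier$seqs),
                   nchar(unname(tier$seqs))))
  rec <- result$records
  lines <- character(0)
  if (nrow(rec)) {
    if (colorspace) {
      idx <- match(rec$read_id, reads$read_id)
      full <- cpp_decode_colors(reads$colors[idx],
                                unname(.base_codes[reads$primer[idx]]))
      cs <- reads$colors[idx]
    } else {
      idx <- match(rec$read_id, names(reads))
      full <- unname(reads[idx])
      cs <- NULL
    }
    seq <- substr(full, 1, rec$aligned_length)
    rev <- rec$strand == "-"
    if (any(rev))
      seq[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[rev])))
    lines <- paste(rec$read_id, ifelse(rev, 16L, 0L), rec$ref_id,
                   rec$position, 255L, paste0(rec$aligned_length, "M"),
                   "*", 0L, 0L, seq, "*",
                   paste0("NM:i:", rec$mismatches),
                   paste0("XT:i:", rec$trim_step),
                   sep = "\t")
    if (!is.null(cs)) lines <- paste0(lines, "\tCS:Z:", cs)
  }
  una <- c(result$unaligned, result$too_short)
  if (length(una)) {
    if (colorspace) {
      idx <- match(una, reads$read_id)
      seq <- cpp_decode_colors(reads$colors[idx],
                               unname(.base_codes[reads$primer[idx]]))
    } else seq <- unname(reads[match(una, names(reads))])
    lines <- c(lines, paste(una, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                            seq, "*", sep = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
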