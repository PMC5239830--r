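#' Hierarchically classify reads through the three filtering tiers
#'
#' Every read is aligned against tier 1 (adapters, structural RNAs,
#' repeats); only reads with no tier-1 placement proceed to tier 2
#' (RefSeq exonic transcripts); only reads unplaced in both proceed to
#' tier 3 (genome). A read's class is the class label of its winning
#' reference (tier 3 entries are all `non_RefSeq`); reads placed nowhere
#' are `unmapped`. Because mitochondrial, rRNA and repeat references sit
#' in tier 1, their reads never reach tier 2 even when a tier-2
#' transcript shares sequence. With `k = 1` each aligned read gets
#' exactly one assignment (contribution mode); with `k = 2` up to two
#' placements per read are retained in `records` for fragment counting.
#'
#' @param reads A `color_read_set` or named character vector of
#'   nucleotide sequences.
#' @param tiers List of three `reference_tier` objects (see
#'   [build_tiers()]).
#' @param params [align_params()]; `k = 1` for contribution tables,
#'   `k = 2` for FPKM quantification.
#' @param schedule Shared [make_trim_schedule()] for all tiers (default:
#'   ladder from the read length down to 19 nt).
#' @return A `classification` list: `assignments` (one row per aligned
#'   read: read_id, class, tier_index, ref_id, position, strand,
#'   aligned_length, mismatches, trim_step), `records` (all retained
#'   placements, up to `k` per read, with tier_index and class),
#'   `unmapped` and `too_short` read-id vectors, and `n_reads`.
#' @export
classify_reads <- function(reads, tiers, params = align_params(k = 1L),
                           schedule = NULL) {
  stopifnot(length(tiers) == 3)
  colorspace <- inherits(reads, "color_read_set")
  n_reads <- if (colorspace) nrow(reads) else length(reads)
  if (!colorspace && is.null(names(reads)) && n_reads > 0)
    names(reads) <- paste0("read", seq_len(n_reads))
  if (is.null(schedule)) {
    maxlen <- if (colorspace) suppressWarnings(max(nchar(reads$colors), 19L))
              else suppressWarnings(max(nchar(reads), 19L))
    schedule <- make_trim_schedule(max(maxlen, 19L), 19L)
  }
  remaining <- reads
  too_short <- character(0)
  all_records <- vector("list", 3)
  for (t in 1:3) {
    tier <- tiers[[t]]
    stopifnot(inherits(tier, "reference_tier"), tier$tier_index == t)
    nrem <- if (colorspace) nrow(remaining) else length(remaining)
    if (nrem == 0) break
    res <- align_library(remaining, tier, params, schedule)
    rec <- res$records
    if (nrow(rec)) {
      rec$tier_index <- t
      rec$class <- unname(tier$classes[rec$ref_id])
      all_records[[t]] <- rec
    }
    if (t == 1) too_short <- res$too_short
    keep <- if (colorspace) remaining$read_id %in% res$unaligned
            else names(remaining) %in% res$unaligned
    remaining <- if (colorspace) remaining[keep, , drop = FALSE]
                 else remaining[keep]
  }
  records <- do.call(rbind, all_records[!vapply(all_records, is.null, TRUE)])
  if (is.null(records)) {
    records <- cbind(.empty_records(),
                     data.frame(tier_index = integer(0),
                                class = character(0)))
  }
  # winning (rank-1) placement per read: records come out of the aligner
  # already ranked, so the first occurrence wins
  assignments <- records[!duplicated(records$read_id), , drop = FALSE]
  rownames(assignments) <- NULL
  unmapped <- if (colorspace) remaining$read_id else names(remaining)
  structure(list(assignments = assignments, records = records,
                 unmapped = as.character(unmapped),
                 too_short = too_short, n_reads = n_reads),
            class = "classification")
}

#' Per-library RNA-class contribution table
#'
#' Counts reads per reportable class and expresses each as a percentage
#' of the total mapped, reportable reads. Adapter-class reads are
#' excluded from the total: they are sequencing artifacts, not library
#' content. Percentages over reportable classes sum to 100.
#'
#' @param assignments A `classification` (from [classify_reads()] with
#'   `k = 1`) or its `assignments` data frame.
#' @param library_id Library identifier for the table.
#' @return A `class_table` data frame with columns `library_id`,
#'   `class` (all reportable classes, reporting order), `reads`, `pct`,
#'   and attribute `total_mapped`. With zero reportable reads the
#'   percentages are `NA` and a warning is raised.
#' @export
class_table <- function(assignments, library_id = "library") {
  if (inherits(assignments, "classification"))
    assignments <- assignments$assignments
  cls <- reportable_classes()
  rep_asn <- assignments[assignments$class %in% cls, , drop = FALSE]
  counts <- table(factor(rep_asn$class, levels = cls))
  total <- sum(counts)
  pct <- if (total > 0) 100 * as.numeric(counts) / total else {
    warning("no reportable mapped reads in ", library_id)
    rep(NA_real_, length(cls))
  }
  out <- data.frame(library_id = library_id, class = cls,
                    reads = as.integer(counts), pct = pct,
                    stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- total
  class(out) <- c("class_table", "data.frame")
  out
}

#' Write class-contribution tables
#'
#' `write_class_table()` writes the long form (library_id, class, reads,
#' pct). `class_table_wide()` lays several libraries out side by side,
#' classes as rows, as in a fraction-by-cohort contribution table.
#'
#' @param x A `class_table`, or for the wide form a list of them.
#' @param path Output TSV path.
#' @export
write_class_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_table
#' @param tables Named list of `class_table` objects.
#' @return `class_table_wide()`: matrix of percentages, classes x
#'   libraries, with a `total_mapped` attribute per library.
#' @export
class_table_wide <- function(tables) {
  cls <- reportable_classes()
  m <- vapply(tables, function(t) t$pct[match(cls, t$class)],
              numeric(length(cls)))
  m <- matrix(m, nrow = length(cls),
              dimnames = list(cls, vapply(tables, function(t)
                t$library_id[1], "")))
  attr(m, "total_mapped") <- vapply(tables, attr, 0L, "total_mapped")
  m
}
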