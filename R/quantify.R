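#' Fragment counts from k = 2 placements
#'
#' Converts retained placements (at most two per read) into per-feature
#' fragment counts. A read with a single placement contributes 1 to its
#' feature; a read with two placements contributes 1/2 to each (uniform
#' split), so counts always sum to the number of placed reads.
#' `multi = "primary"` instead gives the whole fragment to the top-ranked
#' placement.
#'
#' @param records Placement data frame (e.g. the `records` element of a
#'   [classify_reads()] result run with `k = 2`): needs `read_id` and
#'   `ref_id`; rows per read must be in rank order for `multi = "primary"`.
#' @param features Character vector of feature ids to count over.
#' @param multi `"split"` (default) or `"primary"`.
#' @return Named numeric vector of fragment counts over `features`.
#' @export
count_fragments <- function(records, features, multi = c("split", "primary")) {
  multi <- match.arg(multi)
  out <- setNames(numeric(length(features)), features)
  if (!nrow(records)) return(out)
  if (multi == "primary") {
    records <- records[!duplicated(records$read_id), , drop = FALSE]
    w <- rep(1, nrow(records))
  } else {
    nplace <- table(records$read_id)
    w <- 1 / as.numeric(nplace[records$read_id])
  }
  keep <- records$ref_id %in% features
  agg <- tapply(w[keep], records$ref_id[keep], sum)
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Fragments per kilobase of feature per million mapped fragments
#'
#' `fpkm = count * 1e9 / (feature_length * total_mapped)`. Doubling every
#' count together with the mapped total leaves FPKM unchanged, and
#' `sum(fpkm * length) / 1e9 == sum(count) / total_mapped`.
#'
#' @param count Fragment count(s), possibly fractional.
#' @param feature_length Feature length(s) in nt, > 0.
#' @param total_mapped Total mapped fragments in the library, > 0.
#' @return Numeric FPKM value(s).
#' @export
fpkm <- function(count, feature_length, total_mapped) {
  if (any(total_mapped <= 0))
    stop("total_mapped must be > 0", call. = FALSE)
  if (any(feature_length <= 0))
    stop("feature_length must be > 0", call. = FALSE)
  count * 1e9 / (feature_length * total_mapped)
}

#' Minimum-alignment-count eligibility filter
#'
#' A feature enters differential testing only when its fragment count
#' summed across the compared libraries reaches the cut-off (default
#' 100), excluding low-abundance features whose dispersion cannot be
#' estimated usefully.
#'
#' @param counts Matrix of fragment counts (features x libraries), or a
#'   named vector of per-feature totals.
#' @param min_alignment_count Non-negative threshold; default 100.
#' @return Character vector of eligible feature ids.
#' @export
apply_min_count <- function(counts, min_alignment_count = 100) {
  if (min_alignment_count < 0)
    stop("min_alignment_count must be >= 0", call. = FALSE)
  totals <- if (is.matrix(counts)) rowSums(counts) else counts
  names(totals)[totals >= min_alignment_count]
}

#' Per-library abundance table and cross-library count matrix
#'
#' `abundance_table()` assembles feature_id, library_id, length, count
#' and fpkm for one library. `count_matrix()` binds per-library fragment
#' counts into the features x libraries matrix used by the differential
#' module.
#'
#' @param counts Named per-feature fragment counts for one library.
#' @param feature_lengths Named feature lengths (nt).
#' @param library_id Library identifier.
#' @param total_mapped Total placed fragments in the library; defaults
#'   to `sum(counts)`.
#' @return A data frame with one row per feature.
#' @export
abundance_table <- function(counts, feature_lengths, library_id,
                            total_mapped = sum(counts)) {
  feats <- names(counts)
  data.frame(feature_id = feats, library_id = library_id,
             length = as.integer(feature_lengths[feats]),
             count = as.numeric(counts),
             fpkm = fpkm(as.numeric(counts),
                         as.numeric(feature_lengths[feats]), total_mapped),
             stringsAsFactors = FALSE)
}

#' @rdname abundance_table
#' @param count_list Named list of per-feature count vectors, one per
#'   library, all over the same feature set.
#' @export
count_matrix <- function(count_list) {
  feats <- names(count_list[[1]])
  m <- vapply(count_list, function(x) as.numeric(x[feats]),
              numeric(length(feats)))
  matrix(m, nrow = length(feats),
         dimnames = list(feats, names(count_list)))
}
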