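#' Construct a reference tier
#'
#' A tier is one stage of the three-step hierarchical filter: tier 1
#' holds adapters/primers plus structural and repeat RNAs, tier 2 holds
#' RefSeq exonic transcripts (mRNA/ncRNA), and tier 3 is the genome
#' stand-in whose entries all carry the `non_RefSeq` label. Class labels
#' are checked against [class_taxonomy()] and against the set a tier may
#' legally contain.
#'
#' @param tier_index 1, 2 or 3.
#' @param seqs Named character vector of A/C/G/T sequences; names are the
#'   reference ids, unique within the tier.
#' @param classes Character vector of class labels, one per sequence
#'   (tier 3 may omit it; entries default to `non_RefSeq`).
#' @param description Free-text description of the tier.
#' @return An object of class `reference_tier`.
#' @export
reference_tier <- function(tier_index, seqs, classes = NULL,
                           description = "") {
  if (!tier_index %in% 1:3) stop("tier_index must be 1, 2 or 3", call. = FALSE)
  .check_bases(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all reference sequences must be named", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate reference ids in tier ", tier_index, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(classes)) {
    if (tier_index != 3)
      stop("classes are required for tiers 1 and 2", call. = FALSE)
    classes <- rep("non_RefSeq", length(seqs))
  }
  if (length(classes) != length(seqs))
    stop("one class label per sequence required", call. = FALSE)
  unknown <- setdiff(unique(classes), class_taxonomy())
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         " for ids ", paste(ids[classes %in% unknown], collapse = ", "),
         call. = FALSE)
  allowed <- tier_allowed_classes(tier_index)
  offending <- !classes %in% allowed
  if (any(offending))
    stop("class label(s) not allowed in tier ", tier_index, ": ",
         paste(unique(classes[offending]), collapse = ", "),
         " (ids ", paste(ids[offending], collapse = ", "), ")", call. = FALSE)
  structure(list(tier_index = as.integer(tier_index), seqs = seqs,
                 classes = setNames(classes, ids),
                 description = description),
            class = "reference_tier")
}

#' @export
print.reference_tier <- function(x, ...) {
  cat(sprintf("reference tier %d: %d entries (%s)\n", x$tier_index,
              length(x$seqs), x$description))
  print(classmap_census(x))
  invisible(x)
}

#' Read a class-map TSV (seq_id <TAB> class_label)
#'
#' @param path Path to a two-column headerless TSV.
#' @return Named character vector mapping seq_id to class label.
#' @export
read_class_map <- function(path) {
  m <- read.delim(path, header = FALSE, colClasses = "character",
                  col.names = c("seq_id", "class_label"))
  if (anyDuplicated(m$seq_id))
    stop("duplicate seq_id in class map: ",
         paste(unique(m$seq_id[duplicated(m$seq_id)]), collapse = ", "),
         call. = FALSE)
  setNames(m$class_label, m$seq_id)
}

#' @rdname read_class_map
#' @param class_map Named character vector (id -> class label).
#' @export
write_class_map <- function(class_map, path) {
  write.table(data.frame(names(class_map), unname(class_map)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the three filtering tiers from FASTA + class-map files
#'
#' Tier 1 must contain at least one `adapter` entry (the filter that
#' removes adapter/primer artifacts before any biological class is
#' assigned); tier-2 labels are restricted to `mRNA`/`ncRNA`; every
#' genome sequence becomes a `non_RefSeq` entry of tier 3.
#'
#' @param tier1_fasta,tier1_classmap Tier-1 FASTA and class-map paths.
#' @param tier2_fasta,tier2_classmap Tier-2 FASTA and class-map paths.
#' @param genome_fasta Genome FASTA path (tier 3).
#' @return List of three `reference_tier` objects.
#' @export
build_tiers <- function(tier1_fasta, tier1_classmap,
                        tier2_fasta, tier2_classmap, genome_fasta) {
  t1 <- .tier_from_files(1, tier1_fasta, tier1_classmap,
                         "adapters, structural RNAs and repeats")
  if (!"adapter" %in% t1$classes)
    stop("tier 1 must contain at least one 'adapter' entry", call. = FALSE)
  t2 <- .tier_from_files(2, tier2_fasta, tier2_classmap,
                         "RefSeq exonic transcripts")
  g <- read_fasta(genome_fasta)
  t3 <- reference_tier(3, g, description = "genome")
  list(t1, t2, t3)
}

.tier_from_files <- function(tier_index, fasta, classmap, description) {
  seqs <- read_fasta(fasta)
  cm <- read_class_map(classmap)
  missing <- setdiff(names(seqs), names(cm))
  if (length(missing))
    stop("tier ", tier_index, " ids missing from class map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reference_tier(tier_index, seqs, unname(cm[names(seqs)]), description)
}

#' Census of reference entries per class
#'
#' @param tier A `reference_tier`.
#' @return Named integer vector: class label -> number of entries; counts
#'   sum to the number of entries in the tier.
#' @export
classmap_census <- function(tier) {
  stopifnot(inherits(tier, "reference_tier"))
  if (!length(tier$classes)) return(integer(0))
  tab <- table(factor(tier$classes, levels = class_taxonomy()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}
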