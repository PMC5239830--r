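#' RNA-class taxonomy
#'
#' The ordered set of RNA classes tracked by the classifier. The first
#' label, `adapter`, marks sequencing adapters/primers; it is filtered
#' during classification and never reported in contribution tables. The
#' remaining thirteen labels are the reportable classes of the
#' per-library contribution table: mitochondrial transcripts, the major
#' structural RNAs (rRNA, tRNA, Y RNA, U snRNAs + 7SK), transcribed
#' genomic repeat families (SINE including 7SL, LINE, LTR, DNA repeats,
#' other repeats), RefSeq mRNA and ncRNA exons, and non-RefSeq
#' (genome-only) RNA.
#'
#' @return Character vector of class labels, in reporting order.
#' @export
class_taxonomy <- function() {
  c("adapter", "mitochondrial_RNA", "rRNA", "tRNA", "YRNA", "snRNA_7SK",
    "SINE", "LINE", "LTR", "DNA_repeat", "other_repeat",
    "mRNA", "ncRNA", "non_RefSeq")
}

#' @rdname class_taxonomy
#' @export
reportable_classes <- function() setdiff(class_taxonomy(), "adapter")

# classes allowed in each filtering tier; mirrors the tier semantics:
# tier 1 = adapters + structural/repeat RNAs, tier 2 = RefSeq exonic
# transcripts, tier 3 = genome (non-RefSeq)
tier_allowed_classes <- function(tier_index) {
  switch(tier_index,
    c("adapter", "mitochondrial_RNA", "rRNA", "tRNA", "YRNA", "snRNA_7SK",
      "SINE", "LINE", "LTR", "DNA_repeat", "other_repeat"),
    c("mRNA", "ncRNA"),
    "non_RefSeq")
}
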