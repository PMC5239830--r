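#' Simulation configuration
#'
#' Geometry and chemistry knobs of the synthetic library generator,
#' chosen to match the study conditions the pipeline assumes: 50-nt
#' color-space reads from inserts size-selected to be longer than 19 nt
#' and at most 100 nt, with 3' adapter read-through when the insert is
#' shorter than the read.
#'
#' @param seed Integer seed; identical configs give byte-identical
#'   output.
#' @param n_reads Reads per library (default 100,000).
#' @param read_length Read length in colors (default 50).
#' @param insert_min Smallest retained insert, nt (default 20; the size
#'   selection keeps inserts strictly longer than 19 nt).
#' @param insert_max Largest retained insert, nt (default 100).
#' @param adapter 3' adapter sequence appended after short inserts. The
#'   default is a fixed synthetic 35-mer, not a vendor sequence.
#' @param error_rate Per-color substitution probability (default 0; the
#'   study states no error model).
#' @param primer Sequencing primer base for color encoding (default
#'   `"T"`, the platform convention).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_reads = 100000L, read_length = 50L,
                       insert_min = 20L, insert_max = 100L,
                       adapter = "CGCCTTGGCCGTACAGCAGCATCGTTACGTTAGCC",
                       error_rate = 0, primer = "T") {
  if (insert_min < 20)
    stop("insert_min must be > 19 nt (size selection floor)", call. = FALSE)
  if (insert_max < insert_min)
    stop("insert_max must be >= insert_min", call. = FALSE)
  if (read_length < 19) stop("read_length must be >= 19", call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]", call. = FALSE)
  .check_bases(adapter)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 adapter = adapter, error_rate = error_rate,
                 primer = primer),
            class = "sim_config")
}

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reference census: entries per class with class-typical length ranges
.reference_plan <- function() {
  list(
    mitochondrial_RNA = list(n = 8, len = c(70, 1600), prefix = "mtRNA"),
    rRNA = list(n = 4, len = rbind(c(5070, 5070), c(1869, 1869),
                                   c(156, 156), c(121, 121)),
                prefix = "rRNA"),
    tRNA = list(n = 20, len = c(70, 90), prefix = "tRNA"),
    YRNA = list(n = 5, len = c(95, 115), prefix = "YRNA"),
    snRNA_7SK = list(n = 13, len = c(100, 331), prefix = "snRNA"),
    SINE = list(n = 6, len = c(100, 350), prefix = "SINE"),
    LINE = list(n = 3, len = c(1000, 6000), prefix = "LINE"),
    LTR = list(n = 3, len = c(300, 1000), prefix = "LTR"),
    DNA_repeat = list(n = 3, len = c(200, 1500), prefix = "DNArep"),
    other_repeat = list(n = 3, len = c(200, 1000), prefix = "otherrep"),
    mRNA = list(n = 30, len = c(500, 3000), prefix = "mRNA"),
    ncRNA = list(n = 12, len = c(200, 2000), prefix = "ncRNA"))
}

#' Generate the synthetic reference tiers
#'
#' Builds random reference sequences with class-typical lengths for
#' every class of the taxonomy -- structural RNAs, repeat consensi and
#' the adapter in tier 1, exonic mRNA/ncRNA transcripts in tier 2 and a
#' 60-kb genome stand-in as tier 3 -- together with the class map and a
#' manifest recording every id, tier, class and length. All sequences
#' are synthetic: random sequence of realistic geometry, with no human
#' homology.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, tier FASTAs, class maps
#'   and the manifest TSV are written there.
#' @return List with `tiers` (three `reference_tier`s) and `manifest`
#'   (data frame: seq_id, tier, class, length).
#' @export
generate_references <- function(config = sim_config(), dir = NULL) {
  .with_seed(config$seed, function() {
    plan <- .reference_plan()
    ids <- character(0); classes <- character(0); seqs <- character(0)
    for (cl in names(plan)) {
      p <- plan[[cl]]
      lens <- if (is.matrix(p$len)) {
        as.integer(p$len[, 1])
      } else {
        sample(p$len[1]:p$len[2], p$n, replace = TRUE)
      }
      for (i in seq_len(p$n)) {
        ids <- c(ids, sprintf("%s_%02d", p$prefix, i))
        classes <- c(classes, cl)
        seqs <- c(seqs, .random_seq(lens[i]))
      }
    }
    names(seqs) <- ids
    adapters <- c(adapter_p2 = config$adapter, adapter_primer = .random_seq(40))
    t1_cls <- setdiff(tier_allowed_classes(1), "adapter")
    tier1_seqs <- c(adapters, seqs[classes %in% t1_cls])
    tier1_classes <- c("adapter", "adapter", classes[classes %in% t1_cls])
    tier2_seqs <- seqs[classes %in% c("mRNA", "ncRNA")]
    tier2_classes <- classes[classes %in% c("mRNA", "ncRNA")]
    genome <- c(chr1 = .random_seq(60000))
    t1 <- reference_tier(1, tier1_seqs, tier1_classes,
                         "adapters, structural RNAs and repeats")
    t2 <- reference_tier(2, tier2_seqs, tier2_classes,
                         "RefSeq-like exonic transcripts")
    t3 <- reference_tier(3, genome, description = "genome stand-in")
    tiers <- list(t1, t2, t3)
    manifest <- do.call(rbind, lapply(tiers, function(t)
      data.frame(seq_id = names(t$seqs), tier = t$tier_index,
                 class = unname(t$classes), length = nchar(unname(t$seqs)),
                 stringsAsFactors = FALSE)))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(t1$seqs, file.path(dir, "tier1.fasta"))
      write_class_map(t1$classes, file.path(dir, "tier1_classmap.tsv"))
      write_fasta(t2$seqs, file.path(dir, "tier2.fasta"))
      write_class_map(t2$classes, file.path(dir, "tier2_classmap.tsv"))
      write_fasta(t3$seqs, file.path(dir, "genome.fasta"))
      write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(tiers = tiers, manifest = manifest)
  })
}

#' Audit reference uniqueness
#'
#' Checks that no substring of read length (on either strand) is shared
#' between two reference entries, which would make class assignment
#' ambiguous by construction. Used as a generator self-check.
#'
#' @param tiers List of `reference_tier` objects.
#' @param k Substring length to audit (default 50, the read length).
#' @return Data frame of collisions (`kmer`, `entries`); zero rows when
#'   the reference set is clean.
#' @export
audit_reference_uniqueness <- function(tiers, k = 50L) {
  ids <- character(0); kmers <- character(0)
  for (tier in tiers) {
    for (i in seq_along(tier$seqs)) {
      s <- tier$seqs[[i]]
      L <- nchar(s)
      if (L < k) next
      km <- substring(s, 1:(L - k + 1), k:L)
      rc <- .revcomp(km)
      canon <- ifelse(km <= rc, km, rc)
      canon <- unique(canon)
      kmers <- c(kmers, canon)
      ids <- c(ids, rep(names(tier$seqs)[i], length(canon)))
    }
  }
  dup <- kmers[duplicated(kmers)]
  if (!length(dup)) {
    return(data.frame(kmer = character(0), entries = character(0),
                      stringsAsFactors = FALSE))
  }
  bad <- unique(dup)
  entries <- vapply(bad, function(km)
    paste(unique(ids[kmers == km]), collapse = ","), "")
  data.frame(kmer = bad, entries = entries, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate one color-space library
#'
#' Draws each read's class from the profile proportions, a feature
#' within the class by log-normal abundance weights, and a fragment
#' uniformly within the feature with insert length in
#' `[insert_min, insert_max]` nt (the size-selection window). The read
#' is the first `read_length` bases of insert-plus-adapter, so inserts
#' shorter than the read run through into adapter and must be resolved
#' by the trimming ladder, then color-encoded from the primer base.
#' Genome-derived (`non_RefSeq`) fragments come from either strand;
#' transcript fragments from the sense strand.
#'
#' @param profile A [fraction_profile()].
#' @param references Result of [generate_references()].
#' @param config A [sim_config()]; `config$seed` fixes the library.
#' @param library_id Identifier used in read names.
#' @param boost Optional named vector of per-feature abundance
#'   multipliers (planted differential effects).
#' @return List with `reads` (a `color_read_set`) and `truth` (read_id,
#'   class, feature_id, start, end, strand, insert_length; coordinates
#'   1-based fully closed).
#' @export
simulate_library <- function(profile, references, config = sim_config(),
                             library_id = "library", boost = NULL) {
  .check_profile(profile)
  man <- references$manifest
  seqs <- c(references$tiers[[1]]$seqs, references$tiers[[2]]$seqs,
            references$tiers[[3]]$seqs)
  .with_seed(config$seed, function() {
    p <- profile$class_proportions
    cls_n <- as.integer(rmultinom(1, config$n_reads, p))
    names(cls_n) <- names(p)
    feat_id <- character(0); cls_out <- character(0)
    for (cl in names(p)[cls_n > 0]) {
      feats <- if (cl == "non_RefSeq") man$seq_id[man$tier == 3]
               else man$seq_id[man$class == cl]
      if (!length(feats))
        stop("class '", cl, "' has nonzero proportion but no reference entries",
             call. = FALSE)
      w <- rlnorm(length(feats), 0, profile$sdlog)
      if (!is.null(boost)) {
        hit <- feats %in% names(boost)
        w[hit] <- w[hit] * boost[feats[hit]]
      }
      draw <- sample(feats, cls_n[cl], replace = TRUE, prob = w)
      feat_id <- c(feat_id, draw)
      cls_out <- c(cls_out, rep(cl, cls_n[cl]))
    }
    n <- length(feat_id)
    if (n == 0) {
      return(list(reads = color_reads(character(0), character(0),
                                      character(0), list()),
                  truth = data.frame(read_id = character(0),
                                     class = character(0),
                                     feature_id = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0),
                                     insert_length = integer(0))))
    }
    ord <- sample.int(n)           # shuffle so read order carries no signal
    feat_id <- feat_id[ord]; cls_out <- cls_out[ord]
    L <- nchar(seqs[feat_id])
    maxlen <- pmin(config$insert_max, L)
    ilen <- config$insert_min +
      floor(runif(n) * (maxlen - config$insert_min + 1))
    start <- 1L + floor(runif(n) * (L - ilen + 1))
    end <- as.integer(start + ilen - 1)
    strand <- rep("+", n)
    genome_read <- cls_out == "non_RefSeq"
    strand[genome_read] <- sample(c("+", "-"), sum(genome_read),
                                  replace = TRUE)
    insert <- substring(seqs[feat_id], start, end)
    rev <- strand == "-"
    if (any(rev)) insert[rev] <- .revcomp(insert[rev])
    pad <- strrep(config$adapter,
                  ceiling(config$read_length / nchar(config$adapter)) + 1)
    bases <- substr(paste0(insert, pad), 1, config$read_length)
    colors <- encode_colorspace(bases, config$primer)
    if (config$error_rate > 0) {
      colors <- vapply(colors, function(cstr) {
        v <- strsplit(cstr, "")[[1]]
        hit <- which(runif(length(v)) < config$error_rate)
        for (j in hit) v[j] <- sample(setdiff(c("0", "1", "2", "3"), v[j]), 1)
        paste(v, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    read_id <- sprintf("%s_r%06d", library_id, seq_len(n))
    reads <- color_reads(read_id, config$primer, colors, 30L)
    truth <- data.frame(read_id = read_id, class = cls_out,
                        feature_id = feat_id, start = as.integer(start),
                        end = end, strand = strand,
                        insert_length = as.integer(ilen),
                        row.names = NULL, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Generate the full 15-library study fixture
#'
#' One library per (fraction, cohort) pair -- five blood fractions times
#' three donor cohorts -- each simulated from its default class-mixture
#' profile, over a shared synthetic reference set. Optional planted
#' effects multiply a feature's abundance weight in every library of a
#' fraction, for differential-power experiments.
#'
#' @param config A [sim_config()]; per-library seeds are derived from
#'   `config$seed`.
#' @param planted Optional data frame with columns `feature_id`,
#'   `fraction`, `fold`.
#' @param dir Optional output directory: references, per-library
#'   csfasta/qual, truth tables and the sample sheet are written there.
#' @return List with `references`, `sample_sheet` (library_id, fraction,
#'   cohort) and `libraries` (named list of `simulate_library()`
#'   results).
#' @export
make_fixture <- function(config = sim_config(), planted = NULL,
                         dir = NULL) {
  refs <- generate_references(config, dir = if (is.null(dir)) NULL
                              else file.path(dir, "references"))
  fractions <- c("I", "II", "III", "IV", "V")
  cohorts <- c("H", "LSCC", "LAC")
  ss <- expand.grid(cohort = cohorts, fraction = fractions,
                    stringsAsFactors = FALSE)[, 2:1]
  ss$library_id <- paste(ss$fraction, ss$cohort, sep = "_")
  ss <- ss[, c("library_id", "fraction", "cohort")]
  libs <- vector("list", nrow(ss))
  names(libs) <- ss$library_id
  for (i in seq_len(nrow(ss))) {
    prof <- fraction_profile(ss$fraction[i], ss$cohort[i])
    cfg <- config
    cfg$seed <- (config$seed + i * 7919L) %% .Machine$integer.max
    boost <- NULL
    if (!is.null(planted)) {
      sel <- planted$fraction == ss$fraction[i]
      if (any(sel)) boost <- setNames(planted$fold[sel],
                                      planted$feature_id[sel])
    }
    libs[[i]] <- simulate_library(prof, refs, cfg, ss$library_id[i],
                                  boost = boost)
  }
  if (!is.null(dir)) {
    rd <- file.path(dir, "reads")
    dir.create(rd, recursive = TRUE, showWarnings = FALSE)
    for (id in names(libs)) {
      write_csfasta(libs[[id]]$reads, file.path(rd, paste0(id, ".csfasta")),
                    file.path(rd, paste0(id, ".qual")))
      write.table(libs[[id]]$truth,
                  file.path(rd, paste0(id, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(ss, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(references = refs, sample_sheet = ss, libraries = libs)
}
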