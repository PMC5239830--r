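#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> align/classify -> class tables -> quantify
#' -> differential contrasts over the 15-library study layout, writing
#' every stage's outputs plus a JSON run manifest (seed, config hash,
#' package version, per-stage read accounting) to `outdir`. Reruns with
#' the same config produce identical result files.
#'
#' Config keys (YAML file or list): `seed`, `n_reads`, `read_length`,
#' `insert_min`, `insert_max`, `adapter`, `error_rate`, `primer`,
#' `max_mismatches`, `trim_steps` (optional schedule override),
#' `min_alignment_count`, `write_sam`, and optionally `reads_dir` +
#' `sample_sheet` + `references_dir` to run on pre-existing inputs
#' instead of simulating.
#'
#' @param config Path to a YAML config, or a named list.
#' @param outdir Output directory.
#' @param stages Subset of `c("simulate", "classify", "quantify",
#'   "diff")` to run; earlier stage outputs must exist in memory, so the
#'   subset must be a prefix unless inputs are loaded from disk.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "classify", "quantify",
                                    "diff")) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file does not exist: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, n_reads = 10000L, read_length = 50L,
                   insert_min = 20L, insert_max = 100L,
                   adapter = sim_config()$adapter, error_rate = 0,
                   primer = "T", max_mismatches = 2L,
                   min_alignment_count = 100, write_sam = FALSE,
                   trim_steps = NULL)
  config <- utils::modifyList(defaults, config)
  cfg <- sim_config(seed = config$seed, n_reads = config$n_reads,
                    read_length = config$read_length,
                    insert_min = config$insert_min,
                    insert_max = config$insert_max,
                    adapter = config$adapter,
                    error_rate = config$error_rate,
                    primer = config$primer)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfg_path)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("solidfrac")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   stages = list())
  schedule <- make_trim_schedule(config$read_length, 19L,
                                 steps = config$trim_steps)

  # --- inputs: simulate or load -------------------------------------
  if (!is.null(config$reads_dir)) {
    if (is.null(config$sample_sheet) || !file.exists(config$sample_sheet))
      stop("sample sheet missing: ",
           if (is.null(config$sample_sheet)) "(not set)"
           else config$sample_sheet, call. = FALSE)
    ss <- read.delim(config$sample_sheet, colClasses = "character")
    rdir <- config$references_dir
    tiers <- build_tiers(file.path(rdir, "tier1.fasta"),
                         file.path(rdir, "tier1_classmap.tsv"),
                         file.path(rdir, "tier2.fasta"),
                         file.path(rdir, "tier2_classmap.tsv"),
                         file.path(rdir, "genome.fasta"))
    refs <- list(tiers = tiers,
                 manifest = do.call(rbind, lapply(tiers, function(t)
                   data.frame(seq_id = names(t$seqs), tier = t$tier_index,
                              class = unname(t$classes),
                              length = nchar(unname(t$seqs))))))
    libs <- lapply(ss$library_id, function(id) {
      list(reads = read_csfasta(
        file.path(config$reads_dir, paste0(id, ".csfasta")),
        file.path(config$reads_dir, paste0(id, ".qual"))),
        truth = NULL)
    })
    names(libs) <- ss$library_id
    fixture <- list(references = refs, sample_sheet = ss, libraries = libs)
  } else if ("simulate" %in% stages) {
    fixture <- make_fixture(cfg, dir = outdir)
    manifest$stages$simulate <- list(
      n_libraries = length(fixture$libraries),
      n_reads_per_library = config$n_reads)
  } else stop("no input reads: run the simulate stage or set reads_dir",
              call. = FALSE)
  ss <- fixture$sample_sheet
  tiers <- fixture$references$tiers
  man <- fixture$references$manifest
  result <- list(fixture = fixture, manifest = manifest)
  if (!any(c("classify", "quantify", "diff") %in% stages))
    return(invisible(.finish_manifest(result, outdir)))

  # --- classification (k = 1) and class tables ----------------------
  ctdir <- file.path(outdir, "class_tables")
  dir.create(ctdir, showWarnings = FALSE)
  samdir <- file.path(outdir, "alignments")
  if (isTRUE(config$write_sam)) dir.create(samdir, showWarnings = FALSE)
  params1 <- align_params(config$max_mismatches, k = 1L)
  tables <- list(); accounting <- list()
  cls1 <- list()
  for (id in ss$library_id) {
    cl <- classify_reads(fixture$libraries[[id]]$reads, tiers, params1,
                         schedule)
    cls1[[id]] <- cl
    tables[[id]] <- class_table(cl, id)
    write_class_table(tables[[id]],
                      file.path(ctdir, paste0(id, "_class_table.tsv")))
    accounting[[id]] <- list(
      reads = cl$n_reads,
      aligned = nrow(cl$assignments),
      adapter = sum(cl$assignments$class == "adapter"),
      unmapped = length(cl$unmapped),
      too_short = length(cl$too_short))
    if (isTRUE(config$write_sam)) {
      res <- structure(list(records = cl$assignments,
                            unaligned = cl$unmapped,
                            too_short = cl$too_short),
                       class = "alignment_result")
      # merged header across the three tiers; write_sam only needs seqs
      merged <- structure(list(tier_index = 1L,
                               seqs = c(tiers[[1]]$seqs, tiers[[2]]$seqs,
                                        tiers[[3]]$seqs),
                               description = "merged"),
                          class = "reference_tier")
      write_sam(res, fixture$libraries[[id]]$reads, merged,
                file.path(samdir, paste0(id, ".sam")))
    }
  }
  wide <- class_table_wide(tables)
  write.table(data.frame(class = rownames(wide), wide,
                         check.names = FALSE),
              file.path(ctdir, "class_table_wide.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  result$class_tables <- tables
  manifest$stages$classify <- accounting

  if (!any(c("quantify", "diff") %in% stages)) {
    result$manifest <- manifest
    return(invisible(.finish_manifest(result, outdir)))
  }

  # --- quantification (k = 2) ---------------------------------------
  qdir <- file.path(outdir, "quantify")
  dir.create(qdir, showWarnings = FALSE)
  params2 <- align_params(config$max_mismatches, k = 2L)
  feats <- man$seq_id[man$tier %in% c(1, 2) & man$class != "adapter"]
  flen <- setNames(man$length, man$seq_id)
  counts <- list()
  for (id in ss$library_id) {
    cl2 <- classify_reads(fixture$libraries[[id]]$reads, tiers, params2,
                          schedule)
    counts[[id]] <- count_fragments(cl2$records, feats)
    total <- length(unique(cl2$records$read_id))
    ab <- abundance_table(counts[[id]], flen, id,
                          total_mapped = max(total, 1))
    write.table(ab, file.path(qdir, paste0(id, "_abundance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cm <- count_matrix(counts)
  write.table(data.frame(feature_id = rownames(cm), cm,
                         check.names = FALSE),
              file.path(qdir, "count_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  result$count_matrix <- cm
  manifest$stages$quantify <- list(n_features = nrow(cm),
                                   n_libraries = ncol(cm))

  if ("diff" %in% stages) {
    ddir <- file.path(outdir, "diff")
    dir.create(ddir, showWarnings = FALSE)
    contrasts <- run_contrasts(cm, ss, config$min_alignment_count)
    classes <- setNames(man$class, man$seq_id)
    for (nm in names(contrasts))
      write_diff_result(contrasts[[nm]],
                        file.path(ddir, paste0(nm, ".tsv")), classes)
    result$contrasts <- contrasts
    manifest$stages$diff <- list(
      n_contrasts = length(contrasts),
      n_eligible = vapply(contrasts, function(x) sum(x$eligible), 0))
  }
  result$manifest <- manifest
  invisible(.finish_manifest(result, outdir))
}

.finish_manifest <- function(result, outdir) {
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result
}
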