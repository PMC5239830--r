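test_that("reference generation is deterministic and self-consistent", {
  cfg <- sim_config(seed = 9, n_reads = 10)
  d1 <- tempfile(); d2 <- tempfile()
  generate_references(cfg, dir = d1)
  generate_references(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  refs <- generate_references(cfg)
  # every reportable class is represented somewhere in the tiers
  expect_setequal(unique(refs$manifest$class),
                  c("adapter", reportable_classes()))
})

test_that("no read-length substring is shared between reference entries", {
  cfg <- sim_config(seed = 13, n_reads = 10)
  refs <- generate_references(cfg)
  collisions <- audit_reference_uniqueness(refs$tiers, k = 50)
  expect_equal(nrow(collisions), 0L)
  # the audit does catch real collisions
  set.seed(700)
  shared <- random_dna(60)
  bad <- list(
    reference_tier(1, c(a = paste0(shared, random_dna(20)),
                        ad = random_dna(30)), c("tRNA", "adapter")),
    reference_tier(2, c(b = paste0(random_dna(15), shared)), "mRNA"))
  hits <- audit_reference_uniqueness(bad, k = 50)
  expect_gt(nrow(hits), 0)
  expect_true(any(grepl("a", hits$entries) & grepl("b", hits$entries)))
})

test_that("libraries are deterministic with complete truth tables", {
  cfg <- sim_config(seed = 21, n_reads = 400)
  refs <- generate_references(cfg)
  prof <- fraction_profile("IV", "LSCC")
  l1 <- simulate_library(prof, refs, cfg, "libA")
  l2 <- simulate_library(prof, refs, cfg, "libA")
  expect_identical(l1, l2)
  expect_equal(nrow(l1$reads), 400)
  expect_setequal(l1$truth$read_id, l1$reads$read_id)
  expect_false(anyDuplicated(l1$truth$read_id) > 0)
})

test_that("read geometry matches the size-selected library design", {
  cfg <- sim_config(seed = 22, n_reads = 500)
  refs <- generate_references(cfg)
  lib <- simulate_library(fraction_profile("I", "H"), refs, cfg, "lib")
  expect_true(all(nchar(lib$reads$colors) == 50))
  expect_true(all(lib$truth$insert_length > 19))
  expect_true(all(lib$truth$insert_length <= 100))
  expect_true(all(lib$truth$end - lib$truth$start + 1 ==
                    lib$truth$insert_length))
  # inserts shorter than the read run through into adapter sequence:
  # decoding such a read past its insert must hit the adapter prefix
  short <- lib$truth[lib$truth$insert_length < 50 &
                       lib$truth$strand == "+", ][1, ]
  rd <- lib$reads[lib$reads$read_id == short$read_id, ]
  bases <- decode_colorspace(rd$primer, rd$colors)
  tail_part <- substr(bases, short$insert_length + 1, 50)
  expect_equal(tail_part, substr(cfg$adapter, 1, nchar(tail_part)))
})

test_that("degenerate profiles and empty libraries behave", {
  cfg <- sim_config(seed = 23, n_reads = 120)
  refs <- generate_references(cfg)
  prof <- fraction_profile("I", "H")
  prof$class_proportions[] <- 0
  prof$class_proportions["rRNA"] <- 1
  lib <- simulate_library(prof, refs, cfg, "pure")
  expect_true(all(lib$truth$class == "rRNA"))

  cfg0 <- sim_config(seed = 23, n_reads = 0)
  lib0 <- simulate_library(prof, refs, cfg0, "none")
  expect_equal(nrow(lib0$reads), 0)
  expect_equal(nrow(lib0$truth), 0)

  # a class with no reference entries cannot be requested
  prof_bad <- prof
  refs_bad <- refs
  refs_bad$manifest <- refs$manifest[refs$manifest$class != "rRNA", ]
  expect_error(simulate_library(prof_bad, refs_bad, cfg, "x"),
               "nonzero proportion")
})

test_that("planted boosts reweight only the target feature", {
  cfg <- sim_config(seed = 31, n_reads = 4000)
  refs <- generate_references(cfg)
  prof <- fraction_profile("II", "H")
  target <- refs$manifest$seq_id[refs$manifest$class == "mRNA"][1]
  plain <- simulate_library(prof, refs, cfg, "lib")
  boosted <- simulate_library(prof, refs, cfg, "lib",
                              boost = setNames(64, target))
  # same seed: class totals identical, target feature strongly enriched
  expect_equal(table(plain$truth$class), table(boosted$truth$class))
  n_plain <- sum(plain$truth$feature_id == target)
  n_boost <- sum(boosted$truth$feature_id == target)
  expect_gt(n_boost, n_plain)
})

test_that("the full fixture covers 5 fractions x 3 cohorts", {
  cfg <- sim_config(seed = 41, n_reads = 50)
  fx <- make_fixture(cfg)
  expect_equal(nrow(fx$sample_sheet), 15)
  expect_setequal(unique(fx$sample_sheet$fraction),
                  c("I", "II", "III", "IV", "V"))
  expect_setequal(unique(fx$sample_sheet$cohort), c("H", "LSCC", "LAC"))
  expect_length(fx$libraries, 15)
  expect_true(all(vapply(fx$libraries, function(l) nrow(l$reads), 0L) == 50))
  # libraries differ from each other (distinct derived seeds)
  expect_false(identical(fx$libraries[[1]]$reads$colors,
                         fx$libraries[[2]]$reads$colors))
})

test_that("simulated mixtures track their generating profile", {
  cfg <- sim_config(seed = 51, n_reads = 20000)
  refs <- generate_references(cfg)
  prof <- fraction_profile("III", "H")
  lib <- simulate_library(prof, refs, cfg, "f3h")
  got <- table(factor(lib$truth$class, levels = reportable_classes()))
  got_pct <- 100 * as.numeric(got) / sum(got)
  want_pct <- 100 * unname(prof$class_proportions[reportable_classes()])
  expect_true(all(abs(got_pct - want_pct) < 2))
})
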