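test_that("the 50->19 ladder has 11 steps and the documented lengths", {
  s <- make_trim_schedule(50, 19)
  expect_length(s$steps, 11)
  expect_equal(s$steps, c(4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L))
  expect_equal(s$lengths,
               c(50L, 46L, 43L, 40L, 37L, 34L, 31L, 28L, 25L, 23L, 21L, 19L))
})

test_that("generic schedules use the fewest 4/3/2 steps, larger first", {
  expect_equal(make_trim_schedule(19, 19)$steps, integer(0))
  expect_equal(make_trim_schedule(23, 19)$steps, 4L)
  expect_error(make_trim_schedule(50, 18), ">= 19")
  expect_error(make_trim_schedule(18, 19), "initial_length")
  expect_error(make_trim_schedule(20, 19), "no schedule")
  set.seed(301)
  for (i in 1:20) {
    minl <- sample(19:30, 1)
    init <- minl + sample(c(0, 2:40), 1)
    s <- make_trim_schedule(init, minl)
    d <- init - minl
    expect_true(all(s$steps %in% c(4L, 3L, 2L)))
    expect_equal(sum(s$steps), d)
    if (d >= 2) expect_length(s$steps, ceiling(d / 4))
    expect_true(all(diff(s$lengths) < 0))
    expect_equal(s$lengths[length(s$lengths)], minl)
    expect_false(is.unsorted(rev(s$steps)))  # larger sizes first
  }
  # explicit override is validated
  expect_equal(make_trim_schedule(29, 19, steps = c(2, 4, 4))$steps,
               c(2L, 4L, 4L))
  expect_error(make_trim_schedule(29, 19, steps = c(5, 5)), "step sizes")
  expect_error(make_trim_schedule(29, 19, steps = c(4, 4)), "sum")
})

test_that("exact reads place uniquely with no trimming", {
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  rseq <- substr(tiers[[1]]$seqs[["rrna1"]], 101, 150)
  rec <- align_read(as_color_read(rseq), tiers[[1]], schedule = sched)
  expect_equal(attr(rec, "status"), "aligned")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ref_id, "rrna1")
  expect_equal(rec$position, 101L)
  expect_equal(rec$mismatches, 0L)
  expect_equal(rec$trim_step, 0L)
  expect_equal(rec$strand, "+")
})

test_that("reverse-strand placements are found and reported 1-based", {
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  window <- substr(tiers[[1]]$seqs[["rrna1"]], 201, 250)
  rec <- align_read(as_color_read(oracle_revcomp(window)), tiers[[1]],
                    schedule = sched)
  expect_equal(rec$strand, "-")
  expect_equal(rec$position, 201L)
  expect_equal(rec$mismatches, 0L)
})

test_that("adapter read-through resolves at the right ladder step", {
  set.seed(302)
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  adapter <- tiers[[1]]$seqs[["adapter_x"]]
  insert <- substr(tiers[[2]]$seqs[["mrna1"]], 301, 328)  # 28-nt insert
  bases <- substr(paste0(insert, adapter, adapter), 1, 50)
  rec <- align_read(as_color_read(bases), tiers[[2]], schedule = sched)
  expect_equal(rec$ref_id, "mrna1")
  expect_equal(rec$aligned_length, 28L)
  expect_equal(rec$trim_step, which(sched$lengths == 28) - 1L)
  expect_equal(rec$position, 301L)
})

test_that("unplaceable and short reads are reported, never thrown", {
  set.seed(303)
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  rec <- align_read(as_color_read(random_dna(50)), tiers[[1]],
                    schedule = sched)
  expect_equal(nrow(rec), 0L)
  expect_equal(attr(rec, "status"), "unaligned")
  shorty <- align_read(as_color_read(random_dna(15)), tiers[[1]],
                       schedule = sched)
  expect_equal(attr(shorty, "status"), "too_short")
})

test_that("library alignment accounts for every read exactly once", {
  set.seed(304)
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  empty <- align_library(color_reads(character(0), character(0),
                                     character(0), list()),
                         tiers[[1]], schedule = sched)
  expect_equal(nrow(empty$records), 0L)
  expect_length(empty$unaligned, 0L)

  refseq <- tiers[[1]]$seqs[["rrna1"]]
  n_hit <- 30
  starts <- sample(1:(nchar(refseq) - 50), n_hit, TRUE)
  hit_bases <- substring(refseq, starts, starts + 49)
  miss_bases <- replicate(10, random_dna(50))
  all_bases <- c(hit_bases, miss_bases)
  ids <- paste0("rd", seq_along(all_bases))
  reads <- color_reads(ids, "T",
                       vapply(all_bases, oracle_encode, "", primer = "T"))
  res <- align_library(reads, tiers[[1]], schedule = sched)
  got <- unique(res$records$read_id)
  expect_setequal(c(got, res$unaligned), ids)
  expect_length(intersect(got, res$unaligned), 0)
  expect_setequal(res$unaligned, paste0("rd", n_hit + 1:10))
})

test_that("alignment is monotone in the mismatch allowance and k", {
  set.seed(305)
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  refseq <- tiers[[1]]$seqs[["mito1"]]
  bases <- character(30)
  for (i in 1:30) {
    st <- sample(1:(nchar(refseq) - 50), 1)
    b <- strsplit(substr(refseq, st, st + 49), "")[[1]]
    nmut <- sample(0:3, 1)
    for (j in sample(50, nmut)) b[j] <- sample(setdiff(c("A","C","G","T"), b[j]), 1)
    bases[i] <- paste(b, collapse = "")
  }
  reads <- color_reads(paste0("rd", 1:30), "T",
                       vapply(bases, oracle_encode, "", primer = "T"))
  n_aligned <- vapply(0:4, function(mm) {
    res <- align_library(reads, tiers[[1]],
                         align_params(max_mismatches = mm), sched)
    length(unique(res$records$read_id))
  }, 0L)
  expect_false(is.unsorted(n_aligned))

  res1 <- align_library(reads, tiers[[1]], align_params(k = 1), sched)
  res2 <- align_library(reads, tiers[[1]], align_params(k = 2), sched)
  top2 <- res2$records[!duplicated(res2$records$read_id), ]
  expect_equal(norm_records(res1$records), norm_records(top2))
})

test_that("the aligner reproduces the exhaustive brute-force scan", {
  set.seed(306)
  for (inst in 1:6) {
    nref <- sample(2:5, 1)
    refs <- setNames(vapply(seq_len(nref), function(i)
      random_dna(sample(80:250, 1)), ""), paste0("ref", seq_len(nref)))
    tier <- reference_tier(1, refs, rep("tRNA", nref))
    sched <- make_trim_schedule(50, 19)
    colorspace <- inst %% 2 == 0
    for (r in 1:8) {
      kind <- sample(c("planted", "mutated", "random", "readthrough"), 1)
      src <- sample(names(refs), 1)
      L <- nchar(refs[[src]])
      bases <- switch(kind,
        planted = { st <- sample(1:(L - 50), 1)
                    substr(refs[[src]], st, st + 49) },
        mutated = { st <- sample(1:(L - 50), 1)
                    b <- strsplit(substr(refs[[src]], st, st + 49), "")[[1]]
                    for (j in sample(50, 2))
                      b[j] <- sample(setdiff(c("A","C","G","T"), b[j]), 1)
                    paste(b, collapse = "") },
        random = random_dna(50),
        readthrough = { ins <- sample(20:45, 1)
                        st <- sample(1:(L - ins), 1)
                        substr(paste0(substr(refs[[src]], st, st + ins - 1),
                                      random_dna(60)), 1, 50) })
      if (sample(c(TRUE, FALSE), 1)) bases <- oracle_revcomp(bases)
      if (colorspace) {
        read <- list(colors = oracle_encode(bases, "T"), primer = "T")
        got <- align_read(color_reads("q", "T", read$colors), tier,
                          align_params(k = 2), sched)
      } else {
        read <- bases
        got <- align_read(setNames(bases, "q"), tier, align_params(k = 2),
                          sched)
      }
      want <- oracle_align_read(read, refs, max_mm = 2, k = 2,
                                schedule = sched)
      if (is.null(want$records)) {
        expect_equal(nrow(got), 0L)
        expect_equal(attr(got, "status"), want$status)
      } else {
        expect_equal(norm_records(got), want$records)
      }
    }
  }
})

test_that("SAM output has valid mandatory fields and accounting", {
  set.seed(307)
  tiers <- tiny_tiers()
  sched <- make_trim_schedule(50, 19)
  refseq <- tiers[[1]]$seqs[["rrna1"]]
  bases <- c(substr(refseq, 11, 60), random_dna(50))
  reads <- color_reads(c("hit", "miss"), "T",
                       vapply(bases, oracle_encode, "", primer = "T"))
  res <- align_library(reads, tiers[[1]], schedule = sched)
  sam <- tempfile(fileext = ".sam")
  write_sam(res, reads, tiers[[1]], sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:rrna1\tLN:500$", lines)))
  body <- lines[!grepl("^@", lines)]
  expect_length(body, 2)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[1:6], c("hit", "0", "rrna1", "11", "255", "50M"))
  expect_equal(f[10], substr(refseq, 11, 60))
  expect_true("NM:i:0" %in% f)
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[2], "4")
})
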