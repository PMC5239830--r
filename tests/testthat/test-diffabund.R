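nb_matrix <- function(nfeat, libs, mu, alpha, seed) {
  set.seed(seed)
  m <- matrix(rnbinom(nfeat * length(libs), mu = rep(mu, length(libs)),
                      size = 1 / alpha),
              nrow = nfeat, dimnames = list(paste0("f", seq_len(nfeat)),
                                            libs))
  m
}

test_that("upper-quartile factors scale by the 75th nonzero percentile", {
  cnts <- cbind(a = c(100, 100, 100, 0), b = c(400, 400, 400, 0))
  f <- upper_quartile_factors(cnts)
  expect_equal(unname(f), c(0.5, 2.0))
  same <- cbind(x = c(5, 10, 20), y = c(5, 10, 20))
  expect_equal(unname(upper_quartile_factors(same)), c(1, 1))
  set.seed(601)
  m <- matrix(rpois(200, 40), 20,
              dimnames = list(NULL, paste0("l", 1:10)))
  expect_equal(exp(mean(log(upper_quartile_factors(m)))), 1)
  bad <- cbind(ok = c(1, 2), dead = c(0, 0))
  expect_error(upper_quartile_factors(bad), "dead")
})

test_that("dispersion estimates recover the generating parameter", {
  libs <- paste0("l", 1:6)
  d <- contrast_design(libs[1:3], libs[4:6], dispersion = "blind")
  # Poisson data: estimated dispersion collapses toward zero
  m0 <- nb_matrix(50, libs, rlnorm(50, log(80), 0.5), 1e-9, seed = 602)
  a0 <- estimate_dispersion(m0, d)
  expect_lte(median(a0), 0.05)
  # NB alpha = 0.5: median recovery within a factor ~2
  m5 <- nb_matrix(200, libs, rlnorm(200, log(200), 0.7), 0.5, seed = 603)
  a5 <- estimate_dispersion(m5, d)
  expect_gte(median(a5), 0.2)
  expect_lte(median(a5), 1.0)
  # 1-vs-1 blind pooling still yields finite estimates
  d11 <- contrast_design("l1", "l2")
  expect_equal(d11$dispersion, "blind")
  a11 <- estimate_dispersion(m5[, 1:2], d11)
  expect_true(all(is.finite(a11)) && all(a11 > 0))
})

test_that("per-condition dispersion takes the per-feature maximum", {
  libs <- paste0("l", 1:6)
  d <- contrast_design(libs[1:3], libs[4:6])
  expect_equal(d$dispersion, "per_condition")
  m <- cbind(nb_matrix(100, libs[1:3], rep(100, 100), 0.01, seed = 604),
             nb_matrix(100, libs[4:6], rep(100, 100), 1.0, seed = 605))
  colnames(m) <- libs
  da <- contrast_design(libs[1:3], libs[4:6], dispersion = "per_condition")
  amax <- estimate_dispersion(m, da)
  aa <- estimate_dispersion(m, contrast_design(libs[1:3], "l4",
                                               dispersion = "blind"))
  expect_gte(median(amax), 0.3)  # dominated by the noisy group
})

test_that("the NB test behaves at the fixed points", {
  libs <- paste0("l", 1:6)
  d <- contrast_design(libs[1:3], libs[4:6])
  m <- matrix(rep(c(30, 50, 70), 2 * 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), libs))
  res <- nb_test(m, d)
  expect_s3_class(res, "diff_result")
  expect_equal(res$log2_fold_change, rep(0, 4))
  expect_true(all(res$p_value >= 0.99))

  m2 <- rbind(big = c(10, 11, 9, 1000, 980, 1020),
              null = c(50, 55, 45, 52, 48, 50))
  colnames(m2) <- libs
  res2 <- nb_test(m2, d)
  expect_lt(res2$p_value[1], 0.01)
  expect_gt(res2$log2_fold_change[1], 6)

  # ineligible features carry no p or q
  res3 <- nb_test(m2, d, eligible = "big")
  expect_true(is.na(res3$p_value[2]) && is.na(res3$q_value[2]))
  expect_false(res3$eligible[2])
})

test_that("swapping the groups negates the fold change, keeps p", {
  libs <- paste0("l", 1:6)
  m <- nb_matrix(40, libs, rlnorm(40, log(100), 1), 0.1, seed = 606)
  d <- contrast_design(libs[1:3], libs[4:6])
  dsw <- contrast_design(libs[4:6], libs[1:3])
  r1 <- nb_test(m, d)
  r2 <- nb_test(m, dsw)
  expect_equal(r2$log2_fold_change, -r1$log2_fold_change)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("q-values equal a brute-force Benjamini-Hochberg computation", {
  libs <- paste0("l", 1:6)
  m <- nb_matrix(60, libs, rlnorm(60, log(100), 1), 0.1, seed = 607)
  d <- contrast_design(libs[1:3], libs[4:6])
  res <- nb_test(m, d)
  p <- res$p_value
  n <- length(p)
  ord <- order(p)
  q_brute <- numeric(n)
  q_brute[ord] <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  q_brute <- pmin(q_brute, 1)
  expect_equal(res$q_value, q_brute)
})

test_that("contrast designs validate their groups", {
  expect_error(contrast_design(character(0), "b"), "nonempty")
  expect_error(contrast_design(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("run_contrasts enumerates the study's 20 comparisons", {
  libs <- as.vector(outer(c("H", "LSCC", "LAC"),
                          c("I", "II", "III", "IV", "V"),
                          function(co, fr) paste(fr, co, sep = "_")))
  ss <- data.frame(library_id = libs,
                   fraction = sub("_.*", "", libs),
                   cohort = sub(".*_", "", libs),
                   stringsAsFactors = FALSE)
  nfeat <- 40
  mu <- rlnorm(nfeat, log(150), 0.8)
  m <- nb_matrix(nfeat, libs, mu, 0.05, seed = 608)
  # plant an 8-fold boost in every fraction-IV library
  set.seed(609)
  iv <- grepl("^IV_", libs)
  m["f1", iv] <- rnbinom(sum(iv), mu = 8 * mu[1], size = 1 / 0.05)
  res <- run_contrasts(m, ss)
  expect_length(res, 20)
  expect_true(all(c("I_vs_II", "II_vs_IV", "H_vs_LSCC_III",
                    "H_vs_LAC_V") %in% names(res)))
  r24 <- res[["II_vs_IV"]]
  expect_lt(r24$q_value[r24$feature_id == "f1"], 0.05)
  expect_gt(r24$log2_fold_change[r24$feature_id == "f1"], 2)
  # cohort contrasts are 1-vs-1 and still produce finite results
  hc <- res[["H_vs_LSCC_I"]]
  expect_true(all(is.finite(hc$p_value[hc$eligible])))

  ss_bad <- ss; ss_bad$fraction[1] <- "VI"
  expect_error(run_contrasts(m, ss_bad), "I-V")
  expect_error(run_contrasts(m[, -1], ss), "missing from count matrix")
})

test_that("few features reject when nothing is planted", {
  libs <- as.vector(outer(c("H", "LSCC", "LAC"),
                          c("I", "II", "III", "IV", "V"),
                          function(co, fr) paste(fr, co, sep = "_")))
  ss <- data.frame(library_id = libs,
                   fraction = sub("_.*", "", libs),
                   cohort = sub(".*_", "", libs),
                   stringsAsFactors = FALSE)
  nfeat <- 60
  m <- nb_matrix(nfeat, libs, rlnorm(nfeat, log(200), 0.6), 0.1,
                 seed = 610)
  res <- run_contrasts(m, ss)
  frac_res <- res[grep("_vs_", names(res))[1:10]]
  any_sig <- Reduce(`|`, lapply(frac_res, function(r)
    !is.na(r$q_value) & r$q_value < 0.05))
  expect_lte(mean(any_sig), 0.10)
})
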