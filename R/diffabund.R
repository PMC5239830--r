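#' Contrast design for differential-distribution testing
#'
#' Two designs mirror the study's two comparison schemes: fraction
#' versus fraction, with the donor cohorts acting as replicates of the
#' same fractionation, and cohort versus cohort within one fraction,
#' which pits single libraries against each other. Dispersion handling
#' follows the replication structure: `blind` pools all libraries of the
#' contrast as one group (used when any group has a single library),
#' `per_condition` estimates within each group and takes the maximum.
#'
#' @param group_a,group_b Character vectors of library ids; disjoint,
#'   each nonempty.
#' @param mode `"fraction_vs_fraction"` or `"cohort_vs_cohort"`.
#' @param dispersion `"auto"` (default: blind if any group is a single
#'   library, per_condition otherwise), `"blind"` or `"per_condition"`.
#' @return A `contrast_design` list.
#' @export
contrast_design <- function(group_a, group_b,
                            mode = c("fraction_vs_fraction",
                                     "cohort_vs_cohort"),
                            dispersion = c("auto", "blind",
                                           "per_condition")) {
  mode <- match.arg(mode)
  dispersion <- match.arg(dispersion)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  if (dispersion == "auto")
    dispersion <- if (min(length(group_a), length(group_b)) == 1)
      "blind" else "per_condition"
  structure(list(group_a = group_a, group_b = group_b, mode = mode,
                 dispersion = dispersion),
            class = "contrast_design")
}

#' Upper-quartile library size factors
#'
#' Library j is scaled by `UQ_j / geometric_mean(UQ)`, where `UQ_j` is
#' the 75th percentile of its nonzero feature counts; the geometric mean
#' of the returned factors is 1, so normalized counts stay on the scale
#' of the raw counts.
#'
#' @param counts Features x libraries count matrix; every library must
#'   have at least one nonzero count.
#' @return Named numeric vector of size factors; divide counts by these.
#' @export
upper_quartile_factors <- function(counts) {
  counts <- as.matrix(counts)
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(NA_real_)
    unname(quantile(nz, 0.75))
  })
  if (anyNA(uq))
    stop("library with all-zero counts: ",
         paste(colnames(counts)[is.na(uq)], collapse = ", "),
         call. = FALSE)
  uq / exp(mean(log(uq)))
}

# per-feature method-of-moments dispersion of one group of libraries:
# alpha = (var - mean) / mean^2 under Var = mu + alpha mu^2
.mom_alpha <- function(mat) {
  mu <- rowMeans(mat)
  if (ncol(mat) < 2) return(rep(NA_real_, nrow(mat)))
  v <- apply(mat, 1, var)
  ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
}

# mean-dispersion trend alpha(mu) = a0 + a1/mu fitted on features with a
# usable raw moment estimate; constant fallback when too few support it
.trend_pred <- function(alpha_raw, mu, floor = 1e-8) {
  ok <- is.finite(alpha_raw) & alpha_raw > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- lm(alpha_raw[ok] ~ I(1 / mu[ok]))
    pmax(coef(fit)[1] + coef(fit)[2] / pmax(mu, 1e-8), floor)
  } else if (sum(ok) >= 1) {
    rep(max(median(alpha_raw[ok]), floor), length(mu))
  } else rep(floor, length(mu))
}

# moderated per-group dispersion: raw method-of-moments estimates are
# shrunk toward the trend with weight d/(d + prior_df), d = residual df
# of the group; features with no usable raw estimate take the trend
.group_alpha <- function(mat, prior_df, floor = 1e-8) {
  mu <- rowMeans(mat)
  raw <- .mom_alpha(mat)
  trend <- .trend_pred(raw, mu, floor)
  d <- max(ncol(mat) - 1, 0)
  w <- d / (d + prior_df)
  raw_filled <- ifelse(is.finite(raw) & raw > 0, raw, trend)
  pmax(w * raw_filled + (1 - w) * trend, floor)
}

#' Per-feature negative-binomial dispersion
#'
#' Fits the variance model `Var = mu + alpha * mu^2` by per-feature
#' method of moments on normalized counts, moderated toward a fitted
#' mean-dispersion trend: the raw estimate is shrunk with weight
#' `d / (d + prior_df)` where `d` is the group's residual degrees of
#' freedom, so that the handful of features whose replicate variance is
#' accidentally tiny do not get wildly optimistic standard errors.
#' Features with no usable replicate variance take the trend value. In
#' `blind` mode all libraries of the contrast are pooled as a single
#' group; in `per_condition` mode the dispersion is estimated within
#' each group and the per-feature maximum is taken. Estimates are
#' floored at 1e-8.
#'
#' @param norm_counts Normalized count matrix (features x libraries).
#' @param design A [contrast_design()].
#' @param prior_df Trend weight expressed as prior degrees of freedom
#'   (default 4).
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(norm_counts, design, prior_df = 4) {
  stopifnot(inherits(design, "contrast_design"))
  norm_counts <- as.matrix(norm_counts)
  a_cols <- design$group_a
  b_cols <- design$group_b
  if (design$dispersion == "blind") {
    m <- norm_counts[, c(a_cols, b_cols), drop = FALSE]
    alpha <- .group_alpha(m, prior_df)
  } else {
    aa <- .group_alpha(norm_counts[, a_cols, drop = FALSE], prior_df)
    ab <- .group_alpha(norm_counts[, b_cols, drop = FALSE], prior_df)
    alpha <- pmax(aa, ab)
  }
  setNames(alpha, rownames(norm_counts))
}

#' Negative-binomial test of equal means between two groups
#'
#' Wald test on the log of the group means with the NB variance model:
#' `Var(log mean_g) ~ (1/mu_g + alpha) / n_g`. Group means of zero are
#' stabilized at `0.5 / n_g` for the statistic; the reported log2 fold
#' change (B over A) is the raw ratio of normalized means (infinite when
#' one group is all zero, 0 when both are). Benjamini-Hochberg q-values
#' are computed across eligible features only; ineligible features are
#' flagged with `NA` p and q.
#'
#' @param norm_counts Normalized count matrix (features x libraries).
#' @param design A [contrast_design()].
#' @param alpha Per-feature dispersions; default
#'   [estimate_dispersion()] under `design`.
#' @param eligible Character vector of eligible feature ids (see
#'   [apply_min_count()]); default all features.
#' @return A `diff_result` data frame: feature_id, mean_a, mean_b,
#'   log2_fold_change, statistic, p_value, q_value, eligible.
#' @export
nb_test <- function(norm_counts, design, alpha = NULL, eligible = NULL) {
  stopifnot(inherits(design, "contrast_design"))
  norm_counts <- as.matrix(norm_counts)
  if (is.null(alpha)) alpha <- estimate_dispersion(norm_counts, design)
  feats <- rownames(norm_counts)
  if (is.null(feats)) feats <- paste0("feature", seq_len(nrow(norm_counts)))
  if (is.null(eligible)) eligible <- feats
  na <- length(design$group_a)
  nb <- length(design$group_b)
  ma <- rowMeans(norm_counts[, design$group_a, drop = FALSE])
  mb <- rowMeans(norm_counts[, design$group_b, drop = FALSE])
  sa <- pmax(ma, 0.5 / na)
  sb <- pmax(mb, 0.5 / nb)
  se <- sqrt((1 / sa + alpha) / na + (1 / sb + alpha) / nb)
  stat <- (log(sb) - log(sa)) / se
  p <- 2 * pnorm(-abs(stat))
  lfc <- ifelse(ma == 0 & mb == 0, 0, log2(mb / ma))
  elig <- feats %in% eligible
  p[!elig] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[elig] <- p.adjust(p[elig], method = "BH")
  out <- data.frame(feature_id = feats, mean_a = ma, mean_b = mb,
                    log2_fold_change = lfc, statistic = stat,
                    p_value = p, q_value = q, eligible = elig,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Run all study-style contrasts over a count matrix
#'
#' Enumerates the ten fraction-versus-fraction contrasts (cohorts as
#' replicates, per-condition dispersion) and the ten cohort contrasts
#' (healthy vs LSCC and healthy vs LAC within each fraction; single
#' libraries, hence blind dispersion). For each contrast, size factors
#' and the eligibility filter are evaluated on the libraries of that
#' contrast only.
#'
#' @param counts Raw fragment count matrix, features x libraries.
#' @param sample_sheet Data frame with columns `library_id`, `fraction`
#'   (I-V) and `cohort` (H/LSCC/LAC).
#' @param min_alignment_count Eligibility cut-off (default 100).
#' @return Named list of `diff_result` tables, e.g. `II_vs_IV` and
#'   `H_vs_LSCC_III`.
#' @export
run_contrasts <- function(counts, sample_sheet, min_alignment_count = 100) {
  counts <- as.matrix(counts)
  req <- c("library_id", "fraction", "cohort")
  if (!all(req %in% names(sample_sheet)))
    stop("sample sheet needs columns library_id, fraction, cohort",
         call. = FALSE)
  ss <- sample_sheet
  if (any(!ss$fraction %in% c("I", "II", "III", "IV", "V")))
    stop("fraction labels must be I-V", call. = FALSE)
  if (any(!ss$cohort %in% c("H", "LSCC", "LAC")))
    stop("cohort labels must be H, LSCC or LAC", call. = FALSE)
  missing <- setdiff(ss$library_id, colnames(counts))
  if (length(missing))
    stop("libraries missing from count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  libs_of <- function(fr) ss$library_id[ss$fraction == fr]
  fractions <- intersect(c("I", "II", "III", "IV", "V"),
                         unique(ss$fraction))
  out <- list()
  if (length(fractions) >= 2) {
    pairs <- combn(fractions, 2)
    for (i in seq_len(ncol(pairs))) {
      fa <- pairs[1, i]; fb <- pairs[2, i]
      d <- contrast_design(libs_of(fa), libs_of(fb),
                           mode = "fraction_vs_fraction")
      out[[paste0(fa, "_vs_", fb)]] <-
        .run_one_contrast(counts, d, min_alignment_count)
    }
  }
  for (fr in fractions) {
    h <- ss$library_id[ss$fraction == fr & ss$cohort == "H"]
    for (co in c("LSCC", "LAC")) {
      g <- ss$library_id[ss$fraction == fr & ss$cohort == co]
      if (!length(h) || !length(g)) next
      d <- contrast_design(h, g, mode = "cohort_vs_cohort")
      out[[paste0("H_vs_", co, "_", fr)]] <-
        .run_one_contrast(counts, d, min_alignment_count)
    }
  }
  out
}

.run_one_contrast <- function(counts, design, min_alignment_count) {
  cols <- c(design$group_a, design$group_b)
  sub <- counts[, cols, drop = FALSE]
  eligible <- apply_min_count(sub, min_alignment_count)
  factors <- upper_quartile_factors(sub)
  norm <- sweep(sub, 2, factors, "/")
  nb_test(norm, design, eligible = eligible)
}

#' @rdname run_contrasts
#' @param result A `diff_result`.
#' @param classes Optional named vector mapping feature_id to RNA class,
#'   added as a `class` column.
#' @param path Output TSV path.
#' @export
write_diff_result <- function(result, path, classes = NULL) {
  df <- as.data.frame(result)
  if (!is.null(classes))
    df <- cbind(df[1], class = unname(classes[df$feature_id]),
                df[-1])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
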