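# Default per-library class mixtures: relative contribution (%) of each
# reportable RNA class in the five blood fractions (I cells, II plasma,
# III 16,000g pellet, IV 160,000g pellet, V 160,000g supernatant) for
# the three donor cohorts (H healthy, LSCC lung squamous cell carcinoma,
# LAC lung adenocarcinoma). Printed columns do not sum exactly to 100;
# they are renormalized to proportions when used as sampling targets.
.default_mixtures <- function() {
  cls <- reportable_classes()
  cols <- as.vector(outer(c("H", "LSCC", "LAC"),
                          c("I", "II", "III", "IV", "V"),
                          function(co, fr) paste(fr, co, sep = "_")))
  m <- matrix(c(
    # I_H   I_LSCC  I_LAC  II_H  II_LSCC II_LAC III_H III_LSCC III_LAC
    # IV_H  IV_LSCC IV_LAC V_H   V_LSCC  V_LAC
     2.45,  5.38,  0.72, 13.76,  8.89,  0.33, 17.84, 12.01,  1.01,
     2.83,  1.16,  0.12,  7.52,  0.61,  0.09,
    23.69, 18.21, 27.63, 35.01, 18.06,  4.36, 40.39, 19.89,  1.81,
    20.60, 25.17, 51.27, 29.61, 12.18,  2.20,
     0.70,  0.36,  2.74,  2.39,  0.70,  0.21,  0.42,  0.23,  1.05,
     0.50,  0.57,  0.52,  1.06,  0.86,  0.53,
     1.83,  0.88,  1.53,  1.48,  1.31,  0.37,  5.01,  1.29,  4.80,
     1.31,  0.79,  0.64,  1.62,  0.25,  3.73,
     0.52,  0.22,  0.56,  0.20,  0.07,  0.07,  0.06,  0.04,  0.02,
     0.17,  0.31,  0.70,  0.18,  0.15,  0.12,
     1.18,  0.27,  0.79,  0.61,  0.28,  0.16,  0.64,  0.47,  0.08,
     0.17,  0.26,  0.14,  0.51,  0.13,  0.06,
     0.46,  0.23,  0.17,  0.23,  0.35,  0.15,  0.15,  0.28,  0.14,
     0.18,  0.32,  0.17,  0.28,  0.51,  0.18,
     0.09,  0.06,  0.04,  0.06,  0.09,  0.02,  0.04,  0.07,  0.05,
     0.03,  0.10,  0.08,  0.07,  0.17,  0.05,
     0.04,  0.08,  0.17,  0.03,  0.05,  0.02,  0.02,  0.05,  0.04,
     0.08,  0.06,  0.08,  0.05,  0.06,  0.03,
     0.03,  0.07,  0.03,  0.09,  0.07,  0.02,  0.06,  0.05,  0.03,
     0.05,  0.25,  0.13,  0.75,  3.85,  0.03,
    22.50, 30.54, 26.08, 19.80, 34.12, 30.24, 15.21, 29.88, 31.28,
    25.16, 33.98, 20.11, 21.09, 35.80, 31.36,
    22.71,  3.55,  2.95,  2.84,  2.92,  4.16,  1.62,  3.27, 16.30,
     2.25,  3.13,  2.95,  3.60,  3.19, 17.93,
    23.79, 40.14, 36.60, 23.50, 33.10, 59.89, 18.54, 32.47, 43.39,
    46.67, 33.89, 23.08, 33.67, 42.23, 43.69),
    nrow = length(cls), byrow = TRUE)
  colnames(m) <- cols
  rownames(m) <- cls
  m
}

#' Default class-mixture profiles for the five blood fractions
#'
#' `fraction_mixtures()` returns the default relative contribution (%)
#' of every reportable RNA class for each of the 15 (fraction, cohort)
#' libraries. `fraction_profile()` turns one column into a sampling
#' profile for the read simulator; its proportions are the column
#' renormalized to sum to 1.
#'
#' @return `fraction_mixtures()`: a 13 x 15 matrix, classes x
#'   `fraction_cohort` columns.
#' @export
fraction_mixtures <- function() .default_mixtures()

#' @rdname fraction_mixtures
#' @param fraction One of I-V.
#' @param cohort One of H, LSCC, LAC.
#' @param sdlog Log-normal sd of per-feature abundance weights within a
#'   class (default 1): a handful of features dominate each class, as in
#'   real small RNA libraries.
#' @return `fraction_profile()`: a `fraction_profile` list with
#'   `fraction`, `cohort`, `class_proportions` (sums to 1) and `sdlog`.
#' @export
fraction_profile <- function(fraction, cohort, sdlog = 1) {
  m <- .default_mixtures()
  col <- paste(fraction, cohort, sep = "_")
  if (!col %in% colnames(m))
    stop("no default profile for fraction ", fraction, ", cohort ",
         cohort, call. = FALSE)
  p <- m[, col] / sum(m[, col])
  structure(list(fraction = fraction, cohort = cohort,
                 class_proportions = p, sdlog = sdlog),
            class = "fraction_profile")
}

.check_profile <- function(profile) {
  p <- profile$class_proportions
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class proportions must be >= 0 and sum to 1", call. = FALSE)
  invisible(profile)
}
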