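#' Detect differentially phosphorylated peptides in a normalized pair
#'
#' For each peptide, the `l` spot values of the two arrays are paired by
#' replicate index and a two-sided paired t-test is computed; the peptide
#' is called differential when `p < alpha`. Degenerate difference vectors
#' are resolved by the limiting behaviour of the t-test: all differences
#' exactly zero is never detected (`p = 1`); constant nonzero differences
#' are always detected (`p = 0`).
#'
#' @param normalized A normalized tibble (see [normalize_arrays()])
#'   containing exactly the two arrays of the pair, or more arrays with the
#'   pair selected through `template_id`/`replicate_id`.
#' @param template_id,replicate_id Array identifiers of the pair; default
#'   to the first and second `array_id` present.
#' @param alpha Significance level.
#' @return A tibble with one row per peptide: `peptide_id`, `mean_diff`,
#'   `statistic`, `df`, `p_value`, `detected`.
#' @export
detect_differential <- function(normalized, template_id = NULL,
                                replicate_id = NULL, alpha = 0.05) {
  req <- c("array_id", "peptide_id", "replicate_index", "value")
  missing_cols <- setdiff(req, names(normalized))
  if (length(missing_cols) > 0) {
    abort(paste0("format error: missing column(s) ",
                 paste0("'", missing_cols, "'", collapse = ", "), "."))
  }
  ids <- unique(normalized$array_id)
  template_id <- template_id %||% ids[1]
  replicate_id <- replicate_id %||% setdiff(ids, template_id)[1]
  x <- normalized[normalized$array_id == template_id, ]
  y <- normalized[normalized$array_id == replicate_id, ]
  if (nrow(x) == 0 || nrow(y) == 0) {
    abort("validation error: pair arrays not found in `normalized`.")
  }
  peps <- unique(x$peptide_id)
  if (!identical(peps, unique(y$peptide_id))) {
    abort("validation error: pair arrays are not comparable.")
  }
  l <- nrow(x) / length(peps)
  if (l < 2) abort("validation error: paired t-test needs l >= 2.")
  ox <- order(match(x$peptide_id, peps), x$replicate_index)
  oy <- order(match(y$peptide_id, peps), y$replicate_index)
  dmat <- matrix(y$value[oy] - x$value[ox], nrow = length(peps),
                 byrow = TRUE)
  md <- rowMeans(dmat)
  sdd <- sqrt(rowSums((dmat - md)^2) / (l - 1))
  tt <- md / (sdd / sqrt(l))
  p <- 2 * pt(-abs(tt), df = l - 1)
  zero_sd <- sdd == 0
  p[zero_sd & md == 0] <- 1
  p[zero_sd & md != 0] <- 0
  tibble::tibble(
    peptide_id = peps,
    mean_diff = md,
    statistic = tt,
    df = l - 1,
    p_value = p,
    detected = p < alpha
  )
}

#' Confusion sets for seeded-truth classification
#'
#' Partition of the peptides of a pair into true/false positives and
#' negatives given the seeded ground-truth set `P` and the detected set
#' `F`: `TP = P  intersect F`, `FP = (N - P) intersect F`,
#' `TN = (N - P) intersect (N - F)`, `FN = P intersect (N - F)`.
#'
#' @param seeded Character vector of seeded (ground-truth positive)
#'   peptide ids, a subset of `all_peptides`.
#' @param detected Character vector of detected peptide ids, a subset of
#'   `all_peptides`.
#' @param all_peptides Character vector of all peptide ids on the pair.
#' @return An object of class `confusion_sets`: list with `TP`, `FP`,
#'   `TN`, `FN`, `P`, `F`, `N`.
#' @export
confusion_sets <- function(seeded, detected, all_peptides) {
  seeded <- unique(as.character(seeded))
  detected <- unique(as.character(detected))
  all_peptides <- unique(as.character(all_peptides))
  if (!all(seeded %in% all_peptides)) {
    abort("validation error: `seeded` is not a subset of `all_peptides`.")
  }
  if (!all(detected %in% all_peptides)) {
    abort("validation error: `detected` is not a subset of `all_peptides`.")
  }
  neg <- setdiff(all_peptides, seeded)
  structure(
    list(
      TP = intersect(seeded, detected),
      FP = intersect(neg, detected),
      TN = setdiff(neg, detected),
      FN = setdiff(seeded, detected),
      P = seeded, F = detected, N = all_peptides
    ),
    class = "confusion_sets"
  )
}

#' @export
print.confusion_sets <- function(x, ...) {
  cat("<confusion_sets> TP=", length(x$TP), " FP=", length(x$FP),
      " TN=", length(x$TN), " FN=", length(x$FN),
      " (N=", length(x$N), ")\n", sep = "")
  invisible(x)
}

#' Classification performance measures
#'
#' Specificity `|TN|/(|TN|+|FP|)`, sensitivity `|TP|/(|TP|+|FN|)`,
#' precision `|TP|/(|TP|+|FP|)` and accuracy
#' `(|TP|+|TN|)/(|TP|+|TN|+|FP|+|FN|)` from a confusion partition.
#' Undefined ratios are resolved and flagged so that aggregate averaging
#' stays total: precision with no positive calls is 0
#' (`flag_no_positive_calls`); sensitivity with no seeded positives is
#' vacuously 1 (`flag_vacuous_sensitivity`); specificity with no negatives
#' is vacuously 1.
#'
#' @param x A [confusion_sets()] object.
#' @return A one-row tibble with the four measures and the two flags.
#' @export
performance_measures <- function(x) {
  if (!inherits(x, "confusion_sets")) {
    abort("validation error: `x` must be a confusion_sets object.")
  }
  tp <- length(x$TP); fp <- length(x$FP)
  tn <- length(x$TN); fn <- length(x$FN)
  tibble::tibble(
    specificity = if (tn + fp == 0) 1 else tn / (tn + fp),
    sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    flag_vacuous_sensitivity = tp + fn == 0,
    flag_no_positive_calls = tp + fp == 0
  )
}

#' Shapiro-Wilk test of peptide-mean normality
#'
#' Tests the null hypothesis that the per-peptide mean background-corrected
#' intensities of one array are normally distributed. On realistic kinome
#' data (right-skewed intensities) this null is rejected, which is why the
#' simulator does not draw peptide means from a normal distribution.
#'
#' @param array A single kinome array tibble with at least 3 peptides.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_wilk_peptide_means <- function(array) {
  validate_kinome_array(array, single_array = TRUE)
  means <- peptide_means(array)$abc
  if (length(means) < 3) {
    abort("validation error: Shapiro-Wilk needs at least 3 peptides.")
  }
  if (sd(means) == 0) {
    abort("validation error: peptide means are constant.")
  }
  shapiro.test(means)$p.value
}

#' Two-sample Kolmogorov-Smirnov test on peptide means
#'
#' Compares the distributions of per-peptide mean background-corrected
#' intensities of two arrays -- the check that a synthesized replicate
#' preserves the template's intensity distribution.
#'
#' @param array1,array2 Comparable single kinome array tibbles.
#' @return The two-sample KS p-value.
#' @export
ks_two_sample <- function(array1, array2) {
  validate_kinome_array(array1, single_array = TRUE)
  validate_kinome_array(array2, single_array = TRUE)
  m1 <- peptide_means(array1)$abc
  m2 <- peptide_means(array2)$abc
  suppressWarnings(ks.test(m1, m2)$p.value)
}
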