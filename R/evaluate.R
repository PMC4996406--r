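#' Run the full performance-evaluation procedure
#'
#' Orchestrates the benchmark over a set of comparable arrays: for each of
#' `n_pairs` templates, (i) synthesize an inter-array technical replicate,
#' (ii) draw a uniform random subset of `n_seeds` peptides with independent
#' Bernoulli(0.5) directions and seed artificial differential
#' phosphorylation (failed seeds are excluded from the ground-truth
#' positive set), (iii) for each normalization method, normalize the
#' (template, seeded replicate) pair, detect differential peptides with
#' the paired t-test, and (iv) score the detection against the seeded
#' truth. All per-pair child seeds derive deterministically from
#' `master_seed`, so identical inputs give identical record tables.
#'
#' @param arrays A kinome array tibble with `n` stacked comparable arrays
#'   (they serve as both the repository and the templates).
#' @param n_pairs Number of template/replicate pairs (default: all arrays).
#' @param n_seeds Number of candidate peptides seeded per pair.
#' @param fc_threshold,noisy_fraction,alpha Synthesis and detection
#'   parameters (fold-change threshold `T`, noisy-peptide fraction `theta`,
#'   significance level).
#' @param methods Normalization methods to score; any subset of
#'   `"raw"`, `"log2"`, `"vsn_glog"`.
#' @param master_seed Integer seed governing the whole run.
#' @return A tibble of class `kinosynth_eval` with one row per pair and
#'   method: the four performance measures, their flags, `n_seeded`,
#'   `n_detected` and the per-pair child seeds. The per-pair seeded sets
#'   are attached as attribute `"seeded_sets"`.
#' @export
run_performance_evaluation <- function(arrays, n_pairs = NULL,
                                       n_seeds = 30, fc_threshold = 2,
                                       noisy_fraction = 0.05, alpha = 0.05,
                                       methods = c("log2", "vsn_glog"),
                                       master_seed = 1) {
  methods <- match.arg(methods, c("raw", "log2", "vsn_glog"),
                       several.ok = TRUE)
  repo <- build_repository(arrays)
  arr_list <- split_arrays(arrays)
  n <- length(arr_list)
  n_pairs <- n_pairs %||% n
  if (n_pairs < 1 || n_pairs > n) {
    abort("validation error: n_pairs must be between 1 and the number of arrays.")
  }
  m <- repo$m
  seeds <- withr::with_seed(
    master_seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_pairs * 3L),
           ncol = 3L)
  )
  records <- vector("list", n_pairs)
  seeded_sets <- vector("list", n_pairs)
  for (q in seq_len(n_pairs)) {
    template <- arr_list[[q]]
    pair_id <- template$array_id[1]
    y <- synthesize_replicate(template, repo,
                              fc_threshold = fc_threshold,
                              noisy_fraction = noisy_fraction,
                              alpha = alpha, seed = seeds[q, 1])
    pick <- withr::with_seed(seeds[q, 2], list(
      idx = sample.int(m, min(n_seeds, m)),
      dir = rbinom(min(n_seeds, m), 1, 0.5)
    ))
    sr <- seed_phosphorylation(y, repo, template,
                               peptide_indices = pick$idx,
                               directions = pick$dir,
                               fc_threshold = fc_threshold,
                               alpha = alpha, seed = seeds[q, 3])
    seeded_sets[[q]] <- sr$seeded
    pair <- dplyr::bind_rows(template, sr$array)
    rows <- lapply(methods, function(mth) {
      norm <- normalize_arrays(pair, method = mth)
      det <- detect_differential(norm, template_id = pair_id,
                                 replicate_id = sr$array$array_id[1],
                                 alpha = alpha)
      cs <- confusion_sets(sr$seeded, det$peptide_id[det$detected],
                           repo$peptide_ids)
      pm <- performance_measures(cs)
      dplyr::bind_cols(
        tibble::tibble(pair_id = pair_id, method = mth),
        pm,
        tibble::tibble(n_seeded = length(sr$seeded),
                       n_failed_seeds = length(sr$failed),
                       n_detected = sum(det$detected))
      )
    })
    records[[q]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(records)
  out <- dplyr::bind_cols(
    out,
    tibble::tibble(
      seed_synthesis = rep(seeds[, 1], each = length(methods)),
      seed_pick = rep(seeds[, 2], each = length(methods)),
      seed_seeding = rep(seeds[, 3], each = length(methods))
    )
  )
  attr(out, "seeded_sets") <- setNames(
    seeded_sets, vapply(arr_list[seq_len(n_pairs)],
                        function(a) a$array_id[1], character(1)))
  attr(out, "config") <- list(n_pairs = n_pairs, n_seeds = n_seeds,
                              fc_threshold = fc_threshold,
                              noisy_fraction = noisy_fraction,
                              alpha = alpha, methods = methods,
                              master_seed = master_seed)
  class(out) <- c("kinosynth_eval", class(out))
  out
}

#' @method tidy kinosynth_eval
#' @export
#' @rdname run_performance_evaluation
#' @param x A `kinosynth_eval` record table.
#' @param ... Unused.
tidy.kinosynth_eval <- function(x, ...) {
  x |>
    tidyr::pivot_longer(
      cols = c("specificity", "sensitivity", "precision", "accuracy"),
      names_to = "measure", values_to = "value"
    ) |>
    dplyr::group_by(.data$method, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' @method glance kinosynth_eval
#' @export
#' @rdname run_performance_evaluation
glance.kinosynth_eval <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_pairs = cfg$n_pairs,
    n_methods = length(cfg$methods),
    n_seeds = cfg$n_seeds,
    fc_threshold = cfg$fc_threshold,
    noisy_fraction = cfg$noisy_fraction,
    alpha = cfg$alpha,
    mean_seeded = mean(x$n_seeded[!duplicated(x$pair_id)])
  )
}

#' Compare two normalization methods on the evaluation records
#'
#' For each performance measure, runs a median-centered (Brown-Forsythe)
#' Levene test for equality of variances between the two methods' per-pair
#' scores, then a paired t-test on the per-pair differences (`df = n' - 1`).
#' The Levene result is reported alongside the paired test for fidelity to
#' the classical workflow; a Welch two-sample t-test is also reported as a
#' sensitivity check (a paired design has a single difference variance, so
#' the equal/unequal-variance distinction does not alter the paired test
#' itself). Pairs where the two methods differ by an exact constant have
#' zero difference variance; they are reported with
#' `note = "deterministic difference"` and no t p-value.
#'
#' @param records A [run_performance_evaluation()] record table (or any
#'   tibble with `pair_id`, `method` and the four measure columns).
#' @param method_a,method_b The two methods to compare.
#' @param alpha Significance level annotated on the comparison.
#' @return A tibble of class `kinosynth_comparison`, one row per measure:
#'   Levene F and p, paired `t`, `df`, `p_value`, per-method means, Welch
#'   statistics, and `note`.
#' @export
compare_methods <- function(records, method_a, method_b, alpha = 0.05) {
  measures <- c("specificity", "sensitivity", "accuracy", "precision")
  need <- c("pair_id", "method", measures)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("format error: missing column(s) ",
                 paste0("'", missing_cols, "'", collapse = ", "), "."))
  }
  ra <- records[records$method == method_a, ]
  rb <- records[records$method == method_b, ]
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    abort("validation error: both methods must be present in `records`.")
  }
  if (!setequal(ra$pair_id, rb$pair_id) ||
      anyDuplicated(ra$pair_id) || anyDuplicated(rb$pair_id)) {
    abort("validation error: mismatched pair ids between methods.")
  }
  rb <- rb[match(ra$pair_id, rb$pair_id), ]
  n <- nrow(ra)
  rows <- lapply(measures, function(ms) {
    xa <- ra[[ms]]
    xb <- rb[[ms]]
    grp <- factor(rep(c(method_a, method_b), each = n))
    lev <- car::leveneTest(c(xa, xb), group = grp, center = median)
    d <- xa - xb
    if (sd(d) == 0) {
      tt <- if (all(d == 0)) {
        list(statistic = 0, p.value = 1, note = "no difference")
      } else {
        list(statistic = NA_real_, p.value = NA_real_,
             note = "deterministic difference")
      }
    } else {
      ht <- t.test(xa, xb, paired = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
                 note = NA_character_)
    }
    welch <- if (sd(xa) == 0 && sd(xb) == 0) {
      list(statistic = NA_real_, p.value = NA_real_)
    } else {
      hw <- t.test(xa, xb, var.equal = FALSE)
      list(statistic = unname(hw$statistic), p.value = hw$p.value)
    }
    tibble::tibble(
      measure = ms,
      levene_F = lev$`F value`[1],
      levene_p = lev$`Pr(>F)`[1],
      statistic = tt$statistic,
      df = n - 1L,
      p_value = tt$p.value,
      mean_a = mean(xa),
      mean_b = mean(xb),
      welch_statistic = welch$statistic,
      welch_p = welch$p.value,
      note = tt$note
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "methods") <- c(method_a, method_b)
  attr(out, "alpha") <- alpha
  class(out) <- c("kinosynth_comparison", class(out))
  out
}
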