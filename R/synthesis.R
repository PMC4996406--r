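#' Generalized fold change
#'
#' `final / initial` when both values are positive, `initial / final` when
#' both are negative. When the two values straddle zero (or either is
#' exactly zero) the ratio definition does not apply and the sign-crossing
#' marker `NA_real_` is returned; the synthesis algorithms never need a
#' fold-change value in that case because their decisions are made through
#' the bound t-tests, which are well defined for any signs.
#'
#' @param initial,final Numeric vectors of mean background-corrected
#'   intensities.
#' @return Numeric vector of fold changes (`NA` marks sign crossings).
#' @export
generalized_fold_change <- function(initial, final) {
  dplyr::case_when(
    initial > 0 & final > 0 ~ final / initial,
    initial < 0 & final < 0 ~ initial / final,
    .default = NA_real_
  )
}

#' Fold-change bounds around a mean intensity
#'
#' For a peptide with mean background-corrected intensity `abc` and a
#' fold-change threshold `T > 1`, the upper and lower mean bounds within
#' which a candidate is considered non-differentially phosphorylated are
#' `v = T * abc`, `w = abc / T` for positive `abc` and `v = abc / T`,
#' `w = abc * T` for nonpositive `abc`; `v >= w` always, and `abc = 0`
#' degenerates to `v = w = 0`.
#'
#' @param abc Numeric vector of mean background-corrected intensities.
#' @param fc_threshold Fold-change threshold `T` (> 1).
#' @return A tibble with columns `abc`, `v`, `w`.
#' @export
fold_change_bounds <- function(abc, fc_threshold) {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1 ||
      fc_threshold <= 1) {
    abort("validation error: fc_threshold must be a single value > 1.")
  }
  tibble::tibble(
    abc = abc,
    v = ifelse(abc <= 0, abc / fc_threshold, abc * fc_threshold),
    w = ifelse(abc <= 0, abc * fc_threshold, abc / fc_threshold)
  )
}

#' Is a replicate set statistically within fold-change bounds?
#'
#' `TRUE` when the mean of `values` is neither statistically bigger than
#' the upper bound `v` nor statistically less than the lower bound `w`,
#' each judged by a one-sided one-sample t-test at level `alpha`. A
#' zero-variance replicate set falls back to the exact comparison
#' `w <= mean <= v`.
#'
#' @param values Background-corrected spot values of one replicate set.
#' @param v,w Upper and lower mean bounds (see [fold_change_bounds()]).
#' @param alpha Significance level.
#' @return A single logical.
#' @export
mean_within_bounds <- function(values, v, w, alpha = 0.05) {
  stopifnot(length(values) >= 1, v >= w)
  if (length(values) < 2 || sd(values) == 0) {
    m <- mean(values)
    return(m <= v && m >= w)
  }
  p_hi <- t.test(values, mu = v, alternative = "greater")$p.value
  p_lo <- t.test(values, mu = w, alternative = "less")$p.value
  p_hi >= alpha && p_lo >= alpha
}

#' Is a replicate set statistically equivalent to a target mean?
#'
#' `TRUE` when a two-sided one-sample t-test of `values` against
#' `target_mean` is not significant at level `alpha`. A zero-variance
#' replicate set falls back to exact equality with the target.
#'
#' @param values Background-corrected spot values of one replicate set.
#' @param target_mean The mean to compare against.
#' @param alpha Significance level.
#' @return A single logical.
#' @export
mean_equivalent <- function(values, target_mean, alpha = 0.05) {
  stopifnot(length(values) >= 1)
  if (length(values) < 2 || sd(values) == 0) {
    return(mean(values) == target_mean)
  }
  t.test(values, mu = target_mean)$p.value >= alpha
}

# internal: shared validation for synthesis entry points
check_template_against_repo <- function(repo, template) {
  if (!inherits(repo, "kinome_repository")) {
    abort("validation error: `repo` must be a kinome_repository.")
  }
  validate_kinome_array(template, single_array = TRUE)
  ids <- peptide_order(template)
  if (!identical(ids, repo$peptide_ids)) {
    abort("validation error: template peptide sequence does not match the repository.")
  }
  if (nrow(template) / length(ids) != repo$l) {
    abort("validation error: template replicate count does not match the repository.")
  }
  invisible(ids)
}

# internal: copy repository entry (or template row block) into the output
# spot matrices -- every emitted replicate set is bit-identical to its
# source; no values are invented.
assemble_array <- function(out_id, peptide_ids, l, fg, bg) {
  m <- length(peptide_ids)
  tibble::tibble(
    array_id = out_id,
    peptide_id = rep(peptide_ids, each = l),
    replicate_index = rep(seq_len(l), m),
    foreground = as.vector(t(fg)),
    background = as.vector(t(bg))
  )
}

#' Synthesize an inter-array technical replicate
#'
#' Builds an array `Y` that is an inter-array technical replicate of the
#' template `X`: an array with no differentially phosphorylated peptides
#' relative to `X`. For each peptide, with probability `noisy_fraction` the
#' peptide is routed through the perturbation branch: candidates from the
#' repository are scanned in a fresh seeded random permutation and the
#' first whose mean is neither statistically bigger than `v` nor
#' statistically less than `w` (the fold-change bounds around the
#' template's mean) is assigned. Otherwise the first candidate whose mean
#' is statistically equivalent to the template peptide's mean is assigned.
#' If no candidate qualifies the template's own spots are copied. Entries
#' are sampled with replacement: the repository is never consumed.
#'
#' A template mean of exactly zero makes the bound branch degenerate
#' (`v = w = 0`); it falls back to the equivalence criterion against 0.
#'
#' @param template A single kinome array tibble, comparable with the
#'   repository sources.
#' @param repo A [build_repository()] object.
#' @param fc_threshold Fold-change threshold `T` (> 1).
#' @param noisy_fraction Probability `theta` that a peptide is routed
#'   through the perturbation branch.
#' @param alpha Significance level for the candidate t-tests.
#' @param seed Optional integer seed (identical inputs and seed give an
#'   identical replicate).
#' @param array_id Identifier of the synthesized array; default appends
#'   `"-rep"` to the template's.
#' @return A kinome array tibble comparable with `template`, carrying a
#'   `provenance` attribute (see [synthesis_provenance()]).
#' @export
synthesize_replicate <- function(template, repo, fc_threshold = 2,
                                 noisy_fraction = 0.05, alpha = 0.05,
                                 seed = NULL, array_id = NULL) {
  ids <- check_template_against_repo(repo, template)
  if (noisy_fraction < 0 || noisy_fraction > 1) {
    abort("validation error: noisy_fraction must be in [0, 1].")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("validation error: alpha must be in (0, 1).")
  }
  bounds_all <- fold_change_bounds(numeric(0), fc_threshold)  # validates T
  m <- repo$m
  l <- repo$l
  tx <- bc_matrix(template)
  abc <- rowMeans(tx)
  en <- repo$entries
  n_entries <- nrow(en)
  out_id <- array_id %||% paste0(template$array_id[1], "-rep")

  run <- function() {
    fg <- matrix(NA_real_, m, l)
    bg <- matrix(NA_real_, m, l)
    branch <- character(m)
    src_entry <- rep(NA_integer_, m)
    t_ord <- order(match(template$peptide_id, ids),
                   template$replicate_index)
    tfg <- matrix(template$foreground[t_ord], m, l, byrow = TRUE)
    tbg <- matrix(template$background[t_ord], m, l, byrow = TRUE)
    for (t in seq_len(m)) {
      u <- runif(1)
      perm <- sample.int(n_entries)
      if (u <= noisy_fraction && abc[t] != 0) {
        branch[t] <- "perturb"
        b <- fold_change_bounds(abc[t], fc_threshold)
        qualifies <- function(idx) {
          p_mean_greater(en$mean_abc[idx], en$sd_abc[idx], l, b$v) >= alpha &
            p_mean_less(en$mean_abc[idx], en$sd_abc[idx], l, b$w) >= alpha
        }
      } else {
        branch[t] <- if (u <= noisy_fraction) "perturb" else "match"
        qualifies <- function(idx) {
          p_mean_two_sided(en$mean_abc[idx], en$sd_abc[idx], l,
                           abc[t]) >= alpha
        }
      }
      hit <- first_qualifier(perm, qualifies)
      if (is.na(hit)) {
        fg[t, ] <- tfg[t, ]
        bg[t, ] <- tbg[t, ]
      } else {
        fg[t, ] <- repo$foreground[hit, ]
        bg[t, ] <- repo$background[hit, ]
        src_entry[t] <- hit
      }
    }
    y <- assemble_array(out_id, ids, l, fg, bg)
    attr(y, "provenance") <- tibble::tibble(
      peptide_id = ids,
      branch = branch,
      fallback = is.na(src_entry),
      source_array_id = ifelse(is.na(src_entry), NA_character_,
                               en$array_id[src_entry]),
      source_peptide_id = ifelse(is.na(src_entry), NA_character_,
                                 en$peptide_id[src_entry])
    )
    attr(y, "synthesis_params") <- list(fc_threshold = fc_threshold,
                                        noisy_fraction = noisy_fraction,
                                        alpha = alpha, seed = seed)
    y
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Provenance of a synthesized array
#'
#' @param x An array produced by [synthesize_replicate()] or the `array`
#'   component of [seed_phosphorylation()].
#' @return A tibble with one row per peptide: which branch the peptide was
#'   routed through, whether the template fallback was used, and the source
#'   repository entry.
#' @export
synthesis_provenance <- function(x) {
  prov <- attr(x, "provenance")
  if (is.null(prov)) {
    abort("`x` carries no synthesis provenance attribute.")
  }
  prov
}

#' Re-check a synthesized replicate against its template
#'
#' Re-applies the construction criteria of the replicate synthesis to every
#' peptide: a peptide is flagged differential only if its replicate set is
#' neither statistically within the fold-change bounds around the
#' template's mean nor statistically equivalent to that mean. For a
#' correctly synthesized inter-array technical replicate no peptide should
#' be flagged.
#'
#' @param replicate,template Comparable single kinome array tibbles.
#' @param fc_threshold,alpha Parameters used for synthesis.
#' @return A tibble with one row per peptide: template and replicate means,
#'   the two criterion outcomes, and `flagged_differential`.
#' @export
replicate_consistency <- function(replicate, template, fc_threshold = 2,
                                  alpha = 0.05) {
  validate_kinome_array(template, single_array = TRUE)
  validate_kinome_array(replicate, single_array = TRUE)
  check_comparable(list(template, replicate))
  tx <- bc_matrix(template)
  ty <- bc_matrix(replicate)
  ids <- peptide_order(template)
  abc_x <- rowMeans(tx)
  abc_y <- rowMeans(ty)
  b <- fold_change_bounds(abc_x, fc_threshold)
  within <- logical(length(ids))
  equiv <- logical(length(ids))
  for (t in seq_along(ids)) {
    within[t] <- abc_x[t] != 0 &&
      mean_within_bounds(ty[t, ], b$v[t], b$w[t], alpha)
    equiv[t] <- mean_equivalent(ty[t, ], abc_x[t], alpha)
  }
  tibble::tibble(
    peptide_id = ids,
    abc_template = abc_x,
    abc_replicate = abc_y,
    within_bounds = within,
    equivalent = equiv,
    flagged_differential = !(within | equiv)
  )
}

#' Seed artificial differential phosphorylation
#'
#' Starting from a copy of the replicate `Y`, attempts to make each
#' requested peptide differentially phosphorylated relative to the template
#' `X`. To phosphorylate (direction 1) a peptide, repository candidates are
#' scanned in a fresh seeded random permutation for the first whose mean is
#' statistically bigger than the upper bound `v` (one-sided one-sample
#' t-test at level `alpha`); to dephosphorylate (direction 0), statistically
#' less than `w`. Peptides for which no candidate qualifies -- e.g. an
#' attempt to further phosphorylate an already extreme peptide -- are
#' reported as failed and left unchanged, so the seeded set may be smaller
#' than the candidate list.
#'
#' @param replicate The inter-array technical replicate `Y` to modify.
#' @param repo A [build_repository()] object.
#' @param template The template array `X` whose means define the bounds.
#' @param peptide_indices Distinct 1-based indices (in template peptide
#'   order) of candidate peptides. A warning is issued above 15% of `m`,
#'   the upper end of the differential fraction seen on real kinome arrays.
#' @param directions Same-length 0/1 vector; 1 phosphorylates, 0
#'   dephosphorylates.
#' @param fc_threshold,alpha,seed As in [synthesize_replicate()].
#' @param array_id Identifier of the seeded array; default appends
#'   `"-seeded"` to the replicate's.
#' @return An object of class `seeded_replicate`: a list with `array` (the
#'   modified kinome array tibble), `seeded` and `failed` (character
#'   vectors of peptide ids), and `report` (one row per requested peptide).
#' @export
seed_phosphorylation <- function(replicate, repo, template,
                                 peptide_indices, directions,
                                 fc_threshold = 2, alpha = 0.05,
                                 seed = NULL, array_id = NULL) {
  ids <- check_template_against_repo(repo, template)
  validate_kinome_array(replicate, single_array = TRUE)
  check_comparable(list(template, replicate))
  m <- repo$m
  l <- repo$l
  peptide_indices <- as.integer(peptide_indices)
  if (anyDuplicated(peptide_indices) ||
      any(peptide_indices < 1 | peptide_indices > m)) {
    abort("validation error: peptide_indices must be distinct values in 1..m.")
  }
  if (length(directions) != length(peptide_indices) ||
      !all(directions %in% c(0, 1))) {
    abort("validation error: directions must be a 0/1 vector matching peptide_indices.")
  }
  if (length(peptide_indices) > 0.15 * m) {
    warn(paste0("seeding ", length(peptide_indices), " of ", m,
                " peptides exceeds ~15%, the differential fraction",
                " typical of real kinome arrays."))
  }
  tx <- bc_matrix(template)
  abc <- rowMeans(tx)
  en <- repo$entries
  n_entries <- nrow(en)
  out_id <- array_id %||% paste0(replicate$array_id[1], "-seeded")

  run <- function() {
    y_ord <- order(match(replicate$peptide_id, ids),
                   replicate$replicate_index)
    fg <- matrix(replicate$foreground[y_ord], m, l, byrow = TRUE)
    bg <- matrix(replicate$background[y_ord], m, l, byrow = TRUE)
    status <- character(length(peptide_indices))
    src_entry <- rep(NA_integer_, length(peptide_indices))
    for (q in seq_along(peptide_indices)) {
      t <- peptide_indices[q]
      b <- fold_change_bounds(abc[t], fc_threshold)
      qualifies <- if (directions[q] == 1) {
        function(idx) {
          p_mean_greater(en$mean_abc[idx], en$sd_abc[idx], l, b$v) < alpha
        }
      } else {
        function(idx) {
          p_mean_less(en$mean_abc[idx], en$sd_abc[idx], l, b$w) < alpha
        }
      }
      hit <- first_qualifier(sample.int(n_entries), qualifies)
      if (is.na(hit)) {
        status[q] <- "failed"
      } else {
        fg[t, ] <- repo$foreground[hit, ]
        bg[t, ] <- repo$background[hit, ]
        src_entry[q] <- hit
        status[q] <- "seeded"
      }
    }
    yp <- assemble_array(out_id, ids, l, fg, bg)
    report <- tibble::tibble(
      peptide_index = peptide_indices,
      peptide_id = ids[peptide_indices],
      direction = as.integer(directions),
      status = status,
      source_array_id = ifelse(is.na(src_entry), NA_character_,
                               en$array_id[src_entry]),
      source_peptide_id = ifelse(is.na(src_entry), NA_character_,
                                 en$peptide_id[src_entry])
    )
    structure(
      list(array = yp,
           seeded = report$peptide_id[report$status == "seeded"],
           failed = report$peptide_id[report$status == "failed"],
           report = report),
      class = "seeded_replicate"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.seeded_replicate <- function(x, ...) {
  cat("<seeded_replicate> ", x$array$array_id[1], ": ",
      length(x$seeded), " seeded, ", length(x$failed), " failed of ",
      nrow(x$report), " requested\n", sep = "")
  invisible(x)
}

#' @rdname seed_phosphorylation
#' @param x A `seeded_replicate` object.
#' @param ... Unused.
#' @method tidy seeded_replicate
#' @export
tidy.seeded_replicate <- function(x, ...) {
  x$report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
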