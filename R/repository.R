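#' Build a measurement repository from comparable arrays
#'
#' Pools every peptide replicate set (the `l` spots of one peptide on one
#' array) from `n` comparable arrays into a single immutable repository of
#' `n * m` entries, in deterministic (array, peptide) order. Entries keep
#' their raw foreground and background spot values; per-entry summary
#' statistics (mean and standard deviation of the background-corrected
#' values) are precomputed once for the candidate scans of the replicate
#' synthesis and seeding algorithms.
#'
#' @param arrays A kinome array tibble with several stacked comparable
#'   arrays, or a list of single-array tibbles.
#' @return An object of class `kinome_repository` with components
#'   `entries` (tibble: `entry_id`, `array_id`, `peptide_id`, `mean_abc`,
#'   `sd_abc`), `foreground`/`background` (numeric matrices, one row per
#'   entry, `l` columns), and the shared `peptide_ids`, `n`, `m`, `l`.
#' @export
build_repository <- function(arrays) {
  arr_list <- split_arrays(arrays)
  if (length(arr_list) == 0) {
    abort("validation error: empty set of source arrays.")
  }
  for (a in arr_list) validate_kinome_array(a, single_array = TRUE)
  shape <- check_comparable(arr_list)
  m <- length(shape$peptide_ids)
  l <- shape$l
  n <- length(arr_list)
  fg <- matrix(NA_real_, nrow = n * m, ncol = l)
  bg <- matrix(NA_real_, nrow = n * m, ncol = l)
  array_ids <- character(n * m)
  for (i in seq_len(n)) {
    a <- arr_list[[i]]
    ord <- order(match(a$peptide_id, shape$peptide_ids), a$replicate_index)
    rows <- (i - 1L) * m + seq_len(m)
    fg[rows, ] <- matrix(a$foreground[ord], nrow = m, byrow = TRUE)
    bg[rows, ] <- matrix(a$background[ord], nrow = m, byrow = TRUE)
    array_ids[rows] <- a$array_id[1]
  }
  bc <- fg - bg
  mean_abc <- rowMeans(bc)
  sd_abc <- if (l > 1) {
    sqrt(rowSums((bc - mean_abc)^2) / (l - 1))
  } else {
    rep(0, n * m)
  }
  structure(
    list(
      entries = tibble::tibble(
        entry_id = seq_len(n * m),
        array_id = array_ids,
        peptide_id = rep(shape$peptide_ids, n),
        mean_abc = mean_abc,
        sd_abc = sd_abc
      ),
      foreground = fg,
      background = bg,
      peptide_ids = shape$peptide_ids,
      n = n, m = m, l = l
    ),
    class = "kinome_repository"
  )
}

#' @export
print.kinome_repository <- function(x, ...) {
  cat("<kinome_repository>\n")
  cat("  ", x$n, " arrays x ", x$m, " peptides x ", x$l,
      " replicates (", nrow(x$entries), " entries)\n", sep = "")
  invisible(x)
}

# --- vectorized one-sample t-test tail probabilities over repository
# entries; zero within-replicate variance falls back to exact comparison
# (the limiting behaviour of the t-test as sd -> 0) -------------------------

p_mean_greater <- function(mean, sd, l, bound) {
  p <- ifelse(mean > bound, 0, 1)
  ok <- sd > 0
  if (any(ok)) {
    t <- (mean[ok] - bound) / (sd[ok] / sqrt(l))
    p[ok] <- pt(t, df = l - 1, lower.tail = FALSE)
  }
  p
}

p_mean_less <- function(mean, sd, l, bound) {
  p <- ifelse(mean < bound, 0, 1)
  ok <- sd > 0
  if (any(ok)) {
    t <- (mean[ok] - bound) / (sd[ok] / sqrt(l))
    p[ok] <- pt(t, df = l - 1, lower.tail = TRUE)
  }
  p
}

p_mean_two_sided <- function(mean, sd, l, target) {
  p <- ifelse(mean == target, 1, 0)
  ok <- sd > 0
  if (any(ok)) {
    t <- (mean[ok] - target) / (sd[ok] / sqrt(l))
    p[ok] <- 2 * pt(-abs(t), df = l - 1)
  }
  p
}

# internal: first index of `perm` whose entry satisfies `qualifies`
# (a vectorized predicate over entry indices), scanning in chunks so the
# usual case touches only a small prefix of the permutation.
first_qualifier <- function(perm, qualifies, chunk = 1024L) {
  n <- length(perm)
  start <- 1L
  while (start <= n) {
    stop_ <- min(start + chunk - 1L, n)
    idx <- perm[start:stop_]
    hit <- which(qualifies(idx))
    if (length(hit) > 0) return(idx[hit[1]])
    start <- stop_ + 1L
  }
  NA_integer_
}
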