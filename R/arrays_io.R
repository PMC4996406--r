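#' @title Kinome array tables
#' @description
#' A kinome array is stored as a long tibble with one row per spot
#' (within-array technical replicate) and columns `array_id`, `peptide_id`,
#' `replicate_index`, `foreground`, `background`. Foreground and background
#' are raw scanner intensities; the background-corrected value
#' `foreground - background` may be negative, which is deliberate: negative
#' corrected intensities are a real feature of kinome data at low
#' signal-to-noise and several methods in this package exist to cope with
#' them. A tibble may hold one array or several comparable arrays stacked.
#' @name kinome-array
NULL

.kinome_cols <- c("array_id", "peptide_id", "replicate_index",
                  "foreground", "background")

#' Validate a kinome array tibble
#'
#' Checks the structural invariants of the long array format: required
#' columns, finite numeric intensities, a constant within-array replicate
#' count `l` per peptide, and unique `(peptide_id, replicate_index)` pairs
#' within each array.
#'
#' @param x A data frame in the long kinome array format.
#' @param single_array If `TRUE`, require exactly one `array_id`.
#' @return `x`, invisibly, as a tibble.
#' @export
validate_kinome_array <- function(x, single_array = FALSE) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame in the long kinome array format.")
  }
  missing_cols <- setdiff(.kinome_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("format error: missing column(s) ",
                 paste0("'", missing_cols, "'", collapse = ", "), "."))
  }
  x <- tibble::as_tibble(x)
  for (col in c("replicate_index", "foreground", "background")) {
    if (!is.numeric(x[[col]])) {
      abort(paste0("parse error: column '", col, "' is not numeric."))
    }
    if (any(!is.finite(x[[col]]))) {
      abort(paste0("validation error: column '", col,
                   "' contains non-finite values."))
    }
  }
  if (single_array && dplyr::n_distinct(x$array_id) != 1L) {
    abort("validation error: expected a single array_id.")
  }
  counts <- x |>
    dplyr::count(.data$array_id, .data$peptide_id)
  bad <- counts |>
    dplyr::group_by(.data$array_id) |>
    dplyr::filter(.data$n != .data$n[1]) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    abort(paste0("validation error: ragged replicate counts for peptide(s) ",
                 paste0("'", unique(bad$peptide_id), "'", collapse = ", "),
                 "."))
  }
  dup <- x |>
    dplyr::count(.data$array_id, .data$peptide_id, .data$replicate_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("validation error: duplicated replicate_index for peptide '",
                 dup$peptide_id[1], "' on array '", dup$array_id[1], "'."))
  }
  invisible(x)
}

#' Read a kinome array from disk
#'
#' Reads either the canonical long tab-separated dialect (columns
#' `array_id`, `peptide_id`, `replicate_index`, `foreground`, `background`)
#' or a minimal GenePix Results (GPR) dialect. The GPR reader skips the ATF
#' header block, takes `Name` as the peptide identifier and two configurable
#' intensity columns as foreground and background; replicate indices are
#' assigned in file order within each peptide.
#'
#' @param path Path to the file.
#' @param dialect `"long_tsv"` (default) or `"gpr"`.
#' @param array_id Array identifier for the GPR dialect (defaults to the
#'   file name without extension); ignored for `long_tsv`, which carries its
#'   own `array_id` column.
#' @param gpr_foreground,gpr_background Names of the GPR intensity columns
#'   used as foreground and background.
#' @return A kinome array tibble (see [validate_kinome_array()]), peptides
#'   in first-occurrence order.
#' @export
read_kinome_array <- function(path, dialect = c("long_tsv", "gpr"),
                              array_id = NULL,
                              gpr_foreground = "F532 Median",
                              gpr_background = "B532 Median") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: '", path, "'."))
  }
  if (dialect == "long_tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    missing_cols <- setdiff(.kinome_cols, header)
    if (length(missing_cols) > 0) {
      abort(paste0("format error: missing column(s) ",
                   paste0("'", missing_cols, "'", collapse = ", "),
                   " in '", path, "'."))
    }
    x <- suppressWarnings(readr::read_tsv(
      path,
      col_types = readr::cols(
        array_id = readr::col_character(),
        peptide_id = readr::col_character(),
        replicate_index = readr::col_integer(),
        foreground = readr::col_double(),
        background = readr::col_double()
      ),
      progress = FALSE
    ))
    probs <- readr::problems(x)
    if (nrow(probs) > 0) {
      abort(paste0("parse error: non-numeric or malformed value at line ",
                   probs$row[1], " of '", path, "'."))
    }
    x <- x |>
      dplyr::group_by(.data$array_id) |>
      dplyr::arrange(match(.data$peptide_id, unique(.data$peptide_id)),
                     .data$replicate_index, .by_group = TRUE) |>
      dplyr::ungroup()
    validate_kinome_array(x)
    return(x)
  }
  # GPR: ATF 1.0 header, then a line "<n_header_records>\t<n_columns>",
  # then n_header_records metadata lines, then the column header + records.
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^ATF", lines[1])) {
    abort(paste0("format error: '", path, "' is not an ATF/GPR file."))
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(counts) < 2 || any(is.na(counts[1:2]))) {
    abort("format error: malformed ATF record-count line.")
  }
  n_header <- counts[1]
  tab <- read.delim(text = paste(lines[-seq_len(2 + n_header)],
                                 collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("Name", gpr_foreground, gpr_background)) {
    if (!col %in% names(tab)) {
      abort(paste0("format error: missing column '", col, "' in '",
                   path, "'."))
    }
  }
  for (col in c(gpr_foreground, gpr_background)) {
    if (!is.numeric(tab[[col]])) {
      abort(paste0("parse error: non-numeric values in GPR column '",
                   col, "'."))
    }
  }
  if (is.null(array_id)) {
    array_id <- sub("\\.[^.]*$", "", basename(path))
  }
  x <- tibble::tibble(
    array_id = array_id,
    peptide_id = as.character(tab$Name),
    foreground = as.numeric(tab[[gpr_foreground]]),
    background = as.numeric(tab[[gpr_background]])
  ) |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::mutate(replicate_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(.kinome_cols))
  validate_kinome_array(x)
  x
}

#' Write a kinome array to disk
#'
#' Serializes one or more stacked arrays in the long tab-separated dialect.
#' Intensities are written with full double precision so that
#' `read_kinome_array()` reproduces the array exactly, including negative
#' background-corrected spots (no clipping is applied).
#'
#' @param array A kinome array tibble.
#' @param path Output path.
#' @return `array`, invisibly.
#' @export
write_kinome_array <- function(array, path) {
  validate_kinome_array(array)
  readr::write_tsv(array[.kinome_cols], path, progress = FALSE)
  invisible(array)
}

#' Background-corrected spot intensity
#'
#' The corrected value is simply `foreground - background`; it may be
#' negative or zero when the signal-to-noise ratio is low.
#'
#' @param foreground,background Numeric vectors of raw intensities.
#' @return Numeric vector of corrected intensities.
#' @export
background_corrected <- function(foreground, background) {
  stopifnot(is.numeric(foreground), is.numeric(background),
            length(foreground) == length(background))
  foreground - background
}

#' Mean background-corrected intensity of one replicate set
#'
#' The mean over the `l` within-array replicate spots of one peptide --
#' the per-peptide summary (`abc`) that drives the fold-change bounds of
#' the replicate synthesis and seeding algorithms.
#'
#' @param foreground,background Raw intensities of the spots of one peptide.
#' @return A single numeric value.
#' @export
peptide_mean_abc <- function(foreground, background) {
  if (length(foreground) == 0) {
    abort("validation error: empty replicate set.")
  }
  mean(background_corrected(foreground, background))
}

#' Per-peptide mean background-corrected intensities
#'
#' @param array A kinome array tibble (one or several stacked arrays).
#' @return A tibble with columns `array_id`, `peptide_id`, `abc`, peptides
#'   in first-occurrence order within each array.
#' @export
peptide_means <- function(array) {
  validate_kinome_array(array)
  array |>
    dplyr::mutate(.row = dplyr::row_number(),
                  .bc = .data$foreground - .data$background) |>
    dplyr::group_by(.data$array_id, .data$peptide_id) |>
    dplyr::summarise(abc = mean(.data$.bc), .first = min(.data$.row),
                     .groups = "drop") |>
    dplyr::arrange(.data$.first) |>
    dplyr::select("array_id", "peptide_id", "abc")
}

# internal: peptide order of a single array (first occurrence)
peptide_order <- function(array) {
  unique(array$peptide_id)
}

# internal: m x l matrix of background-corrected values for a single array,
# rows in peptide first-occurrence order, columns replicate index 1..l
bc_matrix <- function(array) {
  ids <- peptide_order(array)
  l <- nrow(array) / length(ids)
  ord <- order(match(array$peptide_id, ids), array$replicate_index)
  mat <- matrix(array$foreground[ord] - array$background[ord],
                nrow = length(ids), ncol = l, byrow = TRUE)
  rownames(mat) <- ids
  mat
}

# internal: split a stacked tibble into a list of single-array tibbles in
# first-occurrence order of array_id
split_arrays <- function(arrays) {
  if (is.data.frame(arrays)) {
    ids <- unique(arrays$array_id)
    lapply(ids, function(id) arrays[arrays$array_id == id, ])
  } else {
    arrays
  }
}

# internal: check that arrays share peptide sequence and replicate count
check_comparable <- function(array_list) {
  ref <- peptide_order(array_list[[1]])
  l_ref <- nrow(array_list[[1]]) / length(ref)
  for (a in array_list[-1]) {
    ids <- peptide_order(a)
    if (!identical(ids, ref)) {
      off <- union(setdiff(ids, ref), setdiff(ref, ids))
      if (length(off) == 0) off <- "(same set, different order)"
      abort(paste0("validation error: arrays are not comparable; ",
                   "mismatching peptide sequence: ",
                   paste(head(off, 5), collapse = ", "), "."))
    }
    if (nrow(a) / length(ids) != l_ref) {
      abort(paste0("validation error: arrays are not comparable; ",
                   "replicate counts differ (", nrow(a) / length(ids),
                   " vs ", l_ref, ")."))
    }
  }
  invisible(list(peptide_ids = ref, l = as.integer(l_ref)))
}
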