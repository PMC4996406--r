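#' Log2 transform of background-corrected intensities
#'
#' Positive background-corrected values are log2-transformed; nonpositive
#' values (including the negatives produced by background correction at low
#' signal-to-noise) are mapped to zero. The zero-mapping is what destroys
#' information for peptides whose intensities sit near or below background:
#' all such spots collapse onto a single value.
#'
#' @param array A kinome array tibble (one or several stacked arrays).
#' @return A normalized tibble with columns `array_id`, `peptide_id`,
#'   `replicate_index`, `value`, `method`.
#' @export
log2_transform <- function(array) {
  validate_kinome_array(array)
  x <- array$foreground - array$background
  tibble::tibble(
    array_id = array$array_id,
    peptide_id = array$peptide_id,
    replicate_index = array$replicate_index,
    value = ifelse(x > 0, log2(pmax(x, .Machine$double.xmin)), 0),
    method = "log2"
  )
}

# internal: per-(array, peptide) mean and variance of background-corrected
# values, as matrices over the shared peptide order
pair_stats <- function(arr_list) {
  mats <- lapply(arr_list, bc_matrix)
  means <- vapply(mats, rowMeans, numeric(nrow(mats[[1]])))
  vars <- vapply(mats, function(m) apply(m, 1, var),
                 numeric(nrow(mats[[1]])))
  list(mats = mats, means = means, vars = vars)
}

#' Estimate the two-component error model from replicate spots
#'
#' Fits the mean-variance relationship implied by the Rocke-Durbin model,
#' `Var(Y) ~ sigma_mult^2 * (mean - alpha)^2 + sigma_add^2`, to the
#' per-peptide within-array replicate statistics pooled over all arrays,
#' by maximum likelihood under a scaled chi-square model for the sample
#' variances (robust to the heavy right tail of variance estimates).
#'
#' @param arrays A kinome array tibble with one or more arrays.
#' @return A one-row tibble: `alpha_offset`, `sigma_additive`,
#'   `sigma_multiplicative`.
#' @export
estimate_error_model <- function(arrays) {
  arr_list <- split_arrays(arrays)
  for (a in arr_list) validate_kinome_array(a, single_array = TRUE)
  check_comparable(arr_list)
  st <- pair_stats(arr_list)
  mn <- as.vector(st$means)
  vr <- as.vector(st$vars)
  keep <- vr > 0
  if (sum(keep) < 10) {
    abort("validation error: too few peptides with nonzero replicate variance.")
  }
  mn <- mn[keep]
  vr <- vr[keep]
  a0 <- quantile(mn, 0.05, names = FALSE)
  low <- mn <= quantile(mn, 0.2, names = FALSE)
  hig <- mn >= quantile(mn, 0.8, names = FALSE)
  se2_0 <- max(median(vr[low]), 1e-8)
  sg2_0 <- max((median(vr[hig]) - se2_0) /
                 max(median((mn[hig] - a0)^2), 1e-8), 1e-6)
  nll <- function(p) {
    pred <- exp(p[3]) * (mn - p[1])^2 + exp(p[2])
    sum(log(pred) + vr / pred)
  }
  fit <- optim(c(a0, log(se2_0), log(sg2_0)), nll,
               method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-10))
  tibble::tibble(
    alpha_offset = fit$par[1],
    sigma_additive = sqrt(exp(fit$par[2])),
    sigma_multiplicative = sqrt(exp(fit$par[3]))
  )
}

#' Calibrated generalized-log (arcsinh) variance-stabilizing transform
#'
#' Re-implementation of the VSN transform class: each array's
#' background-corrected values are mapped through
#' `h_i(x) = asinh((x - a_i) / b_i)`, which behaves like a logarithm for
#' large positive `x`, like a linear map near zero, and -- unlike the Log2
#' method -- transforms negative inputs to finite negative values instead
#' of discarding them.
#'
#' Calibration has two stages. First the pooled two-component error model
#' is estimated ([estimate_error_model()]); it fixes the anchor array's
#' parameters (`a_1` at the estimated offset, `b_1 = sigma_additive /
#' sigma_multiplicative`, the scale at which the additive and
#' multiplicative noise components balance). Then the remaining arrays'
#' `(a_i, b_i)` are refined by coordinate descent, minimizing the pooled
#' within-peptide variance of transformed values across arrays with a
#' least-trimmed objective (`lts_quantile` of peptides kept) so that a
#' minority of genuinely differential peptides cannot drag the calibration.
#'
#' @param arrays A kinome array tibble with at least two comparable arrays.
#' @param lts_quantile Fraction of peptides (those with the smallest
#'   within-peptide variances) retained by the trimmed objective.
#' @param max_iter Maximum number of coordinate-descent sweeps.
#' @param tol Stop when the relative objective decrease falls below this.
#' @return An object of class `glog_fit`: list with `normalized` (long
#'   tibble of transformed values, `method = "vsn_glog"`), `params` (tibble
#'   of per-array `a`, `b`, `iterations_run`, `converged`), and the final
#'   `objective`.
#' @export
vsn_glog_transform <- function(arrays, lts_quantile = 0.9,
                               max_iter = 100, tol = 1e-8) {
  arr_list <- split_arrays(arrays)
  if (length(arr_list) < 2) {
    abort("validation error: between-array calibration needs >= 2 arrays.")
  }
  for (a in arr_list) validate_kinome_array(a, single_array = TRUE)
  check_comparable(arr_list)
  st <- pair_stats(arr_list)
  if (all(st$vars == 0) && all(apply(st$means, 1, var) == 0)) {
    abort("validation error: degenerate input (all values identical).")
  }
  n <- length(arr_list)
  m <- nrow(st$mats[[1]])
  est <- estimate_error_model(arrays)
  a_par <- rep(est$alpha_offset, n)
  b_par <- rep(max(est$sigma_additive / max(est$sigma_multiplicative, 1e-8),
                   1e-6), n)
  # bring arrays to the same scale before refinement: robust (trimmed
  # least squares) affine alignment of peptide means onto the anchor
  # array, so that the variance objective starts from an identified
  # calibration and cannot be dragged by differential peptides
  mean1 <- rowMeans(st$mats[[1]])
  for (i in seq_len(n)[-1]) {
    mi <- rowMeans(st$mats[[i]])
    keep <- rep(TRUE, length(mi))
    s_i <- 1
    o_i <- 0
    for (iter in 1:3) {
      fit <- stats::lm.fit(cbind(1, mean1[keep]), mi[keep])
      o_i <- fit$coefficients[1]
      s_i <- fit$coefficients[2]
      res <- abs(mi - (o_i + s_i * mean1))
      keep <- res <= quantile(res, lts_quantile, names = FALSE)
    }
    if (!is.finite(s_i) || s_i <= 0) {
      s_i <- 1
      o_i <- median(mi) - median(mean1)
    }
    a_par[i] <- o_i + s_i * a_par[1]
    b_par[i] <- s_i * b_par[1]
  }
  n_keep <- max(ceiling(lts_quantile * m), 2L)
  # profile objective: log pooled within-peptide variance of transformed
  # values plus the mean log-Jacobian penalty (-2 log h'), evaluated on the
  # `n_keep` peptides with the smallest variances. Without the Jacobian
  # term the criterion would reward flattening the transform outright;
  # with it the optimum sits at the variance-stabilizing calibration.
  objective <- function(av, bv) {
    h <- matrix(NA_real_, m, 0)
    lj <- matrix(NA_real_, m, 0)
    for (i in seq_len(n)) {
      centred <- st$mats[[i]] - av[i]
      h <- cbind(h, asinh(centred / bv[i]))
      lj <- cbind(lj, log(bv[i]^2 + centred^2))
    }
    rm_ <- rowMeans(h)
    pep_var <- rowSums((h - rm_)^2) / (ncol(h) - 1)
    keep <- order(pep_var)[seq_len(n_keep)]
    log(mean(pep_var[keep])) + mean(lj[keep, ])
  }
  obj <- objective(a_par, b_par)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)[-1]) {
      opt <- optim(
        c(a_par[i], log(b_par[i])),
        function(p) {
          av <- a_par; bv <- b_par
          av[i] <- p[1]; bv[i] <- exp(p[2])
          objective(av, bv)
        },
        method = "Nelder-Mead",
        control = list(maxit = 80)
      )
      a_par[i] <- opt$par[1]
      b_par[i] <- exp(opt$par[2])
    }
    new_obj <- objective(a_par, b_par)
    if (obj - new_obj <= tol * max(abs(obj), 1e-12)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) {
    warn("glog calibration did not converge; results returned anyway.")
  }
  normalized <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    a <- arr_list[[i]]
    tibble::tibble(
      array_id = a$array_id,
      peptide_id = a$peptide_id,
      replicate_index = a$replicate_index,
      value = asinh((a$foreground - a$background - a_par[i]) / b_par[i]),
      method = "vsn_glog"
    )
  }))
  structure(
    list(
      normalized = normalized,
      params = tibble::tibble(
        array_id = vapply(arr_list, function(a) a$array_id[1], character(1)),
        a = a_par,
        b = b_par,
        iterations_run = iterations,
        converged = converged
      ),
      objective = obj,
      error_model = est
    ),
    class = "glog_fit"
  )
}

#' @export
print.glog_fit <- function(x, ...) {
  cat("<glog_fit> ", nrow(x$params), " arrays, objective ",
      format(x$objective, digits = 6),
      if (x$params$converged[1]) " (converged)\n" else " (NOT converged)\n",
      sep = "")
  invisible(x)
}

#' @rdname vsn_glog_transform
#' @param x A `glog_fit` object.
#' @param ... Unused.
#' @method tidy glog_fit
#' @export
tidy.glog_fit <- function(x, ...) {
  x$params
}

#' @rdname vsn_glog_transform
#' @method glance glog_fit
#' @export
glance.glog_fit <- function(x, ...) {
  tibble::tibble(
    n_arrays = nrow(x$params),
    objective = x$objective,
    iterations = x$params$iterations_run[1],
    converged = x$params$converged[1]
  )
}

#' Normalize arrays by a named method
#'
#' Dispatcher over the normalization methods under comparison: `"raw"`
#' (identity on background-corrected values), `"log2"`
#' ([log2_transform()]) and `"vsn_glog"` ([vsn_glog_transform()], which
#' requires at least two arrays).
#'
#' @param arrays A kinome array tibble.
#' @param method One of `"raw"`, `"log2"`, `"vsn_glog"`.
#' @param ... Passed on to [vsn_glog_transform()].
#' @return A normalized tibble with columns `array_id`, `peptide_id`,
#'   `replicate_index`, `value`, `method`; for `"vsn_glog"` the fitted
#'   parameters are attached as attribute `"glog_params"`.
#' @export
normalize_arrays <- function(arrays, method = c("raw", "log2", "vsn_glog"),
                             ...) {
  method <- match.arg(method)
  if (method == "raw") {
    validate_kinome_array(arrays)
    return(tibble::tibble(
      array_id = arrays$array_id,
      peptide_id = arrays$peptide_id,
      replicate_index = arrays$replicate_index,
      value = arrays$foreground - arrays$background,
      method = "raw"
    ))
  }
  if (method == "log2") {
    return(log2_transform(arrays))
  }
  fit <- vsn_glog_transform(arrays, ...)
  out <- fit$normalized
  attr(out, "glog_params") <- fit$params
  out
}
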