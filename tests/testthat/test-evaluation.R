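eval_fixture <- function() {
  arrs <- simulate_repository(n = 6, m = 60, l = 9, seed = 71)
  run_performance_evaluation(arrs, n_pairs = 3, n_seeds = 6,
                             methods = c("raw", "log2"), master_seed = 72)
}

test_that("the evaluation loop produces a complete, reproducible table", {
  rec <- eval_fixture()
  expect_equal(nrow(rec), 3 * 2)
  expect_setequal(unique(rec$method), c("raw", "log2"))
  for (ms in c("specificity", "sensitivity", "precision", "accuracy")) {
    expect_true(all(rec[[ms]] >= 0 & rec[[ms]] <= 1))
  }
  expect_true(all(rec$n_seeded <= 6))
  expect_length(attr(rec, "seeded_sets"), 3)
  rec2 <- eval_fixture()
  expect_equal(as.data.frame(rec), as.data.frame(rec2))

  td <- tidy(rec)
  expect_setequal(td$measure,
                  c("specificity", "sensitivity", "precision", "accuracy"))
  expect_true(all(td$mean >= 0 & td$mean <= 1))
  expect_equal(glance(rec)$n_pairs, 3)
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("a run without seeds gives vacuous sensitivity and empty truth", {
  arrs <- simulate_repository(n = 4, m = 50, l = 9, seed = 73)
  rec <- run_performance_evaluation(arrs, n_pairs = 2, n_seeds = 0,
                                    methods = "raw", master_seed = 74)
  expect_true(all(rec$n_seeded == 0))
  expect_true(all(rec$flag_vacuous_sensitivity))
  expect_true(all(rec$sensitivity == 1))
  expect_equal(rec$specificity, 1 - rec$n_detected / 50)
})

test_that("raw detection finds most seeded 2-fold changes", {
  arrs <- simulate_repository(n = 10, m = 150, l = 9, seed = 75)
  rec <- run_performance_evaluation(arrs, n_pairs = 10, n_seeds = 15,
                                    methods = "raw", master_seed = 76)
  expect_gt(mean(rec$sensitivity), 0.5)
})

test_that("method comparison handles identical and shifted records", {
  rec <- eval_fixture()
  dup <- dplyr::bind_rows(
    dplyr::mutate(rec[rec$method == "raw", ], method = "m1"),
    dplyr::mutate(rec[rec$method == "raw", ], method = "m2")
  )
  cmp <- compare_methods(dup, "m1", "m2")
  expect_equal(cmp$statistic, rep(0, 4))
  expect_equal(cmp$p_value, rep(1, 4))

  shifted <- dplyr::bind_rows(
    dplyr::mutate(rec[rec$method == "raw", ], method = "m1"),
    rec[rec$method == "raw", ] |>
      dplyr::mutate(method = "m2",
                    sensitivity = pmin(sensitivity + 0.3, 2),
                    specificity = pmin(specificity + 0.3, 2),
                    accuracy = pmin(accuracy + 0.3, 2),
                    precision = pmin(precision + 0.3, 2))
  )
  cmp2 <- compare_methods(shifted, "m1", "m2")
  expect_true(all(cmp2$note == "deterministic difference"))
  expect_true(all(is.na(cmp2$p_value)))

  expect_error(compare_methods(rec, "raw", "vsn_glog"), "both methods")
})

test_that("Levene and paired t agree with brute-force formula oracles", {
  withr::with_seed(77, {
    n <- 12
    base <- tibble::tibble(pair_id = paste0("pair", 1:n))
    mk <- function(method, centre, spread) {
      dplyr::mutate(base, method = method,
                    specificity = runif(n, centre, centre + spread),
                    sensitivity = runif(n, centre - 0.2, centre + spread),
                    accuracy = runif(n, centre, centre + spread),
                    precision = runif(n, centre - 0.1, centre + spread))
    }
    rec <- dplyr::bind_rows(mk("mA", 0.5, 0.2), mk("mB", 0.6, 0.35))
  })
  cmp <- compare_methods(rec, "mA", "mB")
  for (ms in cmp$measure) {
    xa <- rec[[ms]][rec$method == "mA"]
    xb <- rec[[ms]][rec$method == "mB"]
    lev <- oracle_levene(c(xa, xb), rep(c("mA", "mB"), each = 12))
    row <- cmp[cmp$measure == ms, ]
    expect_equal(row$levene_F, lev$statistic, tolerance = 1e-10)
    expect_equal(row$levene_p, lev$p.value, tolerance = 1e-10)
    tt <- oracle_t_paired(xb, xa)
    expect_equal(row$statistic, tt$statistic, tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$df, 11)
    expect_equal(row$mean_a, mean(xa))
  }
})

test_that("QC plots encode the pair structure and react to noise level", {
  tpl <- std_list[[9]]
  y <- synthesize_replicate(tpl, std_repo, seed = 78)
  idx <- withr::with_seed(79, sample.int(297, 25))
  sr <- seed_phosphorylation(y, std_repo, tpl, idx,
                             rep(c(0, 1), length.out = 25), seed = 80)
  p <- plot_pair_scatter(tpl, sr$array, seeded = sr$seeded)
  expect_s3_class(p, "ggplot")
  expect_equal(sum(p$data$seeded), length(sr$seeded))
  expect_s3_class(plot_intensity_histogram(tpl), "ggplot")

  out <- withr::local_tempdir()
  paths <- qc_plots(tpl, sr$array, seeded = sr$seeded, out_dir = out)
  expect_true(all(file.exists(paths)))

  # identical arrays sit exactly on the identity line
  p0 <- plot_pair_scatter(tpl, dplyr::mutate(tpl, array_id = "copy"))
  expect_equal(p0$data$template, p0$data$replicate)

  # higher fold-change threshold and noisy fraction spread the scatter
  rms <- function(fc, theta, seeds) {
    mean(vapply(seeds, function(s) {
      yy <- synthesize_replicate(tpl, std_repo, fc_threshold = fc,
                                 noisy_fraction = theta, seed = s)
      mx <- peptide_means(tpl)$abc
      my <- peptide_means(yy)$abc
      sqrt(mean((my - mx)^2))
    }, numeric(1)))
  }
  expect_gt(rms(4, 0.15, 81:83), rms(2, 0.05, 81:83))
})
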