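test_that("identical arrays yield an empty detection set", {
  a <- bc_array(matrix(1:40, 8, 5), array_id = "A")
  b <- dplyr::mutate(a, array_id = "B")
  det <- detect_differential(normalize_arrays(dplyr::bind_rows(a, b), "raw"))
  expect_equal(sum(det$detected), 0)
  expect_true(all(det$p_value == 1))
})

test_that("degenerate-variance differences follow the limiting t rules", {
  a <- bc_array(matrix(10, 5, 4), array_id = "A")
  shifted <- matrix(10, 5, 4)
  shifted[3, ] <- 15  # one peptide moved by a constant +5
  b <- bc_array(shifted, array_id = "B")
  det <- detect_differential(normalize_arrays(dplyr::bind_rows(a, b), "raw"))
  expect_equal(det$peptide_id[det$detected], "pep_003")
  expect_equal(det$p_value[det$peptide_id == "pep_003"], 0)
})

test_that("paired detection matches a brute-force t oracle", {
  d <- c(2, -1, 3, 0, 1, 2, -2, 1, 0)
  x <- rep(100, 9)
  a <- bc_array(matrix(x, 1), array_id = "A")
  b <- bc_array(matrix(x + d, 1), array_id = "B")
  det <- detect_differential(normalize_arrays(dplyr::bind_rows(a, b), "raw"))
  o <- oracle_t_paired(x, x + d)
  expect_equal(det$statistic, o$statistic)
  expect_equal(det$p_value, o$p.value)
  expect_equal(det$detected, o$p.value < 0.05)

  withr::with_seed(61, {
    for (i in 1:25) {
      xx <- rnorm(7, 50, 10)
      yy <- rnorm(7, 50 + runif(1, -10, 10), 10)
      a <- bc_array(matrix(xx, 1), array_id = "A")
      b <- bc_array(matrix(yy, 1), array_id = "B")
      det <- detect_differential(
        normalize_arrays(dplyr::bind_rows(a, b), "raw"))
      o <- oracle_t_paired(xx, yy)
      expect_equal(det$p_value, o$p.value, tolerance = 1e-12)
    }
  })
})

test_that("detection is symmetric under sign reversal", {
  withr::with_seed(62, {
    xm <- matrix(rnorm(60, 100, 20), 10, 6)
    ym <- matrix(rnorm(60, 100, 20), 10, 6)
  })
  a <- bc_array(xm, array_id = "A")
  b <- bc_array(ym, array_id = "B")
  det1 <- detect_differential(normalize_arrays(dplyr::bind_rows(a, b), "raw"))
  # negate all differences by swapping the roles of the arrays
  det2 <- detect_differential(normalize_arrays(dplyr::bind_rows(b, a), "raw"),
                              template_id = "B", replicate_id = "A")
  expect_equal(det1$detected, det2$detected)
  expect_equal(det1$p_value, det2$p_value)
})

test_that("confusion sets implement the set algebra literally", {
  N <- paste0("p", 1:10)
  cs <- confusion_sets(c("p1", "p2", "p3"), c("p2", "p3", "p4"), N)
  expect_setequal(cs$TP, c("p2", "p3"))
  expect_equal(cs$FP, "p4")
  expect_equal(cs$FN, "p1")
  expect_length(cs$TN, 6)

  cs0 <- confusion_sets(character(0), character(0), N)
  expect_setequal(cs0$TN, N)
  expect_length(c(cs0$TP, cs0$FP, cs0$FN), 0)

  expect_error(confusion_sets("zz", character(0), N), "subset")

  withr::with_seed(63, {
    ids <- sprintf("pep_%03d", 1:297)
    for (i in 1:20) {
      P <- sample(ids, rbinom(1, 60, 0.5))
      F_ <- sample(ids, rbinom(1, 60, 0.5))
      cs <- confusion_sets(P, F_, ids)
      counts <- oracle_confusion(P, F_, ids)
      expect_equal(lengths(cs[c("TP", "FP", "TN", "FN")]),
                   counts[c("TP", "FP", "TN", "FN")])
      # partition property
      expect_setequal(c(cs$TP, cs$FP, cs$TN, cs$FN), ids)
    }
  })
})

test_that("performance measures follow the four ratios with flagged edges", {
  cs <- confusion_sets(paste0("p", 1:4), paste0("p", c(1, 2, 5)),
                       paste0("p", 1:8))
  pm <- performance_measures(cs)
  expect_equal(pm$sensitivity, 0.5)
  expect_equal(pm$specificity, 0.75)
  expect_equal(pm$precision, 2 / 3)
  expect_equal(pm$accuracy, 0.625)

  perfect <- confusion_sets("p1", "p1", c("p1", "p2"))
  expect_equal(unlist(performance_measures(perfect)[1:4]),
               c(specificity = 1, sensitivity = 1, precision = 1,
                 accuracy = 1))

  vac <- performance_measures(confusion_sets(character(0), character(0),
                                             c("p1", "p2")))
  expect_equal(vac$sensitivity, 1)
  expect_equal(vac$precision, 0)
  expect_true(vac$flag_vacuous_sensitivity)
  expect_true(vac$flag_no_positive_calls)
})

test_that("Shapiro-Wilk helper rejects skewed arrays and flags constants", {
  expect_lt(shapiro_wilk_peptide_means(std_list[[7]]), 0.05)
  withr::with_seed(64, {
    normal <- bc_array(matrix(rnorm(297 * 2, 100, 10), 297, 2))
  })
  expect_gt(shapiro_wilk_peptide_means(normal), 1e-6)
  flat <- bc_array(matrix(5, 4, 2))
  expect_error(shapiro_wilk_peptide_means(flat), "constant")
  tiny <- bc_array(matrix(1:4, 2, 2))
  expect_error(shapiro_wilk_peptide_means(tiny), "3 peptides")
})

test_that("KS helper separates distinct and identical distributions", {
  a <- std_list[[8]]
  expect_equal(ks_two_sample(a, a), 1)
  withr::with_seed(65, {
    n1 <- bc_array(matrix(rnorm(297 * 2, 0, 1), 297, 2), array_id = "A")
    n2 <- bc_array(matrix(rnorm(297 * 2, 10, 1), 297, 2), array_id = "B")
  })
  expect_lt(ks_two_sample(n1, n2), 1e-10)
})
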