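test_that("repository pooling preserves entries and shapes", {
  arrs <- simulate_repository(n = 2, m = 3, l = 4, seed = 21)
  repo <- build_repository(arrs)
  expect_equal(nrow(repo$entries), 6)
  expect_equal(nrow(std_repo$entries), 48 * 297)
  # entry lookup returns the exact source spots
  e <- repo$entries[5, ]
  src <- arrs[arrs$array_id == e$array_id & arrs$peptide_id == e$peptide_id, ]
  expect_equal(repo$foreground[5, ], src$foreground)
  expect_equal(repo$background[5, ], src$background)
  expect_equal(e$mean_abc, mean(src$foreground - src$background))
})

test_that("incomparable arrays are rejected with the offending detail", {
  a <- bc_array(matrix(1:6, 2), array_id = "A")
  b <- bc_array(matrix(1:6, 2), array_id = "B",
                peptide_ids = c("pep_001", "other"))
  expect_error(build_repository(dplyr::bind_rows(a, b)), "other")
  c <- bc_array(matrix(1:8, 2), array_id = "C")
  expect_error(build_repository(list(a, c)), "replicate counts")
})

test_that("generalized fold change follows the sign-aware definition", {
  expect_equal(generalized_fold_change(2, 8), 4)
  expect_equal(generalized_fold_change(-8, -2), 4)
  expect_equal(generalized_fold_change(5, 5), 1)
  expect_true(is.na(generalized_fold_change(-3, 6)))
  expect_true(is.na(generalized_fold_change(0, 6)))
})

test_that("fold-change bounds branch on the sign of the mean", {
  expect_equal(fold_change_bounds(10, 2)[c("v", "w")],
               tibble::tibble(v = 20, w = 5))
  expect_equal(fold_change_bounds(-10, 2)[c("v", "w")],
               tibble::tibble(v = -5, w = -20))
  expect_equal(fold_change_bounds(0, 2)[c("v", "w")],
               tibble::tibble(v = 0, w = 0))
  expect_error(fold_change_bounds(1, 1), "fc_threshold")
  b <- withr::with_seed(5, fold_change_bounds(rnorm(200, 0, 50), 3))
  expect_true(all(b$v >= b$w))
})

test_that("bound and equivalence predicates match brute-force t oracles", {
  expect_true(mean_within_bounds(rep(10, 9), v = 20, w = 5))
  expect_false(mean_within_bounds(rep(30, 9), v = 20, w = 5))
  x <- c(18, 19, 20, 21, 22, 18, 20, 21, 19)
  expect_equal(
    mean_within_bounds(x, 20, 5, 0.05),
    oracle_t_one_sample(x, 20, "greater")$p.value >= 0.05 &&
      oracle_t_one_sample(x, 5, "less")$p.value >= 0.05
  )
  y <- c(9.5, 10.2, 10.1, 9.8, 10.4, 9.9, 10.0, 10.3, 9.6)
  expect_true(mean_equivalent(y, 10))
  expect_equal(mean_equivalent(y, 10, 0.05),
               oracle_t_one_sample(y, 10)$p.value >= 0.05)
  expect_true(mean_equivalent(rep(3.3, 5), 3.3))
  expect_false(mean_equivalent(y + 1000, 10))
})

test_that("vectorized scan probabilities agree with the scalar predicates", {
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- rnorm(9, runif(1, -50, 400), runif(1, 0.5, 60))
      v <- runif(1, -50, 500)
      w <- v - runif(1, 0, 300)
      m <- mean(x); s <- sd(x)
      expect_equal(
        kinosynth:::p_mean_greater(m, s, 9, v) >= 0.05 &&
          kinosynth:::p_mean_less(m, s, 9, w) >= 0.05,
        mean_within_bounds(x, v, w, 0.05)
      )
      expect_equal(kinosynth:::p_mean_two_sided(m, s, 9, v) >= 0.05,
                   mean_equivalent(x, v, 0.05))
    }
  })
})

test_that("self-repository synthesis flags no peptide as differential", {
  tpl <- std_list[[1]]
  self_repo <- build_repository(tpl)
  y <- synthesize_replicate(tpl, self_repo, noisy_fraction = 0,
                            seed = 31)
  cc <- replicate_consistency(y, tpl)
  expect_equal(sum(cc$flagged_differential), 0)
  expect_true(all(synthesis_provenance(y)$branch == "match"))
})

test_that("an impossible repository triggers the template fallback everywhere", {
  tpl <- std_list[[2]]
  shifted <- dplyr::mutate(std_arrays, foreground = foreground + 1e6)
  far_repo <- build_repository(shifted)
  y <- synthesize_replicate(tpl, far_repo, noisy_fraction = 0.5,
                            seed = 32, array_id = "Yfall")
  expect_equal(y$foreground, tpl$foreground)
  expect_equal(y$background, tpl$background)
  expect_true(all(synthesis_provenance(y)$fallback))
})

test_that("synthesis is deterministic and spot sets keep provenance", {
  tpl <- std_list[[3]]
  y1 <- synthesize_replicate(tpl, std_repo, seed = 33)
  y2 <- synthesize_replicate(tpl, std_repo, seed = 33)
  expect_equal(as.data.frame(y1), as.data.frame(y2))
  prov <- synthesis_provenance(y1)
  # every emitted replicate set is bit-identical to its recorded source
  ids <- unique(tpl$peptide_id)
  for (t in sample(seq_along(ids), 25)) {
    spots <- y1[y1$peptide_id == ids[t], ]
    if (prov$fallback[t]) {
      src <- tpl[tpl$peptide_id == ids[t], ]
    } else {
      src <- std_arrays[std_arrays$array_id == prov$source_array_id[t] &
                          std_arrays$peptide_id == prov$source_peptide_id[t], ]
    }
    expect_identical(spots$foreground, src$foreground)
    expect_identical(spots$background, src$background)
  }
})

test_that("seeding partitions requests into seeded and failed", {
  tpl <- std_list[[4]]
  y <- synthesize_replicate(tpl, std_repo, seed = 34)
  # empty request is a no-op
  sr0 <- seed_phosphorylation(y, std_repo, tpl, integer(0), integer(0),
                              seed = 35)
  expect_equal(sr0$array[-1], y[-1], ignore_attr = TRUE)
  expect_length(sr0$seeded, 0)

  idx <- withr::with_seed(36, sample.int(297, 20))
  dirs <- withr::with_seed(37, rbinom(20, 1, 0.5))
  sr <- seed_phosphorylation(y, std_repo, tpl, idx, dirs, seed = 38)
  ids <- unique(tpl$peptide_id)
  expect_setequal(c(sr$seeded, sr$failed), ids[idx])
  expect_length(intersect(sr$seeded, sr$failed), 0)
  expect_lte(length(sr$seeded), 20)
  expect_equal(tidy(sr), sr$report)

  # unchanged peptides are bit-identical to the input replicate
  untouched <- setdiff(ids, ids[idx])
  expect_identical(
    sr$array$foreground[sr$array$peptide_id %in% untouched],
    y$foreground[y$peptide_id %in% untouched]
  )
})

test_that("seeding an already-saturated peptide fails and reports it", {
  tpl <- std_list[[5]]
  ids <- unique(tpl$peptide_id)
  # push one peptide far beyond anything in the repository
  boosted <- dplyr::mutate(
    tpl, foreground = ifelse(peptide_id == ids[1], foreground + 1e9,
                             foreground))
  y <- synthesize_replicate(boosted, std_repo, noisy_fraction = 0,
                            seed = 39)
  sr <- seed_phosphorylation(y, std_repo, boosted, 1L, 1L, seed = 40)
  expect_equal(sr$failed, ids[1])
  expect_length(sr$seeded, 0)
  expect_identical(sr$array$foreground, y$foreground)
})

test_that("out-of-range or malformed seed requests are rejected", {
  tpl <- std_list[[6]]
  y <- synthesize_replicate(tpl, std_repo, seed = 41)
  expect_error(seed_phosphorylation(y, std_repo, tpl, c(1, 1), c(1, 0)),
               "distinct")
  expect_error(seed_phosphorylation(y, std_repo, tpl, 9999L, 1L), "1..m")
  expect_error(seed_phosphorylation(y, std_repo, tpl, 1:2, c(2, 0)),
               "directions")
  expect_warning(
    seed_phosphorylation(y, std_repo, tpl, 1:60, rep(1, 60), seed = 42),
    "15%")
})
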