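# Brute-force oracles, independent of the package implementation: plain
# arithmetic formulas plus distribution tail functions only.

oracle_t_one_sample <- function(x, mu,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  t <- (sum(x) / n - mu) / (sqrt(sum((x - sum(x) / n)^2) / (n - 1)) / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), n - 1),
              greater = stats::pt(t, n - 1, lower.tail = FALSE),
              less = stats::pt(t, n - 1))
  list(statistic = t, p.value = p)
}

oracle_t_paired <- function(x, y) {
  d <- y - x
  oracle_t_one_sample(d, 0)
}

# median-centered (Brown-Forsythe) Levene F from first principles
oracle_levene <- function(values, groups) {
  groups <- as.factor(groups)
  z <- abs(values - tapply(values, groups, median)[groups])
  k <- nlevels(groups)
  n <- length(values)
  zbar <- mean(z)
  zi <- tapply(z, groups, mean)
  ni <- tabulate(groups)
  num <- sum(ni * (zi - zbar)^2) / (k - 1)
  den <- sum((z - zi[groups])^2) / (n - k)
  f <- num / den
  list(statistic = f,
       p.value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# element-by-element confusion counting
oracle_confusion <- function(seeded, detected, all_peptides) {
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (p in all_peptides) {
    pos <- p %in% seeded
    call <- p %in% detected
    key <- if (pos && call) "TP" else if (!pos && call) "FP" else
      if (!pos && !call) "TN" else "FN"
    counts[key] <- counts[key] + 1
  }
  counts
}

oracle_measures <- function(counts) {
  c(specificity = unname(counts["TN"] / (counts["TN"] + counts["FP"])),
    sensitivity = unname(counts["TP"] / (counts["TP"] + counts["FN"])),
    precision = unname(counts["TP"] / (counts["TP"] + counts["FP"])),
    accuracy = unname((counts["TP"] + counts["TN"]) / sum(counts)))
}

# build a kinome array tibble from a matrix of background-corrected values
# (rows = peptides, cols = replicates); background fixed at 100
bc_array <- function(bc, array_id = "A", background = 100,
                     peptide_ids = NULL) {
  bc <- as.matrix(bc)
  m <- nrow(bc)
  l <- ncol(bc)
  ids <- peptide_ids %||% sprintf("pep_%03d", seq_len(m))
  tibble::tibble(
    array_id = array_id,
    peptide_id = rep(ids, each = l),
    replicate_index = rep(seq_len(l), m),
    foreground = as.vector(t(bc)) + background,
    background = background
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
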