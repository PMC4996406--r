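#' Template-versus-replicate scatter of peptide means
#'
#' Each point is one peptide's mean background-corrected intensity on the
#' template (horizontal) and on the synthesized array (vertical); the
#' identity line marks perfect replication, and seeded differentially
#' phosphorylated peptides are highlighted.
#'
#' @param template,replicate Comparable single kinome array tibbles.
#' @param seeded Optional character vector of seeded peptide ids.
#' @return A ggplot object.
#' @export
plot_pair_scatter <- function(template, replicate, seeded = NULL) {
  mx <- peptide_means(template)
  my <- peptide_means(replicate)
  df <- tibble::tibble(
    peptide_id = mx$peptide_id,
    template = mx$abc,
    replicate = my$abc[match(mx$peptide_id, my$peptide_id)],
    seeded = mx$peptide_id %in% (seeded %||% character(0))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$template, .data$replicate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$seeded),
                        alpha = 0.7, size = 1.4) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"),
      labels = c(`FALSE` = "unchanged", `TRUE` = "seeded"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "template mean background-corrected intensity",
      y = "synthesized mean background-corrected intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of peptide mean intensities with a density curve
#'
#' @param array A single kinome array tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_intensity_histogram <- function(array, bins = 40) {
  df <- peptide_means(array)
  ggplot2::ggplot(df, ggplot2::aes(.data$abc)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "darkgreen",
                            colour = "white") +
    ggplot2::geom_density(colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "mean background-corrected intensity",
                  y = "density",
                  title = df$array_id[1]) +
    ggplot2::theme_minimal()
}

#' Write QC plots for a template/replicate pair
#'
#' Saves the pair scatter and the two per-array intensity histograms as
#' PNG files under `out_dir`.
#'
#' @inheritParams plot_pair_scatter
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Invisibly, the paths of the written files.
#' @export
qc_plots <- function(template, replicate, seeded = NULL, out_dir = ".",
                     prefix = "qc", width = 6, height = 5, dpi = 150) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, paste0(
    prefix, "_",
    c("scatter", "hist_template", "hist_replicate"), ".png"
  ))
  ggplot2::ggsave(paths[1], plot_pair_scatter(template, replicate, seeded),
                  width = width, height = height, dpi = dpi)
  ggplot2::ggsave(paths[2], plot_intensity_histogram(template),
                  width = width, height = height, dpi = dpi)
  ggplot2::ggsave(paths[3], plot_intensity_histogram(replicate),
                  width = width, height = height, dpi = dpi)
  invisible(paths)
}

#' Boxplots of performance measures by normalization method
#'
#' @param object A [run_performance_evaluation()] record table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinosynth_eval
#' @export
autoplot.kinosynth_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("specificity", "sensitivity", "precision", "accuracy"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}
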