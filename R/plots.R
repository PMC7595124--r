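# ggplot2 views of the main result types.

#' Plot a diagnostic k-mer density track
#'
#' Per-window counts of A- and B-labeled k-mer occurrences along each
#' chromosome, optionally overlaid with inferred ancestry segments.
#'
#' @param track Tibble from [density_track()].
#' @param segments Optional segments from [segment_ancestry()].
#' @return A ggplot object.
#' @export
plot_density_track <- function(track, segments = NULL) {
  long <- tidyr::pivot_longer(track, c("n_A", "n_B"), names_to = "subgenome",
                              values_to = "count")
  long$subgenome <- sub("n_", "", long$subgenome)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                          y = .data$count,
                                          colour = .data$subgenome)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(A = "#2166ac", B = "#b2182b")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "diagnostic k-mer occurrences",
                  colour = "subgenome") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = -1, yend = -1, colour = .data$state),
      inherit.aes = FALSE, linewidth = 2)
  }
  p
}

#' Plot per-accession ancestry dosage segments
#'
#' One horizontal bar per (imputed) haploid chromosome copy, colored by
#' species ancestry, in the style of chromosome-painting figures.
#'
#' @param segments A `dosage_segments` tibble from [smooth_dosage()].
#' @param ploidy Accession ploidy; defaults to the attribute on `segments`.
#' @return A ggplot object.
#' @export
plot_dosage_segments <- function(segments, ploidy = NULL) {
  ploidy <- ploidy %||% attr(segments, "ploidy")
  bars <- dplyr::bind_rows(lapply(seq_len(ploidy), function(copy) {
    dplyr::mutate(segments, copy = copy,
                  species = ifelse(copy <= .data$dosage_1, "species 1",
                                   "species 2"))
  }))
  ggplot2::ggplot(bars) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start / 1e6,
                                    xmax = .data$end / 1e6,
                                    ymin = .data$copy - 0.45,
                                    ymax = .data$copy + 0.45,
                                    fill = .data$species)) +
    ggplot2::scale_fill_manual(values = c("species 1" = "#b2182b",
                                          "species 2" = "#2166ac")) +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "left") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (Mb)", y = "haploid chromosome copies",
                  fill = "ancestry") +
    ggplot2::theme_minimal()
}

#' Plot the homeolog expression-bias distribution
#'
#' Histogram of per-pair log2 B/A cpm ratios with the median marked.
#'
#' @param records Record tibble from [pair_cpm_records()].
#' @param min_cpm Expression floor applied to both members.
#' @return A ggplot object.
#' @export
plot_expression_bias <- function(records, min_cpm = 0.5) {
  both <- records$cpm_A > min_cpm & records$cpm_B > min_cpm
  ratios <- tibble(log2_ratio = log2(records$cpm_B[both] / records$cpm_A[both]))
  med <- median(ratios$log2_ratio)
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = med, colour = "#b2182b") +
    ggplot2::labs(x = "log2(B/A cpm)", y = "homeolog pairs",
                  subtitle = sprintf("median B/A = %.3f", 2^med)) +
    ggplot2::theme_minimal()
}
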