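# ggplot2 presentation of the main result types

#' Bar chart of contig-end annotation categories
#'
#' @param ends Output of [annotate_ends()].
#' @return A ggplot object.
#' @export
plot_end_annotation <- function(ends) {
  counts <- ends %>% dplyr::count(.data$label, sort = TRUE)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.1,
                       size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contig ends",
                  title = "Contig ends by nonredundant annotation") +
    ggplot2::theme_minimal()
}

#' Observed vs random counts for a permutation-enrichment result
#'
#' Shows the random distribution per track with the observed count and fold
#' enrichment.
#'
#' @param object An `asm_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asm_enrichment
#' @export
autoplot.asm_enrichment <- function(object, ...) {
  rc <- attr(object, "random_counts")
  rand <- purrr::imap_dfr(rc, ~ tibble(track = .y, count = .x))
  obs <- tidy(object)
  ggplot2::ggplot(rand, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::geom_text(
      data = obs,
      ggplot2::aes(x = Inf, y = Inf,
                   label = sprintf("fold %.2f, p %.2g", .data$fold,
                                   .data$p)),
      hjust = 1.1, vjust = 1.5, size = 3) +
    ggplot2::facet_wrap(~track, scales = "free") +
    ggplot2::labs(x = "ends near track (random placements)", y = NULL,
                  title = "Permutation enrichment of contig ends") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome-wide dot plot of alignment discontinuities
#'
#' Position along each chromosome vs event size, coloured by class
#' (expansion/contraction), CENSAT-flagged events hollow.
#'
#' @param discs Output of [censat_flagging()] (or
#'   [find_discontinuities()]).
#' @return A ggplot object.
#' @export
plot_discontinuities <- function(discs) {
  d <- discs %>% filter(.data$class %in% c("contraction", "expansion"))
  if (!"censat_flag" %in% names(d)) d$censat_flag <- FALSE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 1e6,
                                  y = .data$event_size,
                                  colour = .data$class,
                                  shape = .data$censat_flag)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(contraction = "firebrick",
                                            expansion = "steelblue")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mbp)", y = "event size (bp)",
                  colour = NULL, shape = "CENSAT",
                  title = "Contig alignment discontinuities") +
    ggplot2::theme_minimal()
}

#' Base pairs per copy-number category
#'
#' @param calls Output of [classify_cnv()].
#' @return A ggplot object.
#' @export
plot_cnv_categories <- function(calls) {
  d <- calls %>%
    group_by(.data$category) %>%
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$bp / 1e6)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "Mbp",
                  title = "Multi-coverage bases by CNV category") +
    ggplot2::theme_minimal()
}

#' Binned dinucleotide profile with enriched bins highlighted
#'
#' @param profile A [dinucleotide_profile()].
#' @param t An [asm_thresholds()] object (for the Z cut-off).
#' @return A ggplot object.
#' @export
plot_dinucleotide_profile <- function(profile, t = asm_thresholds()) {
  dinucs <- attr(profile, "dinucs")
  long <- profile %>%
    tidyr::pivot_longer(dplyr::all_of(dinucs), names_to = "dinuc",
                        values_to = "count") %>%
    group_by(.data$dinuc) %>%
    mutate(z = (.data$count - mean(.data$count)) /
             stats::sd(.data$count)) %>%
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$count)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = ~ filter(.x, .data$z >= t$z_cutoff),
                        colour = "red", size = 0.8) +
    ggplot2::facet_wrap(~dinuc, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = "dinucleotides per bin",
                  title = "Binned dinucleotide counts (enriched bins red)") +
    ggplot2::theme_minimal()
}
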