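# ggplot2 helpers for the main result types. These are thin views over the
# tidied objects; all statistics are computed by the analysis functions.

#' Plot a positional base-probability matrix
#'
#' Stacked per-position base probabilities, the bar form of a sequence logo.
#'
#' @param object A `freq_matrix` from [freq_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot freq_matrix
#' @export
autoplot.freq_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = c("A", "C", "G", "U"),
                              names_to = "base", values_to = "prob")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$position, levels = sort(unique(.data$position))),
    y = .data$prob, fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", U = "#D62839")) +
    ggplot2::labs(x = "position", y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PSSM as a position-by-base heat map
#'
#' @param object A `pssm` from [build_pssm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pssm
#' @export
autoplot.pssm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = factor(.data$position, levels = sort(unique(.data$position))),
    y = .data$base, fill = .data$log2_freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position", y = NULL, fill = "log2 freq") +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of a differential-splicing fit
#'
#' Pooled delta-PSI against -log10 genotype q-value, coloured by the
#' significance category when present.
#'
#' @param object A `diffsplice_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffsplice_fit
#' @export
autoplot.diffsplice_fit <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$q_genotype)) |>
    mutate(neglog_q = -log10(pmax(.data$q_genotype, 1e-300)))
  aes <- if ("category" %in% names(df)) {
    ggplot2::aes(x = .data$delta_psi, y = .data$neglog_q,
                 colour = .data$category)
  } else {
    ggplot2::aes(x = .data$delta_psi, y = .data$neglog_q)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = expression(Delta * "PSI (mutant - wt)"),
                  y = expression(-log[10] ~ "q (genotype)")) +
    ggplot2::theme_minimal()
}

#' Genome-scan view of a bulked-segregant track
#'
#' Per-SNP pool allele fractions (when present) with the raw and tri-cube
#' smoothed G statistics along the chromosome.
#'
#' @param object A `bsa_track` from [smooth_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_track
#' @export
autoplot.bsa_track <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g_raw), colour = "grey70",
                        size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g_smooth), colour = "#1b7837",
                       linewidth = 0.9) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "G statistic") +
    ggplot2::theme_minimal()
  p
}

#' Scatter of U5 against U6 interaction scores
#'
#' @param scores Tibble with `u5_ll` and `u6_ll` columns ([score_sites()]).
#' @param colour Optional column name used for point colour (e.g. a class
#'   flag).
#' @return A ggplot object.
#' @export
plot_score_scatter <- function(scores, colour = NULL) {
  aes <- if (!is.null(colour)) {
    ggplot2::aes(x = .data$u5_ll, y = .data$u6_ll,
                 colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$u5_ll, y = .data$u6_ll)
  }
  ggplot2::ggplot(scores, aes) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::labs(x = "U5 log-likelihood (-2..-1)",
                  y = "U6 log-likelihood (+3..+5)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
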