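# ggplot2 views of the main result types. Each returns a plot object the
# caller can theme further.

#' Plot a per-site methylation histogram
#'
#' @param hist Tibble from [methylation_histogram()].
#' @return A ggplot object.
#' @export
plot_methylation_histogram <- function(hist) {
  w <- hist$bin_end[1] - hist$bin_start[1]
  hist <- mutate(hist, mid = (.data$bin_start + .data$bin_end) / 2)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$n)) +
    ggplot2::geom_col(width = w, fill = "grey30") +
    ggplot2::labs(x = "methylation (%)", y = "CpG sites") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-region-class methylation change
#'
#' @param deltas `deltas` tibble from [region_delta_distribution()].
#' @return A ggplot object.
#' @export
plot_region_deltas <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$label, y = .data$delta)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.6, scale = "width") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Δ methylation (pct points)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a metagene methylation profile
#'
#' @param profile Tibble from [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$meth_pct,
                                        colour = .data$zone)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "bin (5' → 3')", y = "methylation (%)") +
    ggplot2::theme_minimal()
}

#' Plot a peak enrichment profile against its permutation envelope
#'
#' @param profile Tibble from [permutation_background()].
#' @return A ggplot object.
#' @export
plot_peak_enrichment <- function(profile) {
  mid <- (profile$bin_start + profile$bin_end) / 2
  df <- mutate(profile, mid = mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$perm_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "firebrick") +
    ggplot2::labs(x = "distance to region midpoint (bp)", y = "peaks per bin") +
    ggplot2::theme_minimal()
}

#' Bar plot of DEG counts binned by fold-change
#'
#' @param deg Tibble from [deg_call()].
#' @return A ggplot object.
#' @export
plot_deg_counts <- function(deg) {
  df <- deg |>
    filter(.data$deg_status != "ns") |>
    count(.data$deg_status, .data$lfc_bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deg_status, y = .data$n,
                                   fill = .data$lfc_bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "DEGs", fill = "|log2FC|") +
    ggplot2::theme_minimal()
}
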