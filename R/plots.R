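#' Plot cluster peptide counts
#'
#' Bar plot of the number of peptides assigned to each allele and the
#' trash cluster. Requires ggplot2.
#'
#' @param result A `deconvolution_result`.
#' @return A ggplot object.
#' @export
plot_cluster_counts <- function(result) {
  stopifnot(inherits(result, "deconvolution_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(cluster = names(result$cluster_counts),
                   count = as.integer(result$cluster_counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "peptides") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-cluster length distributions
#'
#' @param result A `deconvolution_result`.
#' @param clusters Clusters to include (default all).
#' @return A ggplot object (faceted histogram).
#' @export
plot_length_distributions <- function(result, clusters = NULL) {
  stopifnot(inherits(result, "deconvolution_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (is.null(clusters)) clusters <- names(result$cluster_counts)
  df <- do.call(rbind, lapply(clusters, function(cl) {
    h <- length_distribution(result, cl)
    data.frame(cluster = cl, length = as.integer(names(h)),
               count = as.integer(h))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot a KL sequence logo as stacked letters
#'
#' Letters at each core position are stacked by frequency-weighted KL
#' height (bits). A plain text-based rendering: exact glyph geometry of
#' dedicated logo tools is out of scope, but heights match
#' [kl_logo_data()].
#'
#' @param logo Output of [kl_logo_data()], or a `motif_summary`.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (inherits(logo, "motif_summary"))
    logo <- kl_logo_data(logo$freq)
  h <- logo$heights[logo$heights$height > 0, ]
  h <- h[order(h$position, h$height), ]
  h$ymax <- stats::ave(h$height, h$position, FUN = cumsum)
  h$ymin <- h$ymax - h$height
  ggplot2::ggplot(h) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$position, y = (.data$ymin + .data$ymax) / 2,
                   label = .data$residue, size = .data$height),
      show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = 1:9, labels = paste0("P", 1:9)) +
    ggplot2::labs(x = NULL, y = "bits") +
    ggplot2::theme_minimal()
}
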