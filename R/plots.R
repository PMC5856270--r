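#' Signal cluster plot for one probe
#'
#' A-channel versus B-channel intensity scatter faceted by array condition
#' (G, D, U), coloured by genotype call when available — the plot used for
#' manual review of candidate probes. Heterozygotes of a cis-ASM probe sit on
#' the diagonal in G and collapse towards one axis in D; imprinted probes
#' collapse towards both axes.
#'
#' @param intensities Long intensity table.
#' @param snp_id Probe to plot.
#' @param genotypes Optional genotype call table.
#' @return A ggplot object.
#' @export
plot_signal_clusters <- function(intensities, snp_id, genotypes = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_signal_clusters requires the ggplot2 package")
  }
  validate_intensities(intensities)
  x <- intensities[intensities$snp_id == snp_id, ]
  if (nrow(x) == 0) stop("no intensity records for ", snp_id)
  x$condition <- factor(x$condition, levels = c("G", "D", "U"))
  if (!is.null(genotypes)) {
    g <- genotypes[genotypes$snp_id == snp_id, c("sample_id", "call")]
    x <- merge(x, g, by = "sample_id", all.x = TRUE)
    p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$intensity_a,
                                         y = .data$intensity_b,
                                         colour = .data$call))
  } else {
    p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$intensity_a,
                                         y = .data$intensity_b))
  }
  p + ggplot2::geom_point() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(title = snp_id, x = "allele A intensity",
                  y = "allele B intensity")
}
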