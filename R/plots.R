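#' Manhattan-style plot of a scan result
#'
#' Plots -log10 P-values along the chromosome-concatenated map, with
#' optional horizontal threshold lines. Requires ggplot2.
#'
#' @param scan data.frame with `chrom`, `pos`, `p_value` (e.g. from
#'   [flk_scan()] or [hapflk_scan()])
#' @param thresholds named numeric vector of P-value thresholds to draw
#' @return a ggplot object
#' @export
manhattan_plot <- function(scan, thresholds = c(nominal = 0.05)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ord <- order(scan$chrom, scan$pos)
  d <- scan[ord, ]
  offs <- c(0, cumsum(tapply(d$pos, d$chrom, max)))
  d$x <- d$pos + offs[match(d$chrom, sort(unique(d$chrom)))]
  d$logp <- -log10(pmax(d$p_value, 1e-300))
  gg <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$x, y = .data$logp, colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](P)))
  for (i in seq_along(thresholds)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(thresholds[i]),
                                   linetype = 2)
  }
  gg
}

#' MDS scatter plot of individuals coloured by population
#'
#' @param mds result of [classical_mds()]
#' @param pops population label per individual
#' @return a ggplot object
#' @export
mds_plot <- function(mds, pops) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- data.frame(C1 = mds$points[, 1], C2 = mds$points[, 2], pop = pops)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$C1, y = .data$C2,
                                  colour = .data$pop)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2")
}
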