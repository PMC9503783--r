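#' Plot a chemical space with library overlays
#'
#' Two-row panel layout: scatter plots of the pairwise principal-component
#' planes (PC1-PC2, PC2-PC3, PC3-PC1 for three components) with up to
#' three overlay sets (e.g. full library in grey, BD in blue, BCL in
#' green), and per-component density histograms below — the standard view
#' for judging how a subset occupies a combinatorial library's space.
#'
#' @param x a `chem_space`.
#' @param overlays named list of row-index vectors into the space (plotted
#'   over the full set, in order).
#' @param pcs components to display (default the first `min(m, 3)`).
#' @param cols colors: first for the full space, then one per overlay.
#' @param cex point size.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.chem_space <- function(x, overlays = NULL,
                            pcs = seq_len(min(x$m, 3L)),
                            cols = c("#E8D88F", "#3B6FB6", "#3FA34D", "#C23B22"),
                            cex = 0.5, ...) {
  sc <- x$scores
  pcs <- pcs[pcs <= ncol(sc)]
  .check(length(pcs) >= 1L, "no components to plot")
  pairs <- if (length(pcs) >= 3L) list(pcs[c(1, 2)], pcs[c(2, 3)], pcs[c(3, 1)])
           else if (length(pcs) == 2L) list(pcs[c(1, 2)])
           else list(pcs[c(1, 1)])
  old <- graphics::par(mfrow = c(2, max(length(pairs), length(pcs))),
                       mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old), add = TRUE)
  ocols <- cols[-1]
  for (pr in pairs) {
    graphics::plot(sc[, pr[1]], sc[, pr[2]], pch = 16, cex = cex,
                   col = cols[1],
                   xlab = colnames(sc)[pr[1]], ylab = colnames(sc)[pr[2]], ...)
    if (!is.null(overlays))
      for (i in seq_along(overlays))
        graphics::points(sc[overlays[[i]], pr[1]], sc[overlays[[i]], pr[2]],
                         pch = 16, cex = cex * 1.4,
                         col = ocols[(i - 1L) %% length(ocols) + 1L])
    if (!is.null(overlays) && pr[1] == pairs[[1]][1] && pr[2] == pairs[[1]][2])
      graphics::legend("topright", bty = "n", pch = 16,
                       col = c(cols[1], ocols[seq_along(overlays)]),
                       legend = c("all", names(overlays)), cex = 0.8)
  }
  for (pc in pcs) {
    dall <- stats::density(sc[, pc])
    ymax <- max(dall$y)
    dens <- list()
    if (!is.null(overlays))
      for (i in seq_along(overlays)) {
        v <- sc[overlays[[i]], pc]
        if (length(v) >= 2L) {
          dens[[i]] <- stats::density(v)
          ymax <- max(ymax, dens[[i]]$y)
        }
      }
    graphics::plot(dall, col = cols[1], lwd = 2, main = "",
                   xlab = colnames(sc)[pc], ylim = c(0, ymax))
    for (i in seq_along(dens))
      if (!is.null(dens[[i]]))
        graphics::lines(dens[[i]], col = ocols[(i - 1L) %% length(ocols) + 1L],
                        lwd = 2)
  }
  invisible(x)
}
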