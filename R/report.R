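## draw one scatter of study (k0, k1) estimates with ellipses
plot_panel <- function(study, main, xlim, ylim, rel_ellipse = NULL,
                       unrel_ellipse = NULL, highlight = NULL) {
  graphics::plot(study$k0, study$k1, xlim = xlim, ylim = ylim,
                 xlab = expression(hat(P)(Z == 0)),
                 ylab = expression(hat(P)(Z == 1)),
                 main = main, pch = 20, col = "grey30", cex = 0.7)
  if (!is.null(rel_ellipse)) {
    b <- ellipse_boundary(rel_ellipse)
    graphics::lines(b[, 1], b[, 2], col = "blue", lwd = 2)
  }
  if (!is.null(unrel_ellipse)) {
    b <- ellipse_boundary(unrel_ellipse)
    graphics::lines(b[, 1], b[, 2], col = "magenta", lwd = 2)
  }
  if (!is.null(highlight) && nrow(highlight)) {
    graphics::points(highlight$k0, highlight$k1, col = "red", pch = 1,
                     cex = 1.6, lwd = 2)
  }
}

## does an ellipse's bounding box intersect the window?
ellipse_overlaps_window <- function(e, xlim, ylim) {
  b <- ellipse_boundary(e)
  any(b[, 1] >= xlim[1] & b[, 1] <= xlim[2] &
        b[, 2] >= ylim[1] & b[, 2] <= ylim[2])
}

#' Plot a relatedness-check result
#'
#' With `which = "overview"`, plots the estimated IBD coefficients
#' \eqn{\hat P(Z=1)} versus \eqn{\hat P(Z=0)} for all study pairs with the
#' Bonferroni-adjusted unrelated ellipse superposed (when available).  With
#' a relationship name, the plotting window is restricted to the
#' neighborhood of that relationship's prediction ellipse, the unrelated
#' ellipse is added when it overlaps the window, and automatically flagged
#' pairs are circled.
#'
#' @param x an `ibd_result` from [run_ibdcheck()].
#' @param which `"overview"` or a simulated relationship name.
#' @param expand window expansion factor around the relationship ellipse.
#' @param ... unused.
#' @export
plot.ibd_result <- function(x, which = "overview", expand = 1.8, ...) {
  st <- x$study[x$study$status == "ok", ]
  if (identical(which, "overview")) {
    xr <- range(st$k0, finite = TRUE); yr <- range(st$k1, finite = TRUE)
    unrel <- x$ellipses$unrelated_adjusted
    if (!is.null(unrel)) {
      b <- ellipse_boundary(unrel)
      xr <- range(xr, b[, 1]); yr <- range(yr, b[, 2])
    }
    plot_panel(st, "IBD coefficients for all study pairs", xr, yr,
               unrel_ellipse = unrel)
    return(invisible(x))
  }
  e <- x$ellipses[[which]]
  if (is.null(e)) stop("no simulated relationship '", which, "' in result")
  b <- ellipse_boundary(e)
  cx <- mean(range(b[, 1])); cy <- mean(range(b[, 2]))
  hw <- max(diff(range(b[, 1])), 0.02) * expand / 2
  hh <- max(diff(range(b[, 2])), 0.02) * expand / 2
  xlim <- c(cx - hw, cx + hw); ylim <- c(cy - hh, cy + hh)
  unrel <- x$ellipses$unrelated_adjusted
  if (!is.null(unrel) && !ellipse_overlaps_window(unrel, xlim, ylim))
    unrel <- NULL
  hl <- if (!is.null(x$flagged))
    x$flagged[x$flagged$relationship == which, , drop = FALSE]
  plot_panel(st, paste("Possible", which, "pairs"), xlim, ylim,
             rel_ellipse = e, unrel_ellipse = unrel, highlight = hl)
  invisible(x)
}

#' Write the full report of a run
#'
#' Writes TSVs for the study estimates, per-relationship simulated
#' estimates, flagged pairs and QC report, plus static PDF plots: one
#' overview of all study pairs (with the adjusted unrelated ellipse) and,
#' when pairs were simulated, one windowed plot per non-unrelated
#' relationship with flagged pairs highlighted.
#'
#' @param result an `ibd_result`.
#' @param outdir output directory (created if needed).
#' @return character vector of files written.
#' @export
render_report <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
    files <<- c(files, path)
  }
  put(result$study, "ibd_estimates.tsv")
  put(result$qc_report, "qc_report.tsv")
  if (length(result$sim))
    put(do.call(rbind, result$sim), "simulated_estimates.tsv")
  if (!is.null(result$flagged)) put(result$flagged, "flagged_pairs.tsv")

  pdf_plot <- function(name, expr) {
    path <- file.path(outdir, name)
    grDevices::pdf(path, width = 6, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    files <<- c(files, path)
  }
  pdf_plot("plot_overview.pdf", plot(result, "overview"))
  for (rel in setdiff(names(result$sim), "unrelated"))
    pdf_plot(paste0("plot_", gsub("[^A-Za-z0-9]", "_", rel), ".pdf"),
             plot(result, rel))
  files
}
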