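open_device <- function(file, width, height) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         stop("unsupported image format: .", ext, " (use png, pdf or svg)"))
}

check_results_table <- function(results, need = c("p")) {
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(results) == 0L) stop("results table is empty")
  if (all(is.na(results$p))) stop("all p-values are missing")
  invisible(TRUE)
}

#' Manhattan plot of GWAS results
#'
#' Plots `-log10(p)` against cumulative genomic position with chromosomes
#' alternately shaded and a horizontal genome-wide significance line.
#' Separate from the GWAS routine so base-graphics parameters stay under
#' the user's control. The input table is never modified.
#'
#' @param results data.frame with columns `chrom`, `pos`, `p` (markers
#'   with missing p are skipped).
#' @param threshold significance level for the horizontal line; default
#'   Bonferroni `0.05 / m` with `m` the number of rows.
#' @param file optional output image path (`.png`, `.pdf` or `.svg`); when
#'   `NULL`, draws on the current device.
#' @param width,height device size in inches.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list describing the rendered plot: `threshold`,
#'   `threshold_y` (the line's y-value), `n_points`, `chrom_offsets`.
#' @export
manhattan_plot <- function(results, threshold = NULL, file = NULL,
                           width = 8, height = 4, main = "", ...) {
  check_results_table(results, c("chrom", "pos", "p"))
  if (is.null(threshold)) threshold <- 0.05 / nrow(results)
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)")
  ok <- !is.na(results$p)
  chrom <- as.character(results$chrom)[ok]
  pos <- results$pos[ok]
  p <- results$p[ok]
  chroms <- unique(chrom)
  offsets <- stats::setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (cc in chroms) {
    offsets[cc] <- run
    run <- run + max(pos[chrom == cc]) + 1
  }
  x <- pos + offsets[chrom]
  y <- -log10(p)
  cols <- ifelse(match(chrom, chroms) %% 2 == 1, "grey25", "steelblue")
  ty <- -log10(threshold)
  if (!is.null(file)) {
    open_device(file, width, height)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x, y, pch = 20, cex = 0.6, col = cols,
                 xlab = "genomic position", ylab = expression(-log[10](p)),
                 ylim = c(0, max(y, ty) * 1.05), main = main, xaxt = "n", ...)
  mids <- vapply(chroms, function(cc) mean(range(x[chrom == cc])), numeric(1))
  graphics::axis(1, at = mids, labels = chroms)
  graphics::abline(h = ty, col = "red", lty = 2)
  invisible(list(threshold = threshold, threshold_y = ty,
                 n_points = length(x), chrom_offsets = offsets))
}

#' QQ plot of GWAS p-values
#'
#' Observed versus expected `-log10(p)` under the uniform null, with the
#' identity line. Expected quantiles are `(i - 0.5) / m` over the `m`
#' non-missing p-values; `p = 1` maps to 0 without infinities.
#'
#' @param results data.frame with a `p` column (at least one non-missing).
#' @param file optional output image path (`.png`, `.pdf` or `.svg`).
#' @param width,height device size in inches.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list: `observed`, `expected` (both `-log10` scale,
#'   ascending), `n_points`.
#' @export
qq_plot <- function(results, file = NULL, width = 5, height = 5,
                    main = "", ...) {
  check_results_table(results, "p")
  p <- sort(results$p[!is.na(results$p)])
  mN <- length(p)
  expected <- -log10((seq_len(mN) - 0.5) / mN)
  observed <- -log10(pmax(p, .Machine$double.xmin))
  # both ascending for plotting: largest p first
  if (!is.null(file)) {
    open_device(file, width, height)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(rev(expected), rev(observed), pch = 20, cex = 0.6,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), main = main, ...)
  graphics::abline(0, 1, col = "red")
  invisible(list(observed = rev(observed), expected = rev(expected),
                 n_points = mN))
}
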