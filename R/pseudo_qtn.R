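#' Bin-size defaults keyed to marker density
#'
#' Model selection searches over a small set of physical bin widths whose
#' scale tracks the number of markers on the panel. The lookup below maps a
#' marker count to four candidate widths (base pairs); an arbitrary `m`
#' uses the nearest tabulated density on the log scale.
#'
#' @param m marker count.
#' @return numeric vector of four bin widths in base pairs.
#' @export
default_bin_sizes <- function(m) {
  dens <- c(1e4, 5e4, 6e4, 1e5, 5e5, 1e6, 5e6)
  sizes <- list(c(500, 1000, 1500, 2000),
                c(2500, 5000, 7500, 10000),
                c(2500, 5000, 7500, 10000),
                c(5000, 10000, 15000, 20000),
                c(25000, 50000, 75000, 100000),
                c(50000, 100000, 150000, 200000),
                c(250000, 500000, 750000, 1000000))
  sizes[[which.min(abs(log(dens) - log(max(m, 1))))]]
}

#' Pseudo-QTN selection configuration
#'
#' @param m marker count used to pick default bin sizes (ignored when
#'   `bin_sizes` is given).
#' @param bin_sizes base-pair bin widths to search (default keyed to `m`,
#'   see [default_bin_sizes()]).
#' @param qtn_counts candidate pseudo-QTN set sizes, ascending.
#' @param eligibility_threshold largest scan p-value a marker may have and
#'   still become a pseudo-QTN candidate (default 0.01).
#' @param cor_filter squared-correlation cap between selected pseudo-QTNs;
#'   the later-ranked member of an offending pair is dropped (default 0.7).
#' @return list of class `bin_config`.
#' @export
bin_config <- function(m = NULL, bin_sizes = NULL,
                       qtn_counts = c(10L, 20L, 30L),
                       eligibility_threshold = 0.01, cor_filter = 0.7) {
  if (is.null(bin_sizes)) {
    if (is.null(m)) stop("supply either m or bin_sizes")
    bin_sizes <- default_bin_sizes(m)
  }
  bin_sizes <- as.numeric(bin_sizes)
  qtn_counts <- as.integer(qtn_counts)
  if (any(bin_sizes <= 0)) stop("bin sizes must be positive")
  if (any(qtn_counts <= 0L)) stop("qtn_counts must be positive")
  if (is.unsorted(qtn_counts)) stop("qtn_counts must be ascending")
  if (eligibility_threshold <= 0 || eligibility_threshold > 1)
    stop("eligibility_threshold must be in (0, 1]")
  structure(list(bin_sizes = bin_sizes, qtn_counts = qtn_counts,
                 eligibility_threshold = eligibility_threshold,
                 cor_filter = cor_filter),
            class = "bin_config")
}

#' Assign markers to physical bins
#'
#' Bin label is the pair (chromosome, `floor((pos - 1) / bin_size)`), so a
#' 1-based position exactly at a bin-width multiple closes the bin (position
#' 500 with width 500 is bin 0; position 501 opens bin 1).
#'
#' @param info a [marker_info()] data.frame.
#' @param bin_size bin width in base pairs (positive).
#' @return character vector of bin labels, length `nrow(info)`.
#' @export
assign_bins <- function(info, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a positive number")
  if (any(info$pos < 1)) stop("positions must be 1-based positive")
  paste(info$chrom, floor((info$pos - 1) / bin_size), sep = ":")
}

#' Best marker per bin, ranked
#'
#' Keeps the smallest-p marker in every bin and ranks the winners by
#' ascending p-value. All ties (within a bin and in the overall ranking)
#' break by ascending (chromosome, position, marker index), which makes the
#' selection invariant to marker input order. Markers with missing p-values
#' never become candidates.
#'
#' @param scan a `scan_result` (needs a `p` column aligned with `info`).
#' @param info [marker_info()] aligned with the scan.
#' @param bins bin labels from [assign_bins()].
#' @return data.frame: `index` (marker column index), `p`, `bin`, ranked.
#' @export
top_per_bin <- function(scan, info, bins) {
  p <- scan$p
  if (length(p) != length(bins) || length(p) != nrow(info))
    stop("p-values, bins and marker info must be aligned")
  keep <- which(!is.na(p))
  if (!length(keep))
    return(data.frame(index = integer(0), p = numeric(0),
                      bin = character(0), stringsAsFactors = FALSE))
  ord <- keep[order(p[keep], info$chrom[keep], info$pos[keep], keep,
                    method = "radix")]
  win <- ord[!duplicated(bins[ord])]
  data.frame(index = win, p = p[win], bin = bins[win],
             stringsAsFactors = FALSE)
}

new_pseudo_qtn_set <- function(indices, bin_size, qtn_count, p = NULL) {
  structure(list(indices = as.integer(indices), bin_size = bin_size,
                 qtn_count = as.integer(qtn_count), p = p),
            class = "pseudo_qtn_set")
}

#' @export
print.pseudo_qtn_set <- function(x, ...) {
  cat(sprintf("pseudo_qtn_set: %d markers (bin %g bp, target count %d)\n",
              length(x$indices), x$bin_size, x$qtn_count))
  invisible(x)
}

#' Build candidate pseudo-QTN sets over the (bin size, count) grid
#'
#' For each bin width, markers are binned, the best marker per bin is
#' ranked by p-value, and candidates failing the eligibility threshold are
#' discarded. Each target set size then takes the best eligible candidates
#' in rank order, greedily skipping any candidate whose squared correlation
#' (genotypes on the masked samples) with an already-accepted member
#' exceeds the `cor_filter` cap — highly redundant covariates would
#' otherwise degenerate the fixed design. Sets may come out smaller than
#' their target size, or empty.
#'
#' @param mat [marker_matrix()] (for the correlation filter).
#' @param info [marker_info()] aligned with the matrix columns.
#' @param scan `scan_result` from the previous iteration.
#' @param config [bin_config()].
#' @param mask integer row indices of phenotype-complete samples.
#' @return list of `pseudo_qtn_set`, one per (bin_size, qtn_count) pair.
#' @export
build_candidate_sets <- function(mat, info, scan, config, mask = NULL) {
  stopifnot(inherits(config, "bin_config"))
  if (is.null(mask)) mask <- seq_len(mat$n)
  out <- vector("list", length(config$bin_sizes) * length(config$qtn_counts))
  i <- 0L
  for (bs in config$bin_sizes) {
    bins <- assign_bins(info, bs)
    ranked <- top_per_bin(scan, info, bins)
    eligible <- ranked[ranked$p <= config$eligibility_threshold, , drop = FALSE]
    max_count <- max(config$qtn_counts)
    accepted <- integer(0)
    acc_p <- numeric(0)
    if (nrow(eligible)) {
      Zacc <- NULL
      for (r in seq_len(nrow(eligible))) {
        if (length(accepted) >= max_count) break
        idx <- eligible$index[r]
        x <- mat$values[mask, idx]
        if (stats::var(x) < 1e-12) next
        if (!is.null(Zacc)) {
          r2 <- suppressWarnings(stats::cor(x, Zacc))^2
          if (any(r2 > config$cor_filter, na.rm = TRUE)) next
        }
        accepted <- c(accepted, idx)
        acc_p <- c(acc_p, eligible$p[r])
        Zacc <- cbind(Zacc, x)
      }
    }
    for (qc in config$qtn_counts) {
      i <- i + 1L
      take <- seq_len(min(qc, length(accepted)))
      out[[i]] <- new_pseudo_qtn_set(accepted[take], bs, qc, acc_p[take])
    }
  }
  out
}
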