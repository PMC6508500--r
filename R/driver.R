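#' Run configuration for the iterative GWAS driver
#'
#' @param max_iterations iteration cap (default 20).
#' @param bin_sizes base-pair bin widths for pseudo-QTN selection
#'   (default: keyed to the marker count, see [default_bin_sizes()]).
#' @param qtn_counts candidate pseudo-QTN set sizes (default 10, 20, 30).
#' @param eligibility_threshold largest scan p-value a marker may have to
#'   become a pseudo-QTN candidate (default 0.01).
#' @param cor_filter squared-correlation cap among selected pseudo-QTNs.
#' @param n_workers_scan forked workers for the marker scan.
#' @param n_workers_reml forked workers for the REML model search.
#' @param reoptimize_bins re-run the (bin size, count) search every
#'   iteration (default TRUE) rather than freezing the first winner.
#' @param verbose log one structured line per iteration.
#' @return list of class `run_config`.
#' @export
run_config <- function(max_iterations = 20L, bin_sizes = NULL,
                       qtn_counts = c(10L, 20L, 30L),
                       eligibility_threshold = 0.01, cor_filter = 0.7,
                       n_workers_scan = 1L, n_workers_reml = 1L,
                       reoptimize_bins = TRUE, verbose = FALSE) {
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L)
    stop("max_iterations must be >= 1")
  structure(list(max_iterations = max_iterations, bin_sizes = bin_sizes,
                 qtn_counts = as.integer(qtn_counts),
                 eligibility_threshold = eligibility_threshold,
                 cor_filter = cor_filter,
                 n_workers_scan = as.integer(n_workers_scan),
                 n_workers_reml = as.integer(n_workers_reml),
                 reoptimize_bins = isTRUE(reoptimize_bins),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

set_key <- function(idx) paste(sort(idx), collapse = ",")

#' Iterative fixed/random-effect GWAS (FarmCPU)
#'
#' Alternates two models until the pseudo-QTN set stabilizes. Iteration 1
#' scans every marker with the fixed-effect model (intercept + optional
#' population-structure covariates). Each later iteration turns the
#' previous scan's p-values into candidate pseudo-QTN sets (one top marker
#' per genomic bin, over a grid of bin sizes and set sizes), scores each
#' candidate configuration by the restricted log-likelihood of a
#' random-effects model whose kinship is built from that set's genotypes,
#' and rescans all markers with the winning set added to the fixed part as
#' covariates. The loop stops when the selected set equals the previous
#' one (as a set), when a two-cycle repeats, or at `max_iterations`.
#'
#' Markers serving as pseudo-QTN covariates are not tested against
#' themselves; in every iteration (including the final output) their
#' reported effect, standard error, t and p are substituted from their
#' covariate t-tests in that iteration's fixed design, so each scan table
#' has a usable row for every marker and current pseudo-QTNs remain
#' visible to the next round of selection.
#'
#' @param mat [marker_matrix()] with no missing genotypes (see
#'   [impute_missing()]).
#' @param info [marker_info()] aligned with the matrix columns.
#' @param y phenotype: numeric vector in matrix row order, or a
#'   [read_phenotype()] table (aligned strictly by sample ID).
#' @param covariates optional numeric matrix (n x q) or
#'   [read_covariates()] table.
#' @param config [run_config()].
#' @return object of class `farmcpu_result`: `results` (per-marker table:
#'   marker, chrom, pos, n_used, effect, se, t, p), `history` (one row per
#'   iteration), `converged`, `reason` (`"stable"`, `"cycle"` or
#'   `"max_iterations"`), `iterations`, `pseudo_qtns` (final set).
#' @export
run_farmcpu <- function(mat, info, y, covariates = NULL,
                        config = run_config()) {
  stopifnot(inherits(mat, "marker_matrix"), inherits(config, "run_config"))
  if (nrow(info) != mat$m) stop("marker info rows must equal marker count")
  if (!is.numeric(y) || !is.null(dim(y)) || inherits(y, "data.frame")) {
    al <- align_phenotype(mat, y, covariates)
    y <- al$y
    covariates <- al$covariates
  } else if (!is.null(covariates) && !is.matrix(covariates)) {
    covariates <- align_phenotype(mat, y, covariates)$covariates
  }
  mask <- which(!is.na(y))
  if (!length(mask)) stop("zero usable samples after phenotype masking")
  vy <- stats::var(y[mask])
  if (!is.finite(vy) || vy <= 0)
    stop("phenotype variance is non-finite or zero")

  bcfg <- bin_config(m = mat$m, bin_sizes = config$bin_sizes,
                     qtn_counts = config$qtn_counts,
                     eligibility_threshold = config$eligibility_threshold,
                     cor_filter = config$cor_filter)
  X_reml <- cbind(`(Intercept)` = rep(1, length(mask)),
                  if (!is.null(covariates)) covariates[mask, , drop = FALSE])

  # Markers serving as pseudo-QTN covariates are collinear with the fixed
  # part and scan as NA; their covariate t-tests from the fixed design are
  # substituted into the scan table every iteration, so they stay visible
  # to the next round of selection and to the final output.
  scan_with <- function(set_idx) {
    fixed <- build_fixed_design(y, covariates, set_idx, mat)
    scan <- scan_parallel(mat, fixed, config$n_workers_scan)
    if (length(fixed$pseudo_qtns)) {
      ct <- fixed$coef_table
      offset <- 1L + fixed$q  # rows before the pseudo-QTN columns
      for (s in seq_along(fixed$pseudo_qtns)) {
        ridx <- fixed$pseudo_qtns[s]
        scan$effect[ridx] <- ct$estimate[offset + s]
        scan$se[ridx] <- ct$se[offset + s]
        scan$t[ridx] <- ct$t[offset + s]
        scan$p[ridx] <- ct$p[offset + s]
        scan$n_used[ridx] <- fixed$n_eff
      }
    }
    list(fixed = fixed, scan = scan)
  }

  sets <- list(integer(0))
  it1 <- scan_with(integer(0))
  scans <- list(it1$scan)
  fixeds <- list(it1$fixed)
  hist_rows <- list(data.frame(iteration = 1L, n_pseudo_qtn = 0L,
                               bin_size = NA_real_, qtn_count = NA_integer_,
                               loglik = NA_real_, set = "",
                               stringsAsFactors = FALSE))
  converged <- FALSE
  reason <- "max_iterations"
  final_it <- 1L

  if (config$max_iterations >= 2L) {
    frozen_bins <- NULL
    for (it in 2:config$max_iterations) {
      cfg_it <- if (!config$reoptimize_bins && !is.null(frozen_bins)) {
        bin_config(bin_sizes = frozen_bins, qtn_counts = bcfg$qtn_counts,
                   eligibility_threshold = bcfg$eligibility_threshold,
                   cor_filter = bcfg$cor_filter)
      } else bcfg
      cand <- build_candidate_sets(mat, info, scans[[it - 1L]], cfg_it, mask)
      sel <- select_best_config(mat, cand, y, X_reml, mask,
                                config$n_workers_reml)
      if (is.null(sel)) {
        S <- integer(0)
        sel_bin <- NA_real_; sel_count <- NA_integer_; sel_ll <- NA_real_
      } else {
        S <- sel$set$indices
        sel_bin <- sel$set$bin_size
        sel_count <- sel$set$qtn_count
        sel_ll <- sel$fit$loglik
        if (!config$reoptimize_bins && is.null(frozen_bins))
          frozen_bins <- sel$set$bin_size
      }
      if (setequal(S, sets[[it - 1L]])) {
        converged <- TRUE
        reason <- "stable"
        final_it <- it - 1L
        break
      }
      res <- scan_with(S)
      scans[[it]] <- res$scan
      fixeds[[it]] <- res$fixed
      sets[[it]] <- S
      final_it <- it
      hist_rows[[it]] <- data.frame(iteration = it,
                                    n_pseudo_qtn = length(S),
                                    bin_size = sel_bin,
                                    qtn_count = sel_count,
                                    loglik = sel_ll, set = set_key(S),
                                    stringsAsFactors = FALSE)
      if (config$verbose)
        message(sprintf(
          "iteration %d: %d pseudo-QTNs (bin %s bp, count %s, logLik %s) set=[%s]",
          it, length(S), format(sel_bin), format(sel_count),
          format(sel_ll), set_key(S)))
      if (it >= 3L && setequal(S, sets[[it - 2L]])) {
        converged <- TRUE
        reason <- "cycle"
        break
      }
    }
    if (!converged && config$max_iterations >= 2L)
      warning("pseudo-QTN set did not converge within max_iterations; ",
              "returning the last iteration's results")
  } else {
    converged <- TRUE
    reason <- "stable"
  }

  final_scan <- scans[[final_it]]
  final_set <- sets[[final_it]]
  results <- data.frame(marker = mat$marker_names,
                        chrom = if ("chrom" %in% names(info)) info$chrom
                                else NA_character_,
                        pos = if ("pos" %in% names(info)) info$pos
                              else NA_real_,
                        n_used = final_scan$n_used,
                        effect = final_scan$effect, se = final_scan$se,
                        t = final_scan$t, p = final_scan$p,
                        stringsAsFactors = FALSE)
  structure(list(results = results,
                 history = do.call(rbind, hist_rows),
                 converged = converged, reason = reason,
                 iterations = final_it, pseudo_qtns = final_set),
            class = "farmcpu_result")
}

#' @export
print.farmcpu_result <- function(x, ...) {
  cat(sprintf("farmcpu_result: %d markers, %d iteration(s), converged=%s (%s)\n",
              nrow(x$results), x$iterations, x$converged, x$reason))
  cat(sprintf("  final pseudo-QTN set: %d marker(s)\n", length(x$pseudo_qtns)))
  top <- x$results[order(x$results$p), ]
  cat("  top associations:\n")
  print(utils::head(top[, c("marker", "chrom", "pos", "effect", "se", "t", "p")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Write GWAS results and iteration history as TSV
#'
#' `results.tsv` has the fixed column order marker, chrom, pos, n_used,
#' effect, se, t, p (markers in map order, `NA` for dropped markers);
#' `history.tsv` has one row per iteration.
#'
#' @param result [run_farmcpu()] output.
#' @param outdir output directory (created if absent).
#' @return named vector of file paths, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "farmcpu_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(outdir, "results.tsv"),
             history = file.path(outdir, "history.tsv"))
  utils::write.table(result$results, paths["results"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(result$history, paths["history"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(paths)
}

#' Read back a results TSV
#'
#' @param path file written by [write_results()].
#' @return data.frame with the result schema.
#' @export
read_results <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                    na.strings = "NA")
}
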