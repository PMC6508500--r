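#' Build the fixed part of the partitioned scan design
#'
#' The scan design matrix is split into a constant part — intercept,
#' population-structure covariates and the current pseudo-QTN genotype
#' columns — and a variable part holding one marker at a time. This
#' function assembles the constant part on the phenotype-complete rows,
#' factorizes it once (thin QR), and residualizes the phenotype against it,
#' so that every one of the `m` per-marker fits reuses the factorization.
#'
#' Rows with missing phenotype are represented by an index mask; the marker
#' matrix itself is never subsetted or copied. Coefficients, standard
#' errors, t- and p-values of the fixed columns themselves are computed
#' here once per iteration; the driver uses them to report statistics for
#' markers currently serving as pseudo-QTN covariates.
#'
#' @param y numeric phenotype vector aligned to the matrix rows (NA allowed).
#' @param covariates numeric matrix (n x q) or NULL.
#' @param pseudo_qtns integer vector of marker column indices (may be empty).
#' @param mat a [marker_matrix()] with no missing genotypes.
#' @return object of class `fixed_design`: `mask` (1-based complete rows),
#'   `n_eff`, `k` (fixed columns incl. intercept), `q`, `t` (pseudo-QTN
#'   count), `Q` (orthonormal basis), `y_res` (residualized phenotype),
#'   `coef_table` (per fixed column: estimate, se, t, p on
#'   `n_eff - k` df), `pseudo_qtns`.
#' @export
build_fixed_design <- function(y, covariates = NULL,
                               pseudo_qtns = integer(0), mat) {
  stopifnot(inherits(mat, "marker_matrix"))
  if (length(y) != mat$n) stop("phenotype length != number of individuals")
  if (anyNA(mat$values)) stop("genotypes contain missing values; run impute_missing() first")
  pseudo_qtns <- as.integer(pseudo_qtns)
  if (length(pseudo_qtns) &&
      (min(pseudo_qtns) < 1L || max(pseudo_qtns) > mat$m))
    stop("pseudo-QTN index out of range")
  mask <- which(!is.na(y))
  n_eff <- length(mask)
  if (n_eff == 0L) stop("no samples with non-missing phenotype")
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  t_n <- length(pseudo_qtns)
  X <- matrix(1, n_eff, 1L)
  nms <- "(Intercept)"
  if (q > 0L) {
    X <- cbind(X, covariates[mask, , drop = FALSE])
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- paste0("cov", seq_len(q))
    nms <- c(nms, cn)
  }
  if (t_n > 0L) {
    X <- cbind(X, mat$values[mask, pseudo_qtns, drop = FALSE])
    nms <- c(nms, mat$marker_names[pseudo_qtns])
  }
  colnames(X) <- nms
  k <- ncol(X)
  if (n_eff <= k) stop("not enough phenotype-complete samples for the fixed design")
  qr0 <- qr(X)
  if (qr0$rank < k) {
    offending <- nms[qr0$pivot[(qr0$rank + 1L):k]]
    stop("fixed design is rank deficient; offending column(s): ",
         paste(offending, collapse = ", "))
  }
  Q <- qr.Q(qr0)
  ym <- y[mask]
  y_res <- ym - Q %*% crossprod(Q, ym)
  y_res <- as.vector(y_res - Q %*% crossprod(Q, y_res))  # second pass
  coef <- qr.coef(qr0, ym)[qr0$pivot]
  names(coef) <- nms
  rss0 <- sum(y_res^2)
  df0 <- n_eff - k
  R <- qr.R(qr0)
  xtx_inv <- chol2inv(R)
  se <- sqrt(pmax(rss0 / df0 * diag(xtx_inv), 0))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df0, lower.tail = FALSE)
  structure(
    list(mask = mask, n_eff = n_eff, k = k, q = q, t = t_n,
         pseudo_qtns = pseudo_qtns, Q = Q, y_res = y_res,
         coef_table = data.frame(column = nms, estimate = coef, se = se,
                                 t = tval, p = pval, row.names = NULL,
                                 stringsAsFactors = FALSE)),
    class = "fixed_design")
}

#' Scan markers with single-marker OLS
#'
#' For each marker, fits the full fixed-effect model
#' `y ~ intercept + covariates + pseudo-QTNs + marker` on the
#' phenotype-complete rows and reports the marker coefficient, its standard
#' error, t-statistic and two-sided p-value on
#' `n_eff - (q + t + 2)` residual degrees of freedom. Internally the fit
#' reuses the cached factorization of the fixed part, so per-marker cost is
#' linear in `n_eff`; the results are numerically equal to a from-scratch
#' OLS refit. Markers that are constant on the masked rows, or collinear
#' with the fixed part (including the pseudo-QTNs themselves), get missing
#' results and the scan continues.
#'
#' @param mat a [marker_matrix()] with no missing genotypes.
#' @param fixed a [build_fixed_design()] object built on the same phenotype.
#' @param chunk integer vector of marker indices (default: all markers).
#' @return `scan_result` data.frame: marker, n_used, effect, se, t, p.
#' @export
scan_markers <- function(mat, fixed, chunk = NULL) {
  stopifnot(inherits(mat, "marker_matrix"), inherits(fixed, "fixed_design"))
  if (is.null(chunk)) chunk <- seq_len(mat$m)
  chunk <- as.integer(chunk)
  if (length(chunk) && (min(chunk) < 1L || max(chunk) > mat$m))
    stop("marker chunk index out of range")
  kern <- scan_chunk_cpp(mat$values, chunk, fixed$mask, fixed$Q,
                         fixed$y_res, 1e-12, 1e-10)
  df <- fixed$n_eff - fixed$k - 1L
  se <- sqrt(kern$rss / df / kern$sxx)
  tval <- kern$effect / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(marker = mat$marker_names[chunk],
                    n_used = ifelse(is.na(kern$effect), NA_integer_,
                                    fixed$n_eff),
                    effect = kern$effect, se = se, t = tval, p = pval,
                    stringsAsFactors = FALSE)
  attr(out, "df") <- df
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Deterministic parallel marker scan
#'
#' Splits the marker range into contiguous chunks and scans them on
#' `n_workers` forked workers. Each marker's fit is independent and its
#' arithmetic is identical regardless of chunking, so the assembled table
#' is bitwise-identical to a serial [scan_markers()] call for any
#' `n_workers` and any chunk size; marker order is preserved.
#'
#' @param mat,fixed as in [scan_markers()].
#' @param n_workers positive integer worker count.
#' @param chunk_size markers per chunk (default: balanced over workers).
#' @return `scan_result` data.frame as from [scan_markers()].
#' @export
scan_parallel <- function(mat, fixed, n_workers = 1L, chunk_size = NULL) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1")
  m <- mat$m
  if (is.null(chunk_size))
    chunk_size <- max(1L, ceiling(m / max(n_workers, 1L)))
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L) stop("chunk_size must be >= 1")
  starts <- seq.int(1L, m, by = chunk_size)
  chunks <- lapply(starts, function(s) seq.int(s, min(s + chunk_size - 1L, m)))
  worker <- function(idx) scan_markers(mat, fixed, chunk = idx)
  parts <- if (n_workers == 1L || length(chunks) == 1L ||
               .Platform$OS.type == "windows") {
    lapply(chunks, worker)
  } else {
    parallel::mclapply(chunks, worker, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  }
  err <- vapply(parts, function(p) inherits(p, "try-error") ||
                  !inherits(p, "data.frame"), logical(1))
  if (any(err)) stop("parallel scan worker failed")
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "df") <- attr(parts[[1]], "df")
  class(out) <- c("scan_result", "data.frame")
  out
}
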