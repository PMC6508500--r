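#' Kinship matrix restricted to pseudo-QTN markers
#'
#' VanRaden-style genomic relationship matrix built from the pseudo-QTN
#' genotype columns only (never from all markers): columns are centered by
#' twice their allele frequency on the masked samples and the Gram matrix
#' is scaled by `c = 2 * sum(p_j * (1 - p_j))`, so
#' `K = Z_c Z_c' / c`. Zero-variance pseudo-QTN columns are dropped with a
#' warning; if nothing remains the call errors (the caller then skips the
#' random-effects step).
#'
#' @param mat [marker_matrix()] with no missing genotypes.
#' @param set a `pseudo_qtn_set` or integer vector of marker indices.
#' @param mask integer row indices of phenotype-complete samples
#'   (default: all rows).
#' @return symmetric PSD matrix `n_eff x n_eff` of class `kinship`.
#' @export
pseudo_kinship <- function(mat, set, mask = NULL) {
  idx <- if (inherits(set, "pseudo_qtn_set")) set$indices else as.integer(set)
  if (!length(idx)) stop("empty pseudo-QTN set: no kinship can be built")
  if (is.null(mask)) mask <- seq_len(mat$n)
  Z <- mat$values[mask, idx, drop = FALSE]
  p <- colMeans(Z) / 2
  vr <- apply(Z, 2, stats::var)
  keep <- vr >= 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance pseudo-QTN column(s)",
                    sum(!keep)))
    Z <- Z[, keep, drop = FALSE]
    p <- p[keep]
  }
  if (!ncol(Z)) stop("all pseudo-QTN columns are constant on the masked samples")
  Zc <- sweep(Z, 2, 2 * p)
  cc <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Zc) / cc
  K <- (K + t(K)) / 2
  class(K) <- c("kinship", class(K))
  K
}

# Restricted log-likelihood profile in delta = sigma_e^2 / sigma_a^2 for
# y ~ N(Xb, sigma_a^2 (K + delta I)), after rotating onto an orthonormal
# basis A of the complement of span(X): with lambda = eigenvalues of A'KA
# and eta = U'A'y, the profiled restricted log-likelihood is
#   -1/2 [ q log(2 pi sigma_a^2) + sum log(lambda + delta) + q ],
# sigma_a^2 = sum(eta^2 / (lambda + delta)) / q,  q = n - ncol(X).
reml_profile <- function(lambda, eta2, delta) {
  qn <- length(lambda)
  s <- sum(eta2 / (lambda + delta))
  sigma_a2 <- s / qn
  ll <- -0.5 * (qn * log(2 * pi * sigma_a2) + sum(log(lambda + delta)) + qn)
  list(loglik = ll, sigma_a2 = sigma_a2)
}

golden_section <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {  # maximize
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' REML fit of the pseudo-QTN random-effects model
#'
#' Maximizes the restricted likelihood of `y ~ N(Xb, sigma_a^2 K +
#' sigma_e^2 I)` over the single ratio `delta = sigma_e^2 / sigma_a^2` by
#' spectral decomposition: the model is rotated onto an orthonormal basis
#' of the orthogonal complement of `span(X)`, where the covariance is
#' diagonal in the eigenbasis of the projected kinship, and the profiled
#' restricted log-likelihood is a smooth 1-D function of `delta`. The
#' optimum is located deterministically by a coarse log-spaced grid
#' followed by golden-section refinement within the bracketing interval,
#' with endpoint checks; a boundary optimum is returned with a warning.
#'
#' @param y numeric response (complete; already masked).
#' @param X fixed-effect design (intercept + population-structure
#'   covariates; full column rank). Pseudo-QTNs do not enter `X` here —
#'   they act only through `K`.
#' @param K kinship from [pseudo_kinship()], `length(y)` square.
#' @param delta_range search interval for `delta` (default `c(1e-5, 1e5)`).
#' @return object of class `reml_fit`: `sigma_a2`, `sigma_e2`, `delta`,
#'   `loglik` and bookkeeping fields (`n`, `k`).
#' @export
reml_fit <- function(y, X, K, delta_range = c(1e-5, 1e5)) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must be complete (mask before fitting)")
  X <- as.matrix(X)
  if (nrow(X) != n || nrow(K) != n || ncol(K) != n)
    stop("y, X and K dimensions disagree")
  qr0 <- qr(X)
  k <- ncol(X)
  if (qr0$rank < k) stop("X is rank deficient")
  if (max(abs(K - t(K))) > 1e-12 * max(1, max(abs(K))))
    stop("K is not symmetric")
  A <- qr.Q(qr0, complete = TRUE)[, (k + 1L):n, drop = FALSE]
  M <- crossprod(A, K %*% A)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  lambda <- eig$values
  if (min(lambda) < -1e-8 * max(1, max(abs(lambda))))
    stop("K is not positive semidefinite within tolerance")
  lambda <- pmax(lambda, 0)
  eta <- crossprod(eig$vectors, crossprod(A, y))
  eta2 <- as.vector(eta)^2
  if (sum(eta2) <= 0) stop("degenerate response: zero residual variation")
  f <- function(logd) reml_profile(lambda, eta2, exp(logd))$loglik
  lo <- log(delta_range[1]); hi <- log(delta_range[2])
  grid <- seq(lo, hi, length.out = 41L)
  gv <- vapply(grid, f, numeric(1))
  i0 <- which.max(gv)
  boundary <- FALSE
  if (i0 == 1L || i0 == length(grid)) {
    logd <- grid[i0]
    # refine toward the interior edge in case the optimum sits just inside
    nb <- if (i0 == 1L) c(grid[1], grid[2]) else c(grid[length(grid) - 1L],
                                                   grid[length(grid)])
    cand <- golden_section(f, nb[1], nb[2])
    if (f(cand) > f(logd)) logd <- cand else boundary <- TRUE
  } else {
    logd <- golden_section(f, grid[i0 - 1L], grid[i0 + 1L])
  }
  if (boundary)
    warning("REML delta optimum at search boundary; returning boundary fit")
  delta <- exp(logd)
  pr <- reml_profile(lambda, eta2, delta)
  structure(list(sigma_a2 = pr$sigma_a2, sigma_e2 = delta * pr$sigma_a2,
                 delta = delta, loglik = pr$loglik, n = n, k = k,
                 boundary = boundary),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: logLik %.4f, sigma_a2 %.4g, sigma_e2 %.4g (delta %.4g)\n",
              x$loglik, x$sigma_a2, x$sigma_e2, x$delta))
  invisible(x)
}

#' Score candidate pseudo-QTN sets and pick the best
#'
#' Fits the random-effects model of [reml_fit()] for every nonempty
#' candidate set — the kinship is rebuilt from each set's markers — and
#' returns the configuration with the largest restricted log-likelihood.
#' Ties (within 1e-10) break toward fewer pseudo-QTNs, then the smaller
#' bin size. Identical index sets arising from different (bin size, count)
#' pairs are fitted once and shared. Evaluations are independent; with
#' `n_workers > 1` they run on forked workers and, because each fit is
#' deterministic and results are reassembled in candidate order, the
#' outcome is identical to a serial run.
#'
#' @param mat [marker_matrix()].
#' @param sets list of `pseudo_qtn_set` from [build_candidate_sets()].
#' @param y phenotype vector aligned to matrix rows (NA allowed).
#' @param X fixed design on the masked rows (intercept + covariates).
#' @param mask integer indices of phenotype-complete rows.
#' @param n_workers worker count for concurrent REML fits.
#' @return `NULL` when every candidate set is empty; otherwise a list with
#'   `set` (winning `pseudo_qtn_set`), `fit` (`reml_fit`) and `table`
#'   (data.frame over all candidates: bin_size, qtn_count, size, sigma_a2,
#'   sigma_e2, loglik, selected).
#' @export
select_best_config <- function(mat, sets, y, X, mask, n_workers = 1L) {
  nonempty <- which(vapply(sets, function(s) length(s$indices) > 0L,
                           logical(1)))
  if (!length(nonempty)) return(NULL)
  ym <- y[mask]
  keys <- vapply(sets, function(s) paste(sort(s$indices), collapse = ","),
                 character(1))
  ukeys <- unique(keys[nonempty])
  fit_one <- function(key) {
    idx <- sets[[nonempty[match(key, keys[nonempty])]]]
    reml_fit(ym, X, pseudo_kinship(mat, idx, mask))
  }
  fits <- if (n_workers > 1L && length(ukeys) > 1L &&
              .Platform$OS.type != "windows") {
    parallel::mclapply(ukeys, fit_one, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(ukeys, fit_one)
  }
  names(fits) <- ukeys
  tab <- data.frame(
    config = seq_along(sets),
    bin_size = vapply(sets, `[[`, numeric(1), "bin_size"),
    qtn_count = vapply(sets, function(s) as.numeric(s$qtn_count), numeric(1)),
    size = vapply(sets, function(s) length(s$indices), integer(1)),
    sigma_a2 = NA_real_, sigma_e2 = NA_real_, loglik = NA_real_,
    selected = FALSE)
  for (i in nonempty) {
    ft <- fits[[keys[i]]]
    tab$sigma_a2[i] <- ft$sigma_a2
    tab$sigma_e2[i] <- ft$sigma_e2
    tab$loglik[i] <- ft$loglik
  }
  best_ll <- max(tab$loglik, na.rm = TRUE)
  cand <- which(!is.na(tab$loglik) & tab$loglik >= best_ll - 1e-10)
  cand <- cand[order(tab$size[cand], tab$bin_size[cand], cand)]
  win <- cand[1]
  tab$selected[win] <- TRUE
  list(set = sets[[win]], fit = fits[[keys[win]]], table = tab)
}

#' Write the model-selection table as TSV
#'
#' @param selection result of [select_best_config()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_model_selection <- function(selection, path) {
  utils::write.table(selection$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
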