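# Shared fixtures: everything is generated in code at test time.

# small random genotype matrix with integer scores
random_marker_matrix <- function(n, m, seed = 1L, freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.5)
  vals <- vapply(freq, function(p) rbinom(n, 2L, p), numeric(n))
  marker_matrix(matrix(as.double(vals), n, m))
}

evenly_spaced_info <- function(m, n_chrom = 2L, spacing = 100) {
  chrom <- sort(rep(seq_len(n_chrom), length.out = m))
  pos <- unlist(lapply(split(seq_len(m), chrom),
                       function(ix) spacing * seq_along(ix)), use.names = FALSE)
  marker_info(paste0("snp", seq_len(m)), as.character(chrom), pos)
}

write_genotype_tsv <- function(values, path, sample_ids = NULL,
                               marker_names = NULL, missing_code = "NA") {
  n <- nrow(values); m <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  if (is.null(marker_names)) marker_names <- paste0("snp", seq_len(m))
  body <- apply(values, c(1, 2), function(v) {
    if (is.na(v)) missing_code else format(v)
  })
  lines <- c(paste(c("taxa", marker_names), collapse = "\t"),
             vapply(seq_len(n), function(i)
               paste(c(sample_ids[i], body[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

# from-scratch OLS refit of [intercept | covariates | pseudo-QTNs | marker]
# on the masked samples: the independent oracle for the partitioned scan
ols_oracle <- function(mat, y, covariates = NULL, pseudo_qtns = integer(0),
                       marker) {
  mask <- which(!is.na(y))
  X <- cbind(1, if (!is.null(covariates)) covariates[mask, , drop = FALSE],
             if (length(pseudo_qtns)) mat$values[mask, pseudo_qtns, drop = FALSE],
             mat$values[mask, marker])
  fit <- stats::lm.fit(X, y[mask])
  k <- ncol(X)
  df <- length(mask) - k
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  est <- unname(fit$coefficients[k])
  se <- sqrt(rss / df * xtx_inv[k, k])
  tt <- est / se
  list(effect = est, se = se, t = tt,
       p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}

# brute-force restricted multivariate-normal REML: generic 2-parameter
# optimization of the Harville restricted log-likelihood, independent of
# the spectral path it checks
reml_brute <- function(y, X, K) {
  n <- length(y); k <- ncol(X)
  ldXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  nll <- function(par) {
    sa <- exp(par[1]); se <- exp(par[2])
    V <- sa * K + se * diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    XtViX <- crossprod(X, Vi %*% X)
    ldV <- 2 * sum(log(diag(cV)))
    ldXViX <- determinant(XtViX, logarithm = TRUE)$modulus
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    yPy <- drop(crossprod(y, P %*% y))
    0.5 * ((n - k) * log(2 * pi) + ldV + ldXViX - ldXtX + yPy)
  }
  starts <- list(c(0, 0), log(c(var(y), var(y))) / 1,
                 c(log(var(y) / 2), log(var(y) / 2)), c(-2, 0), c(0, -2))
  best <- Inf
  for (s in starts) {
    o <- stats::optim(s, nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
    o2 <- stats::optim(o$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 20000, reltol = 1e-15))
    if (o2$value < best) best <- o2$value
  }
  -best
}

# draw one random mixed-model instance; strong genetic signal keeps the
# variance optimum in the interior of the delta search domain
random_reml_instance <- function(n, k = 2L, n_mark = 15L, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (k - 1L)), n))
  Z <- matrix(rbinom(n * n_mark, 2L, runif(n_mark, 0.2, 0.5)), n)
  p <- colMeans(Z) / 2
  Zc <- sweep(Z, 2, 2 * p)
  K <- tcrossprod(Zc) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  sa <- runif(1, 2, 4); se <- runif(1, 0.5, 1)
  L <- chol(K + 1e-8 * diag(n))
  u <- sqrt(sa) * drop(crossprod(L, rnorm(n)))
  y <- drop(X %*% rnorm(k)) + u + rnorm(n, 0, sqrt(se))
  list(y = y, X = X, K = K)
}

fake_scan <- function(p) {
  out <- data.frame(marker = paste0("snp", seq_along(p)),
                    n_used = length(p), effect = 0, se = 1, t = 0, p = p)
  class(out) <- c("scan_result", "data.frame")
  out
}
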