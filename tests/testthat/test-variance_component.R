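test_that("kinship matches the hand-computed two-sample example", {
  mm <- marker_matrix(matrix(c(0, 2), 2, 1))
  K <- pseudo_kinship(mm, 1L)
  # p = 0.5: centered scores (-1, 1), c = 0.5 -> K = [[2,-2],[-2,2]]
  expect_equal(unclass(K), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
})

test_that("kinship drops constant columns and rejects degenerate sets", {
  mm <- random_marker_matrix(30, 4, seed = 3)
  mm$values[, 2] <- 2
  expect_warning(K <- pseudo_kinship(mm, c(1L, 2L, 3L)), "zero-variance")
  expect_equal(dim(K), c(30L, 30L))
  mm$values[, 3] <- 0
  expect_error(suppressWarnings(pseudo_kinship(mm, c(2L, 3L))), "constant")
  expect_error(pseudo_kinship(mm, integer(0)), "empty")
})

test_that("kinship is symmetric PSD and built from the masked samples", {
  mm <- random_marker_matrix(50, 8, seed = 13)
  mask <- c(2:20, 30:50)
  K <- pseudo_kinship(mm, c(1L, 4L, 7L), mask)
  expect_equal(dim(K), c(length(mask), length(mask)))
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("identity kinship collapses to the closed-form OLS REML value", {
  set.seed(23)
  n <- 40L
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  fit <- reml_fit(y, X, diag(n))
  qn <- n - 2L
  rss <- sum(lm.fit(X, y)$residuals^2)
  ll_closed <- -0.5 * qn * (log(2 * pi * rss / qn) + 1)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
  expect_equal(fit$sigma_a2 + fit$sigma_e2, rss / qn, tolerance = 1e-6)
})

test_that("spectral REML matches the brute-force MVN oracle", {
  for (seed in 1:10) {
    inst <- random_reml_instance(n = sample(25:30, 1), seed = 400 + seed)
    fit <- reml_fit(inst$y, inst$X, inst$K)
    ll_brute <- reml_brute(inst$y, inst$X, inst$K)
    expect_lt(abs(fit$loglik - ll_brute), 1e-6)
  }
})

test_that("REML recovers simulated variance components on average", {
  set.seed(33)
  n <- 500L
  mm <- random_marker_matrix(n, 30, seed = 33)
  K <- pseudo_kinship(mm, seq_len(30L))
  X <- matrix(1, n, 1)
  L <- chol(unclass(K) + 1e-8 * diag(n))
  ratios <- vapply(1:200, function(i) {
    u <- sqrt(2) * drop(crossprod(L, rnorm(n)))
    y <- 5 + u + rnorm(n, 0, 1)
    ft <- reml_fit(y, X, K)
    ft$sigma_a2 / ft$sigma_e2
  }, numeric(1))
  expect_gt(mean(ratios), 2 * 0.85)
  expect_lt(mean(ratios), 2 * 1.15)
})

test_that("loglik is invariant to a consistent relabeling of individuals", {
  inst <- random_reml_instance(25, seed = 77)
  fit <- reml_fit(inst$y, inst$X, inst$K)
  set.seed(78)
  perm <- sample(25)
  fit_p <- reml_fit(inst$y[perm], inst$X[perm, , drop = FALSE],
                    inst$K[perm, perm])
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("duplicated pseudo-QTN columns keep the delta optimum finite", {
  mm <- random_marker_matrix(40, 3, seed = 87)
  mm$values[, 3] <- mm$values[, 1]
  K <- pseudo_kinship(mm, c(1L, 2L, 3L))
  set.seed(88)
  y <- rnorm(40) + mm$values[, 1]
  fit <- suppressWarnings(reml_fit(y, matrix(1, 40, 1), K))
  expect_true(is.finite(fit$loglik))
  expect_true(fit$sigma_a2 >= 0 && fit$sigma_e2 > 0)
})

test_that("select_best_config picks max loglik with deterministic ties", {
  mm <- random_marker_matrix(80, 30, seed = 97)
  info <- evenly_spaced_info(30, n_chrom = 2L)
  set.seed(98)
  y <- rnorm(80) + rowSums(mm$values[, 1:3])
  scan <- scan_markers(mm, build_fixed_design(y, mat = mm))
  cfg <- bin_config(bin_sizes = c(200, 400), qtn_counts = c(2L, 5L),
                    eligibility_threshold = 0.5)
  sets <- build_candidate_sets(mm, info, scan, cfg)
  X <- matrix(1, 80, 1)
  sel <- select_best_config(mm, sets, y, X, seq_len(80))
  expect_equal(sum(sel$table$selected), 1L)
  expect_equal(max(sel$table$loglik, na.rm = TRUE), sel$fit$loglik)
  # identical index sets share one fit: equal logliks for equal sets
  keys <- vapply(sets, function(s) paste(sort(s$indices), collapse = ","),
                 character(1))
  lls <- sel$table$loglik
  for (k in unique(keys[nzchar(keys)])) {
    expect_length(unique(lls[keys == k & !is.na(lls)]), 1L)
  }
  # tie rule: among equal logliks the smaller set and bin size win
  win <- sel$table[sel$table$selected, ]
  equal <- sel$table[!is.na(lls) & lls >= sel$fit$loglik - 1e-10, ]
  expect_equal(win$size, min(equal$size))

  # serial vs parallel evaluation is identical
  sel4 <- select_best_config(mm, sets, y, X, seq_len(80), n_workers = 4L)
  expect_identical(sel4$table, sel$table)
  expect_identical(sel4$fit$loglik, sel$fit$loglik)

  # all-empty candidate list signals no pseudo-QTNs
  empty_sets <- build_candidate_sets(
    mm, info, fake_scan(rep(0.9, 30)),
    bin_config(bin_sizes = 200, qtn_counts = 2L,
               eligibility_threshold = 0.001))
  expect_null(select_best_config(mm, empty_sets, y, X, seq_len(80)))
})

test_that("model-selection table writes as TSV", {
  mm <- random_marker_matrix(40, 10, seed = 107)
  info <- evenly_spaced_info(10, n_chrom = 1L)
  set.seed(108)
  y <- rnorm(40) + mm$values[, 2]
  scan <- scan_markers(mm, build_fixed_design(y, mat = mm))
  sets <- build_candidate_sets(mm, info, scan,
                               bin_config(bin_sizes = 300, qtn_counts = 2L,
                                          eligibility_threshold = 0.9))
  sel <- select_best_config(mm, sets, y, matrix(1, 40, 1), seq_len(40))
  path <- tempfile(fileext = ".tsv")
  write_model_selection(sel, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(sel$table))
  expect_true("loglik" %in% names(back))
})
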