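test_that("worked example matches the closed-form simple regression", {
  mm <- marker_matrix(matrix(c(0, 1, 1, 2), 4, 1))
  y <- c(1, 2, 3, 4)
  fixed <- build_fixed_design(y, mat = mm)
  res <- scan_markers(mm, fixed)
  expect_equal(res$effect, 1.5, tolerance = 1e-12)
  expect_equal(res$se, sqrt(0.25 / 2), tolerance = 1e-12)
  expect_equal(res$t, 3 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-3 / sqrt(0.5), df = 2), tolerance = 1e-12)
  expect_equal(attr(res, "df"), 2)
})

test_that("fixed design basics: projector, masking counts, rank errors", {
  mm <- random_marker_matrix(100, 10, seed = 11)
  y <- rnorm(100)
  # q = 0, t = 0: projector is the mean operator
  fx <- build_fixed_design(y, mat = mm)
  expect_equal(drop(fx$Q %*% crossprod(fx$Q, y)), rep(mean(y), 100),
               tolerance = 1e-10)
  expect_equal(fx$y_res, y - mean(y), tolerance = 1e-10)

  y2 <- y; y2[c(3, 50, 97)] <- NA
  expect_equal(build_fixed_design(y2, mat = mm)$n_eff, 97L)

  # pseudo-QTN duplicating a covariate -> rank deficiency naming the column
  cov <- cbind(pc1 = mm$values[, 4])
  expect_error(build_fixed_design(y, cov, pseudo_qtns = 4L, mat = mm),
               "rank deficient.*snp4")
})

test_that("projector reproduces the fixed columns to 1e-10", {
  mm <- random_marker_matrix(80, 12, seed = 13)
  set.seed(13)
  cov <- matrix(rnorm(160), 80)
  y <- rnorm(80)
  fx <- build_fixed_design(y, cov, pseudo_qtns = c(2L, 9L), mat = mm)
  X <- cbind(1, cov, mm$values[fx$mask, c(2, 9)])
  expect_lt(max(abs(fx$Q %*% crossprod(fx$Q, X) - X)), 1e-10)
})

test_that("scan equals the full-design OLS oracle on random instances", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(15:40, 1)
    q <- sample(0:2, 1)
    t_n <- sample(0:3, 1)
    mm <- random_marker_matrix(n, 8, seed = 100 + rep)
    cov <- if (q > 0) matrix(rnorm(n * q), n) else NULL
    pq <- if (t_n > 0) sample(seq_len(8), t_n) else integer(0)
    y <- rnorm(n) + 0.3 * mm$values[, 1]
    y[sample(n, 2)] <- NA
    fx <- build_fixed_design(y, cov, pq, mm)
    res <- scan_markers(mm, fx)
    for (j in setdiff(seq_len(8), pq)) {
      if (is.na(res$effect[j])) next
      oracle <- ols_oracle(mm, y, cov, pq, j)
      expect_equal(res$effect[j], oracle$effect, tolerance = 1e-8)
      expect_equal(res$se[j], oracle$se, tolerance = 1e-8)
      expect_equal(res$t[j], oracle$t, tolerance = 1e-8)
      expect_equal(res$p[j], oracle$p, tolerance = 1e-8)
    }
  }
})

test_that("constant and collinear markers give missing results, scan continues", {
  mm <- random_marker_matrix(50, 4, seed = 31)
  mm$values[, 2] <- 1  # constant
  y <- rnorm(50)
  cov <- cbind(mm$values[, 3])  # marker 3 is in the fixed part
  fx <- build_fixed_design(y, cov, mat = mm)
  res <- scan_markers(mm, fx)
  expect_true(is.na(res$p[2]))
  expect_true(is.na(res$p[3]))
  expect_false(anyNA(res$p[c(1, 4)]))
  expect_true(all(is.na(res$n_used[2:3])))
})

test_that("p-values lie in (0,1] and t^2 equals the 1-df F statistic", {
  mm <- random_marker_matrix(60, 30, seed = 41)
  y <- rnorm(60)
  fx <- build_fixed_design(y, mat = mm)
  res <- scan_markers(mm, fx)
  ok <- !is.na(res$p)
  expect_true(all(res$p[ok] > 0 & res$p[ok] <= 1))
  # F for adding the marker to the intercept-only model
  j <- which(ok)[1]
  full <- lm(y ~ mm$values[, j])
  f <- anova(full)[1, "F value"]
  expect_equal(res$t[j]^2, f, tolerance = 1e-8)
})

test_that("masking equivalence: index mask equals an explicit row subset", {
  mm <- random_marker_matrix(70, 25, seed = 51)
  y <- rnorm(70)
  y[c(5, 6, 40)] <- NA
  fx <- build_fixed_design(y, mat = mm)
  res_masked <- scan_markers(mm, fx)

  keep <- !is.na(y)
  mm_sub <- marker_matrix(mm$values[keep, , drop = FALSE],
                          mm$sample_ids[keep], mm$marker_names)
  fx_sub <- build_fixed_design(y[keep], mat = mm_sub)
  res_sub <- scan_markers(mm_sub, fx_sub)
  expect_equal(res_masked$effect, res_sub$effect, tolerance = 1e-12)
  expect_equal(res_masked$p, res_sub$p, tolerance = 1e-12)
})

test_that("adding one pseudo-QTN reduces residual df by exactly one", {
  mm <- random_marker_matrix(40, 10, seed = 61)
  y <- rnorm(40)
  r0 <- scan_markers(mm, build_fixed_design(y, mat = mm))
  r1 <- scan_markers(mm, build_fixed_design(y, pseudo_qtns = 3L, mat = mm))
  expect_equal(attr(r0, "df") - attr(r1, "df"), 1L)
})

test_that("parallel scan is bitwise-identical to serial for any chunking", {
  mm <- random_marker_matrix(60, 500, seed = 71)
  y <- rnorm(60)
  fx <- build_fixed_design(y, mat = mm)
  serial <- scan_markers(mm, fx)
  for (cs in c(1L, 97L, 500L)) {
    par4 <- scan_parallel(mm, fx, n_workers = 4L, chunk_size = cs)
    expect_identical(par4$effect, serial$effect)
    expect_identical(par4$p, serial$p)
    expect_identical(par4$marker, serial$marker)
  }
  expect_identical(scan_parallel(mm, fx, n_workers = 1L)$p, serial$p)
  expect_error(scan_parallel(mm, fx, n_workers = 0L), "n_workers")
})

test_that("single-marker matrix scans under many workers", {
  mm <- random_marker_matrix(30, 1, seed = 81)
  fx <- build_fixed_design(rnorm(30), mat = mm)
  res <- scan_parallel(mm, fx, n_workers = 8L)
  expect_equal(nrow(res), 1L)
})

test_that("scan allocates no second full-size copy of the marker matrix", {
  n <- 200L; m <- 400L
  mm <- random_marker_matrix(n, m, seed = 91)
  y <- rnorm(n)
  fx <- build_fixed_design(y, mat = mm)
  log <- tempfile()
  Rprofmem(log, threshold = n * m * 8)
  res <- scan_markers(mm, fx)
  Rprofmem(NULL)
  big <- grep("^[0-9]", readLines(log), value = TRUE)
  expect_length(big, 0)
  expect_equal(nrow(res), m)
})
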