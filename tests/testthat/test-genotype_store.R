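test_that("text genotypes read back with missing cells flagged", {
  vals <- matrix(c(0, 1, 2, 2, NA, 0), nrow = 3)
  path <- write_genotype_tsv(vals, tempfile(fileext = ".tsv"))
  got <- suppressMessages(read_genotypes(path))
  expect_s3_class(got$matrix, "marker_matrix")
  expect_identical(dim(got$matrix), c(3L, 2L))
  expect_true(is.double(got$matrix$values))
  expect_equal(got$matrix$values, vals, ignore_attr = TRUE)
  expect_true(is.na(got$matrix$values[2, 2]))
  expect_message(read_genotypes(path), "1 missing")
})

test_that("degenerate and invalid genotype tables are rejected", {
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(suppressMessages(read_genotypes(empty)), "no markers parsed")

  out_of_range <- write_genotype_tsv(matrix(c(0, 3, 1, 2), 2),
                                     tempfile(fileext = ".tsv"))
  expect_error(suppressMessages(read_genotypes(out_of_range)),
               "out of range")

  bad_cell <- tempfile(fileext = ".tsv")
  writeLines(c("taxa\tsnp1", "ind1\t0", "ind2\tX"), bad_cell)
  expect_error(suppressMessages(read_genotypes(bad_cell, missing_code = "NA")),
               "non-numeric")
})

test_that("orientation transposes correctly", {
  vals <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 2)  # 2 markers x 3 samples
  path <- tempfile(fileext = ".tsv")
  lines <- c("marker\tind1\tind2\tind3",
             paste("snpA", 0, 2, 1, sep = "\t"),
             paste("snpB", 1, 2, 0, sep = "\t"))
  writeLines(lines, path)
  got <- suppressMessages(read_genotypes(path, orientation = "markers-in-rows"))
  expect_identical(dim(got$matrix), c(3L, 2L))
  expect_equal(got$matrix$marker_names, c("snpA", "snpB"))
  expect_equal(got$matrix$values[, 1], c(0, 2, 1))
})

test_that("imputation replaces missing cells by the marker mean only", {
  vals <- matrix(c(0, 0, 1, NA,   2, 1, 0, 2), ncol = 2)
  mm <- marker_matrix(vals)
  imp <- impute_missing(mm)
  expect_equal(imp$values[4, 1], 1 / 3)
  expect_equal(imp$values[1:3, 1], c(0, 0, 1))
  expect_identical(imp$values[, 2], vals[, 2])  # untouched column
  expect_false(anyNA(imp$values))
  # nonmissing mean is preserved exactly
  expect_equal(mean(imp$values[, 1]), mean(vals[1:3, 1]) * 0 + 1 / 3,
               tolerance = 1e-15)
})

test_that("imputation degenerate cases error; minor-allele interval holds", {
  expect_error(impute_missing(marker_matrix(matrix(NA_real_, 2, 1))),
               "all scores missing")
  # minor-allele coding: imputed values in (0, 1] (frequencies kept away
  # from 0.5 so the sample frequency stays minor)
  set.seed(7)
  mm <- random_marker_matrix(200, 20, seed = 7, freq = runif(20, 0.05, 0.4))
  mm <- inject_missing(mm, 0.05, seed = 8)
  miss <- which(is.na(mm$values))
  imp <- impute_missing(mm)
  expect_true(all(imp$values[miss] > 0 & imp$values[miss] <= 1))
})

test_that("backing store round-trips bitwise and rejects bad descriptors", {
  mm <- random_marker_matrix(100, 1000, seed = 3)
  prefix <- tempfile()
  mm <- write_backing(mm, prefix)
  back <- attach_genotypes(prefix)
  expect_identical(back$values, mm$values)  # bitwise
  expect_identical(back$sample_ids, mm$sample_ids)

  # descriptor edited to a byte type -> typed rejection
  dpath <- paste0(prefix, ".desc.json")
  desc <- jsonlite::read_json(dpath, simplifyVector = TRUE)
  desc$dtype <- "char"
  jsonlite::write_json(desc, dpath, auto_unbox = TRUE)
  expect_error(attach_genotypes(prefix), "only a double-type")

  desc$dtype <- "double"
  desc$n <- desc$n + 1L
  jsonlite::write_json(desc, dpath, auto_unbox = TRUE)
  expect_error(attach_genotypes(prefix), "corrupt")

  expect_error(attach_genotypes(tempfile()), "not found")
})

test_that("text -> store -> attach round-trip preserves values", {
  vals <- matrix(c(0, 1, 2, 1.5, 0.25, 2), nrow = 3)
  path <- write_genotype_tsv(vals, tempfile(fileext = ".tsv"))
  got <- suppressMessages(read_genotypes(path))
  prefix <- tempfile()
  write_backing(got$matrix, prefix)
  expect_equal(attach_genotypes(prefix)$values, vals, ignore_attr = TRUE)
})

test_that("imputation rewrites an existing backing store", {
  vals <- matrix(c(0, NA, 2, 1, 1, 1), ncol = 2)
  mm <- marker_matrix(vals)
  prefix <- tempfile()
  mm <- write_backing(mm, prefix)
  imp <- impute_missing(mm)
  expect_identical(attach_genotypes(prefix)$values, imp$values)
})

test_that("phenotype alignment is strict on sample IDs", {
  mm <- random_marker_matrix(4, 3, seed = 5)
  ph <- data.frame(sample_id = c("ind2", "ind1", "ind3", "ind4"),
                   y = c(2, 1, 3, NA))
  al <- align_phenotype(mm, ph)
  expect_equal(al$y, c(1, 2, 3, NA))  # reordered to matrix rows

  expect_error(align_phenotype(mm, ph[1:3, ]), "mismatch")
  ph_extra <- rbind(ph, data.frame(sample_id = "ind99", y = 0))
  expect_error(align_phenotype(mm, ph_extra), "mismatch")

  cov <- data.frame(sample_id = c("ind4", "ind3", "ind2", "ind1"),
                    pc1 = 1:4)
  al2 <- align_phenotype(mm, ph, cov)
  expect_equal(al2$covariates[, 1], c(4, 3, 2, 1))
})
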