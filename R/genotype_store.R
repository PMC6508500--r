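#' @useDynLib farmcpu, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var
NULL

#' File-backed genotype matrix
#'
#' A `marker_matrix` holds an `n` (individuals) by `m` (markers)
#' double-precision genotype matrix, optionally backed by a two-file binary
#' store on disk (a raw little-endian column-major array plus a JSON sidecar
#' descriptor). Genotype scores count copies of the coded allele, so raw
#' scores are in `{0, 1, 2}`; after mean imputation scores are real numbers
#' in `[0, 2]`. Only double precision is accepted: integer or byte typed
#' stores silently truncate imputed scores, which inflates the apparent
#' count of homozygous individuals.
#'
#' @param values numeric matrix, individuals in rows, markers in columns.
#' @param sample_ids character vector of row identifiers.
#' @param marker_names character vector of column identifiers.
#' @param path optional backing-store prefix (see [write_backing()]).
#' @return An object of class `marker_matrix` with fields `values`, `n`,
#'   `m`, `sample_ids`, `marker_names`, `dtype` (always `"double"`) and
#'   `path` (`NA` until a backing store is written).
#' @export
marker_matrix <- function(values, sample_ids = NULL, marker_names = NULL,
                          path = NA_character_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.double(values)) storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  if (is.null(marker_names)) marker_names <- paste0("snp", seq_len(m))
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(values)")
  if (length(marker_names) != m) stop("marker_names length must equal ncol(values)")
  finite <- values[!is.na(values)]
  if (length(finite) && (min(finite) < 0 || max(finite) > 2))
    stop("genotype scores must lie in [0, 2]")
  structure(
    list(values = values, n = n, m = m,
         sample_ids = as.character(sample_ids),
         marker_names = as.character(marker_names),
         dtype = "double", path = path),
    class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers (%s)\n",
              x$n, x$m, x$dtype))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  %d missing genotype cells (pre-imputation)\n", nmiss))
  if (!is.na(x$path)) cat("  backing store:", x$path, "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) c(x$n, x$m)

#' Marker map
#'
#' Validated map of marker name, chromosome label and 1-based base-pair
#' position, aligned column-for-column with a [marker_matrix()].
#'
#' @param name,chrom,pos vectors of equal length.
#' @return data.frame of class `marker_info`.
#' @export
marker_info <- function(name, chrom, pos) {
  pos <- as.numeric(pos)
  if (length(name) != length(chrom) || length(name) != length(pos))
    stop("name, chrom, pos must have equal length")
  if (any(!is.finite(pos)) || any(pos < 1) || any(pos != floor(pos)))
    stop("positions must be positive integers (1-based)")
  out <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    pos = pos, stringsAsFactors = FALSE)
  class(out) <- c("marker_info", "data.frame")
  out
}

#' Read a marker map from TSV
#'
#' Expects a header and three columns: marker name, chromosome, position.
#'
#' @param path TSV file path.
#' @return [marker_info()] data.frame.
#' @export
read_marker_map <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3) stop("marker map needs columns: name, chrom, pos")
  marker_info(dt[[1]], dt[[2]], dt[[3]])
}

#' Read genotypes from a delimited text table
#'
#' Parses a TSV/CSV genotype table (delimiter auto-detected from content by
#' `data.table::fread`) into a [marker_matrix()]. With
#' `orientation = "markers-in-columns"` the first column holds sample IDs
#' and the header holds marker names; with `"markers-in-rows"` the first
#' column holds marker names and the header holds sample IDs. Cells must be
#' numbers in `[0, 2]` or the missing code. Missing cells are kept as `NA`
#' and must be resolved by [impute_missing()] before scanning.
#'
#' @param path delimited text file.
#' @param orientation `"markers-in-columns"` (default) or `"markers-in-rows"`.
#' @param missing_code string encoding missing genotypes (default `"NA"`).
#' @param map optional path to a marker map TSV; markers are matched by name.
#' @param verbose log the count of missing cells (default TRUE).
#' @return list with elements `matrix` ([marker_matrix()]) and `info`
#'   ([marker_info()], or a name-only data.frame when `map` is absent).
#' @export
read_genotypes <- function(path, orientation = c("markers-in-columns",
                                                 "markers-in-rows"),
                           missing_code = "NA", map = NULL, verbose = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (file.size(path) == 0) stop("no markers parsed from ", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = missing_code,
                          data.table = FALSE, colClasses = NULL)
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("no markers parsed from ", path)
  ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      stop(sprintf(
        "non-numeric genotype cell at row %d, column '%s' (value '%s')",
        if (length(bad)) bad[1] else 1L, names(body)[j],
        if (length(bad)) col[bad[1]] else col[1]))
    }
  }
  vals <- as.matrix(body)
  storage.mode(vals) <- "double"
  bad <- which(!is.na(vals) & (vals < 0 | vals > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "genotype score out of range [0,2] at row %d, column '%s' (value %g)",
      bad[1, 1], colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]))
  }
  if (orientation == "markers-in-rows") {
    marker_names <- ids
    sample_ids <- colnames(vals)
    vals <- t(vals)
    dimnames(vals) <- NULL
  } else {
    sample_ids <- ids
    marker_names <- colnames(vals)
    dimnames(vals) <- NULL
  }
  mm <- marker_matrix(vals, sample_ids, marker_names)
  nmiss <- sum(is.na(vals))
  if (verbose)
    message(sprintf("read %d x %d genotypes (%d missing cells)",
                    mm$n, mm$m, nmiss))
  info <- if (!is.null(map)) {
    mi <- read_marker_map(map)
    idx <- match(marker_names, mi$name)
    if (anyNA(idx)) stop("markers absent from map: ",
                         paste(utils::head(marker_names[is.na(idx)], 5),
                               collapse = ", "))
    mi[idx, , drop = FALSE]
  } else {
    data.frame(name = marker_names, stringsAsFactors = FALSE)
  }
  list(matrix = mm, info = info)
}

#' Impute missing genotypes by the marker mean
#'
#' Each missing cell is replaced by the marker's mean over its non-missing
#' scores (equivalently twice the coded-allele frequency). Non-missing cells
#' are untouched. When the coded allele is the minor allele (frequency in
#' (0, 0.5]) every imputed value falls in the interval (0, 1]. If the
#' matrix has a backing store the store is rewritten so reattachment sees
#' the imputed values.
#'
#' @param mat a [marker_matrix()].
#' @return the imputed `marker_matrix` (no missing values remain).
#' @export
impute_missing <- function(mat) {
  stopifnot(inherits(mat, "marker_matrix"))
  v <- mat$values
  miss <- is.na(v)
  if (!any(miss)) return(mat)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("markers with all scores missing: ",
         paste(mat$marker_names[all_missing], collapse = ", "))
  cols <- which(colSums(miss) > 0L)
  for (j in cols) {
    mj <- miss[, j]
    v[mj, j] <- mean(v[!mj, j])
  }
  mat$values <- v
  if (!is.na(mat$path)) write_backing(mat, mat$path)
  mat
}

descriptor_path <- function(prefix) paste0(prefix, ".desc.json")
binary_path <- function(prefix) paste0(prefix, ".bin")

#' Write the binary backing store
#'
#' Serializes the genotype matrix as raw little-endian column-major doubles
#' (`<prefix>.bin`) plus a JSON sidecar descriptor (`<prefix>.desc.json`)
#' recording `n`, `m`, dtype, endianness, layout, sample IDs and marker
#' names. [attach_genotypes()] reopens the pair bitwise-identically without
#' re-parsing text.
#'
#' @param mat a [marker_matrix()].
#' @param prefix path prefix for the two files.
#' @return the `marker_matrix` with its `path` set, invisibly.
#' @export
write_backing <- function(mat, prefix) {
  stopifnot(inherits(mat, "marker_matrix"))
  desc <- list(format = "farmcpu-marker-store", version = 1L,
               n = mat$n, m = mat$m, dtype = "double",
               endian = "little", layout = "column-major",
               sample_ids = mat$sample_ids, marker_names = mat$marker_names)
  jsonlite::write_json(desc, descriptor_path(prefix), auto_unbox = TRUE)
  con <- file(binary_path(prefix), "wb")
  on.exit(close(con))
  writeBin(as.vector(mat$values), con, size = 8L, endian = "little")
  mat$path <- prefix
  invisible(mat)
}

#' Reattach a genotype matrix from its backing store
#'
#' Reads the descriptor, validates it, and maps the binary file back into a
#' [marker_matrix()]. Values are bitwise-identical to those at write time.
#' Exactly one in-memory array of size `n x m` results; no intermediate
#' full-size copy is made. Stores whose descriptor declares any dtype other
#' than double precision are rejected with an error.
#'
#' @param prefix backing-store path prefix as given to [write_backing()].
#' @return a [marker_matrix()].
#' @export
attach_genotypes <- function(prefix) {
  dpath <- descriptor_path(prefix)
  bpath <- binary_path(prefix)
  if (!file.exists(dpath)) stop("descriptor not found: ", dpath)
  if (!file.exists(bpath)) stop("binary backing file not found: ", bpath)
  desc <- jsonlite::read_json(dpath, simplifyVector = TRUE)
  if (!identical(desc$dtype, "double"))
    stop("backing store dtype is '", desc$dtype,
         "': only a double-type store is accepted")
  n <- as.integer(desc$n)
  m <- as.integer(desc$m)
  expected <- as.numeric(n) * m * 8
  actual <- file.size(bpath)
  if (!isTRUE(actual == expected))
    stop(sprintf("backing store corrupt: expected %.0f bytes for %d x %d doubles, found %.0f",
                 expected, n, m, actual))
  con <- file(bpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n * m, size = 8L,
                  endian = "little")
  dim(vals) <- c(n, m)
  marker_matrix(vals, desc$sample_ids, desc$marker_names, path = prefix)
}

#' Read a phenotype table
#'
#' TSV with header; first column sample ID, second column the trait value.
#' Missing trait values are allowed and define the regression sample.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample_id` and `y`, class `phenotype`.
#' @export
read_phenotype <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 2) stop("phenotype table needs sample ID and trait columns")
  out <- data.frame(sample_id = as.character(dt[[1]]),
                    y = as.numeric(dt[[2]]), stringsAsFactors = FALSE)
  class(out) <- c("phenotype", "data.frame")
  out
}

#' Read a covariate table
#'
#' TSV with header; first column sample ID, remaining columns numeric
#' covariates (for example principal components). Missing values are not
#' allowed in covariates.
#'
#' @param path TSV file path.
#' @return data.frame: `sample_id` plus numeric covariate columns.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("covariate table needs sample ID plus >=1 column")
  cv <- dt[, -1, drop = FALSE]
  if (any(!vapply(cv, is.numeric, logical(1))))
    stop("covariate columns must be numeric")
  if (anyNA(cv)) stop("missing values are not allowed in covariates")
  data.frame(sample_id = as.character(dt[[1]]), cv, stringsAsFactors = FALSE)
}

#' Align a phenotype (and covariates) to the marker matrix rows
#'
#' Matching is strict and by identifier: every matrix sample must appear in
#' the phenotype table and vice versa, otherwise an error names the
#' offending IDs. No silent intersection is taken — silent subsetting is
#' exactly what forces hidden copies of the marker matrix downstream.
#'
#' @param mat a [marker_matrix()].
#' @param phenotype data.frame from [read_phenotype()], or a numeric vector
#'   already in matrix row order.
#' @param covariates optional data.frame from [read_covariates()].
#' @return list with `y` (numeric, matrix row order, may contain NA) and
#'   `covariates` (numeric matrix or NULL).
#' @export
align_phenotype <- function(mat, phenotype, covariates = NULL) {
  stopifnot(inherits(mat, "marker_matrix"))
  if (is.numeric(phenotype) && is.null(dim(phenotype))) {
    if (length(phenotype) != mat$n)
      stop("phenotype vector length != number of individuals")
    y <- as.numeric(phenotype)
  } else {
    ids <- as.character(phenotype[[1]])
    if (anyDuplicated(ids)) stop("duplicated sample IDs in phenotype")
    missing_ph <- setdiff(mat$sample_ids, ids)
    extra_ph <- setdiff(ids, mat$sample_ids)
    if (length(missing_ph) || length(extra_ph))
      stop("sample ID mismatch between genotypes and phenotype; ",
           "absent from phenotype: ",
           paste(utils::head(missing_ph, 5), collapse = ", "),
           "; absent from genotypes: ",
           paste(utils::head(extra_ph, 5), collapse = ", "))
    y <- as.numeric(phenotype[[2]])[match(mat$sample_ids, ids)]
  }
  cv <- NULL
  if (!is.null(covariates)) {
    cids <- as.character(covariates[[1]])
    idx <- match(mat$sample_ids, cids)
    if (anyNA(idx))
      stop("covariate table is missing samples: ",
           paste(utils::head(mat$sample_ids[is.na(idx)], 5), collapse = ", "))
    cv <- as.matrix(covariates[idx, -1, drop = FALSE])
    storage.mode(cv) <- "double"
    rownames(cv) <- NULL
    if (anyNA(cv)) stop("missing values are not allowed in covariates")
  }
  list(y = y, covariates = cv)
}
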