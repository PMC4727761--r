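#' Construct a single spectrum
#'
#' A `spectrum` holds one sample's absorbance trace on a wavenumber axis.
#' The axis is canonicalized to strictly ascending order internally (the
#' conventional descending IR display order is applied only when printing),
#' so that derivative signs are unambiguous.
#'
#' @param sample_id Sample identifier (length-1 character).
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone (either direction; stored ascending).
#' @param absorbance Numeric vector of absorbance values (dimensionless),
#'   same length as `wavenumbers`.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `spectrum` with ascending `wavenumbers`.
#' @examples
#' s <- spectrum("s1", c(650, 652, 654), c(0.1, 0.2, 0.15))
#' s$wavenumbers
#' @export
spectrum <- function(sample_id, wavenumbers, absorbance, meta = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    stop("all wavenumber and absorbance values must be finite", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {            # descending input: reverse both axes together
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    if (anyDuplicated(wavenumbers)) {
      stop("duplicate wavenumbers in spectrum '", sample_id, "'", call. = FALSE)
    }
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, wavenumbers = wavenumbers,
         absorbance = absorbance, meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.1f-%.1f cm-1\n", x$sample_id,
              length(x$wavenumbers), max(x$wavenumbers), min(x$wavenumbers)))
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns `wavenumber_cm1,absorbance` (header optional). Descending
#' wavenumber order is accepted and canonicalized by reversing the rows.
#'
#' @param path Path to the CSV file.
#' @param sample_id Sample id; defaults to the file name without extension.
#' @param sep Field separator.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, sample_id = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  # tolerate a single header line of non-numeric fields
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  if (suppressWarnings(anyNA(as.numeric(first[1:2])))) lines <- lines[-1L]
  n <- length(lines)
  wn <- numeric(n); ab <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], sep, fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || anyNA(v)) {
      stop("non-numeric row at line ", i, " of ", path, call. = FALSE)
    }
    wn[i] <- v[1L]; ab[i] <- v[2L]
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  spectrum(sample_id, wn, ab)
}

#' Write a spectrum to CSV
#'
#' Written in descending wavenumber order (IR display convention); the reader
#' canonicalizes back to ascending, so a write/read round trip is lossless.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  ord <- order(spec$wavenumbers, decreasing = TRUE)
  df <- data.frame(wavenumber_cm1 = spec$wavenumbers[ord],
                   absorbance = spec$absorbance[ord])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a set of grid-aligned spectra
#'
#' The calibration matrix X of multivariate analysis: samples in rows,
#' wavenumber grid points in columns.
#'
#' @param grid Strictly ascending common wavenumber vector, cm^-1.
#' @param matrix Numeric matrix, `length(sample_ids)` x `length(grid)`.
#' @param sample_ids Unique sample identifiers, one per row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, matrix, sample_ids) {
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  sample_ids <- as.character(sample_ids)
  if (any(diff(grid) <= 0)) stop("grid must be strictly ascending", call. = FALSE)
  if (ncol(matrix) != length(grid)) {
    stop("matrix has ", ncol(matrix), " columns but grid has ",
         length(grid), " points", call. = FALSE)
  }
  if (nrow(matrix) != length(sample_ids)) {
    stop("row count does not match number of sample ids", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  if (!all(is.finite(matrix))) stop("non-finite absorbance values", call. = FALSE)
  rownames(matrix) <- sample_ids
  structure(list(grid = grid, matrix = matrix, sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d grid points (%.1f-%.1f cm-1)\n",
              nrow(x$matrix), length(x$grid), max(x$grid), min(x$grid)))
  invisible(x)
}

#' Align spectra onto a common wavenumber grid
#'
#' Linear interpolation only; each spectrum must cover the full target grid
#' (no extrapolation). Smoothing belongs to the preprocessing stage.
#'
#' @param spectra A list of [spectrum()] objects.
#' @param target_grid Strictly ascending wavenumber vector, cm^-1.
#' @return A [spectra_set()] on `target_grid`.
#' @export
align_to_grid <- function(spectra, target_grid) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  target_grid <- as.numeric(target_grid)
  if (any(diff(target_grid) <= 0)) {
    stop("target grid must be strictly ascending", call. = FALSE)
  }
  rows <- lapply(spectra, function(s) {
    stopifnot(inherits(s, "spectrum"))
    if (min(target_grid) < min(s$wavenumbers) ||
        max(target_grid) > max(s$wavenumbers)) {
      stop("target grid extends beyond the support of sample '",
           s$sample_id, "'", call. = FALSE)
    }
    stats::approx(s$wavenumbers, s$absorbance, xout = target_grid,
                  method = "linear", ties = "ordered")$y
  })
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  spectra_set(target_grid, do.call(rbind, rows), ids)
}

#' Read a per-sample reference concentration table
#'
#' Columns `sample_id,daidzin,genistin,glycitin[,total]`, concentrations in
#' mg per 500 ul aliquot (the study's reporting unit, nominally from HPLC).
#' A missing `total` column is computed as the sum of the three analytes.
#'
#' @param path CSV path.
#' @param source Provenance label, `"HPLC"` or `"SIMULATED"`. For simulated
#'   references an explicit `total` column must equal the analyte sum.
#' @return A `reference_table`: data frame with attribute `source`.
#' @export
read_reference_table <- function(path, source = c("HPLC", "SIMULATED")) {
  source <- match.arg(source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_table(df, source = source)
}

#' Construct / validate a reference table
#'
#' @param df Data frame with `sample_id` and at least one analyte column
#'   among `daidzin`, `genistin`, `glycitin` (all three required if `total`
#'   is to be derived).
#' @param source Provenance label.
#' @return Validated `reference_table`.
#' @export
reference_table <- function(df, source = c("HPLC", "SIMULATED")) {
  source <- match.arg(source)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column", call. = FALSE)
  analytes <- intersect(c("daidzin", "genistin", "glycitin"), names(df))
  if (length(analytes) == 0L) stop("no analyte columns found", call. = FALSE)
  num_cols <- c(analytes, intersect("total", names(df)))
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", cn, "' must be numeric with no missing values",
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative concentration in column '", cn, "'", call. = FALSE)
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in reference table", call. = FALSE)
  }
  if (!"total" %in% names(df)) {
    if (length(analytes) == 3L) {
      df$total <- df$daidzin + df$genistin + df$glycitin
    }
  } else if (source == "SIMULATED" && length(analytes) == 3L) {
    s <- df$daidzin + df$genistin + df$glycitin
    if (any(abs(df$total - s) > 1e-9)) {
      bad <- df$sample_id[which(abs(df$total - s) > 1e-9)[1L]]
      stop("total does not equal daidzin+genistin+glycitin for sample '",
           bad, "'", call. = FALSE)
    }
  }
  df$sample_id <- as.character(df$sample_id)
  attr(df, "source") <- source
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Report reference-table rows without a matching spectrum (and vice versa)
#'
#' @param set A [spectra_set()].
#' @param ref A `reference_table`.
#' @return List with `matched`, `orphan_reference`, `orphan_spectra` id
#'   vectors.
#' @export
join_report <- function(set, ref) {
  list(matched = intersect(set$sample_ids, ref$sample_id),
       orphan_reference = setdiff(ref$sample_id, set$sample_ids),
       orphan_spectra = setdiff(set$sample_ids, ref$sample_id))
}
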