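#' Read a JCAMP-DX infrared spectrum
#'
#' Minimal JCAMP-DX 4.24 subset: AFFN-encoded `##XYDATA=(X++(Y..Y))` and
#' `##XYPOINTS=(XY..XY)` records with `##XFACTOR`/`##YFACTOR` scaling.
#' `##XUNITS` must be `1/CM` — this package works on wavenumber axes only.
#' Compressed (SQZ/DIF/DUP) ordinate encodings are not supported.
#'
#' @param path Path to a JCAMP-DX file.
#' @param sample_id Optional id; defaults to the `##TITLE` record, falling
#'   back to the file name.
#' @return A [spectrum()] with `meta$yunits` from `##YUNITS`.
#' @export
read_jcamp <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^##", name, "\\s*="), "", lines[hit[1L]],
               ignore.case = TRUE))
  }
  xunits <- ldr("XUNITS")
  if (is.null(xunits) || toupper(xunits) != "1/CM") {
    stop("XUNITS must be 1/CM, got: ",
         if (is.null(xunits)) "<missing>" else xunits, call. = FALSE)
  }
  xfac <- as.numeric(ldr("XFACTOR") %||% "1")
  yfac <- as.numeric(ldr("YFACTOR") %||% "1")
  if (is.na(xfac) || is.na(yfac)) stop("malformed XFACTOR/YFACTOR", call. = FALSE)

  start <- grep("^##(XYDATA|XYPOINTS)\\s*=", lines, ignore.case = TRUE)
  if (length(start) == 0L) stop("no XYDATA or XYPOINTS block", call. = FALSE)
  start <- start[1L]
  kind <- toupper(sub("^##(XYDATA|XYPOINTS).*", "\\1", lines[start],
                      ignore.case = TRUE))
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty data block", call. = FALSE)

  if (kind == "XYDATA") {
    # each line: X Y1 Y2 ... ; successive X from grid checked loosely
    wn <- numeric(0); ab <- numeric(0)
    for (ln in body) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1L]]))
      if (anyNA(v) || length(v) < 2L) {
        stop("malformed XYDATA line: ", ln, call. = FALSE)
      }
      wn <- c(wn, v[1L]); ab <- c(ab, v[-1L])
    }
    npt <- as.numeric(ldr("NPOINTS") %||% length(ab))
    if (length(ab) != npt) {
      stop("NPOINTS mismatch: declared ", npt, ", found ", length(ab),
           call. = FALSE)
    }
    firstx <- as.numeric(ldr("FIRSTX") %||% (wn[1L] * xfac))
    lastx <- as.numeric(ldr("LASTX") %||% NA)
    if (is.na(lastx)) {
      dx <- as.numeric(ldr("DELTAX") %||% NA)
      if (is.na(dx)) stop("LASTX or DELTAX required for XYDATA", call. = FALSE)
      lastx <- firstx + dx * (npt - 1)
    }
    x <- seq(firstx, lastx, length.out = npt)
    y <- ab * yfac
  } else {
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(body), "[,;[:space:]]+"))))
    if (anyNA(vals) || length(vals) %% 2L != 0L) {
      stop("malformed XYPOINTS block", call. = FALSE)
    }
    x <- vals[seq(1L, length(vals), 2L)] * xfac
    y <- vals[seq(2L, length(vals), 2L)] * yfac
  }
  if (is.null(sample_id)) {
    sample_id <- ldr("TITLE") %||% sub("\\.[^.]*$", "", basename(path))
  }
  spectrum(sample_id, x, y,
           meta = list(yunits = ldr("YUNITS") %||% "ABSORBANCE"))
}

#' Write a spectrum as JCAMP-DX
#'
#' Emits an AFFN `##XYPOINTS=(XY..XY)` record with unit factors, descending
#' wavenumber order (IR convention), `##XUNITS=1/CM`.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  ord <- order(spec$wavenumbers, decreasing = TRUE)
  x <- spec$wavenumbers[ord]; y <- spec$absorbance[ord]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", spec$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    paste0("##YUNITS=", spec$meta$yunits %||% "ABSORBANCE"),
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", format(x[1L], digits = 12)),
    paste0("##LASTX=", format(x[length(x)], digits = 12)),
    paste0("##NPOINTS=", length(x)),
    "##XYPOINTS=(XY..XY)",
    paste(format(x, digits = 12, trim = TRUE),
          format(y, digits = 12, trim = TRUE)),
    "##END="
  ), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
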