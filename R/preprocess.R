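#' Offset (mean) correction
#'
#' Subtracts each spectrum's mean intensity from every point of that
#' spectrum, so each row has mean exactly zero. This is the whole-spectrum
#' offset correction used to finish baseline removal.
#'
#' @param m Numeric matrix, samples x wavenumbers.
#' @return Matrix of the same shape with zero row means.
#' @export
offset_correct <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite values in matrix", call. = FALSE)
  sweep(m, 1L, rowMeans(m))
}

#' Linear (anchor-point) baseline correction
#'
#' For each spectrum, subtracts the piecewise-linear function through the
#' spectrum's own values at the anchor wavenumbers; segments at the ends are
#' extended linearly. Values at the anchors become zero. This is a
#' documented, deterministic stand-in for interactive baseline routines of
#' commercial packages.
#'
#' @param m Numeric matrix, samples x wavenumbers.
#' @param grid Ascending wavenumber vector matching `ncol(m)`.
#' @param anchors Two or more wavenumbers within the grid range; each is
#'   snapped to the nearest grid point. Default: the two grid endpoints.
#' @return Baseline-corrected matrix, same shape.
#' @export
baseline_linear <- function(m, grid, anchors = range(grid)) {
  m <- as.matrix(m)
  grid <- as.numeric(grid)
  stopifnot(ncol(m) == length(grid))
  anchors <- sort(as.numeric(anchors))
  if (length(anchors) < 2L) stop("need at least 2 anchors", call. = FALSE)
  if (min(anchors) < min(grid) || max(anchors) > max(grid)) {
    stop("anchor outside grid range", call. = FALSE)
  }
  idx <- vapply(anchors, function(a) which.min(abs(grid - a)), integer(1))
  idx <- unique(idx)
  if (length(idx) < 2L) stop("anchors collapse to fewer than 2 grid points",
                             call. = FALSE)
  ax <- grid[idx]
  # segment index for every grid point, end segments extended
  seg <- findInterval(grid, ax, all.inside = TRUE)
  x0 <- ax[seg]; x1 <- ax[seg + 1L]
  w <- (grid - x0) / (x1 - x0)
  y0 <- m[, idx[seg], drop = FALSE]
  y1 <- m[, idx[seg + 1L], drop = FALSE]
  base <- y0 + sweep(y1 - y0, 2L, w, `*`)
  m - base
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial filtering on a uniform wavenumber grid.
#' Derivatives are returned in physical units (per cm^-1 to the power
#' `deriv`), i.e. scaled by the grid spacing. Edge points are computed with
#' asymmetric polynomial fits rather than truncated; their column indices
#' are flagged in the `"edge_cols"` attribute so downstream calibration can
#' exclude them.
#'
#' @param m Numeric matrix, samples x wavenumbers.
#' @param grid Ascending, uniformly spaced wavenumber vector.
#' @param window Odd filter width in points (default 9).
#' @param polyorder Polynomial degree (default 3); must satisfy
#'   `deriv <= polyorder < window`.
#' @param deriv Derivative order, 0, 1, or 2.
#' @return Filtered matrix of the same shape, attribute `edge_cols` holding
#'   the `(window-1)/2` flagged indices at each end.
#' @export
savgol <- function(m, grid, window = 9L, polyorder = 3L, deriv = 0L) {
  m <- as.matrix(m)
  grid <- as.numeric(grid)
  stopifnot(ncol(m) == length(grid))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L || window < 3L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2", call. = FALSE)
  if (polyorder >= window || polyorder < deriv) {
    stop("need deriv <= polyorder < window", call. = FALSE)
  }
  if (window > length(grid)) {
    stop("window (", window, ") exceeds number of grid points", call. = FALSE)
  }
  d <- diff(grid)
  h <- mean(d)
  if (any(abs(d - h) > 1e-9 * abs(h))) {
    stop("grid is not uniformly spaced; align spectra to a uniform grid first",
         call. = FALSE)
  }
  out <- t(apply(m, 1L, signal::sgolayfilt,
                 p = polyorder, n = window, m = deriv, ts = h))
  dimnames(out) <- dimnames(m)
  half <- (window - 1L) %/% 2L
  n <- length(grid)
  attr(out, "edge_cols") <- c(seq_len(half), seq(n - half + 1L, n))
  out
}

#' Standard normal variate (SNV)
#'
#' Row-wise standardization: subtract the spectrum mean and divide by the
#' spectrum's sample standard deviation (n-1 denominator). Removes
#' multiplicative scatter effects (particle size, light dispersion) from
#' each spectrum independently.
#'
#' @param m Numeric matrix, samples x wavenumbers.
#' @return Matrix with each row at mean 0, sample SD 1.
#' @export
snv <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  if (any(s == 0)) {
    bad <- rownames(m)[which(s == 0)[1L]] %||% as.character(which(s == 0)[1L])
    stop("constant spectrum cannot be SNV-scaled: sample '", bad, "'",
         call. = FALSE)
  }
  sweep(sweep(m, 1L, mu), 1L, s, `/`)
}

#' Restrict a spectral matrix to wavenumber regions
#'
#' Keeps the union of the listed inclusive intervals, preserving the
#' original column order; each column is kept once even if covered by
#' several regions.
#'
#' @param m Numeric matrix, samples x wavenumbers.
#' @param grid Ascending wavenumber vector matching `ncol(m)`.
#' @param regions List of `c(high, low)` wavenumber pairs in cm^-1 (IR
#'   convention: high first).
#' @return List with elements `matrix` and `grid` restricted to the union.
#' @export
select_regions <- function(m, grid, regions) {
  m <- as.matrix(m)
  grid <- as.numeric(grid)
  stopifnot(ncol(m) == length(grid))
  if (length(regions) == 0L) stop("regions must be non-empty", call. = FALSE)
  keep <- rep(FALSE, length(grid))
  for (r in regions) {
    r <- as.numeric(r)
    if (length(r) != 2L) stop("each region must be a (high, low) pair",
                              call. = FALSE)
    hi <- max(r); lo <- min(r)
    if (hi == lo) stop("region must have high > low", call. = FALSE)
    inside <- grid >= lo & grid <= hi
    if (!any(inside)) {
      stop(sprintf("region (%g, %g) contains no grid points", hi, lo),
           call. = FALSE)
    }
    keep <- keep | inside
  }
  list(matrix = m[, keep, drop = FALSE], grid = grid[keep])
}

# ---- recipes ---------------------------------------------------------------

#' Preprocessing recipe steps
#'
#' Constructors for the steps of a [preprocess_recipe()]. The conventional
#' order — baseline/offset, then derivative, then SNV, then region cut — puts
#' scatter normalization after the noise-amplifying derivative and cuts the
#' retained windows last so filter edge effects fall outside them.
#'
#' @param anchors Anchor wavenumbers for [baseline_linear()]; `NULL` means
#'   the grid endpoints at application time.
#' @param window,polyorder,deriv See [savgol()].
#' @param regions See [select_regions()].
#' @return A recipe step (named list with `op` and parameters).
#' @name recipe-steps
NULL

#' @rdname recipe-steps
#' @export
step_offset <- function() list(op = "offset")

#' @rdname recipe-steps
#' @export
step_baseline <- function(anchors = NULL) {
  list(op = "baseline_linear", anchors = anchors)
}

#' @rdname recipe-steps
#' @export
step_savgol <- function(window = 9L, polyorder = 3L, deriv = 1L) {
  list(op = "savgol", window = as.integer(window),
       polyorder = as.integer(polyorder), deriv = as.integer(deriv))
}

#' @rdname recipe-steps
#' @export
step_snv <- function() list(op = "snv")

#' @rdname recipe-steps
#' @export
step_regions <- function(regions) list(op = "select_regions", regions = regions)

#' Build and validate a preprocessing recipe
#'
#' An ordered list of transforms to apply to a [spectra_set()] before PLS.
#'
#' @param ... Recipe steps from [step_offset()] and friends, applied in the
#'   order given.
#' @param drop_edges Drop columns flagged as filter-edge artifacts from the
#'   final design matrix (default `TRUE`).
#' @return An object of class `preprocess_recipe`.
#' @examples
#' preprocess_recipe(step_offset(), step_savgol(9, 3, 1), step_snv(),
#'                   step_regions(list(c(1500, 900))))
#' @export
preprocess_recipe <- function(..., drop_edges = TRUE) {
  steps <- list(...)
  if (length(steps) == 1L && is.null(steps[[1L]]$op) && is.list(steps[[1L]])) {
    steps <- steps[[1L]]   # allow a pre-built list of steps
  }
  known <- c("offset", "baseline_linear", "savgol", "snv", "select_regions")
  for (st in steps) {
    if (is.null(st$op) || !st$op %in% known) {
      stop("unknown recipe step: ", deparse(st$op), call. = FALSE)
    }
    if (st$op == "savgol") {
      if (st$window %% 2L == 0L) stop("savgol window must be odd", call. = FALSE)
      if (!st$deriv %in% 0:2) stop("savgol deriv must be 0, 1 or 2", call. = FALSE)
      if (st$polyorder >= st$window || st$polyorder < st$deriv) {
        stop("savgol needs deriv <= polyorder < window", call. = FALSE)
      }
    }
    if (st$op == "select_regions") {
      if (length(st$regions) == 0L) {
        stop("select_regions step needs non-empty regions", call. = FALSE)
      }
      for (r in st$regions) {
        if (max(r) <= min(r)) stop("region must have high > low", call. = FALSE)
      }
    }
  }
  structure(list(steps = steps, drop_edges = isTRUE(drop_edges)),
            class = "preprocess_recipe")
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  ops <- vapply(x$steps, function(s) s$op, character(1))
  cat("<preprocess_recipe>", if (length(ops)) paste(ops, collapse = " -> ")
      else "(identity)", "\n")
  invisible(x)
}

#' Apply a preprocessing recipe to a spectra set
#'
#' Applies the steps in order and returns the PLS design matrix together
#' with the surviving wavenumber grid. Pure function: identical inputs give
#' identical outputs.
#'
#' @param set A [spectra_set()].
#' @param recipe A [preprocess_recipe()]; an empty recipe returns the matrix
#'   unchanged.
#' @return List with `matrix` (samples x kept wavenumbers) and `grid`.
#' @export
apply_recipe <- function(set, recipe) {
  stopifnot(inherits(set, "spectra_set"), inherits(recipe, "preprocess_recipe"))
  m <- set$matrix
  grid <- set$grid
  edge <- rep(FALSE, length(grid))
  for (st in recipe$steps) {
    switch(st$op,
      offset = { m <- offset_correct(m) },
      baseline_linear = {
        anchors <- st$anchors %||% range(grid)
        m <- baseline_linear(m, grid, anchors)
      },
      savgol = {
        m <- savgol(m, grid, st$window, st$polyorder, st$deriv)
        edge[attr(m, "edge_cols")] <- TRUE
        attr(m, "edge_cols") <- NULL
      },
      snv = { m <- snv(m) },
      select_regions = {
        sel <- select_regions(m, grid, st$regions)
        keep <- grid %in% sel$grid
        edge <- edge[keep]
        m <- sel$matrix
        grid <- sel$grid
      }
    )
  }
  if (recipe$drop_edges && any(edge)) {
    m <- m[, !edge, drop = FALSE]
    grid <- grid[!edge]
  }
  list(matrix = m, grid = grid)
}
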