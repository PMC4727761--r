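#' Fit a PLS1 regression model (NIPALS)
#'
#' Partial least squares with a single response, the workhorse of
#' spectroscopic multivariate calibration: latent variables are extracted to
#' maximize covariance between the (mean-centered) spectral matrix and the
#' concentration vector, so that quantification remains possible despite
#' band overlap. Columns are mean-centered only — no unit-variance scaling,
#' the standard choice for spectra that share units.
#'
#' With one response the NIPALS weight for each component is closed-form
#' (`X'y` normalized), so fitting is deterministic and needs no iteration or
#' convergence tolerance. `X` is deflated after each component; the
#' regression vector `b = W (P'W)^-1 q` maps centered spectra directly to
#' centered predictions.
#'
#' If the residual covariance vanishes before `n_lv` components are
#' extracted (data of lower rank), extraction stops there and the model
#' records the number actually used in `n_lv`.
#'
#' @param X Numeric matrix, samples x variables (already preprocessed).
#' @param y Numeric response vector, mg per 500 ul.
#' @param n_lv Number of latent variables requested, `0 <= n_lv <=
#'   min(nrow(X) - 1, ncol(X))`. `n_lv = 0` gives the intercept-only model
#'   predicting `mean(y)`.
#' @param grid Optional wavenumber annotation for the columns of `X`.
#' @param recipe Optional [preprocess_recipe()] stored for provenance.
#' @param analyte Optional analyte label.
#' @return Object of class `pls1_model`: `x_mean`, `y_mean`, `weights`,
#'   `loadings`, `y_loadings`, `scores`, `b`, `n_lv`, `n_lv_requested`,
#'   `grid`, `recipe`, `analyte`.
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% c(1, -1, 0, 2, 0) + rnorm(12, sd = 0.01)
#' m <- fit_pls1(X, drop(y), n_lv = 3)
#' predict(m, X)
#' @export
fit_pls1 <- function(X, y, n_lv, grid = NULL, recipe = NULL, analyte = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 0L || n_lv > min(n - 1L, p)) {
    stop("n_lv must be between 0 and min(n_samples - 1, n_variables) = ",
         min(n - 1L, p), call. = FALSE)
  }
  if (n_lv >= 1L && stats::var(y) == 0) {
    stop("y has zero variance; cannot fit latent variables", call. = FALSE)
  }
  if (!is.null(grid) && length(grid) != p) {
    stop("grid annotation length must equal ncol(X)", call. = FALSE)
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2))  # reference magnitude for rank stop
  a <- 0L
  while (a < n_lv) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(scale0, 1e-300)) break  # residual rank exhausted
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt <= .Machine$double.eps * n) break
    pl <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qa * t
    a <- a + 1L
    W[, a] <- w; P[, a] <- pl; q[a] <- qa; Tm[, a] <- t
  }
  if (a < n_lv) {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    Tm <- Tm[, seq_len(a), drop = FALSE]
  }
  b <- if (a == 0L) numeric(p) else
    drop(W %*% solve(crossprod(P, W), q))

  structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
         y_loadings = q, scores = Tm, b = b, n_lv = a,
         n_lv_requested = n_lv, grid = grid, recipe = recipe,
         analyte = analyte),
    class = "pls1_model"
  )
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model>%s %d LV(s), %d variables\n",
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$n_lv, length(x$b)))
  invisible(x)
}

#' Predict concentrations from a fitted PLS1 model
#'
#' `y_hat = y_mean + (X_new - x_mean) b`. Negative predictions are returned
#' as-is (clipping would bias SEP) but flagged in the `below_zero`
#' attribute.
#'
#' @param object A `pls1_model`.
#' @param newdata Numeric matrix with the same columns as the training
#'   design matrix (a single spectrum may be given as a vector).
#' @param ... Unused.
#' @return Numeric vector of predictions with logical attribute
#'   `below_zero`.
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_mean), call. = FALSE)
  }
  yhat <- drop(sweep(newdata, 2L, object$x_mean) %*% object$b) + object$y_mean
  yhat <- as.numeric(yhat)
  attr(yhat, "below_zero") <- yhat < 0
  yhat
}

#' Regression vector of a fitted PLS1 model
#'
#' The per-wavenumber coefficient vector in (centered) original variable
#' space — the diagnostic view of which spectral regions drive the
#' prediction.
#'
#' @param model A `pls1_model`.
#' @return Numeric vector, one coefficient per design column, named by
#'   wavenumber when the model carries a grid annotation.
#' @export
regression_vector <- function(model) {
  if (!inherits(model, "pls1_model")) {
    stop("not a fitted pls1_model", call. = FALSE)
  }
  b <- model$b
  if (!is.null(model$grid)) names(b) <- format(model$grid, trim = TRUE)
  b
}

#' Persist / restore a PLS1 model as JSON
#'
#' Stores means, weights, loadings, regression vector, LV count, grid and
#' the preprocessing recipe, so a saved model can be reapplied to new
#' spectra.
#'
#' @param model A `pls1_model`.
#' @param path JSON file path.
#' @return `save_pls1_model`: `path` invisibly. `load_pls1_model`: the
#'   restored `pls1_model`.
#' @export
save_pls1_model <- function(model, path) {
  stopifnot(inherits(model, "pls1_model"))
  doc <- list(
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, b = model$b,
    n_lv = model$n_lv, n_lv_requested = model$n_lv_requested,
    grid = model$grid, analyte = model$analyte,
    recipe = if (is.null(model$recipe)) NULL else unclass(model$recipe)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_pls1_model
#' @export
load_pls1_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  k <- as.integer(doc$n_lv)
  p <- length(doc$x_mean)
  as_mat <- function(rows) {   # serialized row-wise
    if (k == 0L) return(matrix(0, p, 0L))
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  num <- function(x) as.numeric(unlist(x))
  recipe <- NULL
  if (!is.null(doc$recipe)) {
    steps <- lapply(doc$recipe$steps, function(st) {
      if (!is.null(st$regions)) st$regions <- lapply(st$regions, num)
      if (!is.null(st$window)) st$window <- as.integer(st$window)
      if (!is.null(st$polyorder)) st$polyorder <- as.integer(st$polyorder)
      if (!is.null(st$deriv)) st$deriv <- as.integer(st$deriv)
      if (!is.null(st$anchors)) st$anchors <- num(st$anchors)
      st
    })
    recipe <- preprocess_recipe(steps, drop_edges = isTRUE(doc$recipe$drop_edges))
  }
  structure(
    list(x_mean = num(doc$x_mean), y_mean = num(doc$y_mean),
         weights = as_mat(doc$weights), loadings = as_mat(doc$loadings),
         y_loadings = num(doc$y_loadings), scores = NULL,
         b = num(doc$b), n_lv = k,
         n_lv_requested = as.integer(doc$n_lv_requested),
         grid = if (is.null(doc$grid)) NULL else num(doc$grid),
         recipe = recipe, analyte = doc$analyte),
    class = "pls1_model"
  )
}
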