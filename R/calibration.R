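#' Standard error of prediction (SEP)
#'
#' Root-mean-square deviation between reference and predicted values, with
#' denominator n: `sqrt(sum((y_hat - y)^2) / n)`. The accuracy criterion of
#' the calibration: a model quantifies sufficiently only when SEP is below
#' 15 percent of the property mean (see [sep_percent()], [qc_verdict()]).
#'
#' @param y_true Reference values (mg per 500 ul).
#' @param y_pred Predicted values, same length.
#' @return SEP in the units of `y_true`.
#' @export
sep <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1L) stop("need at least one value", call. = FALSE)
  sqrt(sum((y_pred - y_true)^2) / length(y_true))
}

#' SEP as a percentage of the property mean
#'
#' @param sep_value SEP in concentration units.
#' @param y_reference Reference values whose mean sets the scale.
#' @return `100 * sep_value / mean(y_reference)`.
#' @export
sep_percent <- function(sep_value, y_reference) {
  m <- mean(as.numeric(y_reference))
  if (!is.finite(m) || m <= 0) {
    stop("mean of the reference values must be positive", call. = FALSE)
  }
  100 * sep_value / m
}

#' Explained variance (R-squared, percent)
#'
#' `100 * (1 - SS_res / SS_tot)` between reference values and predictions;
#' the "variance" figure of merit of the calibration, ideally approaching
#' 100. May be negative for predictions worse than the mean.
#'
#' @param y_true Reference values (must have nonzero variance).
#' @param y_pred Predictions.
#' @return Explained variance in percent.
#' @export
variance_explained <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true has zero variance", call. = FALSE)
  100 * (1 - sum((y_pred - y_true)^2) / ss_tot)
}

#' Pearson correlation between reference and predicted values
#'
#' @param y_true Reference values.
#' @param y_pred Predictions.
#' @return Correlation coefficient r in [-1, 1].
#' @export
correlation_r <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (stats::var(y_true) == 0 || stats::var(y_pred) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(y_true, y_pred)
}

#' Cross-validation schemes
#'
#' `cv_loo()` is leave-one-out, the deterministic classic for calibration
#' sets of this size; `cv_kfold()` requires an explicit seed so fold
#' assignment is reproducible.
#'
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment (mandatory).
#' @return A scheme description used by [cross_validate()].
#' @export
cv_loo <- function() structure(list(type = "LOO"), class = "cv_scheme")

#' @rdname cv_loo
#' @export
cv_kfold <- function(k, seed) {
  if (missing(seed)) stop("cv_kfold requires an explicit seed", call. = FALSE)
  structure(list(type = "KFOLD", k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Cross-validated SEP as a function of latent-variable count
#'
#' For every LV count from 0 to `max_lv`, held-out predictions are pooled
#' over all folds and a single SEP is computed on the pooled residuals —
#' the SEP-versus-LVs curve whose minimum locates the optimal model
#' complexity (too many LVs model noise and overfit; too few underfit).
#'
#' Each fold is refit from scratch; predictions at k components are exactly
#' those of a model fit with `n_lv = k` on the fold's training samples.
#'
#' @param X Design matrix (preprocessed), samples x variables.
#' @param y Concentration vector.
#' @param max_lv Largest LV count to evaluate;
#'   `max_lv <= min(n - 2, ncol(X))`.
#' @param scheme [cv_loo()] (default) or [cv_kfold()].
#' @return A `sep_curve`: data frame with columns `n_lv`, `sep`; attributes
#'   `predictions` (n x (max_lv+1) matrix of held-out predictions) and
#'   `scheme`.
#' @export
cross_validate <- function(X, y, max_lv, scheme = cv_loo()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples for cross-validation", call. = FALSE)
  max_lv <- as.integer(max_lv)
  if (max_lv < 0L || max_lv > min(n - 2L, ncol(X))) {
    stop("max_lv must be between 0 and min(n_samples - 2, n_variables) = ",
         min(n - 2L, ncol(X)), call. = FALSE)
  }
  stopifnot(inherits(scheme, "cv_scheme"))
  folds <- if (scheme$type == "LOO") {
    as.list(seq_len(n))
  } else {
    if (scheme$k < 2L || scheme$k > n) stop("k must be in 2..n", call. = FALSE)
    assign_folds <- local({
      rs <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
      set.seed(scheme$seed)
      sample(rep_len(seq_len(scheme$k), n))
    })
    split(seq_len(n), assign_folds)
  }

  preds <- matrix(NA_real_, n, max_lv + 1L)
  for (fold in folds) {
    fit <- fit_pls1(X[-fold, , drop = FALSE], y[-fold], max_lv)
    Xc <- sweep(X[fold, , drop = FALSE], 2L, fit$x_mean)
    for (k in 0:max_lv) {
      kk <- min(k, fit$n_lv)     # rank-deficient folds stop early
      bk <- if (kk == 0L) numeric(ncol(X)) else {
        Wk <- fit$weights[, seq_len(kk), drop = FALSE]
        Pk <- fit$loadings[, seq_len(kk), drop = FALSE]
        drop(Wk %*% solve(crossprod(Pk, Wk), fit$y_loadings[seq_len(kk)]))
      }
      preds[fold, k + 1L] <- drop(Xc %*% bk) + fit$y_mean
    }
  }
  curve <- data.frame(n_lv = 0:max_lv,
                      sep = vapply(0:max_lv, function(k)
                        sep(y, preds[, k + 1L]), numeric(1)))
  attr(curve, "predictions") <- preds
  attr(curve, "scheme") <- scheme
  class(curve) <- c("sep_curve", "data.frame")
  curve
}

#' Optimal latent-variable count from a SEP curve
#'
#' The smallest LV count attaining the minimal SEP; ties break toward fewer
#' latent variables (the more parsimonious, more robust model).
#'
#' @param curve A `sep_curve` from [cross_validate()].
#' @return Integer LV count.
#' @export
select_optimal_lv <- function(curve) {
  if (is.null(curve$n_lv) || nrow(curve) == 0L) {
    stop("empty SEP curve", call. = FALSE)
  }
  curve$n_lv[which.min(curve$sep)]
}

#' Quality-control verdict from SEP percent
#'
#' A model is admitted for quantification only when its SEP is strictly
#' under 15 percent of the property mean; otherwise it is usable for
#' estimation only.
#'
#' @param sep_percent_value SEP as percent of the property mean.
#' @param threshold Gate in percent (default 15).
#' @return `"QUANTIFY"` or `"ESTIMATE_ONLY"`.
#' @export
qc_verdict <- function(sep_percent_value, threshold = 15) {
  if (sep_percent_value < threshold) "QUANTIFY" else "ESTIMATE_ONLY"
}

#' Calibrate one analyte: preprocessing, CV model selection, final fit
#'
#' The full model-building loop for a single property: join spectra with
#' reference concentrations, apply the preprocessing recipe, compute the
#' cross-validated SEP curve, pick the optimal LV count, refit on all
#' samples, and report SEP, SEP percent, explained variance, correlation
#' and the QC verdict — all computed on the cross-validated (held-out)
#' predictions, so the figures of merit measure prediction, not
#' reconstruction. Set `training_metrics = TRUE` to additionally report
#' training-set (refit) variance and correlation.
#'
#' @param set A [spectra_set()].
#' @param ref A `reference_table` with matching sample ids.
#' @param analyte One of `"daidzin"`, `"genistin"`, `"glycitin"`, `"total"`.
#' @param recipe A [preprocess_recipe()].
#' @param max_lv Largest LV count to evaluate.
#' @param scheme CV scheme, default [cv_loo()].
#' @param training_metrics Also compute training-set variance/r.
#' @return List with `model` (a `pls1_model`) and `report`
#'   (a `calibration_report`).
#' @export
calibrate_analyte <- function(set, ref, analyte, recipe, max_lv,
                              scheme = cv_loo(), training_metrics = FALSE) {
  stopifnot(inherits(set, "spectra_set"), inherits(ref, "reference_table"))
  analyte <- match.arg(analyte, c("daidzin", "genistin", "glycitin", "total"))
  if (!analyte %in% names(ref)) {
    stop("reference table has no column '", analyte, "'", call. = FALSE)
  }
  ids <- intersect(set$sample_ids, ref$sample_id)
  if (length(ids) < 5L) {
    stop("only ", length(ids), " samples join spectra and reference; need >= 5",
         call. = FALSE)
  }
  sub <- spectra_set(set$grid, set$matrix[ids, , drop = FALSE], ids)
  y <- ref[[analyte]][match(ids, ref$sample_id)]
  if (stats::var(y) == 0) {
    stop("reference values for '", analyte, "' have zero variance",
         call. = FALSE)
  }
  design <- apply_recipe(sub, recipe)
  max_lv <- min(max_lv, length(ids) - 2L, ncol(design$matrix))
  curve <- cross_validate(design$matrix, y, max_lv, scheme)
  k <- select_optimal_lv(curve)
  model <- fit_pls1(design$matrix, y, k, grid = design$grid,
                    recipe = recipe, analyte = analyte)
  y_cv <- attr(curve, "predictions")[, k + 1L]
  s <- sep(y, y_cv)
  sp <- sep_percent(s, y)
  report <- structure(list(
    analyte = analyte,
    n_samples = length(ids),
    n_lv = k,
    sep = s,
    sep_percent = sp,
    variance = variance_explained(y, y_cv),
    r = correlation_r(y, y_cv),
    qc = qc_verdict(sp),
    curve = curve,
    y_reference = y,
    y_cv = y_cv
  ), class = "calibration_report")
  if (training_metrics) {
    y_fit <- predict(model, design$matrix)
    report$training_variance <- variance_explained(y, y_fit)
    report$training_r <- correlation_r(y, y_fit)
  }
  list(model = model, report = report)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "<calibration_report> %s: %d LVs, SEP %.4g mg/500ul (%.2f%%), variance %.1f%%, r %.3f -> %s\n",
    x$analyte, x$n_lv, x$sep, x$sep_percent, x$variance, x$r, x$qc))
  invisible(x)
}

#' One-row data-frame view of a calibration report (Table-1 style)
#'
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @return Data frame with analyte, LV count, SEP, SEP percent, variance,
#'   r and QC verdict.
#' @export
as.data.frame.calibration_report <- function(x, ...) {
  data.frame(analyte = x$analyte, n_samples = x$n_samples, n_lv = x$n_lv,
             sep = x$sep, sep_percent = x$sep_percent,
             variance = x$variance, r = x$r, qc = x$qc,
             stringsAsFactors = FALSE)
}
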