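#' Default per-analyte preprocessing recipes
#'
#' Offset correction, first-derivative Savitzky-Golay over 9 points, SNV,
#' then a wavenumber-region cut. The region windows are the classic
#' fingerprint restrictions 2000-650, 1500-980 and 1500-900 cm^-1; the
#' analyte-to-window pairing is a package default and can be overridden per
#' analyte.
#'
#' @return Named list of [preprocess_recipe()] objects for `daidzin`,
#'   `genistin`, `glycitin`, `total`.
#' @export
default_recipes <- function() {
  mk <- function(region) preprocess_recipe(
    step_offset(), step_savgol(9, 3, 1), step_snv(),
    step_regions(list(region)))
  list(daidzin = mk(c(1500, 980)),
       genistin = mk(c(1500, 900)),
       glycitin = mk(c(1500, 980)),
       total = mk(c(2000, 650)))
}

#' Assemble and validate a pipeline configuration
#'
#' Either a simulation `design` or a pair of in-memory `spectra`/`reference`
#' inputs must be supplied. Unknown fields are rejected.
#'
#' @param design Optional [sim_design()] to generate the calibration data.
#' @param spectra Optional [spectra_set()] (with `reference`).
#' @param reference Optional `reference_table`.
#' @param recipes Named list of [preprocess_recipe()], one per analyte to
#'   calibrate; default [default_recipes()].
#' @param max_lv Largest latent-variable count examined (default 12).
#' @param scheme CV scheme (default [cv_loo()]).
#' @param output_dir Optional directory for reports, models, curves and the
#'   run manifest.
#' @param training_metrics Also report training-set variance/r.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, spectra = NULL, reference = NULL,
                            recipes = default_recipes(), max_lv = 12L,
                            scheme = cv_loo(), output_dir = NULL,
                            training_metrics = FALSE) {
  if (!is.null(design)) stopifnot(inherits(design, "sim_design"))
  if (!is.null(spectra)) stopifnot(inherits(spectra, "spectra_set"))
  if (!is.null(reference)) stopifnot(inherits(reference, "reference_table"))
  if (length(recipes) == 0L || is.null(names(recipes)) ||
      any(!nzchar(names(recipes)))) {
    stop("recipes must be a non-empty named list (one entry per analyte)",
         call. = FALSE)
  }
  bad <- setdiff(names(recipes), c("daidzin", "genistin", "glycitin", "total"))
  if (length(bad)) stop("unknown analyte in recipes: ", bad[1L], call. = FALSE)
  for (r in recipes) stopifnot(inherits(r, "preprocess_recipe"))
  stopifnot(inherits(scheme, "cv_scheme"), max_lv >= 1L)
  structure(list(design = design, spectra = spectra, reference = reference,
                 recipes = recipes, max_lv = as.integer(max_lv),
                 scheme = scheme, output_dir = output_dir,
                 training_metrics = isTRUE(training_metrics)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Schema-checked: only the keys `design`, `recipes`, `max_lv`, `scheme`
#' and `output_dir` are accepted; unknown keys abort. `design` must be a
#' path to a design YAML (see [write_design_yaml()]); each recipe is a list
#' of steps `{op, ...params}` with regions as `[high, low]` pairs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("design", "recipes", "max_lv", "scheme", "output_dir")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$recipes)) stop("config has no analyte recipes", call. = FALSE)
  recipes <- lapply(cfg$recipes, function(steps) {
    steps <- lapply(steps, function(st) {
      if (!is.null(st$regions)) st$regions <- lapply(st$regions, as.numeric)
      if (!is.null(st$window)) st$window <- as.integer(st$window)
      if (!is.null(st$polyorder)) st$polyorder <- as.integer(st$polyorder)
      if (!is.null(st$deriv)) st$deriv <- as.integer(st$deriv)
      st
    })
    preprocess_recipe(steps)
  })
  scheme <- if (is.null(cfg$scheme) || identical(toupper(cfg$scheme$type), "LOO")) {
    cv_loo()
  } else {
    cv_kfold(cfg$scheme$k, cfg$scheme$seed)
  }
  design <- if (!is.null(cfg$design)) read_design_yaml(cfg$design)
  pipeline_config(design = design, recipes = recipes,
                  max_lv = cfg$max_lv %||% 12L, scheme = scheme,
                  output_dir = cfg$output_dir)
}

#' Serialize / load a simulation design as YAML
#'
#' @param design A [sim_design()].
#' @param path YAML file path.
#' @return `write_design_yaml`: `path` invisibly; `read_design_yaml`: a
#'   `sim_design`.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "sim_design"))
  enc_bands <- function(bl) lapply(bl, function(b) unclass(b))
  doc <- list(
    analyte_bands = lapply(design$analyte_bands, enc_bands),
    interferent_bands = enc_bands(design$interferent_bands),
    matrix_bands = enc_bands(design$matrix_bands),
    base_levels = as.list(design$base_levels),
    spike_volumes = design$spike_volumes,
    stock_concentration = design$stock_concentration,
    n_base = design$n_base,
    two_analyte_combos = as.list(design$two_analyte_combos),
    n_replicates = design$n_replicates,
    interferent_level = design$interferent_level,
    baseline_drift = design$baseline_drift,
    scatter_range = design$scatter_range,
    noise_sd = design$noise_sd,
    grid = list(from = min(design$grid), to = max(design$grid),
                by = design$grid[2] - design$grid[1]),
    seed = design$seed
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  dec_bands <- function(bl) lapply(bl, function(b)
    band(b$center, b$fwhm, b$amplitude, b$shape))
  sim_design(
    analyte_bands = lapply(doc$analyte_bands, dec_bands),
    interferent_bands = dec_bands(doc$interferent_bands),
    matrix_bands = dec_bands(doc$matrix_bands),
    base_levels = unlist(doc$base_levels),
    spike_volumes = as.numeric(doc$spike_volumes),
    stock_concentration = doc$stock_concentration,
    n_base = doc$n_base,
    two_analyte_combos = unlist(doc$two_analyte_combos),
    n_replicates = doc$n_replicates,
    interferent_level = doc$interferent_level,
    baseline_drift = lapply(doc$baseline_drift, as.numeric),
    scatter_range = as.numeric(doc$scatter_range),
    noise_sd = doc$noise_sd,
    grid = seq(doc$grid$from, doc$grid$to, by = doc$grid$by),
    seed = doc$seed
  )
}

#' Run the full calibration: one model and report per analyte
#'
#' Generates (or takes) the calibration data, calibrates every analyte in
#' the config's recipe list, and — when an output directory is set — writes
#' per-analyte report JSON, model JSON and SEP-curve CSV plus a run
#' manifest (config hash, seed, versions). Reruns with the same config are
#' byte-identical in the report files.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Named list (per analyte) of `list(model, report)`, invisibly
#'   augmented with the generated `set`/`reference` in attribute `"data"`.
#' @export
run_calibration <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  if (is.null(config$design) &&
      (is.null(config$spectra) || is.null(config$reference))) {
    stop("config carries neither a design nor spectra plus reference",
         call. = FALSE)
  }
  if (!is.null(config$design)) {
    say("simulating calibration set (", design_sample_count(config$design),
        " samples, seed ", config$design$seed, ")")
    dat <- generate_calibration_set(config$design)
    set <- dat$set; ref <- dat$reference
  } else {
    set <- config$spectra; ref <- config$reference
    orphans <- join_report(set, ref)
    if (length(orphans$orphan_reference) || length(orphans$orphan_spectra)) {
      say("unmatched ids: ",
          length(orphans$orphan_reference), " reference-only, ",
          length(orphans$orphan_spectra), " spectra-only")
    }
  }
  out <- list()
  for (analyte in names(config$recipes)) {
    say("calibrating ", analyte, " ...")
    res <- tryCatch(
      calibrate_analyte(set, ref, analyte, config$recipes[[analyte]],
                        config$max_lv, config$scheme,
                        config$training_metrics),
      error = function(e) stop("calibration stage failed for analyte '",
                               analyte, "': ", conditionMessage(e),
                               call. = FALSE))
    say(sprintf("  %d LVs, SEP%% %.2f, variance %.1f%%, r %.3f -> %s",
                res$report$n_lv, res$report$sep_percent,
                res$report$variance, res$report$r, res$report$qc))
    out[[analyte]] <- res
  }
  if (!is.null(config$output_dir)) {
    write_calibration_artifacts(out, config)
  }
  attr(out, "data") <- list(set = set, reference = ref)
  invisible(out)
}

write_calibration_artifacts <- function(results, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (analyte in names(results)) {
    rep <- results[[analyte]]$report
    doc <- list(analyte = rep$analyte, n_samples = rep$n_samples,
                n_lv = rep$n_lv, sep = rep$sep,
                sep_percent = rep$sep_percent, variance = rep$variance,
                r = rep$r, qc = rep$qc)
    jsonlite::write_json(doc, file.path(config$output_dir,
                                        paste0("report_", analyte, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(rep$curve[, c("n_lv", "sep")]),
                     file.path(config$output_dir,
                               paste0("sep_curve_", analyte, ".csv")),
                     row.names = FALSE)
    save_pls1_model(results[[analyte]]$model,
                    file.path(config$output_dir,
                              paste0("model_", analyte, ".json")))
  }
  cfg_strip <- config[c("recipes", "max_lv", "scheme")]
  cfg_strip$design_seed <- config$design$seed
  tf <- tempfile(); on.exit(unlink(tf))
  saveRDS(cfg_strip, tf, version = 3)
  manifest <- list(
    config_hash = unname(tools::md5sum(tf)),
    seed = config$design$seed,
    n_samples = if (!is.null(config$design))
      design_sample_count(config$design),
    analytes = names(results),
    package_version = as.character(utils::packageVersion("ftirquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    date = format(Sys.Date())
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Predict analyte concentrations for a set of spectra
#'
#' Applies each model's own preprocessing recipe and predicts per-sample
#' concentrations. The total isoflavone content is reported twice: from the
#' dedicated total model (when present) and as the sum of the three
#' single-analyte predictions.
#'
#' @param models Named list of `pls1_model` objects (from
#'   [run_calibration()] results or [load_pls1_model()]).
#' @param set A [spectra_set()] of new spectra.
#' @return Data frame: `sample_id`, one column per analyte, companion
#'   `<analyte>_below_zero` flags, and `total_sum` (plus `total` from the
#'   dedicated model if supplied).
#' @export
run_prediction <- function(models, set) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$matrix) == 0L) {
    return(data.frame(sample_id = character(0)))
  }
  out <- data.frame(sample_id = set$sample_ids, stringsAsFactors = FALSE)
  singles <- intersect(c("daidzin", "genistin", "glycitin"), names(models))
  for (analyte in names(models)) {
    model <- models[[analyte]]
    stopifnot(inherits(model, "pls1_model"))
    design <- apply_recipe(set, model$recipe %||% preprocess_recipe())
    if (ncol(design$matrix) != length(model$x_mean)) {
      stop("design matrix for '", analyte, "' has ", ncol(design$matrix),
           " columns; model expects ", length(model$x_mean), call. = FALSE)
    }
    p <- predict(model, design$matrix)
    out[[analyte]] <- as.numeric(p)
    out[[paste0(analyte, "_below_zero")]] <- attr(p, "below_zero")
  }
  if (length(singles) == 3L) {
    out$total_sum <- out$daidzin + out$genistin + out$glycitin
  }
  out
}

#' Compare predicted totals with label declarations
#'
#' Converts per-aliquot predictions (mg per 500 ul) to per-dose contents
#' with an explicit, user-supplied conversion factor — the bridge between
#' extraction aliquot and capsule is a property of the preparation and is
#' never guessed — and reports each preparation's predicted content as a
#' percentage of its declaration.
#'
#' @param predicted Data frame with columns `preparation` and
#'   `predicted_total` (mg per 500 ul aliquot).
#' @param declared Data frame with columns `preparation` and
#'   `declared_total` (mg per dose), all > 0.
#' @param dose_conversion Multiplier from mg per 500 ul to mg per dose;
#'   scalar or named per preparation.
#' @param tolerance Half-width of the "conforms to declaration" band as a
#'   fraction of the declaration (default 0.20).
#' @return Data frame: `preparation`, `declared_total`, `predicted_total`
#'   (mg per dose), `percent_of_declared`, `conforms`.
#' @export
compare_to_declared <- function(predicted, declared, dose_conversion,
                                tolerance = 0.20) {
  stopifnot(all(c("preparation", "predicted_total") %in% names(predicted)),
            all(c("preparation", "declared_total") %in% names(declared)))
  missing_dec <- setdiff(predicted$preparation, declared$preparation)
  if (length(missing_dec)) {
    stop("no declaration for preparation '", missing_dec[1L], "'",
         call. = FALSE)
  }
  dec <- declared$declared_total[match(predicted$preparation,
                                       declared$preparation)]
  if (any(dec <= 0)) stop("declared totals must be > 0", call. = FALSE)
  conv <- if (length(dose_conversion) == 1L && is.null(names(dose_conversion))) {
    rep(dose_conversion, nrow(predicted))
  } else {
    cv <- dose_conversion[predicted$preparation]
    if (anyNA(cv)) stop("missing dose conversion for a preparation",
                        call. = FALSE)
    as.numeric(cv)
  }
  pred_dose <- predicted$predicted_total * conv
  pct <- 100 * pred_dose / dec
  data.frame(preparation = predicted$preparation,
             declared_total = dec,
             predicted_total = pred_dose,
             percent_of_declared = pct,
             conforms = abs(pct - 100) <= 100 * tolerance,
             stringsAsFactors = FALSE)
}
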