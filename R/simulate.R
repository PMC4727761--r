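#' Describe one absorption band
#'
#' @param center Band center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param amplitude Peak absorbance per (mg per 500 ul) of the component
#'   (absolute absorbance for fixed background bands).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A `band_spec`.
#' @export
band <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "band_spec")
}

#' Evaluate a pure-component spectrum from its band list
#'
#' Gaussian: `a * exp(-4 ln2 (v - c)^2 / fwhm^2)`; Lorentzian:
#' `a / (1 + (2 (v - c) / fwhm)^2)`. An empty band list yields a zero
#' vector.
#'
#' @param bands List of [band()] specs.
#' @param grid Ascending wavenumber vector.
#' @return Numeric vector on `grid` (absorbance per unit concentration).
#' @export
component_spectrum <- function(bands, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be ascending", call. = FALSE)
  out <- numeric(length(grid))
  for (b in bands) {
    out <- out + switch(b$shape,
      gaussian = b$amplitude * exp(-4 * log(2) * (grid - b$center)^2 / b$fwhm^2),
      lorentzian = b$amplitude / (1 + (2 * (grid - b$center) / b$fwhm)^2)
    )
  }
  out
}

#' Mass delivered by a spike volume of standard stock solution
#'
#' @param volume_ul Spiked volume in microlitres (>= 0).
#' @param stock_mg_per_ml Stock concentration, mg per mL (default 0.244, the
#'   standard stock used throughout).
#' @return Mass in mg.
#' @examples
#' spike_mass(100)        # 0.0244 mg
#' @export
spike_mass <- function(volume_ul, stock_mg_per_ml = 0.244) {
  if (any(volume_ul < 0)) stop("spike volume must be >= 0", call. = FALSE)
  stock_mg_per_ml * volume_ul / 1000
}

#' Simulation design for a spiking-based calibration set
#'
#' Encodes the standard-addition design the simulator emulates: an extract
#' with fixed base analyte levels, measured unspiked, spiked with single
#' standards over a range of volumes, and as two-analyte fractions with one
#' analyte removed. Spectra follow a Beer-Lambert linear mixture of the
#' analyte, interferent and matrix band profiles, distorted by additive
#' linear baseline drift, a multiplicative scatter factor and Gaussian
#' noise. The sample count is
#' `n_replicates * (n_base + 3 * length(spike_volumes) + length(two_analyte_combos))`.
#'
#' @param analyte_bands Named list (`daidzin`, `genistin`, `glycitin`) of
#'   band lists.
#' @param interferent_bands Band list of the uncorrelated interferent
#'   (red-clover stand-in).
#' @param matrix_bands Band list of the fixed extract-matrix background
#'   (absolute absorbance).
#' @param base_levels Named concentrations of the unspiked extract, mg per
#'   500 ul.
#' @param spike_volumes Spike volumes in ul drawn from the stock.
#' @param stock_concentration Stock concentration, mg per mL.
#' @param n_base Unspiked aliquots per replicate set.
#' @param two_analyte_combos Analytes removed one at a time to form
#'   two-analyte fraction samples.
#' @param n_replicates Independent measurement replicates of the whole
#'   layout (fresh drift/scatter/noise draws).
#' @param interferent_level Upper bound of the per-sample uniform
#'   interferent concentration (0 disables it).
#' @param baseline_drift List with `intercept` and `slope` ranges (AU and AU
#'   per cm^-1).
#' @param scatter_range Multiplicative scatter factor interval around 1.
#' @param noise_sd Gaussian noise SD, absorbance units.
#' @param grid Wavenumber grid, cm^-1.
#' @param seed Integer seed (mandatory); all randomness derives from it.
#' @return A `sim_design`.
#' @export
sim_design <- function(analyte_bands, interferent_bands, matrix_bands,
                       base_levels, spike_volumes,
                       stock_concentration = 0.244,
                       n_base = 3L,
                       two_analyte_combos = c("daidzin", "genistin", "glycitin"),
                       n_replicates = 1L,
                       interferent_level = 0,
                       baseline_drift = list(intercept = c(-0.02, 0.02),
                                             slope = c(-1e-5, 1e-5)),
                       scatter_range = c(0.97, 1.03),
                       noise_sd = 0.002,
                       grid = seq(650, 4000, by = 2),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  analytes <- c("daidzin", "genistin", "glycitin")
  stopifnot(all(analytes %in% names(analyte_bands)),
            all(analytes %in% names(base_levels)),
            all(two_analyte_combos %in% analytes))
  if (any(diff(range(baseline_drift$intercept)) < 0) ||
      baseline_drift$intercept[1] > baseline_drift$intercept[2] ||
      baseline_drift$slope[1] > baseline_drift$slope[2] ||
      scatter_range[1] > scatter_range[2]) {
    stop("drift/scatter ranges must be well-ordered", call. = FALSE)
  }
  structure(list(
    analyte_bands = analyte_bands, interferent_bands = interferent_bands,
    matrix_bands = matrix_bands,
    base_levels = base_levels[analytes],
    spike_volumes = as.numeric(spike_volumes),
    stock_concentration = stock_concentration,
    n_base = as.integer(n_base),
    two_analyte_combos = two_analyte_combos,
    n_replicates = as.integer(n_replicates),
    interferent_level = interferent_level,
    baseline_drift = baseline_drift,
    scatter_range = scatter_range,
    noise_sd = noise_sd,
    grid = as.numeric(grid),
    seed = as.integer(seed)
  ), class = "sim_design")
}

#' Number of samples a design generates
#' @param design A [sim_design()].
#' @return Integer sample count.
#' @export
design_sample_count <- function(design) {
  design$n_replicates *
    (design$n_base + 3L * length(design$spike_volumes) +
       length(design$two_analyte_combos))
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %d samples (%d rep x [%d base + 3x%d spikes + %d fractions]), seed %d\n",
              design_sample_count(x), x$n_replicates, x$n_base,
              length(x$spike_volumes), length(x$two_analyte_combos), x$seed))
  invisible(x)
}

#' Simulate one mixture spectrum
#'
#' Beer-Lambert linear mixing:
#' `x = g * (sum_k c_k s_k + matrix + alpha + beta * v) + noise`, with the
#' scatter factor g, drift intercept/slope and noise drawn from the design's
#' ranges under the given seed.
#'
#' @param concentrations Named vector with `daidzin`, `genistin`,
#'   `glycitin` and optionally `interferent`, mg per 500 ul (>= 0).
#' @param design A [sim_design()].
#' @param sample_id Sample identifier.
#' @param seed Integer seed for this sample's drift/scatter/noise draws.
#' @return A [spectrum()] on the design grid.
#' @export
simulate_mixture <- function(concentrations, design, sample_id, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (any(unlist(concentrations) < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  concentrations <- as.list(concentrations)
  grid <- design$grid
  signal <- numeric(length(grid))
  for (a in c("daidzin", "genistin", "glycitin")) {
    ca <- concentrations[[a]] %||% 0
    if (ca != 0) signal <- signal + ca * component_spectrum(design$analyte_bands[[a]], grid)
  }
  ci <- concentrations[["interferent"]] %||% 0
  if (ci != 0) signal <- signal + ci * component_spectrum(design$interferent_bands, grid)
  signal <- signal + component_spectrum(design$matrix_bands, grid)

  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  alpha <- stats::runif(1, design$baseline_drift$intercept[1],
                        design$baseline_drift$intercept[2])
  beta <- stats::runif(1, design$baseline_drift$slope[1],
                       design$baseline_drift$slope[2])
  g <- stats::runif(1, design$scatter_range[1], design$scatter_range[2])
  noise <- stats::rnorm(length(grid), 0, design$noise_sd)
  spectrum(sample_id, grid, g * (signal + alpha + beta * grid) + noise)
}

#' Generate a full spiking-design calibration set with ground truth
#'
#' Emits, per replicate: (a) `n_base` unspiked aliquots of the base extract;
#' (b) one sample per analyte per spike volume, the base extract plus the
#' spiked standard mass; (c) two-analyte fraction samples with one analyte
#' removed. Every sample gets fresh drift/scatter/noise draws from a
#' per-sample stream derived from the design seed; the interferent
#' concentration is drawn uniformly on `[0, interferent_level]`
#' independently of the analytes. The reference table carries the exact
#' ground-truth concentrations (no reference-measurement error), so method
#' error can be studied in isolation; see `reference_noise_sd` to add
#' HPLC-like reference error.
#'
#' @param design A [sim_design()].
#' @param reference_noise_sd Optional SD of Gaussian error added to the
#'   reported (not true) reference concentrations, mg per 500 ul.
#' @return List with `set` (a [spectra_set()]), `reference`
#'   (a `reference_table`, source `"SIMULATED"`), and `truth` (data frame of
#'   exact concentrations including the interferent).
#' @export
generate_calibration_set <- function(design, reference_noise_sd = 0) {
  stopifnot(inherits(design, "sim_design"))
  analytes <- c("daidzin", "genistin", "glycitin")
  layout <- design_concentration_layout(design)
  ids <- layout$sample_id
  conc <- as.matrix(layout[, analytes])
  n <- length(ids)
  stopifnot(n == design_sample_count(design))

  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(design$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  c_int <- stats::runif(n, 0, 1) * design$interferent_level
  ref_err <- matrix(stats::rnorm(3L * n, 0, 1), n, 3L) * reference_noise_sd

  mat <- matrix(0, n, length(design$grid))
  for (i in seq_len(n)) {
    sp <- simulate_mixture(
      c(as.list(conc[i, ]), interferent = c_int[i]),
      design, ids[i], sample_seeds[i])
    mat[i, ] <- sp$absorbance
  }
  truth <- data.frame(sample_id = ids, conc, interferent = c_int,
                      total = rowSums(conc), stringsAsFactors = FALSE)
  rep_conc <- pmax(conc + ref_err, 0)
  ref <- reference_table(
    data.frame(sample_id = ids, rep_conc, stringsAsFactors = FALSE),
    source = "SIMULATED")
  list(set = spectra_set(design$grid, mat, ids), reference = ref,
       truth = truth)
}

#' Concentration layout of a design (exact ground truth, no spectra)
#'
#' One row per sample the design generates, in generation order: unspiked
#' base aliquots, single-standard spikes, two-analyte fractions, repeated
#' per replicate.
#'
#' @param design A [sim_design()].
#' @return Data frame: `sample_id`, `daidzin`, `genistin`, `glycitin`
#'   (mg per 500 ul).
#' @export
design_concentration_layout <- function(design) {
  analytes <- c("daidzin", "genistin", "glycitin")
  rows <- list()
  for (r in seq_len(design$n_replicates)) {
    for (b in seq_len(design$n_base)) {
      rows[[length(rows) + 1L]] <- c(
        id = sprintf("base%02d_r%d", b, r), design$base_levels)
    }
    for (a in analytes) {
      for (v in design$spike_volumes) {
        cc <- design$base_levels
        cc[[a]] <- cc[[a]] + spike_mass(v, design$stock_concentration)
        rows[[length(rows) + 1L]] <- c(
          id = sprintf("spike_%s_%04.0ful_r%d", a, v, r), cc)
      }
    }
    for (a in design$two_analyte_combos) {
      cc <- design$base_levels
      cc[[a]] <- 0
      rows[[length(rows) + 1L]] <- c(id = sprintf("frac_no_%s_r%d", a, r), cc)
    }
  }
  conc <- do.call(rbind, lapply(rows, function(x) as.numeric(x[analytes])))
  colnames(conc) <- analytes
  data.frame(sample_id = vapply(rows, function(x) x[["id"]], character(1)),
             conc, stringsAsFactors = FALSE)
}

#' Generate an independent test set within the calibration domain
#'
#' Each test composition is a random convex combination of `k` design
#' concentration points, so test samples stay inside the concentration
#' domain the calibration spans — the validity domain of any calibration
#' model — while mixing all three analytes simultaneously (unlike the
#' single-standard spiking layout). The interferent is drawn independently;
#' spectra use the same distortion model as the calibration set.
#'
#' @param design A [sim_design()].
#' @param n Number of test samples.
#' @param seed Integer seed, independent of the design seed.
#' @param k Number of design points mixed per test sample (default 4).
#' @return List with `set`, `reference` and `truth`, as in
#'   [generate_calibration_set()].
#' @export
generate_test_set <- function(design, n, seed, k = 4L) {
  stopifnot(inherits(design, "sim_design"), n >= 1L, k >= 1L)
  analytes <- c("daidzin", "genistin", "glycitin")
  vertices <- as.matrix(design_concentration_layout(design)[, analytes])
  vertices <- unique(vertices)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  conc <- matrix(0, n, 3L, dimnames = list(NULL, analytes))
  for (i in seq_len(n)) {
    pick <- sample.int(nrow(vertices), k, replace = TRUE)
    w <- stats::rexp(k)
    w <- w / sum(w)
    conc[i, ] <- drop(w %*% vertices[pick, , drop = FALSE])
  }
  c_int <- stats::runif(n, 0, 1) * design$interferent_level
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("test%03d", seq_len(n))
  mat <- matrix(0, n, length(design$grid))
  for (i in seq_len(n)) {
    sp <- simulate_mixture(
      c(as.list(conc[i, ]), interferent = c_int[i]),
      design, ids[i], sample_seeds[i])
    mat[i, ] <- sp$absorbance
  }
  truth <- data.frame(sample_id = ids, conc, interferent = c_int,
                      total = rowSums(conc), stringsAsFactors = FALSE)
  ref <- reference_table(
    data.frame(sample_id = ids, conc, stringsAsFactors = FALSE),
    source = "SIMULATED")
  list(set = spectra_set(design$grid, mat, ids), reference = ref,
       truth = truth)
}

#' Default band sets for the three analytes, interferent and matrix
#'
#' Invented mid-IR band patterns: 5 overlapping bands per analyte in the
#' fingerprint region (1800-900 cm^-1) with pairwise overlap inside
#' 1500-900 cm^-1 — overlap is the phenomenon PLS must resolve — plus a
#' broad carbohydrate-rich extract background and a red-clover-like
#' interferent sharing the analyte windows. Amplitudes put the analytes in
#' the minor-component regime (peak contributions of a few hundredths of an
#' absorbance unit atop a matrix background an order of magnitude larger),
#' the situation of a supplement extract and the regime in which SNV row
#' scaling removes scatter without distorting Beer-Lambert linearity.
#'
#' @return Named list `analytes` (list of 3 band lists), `interferent`,
#'   `matrix`.
#' @export
default_band_sets <- function() {
  list(
    analytes = list(
      daidzin = list(band(1630, 35, 1.50), band(1512, 25, 1.17),
                     band(1258, 30, 1.00), band(1070, 30, 1.67),
                     band(1040, 25, 0.83, "lorentzian")),
      genistin = list(band(1650, 30, 1.67), band(1515, 22, 1.00),
                      band(1290, 28, 1.17), band(1180, 30, 1.33),
                      band(1065, 28, 1.50)),
      glycitin = list(band(1620, 30, 1.33), band(1575, 25, 1.00),
                      band(1440, 30, 1.17), band(1205, 35, 1.50),
                      band(1025, 30, 1.33))
    ),
    interferent = list(band(1622, 30, 1.33), band(1512, 25, 1.00),
                       band(1445, 28, 1.00), band(1210, 32, 1.33),
                       band(1030, 28, 1.17, "lorentzian")),
    matrix = list(band(3350, 350, 0.60), band(2928, 70, 0.25),
                  band(1742, 40, 0.30), band(1640, 90, 0.50),
                  band(1540, 60, 0.35), band(1415, 70, 0.40),
                  band(1245, 90, 0.45), band(1055, 130, 1.10),
                  band(925, 55, 0.20))
  )
}

#' Default study-scale simulation design (335 samples)
#'
#' The layout emulates a spiking-based calibration campaign totalling 335
#' samples: 5 replicate measurement series of 10 unspiked aliquots, 18
#' single-standard spike volumes (25-450 ul of the 0.244 mg/mL stock) per
#' analyte, and 3 two-analyte fractions — 5 x (10 + 54 + 3) = 335. Base
#' levels, band shapes and distortion magnitudes are plausible artifact
#' defaults, not measured values.
#'
#' @param seed Integer seed.
#' @return A [sim_design()] generating 335 samples.
#' @export
default_paper_like_design <- function(seed = 1L) {
  bs <- default_band_sets()
  sim_design(
    analyte_bands = bs$analytes,
    interferent_bands = bs$interferent,
    matrix_bands = bs$matrix,
    base_levels = c(daidzin = 0.025, genistin = 0.048, glycitin = 0.012),
    spike_volumes = seq(25, 450, by = 25),
    n_base = 10L,
    n_replicates = 5L,
    interferent_level = 0.01,
    seed = seed
  )
}
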