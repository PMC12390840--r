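#' Ground-truth calibration curve for one mineral and DOC end member
#'
#' Holds the generating parameters of a synthetic co-precipitation
#' calibration: a Freundlich loading isotherm `loading(x) = k_F * x^n_F`
#' (wt% organic carbon as a function of the DOC/Fe(III) mole ratio `x`) and
#' a dual-exponential isotope offset
#' `Delta13C(x) = a1 * exp(-x/x1) + a2 * exp(-x/x2)` (permil) that converges
#' to zero at high `x`. These objects parameterize the synthetic generators
#' and serve as recovery targets for the fitting routines.
#'
#' @param mineral `"goethite"` or `"haematite"`.
#' @param endmember DOC end member: `"M-DOC"` (marine eukaryote analogue),
#'   `"C-DOC"` (cyanobacterial leachate) or `"FA"` (terrestrial fulvic acid).
#' @param k_F Loading prefactor, wt% at `x = 1`. Must be positive.
#' @param n_F Freundlich exponent, in (0, 1].
#' @param a1,a2 Isotope-offset amplitudes, permil.
#' @param x1,x2 Isotope-offset decay scales (dimensionless DOC/Fe ratios),
#'   positive.
#' @param d13c_doc delta13C of the DOC substrate, permil VPDB (used by the
#'   co-precipitation table generator).
#' @return An object of class `feoc_true_calibration`.
#' @seealso [default_truth()], [generate_coprecip_table()]
#' @export
true_calibration <- function(mineral, endmember, k_F, n_F,
                             a1 = 0, a2 = 0, x1 = 0.05, x2 = 0.5,
                             d13c_doc = -21) {
  mineral <- match.arg(mineral, .feoc_minerals)
  endmember <- match.arg(endmember, .feoc_endmembers)
  .assert(.is_num(k_F, 1) && k_F > 0, "k_F must be a positive number",
          "feoc_domain_error")
  .assert(.is_num(n_F, 1) && n_F > 0 && n_F <= 1,
          "n_F must lie in (0, 1]", "feoc_domain_error")
  .assert(.is_num(x1, 1) && x1 > 0 && .is_num(x2, 1) && x2 > 0,
          "decay scales x1, x2 must be positive", "feoc_domain_error")
  structure(list(mineral = mineral, endmember = endmember,
                 k_F = k_F, n_F = n_F, a1 = a1, a2 = a2, x1 = x1, x2 = x2,
                 d13c_doc = d13c_doc),
            class = "feoc_true_calibration")
}

#' Evaluate a ground-truth calibration
#'
#' @param truth A [true_calibration()] object.
#' @param x DOC/Fe(III) mole ratio(s), positive.
#' @return A list with numeric vectors `loading` (wt%) and `delta` (permil).
#' @export
true_curves <- function(truth, x) {
  .assert(all(x > 0), "x must be positive", "feoc_domain_error")
  list(loading = truth$k_F * x^truth$n_F,
       delta = truth$a1 * exp(-x / truth$x1) + truth$a2 * exp(-x / truth$x2))
}

#' Default ground-truth calibration set
#'
#' A complete set of generating curves for two minerals (goethite,
#' haematite) and three DOC end members. Parameters are chosen so that
#' loadings span roughly 0.03-0.5 wt% over a three-decade DOC/Fe(III)
#' range of 0.003-3, matching the dynamic range of geologic iron-ooid
#' records, and so that isotope offsets are a few permil in magnitude,
#' negative (the co-precipitate is slightly 13C-enriched relative to the
#' substrate DOC) and converge to zero at high `x`.
#'
#' @return A named list of [true_calibration()] objects keyed
#'   `"mineral|endmember"`.
#' @export
default_truth <- function() {
  specs <- list(
    list("goethite",  "M-DOC", 0.32, 0.38, -6.0, -4.0, 0.05, 0.50, -21),
    list("goethite",  "C-DOC", 0.22, 0.45, -8.0, -3.0, 0.04, 0.60, -15),
    list("goethite",  "FA",    0.42, 0.30, -5.0, -5.0, 0.06, 0.40, -27),
    list("haematite", "M-DOC", 0.26, 0.40, -7.0, -3.5, 0.05, 0.55, -21),
    list("haematite", "C-DOC", 0.18, 0.47, -9.0, -2.5, 0.04, 0.65, -15),
    list("haematite", "FA",    0.36, 0.32, -5.5, -4.5, 0.06, 0.45, -27))
  out <- lapply(specs, function(s)
    true_calibration(s[[1]], s[[2]], k_F = s[[3]], n_F = s[[4]],
                     a1 = s[[5]], a2 = s[[6]], x1 = s[[7]], x2 = s[[8]],
                     d13c_doc = s[[9]]))
  names(out) <- vapply(out, function(t) .pair_key(t$mineral, t$endmember), "")
  out
}

#' Design of a synthetic co-precipitation experiment
#'
#' @param x_min,x_max Bounds of the DOC/Fe(III) mole ratio grid; the grid is
#'   log-spaced (the calibration experiments span about three orders of
#'   magnitude). `x_max/x_min` must span at least one decade.
#' @param points_per_decade Number of grid points per decade.
#' @param replicates Replicate analyses per ratio and condition (triplicate
#'   elemental-analyser measurements by default).
#' @param sigma_load_abs Additive loading noise, wt% (1 sigma).
#' @param sigma_load_rel Multiplicative loading noise, fraction of the true
#'   loading (1 sigma).
#' @param sigma_delta delta13C noise, permil (1 sigma); the default 0.2
#'   reflects typical instrument reproducibility.
#' @param condition_grid Data frame of synthesis conditions with columns
#'   `temperature` (deg C), `pH`, `duration` (days), `fe_source`
#'   (`"FeCl3"`/`"FeNO3"`), `doc_timing` (`"pre"`/`"post"`) and `fraction`
#'   (`"raw"`, `"-Fh/PC"` or `"-Fh/PC-ads.OC"`).
#' @return An object of class `feoc_experiment_design`.
#' @export
experiment_design <- function(x_min = 0.003, x_max = 3,
                              points_per_decade = 10, replicates = 3,
                              sigma_load_abs = 0.01, sigma_load_rel = 0.05,
                              sigma_delta = 0.2,
                              condition_grid = default_conditions()) {
  .assert(x_min > 0, "x_min must be positive", "feoc_domain_error")
  .assert(x_max / x_min >= 10, "x grid must span at least one decade",
          "feoc_domain_error")
  .assert(all(c(sigma_load_abs, sigma_load_rel, sigma_delta) >= 0),
          "noise magnitudes must be non-negative", "feoc_domain_error")
  .assert(is.data.frame(condition_grid) && nrow(condition_grid) >= 1,
          "condition_grid must be a non-empty data frame", "feoc_domain_error")
  structure(list(x_min = x_min, x_max = x_max,
                 points_per_decade = points_per_decade,
                 replicates = replicates,
                 sigma_load_abs = sigma_load_abs,
                 sigma_load_rel = sigma_load_rel,
                 sigma_delta = sigma_delta,
                 condition_grid = condition_grid),
            class = "feoc_experiment_design")
}

#' Default synthesis-condition grid
#'
#' One environmentally relevant condition (20 deg C, pH 7, 30 days, FeCl3,
#' post-ferrihydrite DOC addition) on the geologically preserved
#' `-Fh/PC-ads.OC` fraction.
#'
#' @param extreme If `TRUE`, append a 95 deg C row, a pH 11.5 row and a raw
#'   fraction row, the conditions and fraction the default selection policy
#'   excludes; useful for exercising the filter.
#' @return Data frame of condition records.
#' @export
default_conditions <- function(extreme = FALSE) {
  base <- data.frame(temperature = 20, pH = 7, duration = 30,
                     fe_source = "FeCl3", doc_timing = "post",
                     fraction = "-Fh/PC-ads.OC",
                     stringsAsFactors = FALSE)
  if (!extreme) return(base)
  rbind(base,
        data.frame(temperature = 95, pH = 7, duration = 30,
                   fe_source = "FeCl3", doc_timing = "post",
                   fraction = "-Fh/PC-ads.OC"),
        data.frame(temperature = 20, pH = 11.5, duration = 30,
                   fe_source = "FeCl3", doc_timing = "post",
                   fraction = "-Fh/PC-ads.OC"),
        data.frame(temperature = 20, pH = 7, duration = 30,
                   fe_source = "FeCl3", doc_timing = "post",
                   fraction = "raw"))
}

#' Ground-truth DOC history for the synthetic geologic record
#'
#' Defines the "true" relative DOC concentration `[DOC]*` and
#' `delta13C_DOC` as functions of age, plus the formations sampled and the
#' measurement noise. The default history is the three-state trajectory the
#' record archive motivates: near-modern `[DOC]*` in the late
#' Palaeoproterozoic-Mesoproterozoic, a 95% drop in the Neoproterozoic, and
#' a return to modern levels in the Phanerozoic, with `delta13C_DOC` about
#' 18 permil lower than today throughout the Proterozoic.
#'
#' @param doc_star Function of age (Ma) returning relative DOC
#'   concentration; must satisfy `doc_star(0) == 1`.
#' @param d13c_doc Function of age (Ma) returning delta13C_DOC (permil VPDB).
#' @param formations Data frame with columns `formation`, `age` (Ma, within
#'   0-1650), `mineral` and `n_samples`.
#' @param x_modern Modern DOC/Fe(III) mole ratio anchoring the record
#'   (constant-iron-flux assumption).
#' @param sigma_load_meas Loading measurement noise, wt% (1 sigma).
#' @param sigma_d13c_meas delta13C measurement noise, permil (1 sigma).
#' @return An object of class `feoc_true_history`.
#' @export
true_history <- function(doc_star = three_state_doc_star(),
                         d13c_doc = function(age) ifelse(age > 540, -38, -20),
                         formations = default_formations(),
                         x_modern = 1,
                         sigma_load_meas = 0.01,
                         sigma_d13c_meas = 0.2) {
  .assert(is.function(doc_star) && is.function(d13c_doc),
          "doc_star and d13c_doc must be functions of age",
          "feoc_domain_error")
  .assert(abs(doc_star(0) - 1) < 1e-12,
          "doc_star must equal 1 at age 0 (modern reference identity)",
          "feoc_domain_error")
  .assert(is.data.frame(formations) &&
            all(c("formation", "age", "mineral", "n_samples") %in%
                  names(formations)),
          "formations needs columns formation, age, mineral, n_samples",
          "feoc_domain_error")
  .assert(all(formations$age >= 0 & formations$age <= 1650),
          "formation ages must lie within 0-1650 Ma", "feoc_domain_error")
  .assert(all(formations$mineral %in% .feoc_minerals),
          "unknown mineral in formations", "feoc_domain_error")
  structure(list(doc_star = doc_star, d13c_doc = d13c_doc,
                 formations = formations, x_modern = x_modern,
                 sigma_load_meas = sigma_load_meas,
                 sigma_d13c_meas = sigma_d13c_meas),
            class = "feoc_true_history")
}

#' Three-state relative DOC history
#'
#' Piecewise-constant `[DOC]*` trajectory: `modern_level` for ages up to
#' `break_young`, `low_level` between `break_young` and `break_old`
#' (the Neoproterozoic drop) and `old_level` beyond `break_old`.
#'
#' @param low_level Neoproterozoic `[DOC]*` (default 0.05, i.e. a 95% drop).
#' @param break_young,break_old Ages (Ma) bounding the low state.
#' @param modern_level,old_level `[DOC]*` outside the low state.
#' @return A function of age (Ma).
#' @export
three_state_doc_star <- function(low_level = 0.05, break_young = 540,
                                 break_old = 1000, modern_level = 1,
                                 old_level = 1) {
  force(low_level); force(break_young); force(break_old)
  force(modern_level); force(old_level)
  function(age) {
    ifelse(age > break_old, old_level,
           ifelse(age > break_young, low_level, modern_level))
  }
}

#' Default synthetic formation table
#'
#' 26 formations totalling 100 samples over 0-1650 Ma, mirroring the size
#' and age structure of the geologic iron-ooid archive: two actively
#' forming modern goethite sites, Phanerozoic goethite and haematite
#' formations (including temporally overlapping Ordovician mineralogies)
#' and a Proterozoic suite extending to the late Palaeoproterozoic.
#'
#' @return Data frame with columns `formation`, `age`, `mineral`,
#'   `n_samples`.
#' @export
default_formations <- function() {
  f <- data.frame(
    formation = c("Modern-A", "Modern-B", "Bakchar", "Cenomanian-A",
                  "Aptian-A", "Callovian-A", "Bajocian-A", "Toarcian-A",
                  "Famennian-A", "Silurian-A", "Aseri-like", "Sillaoru-like",
                  "Ordovician-H1", "Ordovician-H2", "Cambrian-A",
                  "Ediacaran-A", "Cryogenian-A", "Tonian-A", "Tonian-B",
                  "Stenian-A", "Stenian-B", "Ectasian-A", "Ectasian-B",
                  "Calymmian-A", "Calymmian-B", "Statherian-A"),
    age = c(0, 0, 56, 100, 120, 165, 170, 180, 365, 430, 462, 464, 460, 466,
            510, 580, 660, 750, 780, 1050, 1100, 1250, 1300, 1450, 1500,
            1640),
    mineral = c("goethite", "goethite", "goethite", "goethite", "goethite",
                "goethite", "goethite", "goethite", "haematite", "goethite",
                "goethite", "goethite", "haematite", "haematite",
                "haematite", "goethite", "goethite", "goethite", "haematite",
                "goethite", "haematite", "goethite", "haematite", "goethite",
                "haematite", "goethite"),
    n_samples = c(2, 2, 3, 3, 3, 6, 5, 5, 3, 3, 4, 3, 3, 2, 6, 4, 4, 4, 4,
                  4, 4, 5, 4, 5, 4, 5),
    stringsAsFactors = FALSE)
  stopifnot(nrow(f) == 26, sum(f$n_samples) == 100)
  f
}

#' Raman scan phantom definition
#'
#' Describes a synthetic Raman scan with known ground truth: a spatial grid
#' of pixels, a boolean organic-carbon mask, a polynomial baseline, mineral
#' bands, and a G-band (1590 cm-1) present only where the mask is true.
#' The signal-to-noise ratio is defined as G-band amplitude over the
#' Gaussian noise standard deviation.
#'
#' @param grid_shape Integer (rows, cols) of the scan.
#' @param oc_mask Logical matrix of `grid_shape` marking Fe-OC-bearing
#'   pixels; default a centred disc covering roughly half the pixels.
#' @param wavenumber_grid Ascending wavenumbers (cm-1) covering at least
#'   300-1800.
#' @param baseline_coeffs Polynomial baseline coefficients (increasing
#'   order, in wavenumber/1000 units); cubic by default.
#' @param mineral_peaks Data frame `centre`, `width`, `amplitude` of
#'   mineral bands; defaults to three goethite-like bands below 700 cm-1.
#' @param gband `c(centre, width, amplitude)` of the organic G-band.
#' @param snr G-band amplitude divided by noise sigma; `Inf` for noiseless.
#' @return An object of class `feoc_raman_phantom`.
#' @export
raman_phantom <- function(grid_shape = c(20, 20),
                          oc_mask = NULL,
                          wavenumber_grid = seq(200, 1900, by = 2),
                          baseline_coeffs = c(120, 30, -12, 2),
                          mineral_peaks = data.frame(
                            centre = c(299, 385, 550),
                            width = c(10, 12, 14),
                            amplitude = c(300, 450, 250)),
                          gband = c(centre = 1590, width = 30,
                                    amplitude = 100),
                          snr = 10) {
  .assert(length(grid_shape) == 2 && all(grid_shape >= 1),
          "grid_shape must be (rows, cols)", "feoc_domain_error")
  .assert(all(diff(wavenumber_grid) > 0),
          "wavenumber grid must be strictly increasing", "feoc_domain_error")
  .assert(min(wavenumber_grid) <= 300 && max(wavenumber_grid) >= 1800,
          "wavenumber grid must cover 300-1800 cm-1", "feoc_domain_error")
  if (is.null(oc_mask)) {
    r <- grid_shape[1]; c <- grid_shape[2]
    rows <- matrix(seq_len(r), r, c)
    cols <- matrix(seq_len(c), r, c, byrow = TRUE)
    rad <- sqrt(((rows - (r + 1) / 2) / r)^2 + ((cols - (c + 1) / 2) / c)^2)
    oc_mask <- rad <= 0.4
  }
  .assert(is.logical(oc_mask) && all(dim(oc_mask) == grid_shape),
          "oc_mask must be a logical matrix of grid_shape",
          "feoc_domain_error")
  .assert(snr > 0, "snr must be positive", "feoc_domain_error")
  structure(list(grid_shape = as.integer(grid_shape), oc_mask = oc_mask,
                 wavenumber_grid = wavenumber_grid,
                 baseline_coeffs = baseline_coeffs,
                 mineral_peaks = mineral_peaks, gband = gband, snr = snr),
            class = "feoc_raman_phantom")
}
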