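#' Raman processing parameters
#'
#' Bundles the processing chain settings: crop window 300-1800 cm-1
#' (covering the mineral and organic signals), Savitzky-Golay smoothing
#' (polynomial order 3, window 5), polynomial baseline subtraction (first
#' or third order), the band-ratio windows 1450-1700 cm-1 (containing the
#' diagnostic G-band at 1590 cm-1) over 1200-1450 cm-1 (an Fe-OC
#' insensitive background window), and the classification threshold.
#'
#' @param window Crop window, cm-1.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and (odd)
#'   window length in points.
#' @param baseline_order Baseline polynomial order, 1 or 3.
#' @param num_window,den_window Integration windows of the band ratio.
#' @param threshold Classification threshold on the band ratio (`NULL`
#'   until calibrated).
#' @return An object of class `feoc_raman_params`.
#' @export
raman_params <- function(window = c(300, 1800), sg_order = 3, sg_window = 5,
                         baseline_order = 3,
                         num_window = c(1450, 1700),
                         den_window = c(1200, 1450),
                         threshold = NULL) {
  .assert(sg_window %% 2 == 1 && sg_window > sg_order,
          "sg_window must be odd and exceed sg_order", "feoc_domain_error")
  .assert(baseline_order %in% c(1, 3), "baseline_order must be 1 or 3",
          "feoc_domain_error")
  .assert(num_window[1] >= window[1] && num_window[2] <= window[2] &&
            den_window[1] >= window[1] && den_window[2] <= window[2],
          "integration windows must lie within the crop window",
          "feoc_domain_error")
  .assert(is.null(threshold) || threshold > 0,
          "threshold must be positive", "feoc_domain_error")
  structure(list(window = window, sg_order = sg_order,
                 sg_window = sg_window, baseline_order = baseline_order,
                 num_window = num_window, den_window = den_window,
                 threshold = threshold),
            class = "feoc_raman_params")
}

#' Preprocess a Raman spectrum
#'
#' Crops to the processing window, smooths with a Savitzky-Golay filter
#' and subtracts an iteratively fitted polynomial baseline: the polynomial
#' is refit with points above the current fit clipped down to it until
#' convergence, so bands ride on top of the estimated baseline instead of
#' dragging it up (the standard modified-polyfit scheme for Raman
#' spectra). A spectrum that is itself a polynomial of the baseline order
#' is annihilated, and because the smoothing filter reproduces such
#' polynomials exactly, the result is invariant to adding any polynomial
#' of the baseline order to the raw spectrum.
#'
#' @param spectrum Data frame with strictly increasing `wavenumber` (cm-1)
#'   and finite `intensity`.
#' @param params A [raman_params()].
#' @return Data frame `wavenumber`, `intensity` (baseline-subtracted).
#' @export
preprocess_spectrum <- function(spectrum, params = raman_params()) {
  w <- spectrum$wavenumber; y <- spectrum$intensity
  .assert(all(diff(w) > 0), "wavenumbers must be strictly increasing",
          "feoc_data_error")
  .assert(all(is.finite(y)), "intensities must be finite", "feoc_data_error")
  keep <- w >= params$window[1] & w <= params$window[2]
  .assert(sum(keep) >= params$sg_window,
          "too few points inside the processing window", "feoc_data_error")
  w <- w[keep]; y <- y[keep]
  ys <- signal::sgolayfilt(y, p = params$sg_order, n = params$sg_window)
  # centred, scaled abscissa keeps the normal equations well conditioned
  t_scaled <- (w - mean(w)) / (diff(range(w)) / 2)
  X <- outer(t_scaled, 0:params$baseline_order, `^`)
  XtXinv_Xt <- solve(crossprod(X), t(X))
  work <- ys
  scale <- max(abs(ys), 1)
  for (it in seq_len(200L)) {
    base <- as.numeric(X %*% (XtXinv_Xt %*% work))
    clipped <- pmin(work, base)
    if (max(abs(clipped - work)) < 1e-10 * scale) { work <- clipped; break }
    work <- clipped
  }
  base <- as.numeric(X %*% (XtXinv_Xt %*% work))
  data.frame(wavenumber = w, intensity = as.numeric(ys - base))
}

#' Band-ratio statistic of a processed spectrum
#'
#' Trapezoidal integral of the (zero-floored) intensity over the G-band
#' window divided by the integral over the background window. A
#' non-positive denominator marks a degenerate pixel: the ratio is 0 when
#' the numerator is also non-positive and `Inf` otherwise, and the
#' `degenerate` attribute is set; degenerate pixels are reported, never
#' dropped.
#'
#' @param processed Output of [preprocess_spectrum()].
#' @param params A [raman_params()].
#' @return Numeric ratio with logical attribute `degenerate`.
#' @export
band_ratio <- function(processed, params = raman_params()) {
  w <- processed$wavenumber
  y <- pmax(0, processed$intensity)
  .assert(min(w) <= params$den_window[1] && max(w) >= params$num_window[2],
          "processed spectrum does not cover the integration windows",
          "feoc_data_error")
  integ <- function(win) {
    i <- w >= win[1] & w <= win[2]
    .trapz(w[i], y[i])
  }
  num <- integ(params$num_window)
  den <- integ(params$den_window)
  # a denominator that is zero, or negligible against the numerator,
  # carries no background signal to normalize by
  if (den <= 1e-9 * max(num, .Machine$double.eps)) {
    ratio <- if (num <= 0) 0 else Inf
    attr(ratio, "degenerate") <- TRUE
  } else {
    ratio <- num / den
    attr(ratio, "degenerate") <- FALSE
  }
  ratio
}

#' Calibrate a conservative classification threshold
#'
#' The threshold is the maximum band ratio observed on pixels known to be
#' free of Fe-OC (e.g. epoxy resin or silicate/carbonate cement), so that
#' every known-negative pixel classifies as absent under the strict
#' `ratio > threshold` rule. An optional multiplicative margin can widen
#' it further.
#'
#' @param negative_ratios Band ratios of known Fe-OC-free pixels.
#' @param margin Fractional margin added on top of the maximum.
#' @return Threshold value.
#' @export
calibrate_threshold <- function(negative_ratios, margin = 0) {
  .assert(length(negative_ratios) >= 1,
          "need at least one known-negative ratio", "feoc_data_error")
  max(negative_ratios) * (1 + margin)
}

#' Classify a Raman scan into an Fe-OC presence map
#'
#' Runs preprocess, band ratio and thresholding per pixel. Presence uses
#' the strict inequality `ratio > threshold`, so a pixel exactly at the
#' (conservative, max-over-negatives) threshold classifies as absent.
#' Haematite scans are classified but flagged low-confidence: the strong
#' haematite band near 1300 cm-1 can obscure the G-band, so a negative
#' result is not reliable evidence of absence in haematite.
#'
#' @param scan A `feoc_scan` ([generate_raman_scan()]) or list with
#'   `positions`, `wavenumber` and `intensity` matrix.
#' @param params A [raman_params()] with `threshold` set, unless
#'   `negative_pixels` is given.
#' @param negative_pixels Optional integer indices of known Fe-OC-free
#'   pixels used to calibrate the threshold from this scan.
#' @param mineral Scan mineralogy; `"haematite"` sets the low-confidence
#'   flag.
#' @return A `feoc_binary_map`: data frame `row`, `col`, `ratio`,
#'   `presence`, `degenerate`; attributes `threshold` and
#'   `low_confidence`.
#' @export
classify_scan <- function(scan, params = raman_params(),
                          negative_pixels = NULL, mineral = "goethite") {
  .assert(is.matrix(scan$intensity) &&
            ncol(scan$intensity) == length(scan$wavenumber),
          "all spectra must share one wavenumber grid", "feoc_data_error")
  npix <- nrow(scan$intensity)
  ratios <- numeric(npix)
  degen <- logical(npix)
  for (p in seq_len(npix)) {
    sp <- data.frame(wavenumber = scan$wavenumber,
                     intensity = scan$intensity[p, ])
    r <- band_ratio(preprocess_spectrum(sp, params), params)
    ratios[p] <- as.numeric(r)
    degen[p] <- attr(r, "degenerate")
  }
  threshold <- params$threshold
  if (!is.null(negative_pixels)) {
    threshold <- calibrate_threshold(ratios[negative_pixels])
  }
  .assert(!is.null(threshold),
          "no threshold: set params$threshold or supply negative_pixels",
          "feoc_config_error")
  out <- data.frame(row = scan$positions$row, col = scan$positions$col,
                    ratio = ratios, presence = ratios > threshold,
                    degenerate = degen)
  structure(out, threshold = threshold,
            low_confidence = identical(mineral, "haematite"),
            class = c("feoc_binary_map", "data.frame"))
}

#' Diffraction-limited spatial resolution
#'
#' Abbe/Rayleigh estimate `1.22 * lambda / NA` for a confocal Raman
#' microscope; with a 532 nm laser and a 0.25 numerical-aperture objective
#' this gives 2.6 micrometres.
#'
#' @param lambda_nm Laser wavelength, nm.
#' @param na Numerical aperture of the objective.
#' @return Resolution in micrometres.
#' @export
diffraction_limit <- function(lambda_nm = 532, na = 0.25) {
  .assert(lambda_nm > 0 && na > 0,
          "wavelength and numerical aperture must be positive",
          "feoc_domain_error")
  1.22 * lambda_nm / na / 1000
}
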