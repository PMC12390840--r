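#' Fit a CDOM spectral slope
#'
#' Fits `a(lambda) = a_ref * exp(-S * (lambda - lambda_ref))` over a
#' wavelength range, with the reference wavelength fixed to the lower bound
#' of the range so `a_ref` is the fitted absorption there. The default fit
#' is nonlinear least squares on the linear absorption scale, started from
#' (and falling back to) a log-linear regression; with `log_scale = TRUE`
#' the log-linear regression estimate itself is returned.
#'
#' @param spectrum Data frame with ascending `wavelength` (nm) and
#'   non-negative `absorption` (m-1).
#' @param lambda_lo,lambda_hi Fitting range (nm); the conventional ranges
#'   are 275-295 and 350-400.
#' @param log_scale Fit by ordinary regression of `log(a)` instead of
#'   nonlinear least squares.
#' @return A `feoc_slope_fit`: `S` (nm-1), `a_ref` (m-1), `range`, `rmse`
#'   (linear scale).
#' @export
fit_spectral_slope <- function(spectrum, lambda_lo, lambda_hi,
                               log_scale = FALSE) {
  .assert(lambda_lo < lambda_hi, "lambda_lo must be below lambda_hi",
          "feoc_domain_error")
  wl <- spectrum$wavelength; a <- spectrum$absorption
  .assert(all(diff(wl) > 0), "wavelengths must be strictly increasing",
          "feoc_domain_error")
  in_range <- wl >= lambda_lo & wl <= lambda_hi
  pos <- in_range & a > 0
  .assert(sum(pos) >= 3,
          "need at least 3 positive absorbances within the fitting range",
          "feoc_domain_error")
  w <- wl[pos] - lambda_lo; y <- a[pos]
  ll <- lm(log(y) ~ w)
  S0 <- -unname(coef(ll)[2]); aref0 <- exp(unname(coef(ll)[1]))
  est <- c(a_ref = aref0, S = S0)
  if (!log_scale) {
    ssr0 <- sum((y - aref0 * exp(-S0 * w))^2)
    if (ssr0 > 1e-25 * sum(y^2)) {
      df <- data.frame(w = w, y = y)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a_ref * exp(-S * w), data = df,
                          start = list(a_ref = aref0, S = S0),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(fit)) est <- coef(fit)[c("a_ref", "S")]
    }
  }
  resid <- y - est[["a_ref"]] * exp(-est[["S"]] * w)
  structure(list(S = est[["S"]], a_ref = est[["a_ref"]],
                 range = c(lambda_lo, lambda_hi),
                 rmse = sqrt(mean(resid^2)), n_points = length(y)),
            class = "feoc_slope_fit")
}

#' Spectral slope ratio
#'
#' `S_R = S(275-295) / S(350-400)`, an optical proxy for DOC molecular
#' weight and aromaticity.
#'
#' @param fit_275_295,fit_350_400 [fit_spectral_slope()] results (or bare
#'   numeric slopes).
#' @return The dimensionless slope ratio.
#' @export
slope_ratio <- function(fit_275_295, fit_350_400) {
  s1 <- if (inherits(fit_275_295, "feoc_slope_fit")) fit_275_295$S else
    fit_275_295
  s2 <- if (inherits(fit_350_400, "feoc_slope_fit")) fit_350_400$S else
    fit_350_400
  .assert(s2 != 0, "denominator slope is zero", "feoc_domain_error")
  s1 / s2
}

#' Specific UV absorbance at 254 nm
#'
#' Absorption at 254 nm (m-1, interpolated linearly if 254 nm is not on
#' the grid) divided by the DOC concentration (mg C L-1).
#'
#' @param spectrum Absorbance spectrum data frame (`wavelength`,
#'   `absorption`).
#' @param doc_conc DOC concentration (mg C L-1); defaults to the
#'   `doc_conc` attribute of the spectrum.
#' @return SUVA254 in L mg-1 m-1.
#' @export
suva254 <- function(spectrum, doc_conc = attr(spectrum, "doc_conc")) {
  .assert(!is.null(doc_conc) && doc_conc > 0,
          "doc_conc must be positive", "feoc_domain_error")
  wl <- spectrum$wavelength
  .assert(min(wl) <= 254 && max(wl) >= 254,
          "254 nm lies outside the spectrum", "feoc_domain_error")
  a254 <- approx(wl, spectrum$absorption, xout = 254)$y
  a254 / doc_conc
}

#' Fluorescence indices from an excitation-emission matrix
#'
#' Computes the fluorescence index FI = I(Ex 370, Em 470) / I(Ex 370,
#' Em 520) (nearest-grid lookup), the fluorescent DOM content FDOM as the
#' sum of the five canonical peak maxima (A, B, C, M, T), each maximum the
#' largest intensity in a +/- `box` nm window around the named
#' coordinates, and the fractional contribution of each peak.
#'
#' @param eem A `feoc_eem` (list with `ex`, `em` grids and an `intensity`
#'   matrix, excitation x emission).
#' @param box Half-width (nm) of the peak-search window.
#' @return List with `FI`, `FDOM` (Raman units) and `peak_fractions`
#'   (named, summing to 1; all `NA` when FDOM is 0).
#' @export
eem_indices <- function(eem, box = 10) {
  ex <- eem$ex; em <- eem$em; I <- eem$intensity
  .assert(all(is.finite(I)), "EEM intensities must be finite",
          "feoc_domain_error")
  need_ex <- c(370, 250, 270, 350, 320, 290)
  need_em <- c(470, 520, 450, 304, 411, 349)
  .assert(all(need_ex >= min(ex) & need_ex <= max(ex)) &&
            all(need_em >= min(em) & need_em <= max(em)),
          "EEM grids do not cover the required coordinates",
          "feoc_domain_error")
  idx <- function(grid, v) which.min(abs(grid - v))
  fi_num <- I[idx(ex, 370), idx(em, 470)]
  fi_den <- I[idx(ex, 370), idx(em, 520)]
  fi <- fi_num / fi_den
  peaks <- default_eem_peaks()
  maxima <- vapply(seq_len(nrow(peaks)), function(i) {
    exi <- which(abs(ex - peaks$ex[i]) <= box)
    emi <- which(abs(em - peaks$em[i]) <= box)
    max(I[exi, emi, drop = FALSE])
  }, 0)
  names(maxima) <- peaks$peak
  fdom <- sum(maxima)
  fractions <- if (fdom > 0) maxima / fdom else
    setNames(rep(NA_real_, length(maxima)), names(maxima))
  list(FI = fi, FDOM = fdom, peak_fractions = fractions)
}
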