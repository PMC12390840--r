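#' Generate a synthetic co-precipitation table
#'
#' Forward-simulates a co-precipitation experiment: for every ground-truth
#' calibration curve, every point of a log-spaced DOC/Fe(III) grid and
#' every synthesis condition, `replicates` rows are drawn with loading
#' `k_F * x^n_F` plus additive-absolute and multiplicative-relative
#' Gaussian noise (truncated below at zero) and
#' `delta13C_Fe-OC = delta13C_DOC - Delta13C(x)` plus Gaussian noise.
#'
#' @param truth Named list of [true_calibration()] objects (e.g.
#'   [default_truth()]). Each (mineral, end member) pair must appear once.
#' @param design An [experiment_design()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Data frame following the `coprecip` schema (see
#'   [feoc_schemas()]), one row per replicate measurement.
#' @export
generate_coprecip_table <- function(truth, design = experiment_design(),
                                    seed = 1L) {
  .assert(inherits(design, "feoc_experiment_design"),
          "design must be an experiment_design()", "feoc_domain_error")
  .assert(length(truth) >= 1 &&
            all(vapply(truth, inherits, TRUE, "feoc_true_calibration")),
          "truth must be a list of true_calibration() objects",
          "feoc_config_error")
  keys <- vapply(truth, function(t) .pair_key(t$mineral, t$endmember), "")
  .assert(!anyDuplicated(keys),
          "each (mineral, endmember) pair must appear exactly once in truth",
          "feoc_config_error")

  n_dec <- log10(design$x_max / design$x_min)
  n_x <- round(n_dec * design$points_per_decade) + 1L
  x_grid <- 10^seq(log10(design$x_min), log10(design$x_max),
                   length.out = n_x)
  cond <- design$condition_grid

  withr::with_seed(seed, {
    rows <- lapply(truth, function(tr) {
      per_pair <- lapply(seq_len(nrow(cond)), function(ci) {
        n <- n_x * design$replicates
        x <- rep(x_grid, each = design$replicates)
        tc <- true_curves(tr, x)
        load_obs <- pmax(0, tc$loading +
                           rnorm(n, sd = design$sigma_load_abs) +
                           tc$loading * rnorm(n, sd = design$sigma_load_rel))
        feoc_obs <- tr$d13c_doc - tc$delta + rnorm(n, sd = design$sigma_delta)
        data.frame(mineral = tr$mineral, endmember = tr$endmember,
                   x = x, loading = load_obs,
                   d13c_doc = tr$d13c_doc, d13c_feoc = feoc_obs,
                   delta13c = tr$d13c_doc - feoc_obs,
                   temperature = cond$temperature[ci], pH = cond$pH[ci],
                   duration = cond$duration[ci],
                   fe_source = cond$fe_source[ci],
                   doc_timing = cond$doc_timing[ci],
                   fraction = cond$fraction[ci],
                   replicate = rep(seq_len(design$replicates), times = n_x),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_pair)
    })
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic geologic iron-ooid record
#'
#' Forward-models a geologic record from a known DOC history: for every
#' sample of every formation, the end-member mixture at the formation age
#' is taken from `scenario`, the DOC/Fe(III) ratio is
#' `x = x_modern * doc_star(age)` (constant iron flux), and Fe-OC loading
#' and delta13C follow the mixture forward model (loading-weighted isotope
#' mass balance) plus Gaussian measurement noise.
#'
#' @param history A [true_history()].
#' @param truth Ground-truth calibration set as in
#'   [generate_coprecip_table()].
#' @param scenario A [scenario()] defining end-member fractions over time.
#' @param seed Integer seed.
#' @return Data frame following the `record` schema: one row per sample
#'   with `sample_id`, `formation`, `age`, `mineral`, `loading`,
#'   `loading_sd`, `d13c_feoc`, `d13c_sd`, `palaeolatitude`.
#' @export
generate_record <- function(history, truth, scenario, seed = 1L) {
  .assert(inherits(history, "feoc_true_history"),
          "history must be a true_history()", "feoc_domain_error")
  fm <- history$formations
  keys <- vapply(truth, function(t) .pair_key(t$mineral, t$endmember), "")
  names(truth) <- keys

  # evaluate mixture forward model from ground-truth curves
  fwd <- function(mineral, f, x) {
    li <- vapply(.feoc_endmembers, function(em) {
      tr <- truth[[.pair_key(mineral, em)]]
      .assert(!is.null(tr) || f[[em]] == 0,
              sprintf("truth missing pair %s|%s", mineral, em),
              "feoc_config_error")
      if (is.null(tr)) 0 else true_curves(tr, x)$loading
    }, 0)
    di <- vapply(.feoc_endmembers, function(em) {
      tr <- truth[[.pair_key(mineral, em)]]
      if (is.null(tr)) 0 else true_curves(tr, x)$delta
    }, 0)
    L <- sum(f * li)
    .assert(L > 0, "mixture loading is zero", "feoc_domain_error")
    list(loading = L, delta = sum(f * li * di) / L)
  }

  n_tot <- sum(fm$n_samples)
  withr::with_seed(seed, {
    recs <- vector("list", nrow(fm))
    for (i in seq_len(nrow(fm))) {
      n <- fm$n_samples[i]
      age <- fm$age[i]
      f <- scenario_fractions(scenario, age)
      x <- history$x_modern * history$doc_star(age)
      .assert(x > 0, "doc_star history must be positive", "feoc_domain_error")
      fw <- fwd(fm$mineral[i], f, x)
      d13c_true <- history$d13c_doc(age) - fw$delta
      recs[[i]] <- data.frame(
        sample_id = sprintf("%s_%02d", fm$formation[i], seq_len(n)),
        formation = fm$formation[i], age = age, mineral = fm$mineral[i],
        loading = pmax(0, fw$loading +
                         rnorm(n, sd = history$sigma_load_meas)),
        loading_sd = history$sigma_load_meas,
        d13c_feoc = d13c_true + rnorm(n, sd = history$sigma_d13c_meas),
        d13c_sd = history$sigma_d13c_meas,
        palaeolatitude = NA_real_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
  })
  rownames(out) <- NULL
  stopifnot(nrow(out) == n_tot)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic Raman scan from a phantom
#'
#' Per pixel, the spectrum is a polynomial baseline plus the mineral bands,
#' plus the G-band where the organic-carbon mask is true, plus Gaussian
#' noise with standard deviation `gband amplitude / snr`.
#'
#' @param phantom A [raman_phantom()].
#' @param seed Integer seed.
#' @return A `feoc_scan` object: list with `positions` (data frame `row`,
#'   `col`), `wavenumber` and an `intensity` matrix (pixels x wavenumbers).
#' @export
generate_raman_scan <- function(phantom, seed = 1L) {
  .assert(inherits(phantom, "feoc_raman_phantom"),
          "phantom must be a raman_phantom()", "feoc_domain_error")
  w <- phantom$wavenumber_grid
  .assert(min(w) <= 1200 && max(w) >= 1700,
          "wavenumber grid must cover 1200-1700 cm-1", "feoc_domain_error")
  nr <- phantom$grid_shape[1]; nc <- phantom$grid_shape[2]
  npix <- nr * nc
  base <- .polyval(phantom$baseline_coeffs, w / 1000)
  for (i in seq_len(nrow(phantom$mineral_peaks))) {
    p <- phantom$mineral_peaks[i, ]
    base <- base + p$amplitude * exp(-(w - p$centre)^2 / (2 * p$width^2))
  }
  gb <- phantom$gband["amplitude"] *
    exp(-(w - phantom$gband["centre"])^2 / (2 * phantom$gband["width"]^2))
  sigma <- if (is.finite(phantom$snr)) {
    phantom$gband["amplitude"] / phantom$snr
  } else 0
  mask <- as.vector(phantom$oc_mask)
  withr::with_seed(seed, {
    intensity <- matrix(rep(base, each = npix), npix, length(w))
    if (any(mask)) {
      intensity[mask, ] <- intensity[mask, , drop = FALSE] +
        matrix(rep(gb, each = sum(mask)), sum(mask), length(w))
    }
    if (sigma > 0) {
      intensity <- intensity + matrix(rnorm(npix * length(w), sd = sigma),
                                      npix, length(w))
    }
  })
  positions <- data.frame(row = rep(seq_len(nr), times = nc),
                          col = rep(seq_len(nc), each = nr))
  structure(list(positions = positions, wavenumber = w,
                 intensity = intensity, oc_mask = mask, seed = seed),
            class = "feoc_scan")
}

#' Generate a synthetic absorbance spectrum and excitation-emission matrix
#'
#' The absorbance spectrum is piecewise exponential,
#' `a(lambda) = a_ref * exp(-S * (lambda - lambda_ref))`, with slope
#' `s275_295` below the 320 nm splice and `s350_400` above it, anchored so
#' the absorbance at 254 nm equals `a_ref`. The EEM is a sum of bivariate
#' Gaussian peaks at the named fluorophore coordinates.
#'
#' @param s275_295,s350_400 Spectral slopes (nm-1) on the two fitting
#'   ranges; must be non-negative.
#' @param a_ref Absorbance at 254 nm (m-1), positive.
#' @param doc_conc DOC concentration (mg C L-1), attached to the spectrum
#'   for SUVA254.
#' @param eem_peaks Data frame `ex`, `em`, `height`, `width` of EEM peaks;
#'   defaults to the five canonical peaks A, B, C, M, T with unit height.
#' @param noise_abs,noise_eem Gaussian noise sigmas (default 0, noiseless).
#' @param seed Integer seed.
#' @return List with an `absorbance` spectrum (data frame `wavelength`,
#'   `absorption`, attribute `doc_conc`) and an `eem` (list `ex`, `em`,
#'   `intensity`).
#' @export
generate_optical_sample <- function(s275_295 = 0.018, s350_400 = 0.009,
                                    a_ref = 2, doc_conc = 1,
                                    eem_peaks = default_eem_peaks(),
                                    noise_abs = 0, noise_eem = 0,
                                    seed = 1L) {
  .assert(s275_295 >= 0 && s350_400 >= 0,
          "spectral slopes must be non-negative", "feoc_domain_error")
  .assert(a_ref > 0, "a_ref must be positive", "feoc_domain_error")
  wl <- seq(240, 450, by = 1)
  split <- 320
  a <- ifelse(wl <= split,
              a_ref * exp(-s275_295 * (wl - 254)),
              a_ref * exp(-s275_295 * (split - 254)) *
                exp(-s350_400 * (wl - split)))
  ex <- seq(250, 500, by = 5)
  em <- seq(300, 600, by = 2)
  intensity <- matrix(0, length(ex), length(em))
  for (i in seq_len(nrow(eem_peaks))) {
    p <- eem_peaks[i, ]
    intensity <- intensity + p$height *
      outer(exp(-(ex - p$ex)^2 / (2 * p$width^2)),
            exp(-(em - p$em)^2 / (2 * p$width^2)))
  }
  withr::with_seed(seed, {
    if (noise_abs > 0) a <- pmax(0, a + rnorm(length(a), sd = noise_abs))
    if (noise_eem > 0) {
      intensity <- intensity +
        matrix(rnorm(length(intensity), sd = noise_eem),
               nrow(intensity), ncol(intensity))
    }
  })
  spectrum <- data.frame(wavelength = wl, absorption = a)
  attr(spectrum, "doc_conc") <- doc_conc
  list(absorbance = spectrum,
       eem = structure(list(ex = ex, em = em, intensity = intensity),
                       class = "feoc_eem"))
}

#' Canonical EEM fluorophore peaks
#'
#' Peaks A (Ex 250/Em 450), B (270/304), C (350/450), M (320/411) and
#' T (290/349) with unit height and a common width.
#'
#' @param height Peak height, Raman units.
#' @param width Gaussian sigma, nm; the default keeps neighbouring peaks
#'   from bleeding into each other's search windows.
#' @return Data frame `peak`, `ex`, `em`, `height`, `width`.
#' @export
default_eem_peaks <- function(height = 1, width = 8) {
  data.frame(peak = c("A", "B", "C", "M", "T"),
             ex = c(250, 270, 350, 320, 290),
             em = c(450, 304, 450, 411, 349),
             height = height, width = width,
             stringsAsFactors = FALSE)
}
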