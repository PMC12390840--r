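#' Monte Carlo configuration for record reconstruction
#'
#' @param n_draws Number of Monte Carlo draws (>= 100; default 10000).
#' @param seed Integer seed.
#' @param x_bounds Admissible DOC/Fe(III) range for the inversion;
#'   observations mapping outside are clamped to the nearer bound and
#'   flagged (power-law extrapolation far beyond the calibrated range is
#'   unsupported).
#' @param modern_reference_policy `"modern_bin_median"` (the modern
#'   reference ratio is the per-draw median inverted `x` of samples
#'   younger than `modern_max_age`) or `"fixed_x"` (use `x_modern_fixed`).
#' @param x_modern_fixed Modern reference ratio under the `"fixed_x"`
#'   policy.
#' @param modern_max_age Age (Ma) bounding the modern reference bin.
#' @param ci_level Credible-interval level (default 0.95).
#' @return An object of class `feoc_mc_config`.
#' @export
mc_config <- function(n_draws = 10000, seed = 1L,
                      x_bounds = c(1e-4, 1e2),
                      modern_reference_policy = c("modern_bin_median",
                                                  "fixed_x"),
                      x_modern_fixed = 1, modern_max_age = 100,
                      ci_level = 0.95) {
  modern_reference_policy <- match.arg(modern_reference_policy)
  .assert(n_draws >= 100, "n_draws must be at least 100",
          "feoc_domain_error")
  .assert(all(x_bounds > 0) && x_bounds[1] < x_bounds[2],
          "x_bounds must be positive and ordered", "feoc_domain_error")
  .assert(ci_level > 0 && ci_level < 1, "ci_level must lie in (0, 1)",
          "feoc_domain_error")
  structure(list(n_draws = as.integer(n_draws), seed = seed,
                 x_bounds = x_bounds,
                 modern_reference_policy = modern_reference_policy,
                 x_modern_fixed = x_modern_fixed,
                 modern_max_age = modern_max_age, ci_level = ci_level),
            class = "feoc_mc_config")
}

#' Mixture forward model
#'
#' Predicts the Fe-OC signal of a DOC mixture from fitted calibration
#' curves: the loading is the fraction-weighted sum of the end-member
#' loadings, `L(x) = sum_i f_i * L_i(x)`, and the isotope offset follows
#' carbon mass balance, weighting each end-member offset by the carbon it
#' actually contributes, `Delta(x) = sum_i f_i * L_i(x) * Delta_i(x) /
#' L(x)`. With a common substrate `delta13C_DOC`, the predicted
#' co-precipitate composition is `delta13C_Fe-OC = delta13C_DOC -
#' Delta(x)`.
#'
#' @param calibs A `feoc_calibration_set`.
#' @param mineral Mineral of the sample.
#' @param f Simplex vector of end-member fractions, named or ordered
#'   `(M-DOC, C-DOC, FA)`.
#' @param x DOC/Fe(III) mole ratio(s), positive.
#' @return List with vectors `loading` (wt%) and `delta` (permil).
#' @export
forward_model <- function(calibs, mineral, f, x) {
  .assert(all(x > 0), "x must be positive", "feoc_domain_error")
  f <- .check_simplex(f)
  L <- 0; num <- 0
  for (em in .feoc_endmembers) {
    if (f[[em]] == 0) next
    cv <- evaluate_curves(calibs, mineral, em, x)
    L <- L + f[[em]] * cv$loading
    num <- num + f[[em]] * cv$loading * cv$delta
  }
  .assert(all(L > 0), "mixture loading is zero with positive fractions",
          "feoc_degenerate_error")
  list(loading = L, delta = num / L)
}

.check_simplex <- function(f) {
  .assert(length(f) == 3 && all(f >= 0) && abs(sum(f) - 1) < 1e-9,
          "f must be a 3-component simplex vector", "feoc_domain_error")
  if (is.null(names(f))) names(f) <- .feoc_endmembers
  f
}

#' Invert the forward loading model
#'
#' Finds the unique DOC/Fe(III) ratio whose mixture loading matches an
#' observation, by bisection on `log x` (the mixture of Freundlich curves
#' is strictly increasing, so the root is unique). Observations outside
#' the loading range spanned by `x_bounds` clamp to the nearer bound with
#' a flag.
#'
#' @param calibs A `feoc_calibration_set`.
#' @param mineral,f As in [forward_model()].
#' @param L_obs Observed loading(s), wt%, positive.
#' @param x_bounds Search interval.
#' @param rel_tol Relative tolerance on `x`.
#' @return Numeric `x` with logical attribute `clamped`.
#' @export
invert_loading <- function(calibs, mineral, f, L_obs,
                           x_bounds = c(1e-4, 1e2), rel_tol = 1e-10) {
  .assert(all(L_obs > 0), "L_obs must be positive", "feoc_domain_error")
  f <- .check_simplex(f)
  ems <- .feoc_endmembers[f > 0]
  k <- vapply(ems, function(em) .get_fit(calibs, mineral, em)$loading$k_F, 0)
  n <- vapply(ems, function(em) .get_fit(calibs, mineral, em)$loading$n_F, 0)
  fw <- f[ems]
  Lfun <- function(lx) {
    out <- 0
    for (j in seq_along(ems)) out <- out + fw[j] * k[j] * exp(n[j] * lx)
    out
  }
  lo0 <- log(x_bounds[1]); hi0 <- log(x_bounds[2])
  x <- numeric(length(L_obs)); clamped <- logical(length(L_obs))
  Llo <- Lfun(lo0); Lhi <- Lfun(hi0)
  for (i in seq_along(L_obs)) {
    if (L_obs[i] <= Llo) { x[i] <- x_bounds[1]; clamped[i] <- TRUE; next }
    if (L_obs[i] >= Lhi) { x[i] <- x_bounds[2]; clamped[i] <- TRUE; next }
    lo <- lo0; hi <- hi0
    while ((hi - lo) > rel_tol) {
      mid <- (lo + hi) / 2
      if (Lfun(mid) < L_obs[i]) lo <- mid else hi <- mid
    }
    x[i] <- exp((lo + hi) / 2)
  }
  attr(x, "clamped") <- clamped
  x
}

# --- internal machinery for the vectorized Monte Carlo -------------------

# draw loading parameters (k, n) per fit: 2 x n_draws, sampled on
# (log k, n) from the fit covariance, n truncated to (0, 1]
.draw_loading <- function(fit, n_draws) {
  d <- .rmvnorm(n_draws, c(log(fit$k_F), fit$n_F), fit$covariance)
  rbind(k = exp(d[1, ]), n = pmin(pmax(d[2, ], 1e-8), 1))
}

# draw delta parameters per fit: 4 x n_draws on (a1, a2, log x1, log x2),
# decay scales kept ordered x1 <= x2 per draw
.draw_delta <- function(fit, n_draws) {
  d <- .rmvnorm(n_draws, c(fit$a1, fit$a2, log(fit$x1), log(fit$x2)),
                fit$covariance)
  x1 <- exp(d[3, ]); x2 <- exp(d[4, ])
  a1 <- d[1, ]; a2 <- d[2, ]
  swap <- x1 > x2
  if (any(swap)) {
    tmp <- x1[swap]; x1[swap] <- x2[swap]; x2[swap] <- tmp
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  rbind(a1 = a1, a2 = a2, x1 = x1, x2 = x2)
}

# vectorized bisection for mixtures with per-element parameters.
# All arguments are n_s x n_draws matrices (or conformable); K, N are
# lists over end members. Returns list(x, clamped).
.invert_mixture_mat <- function(L_obs, Fw, K, N, x_bounds) {
  lo0 <- log(x_bounds[1]); hi0 <- log(x_bounds[2])
  Lmix <- function(lx) {
    out <- 0
    for (e in seq_along(K)) out <- out + Fw[[e]] * K[[e]] * exp(N[[e]] * lx)
    out
  }
  dims <- dim(L_obs)
  lo <- array(lo0, dims); hi <- array(hi0, dims)
  Llo <- Lmix(lo); Lhi <- Lmix(hi)
  clamp_lo <- L_obs <= Llo; clamp_hi <- L_obs >= Lhi
  # 52 halvings of a ~13.8-wide log interval reach ~3e-15, well below
  # the 1e-10 relative tolerance contract
  for (it in seq_len(52L)) {
    mid <- (lo + hi) / 2
    below <- Lmix(mid) < L_obs
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  x <- exp((lo + hi) / 2)
  x[clamp_lo] <- x_bounds[1]
  x[clamp_hi] <- x_bounds[2]
  list(x = x, clamped = clamp_lo | clamp_hi)
}

# expand per-(mineral, draw) parameter rows to n_s x n_draws matrices
.expand_par <- function(par_by_min, mineral_idx) {
  par_by_min[mineral_idx, , drop = FALSE]
}

#' Monte Carlo reconstruction of a geologic Fe-OC record
#'
#' Inverts measured iron-ooid Fe-OC loadings and delta13C values into
#' relative DOC concentration (`[DOC]*`) and `delta13C_DOC` with full
#' error propagation. Per draw: calibration parameters are sampled from
#' the fit covariances (on their internal parameterizations, truncated to
#' the fit constraints), observations are sampled from their Gaussian
#' measurement errors, each sample's loading is inverted to a DOC/Fe(III)
#' ratio under the end-member mixture at its age, the modern reference
#' ratio is computed from the same draw, and
#' `[DOC]* = x / x_modern` (constant-iron-flux assumption) and
#' `delta13C_DOC = delta13C_Fe-OC + Delta(x)` are recorded. Draws are
#' aggregated to per-sample medians and central credible intervals.
#'
#' Randomness is generated in canonical `sample_id` order, so results are
#' invariant to row ordering and fully reproducible under a fixed seed.
#'
#' @param samples Record table (`record` schema): `sample_id`, `formation`,
#'   `age`, `mineral`, `loading`, `loading_sd`, `d13c_feoc`, `d13c_sd`.
#' @param calibs A `feoc_calibration_set` complete for the scenario.
#' @param scn A [scenario()] (not `"unconstrained"`).
#' @param cfg An [mc_config()].
#' @return Data frame with one row per sample: posterior medians and CI
#'   bounds for `doc_star` and `d13c_doc`, the median inverted `x`, the
#'   end-member fractions at the sample age and the fraction of clamped
#'   draws. Attribute `draws` (when `keep_draws = TRUE`) holds the raw
#'   `doc_star` draw matrix.
#' @param keep_draws Keep the per-sample `doc_star` and `d13c_doc` draw
#'   matrices as attributes.
#' @export
reconstruct_record <- function(samples, calibs, scn, cfg = mc_config(),
                               keep_draws = FALSE) {
  .assert(inherits(cfg, "feoc_mc_config"), "cfg must be an mc_config()",
          "feoc_domain_error")
  need <- c("sample_id", "formation", "age", "mineral", "loading",
            "loading_sd", "d13c_feoc", "d13c_sd")
  .assert(all(need %in% names(samples)),
          paste("samples missing columns:",
                paste(setdiff(need, names(samples)), collapse = ", ")),
          "feoc_data_error")
  ord <- order(samples$sample_id)
  s <- samples[ord, , drop = FALSE]
  n_s <- nrow(s); n_d <- cfg$n_draws
  minerals <- sort(unique(s$mineral))
  mineral_idx <- match(s$mineral, minerals)

  fmat <- t(vapply(s$age, function(a) scenario_fractions(scn, a),
                   numeric(3)))
  colnames(fmat) <- .feoc_endmembers
  ems_used <- .feoc_endmembers[colSums(fmat) > 0]
  for (m in minerals) for (em in ems_used) .get_fit(calibs, m, em)

  modern <- which(s$age >= 0 & s$age < cfg$modern_max_age)
  if (cfg$modern_reference_policy == "modern_bin_median") {
    .assert(length(modern) > 0, paste(
      "no modern reference samples (age <", cfg$modern_max_age,
      "Ma); use the fixed_x policy"), "feoc_config_error")
  }

  res <- withr::with_seed(cfg$seed, {
    # calibration-parameter draws per (mineral, end member)
    kdraw <- ndraw <- list()
    ddraw <- list()
    for (m in minerals) {
      for (em in ems_used) {
        key <- .pair_key(m, em)
        fit <- .get_fit(calibs, m, em)
        ld <- .draw_loading(fit$loading, n_d)
        dd <- .draw_delta(fit$delta, n_d)
        kdraw[[key]] <- ld["k", ]; ndraw[[key]] <- ld["n", ]
        ddraw[[key]] <- dd
      }
    }
    # observation draws (canonical sample order)
    L_obs <- pmax(s$loading + s$loading_sd *
                    matrix(rnorm(n_s * n_d), n_s, n_d),
                  .Machine$double.xmin)
    D_obs <- s$d13c_feoc + s$d13c_sd * matrix(rnorm(n_s * n_d), n_s, n_d)

    # per end member: expanded fraction, k and n matrices (n_s x n_d)
    Fw <- K <- N <- vector("list", length(ems_used))
    names(Fw) <- names(K) <- names(N) <- ems_used
    for (em in ems_used) {
      Fw[[em]] <- matrix(fmat[, em], n_s, n_d)
      km <- do.call(rbind, lapply(minerals, function(m)
        kdraw[[.pair_key(m, em)]]))
      nm <- do.call(rbind, lapply(minerals, function(m)
        ndraw[[.pair_key(m, em)]]))
      K[[em]] <- .expand_par(km, mineral_idx)
      N[[em]] <- .expand_par(nm, mineral_idx)
    }

    inv <- .invert_mixture_mat(L_obs, Fw, K, N, cfg$x_bounds)
    x_mat <- inv$x

    # mixture Delta13C at the inverted ratio, same parameter draws
    Lmix <- 0; Dnum <- 0
    for (em in ems_used) {
      Le <- K[[em]] * x_mat^N[[em]]
      a1 <- .expand_par(do.call(rbind, lapply(minerals, function(m)
        ddraw[[.pair_key(m, em)]]["a1", ])), mineral_idx)
      a2 <- .expand_par(do.call(rbind, lapply(minerals, function(m)
        ddraw[[.pair_key(m, em)]]["a2", ])), mineral_idx)
      x1 <- .expand_par(do.call(rbind, lapply(minerals, function(m)
        ddraw[[.pair_key(m, em)]]["x1", ])), mineral_idx)
      x2 <- .expand_par(do.call(rbind, lapply(minerals, function(m)
        ddraw[[.pair_key(m, em)]]["x2", ])), mineral_idx)
      De <- a1 * exp(-x_mat / x1) + a2 * exp(-x_mat / x2)
      Lmix <- Lmix + Fw[[em]] * Le
      Dnum <- Dnum + Fw[[em]] * Le * De
    }
    delta_mix <- Dnum / Lmix

    x_modern <- if (cfg$modern_reference_policy == "modern_bin_median") {
      apply(x_mat[modern, , drop = FALSE], 2, median)
    } else rep(cfg$x_modern_fixed, n_d)
    doc_star <- sweep(x_mat, 2, x_modern, "/")
    d13c_doc <- D_obs + delta_mix
    list(x_mat = x_mat, doc_star = doc_star, d13c_doc = d13c_doc,
         clamped = inv$clamped)
  })

  alpha <- (1 - cfg$ci_level) / 2
  qs <- function(mat) t(apply(mat, 1, quantile,
                              probs = c(alpha, 0.5, 1 - alpha),
                              names = FALSE))
  qd <- qs(res$doc_star); qc <- qs(res$d13c_doc)
  out <- data.frame(
    sample_id = s$sample_id, formation = s$formation, age = s$age,
    mineral = s$mineral,
    x_med = apply(res$x_mat, 1, median),
    doc_star = qd[, 2], doc_star_lo = qd[, 1], doc_star_hi = qd[, 3],
    d13c_doc = qc[, 2], d13c_doc_lo = qc[, 1], d13c_doc_hi = qc[, 3],
    f_M = fmat[, "M-DOC"], f_C = fmat[, "C-DOC"], f_FA = fmat[, "FA"],
    clamped_frac = rowMeans(res$clamped),
    stringsAsFactors = FALSE)
  # restore the caller's row order
  out <- out[match(samples$sample_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scenario") <- scn$name
  attr(out, "config") <- cfg
  if (keep_draws) {
    reorder <- match(samples$sample_id, s$sample_id)
    attr(out, "draws") <- list(doc_star = res$doc_star[reorder, ,
                                                       drop = FALSE],
                               d13c_doc = res$d13c_doc[reorder, ,
                                                       drop = FALSE])
  }
  class(out) <- c("feoc_reconstruction", "data.frame")
  out
}

#' Free-mixture inversion for a single sample
#'
#' Grid search over the end-member simplex (step 0.05, 231 candidate
#' mixtures) for the composition that minimizes the propagated `[DOC]*`
#' uncertainty, measured as the width of the central credible interval.
#' All candidates share one set of parameter and observation draws (common
#' random numbers), so the search is deterministic under the seed. Ties
#' are broken toward smaller fulvic-acid then smaller C-DOC fractions.
#'
#' @param sample One-row record table.
#' @param calibs Calibration set complete for all three end members.
#' @param cfg An [mc_config()]; the modern reference uses the `fixed_x`
#'   policy (a lone sample carries no modern bin).
#' @param step Simplex grid step.
#' @return List with `f` (the optimal simplex vector), `ci_width`, and the
#'   full `grid` of candidate mixtures and widths.
#' @export
optimize_scenario_free <- function(sample, calibs, cfg = mc_config(),
                                   step = 0.05) {
  .assert(nrow(sample) == 1, "sample must be a single record row",
          "feoc_data_error")
  mineral <- sample$mineral
  for (em in .feoc_endmembers) .get_fit(calibs, mineral, em)
  n_d <- cfg$n_draws
  draws <- withr::with_seed(cfg$seed, {
    ld <- lapply(.feoc_endmembers, function(em)
      .draw_loading(.get_fit(calibs, mineral, em)$loading, n_d))
    names(ld) <- .feoc_endmembers
    L_obs <- pmax(sample$loading + sample$loading_sd * rnorm(n_d),
                  .Machine$double.xmin)
    list(ld = ld, L_obs = L_obs)
  })
  m <- round(1 / step)
  grid <- expand.grid(i = 0:m, j = 0:m)
  grid <- grid[grid$i + grid$j <= m, ]
  cand <- data.frame(f_M = grid$i / m, f_C = grid$j / m,
                     f_FA = 1 - (grid$i + grid$j) / m)
  alpha <- (1 - cfg$ci_level) / 2
  widths <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    fr <- c(cand$f_M[r], cand$f_C[r], cand$f_FA[r])
    ems <- .feoc_endmembers[fr > 0]
    Fw <- lapply(ems, function(em) fr[match(em, .feoc_endmembers)])
    K <- lapply(ems, function(em) matrix(draws$ld[[em]]["k", ], 1))
    N <- lapply(ems, function(em) matrix(draws$ld[[em]]["n", ], 1))
    inv <- .invert_mixture_mat(matrix(draws$L_obs, 1), Fw, K, N,
                               cfg$x_bounds)
    ds <- inv$x / cfg$x_modern_fixed
    q <- quantile(ds, c(alpha, 1 - alpha), names = FALSE)
    widths[r] <- q[2] - q[1]
  }
  cand$ci_width <- widths
  ord <- order(cand$ci_width, cand$f_FA, cand$f_C)
  best <- cand[ord[1], ]
  list(f = setNames(c(best$f_M, best$f_C, best$f_FA), .feoc_endmembers),
       ci_width = best$ci_width, grid = cand)
}
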