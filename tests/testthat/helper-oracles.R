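# Independent oracles used by the tests. These deliberately avoid the
# package's fitting code paths: brute-force grids, random multi-starts and
# textbook formulas.

# dense zooming grid search for loading = k * x^n over k > 0, n in (0, 1]
oracle_freundlich_grid <- function(x, y, rounds = 7, m = 61) {
  k_lo <- max(1e-6, min(y[y > 0]) / max(x)^1)
  k_hi <- max(y) / min(x)^1 + max(y)
  n_lo <- 1e-4; n_hi <- 1
  best <- c(NA, NA, Inf)
  for (r in seq_len(rounds)) {
    ks <- exp(seq(log(k_lo), log(k_hi), length.out = m))
    ns <- seq(n_lo, n_hi, length.out = m)
    for (k in ks) for (n in ns) {
      ssr <- sum((y - k * x^n)^2)
      if (ssr < best[3]) best <- c(k, n, ssr)
    }
    dk <- diff(range(log(ks))) / (m - 1)
    dn <- diff(range(ns)) / (m - 1)
    k_lo <- exp(log(best[1]) - 2 * dk); k_hi <- exp(log(best[1]) + 2 * dk)
    n_lo <- max(1e-6, best[2] - 2 * dn); n_hi <- min(1, best[2] + 2 * dn)
  }
  list(k = best[1], n = best[2], rmse = sqrt(best[3] / length(x)))
}

# random multi-start minimization of the full 4-parameter dual-exponential
oracle_dualexp_multistart <- function(x, d, n_starts = 100, seed = 99) {
  obj <- function(p) {
    x1 <- exp(p[3]); x2 <- exp(p[4])
    sum((d - p[1] * exp(-x / x1) - p[2] * exp(-x / x2))^2)
  }
  set.seed(seed)
  best <- Inf
  rng <- range(log(x))
  for (i in seq_len(n_starts)) {
    st <- c(runif(2, -12, 2), runif(2, rng[1] - 1, rng[2] + 1))
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  sqrt(best / length(x))
}

# textbook Welch statistic and two-tailed p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# a noiseless single-pair co-precipitation table for a given truth record
noiseless_table <- function(truth_one, seed = 1) {
  generate_coprecip_table(
    setNames(list(truth_one), paste(truth_one$mineral, truth_one$endmember,
                                    sep = "|")),
    experiment_design(sigma_load_abs = 0, sigma_load_rel = 0,
                      sigma_delta = 0),
    seed = seed)
}

# a complete noiseless calibration set fitted from default truth
noiseless_calibration <- function(seed = 1) {
  tab <- generate_coprecip_table(
    default_truth(),
    experiment_design(sigma_load_abs = 0, sigma_load_rel = 0,
                      sigma_delta = 0),
    seed = seed)
  fit_calibration_set(tab)
}

# hand-built calibration set with exact curve parameters and optional
# covariances, bypassing the fitting machinery
manual_calibration <- function(pars) {
  fits <- lapply(pars, function(p) {
    lcov <- if (is.null(p$lcov)) matrix(0, 2, 2) else p$lcov
    dcov <- if (is.null(p$dcov)) matrix(0, 4, 4) else p$dcov
    dimnames(lcov) <- list(c("log_k", "n"), c("log_k", "n"))
    nm <- c("a1", "a2", "log_x1", "log_x2")
    dimnames(dcov) <- list(nm, nm)
    list(loading = structure(list(mineral = p$mineral,
                                  endmember = p$endmember,
                                  k_F = p$k, n_F = p$n, covariance = lcov,
                                  rmse = 0, r2 = 1, n_points = 0,
                                  boundary = FALSE),
                             class = "feoc_loading_fit"),
         delta = structure(list(mineral = p$mineral,
                                endmember = p$endmember,
                                a1 = p$a1, a2 = p$a2, x1 = p$x1, x2 = p$x2,
                                covariance = dcov, rmse = 0, r2 = 1,
                                n_points = 0, single_exponential = FALSE),
                           class = "feoc_delta_fit"))
  })
  names(fits) <- vapply(pars, function(p)
    paste(p$mineral, p$endmember, sep = "|"), "")
  structure(list(fits = fits, selection_policy = list(), exclusions = NULL),
            class = "feoc_calibration_set")
}
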