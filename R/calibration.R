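#' Select calibration points by condition policy
#'
#' Co-precipitation signals diverge at extreme synthesis conditions and the
#' raw / partially washed fractions retain organic carbon that does not
#' survive in the geologic record. The default policy therefore keeps only
#' the `-Fh/PC-ads.OC` fraction and drops rows synthesized at 95 deg C or
#' pH 11.5.
#'
#' @param points Co-precipitation table (`coprecip` schema).
#' @param fraction Fraction to retain.
#' @param exclude_temperature Temperatures (deg C) to exclude.
#' @param exclude_pH pH values to exclude.
#' @return Filtered table; attribute `exclusions` holds counts of rows
#'   removed by each rule.
#' @export
select_calibration_points <- function(points,
                                      fraction = "-Fh/PC-ads.OC",
                                      exclude_temperature = 95,
                                      exclude_pH = 11.5) {
  .assert(is.data.frame(points) && nrow(points) > 0,
          "points must be a non-empty data frame", "feoc_data_error")
  drop_frac <- !(points$fraction %in% fraction)
  drop_temp <- points$temperature %in% exclude_temperature
  drop_ph <- points$pH %in% exclude_pH
  keep <- !(drop_frac | drop_temp | drop_ph)
  excl <- c(fraction = sum(drop_frac),
            temperature = sum(drop_temp & !drop_frac),
            pH = sum(drop_ph & !drop_frac & !drop_temp))
  if (!any(keep)) {
    binding <- names(excl)[which.max(excl)]
    .assert(FALSE, sprintf(
      "no calibration points remain after filtering (binding rule: %s)",
      binding), "feoc_data_error")
  }
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

# profiled sum of squares for the Freundlich fit: for fixed n, the optimal
# prefactor is linear, k(n) = sum(y x^n) / sum(x^2n)
.freundlich_ssr <- function(n, x, y) {
  xn <- x^n
  k <- sum(y * xn) / sum(xn * xn)
  list(k = k, ssr = sum((y - k * xn)^2))
}

#' Fit a Freundlich loading isotherm
#'
#' Constrained nonlinear least squares of `loading = k_F * x^n_F` on the
#' linear loading scale (so the RMSE is in wt%), with `n_F` restricted to
#' (0, 1] (sorption isotherm behaviour: concave, monotone non-decreasing)
#' and `k_F > 0`. The exponent is profiled: for fixed `n_F` the optimal
#' `k_F` is closed-form, leaving a one-dimensional bounded optimization.
#' Solutions on the `n_F = 1` boundary are flagged.
#'
#' @param points Rows of a co-precipitation table for a single
#'   (mineral, end member) pair, with at least 3 distinct `x` values.
#' @return A `feoc_loading_fit`: `k_F`, `n_F`, 2x2 `covariance` on
#'   (log k_F, n_F), `rmse` (wt%), `r2`, `n_points`, `boundary` flag.
#' @export
fit_loading_curve <- function(points) {
  .assert(is.data.frame(points) && all(c("x", "loading") %in% names(points)),
          "points must contain x and loading columns", "feoc_data_error")
  mineral <- unique(points$mineral)
  endmember <- unique(points$endmember)
  .assert(length(mineral) <= 1 && length(endmember) <= 1,
          "points must belong to one (mineral, endmember) pair",
          "feoc_data_error")
  x <- points$x; y <- points$loading
  .assert(all(x > 0), "x must be positive", "feoc_domain_error")
  .assert(length(unique(x)) >= 3,
          "need at least 3 distinct x values to fit a loading curve",
          "feoc_insufficient_data_error")

  # coarse scan then bounded refinement; the profiled objective is smooth
  n_grid <- seq(0.01, 1, by = 0.01)
  ssr_grid <- vapply(n_grid, function(n) .freundlich_ssr(n, x, y)$ssr, 0)
  i0 <- which.min(ssr_grid)
  lo <- n_grid[max(1L, i0 - 1L)]; hi <- n_grid[min(length(n_grid), i0 + 1L)]
  opt <- optimize(function(n) .freundlich_ssr(n, x, y)$ssr,
                  lower = lo, upper = hi, tol = 1e-12)
  cand <- list(c(opt$minimum, opt$objective),
               c(1, .freundlich_ssr(1, x, y)$ssr))
  best <- cand[[which.min(vapply(cand, `[`, 0, 2))]]
  n_F <- best[1]
  pr <- .freundlich_ssr(n_F, x, y)
  k_F <- pr$k
  .assert(is.finite(k_F) && k_F > 0,
          "loading fit failed: non-positive prefactor", "feoc_fit_error")
  ssr <- pr$ssr
  m <- length(x)
  yhat <- k_F * x^n_F
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1

  # covariance on (log k_F, n_F) from the Jacobian at the optimum, with a
  # heteroscedasticity-consistent (sandwich) middle term: replicate
  # loading scatter has both an absolute floor and a component
  # proportional to the loading, so a homoscedastic estimate undercovers
  J <- cbind(log_k = yhat, n = yhat * log(x))
  r <- y - yhat
  covariance <- matrix(0, 2, 2)
  if (m > 2 && ssr > 0) {
    bread <- solve(crossprod(J))
    meat <- crossprod(J * r)
    covariance <- (m / (m - 2)) * bread %*% meat %*% bread
  }
  dimnames(covariance) <- list(c("log_k", "n"), c("log_k", "n"))

  structure(list(mineral = if (length(mineral)) mineral else NA_character_,
                 endmember = if (length(endmember)) endmember else
                   NA_character_,
                 k_F = k_F, n_F = n_F, covariance = covariance,
                 rmse = sqrt(ssr / m), r2 = r2, n_points = m,
                 boundary = abs(n_F - 1) < 1e-8),
            class = "feoc_loading_fit")
}

# profiled sum of squares for the dual-exponential: for fixed decay scales
# the amplitudes are linear (2x2 normal equations)
.dualexp_ssr <- function(lx, x, d) {
  e1 <- exp(-x / exp(lx[1])); e2 <- exp(-x / exp(lx[2]))
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)),
             c(sum(e1 * e2), sum(e2 * e2)))
  b <- c(sum(e1 * d), sum(e2 * d))
  a <- tryCatch(solve(G, b), error = function(e) {
    # near-collinear basis (x1 ~ x2): collapse to a single exponential
    atot <- b[1] / G[1, 1]
    c(atot, 0)
  })
  r <- d - a[1] * e1 - a[2] * e2
  list(a = a, ssr = sum(r * r))
}

#' Fit a dual-exponential isotope-offset curve
#'
#' Least squares of `Delta13C(x) = a1 * exp(-x/x1) + a2 * exp(-x/x2)` with
#' positive decay scales, which enforces convergence of the offset to zero
#' at high DOC/Fe(III). The objective is multimodal in (x1, x2), so the
#' fit runs a deterministic 16-point multi-start on a log-spaced (x1, x2)
#' lattice, profiling the (linear) amplitudes at each step, followed by
#' Nelder-Mead refinement of `(log x1, log x2)`. The decay scales are
#' reported in canonical order `x1 <= x2`; a near-degenerate pair
#' (`x1 ~ x2`) is flagged as effectively single-exponential.
#'
#' @param points Rows for a single (mineral, end member) pair with columns
#'   `x` and `delta13c`; at least 5 distinct `x` values.
#' @return A `feoc_delta_fit`: `a1`, `a2`, `x1`, `x2`, 4x4 `covariance` on
#'   (a1, a2, log x1, log x2), `rmse` (permil), `r2`, `n_points`,
#'   `single_exponential` flag.
#' @export
fit_delta_curve <- function(points) {
  .assert(is.data.frame(points) && all(c("x", "delta13c") %in% names(points)),
          "points must contain x and delta13c columns", "feoc_data_error")
  x <- points$x; d <- points$delta13c
  .assert(all(x > 0), "x must be positive", "feoc_domain_error")
  .assert(length(unique(x)) >= 5,
          "need at least 5 distinct x values to fit a delta curve",
          "feoc_insufficient_data_error")
  mineral <- unique(points$mineral); endmember <- unique(points$endmember)

  starts <- log(10^seq(log10(min(x) / 3), log10(max(x) * 3),
                       length.out = 4))
  lattice <- expand.grid(l1 = starts, l2 = starts)
  obj <- function(lx) .dualexp_ssr(lx, x, d)$ssr
  best <- NULL
  for (i in seq_len(nrow(lattice))) {
    st <- as.numeric(lattice[i, ])
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the best start
  best <- optim(best$par, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-15, maxit = 5000))
  .assert(is.finite(best$value), "delta curve fit did not converge",
          "feoc_fit_error")
  pr <- .dualexp_ssr(best$par, x, d)
  x12 <- exp(best$par); a <- pr$a
  if (x12[1] > x12[2]) { x12 <- rev(x12); a <- rev(a) }
  ssr <- pr$ssr
  m <- length(x)
  sst <- sum((d - mean(d))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  single <- abs(log(x12[2] / x12[1])) < 1e-3

  e1 <- exp(-x / x12[1]); e2 <- exp(-x / x12[2])
  J <- cbind(a1 = e1, a2 = e2,
             log_x1 = a[1] * e1 * x / x12[1],
             log_x2 = a[2] * e2 * x / x12[2])
  sigma2 <- if (m > 4) ssr / (m - 4) else 0
  nm <- c("a1", "a2", "log_x1", "log_x2")
  covariance <- matrix(0, 4, 4, dimnames = list(nm, nm))
  if (sigma2 > 0 && !single) {
    covariance <- tryCatch(sigma2 * solve(crossprod(J)),
                           error = function(e) covariance)
    dimnames(covariance) <- list(nm, nm)
  }

  structure(list(mineral = if (length(mineral)) mineral else NA_character_,
                 endmember = if (length(endmember)) endmember else
                   NA_character_,
                 a1 = a[1], a2 = a[2], x1 = x12[1], x2 = x12[2],
                 covariance = covariance, rmse = sqrt(ssr / m), r2 = r2,
                 n_points = m, single_exponential = single),
            class = "feoc_delta_fit")
}

#' Fit a complete calibration set from a co-precipitation table
#'
#' Applies the selection policy, pools points across retained conditions
#' within each (mineral, end member) pair (the calibration signals are
#' consistent across environmentally relevant conditions, so one curve per
#' pair) and fits a loading and a Delta13C curve per pair.
#'
#' @param points Co-precipitation table.
#' @param ... Passed to [select_calibration_points()].
#' @return A `feoc_calibration_set`: named list of
#'   `list(loading =, delta =)` fits keyed `"mineral|endmember"`, with the
#'   selection policy recorded.
#' @export
fit_calibration_set <- function(points, ...) {
  sel <- select_calibration_points(points, ...)
  groups <- split(sel, .pair_key(sel$mineral, sel$endmember))
  fits <- lapply(groups, function(g)
    list(loading = fit_loading_curve(g), delta = fit_delta_curve(g)))
  structure(list(fits = fits,
                 selection_policy = list(...),
                 exclusions = attr(sel, "exclusions")),
            class = "feoc_calibration_set")
}

.get_fit <- function(set, mineral, endmember) {
  key <- .pair_key(mineral, endmember)
  f <- set$fits[[key]]
  .assert(!is.null(f), sprintf("calibration set has no pair %s", key),
          "feoc_lookup_error")
  f
}

#' Evaluate fitted calibration curves
#'
#' @param set A `feoc_calibration_set`.
#' @param mineral,endmember Pair to evaluate.
#' @param x DOC/Fe(III) mole ratio(s), positive.
#' @return List with numeric vectors `loading` (wt%) and `delta` (permil).
#' @export
evaluate_curves <- function(set, mineral, endmember, x) {
  .assert(all(x > 0), "x must be positive", "feoc_domain_error")
  f <- .get_fit(set, mineral, endmember)
  list(loading = f$loading$k_F * x^f$loading$n_F,
       delta = f$delta$a1 * exp(-x / f$delta$x1) +
         f$delta$a2 * exp(-x / f$delta$x2))
}

#' Fit-quality report for a calibration set
#'
#' One row per fitted curve with RMSE, r2 and pass/fail flags against
#' configurable quality thresholds. The defaults (loading RMSE <= 0.09 wt%,
#' Delta13C RMSE <= 1.3 permil, r2 >= 0.83) are the bounds a well-behaved
#' co-precipitation calibration is expected to meet.
#'
#' @param set A `feoc_calibration_set`.
#' @param rmse_loading_max,rmse_delta_max,r2_min Quality thresholds.
#' @return Data frame with columns `mineral`, `endmember`, `curve`,
#'   `rmse`, `r2`, `n_points`, `rmse_pass`, `r2_pass`.
#' @export
fit_quality_report <- function(set, rmse_loading_max = 0.09,
                               rmse_delta_max = 1.3, r2_min = 0.83) {
  .assert(inherits(set, "feoc_calibration_set") && length(set$fits) > 0,
          "set must be a non-empty calibration set", "feoc_data_error")
  rows <- lapply(set$fits, function(f) {
    rbind(data.frame(mineral = f$loading$mineral,
                     endmember = f$loading$endmember, curve = "loading",
                     rmse = f$loading$rmse, r2 = f$loading$r2,
                     n_points = f$loading$n_points,
                     rmse_pass = f$loading$rmse <= rmse_loading_max,
                     r2_pass = f$loading$r2 >= r2_min,
                     stringsAsFactors = FALSE),
          data.frame(mineral = f$delta$mineral,
                     endmember = f$delta$endmember, curve = "delta13c",
                     rmse = f$delta$rmse, r2 = f$delta$r2,
                     n_points = f$delta$n_points,
                     rmse_pass = f$delta$rmse <= rmse_delta_max,
                     r2_pass = f$delta$r2 >= r2_min,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
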