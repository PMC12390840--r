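test_that("selection policy drops extreme conditions and raw fractions", {
  truth <- default_truth()[c("goethite|M-DOC")]
  des <- experiment_design(condition_grid = default_conditions(extreme = TRUE),
                           points_per_decade = 2, replicates = 1)
  tab <- generate_coprecip_table(truth, des, seed = 1)
  sel <- select_calibration_points(tab)
  expect_false(any(sel$temperature == 95))
  expect_false(any(sel$pH == 11.5))
  expect_true(all(sel$fraction == "-Fh/PC-ads.OC"))
  # all-compliant input passes through unchanged
  ok <- tab[tab$temperature != 95 & tab$pH != 11.5 &
              tab$fraction == "-Fh/PC-ads.OC", ]
  rownames(ok) <- NULL
  sel_ok <- select_calibration_points(ok)
  expect_equal(sel_ok, ok, ignore_attr = TRUE)
  expect_identical(unname(attr(sel_ok, "exclusions")), c(0L, 0L, 0L))
  # counting: 10 rows, 4 raw -> 6 retained, exclusion report fraction = 4
  ten <- ok[rep(seq_len(nrow(ok)), length.out = 10), ]
  rownames(ten) <- NULL
  ten$fraction[1:4] <- "raw"
  sel10 <- select_calibration_points(ten)
  expect_identical(nrow(sel10), 6L)
  expect_identical(attr(sel10, "exclusions")[["fraction"]], 4L)
  # empty result names the binding rule
  allraw <- ok[1:5, ]; allraw$fraction <- "raw"
  expect_error(select_calibration_points(allraw), "fraction")
})

test_that("loading fit recovers noiseless parameters and honours the exponent bound", {
  x <- 10^seq(-2, 1, length.out = 30)
  pts <- data.frame(mineral = "goethite", endmember = "M-DOC",
                    x = x, loading = 0.6 * x^0.4)
  fit <- fit_loading_curve(pts)
  expect_equal(fit$k_F, 0.6, tolerance = 1e-6)
  expect_equal(fit$n_F, 0.4, tolerance = 1e-6)
  expect_false(fit$boundary)
  # a linear generating law pins the exponent to the n = 1 boundary
  lin <- data.frame(mineral = "goethite", endmember = "M-DOC",
                    x = x, loading = 0.25 * x)
  flin <- fit_loading_curve(lin)
  expect_equal(flin$n_F, 1)
  expect_true(flin$boundary)
  expect_equal(flin$rmse, 0, tolerance = 1e-12)
  expect_error(fit_loading_curve(pts[c(1, 1, 1), ]), "distinct")
})

test_that("noisy loading fit matches the dense grid-search oracle", {
  x <- rep(10^seq(-2, 1, length.out = 30), each = 1)
  set.seed(21)
  y <- 0.32 * x^0.38 + rnorm(length(x), sd = 0.02)
  pts <- data.frame(mineral = "goethite", endmember = "M-DOC",
                    x = x, loading = y)
  fit <- fit_loading_curve(pts)
  expect_gte(fit$rmse, 0.01)
  expect_lte(fit$rmse, 0.04)
  oracle <- oracle_freundlich_grid(x, y)
  expect_lt(abs(fit$rmse - oracle$rmse), 1e-9)
  expect_lte(fit$rmse, oracle$rmse + 1e-12)
})

test_that("delta curve fit recovers noiseless parameters and decays to zero", {
  x <- 10^seq(-2.5, 1, length.out = 40)
  d <- -6 * exp(-x / 0.05) - 4 * exp(-x / 0.5)
  pts <- data.frame(mineral = "goethite", endmember = "M-DOC",
                    x = x, delta13c = d)
  fit <- fit_delta_curve(pts)
  expect_equal(c(fit$a1, fit$x1, fit$a2, fit$x2),
               c(-6, 0.05, -4, 0.5), tolerance = 1e-4)
  expect_lte(fit$x1, fit$x2)
  # fitted curve converges to zero far beyond the slow decay scale
  far <- 100 * fit$x2
  tail <- fit$a1 * exp(-far / fit$x1) + fit$a2 * exp(-far / fit$x2)
  expect_lt(abs(tail), 1e-4)
})

test_that("delta curve fit reaches the multi-start oracle optimum on noisy data", {
  x <- 10^seq(-2.5, 1, length.out = 40)
  set.seed(31)
  d <- -6 * exp(-x / 0.05) - 4 * exp(-x / 0.5) + rnorm(length(x), sd = 0.2)
  pts <- data.frame(mineral = "goethite", endmember = "M-DOC",
                    x = x, delta13c = d)
  fit <- fit_delta_curve(pts)
  oracle_rmse <- oracle_dualexp_multistart(x, d)
  expect_equal(fit$rmse, oracle_rmse, tolerance = 1e-6)
})

test_that("refitting a fit's own predictions is idempotent", {
  x <- 10^seq(-2, 1, length.out = 25)
  set.seed(5)
  pts <- data.frame(mineral = "goethite", endmember = "C-DOC", x = x,
                    loading = 0.22 * x^0.45 + rnorm(25, sd = 0.01),
                    delta13c = -8 * exp(-x / 0.04) - 3 * exp(-x / 0.6) +
                      rnorm(25, sd = 0.15))
  lf <- fit_loading_curve(pts)
  df <- fit_delta_curve(pts)
  pred <- data.frame(mineral = "goethite", endmember = "C-DOC", x = x,
                     loading = lf$k_F * x^lf$n_F,
                     delta13c = df$a1 * exp(-x / df$x1) +
                       df$a2 * exp(-x / df$x2))
  lf2 <- fit_loading_curve(pred)
  df2 <- fit_delta_curve(pred)
  expect_equal(c(lf2$k_F, lf2$n_F), c(lf$k_F, lf$n_F), tolerance = 1e-8)
  expect_equal(c(df2$a1, df2$a2, df2$x1, df2$x2),
               c(df$a1, df$a2, df$x1, df$x2), tolerance = 1e-6)
})

test_that("fitted loading curves are monotone non-decreasing and vanish at the origin", {
  cal <- noiseless_calibration()
  xg <- 10^seq(-4, 2, length.out = 200)
  for (key in names(cal$fits)) {
    f <- cal$fits[[key]]$loading
    L <- f$k_F * xg^f$n_F
    expect_true(all(diff(L) >= 0))
    expect_equal(f$k_F * 1e-300^f$n_F, 0, tolerance = 1e-30)
  }
})

test_that("evaluate_curves matches closed forms and flags missing pairs", {
  cal <- manual_calibration(list(
    list(mineral = "goethite", endmember = "M-DOC", k = 0.5, n = 1,
         a1 = 0, a2 = 0, x1 = 0.05, x2 = 0.5)))
  ev <- evaluate_curves(cal, "goethite", "M-DOC", 0.1)
  expect_equal(ev$loading, 0.05)
  expect_equal(ev$delta, 0)
  # x -> 0+ limit of a dual exponential is a1 + a2
  cal2 <- manual_calibration(list(
    list(mineral = "goethite", endmember = "M-DOC", k = 0.5, n = 0.5,
         a1 = -6, a2 = -4, x1 = 0.05, x2 = 0.5)))
  ev2 <- evaluate_curves(cal2, "goethite", "M-DOC", 1e-12)
  expect_equal(ev2$delta, -10, tolerance = 1e-9)
  expect_error(evaluate_curves(cal, "haematite", "M-DOC", 1), "no pair")
  expect_error(evaluate_curves(cal, "goethite", "M-DOC", -1), "positive")
})

test_that("fit-quality report applies the default thresholds", {
  cal <- noiseless_calibration()
  rep0 <- fit_quality_report(cal)
  expect_true(all(rep0$rmse < 1e-6))
  expect_true(all(rep0$r2 > 1 - 1e-9))
  expect_true(all(rep0$rmse_pass & rep0$r2_pass))
  expect_identical(formals(fit_quality_report)$rmse_loading_max, 0.09)
  expect_identical(formals(fit_quality_report)$rmse_delta_max, 1.3)
  expect_identical(formals(fit_quality_report)$r2_min, 0.83)
  # a loading rmse of 0.10 wt% fails the loading flag
  cal$fits[[1]]$loading$rmse <- 0.10
  rep1 <- fit_quality_report(cal)
  bad <- rep1[rep1$curve == "loading" &
                rep1$endmember == cal$fits[[1]]$loading$endmember &
                rep1$mineral == cal$fits[[1]]$loading$mineral, ]
  expect_false(bad$rmse_pass)
})

test_that("loading-fit confidence intervals achieve near-nominal coverage", {
  tr <- default_truth()[["goethite|M-DOC"]]
  truth1 <- default_truth()["goethite|M-DOC"]
  des <- experiment_design()
  hits_k <- hits_n <- logical(200)
  for (i in 1:200) {
    tab <- generate_coprecip_table(truth1, des, seed = 5000 + i)
    fit <- fit_loading_curve(tab)
    se <- sqrt(diag(fit$covariance))
    hits_k[i] <- abs(log(fit$k_F) - log(tr$k_F)) <= 1.96 * se[1]
    hits_n[i] <- abs(fit$n_F - tr$n_F) <= 1.96 * se[2]
  }
  expect_gte(mean(hits_k), 0.9)
  expect_gte(mean(hits_n), 0.9)
})
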