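test_that("scenario fractions live on the simplex and follow the transitions", {
  roa <- scenario("rise_of_algae")
  expect_equal(unname(scenario_fractions(roa, 900)), c(0, 1, 0))
  expect_equal(unname(scenario_fractions(roa, 500)), c(1, 0, 0))
  pae <- scenario("proterozoic_active_eukaryotes")
  expect_equal(unname(scenario_fractions(pae, 800)), c(0.5, 0.5, 0))
  expect_equal(unname(scenario_fractions(pae, 100)), c(1, 0, 0))
  expect_equal(unname(scenario_fractions(scenario("FA_only"), 1200)),
               c(0, 0, 1))
  # simplex constraint across scenarios and ages
  for (nm in c("M_only", "C_only", "FA_only", "rise_of_algae",
               "proterozoic_active_eukaryotes")) {
    scn <- scenario(nm)
    for (age in c(0, 123, 541, 780, 781, 1100, 1650)) {
      f <- scenario_fractions(scn, age)
      expect_true(all(f >= 0))
      expect_equal(sum(f), 1)
    }
  }
  # linear ramp spans the step and stays on the simplex
  ramp <- scenario("rise_of_algae", ramp_width = 100)
  f_mid <- scenario_fractions(ramp, 780)
  expect_equal(unname(f_mid), c(0.5, 0.5, 0))
  expect_error(scenario_fractions(roa, 1700), "0-1650")
  expect_error(scenario_fractions(scenario("unconstrained"), 100),
               "unconstrained")
})

test_that("forward model reduces correctly and obeys isotope mass balance", {
  cal <- manual_calibration(list(
    list(mineral = "goethite", endmember = "M-DOC", k = 0.2, n = 0.4,
         a1 = -8, a2 = 0, x1 = 1e12, x2 = 2e12),
    list(mineral = "goethite", endmember = "C-DOC", k = 0.4, n = 0.4,
         a1 = -2, a2 = 0, x1 = 1e12, x2 = 2e12),
    list(mineral = "goethite", endmember = "FA", k = 0.2, n = 0.4,
         a1 = -8, a2 = 0, x1 = 1e12, x2 = 2e12)))
  # unit vector reduces to the single end-member curves
  f1 <- forward_model(cal, "goethite", c(1, 0, 0), 1)
  expect_equal(f1$loading, 0.2)
  expect_equal(f1$delta, -8, tolerance = 1e-9)
  # identical end members make the mixture independent of f
  cal_same <- manual_calibration(lapply(c("M-DOC", "C-DOC", "FA"),
    function(em) list(mineral = "goethite", endmember = em, k = 0.3,
                      n = 0.5, a1 = -5, a2 = -1, x1 = 0.1, x2 = 0.9)))
  fa <- forward_model(cal_same, "goethite", c(0.2, 0.3, 0.5), 0.7)
  fb <- forward_model(cal_same, "goethite", c(1, 0, 0), 0.7)
  expect_equal(fa, fb, tolerance = 1e-12)
  # hand mass balance: L1 = 0.2, L2 = 0.4, d1 = -8, d2 = -2 at x = 1,
  # f = (0.5, 0.5, 0): L = 0.3, Delta = (0.5*0.2*-8 + 0.5*0.4*-2)/0.3 = -4
  fm <- forward_model(cal, "goethite", c(0.5, 0.5, 0), 1)
  expect_equal(fm$loading, 0.3)
  expect_equal(fm$delta, -4, tolerance = 1e-9)
  expect_error(forward_model(cal, "goethite", c(0.5, 0.5, 0.5), 1),
               "simplex")
})

test_that("loading inversion is exact, round-trips and clamps out of range", {
  cal <- manual_calibration(list(
    list(mineral = "goethite", endmember = "M-DOC", k = 0.5, n = 1,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1),
    list(mineral = "goethite", endmember = "C-DOC", k = 0.3, n = 0.5,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1),
    list(mineral = "goethite", endmember = "FA", k = 0.8, n = 0.25,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1)))
  x <- invert_loading(cal, "goethite", c(1, 0, 0), 0.05)
  expect_equal(as.numeric(x), 0.1, tolerance = 1e-9)
  expect_false(attr(x, "clamped"))
  # round trip over random mixtures and ratios
  set.seed(12)
  for (i in 1:100) {
    f <- runif(3); f <- f / sum(f)
    x0 <- 10^runif(1, -3, 1.5)
    L <- forward_model(cal, "goethite", f, x0)$loading
    xi <- invert_loading(cal, "goethite", f, L)
    expect_equal(as.numeric(xi), x0, tolerance = 1e-8)
  }
  # observation above the loading at x_max clamps with a flag
  Lmax <- forward_model(cal, "goethite", c(1, 0, 0), 100)$loading
  xc <- invert_loading(cal, "goethite", c(1, 0, 0), Lmax * 2)
  expect_equal(as.numeric(xc), 100)
  expect_true(attr(xc, "clamped"))
  expect_error(invert_loading(cal, "goethite", c(1, 0, 0), -1), "positive")
})

test_that("noiseless reconstruction recovers the generating history exactly", {
  truth <- default_truth()
  hist <- true_history(sigma_load_meas = 0, sigma_d13c_meas = 0)
  scn <- scenario("rise_of_algae")
  rec <- generate_record(hist, truth, scn, seed = 5)
  rec$loading_sd <- 0; rec$d13c_sd <- 0
  cal <- noiseless_calibration()
  rr <- reconstruct_record(rec, cal, scn, mc_config(n_draws = 200, seed = 1))
  truth_ds <- hist$doc_star(rr$age)
  expect_equal(rr$doc_star, truth_ds, tolerance = 1e-6)
  expect_equal(rr$d13c_doc, hist$d13c_doc(rr$age), tolerance = 1e-5)
  # delta13C_DOC reconstruction is unbiased in the noiseless limit
  expect_lt(max(abs(rr$d13c_doc - hist$d13c_doc(rr$age))), 1e-5)
})

test_that("the modern reference identity holds per draw", {
  truth <- default_truth()
  hist <- true_history()
  scn <- scenario("rise_of_algae")
  rec <- generate_record(hist, truth, scn, seed = 6)
  cal <- noiseless_calibration()
  rr <- reconstruct_record(rec, cal, scn, mc_config(n_draws = 500, seed = 2),
                           keep_draws = TRUE)
  ds <- attr(rr, "draws")$doc_star
  modern <- which(rr$age < 100)
  per_draw_median <- apply(ds[modern, ], 2, median)
  expect_equal(per_draw_median, rep(1, ncol(ds)), tolerance = 1e-12)
})

test_that("reconstruction is reproducible and invariant to sample order", {
  truth <- default_truth()
  hist <- true_history()
  scn <- scenario("proterozoic_active_eukaryotes")
  rec <- generate_record(hist, truth, scn, seed = 8)
  cal <- noiseless_calibration()
  cfg <- mc_config(n_draws = 300, seed = 7)
  r1 <- reconstruct_record(rec, cal, scn, cfg)
  r2 <- reconstruct_record(rec, cal, scn, cfg)
  expect_identical(r1$doc_star, r2$doc_star)
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  r3 <- reconstruct_record(shuffled, cal, scn, cfg)
  m <- match(r1$sample_id, r3$sample_id)
  expect_equal(r1$doc_star, r3$doc_star[m], tolerance = 1e-14)
  expect_equal(r1$d13c_doc_lo, r3$d13c_doc_lo[m], tolerance = 1e-14)
})

test_that("reconstruction demands a modern anchor under the default policy", {
  truth <- default_truth()
  fm <- data.frame(formation = "old", age = 1200, mineral = "goethite",
                   n_samples = 3)
  hist <- true_history(formations = fm)
  scn <- scenario("C_only")
  rec <- generate_record(hist, truth, scn, seed = 1)
  cal <- noiseless_calibration()
  expect_error(reconstruct_record(rec, cal, scn,
                                  mc_config(n_draws = 100, seed = 1)),
               "modern reference")
  # the fixed_x policy works without modern samples
  rr <- reconstruct_record(rec, cal, scn,
                           mc_config(n_draws = 100, seed = 1,
                                     modern_reference_policy = "fixed_x"))
  expect_equal(nrow(rr), 3L)
})

test_that("free-mixture optimization searches the full simplex and favours certainty", {
  lcov_big <- diag(c(0.3, 0.02))
  cal <- manual_calibration(list(
    list(mineral = "goethite", endmember = "M-DOC", k = 0.3, n = 0.4,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1),
    list(mineral = "goethite", endmember = "C-DOC", k = 0.3, n = 0.4,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1, lcov = lcov_big),
    list(mineral = "goethite", endmember = "FA", k = 0.3, n = 0.4,
         a1 = 0, a2 = 0, x1 = 0.1, x2 = 1, lcov = lcov_big)))
  sample1 <- data.frame(sample_id = "s1", formation = "f", age = 400,
                        mineral = "goethite", loading = 0.2,
                        loading_sd = 0, d13c_feoc = -25, d13c_sd = 0,
                        palaeolatitude = NA_real_)
  res <- optimize_scenario_free(sample1, cal,
                                mc_config(n_draws = 400, seed = 3,
                                          modern_reference_policy =
                                            "fixed_x"))
  # simplex grid at step 0.05 has 231 candidates
  expect_identical(nrow(res$grid), 231L)
  # the zero-variance end member wins
  expect_equal(unname(res$f), c(1, 0, 0))
  expect_gte(min(res$grid$ci_width), 0)
})

test_that("record binning follows right-open 100 Myr bins", {
  v <- data.frame(age = c(50, 120, 180), value = c(1, 2, 4))
  b <- bin_record(v)
  expect_identical(nrow(b), 2L)
  b0 <- b[b$bin_lo == 0, ]; b1 <- b[b$bin_lo == 100, ]
  expect_identical(b0$n, 1L)
  expect_identical(b1$n, 2L)
  expect_equal(b1$mean, 3)
  # constant values: zero spread everywhere
  vc <- data.frame(age = c(10, 110, 115, 320), value = 2.5)
  bc <- bin_record(vc)
  expect_true(all(bc$mean == 2.5))
  expect_true(all(bc$sd == 0))
  # boundary ages fall in the right-open upper bin
  vb <- data.frame(age = c(99.9999, 100), value = c(1, 2))
  bb <- bin_record(vb)
  expect_identical(bb$n, c(1L, 1L))
  # per-mineral sub-bins
  vm <- data.frame(age = c(450, 460, 455), value = c(1, 2, 3),
                   mineral = c("goethite", "goethite", "haematite"))
  bm <- bin_record(vm, by_mineral = TRUE)
  expect_identical(sort(unique(bm$mineral)),
                   c("all", "goethite", "haematite"))
  expect_equal(bm$mean[bm$mineral == "goethite"], 1.5)
})

test_that("group comparison matches the Welch formula and is symmetric", {
  g <- c(1, 2, 3)
  res_same <- compare_groups(g, g)
  expect_equal(res_same$t, 0)
  expect_equal(res_same$p, 1)
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  res <- compare_groups(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  res_swap <- compare_groups(b, a)
  expect_equal(res_swap$p, res$p, tolerance = 1e-14)
  expect_equal(res_swap$t, -res$t, tolerance = 1e-14)
  expect_error(compare_groups(1, b), "at least 2")
})

test_that("running averages behave on constant, single-point and linear series", {
  const <- data.frame(age = seq(0, 500, 25), value = 3)
  rc <- running_average(const)
  expect_true(all(rc$value == 3))
  single <- data.frame(age = 250, value = 7)
  rs <- running_average(single, window = 100,
                        grid = seq(0, 500, 10))
  inside <- abs(rs$age - 250) <= 50
  expect_true(all(rs$value[inside] == 7))
  expect_true(all(is.na(rs$value[!inside])))
  lin <- data.frame(age = seq(0, 1000, 10), value = seq(0, 1000, 10) * 2)
  rl <- running_average(lin, window = 100, grid = seq(100, 900, 50))
  expect_equal(rl$value, rl$age * 2, tolerance = 1e-12)
})
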