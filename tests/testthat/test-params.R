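test_that("compound parameters satisfy their defining identities exactly", {
  p <- xyl_params()
  cp <- derive_compound(p)
  expect_identical(cp$E_m, p$pAm_b / p$v_b)
  expect_identical(cp$k_M, p$p_M / p$E_G)
  expect_identical(cp$L_m, p$kappa * p$pAm_b / p$p_M)
  expect_identical(cp$g, p$E_G / (p$kappa * cp$E_m))
  expect_identical(cp$omega, cp$E_m * p$w_E / (p$d_V * p$mu_E))
  ## the two printed routes to the acceleration factor agree within 0.5%
  expect_equal(p$pAm_j / p$pAm_b, p$v_j / p$v_b, tolerance = 0.005)
})

test_that("parameter validation rejects unphysical sets", {
  expect_error(deb_params(kappa = 1.2), "kappa")
  expect_error(deb_params(kappa = -0.1), "positive")
  expect_error(deb_params(p_M = 0), "positive")
  expect_error(deb_params(EH_b = 0.05), "ordered")   # above EH_j
  expect_warning(deb_params(v_j = 0.02), "disagree") # breaks the s_M ratio
})

test_that("parameter files round-trip at full precision", {
  p <- xyl_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_deb_params(p, path)
  q <- read_deb_params(path)
  for (nm in setdiff(names(p), "meta"))
    expect_identical(q[[nm]], p[[nm]], info = nm)
  expect_identical(q$meta$species, p$meta$species)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(bogus = 1), bad, auto_unbox = TRUE)
  expect_error(read_deb_params(bad), "unknown")
})

test_that("Arrhenius correction is 1 at T_ref, increasing, and log-linear in 1/T", {
  p <- xyl_params()
  expect_equal(arrhenius_correction(p$T_ref - 273.15, p), 1)
  Ts <- seq(-1, 25, by = 2)
  cs <- arrhenius_correction(Ts, p)
  expect_true(all(diff(cs) > 0))
  ## ln c(T1) - ln c(T2) = T_A (1/T2K - 1/T1K) for arbitrary pairs
  set.seed(7)
  for (i in 1:20) {
    T12 <- runif(2, 0, 30)
    lhs <- diff(-log(arrhenius_correction(T12, p)))
    rhs <- p$T_A * diff(1 / (T12 + 273.15))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  expect_error(arrhenius_correction(-300, p), "non-physical")
})

test_that("shell-height conversion is stagewise, monotone and invertible", {
  p <- xyl_params()
  expect_identical(shell_height(0, "adult", p), 0)
  V <- 10^seq(-9, 0, length.out = 30)
  for (st in c("larva_accelerating", "adult")) {
    Lw <- shell_height(V, st, p)
    expect_true(all(diff(Lw) > 0))
    expect_equal(structural_volume(Lw, st, p), V, tolerance = 1e-12)
  }
  ## larval and adult shapes differ for the same structure
  expect_gt(shell_height(1e-4, "juvenile", p),
            shell_height(1e-4, "larva_pre_birth", p))
  expect_error(shell_height(1e-4, "imago", p), "unknown life stage")
})

test_that("wet weight is linear in reserve density and at least structural mass", {
  p <- xyl_params()
  expect_identical(wet_weight(0, 1, p), 0)
  V <- 2e-3
  w0 <- wet_weight(V, 0, p)
  w1 <- wet_weight(V, 1, p)
  wh <- wet_weight(V, 0.5, p)
  expect_equal(wh, (w0 + w1) / 2)
  expect_gte(w0, V)
  expect_error(wet_weight(V, 1.5, p), "reserve density")
})

test_that("hatch-threshold calibration reproduces the target hatching age", {
  p <- xyl_params()
  EH_h <- calibrate_hatch_threshold(p, age_hatch_d = 5.6, temp_C = 4)
  expect_equal(EH_h, p$EH_h, tolerance = 1e-6)  # shipped file is calibrated
  lc <- larval_chronology(p, f = 1, T_dispersal = 4)
  expect_equal(lc$age_hatch_d, 5.6, tolerance = 1e-3)
})
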