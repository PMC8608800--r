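test_that("egg cost is self-consistent and increasing in maternal food", {
  p <- xyl_params()
  E0_1 <- initial_reserve(p, 1)
  E0_08 <- initial_reserve(p, 0.8)
  expect_lt(E0_08, E0_1)
  ## forward integration with the returned E_0 reproduces e_b
  for (fm in c(0.8, 1)) {
    E0 <- if (fm == 1) E0_1 else E0_08
    b <- xylodeb:::.embryo_to_birth(p, E0, p$T_ref - 273.15)
    e_b <- b$E / (b$V * derive_compound(p)$E_m)
    expect_equal(e_b, fm, tolerance = 1e-6)
  }
  expect_error(initial_reserve(p, 0), "f_mother")
})

test_that("fluxes honour the kappa-rule bookkeeping and the embryo does not feed", {
  p <- xyl_params()
  st_embryo <- list(E = 5e-3, V = 5e-7, EH = 5e-4, ER = 0, stage = "embryo")
  fl <- deb_fluxes(st_embryo, temp_C = 4, f = 1, p)
  expect_identical(fl[["p_A"]], 0)
  st_ad <- list(E = 10, V = 0.05, EH = p$EH_p, ER = 2, stage = "adult",
                L_b = 0.0105, L_j = 0.0282)
  for (kap in c(0.06, 0.73)) {
    fl <- deb_fluxes(st_ad, temp_C = 11, f = 0.8, p, kappa_eff = kap)
    expect_equal(kap * fl[["p_C"]], fl[["p_S"]] + fl[["p_G"]])
    expect_equal((1 - kap) * fl[["p_C"]], fl[["p_J"]] + fl[["p_R"]])
  }
  expect_error(deb_fluxes(list(E = 1, V = 0, stage = "adult"), 4, 1, p),
               "V = 0")
})

test_that("integrated trajectory agrees with the flux equations (finite differences)", {
  ## independent audit: the R-side flux evaluation against a centred
  ## finite difference of the compiled integration
  p <- xyl_params()
  tr <- xyl_run(f = 1, temp_C = 4, horizon = 821)
  ch <- stage_chronology(tr)
  h <- 1e-3
  for (age in c(200, 600)) {   # juvenile and adult phases
    states <- integrate_life_cycle(p, constant_forcing(4, 1), horizon = 821,
                                   times = c(0, age - h, age, age + h))
    i <- which(abs(states$age_d - age) < h / 10)
    st <- list(E = states$E_J[i], V = states$V_cm3[i], EH = states$EH_J[i],
               ER = states$ER_J[i], stage = states$stage[i],
               L_b = ch$L_b_cm, L_j = ch$L_j_cm)
    fl <- deb_fluxes(st, temp_C = 4, f = 1, p)
    dE_fd <- (states$E_J[i + 1] - states$E_J[i - 1]) / (2 * h)
    dV_fd <- (states$V_cm3[i + 1] - states$V_cm3[i - 1]) / (2 * h)
    expect_equal(dE_fd, fl[["p_A"]] - fl[["p_C"]], tolerance = 1e-6)
    expect_equal(p$E_G * dV_fd, fl[["p_G"]], tolerance = 1e-6)
  }
})

test_that("stage transitions fire in order and maturity is monotone", {
  tr <- xyl_run(f = 1, temp_C = 4, horizon = 821)
  ch <- stage_chronology(tr)
  p <- xyl_params()
  expect_true(all(ch$reached))
  ages <- c(ch$age_hatch_d, ch$age_birth_d, ch$age_metamorphosis_d,
            ch$age_puberty_d)
  expect_true(all(diff(ages) > 0))
  expect_equal(ch$age_settlement_d, ch$age_metamorphosis_d - 7)
  expect_true(all(diff(tr$EH_J) >= -1e-12))
  expect_lte(max(tr$EH_J), p$EH_p + 1e-9)
  expect_true(all(tr$ER_J[tr$age_d < ch$age_puberty_d] == 0))
  expect_true(all(diff(tr$ER_J) >= -1e-12))
  ## events located to the maturity thresholds
  ib <- which.min(abs(tr$age_d - ch$age_birth_d))
  expect_lt(abs(tr$EH_J[ib] - p$EH_b), 1e-9)   # |E_H - threshold| < 1e-9 J
  ## stage labels consistent with the event ages
  expect_true(all(tr$stage[tr$age_d < ch$age_hatch_d] == "embryo"))
  expect_true(all(tr$stage[tr$age_d > ch$age_puberty_d] == "adult"))
})

test_that("energy is conserved along the trajectory", {
  for (tr in list(xyl_run(1, 4, 821), xyl_run(0.5, 11, 404))) {
    E0 <- attr(tr, "E_0")
    p <- xyl_params()
    balance <- tr$cum_assim_J -
      ((tr$E_J - E0) + p$E_G * (tr$V_cm3 - tr$V_cm3[1]) + tr$EH_J +
         tr$ER_J + tr$cum_diss_J)
    scale <- max(tr$cum_assim_J[nrow(tr)], E0)
    expect_lt(max(abs(balance)) / scale, 1e-6)
  }
})

test_that("results are insensitive to the embryo seed volume and output resolution", {
  p <- xyl_params()
  fo <- constant_forcing(4, 1)
  sh <- vapply(c(1e-15, 1e-14), function(vs) {
    tr <- integrate_life_cycle(p, fo, horizon = 450, V_seed = vs,
                               times = c(0, 450))
    tr$shell_height_cm[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(diff(sh)) / sh[1], 1e-3)   # 10x seed changes size < 0.1%
  ## halving the output step does not move the terminal height
  tr1 <- xyl_run(1, 4, 821, dt = 1)
  tr2 <- integrate_life_cycle(p, fo, horizon = 821, dt = 0.5)
  expect_lt(abs(tr1$shell_height_cm[nrow(tr1)] -
                  tr2$shell_height_cm[nrow(tr2)]), 1e-6)
})

test_that("reserve density equilibrates at e = f under constant food", {
  p <- xyl_params()
  E_m <- derive_compound(p)$E_m
  tr <- xyl_run(f = 0.8, temp_C = 11, horizon = 404)
  ch <- stage_chronology(tr)
  late <- tr$age_d > ch$age_metamorphosis_d + 60
  e <- tr$E_J[late] / (tr$V_cm3[late] * E_m)
  expect_equal(max(abs(e - 0.8)), 0, tolerance = 1e-4)
})

test_that("zero food after birth arrests growth and drains reserve to death", {
  ## a larva cut off from food keeps growing briefly on its reserve,
  ## then growth arrests (structure held, no shrinking) and the reserve
  ## is drawn down by maintenance until death
  p <- xyl_params()
  tr <- integrate_life_cycle(
    p, forcing_schedule(c(0, 40), c(4, 4), c(1, 0)), horizon = 821)
  post <- tr[tr$age_d > 40, ]
  expect_true(all(diff(post$E_J) < 0))              # reserve monotone down
  expect_true(all(diff(post$V_cm3) > -1e-15))       # never shrinks
  n <- nrow(post)
  expect_equal(post$V_cm3[n], post$V_cm3[n - 10])   # growth arrested
  ch <- stage_chronology(tr)
  expect_true(ch$died)
  expect_false(ch$reached[["metamorphosis"]])
})

test_that("starvation endurance matches the reserve-drawdown integration", {
  p <- xyl_params()
  ## closed form at T_ref is [E_m]/[p_M], independent of T_A
  expect_equal(starvation_time(p, p$T_ref - 273.15),
               derive_compound(p)$E_m / p$p_M)
  p2 <- deb_params(T_A = 2 * p$T_A)
  expect_equal(starvation_time(p2, p2$T_ref - 273.15),
               starvation_time(p, p$T_ref - 273.15))
  ## ODE cross-check: once growth has arrested under starvation the
  ## drain is linear (structure and maturity held), so time from arrest
  ## to death is exactly E_arrest / (p_S + p_J)
  tr2 <- integrate_life_cycle(
    p, forcing_schedule(c(0, 40), c(4, 4), c(1, 0)), horizon = 821)
  ch2 <- stage_chronology(tr2)
  expect_true(ch2$died)
  post <- tr2[tr2$age_d > 40, ]
  V_final <- post$V_cm3[nrow(post)]
  i_arr <- which(post$V_cm3 > V_final * (1 - 1e-9))[1]
  cf <- arrhenius_correction(4, p)
  drain <- (p$p_M * V_final + p$k_J * min(post$EH_J[i_arr], p$EH_p)) * cf
  expect_equal(ch2$age_death_d - post$age_d[i_arr],
               post$E_J[i_arr] / drain, tolerance = 1e-3)
  expect_error(starvation_time(p, 4, e_start = 0), "e_start")
})

test_that("trajectory CSV writer emits the tidy column set", {
  tr <- xyl_run(1, 4, 821)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- utils::read.csv(path)
  expect_identical(names(df),
                   c("age_d", "T_C", "f", "E_J", "V_cm3", "EH_J", "ER_J",
                     "stage", "shell_height_cm", "wet_weight_g"))
  expect_equal(nrow(df), nrow(tr))
})
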