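test_that("closed-form growth rate matches the simulated late-time slope", {
  ## invariant: within 0.1% over the food x temperature grid
  p <- xyl_params()
  L_m <- derive_compound(p)$L_m
  for (f in c(0.5, 0.8, 1)) for (temp in c(4, 11, 16)) {
    r_B <- von_bertalanffy_rate(p, f, temp)
    tr <- integrate_life_cycle(p, constant_forcing(temp, f), horizon = 900,
                               dt = 5)
    ch <- stage_chronology(tr)
    L_inf <- f * ch$s_M * L_m
    late <- tr$age_d > ch$age_metamorphosis_d + 100
    slope <- -stats::coef(stats::lm(log(L_inf - tr$V_cm3[late]^(1 / 3)) ~
                                      tr$age_d[late]))[[2]]
    expect_equal(slope, r_B, tolerance = 1e-3)
  }
  expect_gt(von_bertalanffy_rate(p, 1, 11), von_bertalanffy_rate(p, 1, 4))
  expect_gt(von_bertalanffy_rate(p, 0.5, 4), von_bertalanffy_rate(p, 1, 4))
  expect_warning(von_bertalanffy_rate(p, 0, 4), "starvation")
})

test_that("shell height at age approaches the ultimate height", {
  p <- xyl_params()
  tr <- integrate_life_cycle(p, constant_forcing(16, 1), horizon = 6000,
                             times = c(0, 6000))
  s_M <- stage_chronology(tr)$s_M
  expect_equal(tr$shell_height_cm[nrow(tr)],
               ultimate_shell_height(p, 1, s_M = s_M), tolerance = 1e-3)
  expect_error(shell_height_at_age(p, constant_forcing(4, 1), -1),
               "precedes")
  expect_error(shell_height_at_age(p, constant_forcing(4, 1), 500,
                                   horizon = 400), "exceeds")
})

test_that("reproductive output increases with food and horizon, zero before puberty", {
  p <- xyl_params()
  t_f1 <- traits_for_scenario(p, 1, 4, 821)
  t_f05 <- traits_for_scenario(p, 0.5, 4, 821)
  t_short <- traits_for_scenario(p, 1, 4, 500)
  expect_gt(t_f1$TRO, t_f05$TRO)
  expect_gt(t_f1$TRO, t_short$TRO)
  pre <- traits_for_scenario(p, 1, 4, 200)   # puberty not yet reached
  expect_true(is.na(pre$age_puberty_d))
  expect_identical(pre$TRO, 0)
  expect_lte(t_f1$Lmax_cm,
             ultimate_shell_height(p, 1, s_M = 2.8) + 1e-6)
})

test_that("larval chronology obeys the settlement convention and PLD ordering", {
  p <- xyl_params()
  tab <- pld_table(p)   # f in {0.5, 0.8, 1} x T in {4, 11, 16}
  expect_equal(tab$pld_d,
               tab$age_metamorphosis_d - tab$age_hatch_d - 7)
  expect_true(all(tab$age_hatch_d < tab$age_birth_d))
  expect_true(all(tab$age_birth_d < tab$age_metamorphosis_d))
  ## PLD decreases with temperature at fixed f and with food at fixed T
  for (fv in unique(tab$f)) {
    s <- tab[tab$f == fv, ]
    expect_true(all(diff(s$pld_d[order(s$T_dispersal_C)]) < 0))
  }
  for (tv in unique(tab$T_dispersal_C)) {
    s <- tab[tab$T_dispersal_C == tv, ]
    expect_true(all(diff(s$pld_d[order(s$f)]) < 0))
  }
  expect_error(larval_chronology(p, f = 0.5, T_dispersal = 0, max_age = 60),
               "not reached")
})

test_that("dwarf scenario: mature at postlarval size, growth slow but not stopped", {
  p <- xyl_params()
  dw <- dwarf_scenario(p, query_ages = c(410, 821))
  expect_true(stage_chronology(dw$trajectory)$reached[["puberty"]])
  ## reproduction buffer already provisioned at the census age
  expect_gt(dw$at_ages$ER_J[1], 0)
  tr <- dw$trajectory
  post_j <- tr$age_d > stage_chronology(dw$trajectory)$age_metamorphosis_d
  expect_true(all(diff(tr$V_cm3[post_j]) > 0))   # growth did not cease
  ## the contrast scenario: starving the juvenile instead of switching
  ## kappa gives a similar size but no reproduction at all
  tr2 <- integrate_life_cycle(
    p, constant_forcing(4, 1,
                        kappa_override = list(at = "metamorphosis",
                                              kappa = p$kappa, f = 0.05)),
    horizon = 821)
  i410 <- which.min(abs(tr2$age_d - 410))
  expect_equal(tr2$shell_height_cm[i410], 0.055, tolerance = 0.2)
  expect_identical(tr2$ER_J[i410], 0)            # remains juvenile
  expect_false(stage_chronology(tr2)$reached[["puberty"]])
})

test_that("across the dwarf range, size grows with kappa and maturity stays early", {
  p <- xyl_params()
  kaps <- c(0.06, 0.12, 0.3, 0.73)
  res <- vapply(kaps, function(k) {
    dw <- dwarf_scenario(p, kappa_post_j = k, query_ages = c(410, 821))
    c(sh = dw$at_ages$shell_height_cm[2], er = dw$at_ages$ER_J[1],
      pub = dw$chronology$age_puberty_d)
  }, numeric(3))
  expect_true(all(diff(res["sh", ]) > 0))   # terminal size increasing in kappa
  ## every allocation in the range reproduces before the 410-d census,
  ## but only the lowest kappas keep the shell at dwarf size
  expect_true(all(res["er", ] > 0))
  expect_true(all(res["pub", ] < 410))
  expect_lt(res["sh", 1], 0.08)
  expect_gt(res["sh", 4], 0.4)
})
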