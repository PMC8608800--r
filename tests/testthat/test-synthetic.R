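test_that("generation is deterministic and substreams are name-stable", {
  s1 <- synthetic_spec(seed = 5)
  a <- generate_observation_set(s1)
  b <- generate_observation_set(synthetic_spec(seed = 5))
  expect_identical(a$zerovariate$value, b$zerovariate$value)
  expect_identical(a$univariate$oak$shell_height_cm,
                   b$univariate$oak$shell_height_cm)
  ## a different seed perturbs the values
  c_ <- generate_observation_set(synthetic_spec(seed = 6))
  expect_false(identical(a$zerovariate$value, c_$zerovariate$value))
  ## changing one series' sampling ages leaves the zerovariate stream and
  ## the other series untouched (per-name substreams)
  d <- generate_observation_set(synthetic_spec(seed = 5,
                                               series_ages = seq(90, 360,
                                                                 by = 90)))
  expect_identical(a$zerovariate$value, d$zerovariate$value)
  expect_error(generate_observation_set(
    synthetic_spec(series_ages = c(100, 1e5))), "beyond")
  expect_error(synthetic_spec(cv_zero = -0.1), "non-negative")
})

test_that("the noise model is multiplicative, lognormal and mean-preserving", {
  set.seed(99)
  x <- xylodeb:::.lognoise(20000, 0.05)
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(stats::sd(x), 0.05, tolerance = 0.05)
  expect_identical(xylodeb:::.lognoise(3, 0), rep(1, 3))
  ## replicate means converge on the noise-free value
  obs0 <- generate_observation_set(synthetic_spec(cv_zero = 0, cv_uni = 0))
  idx <- which(obs0$zerovariate$name == "max_shell_height")
  reps <- vapply(1:200, function(s) {
    set.seed(xylodeb:::.substream_seed(s, "zv_max_shell_height"))
    obs0$zerovariate$value[idx] * xylodeb:::.lognoise(1, 0.05)
  }, numeric(1))
  expect_equal(mean(reps), obs0$zerovariate$value[idx], tolerance = 0.01)
})

test_that("population census reproduces the deployment-sample statistics", {
  spec <- synthetic_spec()   # n = 333, census 410 d, 4 C, f = 1
  sizes <- generate_population_sizes(spec)
  expect_length(sizes, 333)
  expect_equal(attr(sizes, "mean_cm"), 0.27, tolerance = 0.08)
  ## degenerate spec: no settlement spread, no noise -> identical sizes
  s0 <- synthetic_spec(settlement_spread_d = 0, cv_pop = 0, n_pop = 10)
  sz0 <- generate_population_sizes(s0)
  expect_equal(diff(range(sz0)), 0, tolerance = 1e-9)
  tr <- integrate_life_cycle(xyl_params(), constant_forcing(4, 1),
                             horizon = 600)
  ch <- stage_chronology(tr)
  expect_equal(sz0[1], sh_at(tr, ch$age_settlement_d + 410),
               tolerance = 1e-3)
  ## dwarf census matches the dwarf-male sample scale
  dz <- generate_population_sizes(synthetic_spec(n_pop = 64), dwarf = TRUE)
  expect_equal(attr(dz, "mean_cm"), 0.0548, tolerance = 0.2)
  expect_error(generate_population_sizes(
    synthetic_spec(census_age_d = 50, settlement_spread_d = 120)),
    "settlement window")
})

test_that("noisier data degrade the fit score at the true parameters", {
  p <- xyl_params()
  losses <- vapply(c(0, 0.05, 0.15), function(cv) {
    obs <- generate_observation_set(synthetic_spec(seed = 21, cv_zero = cv,
                                                   cv_uni = cv))
    pred <- suppressWarnings(predict_observations(p, obs,
                                                  f_free = list(oak = 0.79)))
    xylodeb:::.sym_loss(xylodeb:::.stack_predictions(pred))
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})
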