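#' Specification for a synthetic observation set
#'
#' Describes how to emulate the observation data the calibration stage
#' expects: a set of zerovariate life-history traits (larval-culture
#' chronology and sizes, puberty and adult traits), two colonization
#' growth series on substrates of different food value (pine at satiety,
#' oak below it), and a census of shell heights from a long-deployment
#' colonization device.  All observed values are generated from a known
#' true parameter set plus multiplicative lognormal noise, so parameter
#' recovery can be tested against a known truth.
#'
#' Noise is mean-preserving lognormal: an observation with noise-free
#' value `m` and coefficient of variation `cv` is
#' `m * exp(s Z - s^2/2)` with `s^2 = log(1 + cv^2)`.  The single seed
#' fans out to one substream per entry and per series (keyed by name),
#' so adding a series never perturbs the values of existing ones.
#'
#' @param params true `deb_params` object.
#' @param temp_larval temperature of the larval-culture context,
#'   degrees C.
#' @param temp_adult temperature of the puberty/adult context, degrees C.
#' @param series_temp_C temperature of the growth series, degrees C.
#' @param series_ages sampling ages of the growth series, d.
#' @param f_pine food level of the pine series (fixed in calibration).
#' @param f_oak true food level of the oak series (free in calibration).
#' @param cv_zero coefficient of variation of zerovariate noise.
#' @param cv_uni coefficient of variation of univariate noise.
#' @param n_pop population census size.
#' @param census_age_d deployment duration before the census, d.
#' @param settlement_spread_d width of the uniform settlement-time
#'   window, d.
#' @param cv_pop measurement noise of the census, as a CV.
#' @param pop_temp_C,pop_f environment of the census population.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params = xylonora_params(),
                           temp_larval = 12, temp_adult = 11,
                           series_temp_C = 11,
                           series_ages = seq(60, 360, by = 30),
                           f_pine = 1, f_oak = 0.79,
                           cv_zero = 0.05, cv_uni = 0.10,
                           n_pop = 333, census_age_d = 410,
                           settlement_spread_d = 120, cv_pop = 0.10,
                           pop_temp_C = 4, pop_f = 1,
                           seed = 1L) {
  stopifnot(inherits(params, "deb_params"))
  if (cv_zero < 0 || cv_uni < 0 || cv_pop < 0)
    stop("coefficients of variation must be non-negative", call. = FALSE)
  if (n_pop <= 0) stop("n_pop must be positive", call. = FALSE)
  if (settlement_spread_d < 0)
    stop("settlement spread must be non-negative", call. = FALSE)
  structure(list(params = params, temp_larval = temp_larval,
                 temp_adult = temp_adult, series_temp_C = series_temp_C,
                 series_ages = series_ages, f_pine = f_pine, f_oak = f_oak,
                 cv_zero = cv_zero, cv_uni = cv_uni,
                 n_pop = n_pop, census_age_d = census_age_d,
                 settlement_spread_d = settlement_spread_d,
                 cv_pop = cv_pop, pop_temp_C = pop_temp_C, pop_f = pop_f,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## deterministic substream seed from the master seed and a name
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
  (as.integer(seed) * 127L + h * 7919L) %% 2147483647L
}

## mean-preserving multiplicative lognormal noise
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate a synthetic observation set
#'
#' Builds the noise-free model predictions for the zerovariate skeleton
#' and the two growth series implied by a [synthetic_spec()], applies the
#' spec's noise model, and returns them as an [observation_set()] ready
#' for [fit_parameters()].  With all CVs at zero the values equal the
#' model predictions exactly, so fitting at the true parameters gives a
#' loss of zero.
#'
#' @param spec a `synthetic_spec`.
#' @return An `observation_set`; the true oak food level and the seed are
#'   recorded in its `notes`.
#' @export
#' @examples
#' \donttest{
#' obs <- generate_observation_set(synthetic_spec(cv_zero = 0, cv_uni = 0))
#' }
generate_observation_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$params
  horizon_guard <- 5 * 821
  if (max(spec$series_ages) > horizon_guard)
    stop("series ages extend beyond any plausible lifespan horizon",
         call. = FALSE)

  skel <- data.frame(
    name = c("age_at_hatching", "age_at_birth",
             "time_birth_to_metamorphosis", "time_birth_to_puberty",
             "shell_height_at_hatching", "shell_height_at_birth",
             "shell_height_at_metamorphosis", "shell_height_at_puberty",
             "max_shell_height", "wet_weight_at_puberty",
             "max_reproduction_rate", "lifespan"),
    unit = c("d", "d", "d", "d", "cm", "cm", "cm", "cm", "cm", "g",
             "oocytes/d", "d"),
    temp_C = c(rep(spec$temp_larval, 3), spec$temp_adult,
               rep(spec$temp_larval, 3), rep(spec$temp_adult, 2),
               spec$temp_adult, spec$temp_adult, spec$temp_adult),
    f = 1,
    weight = c(rep(1, 11), 0),   # lifespan has no predictor: weight 0
    stringsAsFactors = FALSE)
  skel$value <- NA_real_

  obs0 <- observation_set(transform(skel, value = 1)[, c(
    "name", "value", "unit", "temp_C", "f", "weight")])
  pred <- suppressWarnings(predict_observations(p, obs0))
  truth <- pred$zerovariate$predicted
  ## lifespan entry: carried as the 4-degree horizon, not predicted
  truth[skel$name == "lifespan"] <- 821

  values <- vapply(seq_len(nrow(skel)), function(i) {
    set.seed(.substream_seed(spec$seed, paste0("zv_", skel$name[i])))
    truth[i] * .lognoise(1, spec$cv_zero)
  }, numeric(1))
  zv <- data.frame(name = skel$name, value = values, unit = skel$unit,
                   temp_C = skel$temp_C, f = skel$f, weight = skel$weight,
                   stringsAsFactors = FALSE)

  mk_series <- function(nm, f_s, free) {
    sh <- shell_height_at_age(p, constant_forcing(spec$series_temp_C, f_s),
                              age = spec$series_ages)
    set.seed(.substream_seed(spec$seed, paste0("uni_", nm)))
    list(name = nm, age_d = spec$series_ages,
         shell_height_cm = sh * .lognoise(length(sh), spec$cv_uni),
         temp_C = spec$series_temp_C,
         f = if (free) NULL else f_s, f_free = free, weight_total = 1)
  }
  uni <- list(mk_series("pine", spec$f_pine, FALSE),
              mk_series("oak", spec$f_oak, TRUE))

  observation_set(zv, uni,
                  notes = list(synthetic = TRUE, seed = spec$seed,
                               f_oak_true = spec$f_oak,
                               cv_zero = spec$cv_zero,
                               cv_uni = spec$cv_uni))
}

#' Generate a synthetic population shell-height sample
#'
#' Emulates a census of individuals collected from a colonization device
#' after a fixed deployment: colonists settle at times spread uniformly
#' over a window after deployment, each grows along the deterministic
#' trajectory for the remaining time, and measured shell heights carry
#' multiplicative lognormal noise.  An individual that settled at
#' deployment-day `s` has developmental age
#' `age_settlement + (census_age - s)` at the census.
#'
#' @param spec a `synthetic_spec`.
#' @param dwarf if `TRUE`, individuals follow the dwarf-male scenario
#'   (allocation switch at metamorphosis, `kappa = 0.06`, `f = 0.8`).
#' @return Numeric vector of shell heights (cm) of length `spec$n_pop`,
#'   with attributes `mean_cm`, `sd_cm`, `n`.
#' @export
#' @examples
#' \donttest{
#' sizes <- generate_population_sizes(synthetic_spec(n_pop = 50))
#' attr(sizes, "mean_cm")
#' }
generate_population_sizes <- function(spec, dwarf = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$census_age_d < spec$settlement_spread_d)
    stop("census age must be at least the settlement window", call. = FALSE)
  p <- spec$params
  forcing <- if (dwarf)
    constant_forcing(spec$pop_temp_C, 1,
                     kappa_override = list(at = "metamorphosis",
                                           kappa = 0.06, f = 0.8))
  else constant_forcing(spec$pop_temp_C, spec$pop_f)
  horizon <- spec$census_age_d + 600
  tr <- integrate_life_cycle(p, forcing, horizon = horizon, dt = 1)
  ch <- stage_chronology(tr)
  if (!ch$reached[["metamorphosis"]])
    stop("metamorphosis not reached; census population undefined",
         call. = FALSE)
  a_settle <- ch$age_settlement_d

  set.seed(.substream_seed(spec$seed, "population"))
  s <- stats::runif(spec$n_pop, 0, spec$settlement_spread_d)
  ages <- a_settle + (spec$census_age_d - s)
  idx <- vapply(ages, function(a) which.min(abs(tr$age_d - a)), integer(1))
  sizes <- tr$shell_height_cm[idx] * .lognoise(spec$n_pop, spec$cv_pop)
  structure(sizes, mean_cm = mean(sizes), sd_cm = stats::sd(sizes),
            n = spec$n_pop)
}
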