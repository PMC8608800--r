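#' von Bertalanffy growth rate
#'
#' Closed-form post-metamorphosis growth rate of the abj-DEB model at
#' constant food and temperature:
#' `r_B = (k_M / 3) / (1 + f / g)` at the reference temperature,
#' multiplied by the Arrhenius factor.  After metamorphosis (constant
#' `s_M`) structural length follows
#' `dL/dt = r_B (L_inf - L)` with `L_inf = f s_M L_m`, so the simulated
#' late-time growth matches this rate exactly at equilibrium reserve
#' density.
#'
#' @param params a `deb_params` object.
#' @param f scaled functional response in `[0, 1]`; `f = 0` is the
#'   starvation regime (the formula still evaluates, with a warning).
#' @param temp_C temperature, degrees C.
#' @return Growth rate, d^-1.
#' @export
#' @examples
#' von_bertalanffy_rate(deb_params(), f = 1, temp_C = 4)
von_bertalanffy_rate <- function(params, f, temp_C) {
  stopifnot(inherits(params, "deb_params"))
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (f == 0)
    warning("f = 0 is the starvation regime; r_B describes no growth",
            call. = FALSE)
  cp <- derive_compound(params)
  (cp$k_M / 3) / (1 + f / cp$g) * arrhenius_correction(temp_C, params)
}

#' Ultimate shell height
#'
#' `f s_M L_m / delta_M`: the asymptote of the post-metamorphosis von
#' Bertalanffy curve, converted with the adult shape coefficient.
#'
#' @inheritParams von_bertalanffy_rate
#' @param s_M acceleration factor; defaults to the parameter-set value
#'   `pAm_j / pAm_b`.
#' @return Shell height, cm.
#' @export
ultimate_shell_height <- function(params, f = 1, s_M = NULL) {
  stopifnot(inherits(params, "deb_params"))
  cp <- derive_compound(params)
  if (is.null(s_M)) s_M <- cp$s_M_max
  if (is.na(s_M)) stop("no acceleration factor available: supply s_M or ",
                       "set pAm_j in the parameter set", call. = FALSE)
  f * s_M * cp$L_m / params$delta_M
}

#' Shell height at a given age
#'
#' Runs the full life cycle from fertilization under the given forcing
#' and returns the physical shell height at the query age(s), converted
#' with the stage-appropriate shape coefficient.
#'
#' @param params a `deb_params` object.
#' @param forcing a `forcing_schedule`.
#' @param age query age(s), d (all must lie within the horizon).
#' @param horizon simulation horizon, d; defaults to `max(age)`.
#' @param E_0 optional egg reserve, J.
#' @return Shell height(s), cm, in the order of `age`.
#' @export
#' @examples
#' \donttest{
#' shell_height_at_age(xylonora_params(), constant_forcing(4, 1), 410)
#' }
shell_height_at_age <- function(params, forcing, age, horizon = max(age),
                                E_0 = NULL) {
  if (any(age < 0)) stop("age precedes fertilization", call. = FALSE)
  if (any(age > horizon)) stop("age exceeds the forcing horizon",
                               call. = FALSE)
  tr <- integrate_life_cycle(params, forcing, horizon = horizon, E_0 = E_0,
                             times = unique(c(0, sort(age), horizon)))
  idx <- vapply(age, function(a) which.min(abs(tr$age_d - a)), integer(1))
  tr$shell_height_cm[idx]
}

#' Functional traits for one environmental scenario
#'
#' Simulates a full life under constant temperature and food up to the
#' scenario lifespan and summarizes the fundamental traits: closed-form
#' von Bertalanffy growth rate, maximum shell height over the horizon,
#' age at puberty, and total reproductive output
#' `TRO = floor(E_R(horizon) / E_0)`, the number of oocytes the
#' accumulated buffer can provision at egg cost `E_0` (evaluated at the
#' scenario food level; the reproduction efficiency `kappa_R` is applied
#' while the buffer accumulates).
#'
#' @param params a `deb_params` object.
#' @param f scaled functional response in `(0, 1]`.
#' @param temp_C temperature, degrees C.
#' @param horizon scenario lifespan, d.
#' @param label optional scenario label.
#' @return A one-row data frame with columns `scenario`, `f`, `temp_C`,
#'   `r_B_per_d`, `Lmax_cm`, `age_puberty_d`, `TRO`, `horizon_d`.
#'   `age_puberty_d` and `TRO` are `NA` and 0 if puberty is not reached.
#' @export
#' @examples
#' \donttest{
#' traits_for_scenario(xylonora_params(), f = 1, temp_C = 4, horizon = 821)
#' }
traits_for_scenario <- function(params, f, temp_C, horizon,
                                label = sprintf("f=%g, %g C", f, temp_C)) {
  E_0 <- .E0_warm(params, f)
  tr <- integrate_life_cycle(params, constant_forcing(temp_C, f),
                             horizon = horizon, E_0 = E_0,
                             times = c(0, horizon))
  ch <- stage_chronology(tr)
  ER_end <- tr$ER_J[nrow(tr)]
  data.frame(scenario = label, f = f, temp_C = temp_C,
             r_B_per_d = von_bertalanffy_rate(params, f, temp_C),
             Lmax_cm = max(tr$shell_height_cm),
             age_puberty_d = ch$age_puberty_d,
             TRO = floor(ER_end / E_0),
             horizon_d = horizon)
}

#' Trait table over a scenario grid
#'
#' @param params a `deb_params` object.
#' @param f food levels.
#' @param temp_C temperatures, degrees C (recycled against `f` as a full
#'   grid).
#' @param horizon lifespans, d, one per temperature.
#' @return A data frame with one row per `f` x `temp_C` combination.
#' @export
trait_table <- function(params, f = c(1, 0.5), temp_C = c(4, 11),
                        horizon = c(821, 404)) {
  stopifnot(length(horizon) == length(temp_C))
  grid <- expand.grid(temp_C = seq_along(temp_C), f = f)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    j <- grid$temp_C[i]
    traits_for_scenario(params, f = grid$f[i], temp_C = temp_C[j],
                        horizon = horizon[j])
  })
  do.call(rbind, out)
}

.age_at_hatch <- function(params, E_0, temp_C) {
  parms <- .leg_parms(params, temp_C, f = 0, kappa_eff = params$kappa,
                      feeding = FALSE, accel = FALSE, s_fix = 1,
                      L_b = NA, adult = FALSE, root_target = params$EH_h)
  y <- c(E = E_0, V = .V_SEED, EH = 0, ER = 0, cA = 0, cD = 0)
  out <- .run_leg(y, c(0, 2000), parms, atol = 1e-16, rtol = 1e-10)
  troot <- attr(out, "troot")
  if (is.null(troot) || !length(troot))
    stop("embryo does not reach the hatching threshold", call. = FALSE)
  troot[1]
}

#' Larval chronology and pelagic larval duration
#'
#' Reconstructs the early-life chronology of larvae spawned at a deep
#' wood fall and dispersing at another temperature.  Hatching is dated
#' from development at the spawning-site temperature (`T_hatch`); the
#' ages at birth (first feeding) and metamorphosis completion come from a
#' life simulated entirely at the dispersal temperature with egg reserve
#' set by the scenario food level.  Settlement is taken to precede
#' metamorphosis completion by one week, so
#' `PLD = age_metamorphosis - age_hatch - 7`.
#'
#' @param params a `deb_params` object.
#' @param f scaled functional response during dispersal, in `(0, 1]`.
#' @param T_dispersal dispersal temperature, degrees C.
#' @param T_hatch spawning-site temperature, degrees C.
#' @param max_age give up if metamorphosis is not reached by this age, d.
#' @return A one-row data frame of class `larval_chronology` with columns
#'   `f`, `T_dispersal_C`, `age_hatch_d`, `age_birth_d`,
#'   `age_metamorphosis_d`, `age_settlement_d`, `pld_d`.
#' @export
#' @examples
#' \donttest{
#' larval_chronology(xylonora_params(), f = 1, T_dispersal = 16)
#' }
larval_chronology <- function(params, f, T_dispersal, T_hatch = 4,
                              max_age = 500) {
  E_0 <- .E0_warm(params, f)
  a_h <- .age_at_hatch(params, E_0, T_hatch)
  tr <- integrate_life_cycle(params, constant_forcing(T_dispersal, f),
                             horizon = max_age, E_0 = E_0,
                             times = c(0, max_age))
  ch <- stage_chronology(tr)
  if (!ch$reached[["metamorphosis"]])
    stop("metamorphosis not reached within ", max_age, " d at f = ", f,
         ", T = ", T_dispersal, " C", call. = FALSE)
  out <- data.frame(f = f, T_dispersal_C = T_dispersal,
                    age_hatch_d = a_h,
                    age_birth_d = ch$age_birth_d,
                    age_metamorphosis_d = ch$age_metamorphosis_d,
                    age_settlement_d = ch$age_metamorphosis_d - 7,
                    pld_d = ch$age_metamorphosis_d - a_h - 7)
  class(out) <- c("larval_chronology", "data.frame")
  out
}

#' Larval chronology table over a dispersal grid
#'
#' @param params a `deb_params` object.
#' @param f food levels.
#' @param T_dispersal dispersal temperatures, degrees C.
#' @inheritParams larval_chronology
#' @return A data frame with one row per `f` x `T_dispersal` combination.
#' @export
pld_table <- function(params, f = c(0.5, 0.8, 1),
                      T_dispersal = c(4, 11, 16), T_hatch = 4) {
  grid <- expand.grid(T_dispersal = T_dispersal, f = f)
  out <- lapply(seq_len(nrow(grid)), function(i)
    larval_chronology(params, f = grid$f[i],
                      T_dispersal = grid$T_dispersal[i], T_hatch = T_hatch))
  out <- do.call(rbind, out)
  class(out) <- "data.frame"
  out
}

#' Dwarf-male scenario
#'
#' Simulates an individual that switches its allocation fraction `kappa`
#' (and food level) at metamorphosis completion — the mechanism by which
#' dwarf males stay near postlarval size while channelling mobilized
#' energy into maturation and the reproduction buffer.  Growth continues
#' but is very slow; the acceleration factor stays frozen at its achieved
#' value.
#'
#' @param params a `deb_params` object.
#' @param kappa_post_j allocation fraction after metamorphosis, in (0, 1).
#' @param f_post_j food level after metamorphosis, in `[0, 1]`.
#' @param temp_C temperature, degrees C.
#' @param horizon lifespan, d.
#' @param query_ages ages at which shell height and buffer are reported, d.
#' @param f_pre_j food level up to metamorphosis (mother's and larva's).
#' @return A list with elements `trajectory` (a `deb_trajectory`),
#'   `chronology`, and `at_ages` (data frame: `age_d`,
#'   `shell_height_cm`, `ER_J`).
#' @export
#' @examples
#' \donttest{
#' dw <- dwarf_scenario(xylonora_params())
#' dw$at_ages
#' }
dwarf_scenario <- function(params, kappa_post_j = 0.06, f_post_j = 0.8,
                           temp_C = 4, horizon = 821,
                           query_ages = c(410, 821), f_pre_j = 1) {
  if (kappa_post_j <= 0 || kappa_post_j >= 1)
    stop("kappa_post_j must lie in (0, 1)", call. = FALSE)
  forcing <- constant_forcing(temp_C, f_pre_j,
                              kappa_override = list(at = "metamorphosis",
                                                    kappa = kappa_post_j,
                                                    f = f_post_j))
  tr <- integrate_life_cycle(params, forcing, horizon = horizon,
                             times = unique(c(seq(0, horizon, by = 1),
                                              query_ages)))
  ch <- stage_chronology(tr)
  if (ch$died)
    warning("maintenance unpayable under kappa = ", kappa_post_j,
            ": death by starvation at ", round(ch$age_death_d, 1), " d",
            call. = FALSE)
  idx <- vapply(query_ages, function(a) which.min(abs(tr$age_d - a)),
                integer(1))
  list(trajectory = tr, chronology = ch,
       at_ages = data.frame(age_d = query_ages,
                            shell_height_cm = tr$shell_height_cm[idx],
                            ER_J = tr$ER_J[idx]))
}

#' Reproduction rate at a given size
#'
#' Oocytes per day an adult of given structural length can provision at
#' equilibrium reserve density `e = f`:
#' `R = kappa_R ((1 - kappa) p_C - k_J E_H^p) / E_0`.  The default
#' length is the ultimate length, giving the maximum reproduction rate.
#'
#' @param params a `deb_params` object.
#' @param f scaled functional response in `(0, 1]`.
#' @param temp_C temperature, degrees C.
#' @param L structural length, cm; default `f s_M L_m` (ultimate).
#' @param E_0 egg cost, J; computed if `NULL`.
#' @param s_M acceleration factor; defaults to the parameter-set ratio
#'   `pAm_j / pAm_b` (pass a simulated `L_j / L_b` when the
#'   after-metamorphosis rates are not set).
#' @return Oocytes per day.
#' @export
reproduction_rate <- function(params, f = 1, temp_C = 4, L = NULL,
                              E_0 = NULL, s_M = NULL) {
  stopifnot(inherits(params, "deb_params"))
  cp <- derive_compound(params)
  if (is.null(s_M)) s_M <- cp$s_M_max
  if (is.na(s_M))
    stop("no acceleration factor available: supply s_M or set pAm_j",
         call. = FALSE)
  if (is.null(L)) L <- f * s_M * cp$L_m
  if (is.null(E_0)) E_0 <- .E0_warm(params, f)
  cf <- arrhenius_correction(temp_C, params)
  V <- L^3
  Ev <- f * cp$E_m
  p_C <- V * Ev * (params$E_G * params$v_b * cf * s_M / L +
                     params$p_M * cf) / (params$E_G + params$kappa * Ev)
  p_R <- (1 - params$kappa) * p_C - params$k_J * cf * params$EH_p
  max(params$kappa_R * p_R / E_0, 0)
}
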