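## Life-cycle integration: legs of constant (T, f, kappa, stage) are
## integrated with the compiled abj-DEB right-hand side; maturity
## thresholds are located by lsodar's root finder and the driver switches
## stage, records chronology memos and applies any allocation override.

STAGES <- c("embryo", "larva_pre_birth", "larva_accelerating",
            "juvenile", "adult")

.leg_parms <- function(params, temp_C, f, kappa_eff, feeding, accel,
                       s_fix, L_b, adult, root_target) {
  c(params$pAm_b, params$v_b, params$E_G, params$p_M, params$k_J,
    params$EH_p, params$kappa_R, kappa_eff,
    arrhenius_correction(temp_C, params), f,
    as.numeric(feeding), as.numeric(accel), s_fix,
    if (is.na(L_b)) 1 else L_b,
    as.numeric(adult), root_target)
}

.run_leg <- function(y, times, parms, atol, rtol) {
  deSolve::lsodar(y = y, times = times, func = "xylodeb_rhs",
                  parms = parms, dllname = "xylodeb",
                  initfunc = "xylodeb_init", rootfunc = "xylodeb_root",
                  nroot = 3L, atol = atol, rtol = rtol, maxsteps = 50000)
}

## indices of the root components that fired (1 = maturity threshold,
## 2 = reserve exhaustion, 3 = reproduction buffer depleted)
.fired_roots <- function(out) {
  ir <- attr(out, "iroot")
  if (is.null(ir)) integer(0) else which(ir == 1L)
}

## embryo trajectory without event handling (used by shooting and the
## hatch-threshold calibration)
## The egg has no structure: integration starts from a negligible seed
## volume standing in for V(0) = 0.  The default is small enough that
## stage ages change by well under 0.1 d for a further 10-fold reduction.
.V_SEED <- 1e-15

embryo_states <- function(params, E0, temp_C, times, V_seed = .V_SEED,
                          atol = 1e-16, rtol = 1e-10) {
  parms <- .leg_parms(params, temp_C, f = 0, kappa_eff = params$kappa,
                      feeding = FALSE, accel = FALSE, s_fix = 1,
                      L_b = NA, adult = FALSE, root_target = -1)
  y <- c(E = E0, V = V_seed, EH = 0, ER = 0, cA = 0, cD = 0)
  out <- .run_leg(y, times, parms, atol, rtol)
  colnames(out) <- c("time", "E", "V", "EH", "ER", "cA", "cD")
  out
}

## integrate an embryo until the birth threshold; returns the state at
## birth or NULL if the threshold is not reached
.embryo_to_birth <- function(params, E0, temp_C, tmax = 2000,
                             V_seed = .V_SEED, atol = 1e-16, rtol = 1e-10) {
  parms <- .leg_parms(params, temp_C, f = 0, kappa_eff = params$kappa,
                      feeding = FALSE, accel = FALSE, s_fix = 1,
                      L_b = NA, adult = FALSE, root_target = params$EH_b)
  y <- c(E = E0, V = V_seed, EH = 0, ER = 0, cA = 0, cD = 0)
  out <- .run_leg(y, c(0, tmax), parms, atol, rtol)
  if (!1L %in% .fired_roots(out)) return(NULL)
  st <- out[nrow(out), ]
  list(age = st[[1]], E = st[[2]], V = st[[3]], EH = st[[4]])
}

#' Initial reserve of an egg
#'
#' Computes the egg energy content `E_0` by shooting: the value is chosen
#' so that the scaled reserve density at birth (first feeding) equals the
#' mother's food level, `e_b = f_mother` — the maternal-effect rule that
#' well-fed mothers provision eggs more richly.  The embryo does not
#' feed, so the state-space path (and hence `E_0`) is independent of
#' temperature; the shooting integration runs at the reference
#' temperature.
#'
#' @param params a `deb_params` object.
#' @param f_mother scaled functional response experienced by the mother,
#'   in `(0, 1]`.
#' @param tol absolute tolerance on `e_b - f_mother`.
#' @return Egg reserve `E_0`, J.
#' @export
#' @examples
#' \donttest{
#' p <- xylonora_params()
#' initial_reserve(p, 1)
#' }
initial_reserve <- function(params, f_mother, tol = 1e-9) {
  stopifnot(inherits(params, "deb_params"))
  if (!is.numeric(f_mother) || f_mother <= 0 || f_mother > 1)
    stop("f_mother must lie in (0, 1]", call. = FALSE)
  E_m <- params$pAm_b / params$v_b
  T_ref_C <- params$T_ref - 273.15
  eb_gap <- function(E0) {
    b <- .embryo_to_birth(params, E0, T_ref_C)
    if (is.null(b)) return(-f_mother)  # reserve ran out before birth
    b$E / (b$V * E_m) - f_mother
  }
  lo <- 1e-5; hi <- 0.05
  for (i in 1:8) {
    if (eb_gap(hi) > 0) break
    hi <- hi * 4
  }
  for (i in 1:8) {
    if (eb_gap(lo) < 0) break
    lo <- lo / 4
  }
  if (eb_gap(lo) >= 0 || eb_gap(hi) <= 0)
    stop("could not bracket E_0 in [", lo, ", ", hi,
         "] J; check the parameter set (EH_b relative to assimilation ",
         "and maintenance rates)", call. = FALSE)
  stats::uniroot(eb_gap, c(lo, hi), tol = tol)$root
}

## memoized egg-cost solver.  Exact (parameter set, f) keys return the
## cached value, which keeps repeated runs bit-reproducible; on a miss,
## the last solution for the same food level seeds a narrow bracket
## before the full search falls back (the bracket sign check guarantees
## correctness even though the parameters have changed since the guess
## was stored).
.E0_cache <- new.env(parent = emptyenv())
.E0_last <- new.env(parent = emptyenv())

.E0_key <- function(params, f) {
  nums <- unlist(unclass(params)[vapply(unclass(params), is.numeric,
                                        logical(1))], use.names = FALSE)
  paste(sprintf("%.17g", c(nums, f)), collapse = "|")
}

.E0_warm <- function(params, f) {
  key <- .E0_key(params, f)
  hit <- .E0_cache[[key]]
  if (!is.null(hit)) return(hit)
  fkey <- sprintf("f%.10f", f)
  guess <- .E0_last[[fkey]]
  E0 <- NULL
  if (!is.null(guess) && is.finite(guess)) {
    E_m <- params$pAm_b / params$v_b
    T_ref_C <- params$T_ref - 273.15
    gap <- function(x) {
      b <- .embryo_to_birth(params, x, T_ref_C)
      if (is.null(b)) return(-f)
      b$E / (b$V * E_m) - f
    }
    lo <- guess / 1.4; hi <- guess * 1.4
    glo <- gap(lo); ghi <- gap(hi)
    if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0)
      E0 <- stats::uniroot(gap, c(lo, hi), tol = 1e-9,
                           f.lower = glo, f.upper = ghi)$root
  }
  if (is.null(E0)) E0 <- initial_reserve(params, f)
  .E0_cache[[key]] <- E0
  .E0_last[[fkey]] <- E0
  E0
}

#' Energy fluxes of the abj-DEB model
#'
#' Evaluates the instantaneous energy fluxes at a given state:
#' assimilation `p_A`, mobilization `p_C`, somatic maintenance `p_S`,
#' maturity maintenance `p_J`, growth `p_G = kappa p_C - p_S` and the
#' maturity/reproduction flux `p_R = (1 - kappa) p_C - p_J`.  The
#' shape-correction factor is 1 before birth, `L / L_b` during
#' acceleration and `L_j / L_b` after metamorphosis; assimilation is zero
#' before birth.  All rate parameters are multiplied by the Arrhenius
#' factor at `temp_C`.
#'
#' @param state a named list with `E`, `V`, `EH`, `ER` (J, cm^3, J, J),
#'   `stage` (one of the five life stages) and, where relevant, the
#'   memos `L_b` and `L_j` (cm).
#' @param temp_C temperature, degrees C.
#' @param f scaled functional response in `[0, 1]`.
#' @param params a `deb_params` object.
#' @param kappa_eff effective allocation fraction (defaults to
#'   `params$kappa`; the dwarf scenario overrides it).
#' @return Named numeric vector `p_A`, `p_C`, `p_S`, `p_J`, `p_G`, `p_R`
#'   (J d^-1).
#' @export
deb_fluxes <- function(state, temp_C, f, params,
                       kappa_eff = params$kappa) {
  stopifnot(inherits(params, "deb_params"))
  if (is.null(state$V) || state$V <= 0)
    stop("fluxes are undefined at V = 0", call. = FALSE)
  stage <- match.arg(state$stage, STAGES)
  L <- state$V^(1 / 3)
  s <- switch(stage,
              embryo = 1, larva_pre_birth = 1,
              larva_accelerating = L / state$L_b,
              juvenile = state$L_j / state$L_b,
              adult = state$L_j / state$L_b)
  feeding <- !(stage %in% c("embryo", "larva_pre_birth"))
  cf <- arrhenius_correction(temp_C, params)
  Ev <- state$E / state$V
  p_A <- if (feeding) params$pAm_b * s * f * L^2 * cf else 0
  p_C <- state$V * Ev * (params$E_G * params$v_b * cf * s / L +
                           params$p_M * cf) / (params$E_G + kappa_eff * Ev)
  p_S <- params$p_M * state$V * cf
  p_J <- params$k_J * cf * min(state$EH, params$EH_p)
  c(p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J,
    p_G = kappa_eff * p_C - p_S, p_R = (1 - kappa_eff) * p_C - p_J)
}

#' Integrate the abj-DEB life cycle
#'
#' Runs the stage-structured state equations from fertilization under a
#' piecewise-constant forcing schedule.  Maturity thresholds (hatch,
#' birth, metamorphosis completion, puberty) are located by root finding;
#' at birth, feeding switches on and the acceleration of assimilation and
#' conductance begins; at metamorphosis completion the acceleration
#' factor `s_M = L_j / L_b` freezes (and any `kappa` override in the
#' forcing is applied); after puberty, maturity is frozen and the
#' reproduction flux accumulates into the buffer with efficiency
#' `kappa_R`.  When somatic maintenance cannot be met from the `kappa`
#' branch, structure and maturity are held and maintenance is paid from
#' the reproduction buffer, then from reserve; reserve exhaustion ends
#' the integration (death by starvation).
#'
#' @param params a `deb_params` object.
#' @param forcing a `forcing_schedule`.
#' @param horizon simulation horizon (lifespan), d.
#' @param E_0 egg reserve, J; computed with [initial_reserve()] at the
#'   food level of the first forcing segment when `NULL`.
#' @param V_seed negligible seed volume of the embryo, cm^3.
#' @param dt output resolution, d (event ages are always included).
#' @param times optional explicit output ages, d (overrides `dt`).
#' @param atol,rtol integrator tolerances.
#' @return A `deb_trajectory`: a data frame with columns `age_d`, `T_C`,
#'   `f`, `E_J`, `V_cm3`, `EH_J`, `ER_J`, `stage`, `shell_height_cm`,
#'   `wet_weight_g` plus audit columns `cum_assim_J` and `cum_diss_J`,
#'   with the stage chronology attached as attribute `"chronology"`
#'   (see [stage_chronology()]).
#' @export
#' @examples
#' \donttest{
#' p <- xylonora_params()
#' tr <- integrate_life_cycle(p, constant_forcing(4, 1), horizon = 450)
#' stage_chronology(tr)
#' }
integrate_life_cycle <- function(params, forcing, horizon, E_0 = NULL,
                                 V_seed = .V_SEED, dt = 1, times = NULL,
                                 atol = 1e-14, rtol = 1e-10) {
  stopifnot(inherits(params, "deb_params"),
            inherits(forcing, "forcing_schedule"))
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be positive", call. = FALSE)
  if (is.null(E_0))
    E_0 <- .E0_warm(params, f = forcing$segments$f[1])
  if (E_0 <= 0) stop("E_0 must be positive", call. = FALSE)

  grid <- if (is.null(times)) seq(0, horizon, by = dt) else sort(unique(times))
  grid <- unique(c(grid[grid >= 0 & grid <= horizon], horizon))

  ko <- forcing$kappa_override
  breaks <- forcing$segments$start
  if (!is.null(ko) && is.numeric(ko$at)) breaks <- c(breaks, ko$at)
  breaks <- sort(unique(c(breaks[breaks > 0 & breaks < horizon], horizon)))

  stage <- "embryo"
  kappa_eff <- params$kappa
  f_over <- NA_real_
  override_on <- FALSE
  L_b <- NA_real_; L_j <- NA_real_
  ev <- list(hatch = NA_real_, birth = NA_real_, metamorphosis = NA_real_,
             puberty = NA_real_, death = NA_real_)

  apply_override <- function(trigger) {
    if (is.null(ko) || override_on) return(invisible())
    if (is.character(ko$at) && ko$at == trigger) {
      override_on <<- TRUE
      kappa_eff <<- ko$kappa
      if (!is.null(ko$f)) f_over <<- ko$f
    }
    invisible()
  }

  y <- c(E = E_0, V = V_seed, EH = 0, ER = 0, cA = 0, cD = 0)
  t_cur <- 0
  rows <- vector("list", 64); nrow_used <- 0
  push <- function(mat, temp_C, f_used) {
    nrow_used <<- nrow_used + 1
    rows[[nrow_used]] <<- data.frame(
      age_d = mat[, 1], E_J = mat[, 2], V_cm3 = mat[, 3],
      EH_J = mat[, 4], ER_J = mat[, 5], cum_assim_J = mat[, 6],
      cum_diss_J = mat[, 7], T_C = temp_C, f = f_used, stage = stage)
  }

  guard <- 0
  while (t_cur < horizon - 1e-12) {
    guard <- guard + 1
    if (guard > 500) stop("life-cycle driver failed to advance; last age ",
                          t_cur, call. = FALSE)
    env <- forcing_at(forcing, t_cur + 1e-9)
    f_used <- if (override_on && !is.na(f_over)) f_over else env$f
    leg_end <- c(breaks[breaks > t_cur + 1e-12], horizon)[1]
    root_target <- switch(stage,
                          embryo = params$EH_h,
                          larva_pre_birth = params$EH_b,
                          larva_accelerating = params$EH_j,
                          juvenile = params$EH_p,
                          adult = -1)
    parms <- .leg_parms(params, env$temp_C, f_used, kappa_eff,
                        feeding = !(stage %in% c("embryo", "larva_pre_birth")),
                        accel = stage == "larva_accelerating",
                        s_fix = if (stage %in% c("juvenile", "adult") &&
                                    !is.na(L_j)) L_j / L_b else 1,
                        L_b = L_b, adult = stage == "adult",
                        root_target = root_target)
    leg_times <- unique(c(t_cur, grid[grid > t_cur + 1e-12 & grid < leg_end],
                          leg_end))
    out <- .run_leg(y, leg_times, parms, atol, rtol)
    if (attr(out, "istate")[1] < 0)
      stop("integration failed at age ", utils::tail(out[, 1], 1),
           " (stage ", stage, "); last state: E = ",
           signif(utils::tail(out[, 2], 1), 6), " J, V = ",
           signif(utils::tail(out[, 3], 1), 6), " cm^3", call. = FALSE)
    push(out[-1, , drop = FALSE], env$temp_C, f_used)
    n <- nrow(out)
    y <- out[n, 2:7]; names(y) <- c("E", "V", "EH", "ER", "cA", "cD")
    t_new <- unname(out[n, 1])
    fired <- .fired_roots(out)
    if (length(fired) && t_new < leg_end - 1e-12) {
      if (2L %in% fired) {                 # reserve exhausted
        ev$death <- t_new
        t_cur <- t_new
        break
      }
      if (!1L %in% fired) {
        ## buffer-depletion root: resume with the maintenance source
        ## switched; no stage change
        t_cur <- t_new
        next
      }
      if (stage == "embryo") {
        ev$hatch <- t_new; stage <- "larva_pre_birth"
      } else if (stage == "larva_pre_birth") {
        ev$birth <- t_new; L_b <- y[["V"]]^(1 / 3)
        stage <- "larva_accelerating"
        apply_override("birth")
      } else if (stage == "larva_accelerating") {
        ev$metamorphosis <- t_new; L_j <- y[["V"]]^(1 / 3)
        stage <- "juvenile"
        apply_override("metamorphosis")
      } else if (stage == "juvenile") {
        ev$puberty <- t_new; stage <- "adult"
        apply_override("puberty")
      }
    }
    if (!is.null(ko) && is.numeric(ko$at) && !override_on &&
        t_new >= ko$at - 1e-12) {
      override_on <- TRUE
      kappa_eff <- ko$kappa
      if (!is.null(ko$f)) f_over <- ko$f
    }
    t_cur <- t_new
  }

  traj <- do.call(rbind, rows[seq_len(nrow_used)])
  ## initial state row
  env0 <- forcing_at(forcing, 0)
  traj <- rbind(data.frame(age_d = 0, E_J = E_0, V_cm3 = V_seed, EH_J = 0,
                           ER_J = 0, cum_assim_J = 0, cum_diss_J = 0,
                           T_C = env0$temp_C, f = env0$f, stage = "embryo"),
                traj)
  traj <- traj[!duplicated(traj$age_d) | c(TRUE, diff(traj$age_d) > 0), ]
  E_m <- params$pAm_b / params$v_b
  traj$shell_height_cm <- shell_height(traj$V_cm3, traj$stage, params)
  traj$wet_weight_g <- traj$V_cm3 *
    (1 + pmin(pmax(traj$E_J / (traj$V_cm3 * E_m), 0), 1) *
       derive_compound(params)$omega)
  rownames(traj) <- NULL

  chron <- .make_chronology(ev, traj, params, L_b, L_j, horizon)
  structure(traj,
            class = c("deb_trajectory", "data.frame"),
            chronology = chron, params = params, forcing = forcing,
            E_0 = E_0, horizon = horizon)
}

.make_chronology <- function(ev, traj, params, L_b, L_j, horizon) {
  sh_at <- function(age, stage) {
    if (is.na(age)) return(NA_real_)
    i <- which.min(abs(traj$age_d - age))
    shell_height(traj$V_cm3[i], stage, params)
  }
  settlement <- if (!is.na(ev$metamorphosis)) ev$metamorphosis - 7 else NA_real_
  structure(list(
    age_hatch_d = ev$hatch,
    age_birth_d = ev$birth,
    age_metamorphosis_d = ev$metamorphosis,
    age_settlement_d = settlement,
    age_puberty_d = ev$puberty,
    age_death_d = ev$death,
    sh_hatch_cm = sh_at(ev$hatch, "larva_pre_birth"),
    sh_birth_cm = sh_at(ev$birth, "larva_accelerating"),
    sh_metamorphosis_cm = if (is.na(L_j)) NA_real_ else L_j / params$delta_ME,
    sh_puberty_cm = sh_at(ev$puberty, "adult"),
    L_b_cm = L_b, L_j_cm = L_j,
    s_M = if (is.na(L_j)) NA_real_ else L_j / L_b,
    horizon_d = horizon,
    reached = c(hatch = !is.na(ev$hatch), birth = !is.na(ev$birth),
                metamorphosis = !is.na(ev$metamorphosis),
                puberty = !is.na(ev$puberty)),
    died = !is.na(ev$death)),
    class = "stage_chronology")
}

#' Stage chronology of a simulated life
#'
#' Extracts the ages (d) and shell heights (cm) at hatching, birth,
#' metamorphosis completion, settlement (one week before metamorphosis
#' completion, the convention used for pelagic larval duration) and
#' puberty from a trajectory, together with the structural-length memos
#' `L_b`, `L_j` and the realized acceleration factor `s_M = L_j / L_b`.
#' Events not reached within the horizon are `NA` and flagged.
#'
#' @param trajectory a `deb_trajectory` from [integrate_life_cycle()].
#' @return A `stage_chronology` object.
#' @export
stage_chronology <- function(trajectory) {
  stopifnot(inherits(trajectory, "deb_trajectory"))
  attr(trajectory, "chronology")
}

#' @export
print.stage_chronology <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "not reached", sprintf("%.2f", v))
  cat("stage chronology (d):\n")
  cat("  hatch        ", fmt(x$age_hatch_d), "\n")
  cat("  birth        ", fmt(x$age_birth_d), "\n")
  cat("  metamorphosis", fmt(x$age_metamorphosis_d), "\n")
  cat("  settlement   ", fmt(x$age_settlement_d), "\n")
  cat("  puberty      ", fmt(x$age_puberty_d), "\n")
  if (x$died) cat("  death by starvation at", fmt(x$age_death_d), "\n")
  if (!is.na(x$s_M)) cat(sprintf("  s_M = %.4f\n", x$s_M))
  invisible(x)
}

#' Write a trajectory to a tidy CSV file
#'
#' @param trajectory a `deb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "deb_trajectory"))
  cols <- c("age_d", "T_C", "f", "E_J", "V_cm3", "EH_J", "ER_J", "stage",
            "shell_height_cm", "wet_weight_g")
  utils::write.csv(as.data.frame(trajectory)[, cols], path,
                   row.names = FALSE)
  invisible(path)
}

#' Starvation endurance
#'
#' Days until the reserve is exhausted when feeding stops entirely
#' (`f = 0`): structure is held (no shrinking) and the reserve is drawn
#' down by volume-specific somatic maintenance, giving
#' `t = e_start [E_m] / [p_M]` at the reference temperature, divided by
#' the Arrhenius factor at `temp_C`.  Maturity maintenance, three orders
#' of magnitude smaller, is neglected here (the full integrator includes
#' it).
#'
#' @param params a `deb_params` object.
#' @param temp_C temperature, degrees C.
#' @param e_start scaled reserve density at the onset of starvation, in
#'   `(0, 1]`.
#' @return Time to reserve exhaustion, d.
#' @export
#' @examples
#' starvation_time(deb_params(), temp_C = 4)
starvation_time <- function(params, temp_C, e_start = 1) {
  stopifnot(inherits(params, "deb_params"))
  if (e_start <= 0 || e_start > 1)
    stop("e_start must lie in (0, 1]", call. = FALSE)
  E_m <- params$pAm_b / params$v_b
  e_start * (E_m / params$p_M) / arrhenius_correction(temp_C, params)
}
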