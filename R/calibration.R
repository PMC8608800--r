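#' Assemble an observation set
#'
#' An observation set holds zerovariate life-history observations (one
#' value each, with the temperature and food context needed to predict
#' them) and univariate growth series (shell height against age).  A
#' series may have its food level marked free, in which case
#' [fit_parameters()] estimates it jointly with the free parameters.
#'
#' Recognized zerovariate names (units): `age_at_hatching` (d),
#' `age_at_birth` (d), `time_birth_to_metamorphosis` (d),
#' `time_birth_to_puberty` (d), `shell_height_at_hatching`,
#' `shell_height_at_birth`, `shell_height_at_metamorphosis`,
#' `shell_height_at_puberty`, `max_shell_height` (cm),
#' `wet_weight_at_puberty` (g), `max_reproduction_rate` (oocytes/d),
#' and `lifespan` (d).  Lifespan has no predictor in this model (no aging
#' submodule); such entries are carried with a missing prediction and are
#' dropped from the scores with a warning unless their weight is 0.
#'
#' @param zerovariate data frame with columns `name`, `value`, `unit`,
#'   `temp_C`, `f`, `weight` (weights must be non-negative).
#' @param univariate list of series; each a list with `name`, `age_d`,
#'   `shell_height_cm`, `temp_C`, `f` (ignored when `f_free`), `f_free`
#'   (logical), `weight_total` (weight shared uniformly by the points of
#'   the series; defaults to 1 so one series counts as one zerovariate
#'   entry).
#' @param notes optional provenance notes.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(zerovariate, univariate = list(),
                            notes = NULL) {
  need <- c("name", "value", "unit", "temp_C", "f", "weight")
  missing_cols <- setdiff(need, names(zerovariate))
  if (length(missing_cols))
    stop("zerovariate data frame lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(zerovariate$weight < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (anyDuplicated(zerovariate$name))
    stop("duplicated zerovariate names", call. = FALSE)
  univariate <- lapply(univariate, function(s) {
    if (is.null(s$name) || is.null(s$age_d) || is.null(s$shell_height_cm) ||
        is.null(s$temp_C))
      stop("each univariate series needs name, age_d, shell_height_cm, ",
           "temp_C", call. = FALSE)
    if (length(s$age_d) != length(s$shell_height_cm))
      stop("series '", s$name, "': age and shell-height lengths differ",
           call. = FALSE)
    if (is.null(s$f_free)) s$f_free <- FALSE
    if (!s$f_free && is.null(s$f))
      stop("series '", s$name, "': supply f or mark it free", call. = FALSE)
    if (is.null(s$weight_total)) s$weight_total <- 1
    s
  })
  names(univariate) <- vapply(univariate, `[[`, character(1), "name")
  structure(list(zerovariate = zerovariate, univariate = univariate,
                 notes = notes),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("observation set:", nrow(x$zerovariate), "zerovariate entries,",
      length(x$univariate), "univariate series\n")
  invisible(x)
}

## reference run at T_ref for zerovariate predictions; extends the
## horizon until puberty is reached (stage ages at other temperatures
## follow by Arrhenius rescaling, sizes are temperature-free)
.reference_run <- function(params, f, E_0, need_puberty = TRUE) {
  T_ref_C <- params$T_ref - 273.15
  horizon <- 300
  for (i in 1:4) {
    tr <- integrate_life_cycle(params, constant_forcing(T_ref_C, f),
                               horizon = horizon, E_0 = E_0,
                               times = c(0, horizon))
    ch <- stage_chronology(tr)
    if (!need_puberty || ch$reached[["puberty"]]) return(list(tr = tr, ch = ch))
    horizon <- horizon * 2
  }
  list(tr = tr, ch = ch)
}

#' Predict an observation set from a parameter set
#'
#' Computes one model prediction per zerovariate entry and per univariate
#' point, at each entry's temperature and food context.  Stage ages are
#' obtained from a reference simulation at `T_ref` and rescaled by the
#' Arrhenius factor of the entry's temperature (exact for constant
#' forcing); sizes are temperature-free.  Series are simulated at their
#' own temperature and food level.
#'
#' @param params a `deb_params` object.
#' @param obs an `observation_set`.
#' @param f_free named numeric vector giving the food level of every
#'   series marked free (names = series names).
#' @return A list with elements `zerovariate` (data frame `name`,
#'   `observed`, `predicted`, `weight`) and `univariate` (list of data
#'   frames `age_d`, `observed`, `predicted`, `weight`).
#' @export
predict_observations <- function(params, obs, f_free = NULL) {
  stopifnot(inherits(params, "deb_params"), inherits(obs, "observation_set"))
  zv <- obs$zerovariate
  known <- c("age_at_hatching", "age_at_birth", "time_birth_to_metamorphosis",
             "time_birth_to_puberty", "shell_height_at_hatching",
             "shell_height_at_birth", "shell_height_at_metamorphosis",
             "shell_height_at_puberty", "max_shell_height",
             "wet_weight_at_puberty", "max_reproduction_rate", "lifespan")
  bad <- setdiff(zv$name, known)
  if (length(bad))
    stop("no predictor for zerovariate entr",
         if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)

  preds <- rep(NA_real_, nrow(zv))
  if (nrow(zv)) {
    cp <- derive_compound(params)
    E_m <- cp$E_m
    for (fv in unique(zv$f)) {
      sel <- which(zv$f == fv)
      E_0 <- .E0_warm(params, fv)
      ref <- .reference_run(params, fv, E_0)
      ch <- ref$ch; tr <- ref$tr
      a_h_ref <- .age_at_hatch(params, E_0, params$T_ref - 273.15)
      s_M <- ch$s_M
      for (i in sel) {
        cf <- arrhenius_correction(zv$temp_C[i], params)
        preds[i] <- switch(
          zv$name[i],
          age_at_hatching = a_h_ref / cf,
          age_at_birth = ch$age_birth_d / cf,
          time_birth_to_metamorphosis =
            (ch$age_metamorphosis_d - ch$age_birth_d) / cf,
          time_birth_to_puberty = (ch$age_puberty_d - ch$age_birth_d) / cf,
          shell_height_at_hatching = ch$sh_hatch_cm,
          shell_height_at_birth = ch$sh_birth_cm,
          shell_height_at_metamorphosis = ch$sh_metamorphosis_cm,
          shell_height_at_puberty = ch$sh_puberty_cm,
          max_shell_height = ultimate_shell_height(params, fv, s_M = s_M),
          wet_weight_at_puberty = {
            ip <- which.min(abs(tr$age_d - ch$age_puberty_d))
            e_p <- min(max(tr$E_J[ip] / (tr$V_cm3[ip] * E_m), 0), 1)
            tr$V_cm3[ip] * (1 + e_p * cp$omega)
          },
          max_reproduction_rate =
            reproduction_rate(params, f = fv, temp_C = zv$temp_C[i],
                              L = fv * s_M * cp$L_m, E_0 = E_0, s_M = s_M),
          lifespan = NA_real_)
      }
    }
  }

  uni <- lapply(obs$univariate, function(s) {
    f_s <- if (isTRUE(s$f_free)) {
      if (is.null(f_free) || is.null(f_free[[s$name]]))
        stop("series '", s$name, "' has a free food level: supply f_free",
             call. = FALSE)
      f_free[[s$name]]
    } else s$f
    sh <- shell_height_at_age(params, constant_forcing(s$temp_C, f_s),
                              age = s$age_d, horizon = max(s$age_d))
    data.frame(age_d = s$age_d, observed = s$shell_height_cm,
               predicted = sh,
               weight = s$weight_total / length(s$age_d))
  })

  list(zerovariate = data.frame(name = zv$name, observed = zv$value,
                                predicted = preds, weight = zv$weight),
       univariate = uni)
}

## stack all observed/predicted/weight rows of a prediction object
.stack_predictions <- function(pred) {
  z <- pred$zerovariate[, c("observed", "predicted", "weight")]
  u <- lapply(pred$univariate, function(d)
    d[, c("observed", "predicted", "weight")])
  do.call(rbind, c(list(z), u))
}

#' Goodness-of-fit scores
#'
#' `relative_error()` gives per-entry `RE = |p - o| / |o|`.  `mre()` is
#' the weighted mean relative error, ranging from 0 (perfect match)
#' upwards without bound; entries with a zero observed value are excluded
#' with a warning.  `smse()` is the weighted symmetric mean squared
#' error, the mean of `(p - o)^2 / (o^2 + p^2)`: it lies in `[0, 1]`, is
#' 0 only for a perfect match on all weighted entries, and is invariant
#' both to swapping predictions with observations and to a change of
#' units applied to both.  Entries with missing predictions are dropped
#' with a warning unless their weight is 0.
#'
#' @param pred numeric vector of predictions.
#' @param obs numeric vector of observations.
#' @param weights non-negative weights (default: equal).
#' @return `relative_error()`: a vector; `mre()`, `smse()`: a scalar.
#' @export
#' @examples
#' relative_error(2, 1)         # 1
#' smse(2, 1)                   # (2-1)^2 / (1+4) = 0.2
relative_error <- function(pred, obs) {
  abs(pred - obs) / abs(obs)
}

.drop_bad <- function(obs, pred, weights, zero_obs_matters) {
  keep <- rep(TRUE, length(obs))
  na <- !is.finite(pred) | !is.finite(obs)
  if (any(na & weights > 0))
    warning(sum(na & weights > 0),
            " entr(y/ies) with missing predictions excluded from the score",
            call. = FALSE)
  keep[na] <- FALSE
  if (zero_obs_matters) {
    z <- obs == 0
    if (any(z & keep & weights > 0))
      warning("entries with zero observed value excluded from MRE",
              call. = FALSE)
    keep[z] <- FALSE
  }
  keep
}

#' @rdname relative_error
#' @export
mre <- function(obs, pred, weights = rep(1, length(obs))) {
  keep <- .drop_bad(obs, pred, weights, zero_obs_matters = TRUE)
  w <- weights[keep]
  if (!sum(w)) return(NA_real_)
  sum(w * relative_error(pred[keep], obs[keep])) / sum(w)
}

#' @rdname relative_error
#' @export
smse <- function(obs, pred, weights = rep(1, length(obs))) {
  keep <- .drop_bad(obs, pred, weights, zero_obs_matters = FALSE)
  w <- weights[keep]
  if (!sum(w)) return(NA_real_)
  o <- obs[keep]; p <- pred[keep]
  d2 <- (p - o)^2
  den <- o^2 + p^2
  term <- ifelse(den == 0, 0, d2 / den)
  sum(w * term) / sum(w)
}

## the symmetric bounded loss minimized by fit_parameters
.sym_loss <- function(stacked) {
  smse(stacked$observed, stacked$predicted, stacked$weight)
}

#' Estimate DEB parameters from an observation set
#'
#' Minimizes the weighted symmetric bounded loss
#' `sum w_i (p_i - o_i)^2 / (o_i^2 + p_i^2)` over a chosen subset of
#' parameters (plus the food levels of any series marked free) by
#' Nelder-Mead simplex search with a restart schedule.  Positive
#' parameters are searched on the log scale and fractions
#' (`kappa`, `kappa_R`, free `f`) on the logit scale; box bounds are
#' enforced by penalty.  The search is deterministic: each restart
#' re-launches the simplex from the best point found so far and the
#' schedule stops early once two consecutive restarts fail to improve the
#' loss by more than `reltol`.
#'
#' @param obs an `observation_set`.
#' @param free_names character vector: parameter fields to free (e.g.
#'   `"v_b"`, `"kappa"`, `"p_M"`, `"EH_p"`) and/or `"f_<series>"` for a
#'   free series food level (e.g. `"f_oak"`).
#' @param init a `deb_params` object: starting point and source of all
#'   fixed values.
#' @param f_init named numeric vector of starting values for free food
#'   levels (default 0.8).
#' @param lower,upper optional named vectors of bounds on the natural
#'   scale; defaults are `init/10` and `init*10` for positive parameters
#'   and `(0.02, 0.995)` for fractions.
#' @param restarts maximum number of simplex restarts.
#' @param maxit maximum iterations per restart.
#' @param reltol relative convergence tolerance on the loss.
#' @param verbose print restart-level progress.
#' @return An object of class `fit_result`: a list with the estimated
#'   `params`, `f_free`, `loss`, `mre`, `smse`, per-entry
#'   `relative_errors`, `convergence` (logical), `evals`, and the
#'   restart `trace`.
#' @export
fit_parameters <- function(obs, free_names, init, f_init = NULL,
                           lower = NULL, upper = NULL,
                           restarts = 20, maxit = 500, reltol = 1e-6,
                           verbose = FALSE) {
  stopifnot(inherits(obs, "observation_set"), inherits(init, "deb_params"))
  if (!length(free_names)) stop("free_names must be non-empty", call. = FALSE)

  is_f <- startsWith(free_names, "f_")
  f_series <- sub("^f_", "", free_names[is_f])
  par_names <- free_names[!is_f]
  unknown <- setdiff(par_names, names(init))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_series <- setdiff(f_series, names(obs$univariate))
  if (length(missing_series))
    stop("free food level for unknown series: ",
         paste(missing_series, collapse = ", "), call. = FALSE)

  ## search vector: free parameters first, then free food levels
  frac <- c("kappa", "kappa_R")
  start <- c(vapply(par_names, function(n) init[[n]], numeric(1)),
             vapply(f_series, function(n) {
               if (!is.null(f_init) && !is.null(f_init[[paste0("f_", n)]]))
                 f_init[[paste0("f_", n)]] else 0.8
             }, numeric(1)))
  names(start) <- c(par_names, paste0("f_", f_series))
  is_f <- c(rep(FALSE, length(par_names)), rep(TRUE, length(f_series)))
  is_frac <- c(par_names %in% frac, rep(TRUE, length(f_series)))

  lo <- ifelse(is_frac, 0.02, start / 10)
  hi <- ifelse(is_frac, 0.995, start * 10)
  names(lo) <- names(hi) <- names(start)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  to_theta <- function(x) {
    th <- numeric(length(x))
    th[is_frac] <- stats::qlogis(x[is_frac])
    th[!is_frac] <- log(x[!is_frac])
    names(th) <- names(start)
    th
  }
  from_theta <- function(th) {
    x <- numeric(length(th))
    x[is_frac] <- stats::plogis(th[is_frac])
    x[!is_frac] <- exp(th[!is_frac])
    names(x) <- names(start)
    x
  }

  evals <- 0L
  objective <- function(theta) {
    x <- from_theta(theta)
    if (any(x < lo | x > hi))
      return(1 + sum(pmax(lo - x, 0) / lo + pmax(x - hi, 0) / hi))
    p <- unclass(init)
    for (n in par_names) p[[n]] <- x[[n]]
    ## the after-metamorphosis rates are derived quantities (primary times
    ## s_M); drop them from candidates so the realized s_M is simulated
    p$pAm_j <- NA_real_
    p$v_j <- NA_real_
    p <- tryCatch(validate_deb_params(p), error = function(e) NULL)
    if (is.null(p)) return(10)
    f_free <- as.list(x[is_f])
    names(f_free) <- f_series
    evals <<- evals + 1L
    loss <- tryCatch({
      ## reuse previous egg costs as warm starts, keyed by food level role
      pred <- withCallingHandlers(
        predict_observations(p, obs, f_free = f_free),
        warning = function(w) invokeRestart("muffleWarning"))
      .sym_loss(.stack_predictions(pred))
    }, error = function(e) NA_real_)
    if (!is.finite(loss)) return(10)
    loss
  }

  theta <- to_theta(start)
  best <- list(par = theta, value = objective(theta))
  trace <- numeric(0)
  stale <- 0L
  converged <- FALSE
  for (r in seq_len(restarts)) {
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    improved <- opt$value < best$value - reltol * max(abs(best$value), 1e-12)
    if (opt$value < best$value) best <- opt[c("par", "value")]
    trace <- c(trace, best$value)
    if (verbose)
      message(sprintf("restart %d: loss %.6g (%d evals)", r, best$value,
                      evals))
    stale <- if (improved) 0L else stale + 1L
    if (best$value < 1e-12 || stale >= 2L) { converged <- TRUE; break }
  }

  x <- from_theta(best$par)
  p <- unclass(init)
  for (n in par_names) p[[n]] <- x[[n]]
  if (length(par_names)) { p$pAm_j <- NA_real_; p$v_j <- NA_real_ }
  p <- validate_deb_params(p)
  f_free <- as.list(x[is_f]); names(f_free) <- f_series
  pred <- suppressWarnings(predict_observations(p, obs, f_free = f_free))
  stacked <- .stack_predictions(pred)
  res <- list(params = p, f_free = f_free, loss = best$value,
              mre = suppressWarnings(mre(stacked$observed, stacked$predicted,
                                         stacked$weight)),
              smse = suppressWarnings(smse(stacked$observed,
                                           stacked$predicted,
                                           stacked$weight)),
              relative_errors = data.frame(
                name = pred$zerovariate$name,
                RE = relative_error(pred$zerovariate$predicted,
                                    pred$zerovariate$observed)),
              predictions = pred,
              convergence = converged, evals = evals, trace = trace)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("DEB fit: loss %.5g, MRE %.4g, SMSE %.4g (%d evaluations%s)\n",
              x$loss, x$mre, x$smse, x$evals,
              if (x$convergence) "" else ", NOT converged"))
  if (length(x$f_free))
    cat("  free food levels:",
        paste(sprintf("%s = %.3f", names(x$f_free), unlist(x$f_free)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Read or write an observation set
#'
#' The on-disk form is a zerovariate CSV (`name, value, unit, temp_C, f,
#' weight`), a long-format univariate CSV (`series, age_d,
#' shell_height_cm`) and a YAML context file describing each series
#' (`temp_C`, `f` or `f_free`, `weight_total`).
#'
#' @param dir directory holding `zerovariate.csv`, `univariate.csv` and
#'   `context.yml`.
#' @param obs an `observation_set` (for writing).
#' @return `read_observation_set()`: an `observation_set`;
#'   `write_observation_set()`: `dir`, invisibly.
#' @export
read_observation_set <- function(dir) {
  zv <- utils::read.csv(file.path(dir, "zerovariate.csv"),
                        stringsAsFactors = FALSE)
  ctx <- yaml::read_yaml(file.path(dir, "context.yml"))
  uni_path <- file.path(dir, "univariate.csv")
  univariate <- list()
  if (file.exists(uni_path)) {
    long <- utils::read.csv(uni_path, stringsAsFactors = FALSE)
    univariate <- lapply(split(long, long$series), function(d) {
      nm <- d$series[1]
      c(list(name = nm, age_d = d$age_d,
             shell_height_cm = d$shell_height_cm),
        ctx$series[[nm]])
    })
  }
  observation_set(zv, univariate, notes = ctx$notes)
}

#' @rdname read_observation_set
#' @export
write_observation_set <- function(obs, dir) {
  stopifnot(inherits(obs, "observation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(obs$zerovariate, file.path(dir, "zerovariate.csv"),
                   row.names = FALSE)
  if (length(obs$univariate)) {
    long <- do.call(rbind, lapply(obs$univariate, function(s)
      data.frame(series = s$name, age_d = s$age_d,
                 shell_height_cm = s$shell_height_cm)))
    utils::write.csv(long, file.path(dir, "univariate.csv"),
                     row.names = FALSE)
  }
  ctx <- list(series = lapply(obs$univariate, function(s)
    s[intersect(names(s), c("temp_C", "f", "f_free", "weight_total"))]),
    notes = obs$notes)
  yaml::write_yaml(ctx, file.path(dir, "context.yml"))
  invisible(dir)
}
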