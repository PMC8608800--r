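#' Construct and validate a DEB parameter set
#'
#' Bundles the primary parameters of an abj-DEB model together with the
#' auxiliary constants needed for temperature correction and for converting
#' structural volume to measurable quantities (shell height, wet weight).
#' Defaults are the published values for the deep-sea wood borer
#' *Xylonora atlantica*; any subset can be overridden.
#'
#' Rates (`pAm_b`, `v_b`, `p_M`, `k_J`) are specified at the reference
#' temperature `T_ref` and are corrected to ambient temperature with the
#' one-parameter Arrhenius factor (see [arrhenius_correction()]).
#' Temperatures are handled internally in kelvin; every user-facing
#' argument is in degrees Celsius.
#'
#' @param kappa allocation fraction to soma, dimensionless in (0, 1).
#' @param pAm_b maximum surface-specific assimilation rate at birth,
#'   J cm^-2 d^-1 at `T_ref`.
#' @param pAm_j maximum surface-specific assimilation rate after
#'   metamorphosis, J cm^-2 d^-1 (optional; `pAm_j / pAm_b` is the
#'   acceleration factor).
#' @param v_b energy conductance at birth, cm d^-1 at `T_ref`.
#' @param v_j energy conductance after metamorphosis, cm d^-1 (optional).
#' @param E_G volume-specific cost for structure, J cm^-3.
#' @param p_M volume-specific somatic maintenance, J cm^-3 d^-1 at `T_ref`.
#' @param k_J maturity maintenance rate coefficient, d^-1 at `T_ref`.
#' @param kappa_R reproduction efficiency, dimensionless.
#' @param EH_h,EH_b,EH_j,EH_p maturity thresholds at hatching, birth
#'   (first feeding), metamorphosis completion and puberty, J.
#' @param T_A Arrhenius temperature, K.
#' @param T_ref reference temperature, K.
#' @param delta_ME shape coefficient of the isomorphic larva.
#' @param delta_M shape coefficient of the isomorphic juvenile/adult.
#' @param d_V structural dry-mass density, g cm^-3.
#' @param w_E molar weight of reserve, g mol^-1.
#' @param mu_E chemical potential of reserve, J mol^-1.
#' @param meta optional named list of metadata (species, provenance, ...).
#'
#' @return An object of class `deb_params` (a validated named list).
#' @seealso [xylonora_params()] for the shipped parameter file,
#'   [derive_compound()] for compound parameters.
#' @export
#' @examples
#' p <- deb_params()
#' p$kappa
deb_params <- function(kappa = 0.73,
                       pAm_b = 14.36, pAm_j = 38.77,
                       v_b = 0.0053, v_j = 0.0143,
                       E_G = 2349, p_M = 29.22,
                       k_J = 0.002, kappa_R = 0.95,
                       EH_h = 7.5629e-06, EH_b = 1.04e-3,
                       EH_j = 2.03e-2, EH_p = 1.65,
                       T_A = 8000, T_ref = 293.15,
                       delta_ME = 0.629, delta_M = 0.599,
                       d_V = 0.09, w_E = 23.9, mu_E = 550000,
                       meta = list()) {
  p <- list(kappa = kappa, pAm_b = pAm_b, pAm_j = pAm_j,
            v_b = v_b, v_j = v_j, E_G = E_G, p_M = p_M,
            k_J = k_J, kappa_R = kappa_R,
            EH_h = EH_h, EH_b = EH_b, EH_j = EH_j, EH_p = EH_p,
            T_A = T_A, T_ref = T_ref,
            delta_ME = delta_ME, delta_M = delta_M,
            d_V = d_V, w_E = w_E, mu_E = mu_E,
            meta = meta)
  validate_deb_params(p)
}

validate_deb_params <- function(p) {
  num <- c("kappa", "pAm_b", "v_b", "E_G", "p_M", "k_J", "kappa_R",
           "EH_h", "EH_b", "EH_j", "EH_p", "T_A", "T_ref",
           "delta_ME", "delta_M", "d_V", "w_E", "mu_E")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  if (p$kappa >= 1)
    stop("kappa must lie in (0, 1)", call. = FALSE)
  if (p$kappa_R > 1)
    stop("kappa_R cannot exceed 1", call. = FALSE)
  if (!(p$EH_h < p$EH_b && p$EH_b < p$EH_j && p$EH_j < p$EH_p))
    stop("maturity thresholds must be ordered EH_h < EH_b < EH_j < EH_p",
         call. = FALSE)
  for (nm in c("pAm_j", "v_j")) {
    v <- p[[nm]]
    if (!is.null(v) && !(is.na(v)) && (!is.numeric(v) || v <= 0))
      stop("parameter '", nm, "' must be positive or NULL", call. = FALSE)
  }
  if (!is.null(p$pAm_j) && !is.null(p$v_j) &&
      !is.na(p$pAm_j) && !is.na(p$v_j)) {
    r1 <- p$pAm_j / p$pAm_b
    r2 <- p$v_j / p$v_b
    if (abs(r1 - r2) / r2 > 0.005)
      warning("acceleration factor from assimilation (", signif(r1, 4),
              ") and conductance (", signif(r2, 4),
              ") disagree by more than 0.5%", call. = FALSE)
  }
  structure(p, class = "deb_params")
}

#' @export
print.deb_params <- function(x, ...) {
  sp <- if (!is.null(x$meta$species)) x$meta$species else "unspecified species"
  cat("abj-DEB parameter set (", sp, ")\n", sep = "")
  cat(sprintf("  kappa = %.3g  {p_Am}_b = %.4g J/cm^2/d  v_b = %.4g cm/d\n",
              x$kappa, x$pAm_b, x$v_b))
  cat(sprintf("  [E_G] = %.4g J/cm^3  [p_M] = %.4g J/cm^3/d  k_J = %.3g /d\n",
              x$E_G, x$p_M, x$k_J))
  cat(sprintf("  E_H: h %.3g, b %.3g, j %.3g, p %.3g J\n",
              x$EH_h, x$EH_b, x$EH_j, x$EH_p))
  cat(sprintf("  T_A = %.0f K (T_ref = %.2f K); delta_ME = %.3f, delta_M = %.3f\n",
              x$T_A, x$T_ref, x$delta_ME, x$delta_M))
  invisible(x)
}

#' Shipped parameter set for Xylonora atlantica
#'
#' Reads the parameter file installed with the package.  The hatching
#' threshold `EH_h` in this file was calibrated once with
#' [calibrate_hatch_threshold()] so that the simulated age at hatching at
#' 4 degrees C and egg reserve density 1 equals 5.6 d.
#'
#' @return A `deb_params` object.
#' @export
xylonora_params <- function() {
  read_deb_params(system.file("extdata", "xylonora_atlantica_params.json",
                              package = "xylodeb", mustWork = TRUE))
}

#' Read or write a DEB parameter file
#'
#' Parameter files are flat JSON objects keyed by the field names of
#' [deb_params()], with an optional `meta` block.  Round-trip fidelity is
#' preserved at full double precision.
#'
#' @param path file path.
#' @param params a `deb_params` object (for writing).
#' @return `read_deb_params()` returns a `deb_params` object;
#'   `write_deb_params()` returns `path` invisibly.
#' @export
read_deb_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- raw$meta
  raw$meta <- NULL
  known <- names(formals(deb_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter field(s) in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(deb_params, c(raw, list(meta = as.list(meta))))
}

#' @rdname read_deb_params
#' @export
write_deb_params <- function(params, path) {
  stopifnot(inherits(params, "deb_params"))
  x <- unclass(params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Derive compound DEB parameters
#'
#' Computes the compound quantities implied by the primary parameters:
#' maximum reserve capacity `E_m = {p_Am}_b / v_b` (J cm^-3), somatic
#' maintenance rate coefficient `k_M = [p_M] / [E_G]` (d^-1), maximum
#' structural length before acceleration `L_m = kappa {p_Am}_b / [p_M]`
#' (cm), energy investment ratio `g = [E_G] / (kappa E_m)`, the
#' wet-weight coefficient `omega = E_m w_E / (d_V mu_E)`, and the
#' acceleration factor `s_M_max`.  When the after-metamorphosis
#' assimilation rate is supplied, `s_M_max = pAm_j / pAm_b`; otherwise it
#' must be obtained from a simulated trajectory as `L_j / L_b`.
#'
#' @param params a `deb_params` object.
#' @return An object of class `compound_params`: a named list with
#'   elements `E_m`, `k_M`, `L_m`, `g`, `omega`, `s_M_max` (the latter
#'   `NA` if no after-metamorphosis rate is available).
#' @export
#' @examples
#' derive_compound(deb_params())
derive_compound <- function(params) {
  stopifnot(inherits(params, "deb_params"))
  E_m <- params$pAm_b / params$v_b
  out <- list(
    E_m = E_m,
    k_M = params$p_M / params$E_G,
    L_m = params$kappa * params$pAm_b / params$p_M,
    g = params$E_G / (params$kappa * E_m),
    omega = E_m * params$w_E / (params$d_V * params$mu_E),
    s_M_max = if (!is.null(params$pAm_j) && !is.na(params$pAm_j))
      params$pAm_j / params$pAm_b else NA_real_
  )
  structure(out, class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf(paste0("compound DEB parameters: E_m = %.4g J/cm^3, ",
                     "k_M = %.4g /d, L_m = %.4g cm, g = %.4g, s_M = %.4g\n"),
              x$E_m, x$k_M, x$L_m, x$g, x$s_M_max))
  invisible(x)
}

#' Arrhenius temperature correction
#'
#' One-parameter thermal correction multiplying all physiological rates:
#' `c(T) = exp(T_A / T_ref - T_A / T)` with `T` in kelvin.  At the
#' reference temperature the factor is exactly 1, and it increases
#' monotonically with temperature.
#'
#' @param T_celsius ambient temperature, degrees C (vectorized).
#' @param params a `deb_params` object supplying `T_A` and `T_ref`.
#' @return The dimensionless correction factor(s).
#' @export
#' @examples
#' p <- deb_params()
#' arrhenius_correction(p$T_ref - 273.15, p)  # 1 by construction
arrhenius_correction <- function(T_celsius, params) {
  stopifnot(inherits(params, "deb_params"))
  if (any(!is.finite(T_celsius)) || any(T_celsius <= -273.15))
    stop("non-physical temperature: must exceed absolute zero (-273.15 C)",
         call. = FALSE)
  exp(params$T_A / params$T_ref - params$T_A / (T_celsius + 273.15))
}

#' Convert structural volume to physical shell height
#'
#' Shell height is `V^(1/3) / delta`, with the larval shape coefficient
#' `delta_ME` for stages up to metamorphosis completion and the
#' juvenile/adult coefficient `delta_M` after it.
#'
#' @param V structural volume, cm^3 (vectorized, non-negative).
#' @param stage one of `"embryo"`, `"larva_pre_birth"`,
#'   `"larva_accelerating"` (larval shape) or `"juvenile"`, `"adult"`
#'   (adult shape); may be a vector matching `V`.
#' @param params a `deb_params` object.
#' @return Shell height(s), cm.
#' @export
shell_height <- function(V, stage, params) {
  stopifnot(inherits(params, "deb_params"))
  if (any(V < 0)) stop("structural volume must be non-negative", call. = FALSE)
  V^(1 / 3) / shape_coefficient(stage, params)
}

#' Convert physical shell height to structural volume
#'
#' Inverse of [shell_height()].
#'
#' @param Lw shell height, cm (vectorized, non-negative).
#' @inheritParams shell_height
#' @return Structural volume(s), cm^3.
#' @export
structural_volume <- function(Lw, stage, params) {
  stopifnot(inherits(params, "deb_params"))
  if (any(Lw < 0)) stop("shell height must be non-negative", call. = FALSE)
  (Lw * shape_coefficient(stage, params))^3
}

shape_coefficient <- function(stage, params) {
  larval <- c("embryo", "larva_pre_birth", "larva_accelerating")
  adult <- c("juvenile", "adult")
  bad <- setdiff(unique(stage), c(larval, adult))
  if (length(bad))
    stop("unknown life stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ifelse(stage %in% larval, params$delta_ME, params$delta_M)
}

#' Wet weight from structure and scaled reserve density
#'
#' `Ww = V (1 + e * omega)` with `omega = E_m w_E / (d_V mu_E)`: the
#' contribution of reserve is linear in the scaled reserve density `e`.
#' The reproduction buffer is not included.
#'
#' @param V structural volume, cm^3.
#' @param e scaled reserve density in `[0, 1]`.
#' @param params a `deb_params` object.
#' @return Wet weight, g.
#' @export
wet_weight <- function(V, e, params) {
  stopifnot(inherits(params, "deb_params"))
  if (any(V < 0)) stop("structural volume must be non-negative", call. = FALSE)
  if (any(e < 0 | e > 1)) stop("scaled reserve density must lie in [0, 1]",
                               call. = FALSE)
  cp <- derive_compound(params)
  V * (1 + e * cp$omega)
}

#' Calibrate the hatching maturity threshold
#'
#' The hatching threshold `EH_h` is rarely reported.  This helper fixes it
#' so that the simulated age at hatching for an embryo developing at a
#' given temperature (egg provisioned at reserve density `f_egg`) equals a
#' target age: it integrates the embryo and reads the maturity reached at
#' that age.
#'
#' @param params a `deb_params` object (its `EH_h` is ignored).
#' @param age_hatch_d target age at hatching, d.
#' @param temp_C incubation temperature, degrees C.
#' @param f_egg scaled reserve density of the egg at birth (maternal food
#'   level).
#' @return The calibrated threshold, J.
#' @export
calibrate_hatch_threshold <- function(params, age_hatch_d = 5.6,
                                      temp_C = 4, f_egg = 1) {
  stopifnot(inherits(params, "deb_params"))
  E0 <- initial_reserve(params, f_egg)
  st <- embryo_states(params, E0, temp_C, times = c(0, age_hatch_d))
  EH <- unname(st[nrow(st), "EH"])
  if (EH >= params$EH_b)
    stop("embryo reaches the birth threshold before the target hatch age; ",
         "check age_hatch_d and temperature", call. = FALSE)
  EH
}
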