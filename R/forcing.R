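#' Piecewise-constant environmental forcing
#'
#' A forcing schedule is an ordered set of contiguous segments, each with
#' a start age (d), a temperature (degrees C) and a scaled functional
#' response `f` in `[0, 1]`.  The first segment must start at age 0; each
#' segment extends to the start of the next (the last to the simulation
#' horizon).  An optional allocation override switches the somatic
#' allocation fraction `kappa` (and optionally `f`) when a life-stage
#' event fires or a given age is passed — used for the dwarf-male
#' scenario, where `kappa` drops at metamorphosis completion.
#'
#' @param start numeric vector of segment start ages, d (first must be 0,
#'   strictly increasing).
#' @param temp_C temperature per segment, degrees C.
#' @param f scaled functional response per segment, in `[0, 1]`.
#' @param kappa_override `NULL`, or a list with elements `at` (either a
#'   stage name among `"birth"`, `"metamorphosis"`, `"puberty"`, or a
#'   numeric age in d), `kappa` (the new allocation fraction), and
#'   optionally `f` (a new food level applied from the same moment).
#' @return An object of class `forcing_schedule`.
#' @export
#' @examples
#' forcing_schedule(0, 4, 1)
#' forcing_schedule(c(0, 100), c(4, 11), c(1, 0.8))
forcing_schedule <- function(start, temp_C, f, kappa_override = NULL) {
  if (length(start) == 0) stop("forcing needs at least one segment",
                               call. = FALSE)
  if (!(length(start) == length(temp_C) && length(start) == length(f)))
    stop("start, temp_C and f must have equal lengths", call. = FALSE)
  if (start[1] != 0)
    stop("first forcing segment must start at age 0 (got ", start[1], ")",
         call. = FALSE)
  if (length(start) > 1 && any(diff(start) <= 0))
    stop("segment start ages must be strictly increasing", call. = FALSE)
  if (any(f < 0 | f > 1))
    stop("f must lie in [0, 1]; offending segment(s): ",
         paste(which(f < 0 | f > 1), collapse = ", "), call. = FALSE)
  if (any(temp_C <= -273.15))
    stop("non-physical temperature in forcing segment(s): ",
         paste(which(temp_C <= -273.15), collapse = ", "), call. = FALSE)
  if (!is.null(kappa_override)) {
    if (is.null(kappa_override$at) || is.null(kappa_override$kappa))
      stop("kappa_override needs elements 'at' and 'kappa'", call. = FALSE)
    if (is.character(kappa_override$at) &&
        !kappa_override$at %in% c("birth", "metamorphosis", "puberty"))
      stop("kappa_override$at must be an age or one of ",
           "'birth', 'metamorphosis', 'puberty'", call. = FALSE)
    k <- kappa_override$kappa
    if (!is.numeric(k) || k <= 0 || k >= 1)
      stop("kappa_override$kappa must lie in (0, 1)", call. = FALSE)
    if (!is.null(kappa_override$f) &&
        (kappa_override$f < 0 || kappa_override$f > 1))
      stop("kappa_override$f must lie in [0, 1]", call. = FALSE)
  }
  structure(list(segments = data.frame(start = as.numeric(start),
                                       temp_C = as.numeric(temp_C),
                                       f = as.numeric(f)),
                 kappa_override = kappa_override),
            class = "forcing_schedule")
}

#' Constant-environment forcing
#'
#' @param temp_C temperature, degrees C.
#' @param f scaled functional response in `[0, 1]`.
#' @inheritParams forcing_schedule
#' @return A one-segment `forcing_schedule`.
#' @export
constant_forcing <- function(temp_C, f, kappa_override = NULL) {
  forcing_schedule(0, temp_C, f, kappa_override)
}

#' @export
print.forcing_schedule <- function(x, ...) {
  cat("forcing schedule with", nrow(x$segments), "segment(s):\n")
  print(x$segments, row.names = FALSE)
  if (!is.null(x$kappa_override)) {
    ko <- x$kappa_override
    cat("kappa override at", as.character(ko$at), "-> kappa =", ko$kappa,
        if (!is.null(ko$f)) paste0(", f = ", ko$f) else "", "\n")
  }
  invisible(x)
}

#' Read or write a forcing schedule (YAML or JSON)
#'
#' The file holds a list `segments` of `{start, temp_C, f}` mappings and
#' an optional `kappa_override` mapping.  Validation errors name the
#' offending segment.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @param forcing a `forcing_schedule` (for writing).
#' @return `read_forcing()` returns a `forcing_schedule`;
#'   `write_forcing()` returns `path` invisibly.
#' @export
read_forcing <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- raw$segments
  if (is.null(segs) || !length(segs))
    stop("'", path, "': no forcing segments found", call. = FALSE)
  get_field <- function(seg, nm, i) {
    v <- seg[[nm]]
    if (is.null(v) || !is.numeric(v))
      stop("'", path, "', segment ", i, ": missing or non-numeric '", nm,
           "'", call. = FALSE)
    v
  }
  start <- vapply(seq_along(segs), function(i)
    get_field(segs[[i]], "start", i), numeric(1))
  temp <- vapply(seq_along(segs), function(i)
    get_field(segs[[i]], "temp_C", i), numeric(1))
  fv <- vapply(seq_along(segs), function(i)
    get_field(segs[[i]], "f", i), numeric(1))
  forcing_schedule(start, temp, fv, kappa_override = raw$kappa_override)
}

#' @rdname read_forcing
#' @export
write_forcing <- function(forcing, path) {
  stopifnot(inherits(forcing, "forcing_schedule"))
  segs <- lapply(seq_len(nrow(forcing$segments)), function(i)
    as.list(forcing$segments[i, ]))
  out <- list(segments = segs)
  if (!is.null(forcing$kappa_override))
    out$kappa_override <- forcing$kappa_override
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

## segment lookup: T, f at a given age
forcing_at <- function(forcing, age) {
  segs <- forcing$segments
  i <- findInterval(age, segs$start)
  i[i < 1L] <- 1L
  list(temp_C = segs$temp_C[i], f = segs$f[i])
}
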