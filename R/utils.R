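# Internal helpers: unit conversion, logging, seeded RNG.

.unit_groups <- list(
  length           = c(m = 1, mm = 1e-3, um = 1e-6),
  force            = c(N = 1, mN = 1e-3, uN = 1e-6),
  torque           = c(N.m = 1, mN.m = 1e-3, uN.m = 1e-6),
  pressure         = c(Pa = 1, kPa = 1e3, MPa = 1e6),
  angular_velocity = c(`rad/s` = 1)
)

#' Convert between units of the same physical dimension
#'
#' Canonical internal units are SI (m, N, N.m, Pa, rad/s). Instrument exports
#' frequently use micro/milli multiples; this converts between them.
#'
#' @param x numeric vector.
#' @param from,to unit names, e.g. `"uN.m"`, `"N.m"`, `"um"`, `"mN"`, `"kPa"`.
#' @return `x` expressed in `to` units.
#' @examples
#' convert_units(25, "uN.m", "N.m")  # 2.5e-05
#' @export
convert_units <- function(x, from, to) {
  grp_of <- function(u) {
    hit <- which(vapply(.unit_groups, function(g) u %in% names(g), logical(1)))
    if (length(hit) == 0L) stop("unknown unit: '", u, "'", call. = FALSE)
    hit[1L]
  }
  gf <- grp_of(from); gt <- grp_of(to)
  if (gf != gt) {
    stop("incompatible units: '", from, "' (", names(.unit_groups)[gf],
         ") vs '", to, "' (", names(.unit_groups)[gt], ")", call. = FALSE)
  }
  g <- .unit_groups[[gf]]
  x * unname(g[from] / g[to])
}

#' Direct preprocessing log messages to a file
#'
#' Every data discard (retraction samples, duplicated angular velocities,
#' substratum-detection fallbacks, per-file pipeline failures) is logged so
#' preprocessing is auditable. By default messages go to the console; give a
#' path to append them to a plain-text log instead, or `NULL` to reset.
#'
#' @param path file path or `NULL`.
#' @return previous value, invisibly.
#' @export
set_log_file <- function(path = NULL) {
  old <- getOption("biofilmmech.log_file")
  options(biofilmmech.log_file = path)
  invisible(old)
}

log_event <- function(...) {
  msg <- paste0(...)
  path <- getOption("biofilmmech.log_file")
  if (is.null(path)) {
    message(msg)
  } else {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", msg, "\n",
        file = path, append = TRUE, sep = "")
  }
  invisible(msg)
}

# Run code with a temporary RNG seed, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}
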