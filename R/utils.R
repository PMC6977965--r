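#' Wrap angles to (-pi, pi]
#'
#' Circular quantities (movement directions, preferred directions, PD shifts)
#' are kept on the half-open interval (-pi, pi] throughout the package;
#' degrees appear only at I/O boundaries.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(pi, -pi, 3 * pi / 2))
wrap_angle <- function(theta) {
  stopifnot(is.numeric(theta))
  -((-theta + pi) %% (2 * pi) - pi)
}

#' Circular mean of angles
#'
#' Direction of the resultant vector of unit vectors at the given angles.
#' A (near-)zero resultant leaves the mean undefined; `NA` is returned with
#' a warning so callers can exclude the case (e.g. a neuron whose bootstrap
#' PDs cancel out).
#'
#' @param theta Angles in radians.
#' @param tol Resultant length below which the mean is declared undefined.
#' @return Scalar angle in (-pi, pi], or `NA_real_` if undefined.
#' @export
circ_mean <- function(theta, tol = 1e-10) {
  s <- mean(sin(theta))
  c <- mean(cos(theta))
  if (sqrt(s^2 + c^2) < tol) {
    warning("circular mean undefined: resultant vector has (near-)zero length")
    return(NA_real_)
  }
  atan2(s, c)
}

#' Derive a stage seed from a master seed
#'
#' One master seed per run deterministically spawns independent per-stage
#' seeds, so that each pipeline stage is individually reproducible without
#' coupling its random stream to earlier stages. The derived seed always
#' fits in a 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master), is.character(stage))
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code))
  as.integer(((abs(master) %% 1000003) * 2011 + (h %% 65011) * 31 + 1) %% 2147483646L) + 1L
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# shared argument checks -----------------------------------------------------

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop_invalid("`%s` must be a positive finite scalar", name)
  }
  invisible(x)
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("spike counts must be nonnegative integers")
  }
  invisible(counts)
}
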