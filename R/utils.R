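# Shared small helpers.

# km per degree of latitude (and of longitude at the equator) on the
# spherical Earth used throughout; matches a 6371-km mean radius closely
# enough for daily-scale displacement propagation.
KM_PER_DEG <- 111.32

#' Wrap angles into (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run expr under a temporary RNG state when seed is given; global RNG is
# untouched either way unless seed is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
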