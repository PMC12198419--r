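#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; `axis` need not be normalized.
#'
#' @param axis length-3 numeric axis.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s * ux + (1 - c_) * (u %o% u)
}

rot_x <- function(a) rot_axis(c(1, 0, 0), a)
rot_y <- function(a) rot_axis(c(0, 1, 0), a)
rot_z <- function(a) rot_axis(c(0, 0, 1), a)

#' Random uniform rotation from Euler Z-Y-X angles
#' @keywords internal
random_euler_rotation <- function() {
  ang <- stats::runif(3, -pi, pi)
  rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3])
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

rmse <- function(x, y) sqrt(mean((x - y)^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
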