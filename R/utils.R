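# Shared geometric helpers and the package-wide anatomical frame convention:
# +X anterior, +Y superior, +Z toward the right-lateral side; floor plane Y = 0;
# the sagittal projection drops Z, the coronal projection drops X.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about the mediolateral (Z) axis
#'
#' Positive angles rotate +X toward +Y (anterior end raised), i.e. a
#' sagittal-plane pitch.
#'
#' @param theta_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), 3, 3)
}

#' Rotation matrix about the anteroposterior (X) axis
#'
#' Positive angles rotate +Y toward +Z, i.e. a coronal-plane tilt.
#'
#' @param theta_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(1, 0, 0,
           0, cos(t), sin(t),
           0, -sin(t), cos(t)), 3, 3)
}

#' Rotation matrix about the vertical (Y) axis
#' @param theta_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_y <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3, 3)
}

# Signed sagittal elevation (degrees) of a direction vector: angle of its XY
# projection above the floor, positive superior. The vector is assumed to be
# oriented anteriorly (positive X component).
sagittal_elevation <- function(v) {
  rad2deg(atan2(v[2], v[1]))
}

# Signed coronal inclination (degrees) of an up-pointing direction: angle of
# its YZ projection away from vertical. `lateral_sign` is +1 for a right foot
# (+Z lateral) and -1 for a left foot, so that the sign convention is
# side-invariant.
coronal_inclination <- function(v, lateral_sign = 1) {
  rad2deg(atan2(lateral_sign * v[3], v[2]))
}

# Wrap an angle difference into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

# Apply a rigid (or similarity) transform to an N x 3 vertex matrix.
apply_transform <- function(v, rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  sweep(scale * (v %*% t(rotation)), 2, -translation)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Used to fan a global seed out into
# per-subject substreams.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
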