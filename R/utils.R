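# Small vector helpers shared across the geometry and synthetic modules.
# Points are plain length-3 numeric vectors (mm); matrices are n x 3.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    stop("cannot normalize a (near-)zero-length vector", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# row-wise cross product of an n x 3 matrix with a fixed length-3 vector
rowcross <- function(m, v) {
  cbind(
    m[, 2] * v[3] - m[, 3] * v[2],
    m[, 3] * v[1] - m[, 1] * v[3],
    m[, 1] * v[2] - m[, 2] * v[1]
  )
}

rownorms <- function(m) sqrt(rowSums(m * m))

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the unit axis `axis`.
#'
#' @param axis length-3 numeric, need not be normalized.
#' @param angle rotation angle in degrees.
#' @return a 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  a <- unit(axis)
  th <- rad(angle)
  K <- matrix(c(
    0, -a[3], a[2],
    a[3], 0, -a[1],
    -a[2], a[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || !all(is.finite(p))) {
    stop(sprintf("%s must be 3 finite coordinates", what), call. = FALSE)
  }
  p
}
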