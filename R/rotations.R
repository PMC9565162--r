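#' Build a deterministic quasi-uniform rotation set
#'
#' Covers SO(3) with unit quaternions laid out on a Super-Fibonacci
#' spiral, a deterministic low-discrepancy construction with near-optimal
#' covering radius. The set size is chosen as \code{ceiling(4 / mu)},
#' where \code{mu = (theta - sin theta) / pi} is the Haar measure of a
#' ball of radius \code{theta} (the nominal spacing) in the rotation-angle
#' metric, so that every rotation lies within the nominal spacing of some
#' member. The identity is prepended at index 1.
#'
#' @param spacing nominal angular spacing in degrees, in (0, 90]
#' @return a \linkS4class{RotationSet}
#' @examples
#' rs <- buildRotationSet(90)
#' rotationCount(rs)
#' @export
buildRotationSet <- function(spacing = 10) {
  stopifnot(spacing > 0, spacing <= 90)
  theta <- spacing * pi / 180
  mu <- (theta - sin(theta)) / pi
  n <- as.integer(ceiling(4 / mu))
  q <- .superFibonacci(n)
  q <- rbind(c(1, 0, 0, 0), q)
  mats <- array(0, c(3, 3, nrow(q)))
  for (i in seq_len(nrow(q))) mats[, , i] <- .quatToMat(q[i, ])
  methods::new("RotationSet", matrices = mats, quaternions = q,
               spacing = spacing)
}

# Super-Fibonacci quaternion spiral (w, x, y, z), n points
.superFibonacci <- function(n) {
  i <- seq_len(n) - 0.5
  t <- i / n
  d <- 2 * pi * i
  PHI <- sqrt(2)
  PSI <- 1.533751168755204288118041
  r <- sqrt(t)
  R <- sqrt(1 - t)
  a <- d / PHI
  b <- d / PSI
  cbind(R * cos(b), r * sin(a), r * cos(a), R * sin(b))
}

#' Angular distance from rotations to the nearest set member
#'
#' For each query rotation, the relative-rotation angle to its nearest
#' neighbor in the set; used to verify the covering property.
#'
#' @param rs a \linkS4class{RotationSet}
#' @param quats m x 4 matrix of query unit quaternions
#' @return numeric vector of angles in degrees
#' @export
coverageGap <- function(rs, quats) {
  dots <- abs(quats %*% t(rs@quaternions))
  dots[dots > 1] <- 1
  2 * acos(apply(dots, 1, max)) * 180 / pi
}
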