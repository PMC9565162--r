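# Rotation and RNG helpers shared across modules.

# quaternion (w, x, y, z) -> 3x3 rotation matrix
.quatToMat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)
  ), 3, 3, byrow = TRUE)
}

# 3x3 rotation matrix -> unit quaternion with w >= 0
.matToQuat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q * q))
}

#' Relative rotation angle between two rotations
#'
#' The geodesic distance on SO(3): the angle of the rotation \code{A^T B},
#' in degrees.
#'
#' @param A,B 3x3 rotation matrices
#' @return angle in degrees, in [0, 180]
#' @export
rotationAngle <- function(A, B = diag(3)) {
  tr <- sum(diag(crossprod(A, B)))
  c_ <- (tr - 1) / 2
  c_ <- min(1, max(-1, c_))
  acos(c_) * 180 / pi
}

# uniform random rotation (Shoemake's subgroup algorithm), consumes 3 draws
.randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  .quatToMat(q)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a subsystem seed from the master seed; keeps results < 2^31.
.deriveSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

# FNV-1a hash of a character vector, hex string; used for provenance stamps.
.textHash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
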