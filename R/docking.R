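#' Rasterize a protein onto a step-function docking grid
#'
#' Step-function approximation of the Lennard-Jones potential on a cubic
#' grid: cells whose center lies within the atom radius (uniform 1.7 A
#' plus half a grid step) of any rotated atom are occupied. For a
#' receptor, occupied cells with at least one empty 6-neighbor form the
#' one-cell attractive surface layer (+1) and deeper occupied cells the
#' repulsive core (-rho); for a ligand every occupied cell scores +1.
#' The grid is cubic with an odd cell count per axis, centered on the
#' molecule's geometric center, and always contains the rotated molecule
#' plus one empty boundary layer.
#'
#' @param p a \linkS4class{Protein}
#' @param rot 3x3 rotation applied about the geometric center
#' @param step grid step in Angstrom (default 3.5)
#' @param role "receptor" or "ligand"
#' @param rho core repulsion magnitude (default 9)
#' @param atomRadius base atom radius before the half-step smear
#' @return a \linkS4class{ScoreGrid}
#' @export
rasterize <- function(p, rot = diag(3), step = 3.5, role = c("receptor", "ligand"),
                      rho = 9, atomRadius = 1.7) {
  role <- match.arg(role)
  stopifnot(step > 0, rho > 0)
  xyz <- as.matrix(p@atoms[, c("x", "y", "z")])
  A <- sweep(xyz, 2, p@center) %*% t(rot)
  rAtom <- atomRadius + step / 2
  occ <- .occupancyGrid(A, step, rAtom)
  if (!any(occ$arr)) stop("empty occupancy grid")
  if (role == "ligand") {
    vals <- occ$arr * 1
  } else {
    core <- .erode6(occ$arr)
    vals <- occ$arr * 1
    vals[core] <- -rho
  }
  methods::new("ScoreGrid", origin = rep(occ$origin, 3), step = step,
               values = vals, role = role)
}

# occupancy on a cubic odd-sized grid symmetric about the origin
.occupancyGrid <- function(A, step, rAtom) {
  m <- max(abs(A)) + rAtom
  hc <- as.integer(ceiling(m / step)) + 1L
  nd <- 2L * hc + 1L
  ax <- (seq_len(nd) - 1L - hc) * step
  occ <- array(FALSE, c(nd, nd, nd))
  r2 <- rAtom * rAtom
  for (a in seq_len(nrow(A))) {
    pnt <- A[a, ]
    ii <- lapply(1:3, function(k) which(abs(ax - pnt[k]) <= rAtom))
    if (any(vapply(ii, length, 1L) == 0L)) next
    dx2 <- (ax[ii[[1]]] - pnt[1])^2
    dy2 <- (ax[ii[[2]]] - pnt[2])^2
    dz2 <- (ax[ii[[3]]] - pnt[3])^2
    blk <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    occ[ii[[1]], ii[[2]], ii[[3]]] <-
      occ[ii[[1]], ii[[2]], ii[[3]], drop = FALSE] | blk
  }
  list(arr = occ, origin = -hc * step)
}

# cells whose 6-neighborhood is fully occupied (the core after 1-cell erosion)
.erode6 <- function(occ) {
  d <- dim(occ)
  core <- occ
  shift <- function(arr, k, by) {
    out <- array(FALSE, dim(arr))
    n <- dim(arr)[k]
    idx <- lapply(dim(arr), seq_len)
    src <- idx
    if (by == 1L) { idx[[k]] <- 2:n; src[[k]] <- 1:(n - 1L) }
    else { idx[[k]] <- 1:(n - 1L); src[[k]] <- 2:n }
    out[idx[[1]], idx[[2]], idx[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (k in 1:3) for (by in c(1L, -1L)) core <- core & shift(occ, k, by)
  core
}

#' Correlate receptor and ligand score grids over all translations
#'
#' Linear (zero-padded, non-circular) correlation
#' \code{score(t) = sum_x receptor(x) * ligand(x - t)} computed by FFT.
#' The result covers every integer translation with any overlap:
#' \code{t} ranges over \code{-(dimL-1) .. (dimR-1)} per axis, recorded in
#' the \code{tauMin} attribute (value of \code{t} at index 1).
#'
#' @param receptor,ligand \linkS4class{ScoreGrid}s with equal steps
#' @return numeric 3D array of scores with attributes \code{tauMin}
#'   (integer translation at index 1 per axis) and \code{step}
#' @export
correlate <- function(receptor, ligand) {
  stopifnot(abs(receptor@step - ligand@step) < 1e-9)
  rv <- receptor@values
  lv <- ligand@values
  dR <- dim(rv)
  dL <- dim(lv)
  P <- dR + dL - 1L
  Q <- vapply(P, function(n) stats::nextn(n, factors = c(2, 3, 5)), numeric(1))
  RP <- array(0, Q)
  RP[seq_len(dR[1]), seq_len(dR[2]), seq_len(dR[3])] <- rv
  LP <- array(0, Q)
  LP[seq_len(dL[1]), seq_len(dL[2]), seq_len(dL[3])] <- lv
  C0 <- Re(stats::fft(stats::fft(RP) * Conj(stats::fft(LP)), inverse = TRUE)) / prod(Q)
  idx <- lapply(1:3, function(k) {
    taus <- (-(dL[k] - 1L)):(dR[k] - 1L)
    (taus %% Q[k]) + 1L
  })
  out <- C0[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out <- round(out, 6)
  attr(out, "tauMin") <- -(dL - 1L)
  attr(out, "step") <- receptor@step
  out
}

#' Dock one ordered pair of proteins
#'
#' Systematic rigid-body search: for every rotation in the set the ligand
#' is rasterized and FFT-correlated against the receptor grid (receptor
#' fixed at the identity orientation); the per-rotation top candidates
#' with positive score are merged into the global top-K pose list, sorted
#' by descending score with ties broken by (rotation index, lexicographic
#' translation). Pose energies are the negated scores, so docked states
#' are negative-energy minima and the monomeric state is zero.
#'
#' @param ligand,receptor \linkS4class{Protein}s (ordered: the ligand is
#'   the molecule that moves)
#' @param rotations a \linkS4class{RotationSet}; built from
#'   \code{spacing} when NULL
#' @param step grid step in Angstrom (default 3.5)
#' @param rho core repulsion magnitude (default 9)
#' @param spacing rotation interval in degrees (default 10)
#' @param topK global number of poses kept (default 30000)
#' @param perRotationCap candidates kept per rotation before the global
#'   merge (default 50)
#' @return data.frame of poses: \code{rot}, \code{tx}, \code{ty},
#'   \code{tz} (integer grid translation), \code{score}, \code{energy},
#'   and the cached pair-frame center displacement \code{dx}, \code{dy},
#'   \code{dz} in Angstrom
#' @export
dockPair <- function(ligand, receptor, rotations = NULL, step = 3.5, rho = 9,
                     spacing = 10, topK = 30000, perRotationCap = 50) {
  if (is.null(rotations)) rotations <- buildRotationSet(spacing)
  gridR <- rasterize(receptor, diag(3), step = step, role = "receptor", rho = rho)
  nrot <- rotationCount(rotations)
  chunks <- vector("list", nrot)
  for (ri in seq_len(nrot)) {
    gridL <- rasterize(ligand, rotationMatrix(rotations, ri), step = step,
                       role = "ligand", rho = rho)
    C <- correlate(gridR, gridL)
    pos <- which(C > 0)
    if (!length(pos)) next
    sc <- C[pos]
    ord <- order(-sc)
    if (length(ord) > perRotationCap) ord <- ord[seq_len(perRotationCap)]
    tauMin <- attr(C, "tauMin")
    d <- dim(C)
    k0 <- pos[ord] - 1L
    t1 <- k0 %% d[1] + tauMin[1]
    t2 <- (k0 %/% d[1]) %% d[2] + tauMin[2]
    t3 <- k0 %/% (d[1] * d[2]) + tauMin[3]
    D0 <- gridR@origin - gridL@origin
    chunks[[ri]] <- data.frame(
      rot = ri, tx = t1, ty = t2, tz = t3, score = sc[ord],
      dx = D0[1] + t1 * step, dy = D0[2] + t2 * step, dz = D0[3] + t3 * step
    )
  }
  poses <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  if (is.null(poses) || nrow(poses) == 0L) {
    warning("no positive-score pose for pair ", ligand@id, " -> ", receptor@id)
    poses <- data.frame(rot = integer(), tx = integer(), ty = integer(),
                        tz = integer(), score = numeric(), dx = numeric(),
                        dy = numeric(), dz = numeric())
  }
  ord <- order(-poses$score, poses$rot, poses$tx, poses$ty, poses$tz)
  poses <- poses[ord, , drop = FALSE]
  if (nrow(poses) > topK) poses <- poses[seq_len(topK), , drop = FALSE]
  poses$energy <- -poses$score
  rownames(poses) <- NULL
  poses[, c("rot", "tx", "ty", "tz", "score", "energy", "dx", "dy", "dz")]
}
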