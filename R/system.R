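#' Minimum-image displacement
#'
#' Maps every displacement component into \code{(-box/2, box/2]} (the
#' boundary tie resolved to \code{+box/2}), i.e. the displacement to the
#' nearest periodic image.
#'
#' @param d numeric vector or matrix of displacement components (Angstrom)
#' @param box cubic box edge (Angstrom)
#' @return object of the same shape as \code{d}
#' @examples
#' minImage(c(499, 0, 0), 500)
#' @export
minImage <- function(d, box) {
  stopifnot(box > 0)
  x <- d - box * round(d / box)
  low <- x <= -box / 2
  x[low] <- x[low] + box
  x
}

# bounding radius of every copy, from its type
.copyRadii <- function(state) {
  vapply(state@proteins, boundingRadius, numeric(1))[state@typeIds]
}

#' Build the initial periodic-box state
#'
#' Places the planned copies in random order on the cubic placement
#' lattice (one copy per site), gives each a uniform random rotation and
#' a uniform jitter within half a lattice step per axis, and wraps into
#' the box. No collision check is applied at this stage: residual
#' overlaps are resolved during the early Monte Carlo steps. No bonds
#' exist yet, so all energies are zero. Fully reproducible under a fixed
#' seed.
#'
#' @param plan a \code{CopyCountPlan} from \code{\link{planCopies}}
#' @param proteins list of \linkS4class{Protein} types, in the plan's
#'   type order
#' @param seed RNG seed for placement
#' @return a \linkS4class{SystemState} at step 0
#' @export
initState <- function(plan, proteins, seed = 1) {
  stopifnot(length(proteins) == length(plan$counts))
  n <- plan$total
  m <- plan$latticeDim
  if (n > m^3) stop("more copies than lattice sites")
  box <- plan$box
  s <- plan$gridStep
  .withSeed(seed, {
    typeIds <- sample(rep(seq_along(proteins), plan$counts))
    sites <- sample.int(m^3, n)
    k0 <- sites - 1L
    sx <- (k0 %% m + 0.5) * s
    sy <- ((k0 %/% m) %% m + 0.5) * s
    sz <- (k0 %/% (m * m) + 0.5) * s
    jit <- matrix(stats::runif(3 * n, -s / 2, s / 2), n, 3)
    pos <- cbind(sx, sy, sz) + jit
    pos <- pos %% box
    rots <- array(0, c(3, 3, n))
    for (i in seq_len(n)) rots[, , i] <- .randomRotation()
    methods::new("SystemState",
      box = box, typeIds = as.integer(typeIds),
      typeNameVec = vapply(proteins, proteinId, character(1)),
      proteins = proteins, rotations = rots,
      pos = unname(pos), upos = unname(pos),
      bondTo = rep(NA_integer_, n), bondEnergy = numeric(n),
      bondPose = rep(NA_integer_, n), bondSince = rep(NA_integer_, n),
      energy = numeric(n), step = 0L
    )
  })
}

#' Neighbor copies of a molecule
#'
#' All copies \code{j != i} whose geometric center lies within
#' \code{r_i + r_j + margin} of copy \code{i}'s center under the minimum
#' image convention. These are the receptors the copy may move to; the
#' default 50 A margin accommodates binding to the first layer of
#' receptors in the crowded environment.
#'
#' @param state a \linkS4class{SystemState}
#' @param i copy id
#' @param margin neighbor margin in Angstrom (default 50)
#' @return integer vector of copy ids
#' @export
neighborsOf <- function(state, i, margin = 50) {
  n <- copyCount(state)
  stopifnot(i >= 1, i <= n)
  radii <- .copyRadii(state)
  d <- minImage(state@pos - matrix(state@pos[i, ], n, 3, byrow = TRUE), state@box)
  d2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
  cut2 <- (radii[i] + radii + margin)^2
  out <- which(d2 < cut2)
  out[out != i]
}

#' Export a state snapshot as a PDB file
#'
#' Writes the C-alpha trace of every copy (world coordinates, wrapped)
#' as one PDB model, copies separated by chain identifiers (recycled)
#' and TER records, for quick visual inspection.
#'
#' @param state a \linkS4class{SystemState}
#' @param file output path
#' @return \code{file}, invisibly
#' @export
writeStatePDB <- function(state, file) {
  con <- file(file, "w")
  on.exit(close(con))
  chains <- rep(c(LETTERS, letters, 0:9), length.out = copyCount(state))
  serial <- 0L
  writeLines(sprintf("REMARK   box %.2f A, step %d", state@box, state@step), con)
  for (i in seq_len(copyCount(state))) {
    p <- state@proteins[[state@typeIds[i]]]
    caw <- sweep(p@calphas, 2, p@center) %*% t(state@rotations[, , i])
    caw <- sweep(caw, 2, state@pos[i, ], "+")
    for (r in seq_len(nrow(caw))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, chains[i], r %% 10000L,
        caw[r, 1], caw[r, 2], caw[r, 3]
      ), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(file)
}
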