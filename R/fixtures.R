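#' Generate a synthetic globular protein structure
#'
#' Builds a compact self-avoiding C-alpha trace (3.8 A virtual bonds)
#' confined to a sphere whose radius scales as N^(1/3), emulating the
#' packing of a globular protein, then decorates each residue with
#' pseudo-side-chain atoms. The result is a fully valid
#' \linkS4class{Protein} whose PDB text (via \code{\link{writePDB}})
#' round-trips through \code{\link{readPDB}}. Deterministic under the
#' seed.
#'
#' @param nResidues number of residues (>= 3)
#' @param shape "globule" (confined walk) or "rod" (extended walk)
#' @param seed RNG seed
#' @param atomsPerResidue pseudo-atoms per residue including the C-alpha
#'   (default 4)
#' @param id protein name; default is derived from the parameters
#' @return a \linkS4class{Protein}
#' @examples
#' p <- syntheticProtein(50, seed = 7)
#' boundingRadius(p)
#' @export
syntheticProtein <- function(nResidues, shape = c("globule", "rod"), seed = 1,
                             atomsPerResidue = 4, id = NULL) {
  shape <- match.arg(shape)
  stopifnot(nResidues >= 3, atomsPerResidue >= 1)
  if (is.null(id)) id <- sprintf("syn%d_%s%d", nResidues, substr(shape, 1, 1), seed)
  bond <- 3.8
  minSep <- 3.6     # non-bonded CA pairs must stay apart (self-avoidance)
  targetR <- 3.3 * nResidues^(1 / 3)
  ca <- .withSeed(seed, .selfAvoidingTrace(nResidues, bond, minSep, targetR, shape))
  atoms <- .withSeed(seed + 1L, .decorateResidues(ca, atomsPerResidue))
  newProtein(id, atoms)
}

# biased self-avoiding walk; backtracks on dead ends, restarts if that
# fails too, errors after bounded tries
.selfAvoidingTrace <- function(n, bond, minSep, targetR, shape) {
  for (attempt in seq_len(60)) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- c(0, 0, 0)
    i <- 2L
    backtracks <- 0L
    while (i <= n) {
      placed <- FALSE
      for (try in seq_len(300)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u * u))
        if (shape == "rod") {
          u <- u + c(3, 0, 0)           # strong axial bias
          u <- u / sqrt(sum(u * u))
        } else {
          # soft pull toward the centroid when drifting past the target
          # radius; kept gentle so tangential escapes remain likely
          prev <- pts[i - 1, ]
          pr <- sqrt(sum(prev^2))
          if (pr > targetR) {
            u <- u + 0.8 * (-prev / pr)
            u <- u / sqrt(sum(u * u))
          }
        }
        cand <- pts[i - 1, ] + bond * u
        if (shape == "globule" && sqrt(sum(cand^2)) > targetR + bond) next
        if (i > 2) {
          dd <- sweep(pts[seq_len(i - 2), , drop = FALSE], 2, cand)
          if (min(rowSums(dd * dd)) < minSep^2) next
        }
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
      if (placed) {
        i <- i + 1L
      } else {
        # dead end: drop the last few residues and regrow
        backtracks <- backtracks + 1L
        if (backtracks > 5L * n) break
        back <- min(i - 2L, 5L)
        if (back < 1L) break
        pts[(i - back):n, ] <- NA_real_
        i <- i - back
      }
    }
    if (i > n) return(pts)
  }
  stop("self-avoidance failure: could not grow a ", n, "-residue trace")
}

# pseudo side chains: extra atoms at 1.6-2.6 A around each CA
.decorateResidues <- function(ca, atomsPerResidue) {
  n <- nrow(ca)
  elems <- c("C", "N", "O")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- data.frame(
      resno = i, elety = "CA", elem = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3]
    )
    for (k in seq_len(atomsPerResidue - 1L)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u * u))
      d <- 1.6 + 0.5 * k
      res <- rbind(res, data.frame(
        resno = i, elety = paste0("CB", k), elem = elems[(k - 1L) %% 3L + 1L],
        x = ca[i, 1] + d * u[1], y = ca[i, 2] + d * u[2], z = ca[i, 3] + d * u[3]
      ))
    }
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

# hand-built minimal Protein: a short compact CA-only trace at a position
.tinyProtein <- function(id, at = c(0, 0, 0)) {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0))
  atoms <- data.frame(
    resno = 1:3, elety = "CA", elem = "C",
    x = ca[, 1] + at[1], y = ca[, 2] + at[2], z = ca[, 3] + at[3]
  )
  newProtein(id, atoms)
}

# abstract marker "protein" with a prescribed bounding radius (collinear
# CA triple); used by toy scenarios where only the radius matters
.markerProtein <- function(id, radius) {
  atoms <- data.frame(
    resno = 1:3, elety = "CA", elem = "C",
    x = c(-radius, 0, radius), y = 0, z = 0
  )
  newProtein(id, atoms)
}

#' Build an enumerable toy scenario
#'
#' Small hand-built systems whose stationary behavior is known in closed
#' form, used to validate the Monte Carlo engine:
#' \describe{
#'   \item{two_state}{two molecules, one ordered pair with two poses of
#'     energies -100 and -50: at temperature T the stationary occupancy
#'     ratio of the deep to the shallow pose is exp(50/T) (1.6487 at
#'     T = 100).}
#'   \item{uniform_walk}{\code{n} mobile walkers hopping with a single
#'     uniform-energy zero-displacement pose onto a static periodic
#'     lattice of anchor copies (immobile: their pose lists are empty),
#'     with the neighbor cutoff tuned so exactly the 6 nearest anchors
#'     are reachable. Each walker is an ideal simple-cubic random walk
#'     with independent increments (collision check off).}
#'   \item{frozen_pair}{one ordered pair with a deep (-10000) and a
#'     shallow (-50) pose: moving out of the deep pose requires an
#'     uphill step of 9950, negligible at low temperature.}
#' }
#'
#' @param name one of "two_state", "uniform_walk", "frozen_pair"
#' @param n copies for \code{uniform_walk} (default 100)
#' @param box box edge in Angstrom (default 200 for the pair scenarios,
#'   250 for the walk)
#' @param hopLength length scale for \code{uniform_walk}: the anchor
#'   lattice spacing is \code{5 * hopLength}
#' @param seed placement seed
#' @return list: \code{proteins}, \code{library}
#'   (\linkS4class{PoseLibrary}), \code{state}
#'   (\linkS4class{SystemState}), \code{config}
#'   (\linkS4class{SimulationConfig} with the scenario's conventions),
#'   \code{expected} (closed-form quantities)
#' @export
buildToyScenario <- function(name = c("two_state", "uniform_walk", "frozen_pair"),
                             n = 100, box = NULL, hopLength = 10, seed = 1) {
  name <- match.arg(name)
  if (name %in% c("two_state", "frozen_pair")) {
    if (is.null(box)) box <- 200
    pA <- .tinyProtein("A")
    pB <- .tinyProtein("B")
    en <- if (name == "two_state") c(-100, -50) else c(-10000, -50)
    # two poses on opposite sides; both keep the pair well inside the
    # neighbor cutoff and far from CA contact
    poses <- data.frame(dx = c(15, -15), dy = 0, dz = 0, energy = en)
    lib <- explicitPoseLibrary(list("A|B" = poses, "B|A" = poses))
    st <- .placePair(pA, pB, box)
    cfg <- simulationConfig(
      box = box, targetV = 0, temperature = if (name == "two_state") 100 else 1,
      steps = 100, collisionCutoff = 0, msdReferenceStep = 0,
      nsPerStep = 20, seed = seed, clusterEvery = 10
    )
    w <- exp(-(en - min(en)) / cfg@temperature)  # shifted to avoid overflow
    expected <- list(
      energies = en,
      occupancyRatio = exp((en[2] - en[1]) / cfg@temperature),
      boltzmann = w / sum(w)
    )
    return(list(proteins = list(pA, pB), library = lib, state = st,
                config = cfg, expected = expected))
  }
  # uniform_walk: n mobile walkers (type W) hop with a single
  # zero-displacement pose onto a static periodic lattice of anchor
  # copies (type L, empty pose lists, hence immobile). Every accepted
  # non-trivial hop is a uniform nearest-neighbor lattice step, so each
  # walker performs an ideal random walk with independent increments:
  # MSD grows linearly with slope equal to the measured per-step mean
  # squared shift.
  s <- 5 * hopLength                     # lattice spacing
  m <- 6L                                # sites per axis
  if (is.null(box)) box <- m * s
  pW <- .tinyProtein("W")
  rW <- boundingRadius(pW)
  # neighbor cutoff between s and s*sqrt(2): exactly the 6 nearest
  # lattice anchors (plus the co-located one) are reachable. A small
  # margin plus a wide anchor radius keeps the walker-walker cutoff
  # tiny, so walkers on different sites never see each other and the
  # N_i/N_j factor stays (almost always) 1.
  margin <- 4
  rL <- 1.15 * s - margin - rW
  pL <- .markerProtein("L", rL)
  rL <- boundingRadius(pL)
  poses <- data.frame(dx = 0, dy = 0, dz = 0, energy = -10)
  lib <- explicitPoseLibrary(list("W|L" = poses))
  nL <- m^3
  st <- .withSeed(seed, {
    k0 <- seq_len(nL) - 1L
    sitePos <- cbind((k0 %% m + 0.5) * s, ((k0 %/% m) %% m + 0.5) * s,
                     (k0 %/% (m * m) + 0.5) * s)
    wSites <- sample.int(nL, n, replace = n > nL)
    pos <- rbind(sitePos[wSites, , drop = FALSE], sitePos)
    ntot <- n + nL
    rots <- array(rep(diag(3), ntot), c(3, 3, ntot))
    methods::new("SystemState",
      box = box, typeIds = c(rep(1L, n), rep(2L, nL)),
      typeNameVec = c("W", "L"), proteins = list(pW, pL),
      rotations = rots, pos = pos, upos = pos,
      bondTo = rep(NA_integer_, ntot), bondEnergy = numeric(ntot),
      bondPose = rep(NA_integer_, ntot), bondSince = rep(NA_integer_, ntot),
      energy = numeric(ntot), step = 0L
    )
  })
  cfg <- simulationConfig(
    box = box, targetV = 0, temperature = 100, steps = 1000,
    neighborMargin = margin, collisionCutoff = 0, msdReferenceStep = 100,
    nsPerStep = 1, seed = seed, clusterEvery = 100, recordEvery = 10
  )
  expected <- list(latticeSpacing = s, energies = -10,
                   hop2PerNontrivialHop = s^2)
  list(proteins = list(pW, pL), library = lib, state = st, config = cfg,
       expected = expected)
}

# deterministic two-molecule placement: centers separated along x
.placePair <- function(pA, pB, box) {
  pos <- rbind(c(box / 2 - 10, box / 2, box / 2),
               c(box / 2 + 10, box / 2, box / 2))
  rots <- array(0, c(3, 3, 2))
  rots[, , 1] <- diag(3)
  rots[, , 2] <- diag(3)
  methods::new("SystemState",
    box = box, typeIds = c(1L, 2L), typeNameVec = c(proteinId(pA), proteinId(pB)),
    proteins = list(pA, pB), rotations = rots,
    pos = pos, upos = pos,
    bondTo = rep(NA_integer_, 2), bondEnergy = numeric(2),
    bondPose = rep(NA_integer_, 2), bondSince = rep(NA_integer_, 2),
    energy = numeric(2), step = 0L
  )
}
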