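#' Protein: a rigid all-atom structure
#'
#' Holds the parsed atomic structure of one protein type: the atom table,
#' the ordered C-alpha trace, and the geometric quantities every downstream
#' stage consumes (geometric center, bounding radius, voxel-estimated
#' molecular volume).
#'
#' @slot id short name (e.g. a PDB code)
#' @slot atoms data.frame with columns \code{resno}, \code{elety},
#'   \code{elem}, \code{x}, \code{y}, \code{z} (coordinates in Angstrom)
#' @slot calphas numeric matrix (nResidues x 3) of C-alpha coordinates in
#'   residue order
#' @slot center geometric center of all atoms (Angstrom)
#' @slot radius maximum center-to-atom distance (Angstrom); a bounding
#'   radius, so the neighbor rule can never exclude a genuine docking pose
#' @slot volume estimated molecular volume (Angstrom^3)
#' @slot nResidues number of residues with a C-alpha
#' @export
setClass("Protein",
  representation(
    id = "character",
    atoms = "data.frame",
    calphas = "matrix",
    center = "numeric",
    radius = "numeric",
    volume = "numeric",
    nResidues = "integer"
  )
)

setValidity("Protein", function(object) {
  msg <- character()
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) msg <- c(msg, "non-finite atom coordinates")
  if (!all(is.finite(object@calphas))) msg <- c(msg, "non-finite C-alpha coordinates")
  # radius 0 is allowed only for the degenerate single-atom case
  if (length(object@radius) != 1L || object@radius < 0 ||
      (object@radius == 0 && nrow(object@atoms) > 1L)) {
    msg <- c(msg, "radius must be a single positive number")
  }
  if (length(object@volume) != 1L || object@volume <= 0) {
    msg <- c(msg, "volume must be a single positive number")
  }
  if (object@nResidues != nrow(object@calphas)) {
    msg <- c(msg, "nResidues must equal the number of C-alpha rows")
  }
  ctr <- colMeans(xyz)
  if (max(abs(ctr - object@center)) > 1e-9) {
    msg <- c(msg, "stored center does not match the atom geometric center")
  }
  if (length(msg)) msg else TRUE
})

#' RotationSet: deterministic quasi-uniform covering of SO(3)
#'
#' @slot matrices 3 x 3 x N array of rotation matrices; index 1 is the
#'   identity
#' @slot quaternions N x 4 matrix of the corresponding unit quaternions
#' @slot spacing nominal nearest-neighbor angular spacing in degrees
#' @export
setClass("RotationSet",
  representation(
    matrices = "array",
    quaternions = "matrix",
    spacing = "numeric"
  )
)

setValidity("RotationSet", function(object) {
  msg <- character()
  d <- dim(object@matrices)
  if (length(d) != 3L || d[1] != 3L || d[2] != 3L) {
    msg <- c(msg, "matrices must be a 3 x 3 x N array")
  } else {
    if (max(abs(object@matrices[, , 1] - diag(3))) > 1e-9) {
      msg <- c(msg, "index 1 must be the identity rotation")
    }
    for (i in seq_len(min(d[3], 32L))) { # spot-check orthonormality
      R <- object@matrices[, , i]
      if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
        msg <- c(msg, sprintf("matrix %d is not a proper rotation", i))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScoreGrid: step-function docking grid
#'
#' Integer-valued 3D grid for one molecule at one orientation. Receptor
#' grids carry +1 on the one-cell surface layer and -rho in the core;
#' ligand grids carry +1 on every occupied cell. The grid is cubic,
#' centered on the molecule's geometric center with an odd cell count per
#' axis, so lattice-compatible 90-degree rotations permute cells exactly.
#'
#' @slot origin coordinate (Angstrom, relative to the molecule center) of
#'   the center of cell (1,1,1)
#' @slot step grid step in Angstrom
#' @slot values 3D numeric array of cell scores
#' @slot role "receptor" or "ligand"
#' @export
setClass("ScoreGrid",
  representation(
    origin = "numeric",
    step = "numeric",
    values = "array",
    role = "character"
  )
)

setValidity("ScoreGrid", function(object) {
  msg <- character()
  if (!object@role %in% c("receptor", "ligand")) {
    msg <- c(msg, "role must be 'receptor' or 'ligand'")
  }
  if (object@step <= 0) msg <- c(msg, "step must be positive")
  v <- object@values
  if (object@role == "ligand" && !all(v %in% c(0, 1))) {
    msg <- c(msg, "ligand grid values must be in {0, +1}")
  }
  if (length(msg)) msg else TRUE
})

#' PoseLibrary: ranked docking poses for every ordered type pair
#'
#' For each ordered (ligand type, receptor type) pair, the top-K
#' positive-score rigid docking poses found by FFT correlation, sorted by
#' descending score with ties broken by (rotation index, lexicographic
#' translation). Each pose row stores the rotation index into the shared
#' \linkS4class{RotationSet}, the integer grid translation, the score, the
#' energy (= -score), and the cached pair-frame center displacement in
#' Angstrom (\code{dx}, \code{dy}, \code{dz}).
#'
#' @slot pairs named list ("lig|rec") of pose data.frames with columns
#'   \code{rot}, \code{tx}, \code{ty}, \code{tz}, \code{score},
#'   \code{energy}, \code{dx}, \code{dy}, \code{dz}
#' @slot rotations the shared RotationSet
#' @slot step docking grid step in Angstrom
#' @slot params list: \code{rho} (core repulsion magnitude), \code{topK},
#'   \code{spacing} (degrees), \code{perRotationCap}
#' @export
setClass("PoseLibrary",
  representation(
    pairs = "list",
    rotations = "RotationSet",
    step = "numeric",
    params = "list"
  )
)

setValidity("PoseLibrary", function(object) {
  msg <- character()
  for (key in names(object@pairs)) {
    tab <- object@pairs[[key]]
    if (nrow(tab)) {
      if (any(tab$score <= 0)) msg <- c(msg, sprintf("pair %s: non-positive pose score", key))
      if (any(tab$energy >= 0)) msg <- c(msg, sprintf("pair %s: non-negative pose energy", key))
      if (is.unsorted(-tab$score)) msg <- c(msg, sprintf("pair %s: not sorted by descending score", key))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: all tunables of a Monte Carlo run
#'
#' @slot box cubic box edge in Angstrom (default 500)
#' @slot targetV target protein volume fraction
#' @slot temperature Metropolis temperature, a scaling factor in docking
#'   score units (default 100)
#' @slot steps number of simulation steps (every molecule attempts one
#'   move per step)
#' @slot neighborMargin added to the two bounding radii in the neighbor
#'   rule (Angstrom, default 50)
#' @slot collisionCutoff minimal allowed CA-CA distance (Angstrom, default
#'   8); 0 disables the collision check
#' @slot topK docking poses kept per ordered pair (default 30000)
#' @slot msdReferenceStep reference step for MSD (default 100), allowing
#'   off-the-grid relaxation first
#' @slot smoothWindow sliding-window width in steps for smoothed series
#'   (default 100)
#' @slot nsPerStep physical time per step in ns (calibrated; default 20)
#' @slot seed master RNG seed
#' @slot clusterEvery compute cluster statistics every this many steps
#' @slot recordEvery record an unwrapped-position snapshot every this many
#'   steps
#' @export
setClass("SimulationConfig",
  representation(
    box = "numeric",
    targetV = "numeric",
    temperature = "numeric",
    steps = "integer",
    neighborMargin = "numeric",
    collisionCutoff = "numeric",
    topK = "integer",
    msdReferenceStep = "integer",
    smoothWindow = "integer",
    nsPerStep = "numeric",
    seed = "integer",
    clusterEvery = "integer",
    recordEvery = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@box <= 0) msg <- c(msg, "box must be > 0")
  if (object@steps < 0) msg <- c(msg, "steps must be >= 0")
  if (object@neighborMargin <= 0) msg <- c(msg, "neighborMargin must be > 0")
  if (object@collisionCutoff < 0) msg <- c(msg, "collisionCutoff must be >= 0")
  if (object@nsPerStep <= 0) msg <- c(msg, "nsPerStep must be > 0")
  if (length(msg)) msg else TRUE
})

#' SystemState: the full periodic-box configuration
#'
#' Placement (rotation matrix, wrapped and unwrapped position) of every
#' molecule copy, the directed bond graph of current docking matches
#' (each copy owns at most one outgoing bond: the match it holds as the
#' ligand), and the per-molecule incremental energies.
#'
#' @slot box cubic box edge (Angstrom)
#' @slot typeIds integer type index per copy
#' @slot typeNameVec type names, indexed by typeIds
#' @slot proteins list of \linkS4class{Protein}, one per type
#' @slot rotations 3 x 3 x n array of per-copy rotation matrices
#' @slot pos n x 3 wrapped positions in [0, box)
#' @slot upos n x 3 unwrapped positions (for MSD)
#' @slot bondTo integer receptor copy id per copy (NA if none)
#' @slot bondEnergy energy of the outgoing match (0 if none)
#' @slot bondPose pose row index of the outgoing match (NA if none)
#' @slot bondSince step at which the current ligand-receptor pair was
#'   formed (NA if none)
#' @slot energy per-molecule energy: sum over all matches the molecule
#'   participates in (outgoing plus incoming)
#' @slot step step counter
#' @export
setClass("SystemState",
  representation(
    box = "numeric",
    typeIds = "integer",
    typeNameVec = "character",
    proteins = "list",
    rotations = "array",
    pos = "matrix",
    upos = "matrix",
    bondTo = "integer",
    bondEnergy = "numeric",
    bondPose = "integer",
    bondSince = "integer",
    energy = "numeric",
    step = "integer"
  )
)

setValidity("SystemState", function(object) {
  msg <- character()
  n <- length(object@typeIds)
  if (nrow(object@pos) != n || nrow(object@upos) != n) {
    msg <- c(msg, "pos/upos must have one row per copy")
  }
  if (n > 0) {
    if (any(object@pos < 0) || any(object@pos >= object@box)) {
      msg <- c(msg, "wrapped positions must lie in [0, box)")
    }
    shift <- (object@upos - object@pos) / object@box
    if (max(abs(shift - round(shift))) > 1e-6) {
      msg <- c(msg, "unwrapped - wrapped must be an integer multiple of box per axis")
    }
    if (any(object@energy > 1e-9)) msg <- c(msg, "molecule energies must be <= 0")
    ok <- !is.na(object@bondTo)
    if (any(object@bondTo[ok] == seq_len(n)[ok])) msg <- c(msg, "self-bonds are not allowed")
    # energy bookkeeping: sum of per-molecule energies = 2 x sum of bond energies
    if (abs(sum(object@energy) - 2 * sum(object@bondEnergy)) > 1e-6) {
      msg <- c(msg, "sum of molecule energies must equal twice the sum of bond energies")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ObservableSeries: per-step observables of one run
#'
#' @slot stats data.frame with one row per step: \code{step},
#'   \code{time_ns}, \code{meanEnergy}, \code{meanShift},
#'   \code{acceptanceRate}, \code{aggregationNumber},
#'   \code{aggregationNumberAll}, \code{monomerFraction}
#' @slot msd steps x types matrix of per-type MSD (Angstrom^2), NA before
#'   the reference step
#' @slot episodes data.frame of bond episodes: \code{ligand},
#'   \code{receptor}, \code{startStep}, \code{endStep}, \code{censored}
#' @slot meta list: msdReferenceStep, smoothWindow, nsPerStep,
#'   temperature, realizedV, box, seed
#' @export
setClass("ObservableSeries",
  representation(
    stats = "data.frame",
    msd = "matrix",
    episodes = "data.frame",
    meta = "list"
  )
)

setValidity("ObservableSeries", function(object) {
  msg <- character()
  ar <- object@stats$acceptanceRate
  if (length(ar) && (any(ar < 0) || any(ar > 1))) {
    msg <- c(msg, "acceptance rate must lie in [0, 1]")
  }
  m <- object@msd
  if (length(m) && any(m < -1e-12, na.rm = TRUE)) msg <- c(msg, "MSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimulationResult: final state, observable series and trajectory
#'
#' @slot finalState the \linkS4class{SystemState} after the last step
#' @slot series the \linkS4class{ObservableSeries}
#' @slot trajectory list: \code{steps} (recorded step numbers, 0 is the
#'   initial state), \code{upos} (nrec x n x 3 unwrapped positions),
#'   \code{typeIds}, \code{typeNames}, \code{box}, \code{nsPerStep}
#' @slot config the \linkS4class{SimulationConfig} used
#' @export
setClass("SimulationResult",
  representation(
    finalState = "SystemState",
    series = "ObservableSeries",
    trajectory = "list",
    config = "SimulationConfig"
  )
)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Protein", function(object) {
  cat(sprintf(
    "Protein '%s': %d residues, %d atoms\n  radius %.2f A, volume %.0f A^3, center (%.2f, %.2f, %.2f)\n",
    object@id, object@nResidues, nrow(object@atoms), object@radius,
    object@volume, object@center[1], object@center[2], object@center[3]
  ))
})

setMethod("show", "RotationSet", function(object) {
  cat(sprintf(
    "RotationSet: %d rotations, nominal spacing %.1f deg (identity at index 1)\n",
    dim(object@matrices)[3], object@spacing
  ))
})

setMethod("show", "PoseLibrary", function(object) {
  np <- vapply(object@pairs, nrow, integer(1))
  cat(sprintf(
    "PoseLibrary: %d ordered pairs, grid step %.2f A, rho %.1f, top-K %d\n",
    length(object@pairs), object@step, object@params$rho, object@params$topK
  ))
  if (length(np)) {
    cat(sprintf("  poses per pair: %s\n",
                paste(sprintf("%s=%d", names(np), np), collapse = ", ")))
  }
})

setMethod("show", "SystemState", function(object) {
  nb <- sum(!is.na(object@bondTo))
  cat(sprintf(
    "SystemState: %d copies of %d types in a %.0f A box (step %d)\n  %d docking bonds, total energy %.1f\n",
    length(object@typeIds), length(object@typeNameVec), object@box,
    object@step, nb, sum(object@bondEnergy)
  ))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: box %.0f A, V %.2f, T %.0f, %d steps, seed %d\n  neighbor margin %.0f A, collision cutoff %.1f A, %.0f ns/step\n",
    object@box, object@targetV, object@temperature, object@steps,
    object@seed, object@neighborMargin, object@collisionCutoff,
    object@nsPerStep
  ))
})

setMethod("show", "ObservableSeries", function(object) {
  cat(sprintf(
    "ObservableSeries: %d steps, %d types, MSD reference step %d\n",
    nrow(object@stats), ncol(object@msd), object@meta$msdReferenceStep
  ))
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult\n")
  show(object@finalState)
  show(object@series)
})

# ---- accessors -------------------------------------------------------------

#' @rdname DockMC-generics
#' @export
setMethod("proteinId", "Protein", function(x) x@id)
#' @rdname DockMC-generics
#' @export
setMethod("caTrace", "Protein", function(x) x@calphas)
#' @rdname DockMC-generics
#' @export
setMethod("geomCenter", "Protein", function(x) x@center)
#' @rdname DockMC-generics
#' @export
setMethod("boundingRadius", "Protein", function(x) x@radius)
#' @rdname DockMC-generics
#' @export
setMethod("molecularVolume", "Protein", function(x) x@volume)
#' @rdname DockMC-generics
#' @export
setMethod("nResidues", "Protein", function(x) x@nResidues)

#' @rdname DockMC-generics
#' @export
setMethod("rotationCount", "RotationSet", function(x) dim(x@matrices)[3])
#' @rdname DockMC-generics
#' @export
setMethod("rotationMatrix", "RotationSet", function(x, i) x@matrices[, , i])

#' @rdname DockMC-generics
#' @export
setMethod("pairKeys", "PoseLibrary", function(x) names(x@pairs))
#' @rdname DockMC-generics
#' @export
setMethod("poseTable", "PoseLibrary", function(x, ligType, recType) {
  key <- paste0(ligType, "|", recType)
  if (is.null(x@pairs[[key]])) stop("no pose table for pair ", key)
  x@pairs[[key]]
})
#' @rdname DockMC-generics
#' @export
setMethod("poseCount", "PoseLibrary", function(x, ...) {
  vapply(x@pairs, nrow, integer(1))
})

#' @rdname DockMC-generics
#' @export
setMethod("copyCount", "SystemState", function(x) length(x@typeIds))
#' @rdname DockMC-generics
#' @export
setMethod("boxSize", "SystemState", function(x) x@box)
#' @rdname DockMC-generics
#' @export
setMethod("positions", "SystemState", function(x) x@pos)
#' @rdname DockMC-generics
#' @export
setMethod("unwrappedPositions", "SystemState", function(x) x@upos)
#' @rdname DockMC-generics
#' @export
setMethod("typeNames", "SystemState", function(x) x@typeNameVec)
#' @rdname DockMC-generics
#' @export
setMethod("typeIds", "SystemState", function(x) x@typeIds)
#' @rdname DockMC-generics
#' @export
setMethod("moleculeEnergies", "SystemState", function(x) x@energy)

#' @describeIn DockMC-generics directed bond edges (ligand -> receptor)
#'   with pose index and energy, one row per current outgoing bond.
#' @export
setMethod("bondGraph", "SystemState", function(x) {
  ok <- which(!is.na(x@bondTo))
  data.frame(
    ligand = ok,
    receptor = x@bondTo[ok],
    pose = x@bondPose[ok],
    energy = x@bondEnergy[ok],
    since = x@bondSince[ok]
  )
})

#' @rdname DockMC-generics
#' @export
setMethod("seriesTable", "ObservableSeries", function(x) x@stats)
#' @rdname DockMC-generics
#' @export
setMethod("msdTable", "ObservableSeries", function(x) x@msd)
#' @rdname DockMC-generics
#' @export
setMethod("bondEpisodes", "ObservableSeries", function(x) x@episodes)

#' @rdname DockMC-generics
#' @export
setMethod("seriesTable", "SimulationResult", function(x) x@series@stats)
#' @rdname DockMC-generics
#' @export
setMethod("bondEpisodes", "SimulationResult", function(x) x@series@episodes)
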