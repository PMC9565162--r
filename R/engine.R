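#' Create a simulation configuration
#'
#' Defaults follow the standard operating point of the method: a 500 A
#' periodic box, temperature 100 (in docking score units, the melting
#' point of the systems studied), a 50 A neighbor margin, an 8 A CA-CA
#' collision cutoff, 30,000 poses per ordered pair, MSD reference at step
#' 100, 100-step smoothing, and 20 ns of physical time per step (the MD
#' calibration).
#'
#' @param box cubic box edge (Angstrom)
#' @param targetV target protein volume fraction
#' @param temperature Metropolis temperature (docking score units)
#' @param steps number of simulation steps
#' @param neighborMargin neighbor-rule margin (Angstrom)
#' @param collisionCutoff minimal CA-CA distance (Angstrom); 0 disables
#'   the collision check
#' @param topK poses kept per ordered pair
#' @param msdReferenceStep reference step for MSD
#' @param smoothWindow sliding window (steps) for smoothed series
#' @param nsPerStep physical ns per simulation step
#' @param seed master RNG seed
#' @param clusterEvery compute cluster statistics every this many steps
#' @param recordEvery record a trajectory snapshot every this many steps
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(box = 500, targetV = 0.3, temperature = 100,
                             steps = 1000, neighborMargin = 50,
                             collisionCutoff = 8, topK = 30000,
                             msdReferenceStep = 100, smoothWindow = 100,
                             nsPerStep = 20, seed = 1, clusterEvery = 1,
                             recordEvery = 1) {
  methods::new("SimulationConfig",
    box = box, targetV = targetV, temperature = temperature,
    steps = as.integer(steps), neighborMargin = neighborMargin,
    collisionCutoff = collisionCutoff, topK = as.integer(topK),
    msdReferenceStep = as.integer(msdReferenceStep),
    smoothWindow = as.integer(smoothWindow), nsPerStep = nsPerStep,
    seed = as.integer(seed), clusterEvery = as.integer(clusterEvery),
    recordEvery = as.integer(recordEvery)
  )
}

#' Metropolis acceptance probability with detailed balance
#'
#' The normalized Metropolis criterion
#' \deqn{P_{ij} = \min\{1,\ \exp[-(E_j - E_i)/T] \times N_i/N_j\},}
#' where \eqn{N_m} is the number of possible moves (receptors to move to)
#' from state \eqn{m}. The \eqn{N_i/N_j} factor restores detailed balance
#' when the move count differs between the two states.
#'
#' @param Ei,Ej state energies before and after the move (docking score
#'   units)
#' @param temperature temperature T (a scaling factor), > 0
#' @param Ni,Nj move counts in states i and j, both >= 1
#' @return acceptance probability in [0, 1]
#' @examples
#' acceptanceProbability(0, 100, temperature = 100, Ni = 4, Nj = 2)
#' @export
acceptanceProbability <- function(Ei, Ej, temperature, Ni, Nj) {
  stopifnot(temperature > 0)
  if (any(Nj < 1)) stop("invalid proposal: N_j must be >= 1 for detailed balance")
  if (any(Ni < 1)) stop("N_i must be >= 1")
  pmin(1, exp(-(Ej - Ei) / temperature) * Ni / Nj)
}

#' Propose a docking move for one molecule
#'
#' Selects a receptor uniformly among the ligand's neighbors and a pose
#' uniformly among the stored poses for that (ligand type, receptor type)
#' pair, and evaluates the move-count normalization: \code{Ni} is the
#' ligand's neighbor count before the move, \code{Nj} its neighbor count
#' after placement at the proposed pose. Returns NULL when the ligand has
#' no neighbors or the pair's pose list is empty; such attempts count as
#' rejected.
#'
#' @param state a \linkS4class{SystemState}
#' @param ligand copy id of the molecule attempting the move
#' @param library a \linkS4class{PoseLibrary}
#' @param neighborMargin neighbor-rule margin (Angstrom)
#' @return a \code{MoveProposal} (list with ligand, receptor, poseIndex,
#'   poseEnergy, Ei, Ej, Ni, Nj, newRot, newPosW) or NULL
#' @export
proposeMove <- function(state, ligand, library, neighborMargin = 50) {
  E <- .stateEnv(state, library, margin = neighborMargin)
  prop <- .corePropose(E, ligand)
  if (is.null(prop)) return(NULL)
  Ei <- sum(state@bondEnergy)
  prop$Ei <- Ei
  prop$Ej <- Ei + prop$dE
  class(prop) <- "MoveProposal"
  prop
}

#' @export
print.MoveProposal <- function(x, ...) {
  cat(sprintf(
    "MoveProposal: ligand %d -> receptor %d (pose %d, energy %.2f)\n  dE = %.2f, Ni = %d, Nj = %d\n",
    x$ligand, x$receptor, x$poseIndex, x$poseEnergy, x$dE, x$Ni, x$Nj
  ))
  invisible(x)
}

#' Collision check for a proposed move
#'
#' Rejects a move iff any C-alpha of the moved ligand lies within the
#' cutoff (minimum image) of any C-alpha of any other copy except the new
#' receptor: a genuine docking interface at grid resolution can have
#' cross-interface CA pairs below the cutoff, and the pose itself defines
#' the sanctioned contact.
#'
#' @param state a \linkS4class{SystemState}
#' @param proposal a \code{MoveProposal}
#' @param cutoff minimal CA-CA distance in Angstrom (default 8)
#' @return TRUE if the move collides (must be rejected), FALSE otherwise
#' @export
collisionCheck <- function(state, proposal, cutoff = 8) {
  stopifnot(!is.null(proposal))
  E <- .stateEnv(state, NULL, collisionCutoff = cutoff)
  .coreCollides(E, proposal)
}

#' Apply an accepted move
#'
#' Replaces the ligand's outgoing bond, updates the ligand, old-receptor
#' and new-receptor energies incrementally, and sets the ligand placement
#' from the pose (wrapped and unwrapped positions kept consistent).
#' Incoming bonds to the ligand are not altered. The incremental energies
#' are verified against a full bond-graph recomputation.
#'
#' @param state a \linkS4class{SystemState}
#' @param proposal an accepted \code{MoveProposal}
#' @return the updated \linkS4class{SystemState}
#' @export
applyMove <- function(state, proposal) {
  stopifnot(!is.null(proposal))
  E <- .stateEnv(state, NULL)
  .coreApply(E, proposal)
  out <- .envToState(E)
  if (max(abs(recomputeEnergies(out) - out@energy)) > 1e-9) {
    stop("internal consistency error: incremental energies diverged from the bond graph")
  }
  out
}

#' Recompute molecule energies from the bond graph
#'
#' Each docking match contributes its (negative) energy to both partners.
#'
#' @param state a \linkS4class{SystemState}
#' @return numeric vector of per-molecule energies
#' @export
recomputeEnergies <- function(state) {
  n <- copyCount(state)
  e <- numeric(n)
  ok <- which(!is.na(state@bondTo))
  if (length(ok)) {
    e[ok] <- e[ok] + state@bondEnergy[ok]
    recSum <- tapply(state@bondEnergy[ok], state@bondTo[ok], sum)
    ridx <- as.integer(names(recSum))
    e[ridx] <- e[ridx] + as.numeric(recSum)
  }
  e
}

#' Run one simulation step
#'
#' Every molecule attempts exactly one move, in a fresh random
#' permutation. Consumes the global RNG stream; seed it for
#' reproducibility.
#'
#' @param state a \linkS4class{SystemState}
#' @param library a \linkS4class{PoseLibrary}
#' @param config a \linkS4class{SimulationConfig} (temperature, margins,
#'   cutoffs are taken from it)
#' @return list: \code{state} (updated), \code{attempts}, \code{accepted},
#'   \code{acceptanceRate}, \code{meanShift}, \code{meanEnergy}
#' @export
runStep <- function(state, library, config) {
  E <- .stateEnv(state, library, margin = config@neighborMargin,
                 collisionCutoff = config@collisionCutoff,
                 temperature = config@temperature)
  res <- .coreStep(E)
  list(
    state = .envToState(E),
    attempts = E$n,
    accepted = as.integer(res[1]),
    acceptanceRate = res[1] / E$n,
    meanShift = res[2] / E$n,
    meanSquaredShift = res[3] / E$n,
    meanEnergy = mean(E$energy)
  )
}

#' Run a minima-hopping Monte Carlo simulation
#'
#' Propagates the system for \code{config@steps} steps, streaming the
#' per-step observables (mean molecule energy, mean shift, acceptance
#' rate, per-type MSD from the reference step, cluster statistics) and
#' recording unwrapped-position snapshots. Fully reproducible under a
#' fixed \code{config@seed}; the caller's RNG state is left untouched.
#'
#' @param state the initial \linkS4class{SystemState}
#' @param library a \linkS4class{PoseLibrary}
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{SimulationResult}
#' @export
runSimulation <- function(state, library, config) {
  steps <- config@steps
  ref <- config@msdReferenceStep
  if (steps > 0 && steps <= ref) {
    warning("steps <= msdReferenceStep; using the initial state as MSD reference")
    ref <- 0L
  }
  nt <- length(state@proteins)
  n <- copyCount(state)
  typeOf <- lapply(seq_len(nt), function(t) which(state@typeIds == t))
  vMeanE <- rep(NA_real_, steps)
  vShift <- rep(NA_real_, steps)
  vShift2 <- rep(NA_real_, steps)
  vAcc <- rep(NA_real_, steps)
  vNc <- rep(NA_real_, steps)
  vNcAll <- rep(NA_real_, steps)
  vMono <- rep(NA_real_, steps)
  msd <- matrix(NA_real_, steps, nt,
                dimnames = list(NULL, state@typeNameVec))
  recSteps <- unique(c(0L, seq_len(steps)[seq_len(steps) %% config@recordEvery == 0L], steps))
  recSteps <- sort(recSteps[recSteps <= steps])
  recMask <- logical(max(steps, 1L))
  recMask[recSteps[recSteps >= 1L]] <- TRUE
  uposRec <- array(NA_real_, c(length(recSteps), n, 3))
  bondToRec <- matrix(NA_integer_, length(recSteps), n)
  bondPoseRec <- matrix(NA_integer_, length(recSteps), n)
  E <- .stateEnv(state, library, margin = config@neighborMargin,
                 collisionCutoff = config@collisionCutoff,
                 temperature = config@temperature)
  .withSeed(.deriveSeed(config@seed, 1L), {
    reci <- 1L
    uposRec[reci, , ] <- E$upos
    bondToRec[reci, ] <- E$bondTo
    bondPoseRec[reci, ] <- E$bondPose
    refU <- if (ref == 0L) E$upos else NULL
    for (t in seq_len(steps)) {
      res <- .coreStep(E)
      vMeanE[t] <- mean(E$energy)
      vShift[t] <- res[2] / n
      vShift2[t] <- res[3] / n
      vAcc[t] <- res[1] / n
      if (t == ref) refU <- E$upos
      if (!is.null(refU) && t >= ref) {
        dd <- E$upos - refU
        dsq <- rowSums(dd * dd)
        for (ty in seq_len(nt)) msd[t, ty] <- mean(dsq[typeOf[[ty]]])
      }
      if (t %% config@clusterEvery == 0L) {
        cl <- .clusterSummary(E$bondTo, n)
        vNc[t] <- cl$Nc
        vNcAll[t] <- cl$NcAll
        vMono[t] <- cl$monomerFraction
      }
      if (recMask[t]) {
        reci <- reci + 1L
        uposRec[reci, , ] <- E$upos
        bondToRec[reci, ] <- E$bondTo
        bondPoseRec[reci, ] <- E$bondPose
      }
    }
  })
  stats <- data.frame(
    step = seq_len(steps), time_ns = seq_len(steps) * config@nsPerStep,
    meanEnergy = vMeanE, meanShift = vShift, meanSquaredShift = vShift2,
    acceptanceRate = vAcc,
    aggregationNumber = vNc, aggregationNumberAll = vNcAll,
    monomerFraction = vMono
  )
  series <- methods::new("ObservableSeries",
    stats = stats, msd = msd,
    episodes = .coreEpisodes(E, censorAt = steps),
    meta = list(
      msdReferenceStep = ref, smoothWindow = config@smoothWindow,
      nsPerStep = config@nsPerStep, temperature = config@temperature,
      box = config@box, seed = config@seed, targetV = config@targetV,
      typeNames = state@typeNameVec
    )
  )
  methods::new("SimulationResult",
    finalState = .envToState(E), series = series,
    trajectory = list(
      steps = recSteps, upos = uposRec, bondTo = bondToRec,
      bondPose = bondPoseRec, typeIds = state@typeIds,
      typeNames = state@typeNameVec, box = state@box,
      nsPerStep = config@nsPerStep, msdReferenceStep = ref
    ),
    config = config
  )
}
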