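# Internal mutable engine core.
#
# The public S4 API (engine.R) is functional: it converts a SystemState to
# this environment representation, runs the single shared core routines,
# and converts back. runSimulation() keeps one environment alive across all
# steps. There is exactly one implementation of the move logic; the
# wrappers only marshal data.

# Build the mutable engine environment from a state (+ optional library).
.stateEnv <- function(state, library = NULL, margin = 50, collisionCutoff = 8,
                      temperature = 100) {
  E <- new.env(parent = baseenv())  # closures bound to E need base ops
  n <- copyCount(state)
  E$n <- n
  E$box <- state@box
  E$margin <- margin
  E$colCut <- collisionCutoff
  E$temp <- temperature
  E$typeId <- state@typeIds
  E$typeNames <- state@typeNameVec
  E$proteins <- state@proteins
  E$px <- state@pos[, 1]
  E$py <- state@pos[, 2]
  E$pz <- state@pos[, 3]
  E$upos <- state@upos
  E$rotList <- lapply(seq_len(n), function(i) state@rotations[, , i])
  E$caLocal <- lapply(state@proteins, function(p) sweep(p@calphas, 2, p@center))
  E$caRel <- lapply(seq_len(n), function(i) {
    E$caLocal[[E$typeId[i]]] %*% t(E$rotList[[i]])
  })
  rByType <- vapply(state@proteins, boundingRadius, numeric(1))
  E$radii <- rByType[E$typeId]
  nt <- length(state@proteins)
  # per-ligand-type squared cutoffs against every copy (neighbor rule
  # and collision prefilter), pre-split to avoid row extraction
  E$cut2ByType <- lapply(seq_len(nt), function(t) (rByType[t] + E$radii + margin)^2)
  E$pre2ByType <- lapply(seq_len(nt), function(t) (rByType[t] + E$radii + collisionCutoff)^2)
  E$bondTo <- state@bondTo
  E$bondE <- state@bondEnergy
  E$bondPose <- state@bondPose
  E$bondSince <- state@bondSince
  E$energy <- state@energy
  E$step <- state@step
  # episode log (grown by doubling); the logger and the move applier are
  # closures whose enclosing environment is E itself: their `<<-` writes
  # modify E's vectors in place, which keeps the hot loop allocation-free
  E$epN <- 0L
  E$epL <- integer(1024)
  E$epR <- integer(1024)
  E$epS <- integer(1024)
  E$epE <- integer(1024)
  E$logFn <- .makeLogFn()
  environment(E$logFn) <- E
  E$applyFn <- .makeApplyFn()
  environment(E$applyFn) <- E
  if (!is.null(library)) {
    E$rotMats <- lapply(seq_len(rotationCount(library@rotations)),
                        function(i) library@rotations@matrices[, , i])
    E$P <- vector("list", nt)
    for (lt in seq_len(nt)) {
      E$P[[lt]] <- vector("list", nt)
      for (rt in seq_len(nt)) {
        key <- paste0(E$typeNames[lt], "|", E$typeNames[rt])
        tab <- library@pairs[[key]]
        if (is.null(tab)) {
          # absent pair: treated as an empty pose list (proposals rejected)
          E$P[[lt]][[rt]] <- list(m = 0L, energy = numeric(0),
                                  rotIdx = integer(0),
                                  D = matrix(0, 0, 3))
          next
        }
        E$P[[lt]][[rt]] <- list(
          m = nrow(tab), energy = tab$energy, rotIdx = tab$rot,
          D = unname(as.matrix(tab[, c("dx", "dy", "dz")]))
        )
      }
    }
    E$warnedEmpty <- matrix(FALSE, nt, nt)
    # a type with no poses in any of its ligand pairs can never move;
    # its attempts are guaranteed-null and skipped without the search
    E$mobileType <- vapply(seq_len(nt), function(lt) {
      any(vapply(E$P[[lt]], function(pp) pp$m > 0L, logical(1)))
    }, logical(1))
  }
  E
}

# Convert the environment back to an immutable SystemState.
.envToState <- function(E) {
  n <- E$n
  rots <- array(0, c(3, 3, n))
  for (i in seq_len(n)) rots[, , i] <- E$rotList[[i]]
  methods::new("SystemState",
    box = E$box, typeIds = E$typeId, typeNameVec = E$typeNames,
    proteins = E$proteins, rotations = rots,
    pos = cbind(E$px, E$py, E$pz, deparse.level = 0), upos = E$upos,
    bondTo = E$bondTo, bondEnergy = E$bondE, bondPose = E$bondPose,
    bondSince = E$bondSince, energy = E$energy, step = as.integer(E$step)
  )
}

# squared minimum-image center distances from `at` to every copy
.coreDist2 <- function(E, at) {
  b <- E$box
  d1 <- E$px - at[1]; d1 <- d1 - b * round(d1 / b)
  d2 <- E$py - at[2]; d2 <- d2 - b * round(d2 / b)
  d3 <- E$pz - at[3]; d3 <- d3 - b * round(d3 / b)
  d1 * d1 + d2 * d2 + d3 * d3
}

# Neighbor ids of copy i were it centered at `at` (wrapped or not).
.coreNeighborIds <- function(E, i, at) {
  d2 <- .coreDist2(E, at)
  out <- which(d2 < E$cut2ByType[[E$typeId[i]]])
  out[out != i]
}

# Propose a move for ligand l. Returns NULL when the ligand has no
# neighbors or the pair's pose list is empty (the attempt counts as
# rejected). Consumes RNG draws: receptor choice, pose choice.
.corePropose <- function(E, l) {
  nbs <- .coreNeighborIds(E, l, c(E$px[l], E$py[l], E$pz[l]))
  Ni <- length(nbs)
  if (Ni == 0L) return(NULL)
  r <- nbs[sample.int(Ni, 1L)]
  pp <- E$P[[E$typeId[l]]][[E$typeId[r]]]
  if (pp$m == 0L) {
    if (!E$warnedEmpty[E$typeId[l], E$typeId[r]]) {
      warning("empty pose list for pair ", E$typeNames[E$typeId[l]], "|",
              E$typeNames[E$typeId[r]], "; proposals involving it are rejected")
      E$warnedEmpty[E$typeId[l], E$typeId[r]] <- TRUE
    }
    return(NULL)
  }
  k <- sample.int(pp$m, 1L)
  Rr <- E$rotList[[r]]
  newPos <- c(E$px[r], E$py[r], E$pz[r]) + as.numeric(Rr %*% pp$D[k, ])
  newPosW <- newPos %% E$box
  newRot <- Rr %*% E$rotMats[[pp$rotIdx[k]]]
  d2 <- .coreDist2(E, newPosW)
  inr <- d2 < E$cut2ByType[[E$typeId[l]]]
  Nj <- sum(inr) - (inr[l])
  list(
    ligand = l, receptor = r, poseIndex = k, poseEnergy = pp$energy[k],
    dE = pp$energy[k] - E$bondE[l], Ni = Ni, Nj = Nj,
    newRot = newRot, newPosW = newPosW
  )
}

# TRUE if the moved ligand's CA trace comes within colCut (minimum image)
# of any other copy's CA trace, the new receptor excepted.
.coreCollides <- function(E, prop) {
  l <- prop$ligand
  at <- prop$newPosW
  d2 <- .coreDist2(E, at)
  cand <- which(d2 < E$pre2ByType[[E$typeId[l]]])
  cand <- cand[cand != l & cand != prop$receptor]
  if (!length(cand)) return(FALSE)
  A <- E$caLocal[[E$typeId[l]]] %*% t(prop$newRot)
  A <- A + matrix(at, nrow(A), 3, byrow = TRUE)
  a2 <- rowSums(A * A)
  cut2 <- E$colCut^2
  for (c2 in cand) {
    # image of copy c2 nearest the proposed ligand position
    p2 <- c(E$px[c2], E$py[c2], E$pz[c2])
    cpos <- p2 - E$box * round((p2 - at) / E$box)
    B <- E$caRel[[c2]] + matrix(cpos, nrow(E$caRel[[c2]]), 3, byrow = TRUE)
    b2 <- rowSums(B * B)
    cr <- A %*% t(B)
    if (min(outer(a2, b2, "+") - 2 * cr) < cut2) return(TRUE)
  }
  FALSE
}

# Metropolis acceptance with the variable-move-count normalization,
# computed on the log scale to avoid overflow on deep downhill moves.
.coreAcceptProb <- function(dE, temp, Ni, Nj) {
  if (Nj < 1L) stop("invalid proposal: no reverse moves (N_j = 0)")
  lp <- -dE / temp + log(Ni) - log(Nj)
  if (lp >= 0) 1 else exp(lp)
}

# Apply an accepted proposal: rebond, incremental energies, placement.
# Returns the squared displacement length (for the shift statistics).
.coreApply <- function(E, prop) {
  E$applyFn(prop)
}

.makeLogFn <- function() {
  function(l, r, from, to) {
    epN <<- epN + 1L
    if (epN > length(epL)) {
      epL <<- c(epL, integer(length(epL)))
      epR <<- c(epR, integer(length(epR)))
      epS <<- c(epS, integer(length(epS)))
      epE <<- c(epE, integer(length(epE)))
    }
    epL[epN] <<- l
    epR[epN] <<- r
    epS[epN] <<- from
    epE[epN] <<- to
    invisible(NULL)
  }
}

.makeApplyFn <- function() {
  function(prop) {
    l <- prop$ligand
    r <- prop$receptor
    oldR <- bondTo[l]
    oldE <- bondE[l]
    if (!is.na(oldR)) {
      energy[l] <<- energy[l] - oldE
      energy[oldR] <<- energy[oldR] - oldE
      if (oldR != r) {
        logFn(l, oldR, bondSince[l], step)
        bondSince[l] <<- as.integer(step)
      }
    } else {
      bondSince[l] <<- as.integer(step)
    }
    energy[l] <<- energy[l] + prop$poseEnergy
    energy[r] <<- energy[r] + prop$poseEnergy
    bondTo[l] <<- as.integer(r)
    bondE[l] <<- prop$poseEnergy
    bondPose[l] <<- as.integer(prop$poseIndex)
    disp <- prop$newPosW - c(px[l], py[l], pz[l])
    disp <- disp - box * round(disp / box)
    upos[l, ] <<- upos[l, ] + disp
    px[l] <<- prop$newPosW[1]
    py[l] <<- prop$newPosW[2]
    pz[l] <<- prop$newPosW[3]
    rotList[[l]] <<- prop$newRot
    caRel[[l]] <<- caLocal[[typeId[l]]] %*% t(prop$newRot)
    sum(disp * disp)  # squared hop length
  }
}

# One simulation step: every molecule attempts exactly one move, in a
# fresh random permutation. Null proposals and collisions count as
# rejected attempts. Returns c(accepted, shiftSum, squaredShiftSum).
.coreStep <- function(E) {
  E$step <- E$step + 1L
  acc <- 0L
  shiftSum <- 0
  shift2Sum <- 0
  for (l in sample.int(E$n)) {
    if (!E$mobileType[E$typeId[l]]) next  # guaranteed-null attempt
    prop <- .corePropose(E, l)
    if (is.null(prop)) next
    if (prop$Nj < 1L) next  # no reverse move: detailed balance demands rejection
    if (E$colCut > 0 && .coreCollides(E, prop)) next
    p <- .coreAcceptProb(prop$dE, E$temp, prop$Ni, prop$Nj)
    if (p >= 1 || stats::runif(1) < p) {
      d2 <- .coreApply(E, prop)
      shiftSum <- shiftSum + sqrt(d2)
      shift2Sum <- shift2Sum + d2
      acc <- acc + 1L
    }
  }
  c(acc, shiftSum, shift2Sum)
}

# Completed episodes as a data.frame; open bonds appended as censored rows.
.coreEpisodes <- function(E, censorAt = NULL) {
  idx <- seq_len(E$epN)
  out <- data.frame(
    ligand = E$epL[idx], receptor = E$epR[idx],
    startStep = E$epS[idx], endStep = E$epE[idx],
    censored = rep(FALSE, E$epN)
  )
  if (!is.null(censorAt)) {
    open <- which(!is.na(E$bondTo))
    if (length(open)) {
      out <- rbind(out, data.frame(
        ligand = open, receptor = E$bondTo[open],
        startStep = E$bondSince[open], endStep = NA_integer_,
        censored = TRUE
      ))
    }
  }
  out
}

# Cluster summary of the current (undirected) bond graph.
.clusterSummary <- function(bondTo, n) {
  ok <- which(!is.na(bondTo))
  if (!length(ok)) {
    return(list(Nc = 1, NcAll = 1, monomerFraction = 1,
                sizes = rep(1L, n), degenerate = TRUE))
  }
  g <- igraph::graph_from_edgelist(cbind(ok, bondTo[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  cs <- as.integer(igraph::components(g)$csize)
  agg <- cs[cs >= 2]
  list(
    Nc = if (length(agg)) mean(agg) else 1,
    NcAll = mean(cs),
    monomerFraction = sum(cs == 1) / n,
    sizes = cs,
    degenerate = length(agg) == 0
  )
}
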