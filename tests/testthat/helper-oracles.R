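# Shared fixtures and independent oracles used across the test files.

# Brute-force linear correlation oracle: scatter-add over occupied ligand
# cells, independent of the FFT path. Returns an array laid out like
# correlate(): tau ascending from -(dimL-1) per axis.
bruteCorrelate <- function(rv, lv) {
  dR <- dim(rv)
  dL <- dim(lv)
  P <- dR + dL - 1L
  out <- array(0, P)
  nz <- which(lv != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    c3 <- nz[r, ]
    w <- lv[c3[1], c3[2], c3[3]]
    # receptor cell x contributes to tau = x - c; tau index = x - c + dL
    out[seq_len(dR[1]) - c3[1] + dL[1],
        seq_len(dR[2]) - c3[2] + dL[2],
        seq_len(dR[3]) - c3[3] + dL[3]] <-
      out[seq_len(dR[1]) - c3[1] + dL[1],
          seq_len(dR[2]) - c3[2] + dL[2],
          seq_len(dR[3]) - c3[3] + dL[3], drop = FALSE] + w * rv
  }
  out
}

# random small integer score grids (receptor-like values {0, 1, -9})
randomGrid <- function(dims, role = "receptor", seed = 1) {
  set.seed(seed)
  vals <- sample(c(0, 0, 1, -9), prod(dims), replace = TRUE)
  if (role == "ligand") vals <- abs(sign(vals))
  methods::new("ScoreGrid", origin = rep(0, 3), step = 1,
               values = array(vals, dims), role = role)
}

# hand-built Protein with a single pseudo-atom
singleAtomProtein <- function(id = "pt", at = c(0, 0, 0), elem = "C") {
  newProtein(id, data.frame(resno = 1L, elety = "CA", elem = elem,
                            x = at[1], y = at[2], z = at[3]))
}

# a three-residue PDB text fixture crafted to the parser contract
threeResiduePDB <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   2       4.214   2.680   0.000  1.00  0.00           C",
    "ATOM      6  C   ALA A   2       5.680   2.280   0.000  1.00  0.00           C",
    "ATOM      7  N   ALA A   3       6.531   3.300   0.000  1.00  0.00           N",
    "ATOM      8  CA  ALA A   3       7.960   3.060   0.000  1.00  0.00           C",
    "ATOM      9  C   ALA A   3       8.770   4.360   0.000  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# state with n randomly placed copies of one tiny protein type
randomTinyState <- function(n, box, seed = 1) {
  p <- DockMC:::.tinyProtein("A")
  set.seed(seed)
  pos <- matrix(runif(n * 3, 0, box), n, 3)
  rots <- array(0, c(3, 3, n))
  for (i in seq_len(n)) rots[, , i] <- DockMC:::.randomRotation()
  methods::new("SystemState",
    box = box, typeIds = rep(1L, n), typeNameVec = "A",
    proteins = list(p), rotations = rots, pos = pos, upos = pos,
    bondTo = rep(NA_integer_, n), bondEnergy = numeric(n),
    bondPose = rep(NA_integer_, n), bondSince = rep(NA_integer_, n),
    energy = numeric(n), step = 0L
  )
}

# minimal hand-built ObservableSeries with constant per-step values
constantSeries <- function(value, steps = 300, acceptance = 0.5) {
  stats <- data.frame(
    step = seq_len(steps), time_ns = seq_len(steps) * 20,
    meanEnergy = -value, meanShift = value, meanSquaredShift = value^2,
    acceptanceRate = acceptance, aggregationNumber = 1,
    aggregationNumberAll = 1, monomerFraction = 1
  )
  methods::new("ObservableSeries",
    stats = stats, msd = matrix(value, steps, 1, dimnames = list(NULL, "A")),
    episodes = data.frame(ligand = integer(), receptor = integer(),
                          startStep = integer(), endStep = integer(),
                          censored = logical()),
    meta = list(msdReferenceStep = 0L, smoothWindow = 100L, nsPerStep = 20,
                temperature = NA_real_, box = NA_real_, seed = 1L)
  )
}

# uniform random unit quaternions (w >= 0 not enforced; coverage uses |dot|)
randomQuaternions <- function(m, seed = 1) {
  set.seed(seed)
  u <- matrix(runif(m * 3), m, 3)
  cbind(
    sqrt(1 - u[, 1]) * sin(2 * pi * u[, 2]),
    sqrt(1 - u[, 1]) * cos(2 * pi * u[, 2]),
    sqrt(u[, 1]) * sin(2 * pi * u[, 3]),
    sqrt(u[, 1]) * cos(2 * pi * u[, 3])
  )
}
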