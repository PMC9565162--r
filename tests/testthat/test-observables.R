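mkTraj <- function(upos, steps = NULL, typeIds = NULL, nsPerStep = 1) {
  nrec <- dim(upos)[1]
  n <- dim(upos)[2]
  list(
    steps = if (is.null(steps)) seq_len(nrec) - 1L else steps,
    upos = upos,
    typeIds = if (is.null(typeIds)) rep(1L, n) else typeIds,
    typeNames = "A", box = 1000, nsPerStep = nsPerStep,
    msdReferenceStep = 0L
  )
}

test_that("MSD is zero for a static trajectory and exact for ballistic drift", {
  upos <- array(0, c(51, 4, 3))
  tr <- mkTraj(upos)
  ms <- msdSeries(tr, referenceStep = 10)
  expect_true(all(ms$msd == 0))
  # drift v per step: MSD(t) = |v|^2 (t - ref)^2 exactly
  v <- c(1.5, -2, 0.5)
  for (k in 1:51) upos[k, , ] <- matrix(v * (k - 1), 4, 3, byrow = TRUE)
  ms2 <- msdSeries(mkTraj(upos), referenceStep = 10)
  expect_equal(ms2$msd, sum(v^2) * ms2$lag^2, tolerance = 1e-12)
})

test_that("MSD recovers the closed-form slope of an ideal lattice walk", {
  set.seed(71)
  nW <- 10000
  steps <- 60
  L <- 4
  hops <- array(0, c(steps + 1, nW, 3))
  for (k in 2:(steps + 1)) {
    ax <- sample(3, nW, replace = TRUE)
    sgn <- sample(c(-1, 1), nW, replace = TRUE)
    hop <- matrix(0, nW, 3)
    hop[cbind(seq_len(nW), ax)] <- sgn * L
    hops[k, , ] <- hops[k - 1, , ] + hop
  }
  ms <- msdSeries(mkTraj(hops), referenceStep = 0)
  fit <- diffusionCoefficient(ms, nsPerStep = 1, window = c(0.1, 0.9))
  expect_equal(fit$slope, L^2, tolerance = 0.05)
})

test_that("MSD is invariant to box wrapping given image counts", {
  sc <- buildToyScenario("uniform_walk", n = 15)
  cfg <- sc$config
  cfg@steps <- 300L
  cfg@recordEvery <- 1L
  res <- suppressWarnings(runSimulation(sc$state, sc$library, cfg))
  tr <- res@trajectory
  box <- tr$box
  wrapped <- tr$upos %% box
  images <- round((tr$upos - wrapped) / box)
  rebuilt <- tr$upos
  rebuilt[] <- wrapped + box * images
  tr2 <- tr
  tr2$upos <- rebuilt
  m1 <- msdSeries(tr, type = "W", referenceStep = 100)
  m2 <- msdSeries(tr2, type = "W", referenceStep = 100)
  expect_identical(m1$msd, m2$msd)
})

test_that("the Einstein relation is applied by definition", {
  lag <- 1:100
  ms <- data.frame(step = lag, lag = lag, msd = 6 * lag)
  expect_equal(diffusionCoefficient(ms, nsPerStep = 1)$D, 1, tolerance = 1e-12)
  ms2 <- data.frame(step = lag, lag = lag, msd = 3 * lag)
  expect_equal(diffusionCoefficient(ms2, nsPerStep = 1)$D, 0.5, tolerance = 1e-12)
  # ns conversion: 20 ns/step divides the per-step slope
  expect_equal(diffusionCoefficient(ms, nsPerStep = 20)$D, 1 / 20,
               tolerance = 1e-12)
})

test_that("a noisy linear MSD recovers its slope within the fit error", {
  set.seed(73)
  lag <- 1:500
  truth <- 2.4
  reps <- sapply(1:20, function(r) {
    ms <- data.frame(step = lag, lag = lag,
                     msd = truth * lag * exp(rnorm(500, 0, 0.05)))
    diffusionCoefficient(ms, nsPerStep = 1)$slope
  })
  expect_lt(abs(median(reps) - truth) / truth, 0.02)
})

test_that("saturated MSD is flagged as a poor fit", {
  lag <- 1:200
  ms <- data.frame(step = lag, lag = lag, msd = 100 * (1 - exp(-lag / 5)))
  expect_warning(fit <- diffusionCoefficient(ms, nsPerStep = 1), "sub-linear")
  expect_false(fit$ok)
})

test_that("time calibration divides out the reference correction factor", {
  expect_equal(calibrateTime(1.1666667, 3.5), 1, tolerance = 1e-6)
  expect_equal(calibrateTime(2 * 3.5 / 3, 3.5), 2, tolerance = 1e-12)
  # linearity in the simulated diffusion rate
  expect_equal(calibrateTime(10, 5, correction = 1), 2, tolerance = 1e-12)
})

test_that("Cohen-Turnbull parameters are recovered exactly from noise-free data", {
  V <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  D <- 4.9 * exp(-7.7 * V / (1 - V))
  fit <- cohenTurnbullFit(V, D)
  expect_equal(fit$D0, 4.9, tolerance = 1e-6)
  expect_equal(fit$gamma, 7.7, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # the log-linear route agrees with the nonlinear one
  expect_equal(unname(fit$linear["D0"]), fit$D0, tolerance = 1e-6)
  expect_equal(unname(fit$linear["gamma"]), fit$gamma, tolerance = 1e-6)
})

test_that("a zero slowdown constant gives a flat Cohen-Turnbull curve", {
  V <- c(0.1, 0.2, 0.3)
  D <- rep(3.2, 3)
  fit <- cohenTurnbullFit(V, D)
  expect_equal(fit$gamma, 0, tolerance = 1e-9)
  expect_equal(fit$D0, 3.2, tolerance = 1e-9)
})

test_that("Cohen-Turnbull fitting tolerates multiplicative noise", {
  set.seed(79)
  V <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  gammas <- sapply(1:20, function(r) {
    D <- 4.9 * exp(-7.7 * V / (1 - V)) * exp(rnorm(5, 0, 0.05))
    cohenTurnbullFit(V, D)$gamma
  })
  expect_lt(abs(median(gammas) - 7.7) / 7.7, 0.10)
  expect_error(cohenTurnbullFit(V, c(1, 2, -3, 4, 5)), "positive")
})

test_that("cluster statistics follow the bond graph exactly", {
  st <- randomTinyState(6, box = 200, seed = 83)
  cl0 <- clusterStats(st)
  expect_identical(cl0$monomerFraction, 1)
  expect_identical(cl0$Nc, 1)
  expect_true(cl0$degenerate)
  # a chain of 4 plus 2 monomers: Nc = 4, monomer fraction 1/3
  st@bondTo <- c(2L, 3L, 4L, NA, NA, NA)
  st@bondEnergy <- c(-10, -10, -10, 0, 0, 0)
  st@bondPose <- c(1L, 1L, 1L, NA, NA, NA)
  st@bondSince <- c(0L, 0L, 0L, NA, NA, NA)
  st@energy <- recomputeEnergies(st)
  cl <- clusterStats(st)
  expect_identical(cl$Nc, 4)
  expect_equal(cl$monomerFraction, 2 / 6, tolerance = 1e-12)
  expect_equal(cl$NcAll, mean(c(4, 1, 1)), tolerance = 1e-12)
})

test_that("cluster sizes match a reference union-find implementation", {
  set.seed(89)
  for (trial in 1:10) {
    n <- 40
    bondTo <- rep(NA_integer_, n)
    pick <- sample(n, 25)
    for (i in pick) bondTo[i] <- sample(setdiff(seq_len(n), i), 1)
    # union-find oracle
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in which(!is.na(bondTo))) {
      a <- find(i); b <- find(bondTo[i])
      if (a != b) parent[a] <- b
    }
    roots <- vapply(seq_len(n), find, integer(1))
    oracleSizes <- sort(as.integer(table(roots)))
    got <- DockMC:::.clusterSummary(bondTo, n)
    expect_identical(sort(got$sizes), oracleSizes)
  }
})

test_that("residence episodes average completed lifetimes and count censoring", {
  eps <- data.frame(
    ligand = c(1L, 2L), receptor = c(2L, 3L),
    startStep = c(10L, 50L), endStep = c(20L, NA),
    censored = c(FALSE, TRUE)
  )
  rt <- residenceTime(eps, nsPerStep = 20)
  expect_equal(rt$meanNs, 200, tolerance = 1e-12)
  expect_identical(rt$nCompleted, 1L)
  expect_identical(rt$nCensored, 1L)
})

test_that("residence time follows the geometric law of the escape probability", {
  # two_state at low T: the deep pose escapes with a known per-attempt
  # probability, so pair lifetimes are irrelevant; instead use a pair
  # where both poses have equal energy and a second receptor provides
  # the escape route with acceptance ~ 1
  p <- DockMC:::.tinyProtein("A")
  pos <- rbind(c(100, 100, 100), c(130, 100, 100), c(100, 130, 100))
  n <- 3L
  rots <- array(rep(diag(3), n), c(3, 3, n))
  st <- methods::new("SystemState",
    box = 300, typeIds = rep(1L, n), typeNameVec = "A", proteins = list(p),
    rotations = rots, pos = pos, upos = pos,
    bondTo = rep(NA_integer_, n), bondEnergy = numeric(n),
    bondPose = rep(NA_integer_, n), bondSince = rep(NA_integer_, n),
    energy = numeric(n), step = 0L
  )
  lib <- explicitPoseLibrary(list(
    "A|A" = data.frame(dx = 12, dy = 0, dz = 0, energy = -10)
  ))
  cfg <- simulationConfig(box = 300, targetV = 0, temperature = 100,
                          steps = 4000, collisionCutoff = 0,
                          msdReferenceStep = 0, nsPerStep = 1, seed = 97,
                          clusterEvery = 100000, recordEvery = 100000)
  res <- runSimulation(st, lib, cfg)
  rt <- residenceTime(bondEpisodes(res), nsPerStep = 1)
  # a bond ends when its ligand accepts a move to the *other* receptor:
  # per step the ligand proposes it with p = 1/2 and acceptance is ~1
  # (equal energies, |Ni/Nj| = 1), so lifetimes ~ geometric(1/2)
  expect_gt(rt$nCompleted, 500)
  expect_equal(rt$meanSteps, 2, tolerance = 0.05)
})

test_that("a constructed sigmoid melts exactly at its center", {
  temps <- c(1, 10, 100, 1000, 10000)
  sL <- lapply(temps, function(T) {
    constantSeries(1 / (1 + exp(-(log10(T) - 2))))
  })
  mc <- meltingCurve(temps, sL, window = 50)
  expect_equal(mc$inflectionT, 100, tolerance = 1e-9)
  expect_false(mc$lowConfidence)
})

test_that("a flat melting scan yields no inflection and a flag", {
  temps <- c(1, 10, 100, 1000)
  sL <- lapply(temps, function(T) constantSeries(0.7))
  mc <- meltingCurve(temps, sL, window = 50)
  expect_true(is.na(mc$inflectionT))
  expect_true(mc$lowConfidence)
})

test_that("size dependence reports slowdowns and exact exponential recovery", {
  D <- c(a = 3, b = 3, c = 3)
  N <- c(a = 50, b = 100, c = 150)
  sd0 <- suppressWarnings(sizeDependence(D, N))
  expect_true(all(sd0$table$slowdown == 1))
  # D ~ exp(-cN): coefficient recovered exactly
  cc <- 0.013
  D2 <- c(a = 1, b = 1, c = 1) * exp(-cc * N)
  sd2 <- suppressWarnings(sizeDependence(D2, N))
  expect_equal(sd2$expCoef, cc, tolerance = 1e-6)
  expect_equal(sd2$expR2, 1, tolerance = 1e-9)
  # Einstein-Stokes synthetic: slowdown linear in N^(1/3)
  D3 <- 100 / N^(1 / 3)
  names(D3) <- names(N)
  sd3 <- suppressWarnings(sizeDependence(D3, N))
  expect_gt(sd3$linR2, 0.999)
})
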