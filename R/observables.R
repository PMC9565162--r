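#' Mean squared displacement from a trajectory
#'
#' MSD(t) = mean over copies of the squared displacement of the unwrapped
#' geometric center since the reference step. The reference (default step
#' 100) allows off-the-grid relaxation of the initial lattice state
#' before displacements are counted.
#'
#' @param trajectory the \code{trajectory} list of a
#'   \linkS4class{SimulationResult} (fields \code{steps}, \code{upos},
#'   \code{typeIds}, \code{typeNames}, \code{nsPerStep})
#' @param type type name or index; NULL pools all copies
#' @param referenceStep reference step (default 100); must be a recorded
#'   step smaller than the last
#' @return data.frame: \code{step}, \code{lag} (steps since reference),
#'   \code{msd} (Angstrom^2)
#' @export
msdSeries <- function(trajectory, type = NULL, referenceStep = 100) {
  steps <- trajectory$steps
  stopifnot(max(steps) > referenceStep)
  refIdx <- which(steps == referenceStep)
  if (!length(refIdx)) stop("reference step ", referenceStep, " was not recorded")
  idx <- seq_len(dim(trajectory$upos)[2])
  if (!is.null(type)) {
    ti <- if (is.character(type)) match(type, trajectory$typeNames) else type
    idx <- which(trajectory$typeIds == ti)
    if (!length(idx)) stop("no copies of type ", type)
  }
  ref <- trajectory$upos[refIdx, idx, , drop = FALSE]
  after <- which(steps >= referenceStep)
  msd <- vapply(after, function(k) {
    dd <- trajectory$upos[k, idx, , drop = FALSE] - ref
    mean(rowSums(matrix(dd, length(idx), 3)^2))
  }, numeric(1))
  data.frame(step = steps[after], lag = steps[after] - referenceStep, msd = msd)
}

#' Diffusion coefficient from an MSD series (Einstein relation)
#'
#' Fits the least-squares slope of MSD versus lag through the origin over
#' a lag window (default the 10-50% span of available lags, avoiding the
#' reference-step transient and terminal noise) and applies the
#' three-dimensional Einstein relation D = MSD(t) / 6t.
#'
#' @param msd data.frame from \code{\link{msdSeries}} (columns \code{lag},
#'   \code{msd})
#' @param nsPerStep physical ns per step used to express D in A^2/ns
#' @param window numeric length-2: lag window as fractions of the maximum
#'   lag (default c(0.1, 0.5))
#' @return list: \code{D} (A^2/ns), \code{DperStep} (A^2/step),
#'   \code{slope} (A^2/step), \code{window} (lag range used), \code{ok}
#'   (FALSE when the MSD is visibly sub-linear/saturated in the window)
#' @export
diffusionCoefficient <- function(msd, nsPerStep = 1, window = c(0.1, 0.5)) {
  lag <- msd$lag
  y <- msd$msd
  maxLag <- max(lag)
  sel <- which(lag >= window[1] * maxLag & lag <= window[2] * maxLag & lag > 0)
  if (length(sel) < 2) stop("lag window contains fewer than 2 points")
  slope <- sum(y[sel] * lag[sel]) / sum(lag[sel]^2)
  # linearity check: slope of the two window halves should agree
  mid <- stats::median(lag[sel])
  lo <- sel[lag[sel] <= mid]
  hi <- sel[lag[sel] > mid]
  ok <- TRUE
  if (length(lo) >= 2 && length(hi) >= 2 && slope > 0) {
    sLo <- sum(y[lo] * lag[lo]) / sum(lag[lo]^2)
    sHi <- sum(y[hi] * lag[hi]) / sum(lag[hi]^2)
    # a saturated MSD halves its through-origin slope from one half-window
    # to the next (flat y), while a linear one keeps it constant
    ok <- (sHi > 0.6 * sLo)
    if (!ok) warning("MSD appears sub-linear/saturated in the fit window")
  }
  list(D = slope / (6 * nsPerStep), DperStep = slope / 6, slope = slope,
       window = range(lag[sel]), ok = ok)
}

#' Calibrate physical time per simulation step
#'
#' Matches the simulated diffusion coefficient (per step) to a reference
#' diffusion coefficient (per ns). The reference may carry a known
#' overestimation factor relative to experiment (default 3, the
#' correction reported for the MD reference data used to calibrate this
#' protocol), which is divided out first.
#'
#' @param dSimPerStep simulated D in A^2/step
#' @param dRefPerNs reference D in A^2/ns
#' @param correction factor by which the reference overestimates
#'   experiment (default 3)
#' @return ns per simulation step
#' @examples
#' calibrateTime(dSimPerStep = 23.3, dRefPerNs = 3.5) # ~20 ns/step
#' @export
calibrateTime <- function(dSimPerStep, dRefPerNs, correction = 3) {
  stopifnot(dSimPerStep > 0, dRefPerNs > 0, correction > 0)
  dSimPerStep / (dRefPerNs / correction)
}

#' Fit the Cohen-Turnbull free-volume law
#'
#' Fits D = D0 * exp(-gamma * V / (1 - V)) to diffusion coefficients
#' measured at several volume fractions: first exactly by linear
#' regression of log D on V/(1-V), then polished by nonlinear least
#' squares (Levenberg-Marquardt) from that start.
#'
#' @param V volume fractions in (0, 1), at least 3 distinct values
#' @param D diffusion coefficients (positive)
#' @return list: \code{D0}, \code{gamma} (nonlinear fit), \code{linear}
#'   (the log-linear estimates), \code{residuals} (on D),
#'   \code{fitted}
#' @examples
#' V <- c(0.1, 0.15, 0.2, 0.25, 0.3)
#' D <- 4.9 * exp(-7.7 * V / (1 - V))
#' cohenTurnbullFit(V, D)[c("D0", "gamma")]
#' @export
cohenTurnbullFit <- function(V, D) {
  stopifnot(length(V) == length(D))
  if (length(unique(V)) < 3) stop("need at least 3 distinct volume fractions")
  if (any(V <= 0 | V >= 1)) stop("volume fractions must lie in (0, 1)")
  if (any(D <= 0)) stop("diffusion coefficients must be positive")
  x <- V / (1 - V)
  lf <- stats::lm(log(D) ~ x)
  D0lin <- exp(unname(stats::coef(lf)[1]))
  gLin <- -unname(stats::coef(lf)[2])
  dat <- data.frame(x = x, D = D)
  # the log-linear solution is exact on noise-free data; the nonlinear
  # polish can then hit a singular gradient, so fall back gracefully
  nl <- tryCatch(
    minpack.lm::nlsLM(D ~ D0 * exp(-g * x), data = dat,
                      start = list(D0 = D0lin, g = gLin),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(nl)) {
    fitted <- D0lin * exp(-gLin * x)
    return(list(D0 = D0lin, gamma = gLin,
                linear = c(D0 = D0lin, gamma = gLin),
                residuals = D - fitted, fitted = fitted))
  }
  cf <- stats::coef(nl)
  list(
    D0 = unname(cf["D0"]), gamma = unname(cf["g"]),
    linear = c(D0 = D0lin, gamma = gLin),
    residuals = as.numeric(stats::residuals(nl)),
    fitted = as.numeric(stats::fitted(nl))
  )
}

#' Cluster statistics of a state
#'
#' Connected components of the undirected docking-bond graph. The
#' aggregation number N_c averages clusters of size >= 2 (the docked
#' aggregates/oligomers); monomers are reported separately, both as a
#' fraction and inside the all-components average \code{NcAll}, since
#' either convention appears in the aggregation literature.
#'
#' @param state a \linkS4class{SystemState}
#' @return list: \code{Nc} (mean size of clusters >= 2; 1 with
#'   \code{degenerate = TRUE} when there are no bonds), \code{NcAll}
#'   (mean over all components incl. monomers), \code{monomerFraction},
#'   \code{histogram} (table of component sizes), \code{sizes},
#'   \code{degenerate}
#' @export
clusterStats <- function(state) {
  cl <- .clusterSummary(state@bondTo, copyCount(state))
  cl$histogram <- table(cl$sizes)
  cl
}

#' Mean residence time of docking bonds
#'
#' A bond episode runs from the creation of a ligand-receptor pair to its
#' replacement (the ligand accepting a move to a different receptor);
#' re-docking onto the same receptor in a new pose does not end the
#' episode. Episodes still alive at the end of the run are right-censored:
#' excluded from the mean and counted.
#'
#' @param episodes episode data.frame (from \code{\link{bondEpisodes}})
#'   with columns \code{startStep}, \code{endStep}, \code{censored}
#' @param nsPerStep physical ns per step
#' @return list: \code{meanSteps}, \code{meanNs}, \code{nCompleted},
#'   \code{nCensored}
#' @export
residenceTime <- function(episodes, nsPerStep = 20) {
  done <- episodes[!episodes$censored, , drop = FALSE]
  life <- done$endStep - done$startStep
  list(
    meanSteps = if (nrow(done)) mean(life) else NA_real_,
    meanNs = if (nrow(done)) mean(life) * nsPerStep else NA_real_,
    nCompleted = nrow(done),
    nCensored = sum(episodes$censored)
  )
}

# centered sliding-window mean, partial windows at the edges
.slidingMean <- function(x, window) {
  if (window <= 1L || length(x) < 2L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Melting curve across a temperature scan
#'
#' For each run, the per-step energy, shift and MSD series are smoothed
#' with a sliding window and averaged over the terminal window, giving
#' one point per temperature. The melting (inflection) temperature is
#' located on the shift-versus-log10(T) curve as the midpoint of the
#' steepest-rise segment, the most direct mobility readout; on a
#' symmetric sigmoid the tied steepest segments average to the exact
#' center. A flat or non-increasing curve yields \code{NA} with
#' \code{lowConfidence = TRUE}.
#'
#' @param temperatures numeric vector of temperatures (>= 4, spanning
#'   several decades for a meaningful inflection)
#' @param seriesList list of \linkS4class{ObservableSeries} (or
#'   \linkS4class{SimulationResult}), one per temperature
#' @param window smoothing / terminal-averaging window in steps
#'   (default 100)
#' @return list: \code{table} (data.frame with temperature, terminal
#'   energy/shift/MSD/acceptance), \code{inflectionT},
#'   \code{lowConfidence}
#' @export
meltingCurve <- function(temperatures, seriesList, window = 100) {
  stopifnot(length(temperatures) == length(seriesList))
  if (length(temperatures) < 4) stop("need at least 4 temperatures")
  term <- function(x, w) {
    sm <- .slidingMean(x, w)
    mean(utils::tail(sm, w))
  }
  rows <- lapply(seq_along(temperatures), function(i) {
    s <- seriesList[[i]]
    if (methods::is(s, "SimulationResult")) s <- s@series
    st <- s@stats
    lastMsd <- s@msd[nrow(s@msd), , drop = FALSE]
    data.frame(
      temperature = temperatures[i],
      energy = term(st$meanEnergy, window),
      shift = term(st$meanShift, window),
      msd = mean(lastMsd, na.rm = TRUE),
      acceptanceRate = term(st$acceptanceRate, window)
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$temperature), ]
  infl <- .inflectionOnLogT(tab$temperature, tab$shift)
  list(table = tab, inflectionT = infl$value, lowConfidence = infl$lowConfidence)
}

# steepest-rise midpoint of y vs log10(T); tied segments averaged
.inflectionOnLogT <- function(temperature, y) {
  lx <- log10(temperature)
  d1 <- diff(y) / diff(lx)
  if (!any(is.finite(d1)) || max(d1) <= 0 ||
      (max(y) - min(y)) < 1e-12 * max(abs(y), 1)) {
    return(list(value = NA_real_, lowConfidence = TRUE))
  }
  top <- which(d1 >= max(d1) * (1 - 1e-6))
  mids <- (lx[top] + lx[top + 1]) / 2
  low <- is.unsorted(y, strictly = FALSE)
  list(value = 10^mean(mids), lowConfidence = low)
}

#' Temperature scan of a system
#'
#' Runs the same initial state over a grid of temperatures (same
#' placement, a distinct derived RNG stream per temperature) and collects
#' the melting curve. The decade grid \code{c(1, 10, 100, 1000, 10000)}
#' spans frozen to overheated behavior for docking-score energy
#' landscapes.
#'
#' @param state initial \linkS4class{SystemState}
#' @param library a \linkS4class{PoseLibrary}
#' @param config a \linkS4class{SimulationConfig}; its temperature slot
#'   is overridden per run
#' @param temperatures temperatures to scan
#' @return list: \code{results} (one \linkS4class{SimulationResult} per
#'   temperature), \code{melting} (from \code{\link{meltingCurve}})
#' @export
scanTemperature <- function(state, library, config,
                            temperatures = c(1, 10, 100, 1000, 10000)) {
  results <- lapply(seq_along(temperatures), function(i) {
    cfg <- config
    cfg@temperature <- temperatures[i]
    cfg@seed <- as.integer(.deriveSeed(config@seed, 100L + i))
    runSimulation(state, library, cfg)
  })
  melting <- meltingCurve(temperatures, results, window = config@smoothWindow)
  list(results = results, melting = melting)
}

#' Diffusion slowdown versus protein size
#'
#' The slowdown of each type relative to the fastest type,
#' D_max / D, together with an exponential fit in the residue count N
#' (log-linear regression) and a linear fit in the Einstein-Stokes size
#' metric R = N^(1/3).
#'
#' @param D named vector of diffusion coefficients per type
#' @param nResiduesPerType named vector of residue counts per type
#' @return list: \code{table} (type, N, D, slowdown), \code{expCoef}
#'   (slowdown ~ exp(expCoef * N)), \code{expR2}, \code{linCoefs}
#'   (intercept/slope of slowdown ~ N^(1/3)), \code{linR2}
#' @export
sizeDependence <- function(D, nResiduesPerType) {
  stopifnot(length(D) >= 2, length(D) == length(nResiduesPerType))
  N <- as.numeric(nResiduesPerType)
  slow <- max(D) / D
  tab <- data.frame(type = names(D), N = N, D = as.numeric(D),
                    slowdown = as.numeric(slow))
  ef <- stats::lm(log(slowdown) ~ N, data = tab)
  lf <- stats::lm(slowdown ~ I(N^(1 / 3)), data = tab)
  list(
    table = tab,
    expCoef = unname(stats::coef(ef)[2]),
    expR2 = summary(ef)$r.squared,
    linCoefs = unname(stats::coef(lf)),
    linR2 = summary(lf)$r.squared
  )
}

#' Write the observable tables of a run as TSV files
#'
#' Emits \code{series.tsv} (per-step scalars), \code{msd.tsv},
#' \code{episodes.tsv} and a \code{summary.json} with terminal values.
#'
#' @param result a \linkS4class{SimulationResult}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeObservables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- result@series
  utils::write.table(s@stats, file.path(dir, "series.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  msd <- data.frame(step = s@stats$step, s@msd, check.names = FALSE)
  utils::write.table(msd, file.path(dir, "msd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(s@episodes, file.path(dir, "episodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- clusterStats(result@finalState)
  rt <- residenceTime(s@episodes, nsPerStep = s@meta$nsPerStep)
  summary <- list(
    steps = nrow(s@stats),
    meanEnergyTerminal = mean(utils::tail(s@stats$meanEnergy, s@meta$smoothWindow)),
    acceptanceTerminal = mean(utils::tail(s@stats$acceptanceRate, s@meta$smoothWindow)),
    aggregationNumber = cl$Nc,
    monomerFraction = cl$monomerFraction,
    residenceTimeNs = rt$meanNs,
    censoredEpisodes = rt$nCensored
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
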