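#' Precompute the pose library for a set of protein types
#'
#' Runs \code{\link{dockPair}} for every ordered (ligand, receptor) pair
#' of the type set (n^2 pairs, self-pairs included, since the box holds
#' many copies of each type) and collects the ranked pose tables into a
#' \linkS4class{PoseLibrary}.
#'
#' @inheritParams dockPair
#' @param proteins list of \linkS4class{Protein} types
#' @param verbose print one line per pair
#' @return a \linkS4class{PoseLibrary}
#' @export
buildPoseLibrary <- function(proteins, rotations = NULL, step = 3.5, rho = 9,
                             spacing = 10, topK = 30000, perRotationCap = 50,
                             verbose = FALSE) {
  if (is.null(rotations)) rotations <- buildRotationSet(spacing)
  ids <- vapply(proteins, proteinId, character(1))
  if (anyDuplicated(ids)) stop("protein ids must be unique")
  pairs <- list()
  for (li in seq_along(proteins)) {
    for (ri in seq_along(proteins)) {
      key <- paste0(ids[li], "|", ids[ri])
      if (verbose) message("docking ", key)
      pairs[[key]] <- dockPair(proteins[[li]], proteins[[ri]],
        rotations = rotations, step = step, rho = rho,
        topK = topK, perRotationCap = perRotationCap
      )
    }
  }
  methods::new("PoseLibrary",
    pairs = pairs, rotations = rotations, step = step,
    params = list(rho = rho, topK = as.integer(topK), spacing = spacing,
                  perRotationCap = as.integer(perRotationCap))
  )
}

#' Build a pose library from explicit poses
#'
#' Constructs a \linkS4class{PoseLibrary} directly from hand-specified
#' pair-frame center displacements and energies (all at the identity
#' rotation). Used by the toy scenarios, where the stationary
#' distribution must be enumerable.
#'
#' @param poses named list, one entry per ordered pair key
#'   \code{"lig|rec"}, each a data.frame with columns \code{dx},
#'   \code{dy}, \code{dz} (Angstrom) and \code{energy} (negative)
#' @return a \linkS4class{PoseLibrary} with step 1 and an identity-only
#'   rotation set
#' @export
explicitPoseLibrary <- function(poses) {
  rot <- methods::new("RotationSet",
    matrices = array(diag(3), c(3, 3, 1)),
    quaternions = matrix(c(1, 0, 0, 0), 1, 4), spacing = 360
  )
  pairs <- lapply(poses, function(tab) {
    stopifnot(all(c("dx", "dy", "dz", "energy") %in% names(tab)),
              all(tab$energy < 0))
    out <- data.frame(
      rot = 1L, tx = tab$dx, ty = tab$dy, tz = tab$dz,
      score = -tab$energy, energy = tab$energy,
      dx = tab$dx, dy = tab$dy, dz = tab$dz
    )
    out[order(-out$score, out$rot, out$tx, out$ty, out$tz), , drop = FALSE]
  })
  methods::new("PoseLibrary",
    pairs = pairs, rotations = rot, step = 1,
    params = list(rho = NA_real_, topK = max(vapply(pairs, nrow, 1L)),
                  spacing = 360, perRotationCap = NA_integer_)
  )
}

#' Compose a stored pose with the receptor's world placement
#'
#' A pose is stored in the pair frame (receptor at the origin, identity
#' orientation). Given the receptor's current world rotation and
#' position, returns the ligand's world placement: world rotation =
#' receptor rotation o pose rotation; world position = receptor position
#' + receptor rotation applied to the pair-frame center displacement.
#'
#' @param library a \linkS4class{PoseLibrary}
#' @param ligType,recType type names of the ordered pair
#' @param poseIndex row in the pair's pose table
#' @param recRot receptor 3x3 world rotation
#' @param recPos receptor world center position (length-3)
#' @return list with \code{rotation} (3x3) and \code{position} (length-3)
#' @export
poseTransform <- function(library, ligType, recType, poseIndex, recRot, recPos) {
  tab <- poseTable(library, ligType, recType)
  stopifnot(poseIndex >= 1, poseIndex <= nrow(tab))
  row <- tab[poseIndex, ]
  D <- c(row$dx, row$dy, row$dz)
  Rpose <- rotationMatrix(library@rotations, row$rot)
  list(
    rotation = recRot %*% Rpose,
    position = as.numeric(recPos + recRot %*% D)
  )
}

# inverse of poseTransform: recover the pair-frame placement from world frames
.pairFrame <- function(ligRot, ligPos, recRot, recPos) {
  list(
    rotation = crossprod(recRot, ligRot),
    displacement = as.numeric(crossprod(recRot, ligPos - recPos))
  )
}

#' Persist a pose library as a directory of text tables
#'
#' Layout: \code{params.json} (grid step, rho, top-K, spacing, and the
#' rotation-set quaternions' hash), \code{rotations.tsv} (unit
#' quaternions), and \code{pairs/<lig>__<rec>.tsv} (one ranked pose table
#' per ordered pair).
#'
#' @param library a \linkS4class{PoseLibrary}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writePoseLibrary <- function(library, dir) {
  dir.create(file.path(dir, "pairs"), recursive = TRUE, showWarnings = FALSE)
  qt <- as.data.frame(library@rotations@quaternions)
  names(qt) <- c("w", "x", "y", "z")
  utils::write.table(format(qt, digits = 17), file.path(dir, "rotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  params <- c(library@params,
              list(step = library@step, spacingNominal = library@rotations@spacing,
                   nRotations = rotationCount(library@rotations)))
  jsonlite::write_json(params, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  for (key in names(library@pairs)) {
    fn <- file.path(dir, "pairs", paste0(gsub("\\|", "__", key), ".tsv"))
    utils::write.table(format(library@pairs[[key]], digits = 17), fn,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a pose library written by \code{\link{writePoseLibrary}}
#'
#' @param dir directory path
#' @return a \linkS4class{PoseLibrary}
#' @export
readPoseLibrary <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  qt <- as.matrix(utils::read.table(file.path(dir, "rotations.tsv"),
                                    header = TRUE, sep = "\t"))
  mats <- array(0, c(3, 3, nrow(qt)))
  for (i in seq_len(nrow(qt))) mats[, , i] <- .quatToMat(qt[i, ])
  rot <- methods::new("RotationSet", matrices = mats, quaternions = unname(qt),
                      spacing = params$spacingNominal)
  files <- list.files(file.path(dir, "pairs"), pattern = "\\.tsv$", full.names = TRUE)
  pairs <- list()
  for (fn in files) {
    key <- gsub("__", "|", sub("\\.tsv$", "", basename(fn)))
    pairs[[key]] <- utils::read.table(fn, header = TRUE, sep = "\t")
  }
  methods::new("PoseLibrary",
    pairs = pairs, rotations = rot, step = params$step,
    params = list(rho = params$rho, topK = as.integer(params$topK),
                  spacing = params$spacing,
                  perRotationCap = as.integer(params$perRotationCap))
  )
}
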