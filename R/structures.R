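#' Construct a Protein from an atom table
#'
#' Computes the C-alpha trace (in residue order), geometric center,
#' bounding radius and voxel-estimated molecular volume from a table of
#' atoms. This is the common constructor behind both \code{\link{readPDB}}
#' and the synthetic-structure generator.
#'
#' @param id short name for the protein (e.g. a PDB code)
#' @param atoms data.frame with columns \code{resno}, \code{elety},
#'   \code{elem}, \code{x}, \code{y}, \code{z}
#' @param voxel voxel edge for the volume estimate (Angstrom)
#' @param probe probe radius added to atomic radii for the volume estimate
#' @return a \linkS4class{Protein}
#' @export
newProtein <- function(id, atoms, voxel = 1, probe = 1.4) {
  stopifnot(all(c("resno", "elety", "elem", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  isCA <- atoms$elety == "CA"
  resWithCA <- unique(atoms$resno[isCA])
  resAll <- unique(atoms$resno)
  if (length(setdiff(resAll, resWithCA))) {
    warning(sprintf("%d residue(s) without a C-alpha excluded from the trace",
                    length(setdiff(resAll, resWithCA))))
  }
  ca <- xyz[isCA, , drop = FALSE]
  center <- colMeans(xyz)
  radius <- sqrt(max(rowSums(sweep(xyz, 2, center)^2)))
  vol <- .voxelVolume(xyz, atoms$elem, voxel = voxel, probe = probe)
  methods::new("Protein",
    id = id, atoms = as.data.frame(atoms), calphas = ca,
    center = center, radius = radius, volume = vol,
    nResidues = nrow(ca)
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses standard ATOM records (PDB v3.3 columns) via
#' \code{bio3d::read.pdb}. Only the first model is used; HETATM records
#' and waters are excluded; alternate locations are resolved to the
#' highest-occupancy (first on ties) conformer. All chains are
#' concatenated: each entry is treated as one rigid molecule.
#'
#' @param path path to a PDB file
#' @param id protein name; defaults to the file base name
#' @param voxel,probe volume-estimate parameters, see
#'   \code{\link{proteinVolume}}
#' @return a \linkS4class{Protein}
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(syntheticProtein(20, seed = 1), pdb)
#' p <- readPDB(pdb)
#' nResidues(p)
#' @export
readPDB <- function(path, id = NULL, voxel = 1, probe = 1.4) {
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error for '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  # altloc: keep blank altlocs; within duplicated (chain, resno, insert, elety)
  # groups keep the highest-occupancy row, first on ties
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1, 1)
  # distinct residue numbering across chains so the trace stays ordered
  resKey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  resno <- as.integer(factor(resKey, levels = unique(resKey)))
  atoms <- data.frame(
    resno = resno, elety = at$elety, elem = toupper(elem),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  newProtein(id, atoms, voxel = voxel, probe = probe)
}

#' Write a Protein to a PDB file
#'
#' Emits standard ATOM records via \code{bio3d::write.pdb}; the output
#' round-trips through \code{\link{readPDB}}.
#'
#' @param p a \linkS4class{Protein}
#' @param file output path
#' @return \code{file}, invisibly
#' @export
writePDB <- function(p, file) {
  a <- p@atoms
  na <- nrow(a)
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = rep("ALA", na), elety = a$elety,
    chain = rep("A", na), o = rep(1, na), b = rep(0, na), elesy = a$elem
  )
  invisible(file)
}

# van der Waals radii (Angstrom) by element; 1.7 default for unknowns
.vdwRadii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               SE = 1.9, FE = 1.4, ZN = 1.39, MG = 1.73)

# voxelized union-of-spheres volume; counts voxel centers inside the
# probe-inflated union
.voxelVolume <- function(xyz, elem, voxel = 1, probe = 1.4, radii = .vdwRadii) {
  stopifnot(voxel > 0)
  r <- radii[toupper(elem)]
  r[is.na(r)] <- 1.7
  r <- r + probe
  lo <- apply(xyz - r, 2, min)
  hi <- apply(xyz + r, 2, max)
  if (voxel > min(hi - lo)) {
    stop("voxel (", voxel, " A) larger than the protein extent: degenerate estimate")
  }
  nd <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  occ <- array(FALSE, nd)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(nd[k]) - 0.5) * voxel)
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]; ra <- r[a]; ra2 <- ra * ra
    ii <- lapply(1:3, function(k) which(abs(ax[[k]] - p[k]) <= ra))
    if (any(vapply(ii, length, 1L) == 0L)) next
    dx2 <- (ax[[1]][ii[[1]]] - p[1])^2
    dy2 <- (ax[[2]][ii[[2]]] - p[2])^2
    dz2 <- (ax[[3]][ii[[3]]] - p[3])^2
    blk <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ra2
    occ[ii[[1]], ii[[2]], ii[[3]]] <-
      occ[ii[[1]], ii[[2]], ii[[3]], drop = FALSE] | blk
  }
  sum(occ) * voxel^3
}

#' Estimate the molecular volume of a protein
#'
#' Voxelized union-of-spheres estimator: counts voxels whose center lies
#' within the probe-inflated union of atom spheres (per-element van der
#' Waals radii, 1.4 A probe by default) and multiplies by the voxel
#' volume. Deterministic for a fixed voxel size, and monotone: adding
#' atoms can never decrease the estimate.
#'
#' @param p a \linkS4class{Protein}
#' @param voxel voxel edge in Angstrom (default 1)
#' @param probe probe radius in Angstrom added to every atomic radius
#'   (default 1.4)
#' @param radii named vector of per-element radii overriding the built-in
#'   van der Waals table
#' @return volume in Angstrom^3
#' @export
proteinVolume <- function(p, voxel = 1, probe = 1.4, radii = .vdwRadii) {
  xyz <- as.matrix(p@atoms[, c("x", "y", "z")])
  .voxelVolume(xyz, p@atoms$elem, voxel = voxel, probe = probe, radii = radii)
}

#' Plan copy counts for a target volume fraction
#'
#' Computes how many copies of each protein type fill a cubic box to a
#' target protein volume fraction, with an equal share of copies per type
#' (remainder of the integer division going to the first types in input
#' order), and the placement lattice step.
#'
#' @param proteins list of \linkS4class{Protein} (the type set)
#' @param box cubic box edge in Angstrom
#' @param targetV target volume fraction, in (0, 0.74)
#' @return a list of class \code{CopyCountPlan}: \code{counts} (named per
#'   type), \code{total}, \code{gridStep} (lattice step, A),
#'   \code{latticeDim} (sites per axis), \code{realizedV}, \code{box},
#'   \code{volumes}
#' @examples
#' ps <- lapply(c(30, 40, 50), function(n) syntheticProtein(n, seed = n))
#' plan <- planCopies(ps, box = 200, targetV = 0.2)
#' plan$counts
#' @export
planCopies <- function(proteins, box, targetV) {
  stopifnot(targetV > 0, targetV < 0.74, box > 0)
  vols <- vapply(proteins, molecularVolume, numeric(1))
  radii <- vapply(proteins, boundingRadius, numeric(1))
  ids <- vapply(proteins, proteinId, character(1))
  if (box <= 2 * max(2 * radii)) {
    stop("box must exceed twice the largest protein diameter")
  }
  k <- length(proteins)
  total <- as.integer(round(targetV * box^3 / mean(vols)))
  if (total < 1L) stop("target volume fraction yields zero copies")
  base <- total %/% k
  counts <- base + as.integer(seq_len(k) <= total %% k)
  names(counts) <- ids
  m <- as.integer(ceiling(total^(1 / 3) - 1e-9))
  gridStep <- box / m
  if (gridStep < max(radii)) {
    stop("infeasible: lattice step ", round(gridStep, 1),
         " A is below the largest protein radius; reduce targetV or enlarge the box")
  }
  if (gridStep < max(2 * radii)) {
    warning("lattice step below the largest protein diameter; initial overlaps ",
            "will be resolved during early MC steps")
  }
  realized <- sum(counts * vols) / box^3
  structure(
    list(counts = counts, total = total, gridStep = gridStep,
         latticeDim = m, realizedV = realized, targetV = targetV,
         box = box, volumes = vols),
    class = "CopyCountPlan"
  )
}

#' @export
print.CopyCountPlan <- function(x, ...) {
  cat(sprintf(
    "CopyCountPlan: %d copies (%s) in a %.0f A box\n  lattice %d^3, step %.1f A; realized V = %.3f (target %.3f)\n",
    x$total, paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
    x$box, x$latticeDim, x$gridStep, x$realizedV, x$targetV
  ))
  invisible(x)
}

#' Per-protein summary table
#'
#' @param proteins list of \linkS4class{Protein}
#' @param file optional path; if given the table is written as TSV
#' @return data.frame with id, n_residues, radius, volume
#' @export
proteinSummary <- function(proteins, file = NULL) {
  tab <- data.frame(
    id = vapply(proteins, proteinId, character(1)),
    n_residues = vapply(proteins, nResidues, integer(1)),
    radius = vapply(proteins, boundingRadius, numeric(1)),
    volume = vapply(proteins, molecularVolume, numeric(1))
  )
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
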