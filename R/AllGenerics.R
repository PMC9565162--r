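#' @title Generics for DockMC classes
#' @description Accessor generics used across the package's S4 classes.
#' @name DockMC-generics
#' @keywords internal
NULL

#' @rdname DockMC-generics
#' @param x an object
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname DockMC-generics
#' @export
setGeneric("caTrace", function(x) standardGeneric("caTrace"))

#' @rdname DockMC-generics
#' @export
setGeneric("geomCenter", function(x) standardGeneric("geomCenter"))

#' @rdname DockMC-generics
#' @export
setGeneric("boundingRadius", function(x) standardGeneric("boundingRadius"))

#' @rdname DockMC-generics
#' @export
setGeneric("molecularVolume", function(x) standardGeneric("molecularVolume"))

#' @rdname DockMC-generics
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname DockMC-generics
#' @export
setGeneric("rotationCount", function(x) standardGeneric("rotationCount"))

#' @rdname DockMC-generics
#' @param i index
#' @export
setGeneric("rotationMatrix", function(x, i) standardGeneric("rotationMatrix"))

#' @rdname DockMC-generics
#' @export
setGeneric("poseCount", function(x, ...) standardGeneric("poseCount"))

#' @rdname DockMC-generics
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname DockMC-generics
#' @param ligType,recType type names of the ordered pair (ligand, receptor)
#' @export
setGeneric("poseTable", function(x, ligType, recType) standardGeneric("poseTable"))

#' @rdname DockMC-generics
#' @export
setGeneric("copyCount", function(x) standardGeneric("copyCount"))

#' @rdname DockMC-generics
#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))

#' @rdname DockMC-generics
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname DockMC-generics
#' @export
setGeneric("unwrappedPositions", function(x) standardGeneric("unwrappedPositions"))

#' @rdname DockMC-generics
#' @export
setGeneric("typeNames", function(x) standardGeneric("typeNames"))

#' @rdname DockMC-generics
#' @export
setGeneric("typeIds", function(x) standardGeneric("typeIds"))

#' @rdname DockMC-generics
#' @export
setGeneric("bondGraph", function(x) standardGeneric("bondGraph"))

#' @rdname DockMC-generics
#' @export
setGeneric("moleculeEnergies", function(x) standardGeneric("moleculeEnergies"))

#' @rdname DockMC-generics
#' @export
setGeneric("seriesTable", function(x) standardGeneric("seriesTable"))

#' @rdname DockMC-generics
#' @export
setGeneric("msdTable", function(x) standardGeneric("msdTable"))

#' @rdname DockMC-generics
#' @export
setGeneric("bondEpisodes", function(x) standardGeneric("bondEpisodes"))
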