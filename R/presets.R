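#' Named scenario presets
#'
#' The three protein mixtures studied with this protocol, by PDB id:
#' \describe{
#'   \item{five_mix}{five arbitrarily selected average-size globular
#'     proteins representing a typical crowded cellular environment
#'     (1mat, 1g81, 3chy, 1jxb, 1cm2).}
#'   \item{gfp_five_mix}{the five-mix plus green fluorescent protein
#'     (1ema), for comparison with GFP diffusion measurements.}
#'   \item{three_mix}{three small proteins: ubiquitin (1ubq), protein G B1
#'     domain (1pga) and villin headpiece (1vii).}
#' }
#' Structures are not bundled; fetch them with \code{\link{fetchPDB}} or
#' supply your own files.
#'
#' @param name preset name
#' @return list: \code{name}, \code{members} (PDB ids), \code{box}
#'   (500 A), \code{volumeFractions} (0.10-0.30), \code{temperature}
#'   (100)
#' @export
scenarioPreset <- function(name = c("five_mix", "gfp_five_mix", "three_mix")) {
  name <- match.arg(name)
  members <- switch(name,
    five_mix = c("1mat", "1g81", "3chy", "1jxb", "1cm2"),
    gfp_five_mix = c("1mat", "1g81", "3chy", "1jxb", "1cm2", "1ema"),
    three_mix = c("1ubq", "1pga", "1vii")
  )
  list(
    name = name, members = members, box = 500,
    volumeFractions = seq(0.10, 0.30, by = 0.05), temperature = 100
  )
}

#' Fetch PDB entries (optional convenience; requires network)
#'
#' Downloads the given entries via \code{bio3d::get.pdb}. Never required
#' by the package's tests, which run on synthetic structures.
#'
#' @param ids PDB ids
#' @param dir destination directory
#' @return character vector of file paths
#' @export
fetchPDB <- function(ids, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(ids, function(id) bio3d::get.pdb(id, path = dir), character(1))
}
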