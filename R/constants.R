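## Physical constants and residue tables used throughout the package.
## Monoisotopic masses from the IUPAC/Unimod tables.

#' @noRd
PROTON_MASS <- 1.007276

#' @noRd
WATER_MASS <- 18.010565

## Monoisotopic residue masses (Da) of the 20 standard amino acids.
#' @noRd
RESIDUE_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

## Modification mass deltas. Only the two modifications the pipeline supports
## are listed: oxidation of methionine ("ox") and carbamidomethylation of
## cysteine ("cam").
#' @noRd
MODIFICATION_MASSES <- c(ox = 15.994915, cam = 57.021464)

## Kyte-Doolittle hydropathy values, used by the composition-only retention
## index of the toy predictor.
#' @noRd
HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Amino-acid and modification constants
#'
#' Returns the fixed constants table shipped with the package: monoisotopic
#' residue masses, the proton and water masses, and the mass deltas of the two
#' supported modifications (oxidation of Met, carbamidomethylation of Cys).
#'
#' @return A list with elements \code{residues}, \code{modifications},
#'   \code{proton}, \code{water}.
#' @examples
#' massConstants()$proton
#' @export
massConstants <- function() {
  list(
    residues = RESIDUE_MASSES,
    modifications = MODIFICATION_MASSES,
    proton = PROTON_MASS,
    water = WATER_MASS
  )
}
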