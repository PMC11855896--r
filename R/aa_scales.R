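#' Amino-acid scales used throughout the package
#'
#' Residue-level constants following the EMBOSS/Pepstats conventions: the
#' Kyte-Doolittle hydropathy index, average residue masses (Da) plus the mass
#' of one water molecule, the pKa table of ionizable groups, the integer/half
#' charge table, and the nine overlapping Pepstats residue categories (Tiny,
#' Small, Aliphatic, Aromatic, Non-polar, Polar, Charged, Basic, Acidic).
#'
#' The ambiguity codes B (Asx) and Z (Glx) appear in the category sets and in
#' the charge and mass tables (mass = mean of the two resolved residues,
#' charge -0.5); they carry no hydropathy or pKa value and are excluded from
#' hydrophobicity and isoelectric-point calculations.
#'
#' @return A list with elements `hydropathy`, `residue_mass`, `water_mass`,
#'   `pka`, `charge`, and `categories` (a named list of character vectors).
#' @export
#' @examples
#' sc <- aa_scales()
#' sc$hydropathy[["I"]]   #  4.5, scale maximum
#' sc$hydropathy[["R"]]   # -4.5, scale minimum
aa_scales <- function() {
  hydropathy <- c(
    A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
  )
  residue_mass <- c(
    A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
    G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
    M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
    S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
  )
  residue_mass <- c(residue_mass,
                    B = unname((residue_mass["N"] + residue_mass["D"]) / 2),
                    Z = unname((residue_mass["Q"] + residue_mass["E"]) / 2))
  pka <- c(
    Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
  )
  charge <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5, B = -0.5, Z = -0.5)
  categories <- list(
    tiny      = c("A", "C", "G", "S", "T"),
    small     = c("A", "B", "C", "D", "G", "N", "P", "S", "T", "V"),
    aliphatic = c("I", "L", "V"),
    aromatic  = c("F", "H", "W", "Y"),
    nonpolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
    polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Z"),
    charged   = c("B", "D", "E", "H", "K", "R", "Z"),
    basic     = c("H", "K", "R"),
    acidic    = c("B", "D", "E", "Z")
  )
  list(hydropathy = hydropathy, residue_mass = residue_mass,
       water_mass = 18.01524, pka = pka, charge = charge,
       categories = categories)
}
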