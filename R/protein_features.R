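#' Residue composition of a protein sequence
#'
#' Frequency of each residue as a percentage of sequence length, over the
#' letters actually observed (B, Z and X are tolerated and counted like any
#' other letter, so the vector always sums to 100).
#'
#' @param sequence a single protein sequence (character scalar).
#' @return Named numeric vector of percentages over the 20 standard residues
#'   plus any ambiguity codes present; sums to 100.
#' @export
#' @examples
#' residue_composition("ACDE")  # 25% each for A, C, D, E
residue_composition <- function(sequence) {
  chars <- aa_validate(sequence)
  lev <- c(AA20, intersect(AA_AMBIG, chars))
  counts <- table(factor(chars, levels = lev))
  out <- 100 * as.vector(counts) / length(chars)
  names(out) <- lev
  out
}

#' Pepstats category frequencies
#'
#' Percentage of residues falling in each of the nine overlapping Pepstats
#' categories. Categories overlap by design (a Lys is simultaneously polar,
#' charged and basic), so the nine values are not normalised against each
#' other; for sequences over the 20 standard residues the polar and non-polar
#' sets partition the alphabet and their percentages sum to exactly 100.
#'
#' @inheritParams residue_composition
#' @return Named numeric vector of nine percentages
#'   (tiny, small, aliphatic, aromatic, nonpolar, polar, charged, basic, acidic).
#' @export
#' @examples
#' category_frequencies("DEHK")[c("polar", "charged", "acidic", "basic")]
category_frequencies <- function(sequence) {
  f <- residue_composition(sequence)
  cats <- aa_scales()$categories
  vapply(cats, function(set) sum(f[names(f) %in% set]), numeric(1))
}

#' Composition-weighted Kyte-Doolittle hydrophobicity
#'
#' The per-protein hydrophobicity score: the percent frequency of each
#' standard residue multiplied by its Kyte-Doolittle hydropathy index and
#' summed. Because frequencies enter as percentages the score is 100 times
#' the classical mean hydropathy (GRAVY) of the same sequence; typical
#' membrane-anchored P450s score around -15 to -20. Ambiguity codes are
#' excluded from both numerator and denominator with a warning.
#'
#' @inheritParams residue_composition
#' @return A single numeric score (percent times hydropathy-index units).
#' @export
#' @examples
#' kd_hydrophobicity("IIII")  #  450, scale maximum
#' kd_hydrophobicity("RRRR")  # -450, scale minimum
kd_hydrophobicity <- function(sequence) {
  chars <- aa_validate(sequence)
  amb <- chars %in% AA_AMBIG
  if (any(amb)) {
    warning(sprintf("%d ambiguous residue(s) excluded from hydrophobicity",
                    sum(amb)))
    chars <- chars[!amb]
  }
  if (!length(chars)) stop("no standard residues in sequence", call. = FALSE)
  h <- aa_scales()$hydropathy
  f <- 100 * table(factor(chars, levels = AA20)) / length(chars)
  sum(as.vector(f) * h[AA20])
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water molecule (Pepstats
#' convention). B and Z use the mean mass of their resolved pair; X is not
#' assignable a mass and raises an error.
#'
#' @inheritParams residue_composition
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(sequence) {
  chars <- aa_validate(sequence)
  if (any(chars == "X")) {
    stop("cannot compute molecular weight with 'X' residues", call. = FALSE)
  }
  sc <- aa_scales()
  sum(sc$residue_mass[chars]) + sc$water_mass
}

#' Integer/half charge of a protein
#'
#' Pepstats-style formal charge: Asp/Glu -1, Lys/Arg +1, His +0.5,
#' Asx/Glx -0.5, all other residues 0.
#'
#' @inheritParams residue_composition
#' @param mean if `TRUE`, return the per-residue mean charge instead of the
#'   per-sequence sum (the default, matching Pepstats output).
#' @return Net charge in charge units.
#' @export
#' @examples
#' net_charge("KRDE")  # 0
#' net_charge("KKH")   # 2.5
net_charge <- function(sequence, mean = FALSE) {
  chars <- aa_validate(sequence)
  ch <- aa_scales()$charge
  total <- sum(ch[chars], na.rm = TRUE)
  if (mean) total / length(chars) else total
}

# Henderson-Hasselbalch net charge of a peptide at a given pH.
# counts: named counts of ionizable side chains; termini always included.
#' @noRd
hh_charge <- function(pH, counts, pka) {
  pos_groups <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
                  H = unname(counts["H"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos <- sum(pos_groups / (1 + 10^(pH - pka[c("Nterm", "K", "R", "H")])))
  neg <- sum(neg_groups / (1 + 10^(pka[c("Cterm", "D", "E", "C", "Y")] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' pH at which the Henderson-Hasselbalch net charge of the peptide (free
#' termini plus ionizable side chains C, D, E, H, K, R, Y with EMBOSS pKa
#' values) crosses zero, located by bisection on pH 0-14 to a charge
#' tolerance of 1e-4. Ambiguity codes are ignored.
#'
#' @inheritParams residue_composition
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectric_point("AAAA")  # (8.6 + 3.6) / 2 = 6.1: only the termini ionize
isoelectric_point <- function(sequence) {
  chars <- aa_validate(sequence)
  chars <- chars[!chars %in% AA_AMBIG]
  if (!length(chars)) stop("no standard residues in sequence", call. = FALSE)
  pka <- aa_scales()$pka
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  # charge is strictly decreasing in pH; termini guarantee a sign change
  f_lo <- hh_charge(lo, counts, pka)
  f_hi <- hh_charge(hi, counts, pka)
  if (f_lo < 0) return(lo)
  if (f_hi > 0) return(hi)
  repeat {
    mid <- (lo + hi) / 2
    f <- hh_charge(mid, counts, pka)
    if (abs(f) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (f > 0) lo <- mid else hi <- mid
  }
}

#' Full per-protein feature table
#'
#' Computes the complete physicochemical feature set for every sequence in a
#' FASTA file or `AAStringSet`: length, molecular weight, charge, isoelectric
#' point, hydrophobicity, the nine category percentages, and the 20 residue
#' frequencies.
#'
#' @param x path to a protein FASTA file, an `AAStringSet`, or a named
#'   character vector of sequences.
#' @return A data.frame with one row per sequence, `seq_id` first, then
#'   `length`, `mol_weight`, `charge`, `pi`, `hydrophobicity`, the nine
#'   category columns, and columns `A` ... `Y` of residue percentages.
#' @export
protein_features <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    x <- Biostrings::readAAStringSet(x)
  }
  seqs <- as_aa_character(x)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    f <- residue_composition(s)
    cats <- category_frequencies(s)
    data.frame(
      seq_id = id,
      length = nchar(s),
      mol_weight = molecular_weight(s),
      charge = net_charge(s),
      pi = isoelectric_point(s),
      hydrophobicity = kd_hydrophobicity(s),
      as.list(cats),
      as.list(f[AA20]),
      check.names = FALSE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the 13 physicochemical protein features
#'
#' The feature family used for the protein-property comparison table
#' (distinct from the 20-residue composition family).
#' @return Character vector of 13 column names of [protein_features()].
#' @export
protein_property_family <- function() {
  c("mol_weight", "pi", "charge", "hydrophobicity",
    "aromatic", "aliphatic", "acidic", "basic", "charged",
    "polar", "nonpolar", "small", "tiny")
}

#' Names of the 20 residue-frequency features
#' @return Character vector (one-letter residue codes).
#' @export
residue_family <- function() AA20
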