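# Simulation studies: planted-effect recovery and type-I error control.
# Both run the classify -> features -> compare path of the pipeline on
# generated cohorts (culling disabled: random-background proteins never
# approach the 80% identity threshold).

#' @noRd
cohort_comparisons <- function(config, workdir = tempfile("study")) {
  bundle <- generate_cohort(config, workdir)
  seqs <- as_aa_character(Biostrings::readAAStringSet(bundle$paths$proteins))
  ortho <- read_ortholog_table(bundle$paths$orthologs)
  labels <- classify_stability(ortho, gene_ids = names(seqs))
  genomic <- genomic_features(bundle$paths$gff3, genome = bundle$paths$genome)
  protein <- protein_features(seqs)
  names(protein)[names(protein) == "seq_id"] <- "gene_id"
  out <- list(
    genomic = compare_groups(genomic, labels, family = genomic_family()),
    protein = compare_groups(protein, labels, family = protein_property_family()),
    residues = compare_groups(protein, labels, family = residue_family()),
    labels = labels, truth = bundle$truth
  )
  unlink(workdir, recursive = TRUE)
  out
}

#' Features designed to differ between classes under the default generator
#'
#' The planted class contrasts: gene structure (length, exon count, intron
#' length), hydrophobicity and aliphatic content, residues enriched in the
#' stable class (Cys, Leu, Trp, Arg) and in the labile class (Glu, Lys, Met),
#' with the expected direction of the stable-minus-labile median difference.
#'
#' @return data.frame with `feature`, `family`, `direction` (+1 stable-up,
#'   -1 labile-up).
#' @export
designed_features <- function() {
  data.frame(
    feature = c("gene_length", "n_exons", "intron_length",
                "hydrophobicity", "aliphatic",
                "C", "L", "W", "R", "E", "K", "M"),
    family = c(rep("genomic", 3), rep("protein", 2), rep("residues", 7)),
    direction = c(1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Planted-effect recovery study
#'
#' Generates `n_seeds` independent cohorts at the default class set-points
#' and records, for every designed feature, whether it came out
#' corrected-significant with the planted direction, and for every declared
#' null feature whether it was (spuriously) flagged.
#'
#' @param n_seeds number of cohorts (default 20).
#' @param genes_per_class genes per class per cohort (default 50).
#' @param base_seed seed from which per-cohort seeds are derived.
#' @param config_fn optional function(seed) returning a [cohort_config()]
#'   (to override generator settings).
#' @return List with `designed` (logical matrix seeds x features: recovered
#'   with correct direction), `null_flagged` (logical matrix seeds x null
#'   features), `recovery_rate`, `null_rate` (per-feature fractions of
#'   seeds), and `label_accuracy` (fraction of genes whose paralog-based
#'   label matched the generator truth, pooled over seeds).
#' @export
run_recovery_study <- function(n_seeds = 20, genes_per_class = 50,
                               base_seed = 1L, config_fn = NULL) {
  des <- designed_features()
  nulls <- c("n_transcripts", "I", "S", "Y")
  null_fam <- c(n_transcripts = "genomic", I = "residues", S = "residues",
                Y = "residues")
  designed <- matrix(NA, n_seeds, nrow(des),
                     dimnames = list(NULL, des$feature))
  null_flagged <- matrix(NA, n_seeds, length(nulls),
                         dimnames = list(NULL, nulls))
  n_match <- 0L; n_total <- 0L
  for (s in seq_len(n_seeds)) {
    seed_s <- (as.integer(base_seed) * 1009L + s * 7919L) %% 2147483647L
    cfg <- if (is.null(config_fn)) {
      cohort_config(seed = seed_s,
                    genes_per_class = c(stable = genes_per_class,
                                        labile = genes_per_class))
    } else config_fn(seed_s)
    cmp <- cohort_comparisons(cfg)
    for (j in seq_len(nrow(des))) {
      tab <- cmp[[des$family[j]]]
      row <- tab[tab$feature == des$feature[j], , drop = FALSE]
      ok <- nrow(row) == 1L && row$significant &&
        sign(row$median_stable - row$median_labile) == des$direction[j]
      designed[s, j] <- isTRUE(ok)
    }
    for (nf in nulls) {
      tab <- cmp[[null_fam[[nf]]]]
      row <- tab[tab$feature == nf, , drop = FALSE]
      null_flagged[s, nf] <- nrow(row) == 1L && isTRUE(row$significant)
    }
    truth_cls <- cmp$truth$class[match(cmp$labels$gene_id, cmp$truth$gene_id)]
    n_match <- n_match + sum(cmp$labels$class == truth_cls)
    n_total <- n_total + length(truth_cls)
  }
  list(designed = designed, null_flagged = null_flagged,
       recovery_rate = colMeans(designed),
       null_rate = colMeans(null_flagged),
       label_accuracy = n_match / n_total)
}

#' Type-I error study on null cohorts
#'
#' Generates cohorts with no planted class difference (both classes share
#' averaged targets) and records, per comparison family, whether any feature
#' was flagged corrected-significant. Under Bonferroni control the
#' per-family any-significant rate should not exceed alpha (up to Monte
#' Carlo error).
#'
#' @param n_cohorts number of null cohorts (default 200).
#' @param genes_per_class genes per class per cohort (default 50).
#' @param base_seed seed from which per-cohort seeds are derived.
#' @param alpha family-wise error rate.
#' @return List with `any_significant` (logical matrix cohorts x families),
#'   `family_rate` (per-family fraction), and `bound`
#'   (alpha + 2 * binomial SE at alpha).
#' @export
run_null_study <- function(n_cohorts = 200, genes_per_class = 50,
                           base_seed = 1L, alpha = 0.05) {
  fams <- c("genomic", "protein", "residues")
  any_sig <- matrix(NA, n_cohorts, length(fams), dimnames = list(NULL, fams))
  for (s in seq_len(n_cohorts)) {
    seed_s <- (as.integer(base_seed) * 2003L + s * 104729L) %% 2147483647L
    cfg <- cohort_config(seed = seed_s,
                         genes_per_class = c(stable = genes_per_class,
                                             labile = genes_per_class),
                         null_cohort = TRUE)
    cmp <- cohort_comparisons(cfg)
    for (f in fams) any_sig[s, f] <- any(cmp[[f]]$significant)
  }
  list(any_significant = any_sig,
       family_rate = colMeans(any_sig),
       bound = alpha + 2 * sqrt(alpha * (1 - alpha) / n_cohorts))
}
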