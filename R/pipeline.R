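#' Pipeline configuration
#'
#' @param proteins,gff3,orthologs,annotations input file paths (annotations
#'   optional, `NULL` to skip enrichment); `genome` optional FASTA for GC.
#' @param cull_threshold percent identity above which sequences are culled.
#' @param run_cull run the redundancy-culling stage (all-vs-all alignment;
#'   disable for large cohorts where only the unculled tables are needed).
#' @param paralog_scope `"species"` or `"group"` (see [count_paralogs()]).
#' @param alpha family-wise error rate for the comparisons.
#' @param out_dir report directory (`NULL`: nothing written).
#' @param seed seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, gff3, orthologs, annotations = NULL,
                            genome = NULL, cull_threshold = 80,
                            run_cull = TRUE,
                            paralog_scope = c("species", "group"),
                            alpha = 0.05, out_dir = NULL, seed = 1L) {
  paralog_scope <- match.arg(paralog_scope)
  stopifnot(cull_threshold > 0, cull_threshold <= 100)
  for (p in c(proteins, gff3, orthologs, annotations, genome)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  structure(list(proteins = proteins, gff3 = gff3, orthologs = orthologs,
                 annotations = annotations, genome = genome,
                 cull_threshold = cull_threshold, run_cull = run_cull,
                 paralog_scope = paralog_scope, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full stable/labile comparison pipeline
#'
#' Orchestrates classification (paralog counts to stable/labile), per-class
#' redundancy culling, genomic and protein feature extraction, the three
#' family-corrected group comparisons (genomic, protein properties, residue
#' frequencies) on the unculled and culled sets, motif conservation per
#' class, annotation proportions with over-representation tests, a
#' chi-squared test on the exon-count distribution, and a stage-count run
#' log.
#'
#' @param config a [pipeline_config()].
#' @return List with `labels`, `culled` (retained/removed ids per class),
#'   `genomic`, `protein` (feature tables), `comparisons` (named list:
#'   `genomic`, `protein`, `residues`, each with `unculled`/`culled`),
#'   `motifs` (per class), `enrichment` (`proportions`, `ora` per class),
#'   `exon_chisq`, and `log` (stage counts). If `config$out_dir` is set the
#'   bundle is also written via [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seqs <- as_aa_character(Biostrings::readAAStringSet(config$proteins))
  ortho <- read_ortholog_table(config$orthologs)
  labels <- classify_stability(ortho, gene_ids = names(seqs),
                               scope = config$paralog_scope)

  models <- parse_gene_models(config$gff3)
  genomic <- genomic_features(models, genome = config$genome)
  names(genomic)[names(genomic) == "gene_id"] <- "gene_id"
  protein <- protein_features(seqs)
  names(protein)[names(protein) == "seq_id"] <- "gene_id"

  by_class <- split(labels$gene_id, labels$class)
  culled <- list()
  if (config$run_cull) {
    for (cl in intersect(c("stable", "labile"), names(by_class))) {
      culled[[cl]] <- cull_redundant(seqs[by_class[[cl]]],
                                     threshold = config$cull_threshold)[c("retained", "removed")]
    }
  } else {
    for (cl in intersect(c("stable", "labile"), names(by_class))) {
      culled[[cl]] <- list(retained = by_class[[cl]], removed = character(0))
    }
  }
  retained <- unlist(lapply(culled, `[[`, "retained"), use.names = FALSE)

  fams <- list(genomic = list(tab = genomic, family = genomic_family()),
               protein = list(tab = protein, family = protein_property_family()),
               residues = list(tab = protein, family = residue_family()))
  comparisons <- lapply(fams, function(f) {
    list(unculled = compare_groups(f$tab, labels, family = f$family,
                                   alpha = config$alpha),
         culled = compare_groups(f$tab[f$tab$gene_id %in% retained, ,
                                       drop = FALSE],
                                 labels, family = f$family,
                                 alpha = config$alpha))
  })

  motifs <- lapply(by_class[intersect(c("stable", "labile"), names(by_class))],
                   function(ids) motif_conservation(seqs[ids]))

  enrichment <- NULL
  if (!is.null(config$annotations)) {
    ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
    props <- proportion_table(ann, labels)
    ora <- lapply(by_class[intersect(c("stable", "labile"), names(by_class))],
                  function(ids) hypergeometric_enrichment(ann, ids, labels$gene_id))
    enrichment <- list(proportions = props, ora = ora)
  }

  exon_chisq <- NULL
  cls <- labels$class[match(genomic$gene_id, labels$gene_id)]
  if (all(c("stable", "labile") %in% cls)) {
    ex <- pmin(genomic$n_exons, 6)   # pool sparse high counts
    tab <- table(cls[cls %in% c("stable", "labile")],
                 ex[cls %in% c("stable", "labile")])
    if (ncol(tab) >= 2L) {
      exon_chisq <- tryCatch(suppressWarnings(chi_squared(unclass(tab))),
                             error = function(e) NULL)
    }
  }

  log <- list(
    seed = config$seed,
    n_input = length(seqs),
    n_stable = sum(labels$class == "stable"),
    n_labile = sum(labels$class == "labile"),
    n_unassigned = sum(labels$class == "unassigned"),
    n_culled_stable = length(culled$stable$retained),
    n_culled_labile = length(culled$labile$retained),
    cull_threshold = config$cull_threshold,
    alpha = config$alpha,
    package_version = as.character(utils::packageVersion("cypstab"))
  )

  results <- list(labels = labels, culled = culled, genomic = genomic,
                  protein = protein, comparisons = comparisons,
                  motifs = motifs, enrichment = enrichment,
                  exon_chisq = exon_chisq, log = log)
  if (!is.null(config$out_dir)) write_report(results, config$out_dir)
  results
}

#' @noRd
format_comparison <- function(tab) {
  out <- tab
  out$median_stable <- sprintf("%.4f", tab$median_stable)
  out$median_labile <- sprintf("%.4f", tab$median_labile)
  out$p <- signif(tab$p, 5)
  out$alpha_corr <- sprintf("%.4f", tab$alpha_corr)
  out
}

#' Write a pipeline report bundle
#'
#' Emits the comparison tables (medians to 4 dp, thresholds to 4 dp),
#' labels, culled id lists, feature tables, motif PFM summaries,
#' enrichment tables (percentages to 1 dp) and a JSON run log, all as TSV
#' with a stable column order.
#'
#' @param results output of [run_pipeline()].
#' @param out_dir directory to write into (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(tab, name) {
    path <- file.path(out_dir, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  w(results$labels, "labels.tsv")
  w(results$genomic, "genomic_features.tsv")
  w(results$protein, "protein_features.tsv")
  for (nm in names(results$comparisons)) {
    for (set in c("unculled", "culled")) {
      w(format_comparison(results$comparisons[[nm]][[set]]),
        sprintf("compare_%s_%s.tsv", nm, set))
    }
  }
  for (cl in names(results$culled)) {
    w(data.frame(gene_id = results$culled[[cl]]$removed),
      sprintf("removed_%s.tsv", cl))
  }
  for (cl in names(results$motifs)) {
    pfms <- results$motifs[[cl]]$pfms
    summ <- do.call(rbind, lapply(names(pfms), function(nm) {
      p <- pfms[[nm]]
      data.frame(motif = nm, column = seq_along(p$consensus),
                 consensus = p$consensus,
                 max_freq = sprintf("%.1f", p$max_freq),
                 ic_bits = sprintf("%.4f", p$ic),
                 n_windows = p$n_windows, stringsAsFactors = FALSE)
    }))
    if (!is.null(summ)) w(summ, sprintf("motif_conservation_%s.tsv", cl))
  }
  if (!is.null(results$enrichment)) {
    pr <- results$enrichment$proportions
    pr$pct <- sprintf("%.1f", pr$pct)
    w(pr, "enrichment_proportions.tsv")
    for (cl in names(results$enrichment$ora)) {
      w(results$enrichment$ora[[cl]], sprintf("enrichment_ora_%s.tsv", cl))
    }
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(results$log, log_path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, log_path)
  invisible(written)
}
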