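#' Per-term, per-class annotation proportion table
#'
#' Counts annotated genes per term within each stability class (and,
#' when the label table has a `species` column, per species within class),
#' with percentages of the class total rounded half-up to one decimal
#' place — the layout of a term-by-class over-representation summary where
#' species percentages are also taken over the class total.
#'
#' @param annotations data.frame with columns `gene_id`, `term_id`
#'   (one row per annotation); a `description` column is carried through.
#' @param labels data.frame with `gene_id`, `class`, optionally `species`.
#' @param class_totals optional named vector of class sizes used as
#'   percentage denominators; defaults to the label counts per class.
#' @return data.frame with columns `term_id`, `class`, `species` (`"all"`
#'   plus each species), `n`, `pct`.
#' @export
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:3), term_id = "GO:1")
#' lab <- data.frame(gene_id = paste0("g", 1:4),
#'                   class = c("stable", "stable", "labile", "stable"))
#' proportion_table(ann, lab)
proportion_table <- function(annotations, labels, class_totals = NULL) {
  stray <- setdiff(annotations$gene_id, labels$gene_id)
  if (length(stray)) {
    message(sprintf("%d annotated gene(s) not in the label table ignored",
                    length(stray)))
    annotations <- annotations[!annotations$gene_id %in% stray, , drop = FALSE]
  }
  if (is.null(class_totals)) {
    class_totals <- table(labels$class)
  }
  if (any(class_totals == 0)) stop("a class total is zero", call. = FALSE)
  ann <- unique(annotations[c("gene_id", "term_id")])
  ann$class <- labels$class[match(ann$gene_id, labels$gene_id)]
  has_species <- "species" %in% names(labels)
  ann$species <- if (has_species) labels$species[match(ann$gene_id, labels$gene_id)]
                 else NA_character_
  classes <- intersect(c("stable", "labile"), unique(labels$class))
  species_levels <- if (has_species) sort(unique(labels$species)) else character(0)
  empty <- data.frame(term_id = character(0), class = character(0),
                      species = character(0), n = integer(0), pct = numeric(0))
  if (!nrow(ann)) return(empty)
  rows <- list()
  for (term in unique(ann$term_id)) {
    for (cl in classes) {
      sub <- ann[ann$term_id == term & ann$class == cl, , drop = FALSE]
      denom <- as.numeric(class_totals[[cl]])
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = term, class = cl, species = "all",
        n = nrow(sub), pct = round_half_up(100 * nrow(sub) / denom, 1),
        stringsAsFactors = FALSE)
      for (sp in species_levels) {
        nsp <- sum(sub$species == sp)
        rows[[length(rows) + 1L]] <- data.frame(
          term_id = term, class = cl, species = sp,
          n = nsp, pct = round_half_up(100 * nsp / denom, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value for observing at least the overlap
#' between a term's annotated genes and a gene class, against a background
#' universe, with Benjamini-Hochberg adjustment across terms.
#'
#' @param annotations data.frame with `gene_id`, `term_id`.
#' @param class_genes character vector of gene ids forming the test set.
#' @param background character vector of gene ids forming the universe
#'   (must contain the class genes and the annotated genes).
#' @return data.frame with `term_id`, `n_term` (annotated in background),
#'   `n_class`, `overlap`, `p` (hypergeometric upper tail), `p_adj` (BH).
#' @export
hypergeometric_enrichment <- function(annotations, class_genes, background) {
  if (!length(background)) stop("empty background", call. = FALSE)
  background <- unique(background)
  class_genes <- intersect(unique(class_genes), background)
  ann <- unique(annotations[c("gene_id", "term_id")])
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  n_bg <- length(background)
  n_class <- length(class_genes)
  terms <- unique(ann$term_id)
  if (!length(terms)) {
    return(data.frame(term_id = character(0), n_term = integer(0),
                      n_class = integer(0), overlap = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  rows <- lapply(terms, function(term) {
    genes <- ann$gene_id[ann$term_id == term]
    k <- length(intersect(genes, class_genes))
    K <- length(genes)
    p <- stats::phyper(k - 1, K, n_bg - K, n_class, lower.tail = FALSE)
    data.frame(term_id = term, n_term = K, n_class = n_class,
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
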