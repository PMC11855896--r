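#' Read an ortholog-group membership table
#'
#' @param path TSV with columns `group_id`, `species`, `gene_id` (header
#'   required).
#' @return data.frame with those three character columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(tab))) {
    stop("ortholog table must have columns group_id, species, gene_id",
         call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("a gene id appears in more than one ortholog-table row", call. = FALSE)
  }
  tab[need]
}

#' Paralog count of a gene
#'
#' Number of other genes sharing the gene's ortholog group. With the default
#' `scope = "species"` only members of the same species count (cross-species
#' members are orthologs, not paralogs); `scope = "group"` counts every other
#' group member.
#'
#' @param table ortholog table (data.frame with `group_id`, `species`,
#'   `gene_id`).
#' @param gene_id gene identifier present in the table.
#' @param scope `"species"` (default) or `"group"`.
#' @return Non-negative integer paralog count.
#' @export
count_paralogs <- function(table, gene_id, scope = c("species", "group")) {
  scope <- match.arg(scope)
  row <- table[table$gene_id == gene_id, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("gene '%s' not in ortholog table", gene_id),
                       call. = FALSE)
  members <- table[table$group_id == row$group_id[1L], , drop = FALSE]
  if (scope == "species") {
    members <- members[members$species == row$species[1L], , drop = FALSE]
  }
  nrow(members) - 1L
}

#' Classify genes as stable or labile from paralog counts
#'
#' Genes with at most three paralogs in their ortholog group are "stable"
#' (evolutionarily conserved lineages); genes with four or more are "labile"
#' (lineage-expanded blooms). Genes absent from the table are labelled
#' `"unassigned"` and reported with a message.
#'
#' @param table ortholog table (see [count_paralogs()]).
#' @param gene_ids genes to label; defaults to every gene in the table.
#' @param max_stable_paralogs class boundary (default 3: k <= 3 stable,
#'   k >= 4 labile).
#' @inheritParams count_paralogs
#' @return data.frame with columns `gene_id`, `species`, `k` (paralog count,
#'   `NA` for unassigned), `class` (`"stable"`, `"labile"`, `"unassigned"`).
#' @export
classify_stability <- function(table, gene_ids = NULL,
                               max_stable_paralogs = 3,
                               scope = c("species", "group")) {
  scope <- match.arg(scope)
  if (is.null(gene_ids)) gene_ids <- table$gene_id
  # group/species sizes in one pass rather than per-gene lookups
  key <- if (scope == "species") {
    paste(table$group_id, table$species, sep = "\r")
  } else {
    table$group_id
  }
  size <- table(key)
  idx <- match(gene_ids, table$gene_id)
  k <- ifelse(is.na(idx), NA_integer_,
              as.integer(size[key[idx]]) - 1L)
  cls <- ifelse(is.na(k), "unassigned",
                ifelse(k <= max_stable_paralogs, "stable", "labile"))
  n_un <- sum(cls == "unassigned")
  if (n_un) message(sprintf("%d gene(s) absent from ortholog table labelled 'unassigned'", n_un))
  data.frame(gene_id = gene_ids,
             species = ifelse(is.na(idx), NA_character_, table$species[idx]),
             k = k, class = cls, stringsAsFactors = FALSE)
}
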