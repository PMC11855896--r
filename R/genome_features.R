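#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon records (1-based inclusive coordinates) and assembles
#' one gene model per `gene` feature, with its transcripts and their exon
#' spans. Files need not be sorted; exons are ordered by start within each
#' transcript. Exons whose `Parent` does not resolve to a known transcript
#' raise a format error naming the offending record.
#'
#' @param path path to a GFF3 file.
#' @return A named list of gene models. Each element is a list with fields
#'   `gene_id`, `seqid`, `strand`, `start`, `end`, and `transcripts` (a named
#'   list of lists with `tx_id` and an integer matrix `exons` with columns
#'   `start`, `end`).
#' @export
parse_gene_models <- function(path) {
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end", "strand"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$Parent <- vapply(gff$Parent, function(p) {
    if (length(p)) as.character(p)[1L] else NA_character_
  }, character(1))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  txs <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  if (anyNA(genes$ID)) stop("gene record without an ID attribute", call. = FALSE)
  if (anyNA(txs$ID)) stop("transcript record without an ID attribute", call. = FALSE)

  tx_gene <- txs$Parent
  names(tx_gene) <- txs$ID
  bad_tx <- which(!tx_gene %in% genes$ID)
  if (length(bad_tx)) {
    stop(sprintf("transcript '%s' has no parent gene record", txs$ID[bad_tx[1L]]),
         call. = FALSE)
  }
  bad_ex <- which(is.na(exons$Parent) | !exons$Parent %in% txs$ID)
  if (length(bad_ex)) {
    id <- exons$ID[bad_ex[1L]]
    stop(sprintf("orphan exon record '%s' (no parent transcript)",
                 if (is.na(id)) sprintf("at %s:%d-%d", exons$seqid[bad_ex[1L]],
                                        exons$start[bad_ex[1L]], exons$end[bad_ex[1L]])
                 else id),
         call. = FALSE)
  }

  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx_ids <- txs$ID[tx_gene == gid]
    transcripts <- lapply(tx_ids, function(tid) {
      ex <- exons[exons$Parent == tid, , drop = FALSE]
      if (!nrow(ex)) stop(sprintf("transcript '%s' has no exons", tid), call. = FALSE)
      ex <- ex[order(ex$start), , drop = FALSE]
      if (any(ex$start < genes$start[i] | ex$end > genes$end[i])) {
        stop(sprintf("exon outside gene span for transcript '%s'", tid),
             call. = FALSE)
      }
      list(tx_id = tid,
           exons = cbind(start = as.integer(ex$start), end = as.integer(ex$end)))
    })
    names(transcripts) <- tx_ids
    if (!length(transcripts)) {
      stop(sprintf("gene '%s' has no transcripts", gid), call. = FALSE)
    }
    list(gene_id = gid, seqid = as.character(genes$seqid[i]),
         strand = as.character(genes$strand[i]),
         start = as.integer(genes$start[i]), end = as.integer(genes$end[i]),
         transcripts = transcripts)
  })
  names(models) <- genes$ID
  models
}

#' Representative transcript of a gene model
#'
#' For genes with multiple transcripts, the transcript with the greatest
#' total exon length is used for exon counting; ties break to the
#' lexicographically smallest transcript id, so the choice is deterministic.
#'
#' @param gene a gene model as returned by [parse_gene_models()].
#' @return The selected transcript (list with `tx_id` and `exons`).
#' @export
select_representative <- function(gene) {
  stopifnot(length(gene$transcripts) >= 1L)
  tot <- vapply(gene$transcripts,
                function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"] + 1L),
                numeric(1))
  ord <- order(-tot, names(gene$transcripts))
  gene$transcripts[[ord[1L]]]
}

#' Genomic feature vector of one gene
#'
#' Computes the six gene-structure features: gene length (span end - start
#' + 1), exon count and total exon length of the representative transcript,
#' total intron length (gene length minus total exon length, floored at zero
#' with a warning if the representative transcript does not span the gene),
#' transcript count, and GC content. GC is 100 * (G+C) / (A+C+G+T) over the
#' full gene span, introns included; ambiguity bases are excluded from both
#' numerator and denominator. Without sequence, GC is `NA`.
#'
#' @param gene a gene model from [parse_gene_models()].
#' @param sequence optional nucleotide sequence of the gene span (character
#'   scalar, 5' to 3' on the annotated reference, length equal to the span).
#' @return One-row data.frame with columns `gene_id`, `gene_length`,
#'   `n_exons`, `exon_length`, `intron_length`, `n_transcripts`, `gc_percent`.
#' @export
compute_genomic_features <- function(gene, sequence = NULL) {
  rep_tx <- select_representative(gene)
  l_gene <- gene$end - gene$start + 1L
  widths <- rep_tx$exons[, "end"] - rep_tx$exons[, "start"] + 1L
  l_exon <- sum(widths)
  l_intron <- l_gene - l_exon
  if (l_intron < 0L) {
    warning(sprintf("gene '%s': total exon length exceeds gene span; intron length floored at 0",
                    gene$gene_id))
    l_intron <- 0L
  }
  gc <- NA_real_
  if (!is.null(sequence)) {
    bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    acgt <- bases[bases %in% c("A", "C", "G", "T")]
    if (length(acgt)) gc <- 100 * sum(acgt %in% c("G", "C")) / length(acgt)
  }
  data.frame(gene_id = gene$gene_id,
             gene_length = l_gene,
             n_exons = nrow(rep_tx$exons),
             exon_length = l_exon,
             intron_length = l_intron,
             n_transcripts = length(gene$transcripts),
             gc_percent = gc,
             stringsAsFactors = FALSE)
}

#' Genomic feature table for a whole annotation
#'
#' @param models gene models from [parse_gene_models()], or a GFF3 path.
#' @param genome optional `DNAStringSet` (or FASTA path) of the reference
#'   contigs named as in the GFF3 `seqid` column, used for GC content.
#' @return data.frame with one row per gene (columns as in
#'   [compute_genomic_features()]).
#' @export
genomic_features <- function(models, genome = NULL) {
  if (is.character(models)) models <- parse_gene_models(models)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  rows <- lapply(models, function(g) {
    seq <- NULL
    if (!is.null(genome)) {
      if (!g$seqid %in% names(genome)) {
        stop(sprintf("contig '%s' not found in genome", g$seqid), call. = FALSE)
      }
      seq <- as.character(Biostrings::subseq(genome[[g$seqid]], g$start, g$end))
    }
    compute_genomic_features(g, seq)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the six genomic features
#' @return Character vector of the genomic comparison family.
#' @export
genomic_family <- function() {
  c("gene_length", "n_exons", "exon_length", "intron_length",
    "n_transcripts", "gc_percent")
}
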