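#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 and affine gap costs
#' (open 10, extend 0.5, the EMBOSS defaults), followed by
#' identity = 100 * identical positions / alignment length, where alignment
#' length counts every column including gap columns.
#'
#' @param seq_a,seq_b protein sequences (character scalars).
#' @param substitution substitution matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @param denominator `"alignment"` (default; all alignment columns) or
#'   `"shorter"` (length of the shorter input sequence).
#' @return List with `identity` (percent), `score`, and `alignment_length`.
#' @export
pairwise_identity <- function(seq_a, seq_b, substitution = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  aa_validate(seq_a); aa_validate(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  cp <- strsplit(p, "")[[1L]]
  cs <- strsplit(s, "")[[1L]]
  matches <- sum(cp == cs & cp != "-")
  alen <- length(cp)
  denom <- if (denominator == "alignment") alen else min(nchar(seq_a), nchar(seq_b))
  list(identity = 100 * matches / denom,
       score = Biostrings::score(aln),
       alignment_length = alen)
}

#' All-vs-all percent identity matrix
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param ... passed to [pairwise_identity()].
#' @return Symmetric numeric matrix of percent identities, diagonal 100.
#' @export
identity_matrix <- function(sequences, ...) {
  seqs <- as_aa_character(sequences)
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pid <- pairwise_identity(seqs[[i]], seqs[[j]], ...)$identity
      m[i, j] <- m[j, i] <- pid
    }
  }
  m
}

#' Remove redundant sequences above an identity threshold
#'
#' Greedy redundancy reduction: while any retained pair exceeds the
#' threshold, the highest-identity pair is found and its shorter member is
#' removed (tie on length: the lexicographically larger id is removed). The
#' result is deterministic and no retained pair exceeds the threshold.
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param threshold percent identity above which a pair is redundant
#'   (default 80; a pair is redundant when identity > threshold).
#' @param idm optional precomputed identity matrix (as from
#'   [identity_matrix()]); computed if missing.
#' @param ... passed to [identity_matrix()].
#' @return List with `retained` and `removed` (character vectors of ids, in
#'   input order) and the full `identity_matrix`.
#' @export
cull_redundant <- function(sequences, threshold = 80, idm = NULL, ...) {
  seqs <- as_aa_character(sequences)
  stopifnot(length(seqs) >= 1L, threshold > 0, threshold <= 100)
  if (is.null(idm)) idm <- identity_matrix(seqs, ...)
  alive <- names(seqs)
  removed <- character(0)
  repeat {
    sub <- idm[alive, alive, drop = FALSE]
    diag(sub) <- -Inf
    if (!length(sub) || max(sub) <= threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- alive[idx[1L]]; b <- alive[idx[2L]]
    la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
    drop_id <- if (la < lb) a else if (lb < la) b else max(a, b)
    removed <- c(removed, drop_id)
    alive <- setdiff(alive, drop_id)
  }
  list(retained = intersect(names(seqs), alive),
       removed = intersect(names(seqs), removed),
       identity_matrix = idm)
}
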