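#' The five P450 signature motif definitions
#'
#' Patterns of the conserved cytochrome P450 signature motifs, N- to
#' C-terminal: helix C (WxxR), helix I (GxE/DTT/S), helix K (ExLR), PERF
#' (PxxFxPE/DRE) and the haem-binding motif (PFxxGxRxCxG/A), where `x`
#' accepts any residue and alternatives are listed together. Each definition
#' carries the pattern (a list of character vectors, one per position; length
#' 1 = fixed residue, `"x"` = wildcard) and a profiling window length: the
#' haem window is 15 columns (the 11-position pattern plus 4 trailing
#' profiled-but-unconstrained columns, spanning the full
#' `PFSAGPRNCIGQRFA`-style consensus); all other windows equal the pattern
#' span.
#'
#' @return Named list of motif definitions, in N-to-C order, each a list with
#'   `name`, `pattern`, `span` and `window`.
#' @export
p450_motifs <- function() {
  def <- function(name, pattern, window = length(pattern)) {
    list(name = name, pattern = pattern, span = length(pattern), window = window)
  }
  list(
    helixC = def("helixC", list("W", "x", "x", "R")),
    helixI = def("helixI", list("G", "x", c("E", "D"), "T", c("T", "S"))),
    helixK = def("helixK", list("E", "x", "L", "R")),
    PERF   = def("PERF", list("P", "x", "x", "F", "x", "P", c("E", "D"), "R", "E")),
    haem   = def("haem", list("P", "F", "x", "x", "G", "x", "R", "x", "C", "x",
                              c("G", "A")), window = 15L)
  )
}

#' @noRd
motif_regex <- function(motif) {
  parts <- vapply(motif$pattern, function(p) {
    if (identical(p, "x")) "." else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, character(1))
  paste(parts, collapse = "")
}

#' @noRd
matches_pattern <- function(window, motif) {
  grepl(paste0("^", motif_regex(motif)), window)
}

#' Scan a sequence for a signature motif
#'
#' Finds every (possibly overlapping) occurrence of the motif pattern, in
#' N-to-C order.
#'
#' @param sequence protein sequence (character scalar).
#' @param motif a motif definition from [p450_motifs()] (or a motif name).
#' @return data.frame with columns `motif`, `start` (1-based), `match` (the
#'   pattern-span substring); zero rows when there is no match.
#' @export
#' @examples
#' scan_motif("PFSAGPRNCIGQRFA", "haem")  # one match at position 1
scan_motif <- function(sequence, motif) {
  if (is.character(motif)) motif <- p450_motifs()[[motif]]
  if (is.null(motif)) stop("unknown motif", call. = FALSE)
  chars <- aa_validate(sequence)
  seq_u <- paste(chars, collapse = "")
  rx <- paste0("(?=(", motif_regex(motif), "))")
  hit <- gregexpr(rx, seq_u, perl = TRUE)[[1L]]
  if (hit[1L] == -1L) {
    return(data.frame(motif = character(0), start = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(hit)
  data.frame(motif = motif$name, start = starts,
             match = substring(seq_u, starts, starts + motif$span - 1L),
             stringsAsFactors = FALSE)
}

#' Anchor one window per motif per sequence
#'
#' Selects at most one match for each of the five motifs, respecting their
#' N-to-C order: the first match of each motif that starts after the end of
#' the previously anchored motif is taken; matches violating the ordering are
#' rejected. Returns the full profiling window (pattern span plus any
#' trailing profiled columns) for each anchored motif; anchors whose window
#' would run past the end of the sequence are dropped.
#'
#' @param sequence protein sequence (character scalar).
#' @param motifs motif definitions (default [p450_motifs()]), in N-to-C order.
#' @return data.frame with columns `motif`, `start`, `match` (pattern span)
#'   and `window` (profiling window, `NA` if truncated by the sequence end).
#' @export
best_motif_windows <- function(sequence, motifs = p450_motifs()) {
  chars <- aa_validate(sequence)
  seq_u <- paste(chars, collapse = "")
  anchor_end <- 0L
  rows <- list()
  for (m in motifs) {
    hits <- scan_motif(seq_u, m)
    hits <- hits[hits$start > anchor_end, , drop = FALSE]
    if (!nrow(hits)) next
    h <- hits[1L, ]
    win_end <- h$start + m$window - 1L
    rows[[m$name]] <- data.frame(
      motif = m$name, start = h$start, match = h$match,
      window = if (win_end <= nchar(seq_u)) substring(seq_u, h$start, win_end)
               else NA_character_,
      stringsAsFactors = FALSE)
    anchor_end <- h$start + m$span - 1L
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), start = integer(0),
                      match = character(0), window = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Position frequency matrix of aligned motif windows
#'
#' Builds the per-column residue frequency matrix (percent) of a set of
#' equal-length windows, with the per-column consensus residue (ties break
#' alphabetically), maximum frequency, and information content in bits
#' (log2(20) + sum of p*log2(p), so identical columns score log2(20) = 4.32).
#'
#' @param windows character vector of equal-length amino-acid windows.
#' @return List of class `cypstab_pfm` with `freq` (20 x width percent
#'   matrix), `n_windows`, `consensus` (character vector), `max_freq`,
#'   and `ic` (bits per column).
#' @export
build_pfm <- function(windows) {
  windows <- windows[!is.na(windows)]
  if (!length(windows)) stop("no windows to profile", call. = FALSE)
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("windows must all have the same length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  freq <- apply(mat, 2L, function(col) {
    100 * table(factor(col, levels = AA20)) / length(col)
  })
  freq <- matrix(as.numeric(freq), nrow = length(AA20), ncol = w,
                 dimnames = list(AA20, seq_len(w)))
  consensus <- apply(freq, 2L, function(col) AA20[which.max(col)])
  max_freq <- apply(freq, 2L, max)
  ic <- apply(freq / 100, 2L, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(freq = freq, n_windows = length(windows),
                 consensus = consensus, max_freq = max_freq, ic = ic),
            class = "cypstab_pfm")
}

#' @export
print.cypstab_pfm <- function(x, ...) {
  cat(sprintf("PFM over %d windows, %d columns\n", x$n_windows, ncol(x$freq)))
  cat("consensus:", paste(x$consensus, collapse = ""), "\n")
  cat("IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Invariant columns of a PFM
#'
#' Column indices whose maximum residue frequency reaches `level` percent
#' (default 100, i.e. totally conserved columns).
#'
#' @param pfm a `cypstab_pfm` from [build_pfm()].
#' @param level conservation level in percent.
#' @return Integer vector of column indices.
#' @export
invariant_columns <- function(pfm, level = 100) {
  unname(which(pfm$max_freq >= level - 1e-9))
}

#' Cohort-level motif conservation summary
#'
#' Anchors one window per motif in every sequence, then builds a PFM per
#' motif from the anchored windows.
#'
#' @param sequences named character vector or `AAStringSet` (or FASTA path).
#' @param motifs motif definitions (default [p450_motifs()]).
#' @return List with `matches` (data.frame of anchored windows with
#'   `seq_id`) and `pfms` (named list of `cypstab_pfm`, motifs with no
#'   anchored window omitted).
#' @export
motif_conservation <- function(sequences, motifs = p450_motifs()) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- Biostrings::readAAStringSet(sequences)
  }
  seqs <- as_aa_character(sequences)
  per_seq <- lapply(names(seqs), function(id) {
    w <- best_motif_windows(seqs[[id]], motifs)
    if (nrow(w)) cbind(seq_id = id, w, stringsAsFactors = FALSE) else NULL
  })
  per_seq <- Filter(Negate(is.null), per_seq)
  matches <- if (length(per_seq)) {
    do.call(rbind, c(per_seq, list(make.row.names = FALSE)))
  } else {
    data.frame(seq_id = character(0), motif = character(0),
               start = integer(0), match = character(0),
               window = character(0), stringsAsFactors = FALSE)
  }
  pfms <- list()
  for (nm in names(motifs)) {
    wins <- matches$window[matches$motif == nm & !is.na(matches$window)]
    if (length(wins)) pfms[[nm]] <- build_pfm(wins)
  }
  list(matches = matches, pfms = pfms)
}
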