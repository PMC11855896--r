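# Shared fixtures, built in code at test time.

# A random peptide over the 20 standard residues.
random_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Write a GFF3 file from a data.frame of (seqid, type, start, end, id, parent).
write_gff_fixture <- function(rows, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t+\t.\t%s",
                     rows$seqid, rows$type, rows$start, rows$end,
                     ifelse(is.na(rows$parent),
                            sprintf("ID=%s", rows$id),
                            sprintf("ID=%s;Parent=%s", rows$id, rows$parent))))
  writeLines(lines, path)
  path
}

# Minimal one-gene fixture: gene 1-1000 with exons 1-300 and 801-1000.
one_gene_gff <- function() {
  write_gff_fixture(data.frame(
    seqid = "chr1", type = c("gene", "mRNA", "exon", "exon"),
    start = c(1L, 1L, 1L, 801L), end = c(1000L, 1000L, 300L, 1000L),
    id = c("g1", "g1.t1", "g1.t1.e1", "g1.t1.e2"),
    parent = c(NA, "g1", "g1.t1", "g1.t1"),
    stringsAsFactors = FALSE))
}

# A small cohort shared by several test files (10 genes per class).
small_cohort <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) {
      cfg <- cohort_config(seed = 42,
                           genes_per_class = c(stable = 10, labile = 10))
      bundle <<- generate_cohort(cfg, tempfile("small_cohort"))
    }
    bundle
  }
})

# Independent Needleman-Wunsch/Gotoh scoring oracle: gap of length L costs
# opening + L * extension, mirroring the conventions of the implementation
# under test but coded from scratch.
nw_affine_score <- function(a, b, open = 10, ext = 0.5) {
  sub <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  Fm <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) Fm[i + 1, 1] <- -(open + i * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], E[i, j], Fm[i, j]) + s
      E[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, E[i + 1, j] - ext)
      Fm[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Fm[i, j + 1] - ext)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], Fm[n + 1, m + 1])
}

# Exhaustive two-sided Mann-Whitney p by enumerating all rank assignments.
mw_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(n, nx)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mn <- nx * ny
  dev <- abs(us - mn / 2)
  mean(dev >= abs(u_obs - mn / 2))
}

# Exact null distribution of U by the counting recurrence (independent of
# stats::pwilcox): number of ways to reach rank-sum statistic u with m of
# m+n ranks.
mw_recurrence_p <- function(u_obs, m, n) {
  memo <- new.env(hash = TRUE)
  cnt <- function(u, m, n) {
    if (u < 0) return(0)
    if (m == 0) return(as.numeric(u == 0))
    if (n == 0) return(as.numeric(u == 0))
    key <- paste(u, m, n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- cnt(u - n, m - 1, n) + cnt(u, m, n - 1)
    memo[[key]] <- v
    v
  }
  total <- choose(m + n, m)
  probs <- vapply(0:(m * n), function(u) cnt(u, m, n), numeric(1)) / total
  dev <- abs(0:(m * n) - m * n / 2)
  sum(probs[dev >= abs(u_obs - m * n / 2)])
}
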