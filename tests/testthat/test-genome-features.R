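test_that("a minimal gene model parses with exact exon coordinates", {
  models <- parse_gene_models(one_gene_gff())
  expect_length(models, 1)
  g <- models$g1
  expect_equal(length(g$transcripts), 1)
  expect_equal(g$transcripts$g1.t1$exons,
               cbind(start = c(1L, 801L), end = c(300L, 1000L)))
})

test_that("multiple transcripts per gene are kept and counted", {
  path <- write_gff_fixture(data.frame(
    seqid = "chr1",
    type = c("gene", "mRNA", "exon", "mRNA", "exon"),
    start = c(1L, 1L, 1L, 1L, 1L),
    end = c(500L, 500L, 500L, 300L, 300L),
    id = c("g1", "g1.t1", "e1", "g1.t2", "e2"),
    parent = c(NA, "g1", "g1.t1", "g1", "g1.t2"),
    stringsAsFactors = FALSE))
  feats <- genomic_features(path)
  expect_equal(feats$n_transcripts, 2)
  expect_equal(feats$exon_length, 500)  # longest transcript wins
})

test_that("orphan exons are a format error naming the record", {
  path <- write_gff_fixture(data.frame(
    seqid = "chr1", type = c("gene", "mRNA", "exon", "exon"),
    start = c(1L, 1L, 1L, 10L), end = c(100L, 100L, 50L, 90L),
    id = c("g1", "g1.t1", "e1", "e2"),
    parent = c(NA, "g1", "g1.t1", "ghost.tx"),
    stringsAsFactors = FALSE))
  expect_error(parse_gene_models(path), "orphan exon.*e2")
})

test_that("the representative transcript maximises exon total with id tie-break", {
  gene <- list(gene_id = "g", start = 1L, end = 5000L, transcripts = list(
    tB = list(tx_id = "tB", exons = cbind(start = 1L, end = 900L)),
    tA = list(tx_id = "tA", exons = cbind(start = c(1L, 1001L),
                                          end = c(700L, 1800L)))
  ))
  expect_equal(select_representative(gene)$tx_id, "tA")  # 1500 beats 900

  gene$transcripts$tA$exons <- cbind(start = 1L, end = 900L)  # tie at 900
  expect_equal(select_representative(gene)$tx_id, "tA")  # lexicographic

  single <- list(transcripts = gene$transcripts["tB"])
  expect_equal(select_representative(single)$tx_id, "tB")
})

test_that("lengths are 1-based inclusive and intron = gene - exon", {
  models <- parse_gene_models(one_gene_gff())
  f <- compute_genomic_features(models$g1)
  expect_equal(f$gene_length, 1000)
  expect_equal(f$n_exons, 2)
  expect_equal(f$exon_length, 500)
  expect_equal(f$intron_length, 500)

  # single exon covering the gene: no intron
  path <- write_gff_fixture(data.frame(
    seqid = "c", type = c("gene", "mRNA", "exon"),
    start = 1L, end = 900L, id = c("g", "g.t", "g.e"),
    parent = c(NA, "g", "g.t"), stringsAsFactors = FALSE))
  f <- genomic_features(path)
  expect_equal(f$intron_length, 0)
  expect_equal(f$gene_length, 900)
})

test_that("GC content counts G+C over unambiguous bases only", {
  models <- parse_gene_models(one_gene_gff())
  g <- models$g1
  g$end <- 8L
  g$transcripts$g1.t1$exons <- cbind(start = 1L, end = 8L)
  expect_equal(compute_genomic_features(g, "GGCCAATT")$gc_percent, 50)
  expect_equal(compute_genomic_features(g, "GGCCAANN")$gc_percent,
               100 * 4 / 6)
  expect_true(is.na(compute_genomic_features(g)$gc_percent))
})

test_that("overlapping exons trigger the floored-intron warning", {
  gene <- list(gene_id = "g", start = 1L, end = 250L, transcripts = list(
    t1 = list(tx_id = "t1", exons = cbind(start = c(1L, 101L),
                                          end = c(150L, 250L)))))
  expect_warning(f <- compute_genomic_features(gene), "floored")
  expect_equal(f$intron_length, 0)
})

test_that("features computed on a generated cohort match the planted structure", {
  b <- small_cohort()
  feats <- genomic_features(b$paths$gff3, genome = b$paths$genome)
  expect_equal(nrow(feats), nrow(b$truth))
  expect_setequal(feats$gene_id, b$truth$gene_id)
  # additivity holds exactly for every gene
  expect_equal(feats$intron_length + feats$exon_length, feats$gene_length)
  expect_true(all(feats$intron_length >= 0))
  expect_true(all(feats$gc_percent > 20 & feats$gc_percent < 75))
})

test_that("the multi-transcript option exercises the longest-transcript rule", {
  cfg <- cohort_config(seed = 9, genes_per_class = c(stable = 6, labile = 6),
                       multi_transcript_rate = 1)
  b <- generate_cohort(cfg, tempfile())
  models <- parse_gene_models(b$paths$gff3)
  n_tx <- vapply(models, function(g) length(g$transcripts), numeric(1))
  expect_true(any(n_tx == 2))
  multi <- models[n_tx == 2]
  for (g in multi) {
    rep_tx <- select_representative(g)
    tot <- vapply(g$transcripts,
                  function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"] + 1L),
                  numeric(1))
    expect_equal(sum(rep_tx$exons[, "end"] - rep_tx$exons[, "start"] + 1L),
                 max(tot))
  }
})
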