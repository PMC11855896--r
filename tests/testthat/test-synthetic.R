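test_that("cohort record counts are conserved across all emitted files", {
  b <- small_cohort()   # 10 + 10 genes
  expect_equal(nrow(b$truth), 20)
  seqs <- Biostrings::readAAStringSet(b$paths$proteins)
  expect_length(seqs, 20)
  models <- parse_gene_models(b$paths$gff3)
  expect_length(models, 20)
  genome <- Biostrings::readDNAStringSet(b$paths$genome)
  expect_length(genome, 20)
  ortho <- read_ortholog_table(b$paths$orthologs)
  expect_setequal(ortho$gene_id, b$truth$gene_id)
  expect_equal(anyDuplicated(b$truth$gene_id), 0)
})

test_that("the same configuration produces byte-identical bundles", {
  cfg <- cohort_config(seed = 99, genes_per_class = c(stable = 6, labile = 6))
  b1 <- generate_cohort(cfg, tempfile())
  b2 <- generate_cohort(cfg, tempfile())
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     label = nm)
  }
  b3 <- generate_cohort(cohort_config(seed = 100,
                                      genes_per_class = c(stable = 6, labile = 6)),
                        tempfile())
  expect_false(identical(readLines(b1$paths$proteins),
                         readLines(b3$paths$proteins)))
})

test_that("labile proteins carry the fixed haem consensus verbatim", {
  b <- small_cohort()
  seqs <- as.character(Biostrings::readAAStringSet(b$paths$proteins))
  lab <- seqs[b$truth$gene_id[b$truth$class == "labile"]]
  expect_true(all(grepl("PFSAGPRNCIGQRFA", lab, fixed = TRUE)))
})

test_that("sample_protein honours degenerate compositions and plants motifs", {
  comp <- setNames(c(100, rep(0, 19)), cypstab:::AA20)
  withr::with_seed(1, {
    s <- sample_protein(comp, 50)
    expect_equal(s, strrep("A", 50))
    # a planted haem window is the only match the scanner finds
    s <- sample_protein(comp, 200, c(haem = "PFSAGPRNCIGQRFA"))
    hits <- scan_motif(s, "haem")
    expect_equal(nrow(hits), 1)
    expect_equal(hits$start, floor(0.88 * 200) + 1)
  })
  expect_error(withr::with_seed(1, sample_protein(comp, 10,
                                                  c(haem = "PFSAGPRNCIGQRFA"))),
               "too short")
  expect_error(sample_protein(comp * 2, 50), "sum to 100")
})

test_that("matched-mode composition tracks the target closely", {
  comp <- aa_scales()$hydropathy  # just for names
  target <- setNames(rep(5, 20), names(comp))
  withr::with_seed(2, {
    s <- sample_protein(target, 400)
    f <- residue_composition(s)
    expect_true(all(abs(f[cypstab:::AA20] - 5) < 0.5))
  })
})

test_that("stable cohorts have higher mean Leu than labile cohorts", {
  cfg <- cohort_config(seed = 1, genes_per_class = c(stable = 50, labile = 50))
  b <- generate_cohort(cfg, tempfile())
  seqs <- as.character(Biostrings::readAAStringSet(b$paths$proteins))
  leu <- vapply(seqs, function(s) residue_composition(s)[["L"]], numeric(1))
  cls <- b$truth$class[match(names(seqs), b$truth$gene_id)]
  expect_gt(mean(leu[cls == "stable"]), mean(leu[cls == "labile"]))
})

test_that("gene models are additive and hit the GC target", {
  withr::with_seed(3, {
    m <- sample_gene_model(1, 900, integer(0), gc = 0.5)
    expect_equal(m$gene_length, 900)
    m <- sample_gene_model(2, c(300, 200), 500, gc = 0.5)
    expect_equal(m$gene_length, 1000)
    expect_equal(m$exons, cbind(start = c(1L, 801L), end = c(300L, 1000L)))
    m <- sample_gene_model(1, 10000, integer(0), gc = 0.45)
    bases <- strsplit(m$sequence, "")[[1]]
    expect_lt(abs(mean(bases %in% c("G", "C")) - 0.45), 0.02)
  })
  expect_error(sample_gene_model(2, c(300, -5), 100, gc = 0.5), "positive")
  expect_error(sample_gene_model(2, c(300, 200), c(500, 100), gc = 0.5))
})

test_that("invalid class compositions are a configuration error", {
  bad <- default_comp <- cypstab:::default_composition_targets()
  bad["stable", "A"] <- bad["stable", "A"] + 5
  expect_error(cohort_config(composition = bad), "sum to 100")
  expect_error(cohort_config(genes_per_class = c(stable = 0, labile = 10)))
})

test_that("null cohorts share identical class targets", {
  cfg <- cohort_config(seed = 5, null_cohort = TRUE)
  expect_equal(cfg$composition["stable", ], cfg$composition["labile", ])
  expect_equal(cfg$genomic$stable, cfg$genomic$labile)
  expect_equal(cfg$term_proportions$stable, cfg$term_proportions$labile)
})

test_that("declared null residues get equal targets while designed contrasts remain", {
  cfg <- cohort_config(seed = 5)
  comp <- cfg$composition
  for (r in intersect(cfg$null_features, colnames(comp))) {
    expect_equal(comp["stable", r], comp["labile", r])
  }
  expect_gt(comp["stable", "L"], comp["labile", "L"])
  expect_lt(comp["stable", "K"], comp["labile", "K"])
  expect_equal(unname(rowSums(comp)), c(100, 100), tolerance = 1e-9)
})
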