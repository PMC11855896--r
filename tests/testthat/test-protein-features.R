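test_that("residue composition is exact on simple sequences and sums to 100", {
  f <- residue_composition("AAAA")
  expect_equal(unname(f["A"]), 100)
  expect_equal(sum(f), 100)

  f <- residue_composition("ACDE")
  expect_equal(unname(f[c("A", "C", "D", "E")]), rep(25, 4))

  withr::local_seed(101)
  for (i in 1:20) {
    s <- random_peptide(sample(5:400, 1))
    expect_equal(sum(residue_composition(s)), 100, tolerance = 1e-12)
  }
})

test_that("residue composition rejects bad input with a useful message", {
  expect_error(residue_composition(""), "empty")
  expect_error(residue_composition("ACDJ"), "'J' at position 4")
})

test_that("category frequencies follow the nine overlapping Pepstats sets", {
  f <- category_frequencies("ILV")
  expect_equal(unname(f["aliphatic"]), 100)
  expect_equal(unname(f["aromatic"]), 0)

  f <- category_frequencies("DEHK")
  expect_equal(unname(f[c("polar", "charged", "acidic", "basic")]),
               c(100, 100, 50, 50))
})

test_that("polar and non-polar percentages are complementary on standard residues", {
  withr::local_seed(7)
  for (i in 1:50) {
    f <- category_frequencies(random_peptide(sample(3:200, 1)))
    expect_equal(unname(f["polar"] + f["nonpolar"]), 100, tolerance = 1e-9)
  }
})

test_that("hydrophobicity hits the scale extremes and the uniform closed form", {
  expect_equal(kd_hydrophobicity("IIII"), 450)
  expect_equal(kd_hydrophobicity("RRRR"), -450)
  # uniform 5% of every residue: H = 5 * sum of the published index values
  kd <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
          1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  uniform <- paste(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   collapse = "")
  expect_equal(kd_hydrophobicity(uniform), 5 * sum(kd), tolerance = 1e-9)
})

test_that("hydrophobicity is permutation invariant and equals 100x GRAVY", {
  withr::local_seed(11)
  for (i in 1:10) {
    s <- random_peptide(60)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(kd_hydrophobicity(s), kd_hydrophobicity(perm))
    # independent GRAVY: mean per-residue hydropathy
    kd <- aa_scales()$hydropathy
    gravy <- mean(kd[strsplit(s, "")[[1]]])
    expect_equal(kd_hydrophobicity(s) / 100, gravy, tolerance = 1e-9)
  }
})

test_that("hydrophobicity excludes ambiguity codes with a warning", {
  expect_warning(h <- kd_hydrophobicity("IIIIX"), "ambiguous")
  expect_equal(h, 450)
  expect_error(suppressWarnings(kd_hydrophobicity("XXX")), "no standard")
})

test_that("molecular weight follows the average-mass table plus one water", {
  expect_equal(molecular_weight("G"), 57.0519 + 18.01524, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 2 * 57.0519 + 18.01524, tolerance = 1e-4)
  # additivity: concatenation loses one water
  withr::local_seed(3)
  s1 <- random_peptide(30); s2 <- random_peptide(45)
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) - 18.01524,
               tolerance = 1e-9)
  # B is the N/D average
  expect_equal(molecular_weight("B"),
               (molecular_weight("N") + molecular_weight("D")) / 2,
               tolerance = 1e-9)
})

test_that("net charge sums the Pepstats charge table", {
  expect_equal(net_charge("KRDE"), 0)
  expect_equal(net_charge("KKH"), 2.5)
  expect_equal(net_charge("AGSTNQ"), 0)
  expect_equal(net_charge("BZ"), -1)
  expect_equal(net_charge("KKKK", mean = TRUE), 1)
})

test_that("isoelectric point matches the two-group closed form and is monotone in Lys", {
  # only termini ionize: pI = (pKa_N + pKa_C) / 2
  expect_equal(isoelectric_point("AAAA"), (8.6 + 3.6) / 2, tolerance = 0.01)
  withr::local_seed(5)
  s <- random_peptide(40)
  pis <- vapply(0:4, function(k) {
    isoelectric_point(paste0(s, strrep("K", k)))
  }, numeric(1))
  expect_true(all(diff(pis) >= -1e-6))
})

test_that("bisection pI agrees with a fine grid scan", {
  withr::local_seed(17)
  grid <- seq(0, 14, by = 0.001)
  for (i in 1:10) {
    s <- random_peptide(sample(10:60, 1))
    pi_bis <- isoelectric_point(s)
    counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(strsplit(s, "")[[1]] == a), numeric(1))
    pka <- aa_scales()$pka
    ch <- vapply(grid, function(ph) cypstab:::hh_charge(ph, counts, pka),
                 numeric(1))
    pi_grid <- grid[which.min(abs(ch))]
    expect_lt(abs(pi_bis - pi_grid), 0.01)
  }
})

test_that("the feature table carries the 13 properties and 20 residues per sequence", {
  seqs <- c(p1 = "MKTLLVAGGHE", p2 = "WWRRCCAAGG")
  tab <- protein_features(seqs)
  expect_equal(nrow(tab), 2)
  expect_true(all(protein_property_family() %in% names(tab)))
  expect_true(all(residue_family() %in% names(tab)))
  expect_equal(tab$length, c(11, 10))
  expect_equal(tab$seq_id, c("p1", "p2"))
})
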