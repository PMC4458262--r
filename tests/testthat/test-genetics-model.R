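# Exact two-locus duplicate-recessive model.

test_that("phenotype rule: sterile iff homozygous recessive at both loci", {
  expect_equal(phenotype_from_genotype(two_locus_genotype("ms5ms5",
                                                          "ms6ms6")), 0L)
  expect_equal(phenotype_from_genotype(two_locus_genotype("Ms5ms5",
                                                          "ms6ms6")), 1L)
  expect_equal(phenotype_from_genotype(two_locus_genotype("Ms5Ms5",
                                                          "Ms6Ms6")), 1L)
  # all 9 classes: only the double recessive is sterile
  ph <- vapply(all_9 <- gmshap:::all_two_locus_genotypes(),
               phenotype_from_genotype, 0L)
  expect_equal(sum(ph == 0L), 1L)
  expect_equal(format(all_9[[which(ph == 0L)]]), "ms5ms5ms6ms6")
})

test_that("genotypes are unordered and malformed input is rejected", {
  expect_identical(two_locus_genotype("aA", "aa"),
                   two_locus_genotype("Aa", "aa"))
  expect_identical(format(two_locus_genotype("ms5Ms5", "Ms6ms6")),
                   "Ms5ms5Ms6ms6")
  expect_error(two_locus_genotype("AaA", "aa"), "malformed")
  expect_error(two_locus_genotype("Ab", "aa"), "malformed")
  expect_error(two_locus_genotype(3, 0), "dosage")
})

test_that("cross distributions are exact and match gamete-pair oracle", {
  # dihybrid self: P(sterile) = 1/16 exactly
  d <- cross_genotype_distribution(two_locus_genotype(1, 1))
  expect_identical(d$num[3, 3] * 16L %/% d$den, 1L)
  expect_identical(sum(d$num), d$den)
  # fertile x sterile with one segregating locus: P(sterile) = 1/2
  s <- gmshap:::sterile_probability(two_locus_genotype(1, 2),
                                    two_locus_genotype(2, 2))
  expect_equal(s[1] / s[2], 0.5)
  # fixed recessive: P(sterile) = 1
  s <- gmshap:::sterile_probability(two_locus_genotype(2, 2),
                                    two_locus_genotype(2, 2))
  expect_equal(s[1] / s[2], 1)
  # equivalence with brute-force 4x4 gamete-pair enumeration, all 81 pairs
  for (a1 in 0:2) for (b1 in 0:2) for (a2 in 0:2) for (b2 in 0:2) {
    d <- cross_genotype_distribution(two_locus_genotype(a1, b1),
                                     two_locus_genotype(a2, b2))
    expect_equal(d$num / d$den, unname(brute_cross_dist(c(a1, b1),
                                                        c(a2, b2))),
                 tolerance = 0, ignore_attr = TRUE)
  }
})

test_that("expected segregation ratios match the classic outcomes", {
  expect_identical(format(expected_segregation(two_locus_genotype(1, 1))),
                   "15:1")
  expect_identical(format(expected_segregation(two_locus_genotype(1, 2))),
                   "3:1")
  expect_identical(format(expected_segregation(two_locus_genotype(2, 1))),
                   "3:1")
  expect_identical(
    format(expected_segregation(two_locus_genotype(1, 2),
                                two_locus_genotype(2, 2))), "1:1")
  expect_identical(format(expected_segregation(two_locus_genotype(0, 0))),
                   "1:0")
})

test_that("segregation ratio equals the phenotype marginal of the cross", {
  gts <- gmshap:::all_two_locus_genotypes()
  for (g1 in gts) for (g2 in gts) {
    d <- cross_genotype_distribution(g1, g2)
    st <- d$num[3, 3]
    r <- expected_segregation(g1, g2)
    expect_equal(r[["sterile"]] / sum(r), st / d$den)
  }
})

test_that("no fertile x fertile cross exceeds 1/4 expected steriles", {
  gts <- Filter(function(g) phenotype_from_genotype(g) == 1L,
                gmshap:::all_two_locus_genotypes())
  worst <- 0
  for (g1 in gts) for (g2 in gts) {
    s <- gmshap:::sterile_probability(g1, g2)
    worst <- max(worst, s[1] / s[2])
  }
  expect_lte(worst, 1 / 4)
})
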