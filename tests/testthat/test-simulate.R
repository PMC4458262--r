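# Meiosis, crossing schemes, breeding design, panel and noise.

test_that("recombination follows the Haldane map function", {
  map <- marker_map(data.frame(
    name = c("ms5", "m0", "m10", "m200"), chromosome = "A12",
    pos_cM = c(10, 10 + 1e-9, 20, 220),
    allele1 = c("Ms", "C", "C", "C"), allele2 = c("ms", "T", "T", "T"),
    recessive_linked = c("ms", "T", "T", "T"),
    type = c("causal", "marker", "marker", "marker")))
  map <- marker_map(rbind(as.data.frame(unclass(map)),
    data.frame(name = "ms6", chromosome = "D12", pos_cM = 0,
               allele1 = "Ms", allele2 = "ms", recessive_linked = "ms",
               type = "causal")))
  founders <- gmshap:::scheme_founders(map)
  f1 <- make_cross(founders$donor, founders$fertile, n = 1,
                   scheme = "cross")
  set.seed(401)
  g <- simulate_gametes(f1, rep(1L, 1e5))[["A12"]]
  loci <- gmshap:::chrom_loci(map, "A12")
  i_causal <- which(loci$name == "ms5")
  # ~0 cM: always co-inherited
  expect_equal(mean(g[, i_causal] != g[, which(loci$name == "m0")]), 0)
  # 10 cM: recombinant fraction matches the closed form within 3 binomial SE
  r10 <- gmshap:::inverse_map_distance(10)
  obs <- mean(g[, i_causal] != g[, which(loci$name == "m10")])
  expect_lt(abs(obs - r10), 3 * sqrt(r10 * (1 - r10) / 1e5))
  # 200 cM: co-inheritance probability approaches 1/2
  obs <- mean(g[, i_causal] != g[, which(loci$name == "m200")])
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 1e5) + 0.01)
})

test_that("crosses reproduce exact Mendelian expectations", {
  map <- default_marker_map()
  founders <- gmshap:::scheme_founders(map)
  f1 <- make_cross(founders$donor, founders$fertile, n = 2,
                   scheme = "cross")
  expect_true(all(true_genotypes(f1) == 1L))  # F1 is AaBb
  set.seed(402)
  f2 <- make_cross(f1, n = 2e4, scheme = "self")
  # sterile fraction ~ 1/16
  p <- 1 / 16
  expect_lt(abs(mean(f2$phenotype == 0L) - p),
            3 * sqrt(p * (1 - p) / 2e4))
  # genotype frequencies match the exact cross distribution (chi-square GOF)
  tg <- true_genotypes(f2)
  obs <- table(factor(tg[, 1], 0:2), factor(tg[, 2], 0:2))
  d <- cross_genotype_distribution(two_locus_genotype(1, 1))
  expect_gt(stats::chisq.test(as.vector(obs),
                              p = as.vector(d$num / d$den))$p.value,
            0.001)
  # fertile x sterile sibcross with one segregating locus: ~1:1
  subset <- gmshap:::subset_population
  aabb <- which(tg[, 1] == 2L & tg[, 2] == 2L)[1]
  Aabb <- which(tg[, 1] == 1L & tg[, 2] == 2L)[1]
  sc <- make_cross(subset(f2, aabb), subset(f2, Aabb), n = 1e4,
                   scheme = "sibcross")
  expect_lt(abs(mean(sc$phenotype == 0L) - 0.5), 4 * sqrt(0.25 / 1e4))
})

test_that("selfing rules and empty crosses behave per contract", {
  map <- default_marker_map()
  founders <- gmshap:::scheme_founders(map)
  expect_error(make_cross(founders$donor, n = 5, scheme = "self"),
               "sterile")
  empty <- make_cross(founders$fertile, n = 0, scheme = "self")
  expect_equal(length(empty$id), 0L)
})

test_that("offspring alleles always trace to a parental haplotype", {
  map <- default_marker_map()
  set.seed(403)
  panel <- simulate_diversity_panel(map, n = 60, target_steriles = 9,
                                    n_founders = 20)
  # with biallelic coding, conservation means: no allele index outside 1:2
  # and, for a homozygous-parent cross, offspring fixed at that allele
  founders <- gmshap:::scheme_founders(map)
  off <- make_cross(founders$fertile, founders$fertile, n = 50,
                    scheme = "cross")
  for (chr in names(off$hap)) {
    fr <- founders$fertile$hap[[chr]]$h1[1, ]
    expect_true(all(t(off$hap[[chr]]$h1) == fr))
    expect_true(all(t(off$hap[[chr]]$h2) == fr))
  }
  expect_true(all(vapply(panel$hap, function(h)
    all(h$h1 %in% 1:2) && all(h$h2 %in% 1:2), TRUE)))
})

test_that("markers co-located with the causal loci recover true genotypes", {
  map <- default_marker_map(tight_offsets = c(-1e-9, 1e-9))
  set.seed(404)
  panel <- simulate_diversity_panel(map, n = 200, target_steriles = 31,
                                    background_single_freq = 0)
  calls <- genotype_calls(panel)
  tg <- true_genotypes(panel)
  rule <- published_gms_rule()
  dos5 <- recessive_encode(calls[, "MOGH583971"], "T")
  dos6 <- recessive_encode(calls[, "MOGH211275"], "C")
  expect_equal(dos5, as.integer(tg[, "ms5"] == 2L), ignore_attr = TRUE)
  expect_equal(dos6, as.integer(tg[, "ms6"] == 2L), ignore_attr = TRUE)
  conf <- evaluate_ruleset(rule, calls, panel$phenotype, map = map)
  expect_equal(conf$accuracy, 1)
})

test_that("the breeding scheme yields the expected family structure", {
  cfg <- sim_config(seed = 405, n_f2 = 150, n_sibcross_f2 = 60)
  sim <- simulate_breeding_scheme(cfg)
  # sibcross-F2 families: expected ratio of the selfed parent is one of
  # 3:1, 15:1 or all-fertile
  ratios <- vapply(sim$sibcross_f2, function(fam) {
    pg <- attr(fam, "parent_genotype")
    format(expected_segregation(two_locus_genotype(pg[1], pg[2])))
  }, "")
  expect_true(all(ratios %in% c("3:1", "15:1", "1:0")))
  # determinism: identical config, identical byte-level outputs
  sim2 <- simulate_breeding_scheme(cfg)
  expect_identical(sim$panel_calls, sim2$panel_calls)
  expect_identical(true_genotypes(sim$f2), true_genotypes(sim2$f2))
})

test_that("panel sterile count concentrates around the calibrated target", {
  set.seed(406)
  counts <- replicate(5, {
    p <- simulate_diversity_panel(default_marker_map())
    sum(p$phenotype == 0L)
  })
  # 99% binomial band around the 164/1044 target, widened for the extra
  # variance contributed by sampling the finite founder pool
  band <- stats::qbinom(c(0.005, 0.995), 1044, 164 / 1044)
  expect_true(all(counts >= band[1] - 15 & counts <= band[2] + 15))
  expect_lt(abs(mean(counts) - 164), 20)
})

test_that("genotyping noise matches its nominal rates", {
  map <- default_marker_map()
  set.seed(407)
  panel <- simulate_diversity_panel(map, n = 400, target_steriles = 63)
  calls <- genotype_calls(panel)
  expect_identical(add_genotyping_noise(calls, map, 0, 0), calls)
  allmiss <- add_genotyping_noise(calls, map, 0, 1)
  expect_true(all(allmiss == "./."))
  noisy <- add_genotyping_noise(calls, map, 0.01, 0)
  ncorrupt <- sum(noisy != calls)
  ncalls <- length(calls)
  expect_lt(abs(ncorrupt - 0.01 * ncalls),
            3 * sqrt(0.01 * 0.99 * ncalls))
  # errors never introduce missing calls
  expect_false(any(noisy == "./."))
})
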