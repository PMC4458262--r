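# Recessive coding, single-marker scan, Fisher exact, cross-locus scan.

test_that("recessive encoding follows the monogenic recessive model", {
  calls <- c("T/T", "C/T", "C/C", "./.", NA)
  expect_equal(recessive_encode(calls, "T", c("C", "T")),
               c(1L, 0L, 0L, NA, NA))
  expect_error(recessive_encode(calls, "G", c("C", "T")),
               "not among the marker's alleles")
})

test_that("Fisher exact p equals brute-force enumeration and fisher.test", {
  # exhaustive over modest margins
  for (m1 in 0:12) for (m2 in 0:12) for (a in 0:m1) for (cc in 0:m2) {
    b <- m1 - a; d <- m2 - cc
    if (m1 + m2 == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d), brute_fisher(a, b, cc, d),
                 tolerance = 1e-12)
  }
  # spot checks against stats::fisher.test on larger tables
  set.seed(701)
  for (k in 1:100) {
    tab <- matrix(rpois(4, 20), 2, 2)
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1],
                                  tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # a diagnostic-scale table: enumeration matches brute-force summation
  expect_equal(fisher_exact_2x2(109, 17, 1, 769),
               brute_fisher(109, 17, 1, 769), tolerance = 1e-12)
})

test_that("Firth fit reduces to the add-half table estimate for 2x2", {
  # saturated single binary predictor: Firth = Haldane-Anscombe correction
  x <- rep(c(1, 0), c(40, 60))
  y <- c(rep(1, 38), rep(0, 2), rep(1, 3), rep(0, 57))
  f <- firth_logistic(x, y)
  tab <- table(x, y) + 0.5
  expect_equal(f$coef[2],
               log(tab["1", "1"] * tab["0", "0"] /
                     (tab["1", "0"] * tab["0", "1"])),
               tolerance = 1e-6, ignore_attr = TRUE)
  # separation: finite estimate, tiny p
  ysep <- as.numeric(x == 1)
  fs <- firth_logistic(x, ysep)
  expect_true(is.finite(fs$coef[2]))
  expect_lt(fs$p_value, 1e-10)
})

test_that("single-marker scan flags separation and ranks causal markers", {
  pn <- make_panel(702, n = 400, steriles = 63, error = 0)
  scan <- single_marker_scan(pn$calls, pn$panel$phenotype, map = pn$map)
  # a perfectly predictive marker separates; penalized p is extreme
  top <- scan[scan$marker %in% diagnostic_markers, ]
  expect_true(all(top$separation | top$p_value < 1e-10))
  expect_true(all(top$p_value < 1e-10))
  expect_true(all(top$method[top$separation] == "firth"))
  # diagnostic markers dominate the ranking; decoys are null
  expect_true(all(scan$marker[1:4] %in% diagnostic_markers))
  expect_gt(min(scan$p_value[!scan$marker %in% diagnostic_markers]), 1e-4)
  # recovered orientations are the published recessive-linked alleles
  expect_equal(scan$recessive_allele[match(diagnostic_markers,
                                           scan$marker)],
               c("T", "T", "C", "G"))
})

test_that("null markers yield uniform p-values", {
  set.seed(703)
  n <- 600
  y <- rbinom(n, 1, 0.8)
  ps <- replicate(300, {
    g <- paste(sample(c("A", "G"), n, TRUE), sample(c("A", "G"), n, TRUE),
               sep = "/")
    g <- paste0(pmin(substr(g, 1, 1), substr(g, 3, 3)), "/",
                pmax(substr(g, 1, 1), substr(g, 3, 3)))
    G <- matrix(g, ncol = 1, dimnames = list(NULL, "m"))
    single_marker_scan(G, y)$p_value
  })
  # two orientations tested per marker, best reported: p is conservative
  # in the far tail but should not be anti-conservative near 0
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("scan errors on degenerate phenotype and constant markers", {
  pn <- make_panel(704, n = 100, steriles = 16, error = 0)
  expect_error(single_marker_scan(pn$calls, rep(1L, 100)), "constant")
  G <- pn$calls
  G[, "synA12_01"] <- "A/A"
  expect_warning(single_marker_scan(G, pn$panel$phenotype),
                 "monomorphic")
})

test_that("ruleset evaluation matches its contracts on edge cases", {
  pn <- make_panel(705, n = 300, steriles = 47, error = 0)
  rule <- published_gms_rule()
  conf <- evaluate_ruleset(rule, pn$calls, pn$panel$phenotype,
                           map = pn$map)
  expect_equal(conf$TP + conf$FP + conf$TN + conf$FN +
                 conf$n_excluded_missing, 300)
  # permutation invariance
  set.seed(705)
  perm <- sample(300)
  conf2 <- evaluate_ruleset(rule, pn$calls[perm, ],
                            pn$panel$phenotype[perm], map = pn$map)
  expect_equal(conf[c("TP", "FP", "TN", "FN", "accuracy")],
               conf2[c("TP", "FP", "TN", "FN", "accuracy")])
  # duplicating a rule marker's data under a new name changes nothing
  G2 <- cbind(pn$calls, MOGH583971b = pn$calls[, "MOGH583971"])
  rule_dup <- haplotype_rule(ms5 = c(MOGH583971 = "T", MOGH582973 = "T",
                                     MOGH583971b = "T"),
                             ms6 = rule$ms6)
  conf3 <- evaluate_ruleset(rule_dup, G2, pn$panel$phenotype)
  expect_equal(conf[c("TP", "FP", "TN", "FN")],
               conf3[c("TP", "FP", "TN", "FN")])
  # degenerate margin: everything fertile -> sensitivity undefined (NA)
  Gf <- matrix(c("C/C", "C/C"), 2, 1,
               dimnames = list(NULL, "MOGH583971"))
  Gf <- cbind(Gf, MOGH582973 = "C/C", MOGH211275 = "G/G",
              MOGH493571 = "A/A")
  conf4 <- evaluate_ruleset(rule, Gf, c(1L, 1L))
  expect_equal(conf4$accuracy, 1)
  expect_true(is.na(conf4$sensitivity))
  # missing calls are excluded and counted
  Gm <- pn$calls
  Gm[1:10, "MOGH583971"] <- "./."
  confm <- evaluate_ruleset(rule, Gm, pn$panel$phenotype)
  expect_equal(confm$n_excluded_missing, 10)
})

test_that("cross-locus scan selects causal-flanking markers", {
  # noiseless with markers co-located with the causal loci: the top rule
  # is exactly perfect and uses only causal-flanking markers
  map0 <- default_marker_map(tight_offsets = c(-1e-9, 1e-9))
  pn <- make_panel(706, error = 0, map = map0)
  cand <- panel_candidates(pn$map)
  scan <- cross_locus_scan(pn$calls, pn$panel$phenotype,
                           cand$A12, cand$D12, map = pn$map)
  expect_true(all(rule_markers(scan$best) %in% diagnostic_markers))
  expect_equal(scan$best_confusion$accuracy, 1)
  expect_equal(scan$rules$accuracy[1], 1)
  # noiseless at the realistic sub-centimorgan spacing: near-perfect
  pn <- make_panel(706, error = 0)
  scan <- cross_locus_scan(pn$calls, pn$panel$phenotype,
                           cand$A12, cand$D12, map = pn$map)
  expect_true(all(rule_markers(scan$best) %in% diagnostic_markers))
  expect_gt(scan$best_confusion$accuracy, 0.995)
  # with 0.5% genotyping error the same structure wins, near-perfectly
  pn <- make_panel(707, error = 0.005)
  scan <- cross_locus_scan(pn$calls, pn$panel$phenotype,
                           cand$A12, cand$D12, map = pn$map)
  expect_true(all(rule_markers(scan$best) %in% diagnostic_markers))
  expect_gt(scan$best_confusion$accuracy, 0.98)
  # the two-markers-per-locus haplotype beats any single-marker rule
  best_single <- with(scan$rules, max(accuracy[n_markers == 2]))
  expect_gt(scan$best_confusion$accuracy, best_single)
})

test_that("scan validates inputs and enforces its combinatorial cap", {
  pn <- make_panel(708, n = 100, steriles = 16, error = 0)
  cand <- panel_candidates(pn$map)
  expect_error(cross_locus_scan(pn$calls, pn$panel$phenotype,
                                cand$A12, cand$A12), "disjoint")
  expect_error(cross_locus_scan(pn$calls, pn$panel$phenotype,
                                character(0), cand$D12), "non-empty")
  expect_error(cross_locus_scan(pn$calls, pn$panel$phenotype,
                                cand$A12, cand$D12, max_rules = 10),
               "max_rules")
})

test_that("scan accuracy degrades no faster than genotyping error", {
  # expected accuracy of the selected rule is non-increasing in the
  # genotyping error rate
  rates <- c(0, 0.01, 0.04)
  mean_acc <- sapply(rates, function(er) {
    mean(sapply(1:8, function(s) {
      pn <- make_panel(709 + s, n = 522, steriles = 82, error = er)
      cand <- panel_candidates(pn$map)
      cross_locus_scan(pn$calls, pn$panel$phenotype, cand$A12, cand$D12,
                       map = pn$map)$best_confusion$accuracy
    }))
  })
  expect_true(all(diff(mean_acc) <= 0.002))
})

test_that("rule indicator agrees between scan table and evaluate_ruleset", {
  pn <- make_panel(710, n = 300, steriles = 47, error = 0.01)
  cand <- panel_candidates(pn$map)
  scan <- cross_locus_scan(pn$calls, pn$panel$phenotype, cand$A12,
                           cand$D12, map = pn$map)
  top <- scan$rules[1, ]
  expect_equal(top$TP, scan$best_confusion$TP)
  expect_equal(top$FP, scan$best_confusion$FP)
  expect_equal(top$TN, scan$best_confusion$TN)
  expect_equal(top$FN, scan$best_confusion$FN)
  expect_equal(top$exact_test_p, scan$best_confusion$exact_test_p)
})
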