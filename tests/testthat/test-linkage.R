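# Two-point recombination estimation, map functions, anchor assignment.

test_that("map functions satisfy their closed forms and inequalities", {
  expect_equal(map_distance(0), 0)
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0.1), -50 * log(0.8))
  expect_equal(map_distance(0.1, "kosambi"), 25 * log(1.2 / 0.8))
  r <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(map_distance(r, "kosambi") < map_distance(r, "haldane")))
  # round trip to 1e-9
  for (mf in c("haldane", "kosambi"))
    expect_equal(inverse_map_distance(map_distance(r, mf), mf), r,
                 tolerance = 1e-9)
  expect_error(map_distance(0.5), "unlinked")
})

test_that("EM recovers the recombination fraction without material bias", {
  set.seed(601)
  for (r in c(0.05, 0.2)) {
    est <- replicate(20, {
      d <- sim_f2_pairs(r, 1000,
                        sample(c("coupling", "repulsion"), 1))
      estimate_rf_f2(d$a, d$b)$r_hat
    })
    expect_lt(abs(mean(est) - r), 0.01)
  }
})

test_that("EM boundary behaviour matches the likelihood", {
  # perfectly co-inherited markers: r = 0, maximal LOD for the sample
  a <- rep(0:2, c(25, 50, 25))
  fit <- estimate_rf_f2(a, a)
  expect_lt(fit$r_hat, 1e-6)
  expect_gt(fit$LOD, 20)
  # independent markers: r ~ 0.5, LOD ~ 0
  set.seed(602)
  d <- sim_f2_pairs(0.5, 1000)
  fit <- estimate_rf_f2(d$a, d$b)
  expect_gt(fit$r_hat, 0.45)
  expect_lt(fit$LOD, 2)
  # error contracts
  expect_error(estimate_rf_f2(rep(1, 50), rep(0:1, 25)), "monomorphic")
  expect_error(estimate_rf_f2(c(NA, NA), c(0, 1)), "missing")
})

test_that("EM matches an independent grid-search oracle", {
  set.seed(603)
  grid <- seq(0, 0.5, by = 0.001)
  for (k in 1:30) {
    r <- stats::runif(1, 0.02, 0.45)
    d <- sim_f2_pairs(r, 300, sample(c("coupling", "repulsion"), 1))
    em <- estimate_rf_f2(d$a, d$b)$r_hat
    ll <- vapply(grid, oracle_rf_loglik, 0, a = d$a, b = d$b)
    expect_lt(abs(em - grid[which.max(ll)]), 0.001 + 1e-9)
  }
})

test_that("Wald intervals achieve near-nominal coverage", {
  set.seed(604)
  hits <- replicate(200, {
    d <- sim_f2_pairs(0.2, 300)
    fit <- estimate_rf_f2(d$a, d$b)
    abs(fit$r_hat - 0.2) <= 1.96 * fit$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("pooled multi-family estimation resolves phase per family", {
  set.seed(605)
  a <- b <- integer(0); fam <- integer(0)
  for (f in 1:6) {
    d <- sim_f2_pairs(0.1, 150, if (f %% 2) "coupling" else "repulsion")
    a <- c(a, d$a); b <- c(b, d$b); fam <- c(fam, rep(f, 150))
  }
  pooled <- estimate_rf_f2(a, b, family = fam)
  expect_lt(abs(pooled$r_hat - 0.1), 0.03)
  # ignoring family structure would mix phases and inflate r toward 0.5
  naive <- estimate_rf_f2(a, b)
  expect_gt(naive$r_hat, pooled$r_hat)
})

test_that("all simulated markers are assigned to their true chromosome", {
  cfg <- sim_config(seed = 606)
  sim <- simulate_breeding_scheme(cfg)
  dos <- calls_to_dosage(sim$sibcross_f2_calls, cfg$map)
  asg <- assign_to_anchor(dos, default_anchors(),
                          family = attr(sim$sibcross_f2_calls, "family"))
  truth <- cfg$map$chromosome[match(asg$marker, cfg$map$name)]
  expect_equal(asg$chromosome, truth)
  # a marker identical to an anchor maps to that chromosome with r = 0
  self <- assign_to_anchor(dos, default_anchors(),
                           new_markers = "CS_A12",
                           family = attr(sim$sibcross_f2_calls, "family"))
  expect_equal(self$chromosome, "A12")
  expect_equal(self$r_hat, 0)
})

test_that("an unlinked background marker stays unassigned at LOD 3", {
  cfg <- sim_config(seed = 607)
  sim <- simulate_breeding_scheme(cfg)
  dos <- calls_to_dosage(sim$sibcross_f2_calls, cfg$map)
  set.seed(607)
  # background marker segregating independently of everything
  dos <- cbind(dos, BG = sample(0:2, nrow(dos), replace = TRUE,
                                prob = c(0.25, 0.5, 0.25)))
  asg <- assign_to_anchor(dos, default_anchors(), new_markers = "BG",
                          family = attr(sim$sibcross_f2_calls, "family"))
  expect_true(is.na(asg$chromosome))
})
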