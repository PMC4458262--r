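# Independent oracles and small fixtures shared across test files.

diagnostic_markers <- c("MOGH583971", "MOGH582973", "MOGH211275",
                        "MOGH493571")

# Brute-force two-locus cross oracle: enumerate all 4 x 4 gamete pairs of
# the two parents explicitly (alleles, not probabilities).  Independent of
# the package's per-locus rational arithmetic.
brute_gametes <- function(g) {
  # g: c(dosage_ms5, dosage_ms6); returns 4 rows of (rec_ms5, rec_ms6)
  a <- switch(g[1] + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  b <- switch(g[2] + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  as.matrix(expand.grid(a = a, b = b))
}

brute_cross_dist <- function(g1, g2) {
  G1 <- brute_gametes(g1)
  G2 <- brute_gametes(g2)
  counts <- matrix(0L, 3, 3)
  for (i in seq_len(nrow(G1))) for (j in seq_len(nrow(G2))) {
    d5 <- G1[i, "a"] + G2[j, "a"]
    d6 <- G1[i, "b"] + G2[j, "b"]
    counts[d5 + 1L, d6 + 1L] <- counts[d5 + 1L, d6 + 1L] + 1L
  }
  counts / 16
}

brute_sterile_prob <- function(g1, g2) brute_cross_dist(g1, g2)[3, 3]

# Simulate F2 dosage pairs by explicit meiosis of a double-heterozygous F1
# (haplotype strands + per-meiosis recombination), independent of the
# package's class-probability code.
sim_f2_pairs <- function(r, n, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  haps <- if (phase == "coupling") rbind(c(1L, 1L), c(0L, 0L))
  else rbind(c(1L, 0L), c(0L, 1L))
  gamete <- function() {
    s1 <- sample(1:2, n, replace = TRUE)
    s2 <- ifelse(stats::runif(n) < r, 3L - s1, s1)
    cbind(a = haps[s1, 1], b = haps[s2, 2])
  }
  g1 <- gamete(); g2 <- gamete()
  list(a = g1[, "a"] + g2[, "a"], b = g1[, "b"] + g2[, "b"])
}

# Independent F2 9-class probabilities from gamete frequencies.
oracle_f2_probs <- function(r, phase = "coupling") {
  rr <- if (phase == "repulsion") 1 - r else r
  p <- c((1 - rr) / 2, rr / 2, rr / 2, (1 - rr) / 2)  # AB, Ab, aB, ab
  da <- c(1L, 1L, 0L, 0L)
  db <- c(1L, 0L, 1L, 0L)
  P <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4)
    P[da[i] + da[j] + 1L, db[i] + db[j] + 1L] <-
      P[da[i] + da[j] + 1L, db[i] + db[j] + 1L] + p[i] * p[j]
  P
}

oracle_rf_loglik <- function(r, a, b) {
  N <- table(factor(a, 0:2), factor(b, 0:2))
  lc <- sum(N * log(pmax(oracle_f2_probs(r, "coupling"), 1e-300)))
  lr <- sum(N * log(pmax(oracle_f2_probs(r, "repulsion"), 1e-300)))
  m <- max(lc, lr)
  m + log(0.5 * exp(lc - m) + 0.5 * exp(lr - m))
}

# Brute-force two-sided Fisher exact p via factorial (lchoose) enumeration
# over all tables with the observed margins.
brute_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0, k - m2):min(k, m1)
  lp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  p <- exp(lp)
  obs <- p[x == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

panel_candidates <- function(map) {
  mk <- setdiff(map_marker_names(map), names(default_anchors()))
  split(mk, map$chromosome[match(mk, map$name)])
}

# One diversity panel + noisy calls, the study-scale configuration.
make_panel <- function(seed, n = 1044, steriles = 164, error = 0.005,
                       map = default_marker_map()) {
  set.seed(seed)
  panel <- simulate_diversity_panel(map, n = n, target_steriles = steriles)
  calls <- add_genotyping_noise(genotype_calls(panel), map, error, 0)
  list(panel = panel, calls = calls, map = map)
}
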