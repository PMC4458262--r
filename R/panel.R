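# Random-mating diversity panel seeded with GMS carrier haplotypes.
#
# The panel emulates an unstructured association-mapping population: a
# founder pool in which each chromosome haplotype is either a "carrier"
# haplotype (recessive causal allele with its diagnostic marker alleles in
# phase, the haplotype private to the GMS lineage) or a "wild" haplotype
# (dominant causal allele; diagnostic marker alleles appear singly at a
# background frequency, but the full in-phase diagnostic haplotype does
# not), followed by one round of random mating with meiotic recombination.
# Sterile plants participate only as seed parents.

# Carrier-gamete frequency c such that the expected sterile fraction of
# random-mating offspring (with fertile-only pollen parents) hits the
# target.  A sterile offspring needs recessive gametes at both loci from
# both parents: the maternal side contributes c^2 (loci independent,
# mothers unconditioned); the paternal side contributes
# E[g5 g6 | fertile] = (c^2 - c^4)/(1 - c^4) (fertility conditioning
# correlates the father's two loci), giving
# P(sterile) = c^4 / (1 + c^2), inverted in closed form.
calibrate_carrier_freq <- function(target_fraction) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  t <- target_fraction
  sqrt((t + sqrt(t^2 + 4 * t)) / 2)
}

#' Simulate an unstructured diversity panel segregating for GMS
#'
#' Generates \code{n} individuals by one round of random mating over a
#' founder gamete pool in which each chromosome haplotype is a GMS-carrier
#' haplotype with probability \code{carrier_freq} (calibrated so the
#' expected number of steriles equals \code{target_steriles}) and a wild
#' haplotype otherwise.  Wild haplotypes carry each diagnostic marker's
#' recessive-linked allele at frequency \code{background_single_freq}, but
#' at most one of a locus's diagnostic markers per haplotype: individual
#' SNP alleles are shared with diverse germplasm while the in-phase
#' multi-marker haplotype is private to the carrier lineage (the premise
#' that makes the haplotype, not any single SNP, diagnostic).  Neutral
#' (decoy) markers segregate at frequency \code{decoy_freq} independently
#' of carrier status.  Pollen parents are restricted to fertile founders.
#'
#' @param map A \code{\link{marker_map}} with one causal locus per
#'   chromosome carrying diagnostic markers.
#' @param n Panel size (default 1044).
#' @param target_steriles Expected number of sterile individuals
#'   (default 164).
#' @param background_single_freq Frequency of a single diagnostic
#'   recessive-linked allele on wild haplotypes (default 0.15).
#' @param decoy_freq Allele-2 frequency at neutral markers (default 0.5).
#' @param n_founders Founder-pool size (default 400).
#' @param map_function Map function for meiosis.
#' @return A population (class \code{"gms_population"}).
#' @export
simulate_diversity_panel <- function(map, n = 1044, target_steriles = 164,
                                     background_single_freq = 0.15,
                                     decoy_freq = 0.5, n_founders = 400,
                                     map_function = "haldane") {
  stopifnot(inherits(map, "gms_map"), target_steriles < n)
  cfreq <- calibrate_carrier_freq(target_steriles / n)
  chrs <- unique(map$chromosome)

  draw_haplotypes <- function(m) {
    # m haplotypes per chromosome, returned as list of m x L matrices
    out <- list()
    for (chr in chrs) {
      loci <- chrom_loci(map, chr)
      L <- nrow(loci)
      h <- matrix(1L, m, L)
      carrier <- stats::runif(m) < cfreq
      diag_idx <- which(loci$type == "marker" & !is.na(loci$recessive_linked))
      causal_idx <- which(loci$type == "causal")
      rl_idx2 <- function(j)  # allele index of the recessive-linked allele
        ifelse(loci$recessive_linked[j] == loci$allele2[j], 2L, 1L)
      other_idx2 <- function(j) 3L - rl_idx2(j)
      # carrier haplotypes: recessive causal + full diagnostic haplotype
      if (length(causal_idx)) h[carrier, causal_idx] <- 2L
      for (j in diag_idx) {
        h[carrier, j] <- rl_idx2(j)
        h[!carrier, j] <- other_idx2(j)
      }
      # wild haplotypes: at most one diagnostic rec-linked allele per locus
      wild <- which(!carrier)
      if (length(diag_idx) && length(wild)) {
        k <- length(diag_idx)
        # pick: 0 = none, 1..k = that diagnostic marker carries the allele
        pr <- c(1 - k * background_single_freq,
                rep(background_single_freq, k))
        if (pr[1] < 0)
          stop("background_single_freq too large for ", k,
               " diagnostic markers", call. = FALSE)
        pick <- sample.int(k + 1L, length(wild), replace = TRUE,
                           prob = pr) - 1L
        for (jj in seq_len(k)) {
          j <- diag_idx[jj]
          h[wild[pick == jj], j] <- rl_idx2(j)
        }
      }
      # neutral markers: independent background frequencies
      neut_idx <- which(loci$type == "marker" & is.na(loci$recessive_linked))
      for (j in neut_idx)
        h[stats::runif(m) < decoy_freq, j] <- 2L
      out[[chr]] <- h
    }
    out
  }

  fh1 <- draw_haplotypes(n_founders)
  fh2 <- draw_haplotypes(n_founders)
  founders <- new_population(
    map,
    hap = stats::setNames(lapply(chrs, function(chr)
      list(h1 = fh1[[chr]], h2 = fh2[[chr]])), chrs),
    phenotype = rep(1L, n_founders),
    id = sprintf("FND_%04d", seq_len(n_founders)))
  founders$phenotype <- assign_phenotype(founders, penetrance = 1)

  make_cross(founders, founders, n = n, scheme = "cross",
             map_function = map_function, id_prefix = "PNL")
}
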