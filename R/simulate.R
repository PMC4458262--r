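# Meiosis, crossing schemes, the full breeding design, and genotyping noise.

#' Genetic map functions
#'
#' Convert a recombination fraction to a map distance in centimorgans
#' (\code{map_distance}) or back (\code{inverse_map_distance}).  Haldane
#' assumes no crossover interference, d = -50 ln(1 - 2r); Kosambi models
#' partial interference, d = 25 ln((1 + 2r) / (1 - 2r)).
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @param d Map distance(s) in cM.
#' @param map_function \code{"haldane"} (default) or \code{"kosambi"}.
#' @return Numeric vector of distances (cM) or recombination fractions.
#' @examples
#' map_distance(0.1)                      # 11.157 cM
#' inverse_map_distance(map_distance(0.1))  # 0.1
#' @export
map_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5); r = 0.5 is unlinked",
         call. = FALSE)
  switch(map_function,
         haldane = -50 * log1p(-2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname map_distance
#' @export
inverse_map_distance <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop("map distance must be non-negative", call. = FALSE)
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * d / 100)),
         kosambi = 0.5 * tanh(d / 50))
}

# Recombination fractions of the adjacent intervals of a chromosome's loci.
interval_rf <- function(pos, map_function = "haldane") {
  if (length(pos) < 2) return(numeric(0))
  inverse_map_distance(diff(pos), map_function)
}

#' Simulate gametes from a population
#'
#' One meiosis per selected parent and chromosome: the transmitted haplotype
#' starts on a random parental strand and switches strand in each adjacent
#' marker interval with probability equal to the interval's recombination
#' fraction (inverse map function of the cM gap; no interference under the
#' Haldane default).
#'
#' @param pop A simulated population.
#' @param parents Integer vector of parent row indices, one gamete per entry.
#' @param map_function Map function used to turn cM gaps into recombination
#'   fractions.
#' @return A named list (per chromosome) of integer allele-index matrices,
#'   one row per gamete.
#' @export
simulate_gametes <- function(pop, parents, map_function = "haldane") {
  n <- length(parents)
  out <- list()
  for (chr in names(pop$hap)) {
    loci <- chrom_loci(pop$map, chr)
    L <- nrow(loci)
    rf <- interval_rf(loci$pos_cM, map_function)
    h1 <- pop$hap[[chr]]$h1[parents, , drop = FALSE]
    h2 <- pop$hap[[chr]]$h2[parents, , drop = FALSE]
    # strand index per locus: cumulative XOR of interval crossovers
    start <- stats::runif(n) < 0.5
    if (L > 1) {
      co <- matrix(stats::runif(n * (L - 1)), n, L - 1) <
        matrix(rf, n, L - 1, byrow = TRUE)
      strand <- (matrix(start, n, L) +
                   cbind(0L, t(apply(co, 1L, cumsum)))) %% 2L
    } else {
      strand <- matrix(as.integer(start), n, 1L)
    }
    g <- ifelse(strand == 0L, h1, h2)
    out[[chr]] <- matrix(as.integer(g), n, L)
  }
  out
}

unite_gametes <- function(map, g_mat, g_pat, phenotype_fun, ids) {
  hap <- list()
  for (chr in names(g_mat)) hap[[chr]] <- list(h1 = g_mat[[chr]],
                                               h2 = g_pat[[chr]])
  pop <- new_population(map, hap, phenotype = rep(1L, nrow(g_mat[[1]])),
                        id = ids)
  pop$phenotype <- phenotype_fun(pop)
  pop
}

#' Cross or self individuals of simulated populations
#'
#' Forms \code{n} offspring from independently simulated gametes.  For
#' \code{scheme = "self"} every offspring takes both gametes from one parent
#' drawn from \code{mothers}, which must all be fertile (a sterile plant has
#' no viable pollen and cannot self).  For \code{"cross"} and
#' \code{"sibcross"} the seed parent is drawn from \code{mothers} (sterile
#' plants are admissible seed parents -- that is the point of genetic male
#' sterility) and the pollen parent from \code{fathers}, which must be
#' fertile.
#'
#' @param mothers,fathers Populations (\code{fathers} ignored for selfing).
#' @param n Number of offspring.
#' @param scheme \code{"cross"}, \code{"self"} or \code{"sibcross"}.
#' @param penetrance Probability that the sterile genotype expresses
#'   sterility (default 1, full penetrance).
#' @param map_function Map function for meiosis.
#' @param id_prefix Prefix for offspring identifiers.
#' @return A new population of size \code{n}.
#' @export
make_cross <- function(mothers, fathers = NULL, n,
                       scheme = c("cross", "self", "sibcross"),
                       penetrance = 1, map_function = "haldane",
                       id_prefix = "ind") {
  scheme <- match.arg(scheme)
  stopifnot(n >= 0)
  if (n == 0)
    return(new_population(mothers$map,
                          lapply(mothers$hap, function(h)
                            list(h1 = h$h1[0, , drop = FALSE],
                                 h2 = h$h2[0, , drop = FALSE])),
                          integer(0), character(0)))
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n))
  phf <- function(pop) assign_phenotype(pop, penetrance)
  if (scheme == "self") {
    if (any(mothers$phenotype == 0L))
      stop("cannot self a sterile individual: no viable pollen",
           call. = FALSE)
    par <- sample.int(pop_size(mothers), n, replace = TRUE)
    g1 <- simulate_gametes(mothers, par, map_function)
    g2 <- simulate_gametes(mothers, par, map_function)
    return(unite_gametes(mothers$map, g1, g2, phf, ids))
  }
  if (is.null(fathers))
    stop("a ", scheme, " needs a pollen-parent population", call. = FALSE)
  fertile_f <- which(fathers$phenotype == 1L)
  if (!length(fertile_f))
    stop("no fertile pollen parents available", call. = FALSE)
  mi <- sample.int(pop_size(mothers), n, replace = TRUE)
  fi <- fertile_f[sample.int(length(fertile_f), n, replace = TRUE)]
  g1 <- simulate_gametes(mothers, mi, map_function)
  g2 <- simulate_gametes(fathers, fi, map_function)
  unite_gametes(mothers$map, g1, g2, phf, ids)
}

subset_population <- function(pop, idx) {
  hap <- lapply(pop$hap, function(h) list(h1 = h$h1[idx, , drop = FALSE],
                                          h2 = h$h2[idx, , drop = FALSE]))
  new_population(pop$map, hap, pop$phenotype[idx], pop$id[idx])
}

#' Add genotyping noise to a call matrix
#'
#' Each call is independently replaced by a uniformly chosen \emph{different}
#' genotype of the same marker with probability \code{error_rate}, and set to
#' missing (\code{"./."}) with probability \code{missing_rate} (missingness
#' is applied after errors and overrides them).
#'
#' @param calls Character call matrix (individuals x markers), "C/T" style.
#' @param map The \code{\link{marker_map}} supplying each marker's alleles.
#' @param error_rate,missing_rate Per-call rates in [0, 1).
#' @return The corrupted call matrix; the input is left untouched so the
#'   true matrix remains available for scoring.
#' @export
add_genotyping_noise <- function(calls, map, error_rate = 0,
                                 missing_rate = 0) {
  stopifnot(error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate <= 1)
  out <- calls
  if (error_rate > 0) {
    for (m in colnames(out)) {
      al <- sort(marker_alleles(map, m))
      states <- c(paste0(al[1], "/", al[1]), paste0(al[1], "/", al[2]),
                  paste0(al[2], "/", al[2]))
      hit <- which(stats::runif(nrow(out)) < error_rate &
                     out[, m] != "./.")
      if (length(hit)) {
        cur <- match(out[hit, m], states)
        # uniformly one of the two other genotypes
        shift <- sample(1:2, length(hit), replace = TRUE)
        out[hit, m] <- states[(cur - 1L + shift) %% 3L + 1L]
      }
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(out)) < missing_rate,
                   nrow(out), ncol(out))
    out[drop] <- "./."
  }
  out
}

#' Simulation configuration for the breeding scheme
#'
#' Bundles and validates the knobs of \code{\link{simulate_breeding_scheme}}.
#'
#' @param seed Integer master seed (mandatory); each stage of the scheme
#'   draws from its own named sub-stream so adding a stage never perturbs
#'   earlier ones.
#' @param map Marker map (default \code{\link{default_marker_map}()}).
#' @param n_f2 F2 family size.
#' @param sibcross_f1_families,n_sibcross_f1 Number and size of the
#'   fertile-x-sterile sibcross families.
#' @param sibcross_f2_families,n_sibcross_f2 Number and size of the selfed
#'   sibcross-F2 families.
#' @param panel_n,panel_steriles Diversity-panel size and target number of
#'   steriles (defaults 1044 and 164, the published panel composition).
#' @param error_rate,missing_rate Genotyping noise applied to the reported
#'   call matrices.
#' @param penetrance Probability the sterile genotype expresses sterility.
#' @param map_function \code{"haldane"} or \code{"kosambi"}.
#' @return A validated list of class \code{"gms_sim_config"}.
#' @export
sim_config <- function(seed, map = default_marker_map(),
                       n_f2 = 200,
                       sibcross_f1_families = 3, n_sibcross_f1 = 30,
                       sibcross_f2_families = 14, n_sibcross_f2 = 80,
                       panel_n = 1044, panel_steriles = 164,
                       error_rate = 0, missing_rate = 0,
                       penetrance = 1,
                       map_function = c("haldane", "kosambi")) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  map_function <- match.arg(map_function)
  stopifnot(inherits(map, "gms_map"),
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            penetrance > 0, penetrance <= 1,
            panel_steriles < panel_n)
  cfg <- list(seed = as.integer(seed), map = map, n_f2 = n_f2,
              sibcross_f1_families = sibcross_f1_families,
              n_sibcross_f1 = n_sibcross_f1,
              sibcross_f2_families = sibcross_f2_families,
              n_sibcross_f2 = n_sibcross_f2,
              panel_n = panel_n, panel_steriles = panel_steriles,
              error_rate = error_rate, missing_rate = missing_rate,
              penetrance = penetrance, map_function = map_function)
  class(cfg) <- "gms_sim_config"
  cfg
}

config_hash <- function(cfg) {
  mapstr <- paste(apply(as.data.frame(unclass(cfg$map)), 1L, paste,
                        collapse = "|"), collapse = ";")
  rest <- cfg[setdiff(names(cfg), "map")]
  fnv1a(paste(mapstr,
              paste(names(rest),
                    vapply(rest, function(v)
                      paste(format(v, digits = 15), collapse = ","), ""),
                    collapse = ";")))
}

# Founders of the breeding scheme: an inbred fertile parent (all dominant
# causal alleles, allele1 at every marker) and an inbred sterile donor
# (recessive causal alleles, with the recessive-linked allele at diagnostic
# markers and allele2 elsewhere), so every marker segregates in the cross.
scheme_founders <- function(map) {
  chrs <- unique(map$chromosome)
  hap_fertile <- hap_donor <- list()
  for (chr in chrs) {
    loci <- chrom_loci(map, chr)
    f <- rep(1L, nrow(loci))
    d <- rep(2L, nrow(loci))
    # donor carries the recessive-linked allele where one is declared
    rl <- loci$recessive_linked
    idx <- which(!is.na(rl))
    d[idx] <- ifelse(rl[idx] == loci$allele2[idx], 2L, 1L)
    f[idx] <- ifelse(rl[idx] == loci$allele2[idx], 1L, 2L)
    hap_fertile[[chr]] <- f
    hap_donor[[chr]] <- d
  }
  list(fertile = inbred_founder(map, 1, "P_fertile", hap_fertile),
       donor = inbred_founder(map, 1, "P_donor", hap_donor))
}

#' Simulate the full GMS breeding scheme
#'
#' Reproduces the study design in silico: an inbred fertile parent crossed
#' to an inbred sterile donor gives the F1; selfing gives the F2; fertile and
#' sterile F2 siblings are sibcrossed to give 1:1-type sibcross-F1 families;
#' fertile sibcross-F1 plants are selfed into sibcross-F2 families (whose
#' expected ratios are 3:1, 15:1 or all-fertile depending on the selfed
#' parent's genotype); and an unstructured random-mating diversity panel is
#' generated with \code{\link{simulate_diversity_panel}}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A named list with populations \code{f1}, \code{f2},
#'   \code{sibcross_f1} (list of families), \code{sibcross_f2} (list of
#'   families, with the selfed parent's true genotype attached as attribute
#'   \code{"parent_genotype"}), \code{panel}, and noisy call matrices
#'   \code{panel_calls} and \code{sibcross_f2_calls} (with a \code{family}
#'   attribute), plus the \code{config}.
#' @export
simulate_breeding_scheme <- function(cfg) {
  stopifnot(inherits(cfg, "gms_sim_config"))
  map <- cfg$map
  founders <- scheme_founders(map)

  f1 <- with_substream(cfg$seed, "f1",
    make_cross(founders$donor, founders$fertile, n = 2,
               scheme = "cross", penetrance = cfg$penetrance,
               map_function = cfg$map_function, id_prefix = "F1"))
  f2 <- with_substream(cfg$seed, "f2",
    make_cross(subset_population(f1, which(f1$phenotype == 1L)[1]),
               n = cfg$n_f2, scheme = "self", penetrance = cfg$penetrance,
               map_function = cfg$map_function, id_prefix = "F2"))

  # fertile x sterile sibcrosses within the F2
  sterile_idx <- which(f2$phenotype == 0L)
  fertile_idx <- which(f2$phenotype == 1L)
  if (!length(sterile_idx))
    stop("no sterile F2 individuals; increase n_f2", call. = FALSE)
  sibcross_f1 <- with_substream(cfg$seed, "sibcross_f1", {
    lapply(seq_len(cfg$sibcross_f1_families), function(k) {
      mother <- subset_population(f2, sample(sterile_idx, 1))
      father <- subset_population(f2, sample(fertile_idx, 1))
      make_cross(mother, father, n = cfg$n_sibcross_f1,
                 scheme = "sibcross", penetrance = cfg$penetrance,
                 map_function = cfg$map_function,
                 id_prefix = sprintf("SC1_%02d", k))
    })
  })

  # self fertile sibcross-F1 plants into sibcross-F2 families
  sibcross_f2 <- with_substream(cfg$seed, "sibcross_f2", {
    pool <- do.call(rbind, lapply(seq_along(sibcross_f1), function(k)
      data.frame(fam = k, idx = which(sibcross_f1[[k]]$phenotype == 1L))))
    picks <- pool[sample.int(nrow(pool), cfg$sibcross_f2_families,
                             replace = TRUE), , drop = FALSE]
    lapply(seq_len(cfg$sibcross_f2_families), function(k) {
      parent <- subset_population(sibcross_f1[[picks$fam[k]]], picks$idx[k])
      fam <- make_cross(parent, n = cfg$n_sibcross_f2, scheme = "self",
                        penetrance = cfg$penetrance,
                        map_function = cfg$map_function,
                        id_prefix = sprintf("SC2_%02d", k))
      attr(fam, "parent_genotype") <- true_genotypes(parent)[1, ]
      fam
    })
  })

  panel <- with_substream(cfg$seed, "panel",
    simulate_diversity_panel(map, n = cfg$panel_n,
                             target_steriles = cfg$panel_steriles,
                             map_function = cfg$map_function))

  panel_calls <- with_substream(cfg$seed, "panel_noise",
    add_genotyping_noise(genotype_calls(panel), map,
                         cfg$error_rate, cfg$missing_rate))

  sc2_calls <- with_substream(cfg$seed, "sibcross_f2_noise", {
    calls <- do.call(rbind, lapply(sibcross_f2, genotype_calls))
    calls <- add_genotyping_noise(calls, map, cfg$error_rate,
                                  cfg$missing_rate)
    attr(calls, "family") <- rep(seq_along(sibcross_f2),
                                 vapply(sibcross_f2, pop_size, 0L))
    calls
  })

  list(f1 = f1, f2 = f2, sibcross_f1 = sibcross_f1,
       sibcross_f2 = sibcross_f2, panel = panel,
       panel_calls = panel_calls, sibcross_f2_calls = sc2_calls,
       config = cfg)
}
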