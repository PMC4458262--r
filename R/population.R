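# Population container: per-chromosome diploid haplotypes over the loci of a
# marker map.  Alleles are stored as integer indices (1 = allele1,
# 2 = allele2); for causal loci index 2 is the recessive allele.

new_population <- function(map, hap, phenotype, id) {
  structure(list(map = map, hap = hap,
                 phenotype = as.integer(phenotype),
                 id = as.character(id)),
            class = "gms_population")
}

#' @export
print.gms_population <- function(x, ...) {
  n <- length(x$id)
  cat("GMS population:", n, "individuals;",
      sum(x$phenotype == 0L), "sterile,", sum(x$phenotype == 1L),
      "fertile\n")
  invisible(x)
}

pop_size <- function(pop) length(pop$id)

chrom_loci <- function(map, chr) map[map$chromosome == chr, , drop = FALSE]

#' True causal genotypes of a simulated population
#'
#' @param pop A simulated population.
#' @return Integer matrix (individuals x 2) of recessive-allele dosages at
#'   ms5 and ms6.
#' @export
true_genotypes <- function(pop) {
  out <- matrix(NA_integer_, pop_size(pop), 2,
                dimnames = list(pop$id, c("ms5", "ms6")))
  for (chr in names(pop$hap)) {
    loci <- chrom_loci(pop$map, chr)
    ci <- which(loci$type == "causal")
    if (length(ci) != 1L) next
    h <- pop$hap[[chr]]
    out[, loci$name[ci]] <- (h$h1[, ci] == 2L) + (h$h2[, ci] == 2L)
  }
  out
}

#' Marker genotype calls of a simulated population
#'
#' Formats the marker portion of the haplotypes as unphased diploid calls
#' ("C/T" style, alleles sorted within a call), the exchange representation
#' used by the association and prediction stages.
#'
#' @param pop A simulated population.
#' @return Character matrix (individuals x markers).
#' @export
genotype_calls <- function(pop) {
  mk <- map_marker_names(pop$map)
  out <- matrix(NA_character_, pop_size(pop), length(mk),
                dimnames = list(pop$id, mk))
  for (chr in names(pop$hap)) {
    loci <- chrom_loci(pop$map, chr)
    h <- pop$hap[[chr]]
    for (j in which(loci$type == "marker")) {
      al <- c(loci$allele1[j], loci$allele2[j])
      a1 <- al[h$h1[, j]]
      a2 <- al[h$h2[, j]]
      lo <- pmin(a1, a2)
      hi <- pmax(a1, a2)
      out[, loci$name[j]] <- paste0(lo, "/", hi)
    }
  }
  out
}

# Build an inbred (fully homozygous) founder population where every
# chromosome carries `hapfun(chr_loci)` on both haplotypes.
inbred_founder <- function(map, n, id_prefix, hap_alleles) {
  chrs <- unique(map$chromosome)
  hap <- list()
  for (chr in chrs) {
    loci <- chrom_loci(map, chr)
    row <- hap_alleles[[chr]]
    stopifnot(length(row) == nrow(loci))
    m <- matrix(rep(as.integer(row), each = n), n, nrow(loci))
    hap[[chr]] <- list(h1 = m, h2 = m)
  }
  pop <- new_population(map, hap, phenotype = rep(1L, n),
                        id = sprintf("%s_%03d", id_prefix, seq_len(n)))
  pop$phenotype <- assign_phenotype(pop, penetrance = 1)
  pop
}

# Phenotype from true genotypes, with optional incomplete penetrance
# (a genetically sterile plant expresses fertility with prob 1 - penetrance;
# fertile genotypes are never scored sterile).
assign_phenotype <- function(pop, penetrance = 1) {
  tg <- true_genotypes(pop)
  sterile <- tg[, "ms5"] == 2L & tg[, "ms6"] == 2L
  ph <- ifelse(sterile, 0L, 1L)
  if (penetrance < 1) {
    flip <- sterile & stats::runif(length(ph)) > penetrance
    ph[flip] <- 1L
  }
  as.integer(ph)
}
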