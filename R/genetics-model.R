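# Exact two-locus duplicate-recessive model for genetic male sterility.
#
# Sterility requires homozygous recessive genotypes at BOTH loci (ms5 on
# chromosome A12, ms6 on D12); a single dominant allele at either locus
# restores fertility.  The loci reside on different chromosomes and assort
# independently.  All expectations here are exact small rationals obtained by
# gamete enumeration; floating-point sampling lives in the simulator.

.locus_names <- c("ms5", "ms6")

# Parse one locus genotype into the count of recessive alleles (0, 1 or 2).
# Accepts integer dosage, generic "AA"/"Aa"/"aa", or gene-style strings such
# as "Ms5ms5".  Genotypes are unordered: "aA" canonicalizes to "Aa".
parse_locus_genotype <- function(x, locus = "ms5") {
  if (is.numeric(x)) {
    if (length(x) != 1L || is.na(x) || !x %in% 0:2)
      stop("locus genotype dosage must be 0, 1 or 2", call. = FALSE)
    return(as.integer(x))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("locus genotype must be a single string or dosage", call. = FALSE)
  orig <- gsub("[0-9]", "", x)
  if (grepl("^(Ms|ms)(Ms|ms)$", orig)) {
    # gene-symbol form: recessive allele written "ms", dominant "Ms"
    n_rec <- sum(substring(orig, c(1, 3), c(2, 4)) == "ms")
  } else if (grepl("^[A-Za-z]{2}$", orig)) {
    # letter form: recessive lower-case (e.g. "Aa"); unordered
    chars <- strsplit(orig, "")[[1]]
    if (toupper(chars[1]) != toupper(chars[2]))
      stop("malformed locus genotype: ", sQuote(x), call. = FALSE)
    n_rec <- sum(chars %in% letters)
  } else {
    stop("malformed locus genotype: ", sQuote(x), call. = FALSE)
  }
  as.integer(n_rec)
}

#' Construct a two-locus genotype
#'
#' A diploid genotype at the two causal male-sterility loci, \code{ms5} and
#' \code{ms6}.  Each locus is stored as the count of recessive alleles
#' (0 = homozygous dominant, 1 = heterozygous, 2 = homozygous recessive);
#' genotypes are unordered, so \code{"Ms5ms5"} and \code{"ms5Ms5"} are the
#' same genotype.
#'
#' @param ms5,ms6 Genotype at each locus: a recessive-allele dosage in
#'   \code{0:2}, a two-letter string (\code{"AA"}, \code{"Aa"}, \code{"aa"}),
#'   or a gene-symbol string (\code{"Ms5ms5"}, \code{"ms6ms6"}).
#' @return An object of class \code{"gms_genotype"} with integer fields
#'   \code{ms5} and \code{ms6}.
#' @examples
#' g <- two_locus_genotype("Ms5ms5", "ms6ms6")
#' phenotype_from_genotype(g)  # fertile
#' @export
two_locus_genotype <- function(ms5, ms6) {
  g <- list(ms5 = parse_locus_genotype(ms5, "ms5"),
            ms6 = parse_locus_genotype(ms6, "ms6"))
  class(g) <- "gms_genotype"
  g
}

#' @export
format.gms_genotype <- function(x, ...) {
  one <- function(d, up, lo)
    paste0(rep(c(up, lo), times = c(2 - d, d)), collapse = "")
  paste0(one(x$ms5, "Ms5", "ms5"), one(x$ms6, "Ms6", "ms6"))
}

#' @export
print.gms_genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

as_gms_genotype <- function(x) {
  if (inherits(x, "gms_genotype")) return(x)
  if (is.numeric(x) && length(x) == 2L)
    return(two_locus_genotype(x[1], x[2]))
  if (is.character(x) && length(x) == 2L)
    return(two_locus_genotype(x[1], x[2]))
  stop("cannot interpret object as a two-locus genotype", call. = FALSE)
}

#' Phenotype implied by a two-locus genotype
#'
#' Under duplicate-recessive epistasis an individual is male sterile if and
#' only if it is homozygous recessive at \emph{both} loci; any dominant
#' allele at either locus gives a fertile phenotype.
#'
#' @param g A \code{\link{two_locus_genotype}} (or something coercible to one).
#' @return Integer phenotype: \code{1} = male fertile, \code{0} = male sterile.
#' @export
phenotype_from_genotype <- function(g) {
  g <- as_gms_genotype(g)
  if (g$ms5 == 2L && g$ms6 == 2L) 0L else 1L
}

# Exact gamete distribution at one locus: probability (in quarters) that a
# transmitted allele is recessive, for dosage 0/1/2 -> 0, 1/2, 1.
# Returned as integer numerators over denominator 2: c(dominant, recessive).
locus_gamete_num <- function(dosage) {
  switch(dosage + 1L, c(2L, 0L), c(1L, 1L), c(0L, 2L))
}

#' Exact offspring genotype distribution of a cross
#'
#' Enumerates gametes of both parents under independent assortment of the two
#' loci (they lie on different chromosomes) and returns the exact probability
#' of each of the nine two-locus genotype classes as integer rationals.
#'
#' @param p1,p2 Parent genotypes (see \code{\link{two_locus_genotype}}).
#'   Omitting \code{p2} gives the selfing distribution of \code{p1}.
#' @return An object of class \code{"gms_cross_dist"}: a list with
#'   \code{num}, a 3 x 3 integer matrix of numerators indexed by recessive
#'   dosage at ms5 (rows, 0--2) and ms6 (columns, 0--2), and \code{den}, the
#'   common denominator.  Probabilities \code{num/den} sum to 1 exactly.
#' @examples
#' d <- cross_genotype_distribution(two_locus_genotype(1, 1))  # dihybrid self
#' d$num[3, 3] / d$den  # P(sterile) = 1/16
#' @export
cross_genotype_distribution <- function(p1, p2 = p1) {
  p1 <- as_gms_genotype(p1)
  p2 <- as_gms_genotype(p2)
  per_locus <- function(d1, d2) {
    g1 <- locus_gamete_num(d1)  # /2
    g2 <- locus_gamete_num(d2)  # /2
    # offspring dosage 0,1,2 numerators over denominator 4
    c(g1[1] * g2[1],
      g1[1] * g2[2] + g1[2] * g2[1],
      g1[2] * g2[2])
  }
  a <- per_locus(p1$ms5, p2$ms5)  # /4
  b <- per_locus(p1$ms6, p2$ms6)  # /4
  num <- outer(a, b)              # /16
  den <- 16L
  g <- gcd2(den, Reduce(gcd2, as.integer(num)))
  structure(list(num = matrix(as.integer(num / g), 3, 3,
                              dimnames = list(ms5 = 0:2, ms6 = 0:2)),
                 den = as.integer(den / g),
                 parents = c(format(p1), format(p2))),
            class = "gms_cross_dist")
}

#' @export
print.gms_cross_dist <- function(x, ...) {
  cat("Offspring genotype distribution of", x$parents[1], "x", x$parents[2],
      "\n(numerators over", x$den, "; rows ms5 dosage, cols ms6 dosage)\n")
  print(x$num)
  invisible(x)
}

# P(sterile) of a cross as an exact rational c(num, den).
sterile_probability <- function(p1, p2 = p1) {
  d <- cross_genotype_distribution(p1, p2)
  c(d$num[3, 3], d$den)
}

#' Expected fertile:sterile segregation ratio of a cross
#'
#' The phenotype marginal of \code{\link{cross_genotype_distribution}},
#' reduced to coprime integer parts.  Classic outcomes in this model are
#' 1:0 (no segregation), 3:1 (one locus segregating), 15:1 (both loci
#' segregating) and 1:1 (fertile x sterile testcross with one segregating
#' locus).
#'
#' @inheritParams cross_genotype_distribution
#' @return An object of class \code{"gms_ratio"}: an integer vector
#'   \code{c(fertile, sterile)} with coprime parts.
#' @examples
#' expected_segregation(two_locus_genotype(1, 1))             # 15:1
#' expected_segregation(two_locus_genotype(1, 2),
#'                      two_locus_genotype(2, 2))             # 1:1
#' @export
expected_segregation <- function(p1, p2 = p1) {
  s <- sterile_probability(p1, p2)
  fertile <- s[2] - s[1]
  sterile <- s[1]
  if (fertile == 0L && sterile == 0L)
    stop("degenerate cross", call. = FALSE)
  g <- gcd2(max(fertile, sterile), min(fertile, sterile))
  if (g == 0L) g <- 1L
  gms_ratio(fertile / g, sterile / g)
}

#' Construct a segregation ratio
#'
#' @param fertile,sterile Non-negative integer parts of a fertile:sterile
#'   ratio; reduced to coprime form on construction.
#' @return An object of class \code{"gms_ratio"}.
#' @export
gms_ratio <- function(fertile, sterile) {
  fertile <- as.integer(fertile)
  sterile <- as.integer(sterile)
  if (is.na(fertile) || is.na(sterile) || fertile < 0L || sterile < 0L ||
      (fertile == 0L && sterile == 0L))
    stop("ratio parts must be non-negative integers, not both zero",
         call. = FALSE)
  g <- gcd2(max(fertile, sterile), min(fertile, sterile))
  if (g == 0L) g <- 1L
  structure(c(fertile = fertile %/% g, sterile = sterile %/% g),
            class = "gms_ratio")
}

#' @export
format.gms_ratio <- function(x, ...) paste0(x[1], ":", x[2])

#' @export
print.gms_ratio <- function(x, ...) {
  cat("fertile:sterile =", format(x), "\n")
  invisible(x)
}

# All 9 two-locus genotypes, as a list, for enumeration-based inversion.
all_two_locus_genotypes <- function() {
  out <- vector("list", 9L)
  k <- 0L
  for (a in 0:2) for (b in 0:2) {
    k <- k + 1L
    out[[k]] <- two_locus_genotype(a, b)
  }
  out
}
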