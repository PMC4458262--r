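# Marker map: loci (causal genes + SNP markers) with chromosome and cM
# positions.  Causal loci carry alleles "Ms" (dominant) / "ms" (recessive);
# markers carry nucleotide alleles, optionally with the allele known to
# travel in phase with the recessive causal allele on carrier haplotypes.

#' Construct a marker map
#'
#' @param df A data frame with columns \code{name}, \code{chromosome},
#'   \code{pos_cM}, \code{allele1}, \code{allele2}, and optionally
#'   \code{recessive_linked} (the allele in phase with the recessive causal
#'   allele on carrier haplotypes; \code{NA} for neutral markers) and
#'   \code{type} (\code{"marker"} or \code{"causal"}; defaults to
#'   \code{"marker"}).
#' @return The validated map, sorted by chromosome and position, with class
#'   \code{"gms_map"}.
#' @export
marker_map <- function(df) {
  req <- c("name", "chromosome", "pos_cM", "allele1", "allele2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("marker map lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$recessive_linked)) df$recessive_linked <- NA_character_
  if (is.null(df$type)) df$type <- "marker"
  df$name <- as.character(df$name)
  df$chromosome <- as.character(df$chromosome)
  df$pos_cM <- as.numeric(df$pos_cM)
  if (anyDuplicated(df$name))
    stop("duplicated locus names in marker map", call. = FALSE)
  if (any(is.na(df$pos_cM)) || any(df$pos_cM < 0))
    stop("cM positions must be non-negative numbers", call. = FALSE)
  if (any(df$allele1 == df$allele2))
    stop("the two alleles of a locus must be distinct", call. = FALSE)
  bad <- !is.na(df$recessive_linked) &
    !(df$recessive_linked == df$allele1 | df$recessive_linked == df$allele2)
  if (any(bad))
    stop("recessive_linked allele not among the locus alleles for: ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  if (!all(df$type %in% c("marker", "causal")))
    stop("locus type must be 'marker' or 'causal'", call. = FALSE)
  df <- df[order(df$chromosome, df$pos_cM, df$name), , drop = FALSE]
  rownames(df) <- NULL
  # positions must be strictly increasing within a chromosome
  for (chr in unique(df$chromosome)) {
    p <- df$pos_cM[df$chromosome == chr]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("cM positions on chromosome ", chr,
           " are not strictly increasing", call. = FALSE)
  }
  class(df) <- c("gms_map", "data.frame")
  df
}

#' @export
print.gms_map <- function(x, ...) {
  cat("Marker map:", sum(x$type == "marker"), "markers and",
      sum(x$type == "causal"), "causal loci on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Marker names of a map (causal loci excluded)
#'
#' @param map A \code{\link{marker_map}}.
#' @return Character vector of marker names.
#' @export
map_marker_names <- function(map) map$name[map$type == "marker"]

map_causal <- function(map) map[map$type == "causal", , drop = FALSE]

marker_alleles <- function(map, marker) {
  i <- match(marker, map$name)
  if (is.na(i)) stop("unknown marker: ", marker, call. = FALSE)
  c(map$allele1[i], map$allele2[i])
}

#' Default two-locus GMS marker map
#'
#' A synthetic map emulating the published marker panel: 23 SNP markers on
#' chromosomes A12 and D12.  The four diagnostic SNPs keep their published
#' names and alleles -- MOGH583971 (C/T, recessive-linked T) and MOGH582973
#' (C/T, T) flanking \code{ms5} on A12; MOGH211275 (C/G, C) and MOGH493571
#' (A/G, G) flanking \code{ms6} on D12 -- and are placed within a fraction of
#' a centimorgan of their causal locus, consistent with the roughly 150-kb
#' haplotype interval reported.  The remaining 19 markers are synthetic
#' decoys spread 4--44 cM away on the same chromosomes, and one
#' chromosome-specific anchor marker per chromosome (\code{CS_A12},
#' \code{CS_D12}) supports linkage-based chromosome assignment.
#'
#' @param tight_offsets Numeric length-2: cM offsets of the two diagnostic
#'   markers relative to their causal locus (defaults \code{c(-0.2, 0.3)}).
#' @return A \code{\link{marker_map}}.
#' @export
default_marker_map <- function(tight_offsets = c(-0.2, 0.3)) {
  stopifnot(length(tight_offsets) == 2, all(abs(tight_offsets) <= 1))
  causal_pos <- 10
  a12_dec <- causal_pos + seq(4, 44, by = 4)          # 11 decoys
  d12_dec <- causal_pos + c(4, 8, 14, 20, 26, 32, 38, 44)  # 8 decoys
  df <- rbind(
    data.frame(name = "ms5", chromosome = "A12", pos_cM = causal_pos,
               allele1 = "Ms", allele2 = "ms", recessive_linked = "ms",
               type = "causal"),
    data.frame(name = c("MOGH583971", "MOGH582973"), chromosome = "A12",
               pos_cM = causal_pos + tight_offsets,
               allele1 = "C", allele2 = "T", recessive_linked = "T",
               type = "marker"),
    data.frame(name = sprintf("synA12_%02d", seq_along(a12_dec)),
               chromosome = "A12", pos_cM = a12_dec,
               allele1 = "A", allele2 = "G", recessive_linked = NA,
               type = "marker"),
    data.frame(name = "CS_A12", chromosome = "A12", pos_cM = causal_pos + 2,
               allele1 = "A", allele2 = "C", recessive_linked = NA,
               type = "marker"),
    data.frame(name = "ms6", chromosome = "D12", pos_cM = causal_pos,
               allele1 = "Ms", allele2 = "ms", recessive_linked = "ms",
               type = "causal"),
    data.frame(name = c("MOGH211275", "MOGH493571"), chromosome = "D12",
               pos_cM = causal_pos + tight_offsets,
               allele1 = c("C", "A"), allele2 = c("G", "G"),
               recessive_linked = c("C", "G"), type = "marker"),
    data.frame(name = sprintf("synD12_%02d", seq_along(d12_dec)),
               chromosome = "D12", pos_cM = d12_dec,
               allele1 = "A", allele2 = "G", recessive_linked = NA,
               type = "marker"),
    data.frame(name = "CS_D12", chromosome = "D12", pos_cM = causal_pos + 2,
               allele1 = "A", allele2 = "C", recessive_linked = NA,
               type = "marker"))
  marker_map(df)
}

#' Default anchor markers of the shipped map
#'
#' @return Named character vector mapping anchor marker names to chromosomes.
#' @export
default_anchors <- function() c(CS_A12 = "A12", CS_D12 = "D12")
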