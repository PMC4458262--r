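# Marker-assisted selection: apply a haplotype rule to new genotypes.

marker_state <- function(calls, recessive_allele) {
  # per-individual zygosity at one marker w.r.t. its recessive allele
  parts <- strsplit(ifelse(is.na(calls), "./.", calls), "/", fixed = TRUE)
  nrec <- vapply(parts, function(p) sum(p == recessive_allele), 0L)
  state <- c("hom_dom", "het", "hom_rec")[nrec + 1L]
  state[calls == "./." | is.na(calls)] <- "missing"
  state
}

locus_zygosity <- function(states) {
  # states: matrix individuals x markers of one locus
  apply(states, 1L, function(s) {
    if (any(s == "missing")) return("missing")
    if (all(s == "hom_rec")) return("homozygous_recessive")
    if (all(s == "het")) return("heterozygous")
    if (all(s == "hom_dom")) return("homozygous_dominant")
    "inconsistent"
  })
}

#' Predict sterility and per-locus zygosity from a haplotype rule
#'
#' For every individual, calls the zygosity of each causal locus from the
#' joint pattern of its rule markers (all homozygous-recessive, all
#' heterozygous, or all homozygous-dominant; disagreement between a locus's
#' markers is surfaced as \code{"inconsistent"} -- on real data it flags
#' recombination between the markers or a genotyping error -- and any
#' missing call as \code{"missing"}).  The predicted phenotype is
#' \code{"sterile"} when both loci are homozygous recessive,
#' \code{"fertile"} when at least one locus is heterozygous or homozygous
#' dominant, and \code{"undetermined"} otherwise.
#'
#' @param G Character call matrix (individuals x markers).
#' @param rule A \code{\link{haplotype_rule}}.
#' @param map Optional marker map for allele validation.
#' @return Data frame with \code{id}, \code{ms5_zygosity},
#'   \code{ms6_zygosity}, \code{predicted}; the rule hash is attached as
#'   attribute \code{"rule_hash"} so predictions trace to a ruleset file.
#' @export
classify_individuals <- function(G, rule, map = NULL) {
  stopifnot(inherits(rule, "gms_rule"))
  mk <- rule_markers(rule)
  miss <- setdiff(mk, colnames(G))
  if (length(miss))
    stop("rule marker(s) absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(map))
    for (m in mk) marker_alleles(map, m)  # validates presence
  states <- function(loc)
    matrix(vapply(names(loc), function(m) marker_state(G[, m], loc[[m]]),
                  character(nrow(G))), nrow = nrow(G))
  z5 <- locus_zygosity(states(rule$ms5))
  z6 <- locus_zygosity(states(rule$ms6))
  pred <- ifelse(
    z5 == "homozygous_recessive" & z6 == "homozygous_recessive", "sterile",
    ifelse(z5 %in% c("heterozygous", "homozygous_dominant") |
             z6 %in% c("heterozygous", "homozygous_dominant"),
           "fertile", "undetermined"))
  out <- data.frame(id = rownames(G) %||% seq_len(nrow(G)),
                    ms5_zygosity = z5, ms6_zygosity = z6,
                    predicted = pred, stringsAsFactors = FALSE)
  attr(out, "rule_hash") <- rule_hash(rule)
  out
}

#' Screen germplasm lines for the recessive haplotypes
#'
#' For each line and causal locus, reports whether the recessive-associated
#' allele is \emph{carried} (homozygous or heterozygous) at every marker of
#' that locus's haplotype -- the screen used to trace which ancestral lines
#' contributed the recessive ms5 and ms6 alleles.
#'
#' @inheritParams classify_individuals
#' @return Data frame with \code{id}, \code{ms5}, \code{ms6} (each
#'   \code{"present"}, \code{"absent"} or \code{NA} when a call is missing).
#' @export
screen_lines_for_alleles <- function(G, rule, map = NULL) {
  stopifnot(inherits(rule, "gms_rule"))
  carried <- function(loc) {
    st <- vapply(names(loc), function(m) marker_state(G[, m], loc[[m]]),
                 character(nrow(G)))
    st <- matrix(st, nrow = nrow(G))
    apply(st, 1L, function(s) {
      if (any(s == "missing")) return(NA_character_)
      if (all(s %in% c("het", "hom_rec"))) "present" else "absent"
    })
  }
  data.frame(id = rownames(G) %||% seq_len(nrow(G)),
             ms5 = carried(rule$ms5), ms6 = carried(rule$ms6),
             stringsAsFactors = FALSE)
}
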