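# Goodness-of-fit testing of observed fertile/sterile counts against
# hypothesized Mendelian ratios, and best-fit classification of families.

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Pearson chi-square of observed fertile/sterile counts against an expected
#' fertile:sterile ratio, with 1 degree of freedom and \emph{no} continuity
#' correction (published segregation tables for this material match only the
#' uncorrected statistic).
#'
#' @param fertile,sterile Observed non-negative counts; total must be
#'   positive.
#' @param ratio Expected ratio: a \code{\link{gms_ratio}} or a length-2
#'   numeric \code{c(fertile_parts, sterile_parts)}.
#' @return Object of class \code{"gms_segtest"}: list with \code{chi_square},
#'   \code{df} (always 1), \code{p_value}, \code{observed}, \code{expected},
#'   \code{ratio}.
#' @examples
#' chisq_ratio_test(399, 35, c(15, 1))  # p = 0.118
#' @export
chisq_ratio_test <- function(fertile, sterile, ratio) {
  if (!inherits(ratio, "gms_ratio")) ratio <- gms_ratio(ratio[1], ratio[2])
  fertile <- as.numeric(fertile)
  sterile <- as.numeric(sterile)
  if (is.na(fertile) || is.na(sterile) || fertile < 0 || sterile < 0 ||
      fertile + sterile <= 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  if (ratio["sterile"] == 0L || ratio["fertile"] == 0L)
    stop("ratio ", format(ratio), " has a zero expected class and is not ",
         "chi-square testable; use an exact binomial test instead",
         call. = FALSE)
  n <- fertile + sterile
  expected <- n * as.numeric(ratio) / sum(ratio)
  observed <- c(fertile = fertile, sterile = sterile)
  chi <- sum((observed - expected)^2 / expected)
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = observed,
                 expected = stats::setNames(expected,
                                            c("fertile", "sterile")),
                 ratio = ratio),
            class = "gms_segtest")
}

#' @export
print.gms_segtest <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Segregation GOF: %s fertile : %s sterile vs %s\n  X-squared = %s, df = 1, p = %s\n",
    format(x$observed[1]), format(x$observed[2]), format(x$ratio),
    format(x$chi_square, digits = digits),
    format(x$p_value, digits = digits)))
  invisible(x)
}

# Parental genotype classes whose expected segregation equals `ratio`,
# found by enumeration over the genetics model: selfs of all fertile
# genotypes and testcrosses of fertile genotypes to the sterile genotype.
invert_ratio <- function(ratio) {
  if (!inherits(ratio, "gms_ratio")) ratio <- gms_ratio(ratio[1], ratio[2])
  gts <- all_two_locus_genotypes()
  sterile_gt <- two_locus_genotype(2, 2)
  hits <- character(0)
  for (g in gts) {
    if (phenotype_from_genotype(g) == 1L) {
      if (identical(unclass(expected_segregation(g)), unclass(ratio)))
        hits <- c(hits, paste0("self of ", format(g)))
      if (identical(unclass(expected_segregation(g, sterile_gt)),
                    unclass(ratio)))
        hits <- c(hits, paste0(format(g), " x ", format(sterile_gt)))
    }
  }
  hits
}

#' Classify a family's segregation against candidate ratios
#'
#' Tests the observed counts against each candidate fertile:sterile ratio,
#' retains candidates with p >= alpha ranked by p (descending), and maps
#' each retained ratio back to the parental genotype classes that produce it
#' under the duplicate-recessive model (inversion by enumeration over selfs
#' and testcrosses to the sterile genotype).  Families where several
#' candidates pass, or where the best p sits within 0.005 of alpha, are
#' flagged.
#'
#' @inheritParams chisq_ratio_test
#' @param candidates List of candidate ratios (default the model's
#'   \code{1:1}, \code{3:1}, \code{15:1}).
#' @param alpha Retention threshold on the GOF p-value (default 0.05).
#' @return Object of class \code{"gms_segclass"}: list with \code{tests}
#'   (data frame over all candidates: ratio, chi_square, p_value, retained,
#'   boundary), \code{best} (best-fitting retained ratio or \code{NULL}),
#'   \code{parental_classes} (character; genotype classes producing the best
#'   ratio), \code{ambiguous}, \code{boundary}.
#' @export
classify_segregation <- function(fertile, sterile,
                                 candidates = list(c(1, 1), c(3, 1),
                                                   c(15, 1)),
                                 alpha = 0.05) {
  if (!length(candidates)) stop("candidate list is empty", call. = FALSE)
  res <- lapply(candidates, function(r)
    chisq_ratio_test(fertile, sterile, r))
  tests <- data.frame(
    ratio = vapply(res, function(t) format(t$ratio), ""),
    chi_square = vapply(res, function(t) t$chi_square, 0),
    p_value = vapply(res, function(t) t$p_value, 0),
    stringsAsFactors = FALSE)
  tests$boundary <- abs(tests$p_value - alpha) <= 0.005
  # boundary cases are retained but flagged, never silently dropped
  tests$retained <- tests$p_value >= alpha | tests$boundary
  ord <- order(-tests$p_value)
  tests <- tests[ord, , drop = FALSE]
  rownames(tests) <- NULL
  best <- if (any(tests$retained)) tests$ratio[tests$retained][1] else NULL
  parental <- if (!is.null(best)) {
    parts <- as.integer(strsplit(best, ":")[[1]])
    invert_ratio(gms_ratio(parts[1], parts[2]))
  } else character(0)
  structure(list(tests = tests, best = best,
                 parental_classes = parental,
                 ambiguous = sum(tests$retained) > 1,
                 boundary = any(tests$boundary & tests$retained)),
            class = "gms_segclass")
}

#' @export
print.gms_segclass <- function(x, ...) {
  print(x$tests, digits = 4)
  if (is.null(x$best)) {
    cat("No candidate ratio retained.\n")
  } else {
    cat("Best fit:", x$best,
        if (x$ambiguous) "(ambiguous: multiple candidates pass)" else "",
        if (x$boundary) "(boundary: p within 0.005 of alpha)" else "", "\n")
    if (length(x$parental_classes))
      cat("Consistent parental classes:\n ",
          paste(x$parental_classes, collapse = "\n  "), "\n")
  }
  invisible(x)
}

#' Segregation report over a table of families
#'
#' @param families Data frame with columns \code{family_id}, \code{fertile},
#'   \code{sterile}.
#' @param candidates,alpha Passed to \code{\link{classify_segregation}}.
#' @return Data frame with one row per family: counts, best-fit ratio,
#'   chi-square and p of the best fit, flags, and the consistent parental
#'   classes collapsed to a single string.
#' @export
segregation_report <- function(families,
                               candidates = list(c(1, 1), c(3, 1),
                                                 c(15, 1)),
                               alpha = 0.05) {
  req <- c("family_id", "fertile", "sterile")
  if (!all(req %in% names(families)))
    stop("families table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(families)), function(i) {
    cl <- classify_segregation(families$fertile[i], families$sterile[i],
                               candidates, alpha)
    top <- cl$tests[1, ]
    data.frame(family_id = families$family_id[i],
               fertile = families$fertile[i],
               sterile = families$sterile[i],
               best_ratio = cl$best %||% NA_character_,
               chi_square = top$chi_square,
               p_value = top$p_value,
               p_printed = formatC(top$p_value, digits = 3,
                                   format = "fg"),
               ambiguous = cl$ambiguous, boundary = cl$boundary,
               parental_classes = paste(cl$parental_classes,
                                        collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published-style sibcross family segregation counts
#'
#' The nine fertile/sterile family counts from the original two-gene GMS
#' characterization of this material: three fertile-by-sterile sibcross F1
#' families tested against 1:1, five selfed F2 families against 3:1, and one
#' selfed F2 family against 15:1.
#'
#' @return Data frame with columns \code{family_id}, \code{generation},
#'   \code{fertile}, \code{sterile}, \code{expected_fertile},
#'   \code{expected_sterile}.
#' @export
sibcross_family_counts <- function() {
  data.frame(
    family_id = c("F1_a", "F1_b", "F1_c",
                  "F2_a", "F2_b", "F2_c", "F2_d", "F2_e", "F2_f"),
    generation = c(rep("sibcross_F1", 3), rep("F2", 6)),
    fertile = c(11, 1, 3, 51, 26, 25, 76, 45, 399),
    sterile = c(19, 2, 0, 27, 16, 11, 18, 20, 35),
    expected_fertile = c(1, 1, 1, 3, 3, 3, 3, 3, 15),
    expected_sterile = rep(1, 9),
    stringsAsFactors = FALSE)
}
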