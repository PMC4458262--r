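# Two-step association analysis for duplicate-recessive male sterility:
# (1) recessive-coded single-marker logistic regression, (2) exhaustive
# cross-locus haplotype search ranked by phenotype predictability.

#' Recessive-coded indicator for one marker
#'
#' Codes each diploid call as 1 if homozygous for the recessive-associated
#' allele, 0 if heterozygous or homozygous for the other allele; missing
#' calls propagate as NA.
#'
#' @param calls Character vector of diploid calls ("C/T" style, "./."
#'   missing).
#' @param recessive_allele The allele whose homozygote predicts the
#'   recessive (sterile-associated) genotype.
#' @param alleles Optional length-2 character: the marker's legal alleles;
#'   when supplied, \code{recessive_allele} must be one of them.
#' @return Integer vector of 0/1/NA.
#' @export
recessive_encode <- function(calls, recessive_allele, alleles = NULL) {
  if (!is.null(alleles) && !recessive_allele %in% alleles)
    stop("recessive allele ", sQuote(recessive_allele),
         " is not among the marker's alleles (",
         paste(alleles, collapse = "/"), ")", call. = FALSE)
  out <- ifelse(calls == paste0(recessive_allele, "/", recessive_allele),
                1L, 0L)
  out[calls == "./." | is.na(calls)] <- NA_integer_
  as.integer(out)
}

# 2 x 2 of indicator vs sterility, used for separation detection.
ind_pheno_table <- function(ind, y) {
  keep <- !is.na(ind)
  table(factor(ind[keep], 0:1), factor(y[keep], 0:1))
}

marker_alleles_from_calls <- function(calls) {
  parts <- unlist(strsplit(calls[!is.na(calls) & calls != "./."],
                           "/", fixed = TRUE))
  sort(unique(parts))
}

#' Single-marker recessive-coded logistic scan
#'
#' For every marker and each candidate recessive-allele orientation, fits a
#' logistic regression of sterility (the positive class) on the
#' recessive-coded indicator and reports, per marker, the orientation with
#' the smaller p-value.  Complete or quasi-complete separation (a zero cell
#' in the indicator-by-phenotype table) switches the fit to Firth-penalised
#' likelihood and flags the marker.  P-values are (penalised) likelihood
#' ratio tests.
#'
#' @param G Character call matrix (individuals x markers).
#' @param y Binary phenotype vector (1 = fertile, 0 = sterile) aligned with
#'   the rows of \code{G}.
#' @param map Optional \code{\link{marker_map}} supplying marker alleles
#'   (otherwise alleles are taken from the observed calls).
#' @param coding \code{"recessive"} (default) or \code{"additive"} (dosage
#'   of the candidate allele as a linear predictor).
#' @return Data frame of class \code{"gms_marker_scan"}: one row per marker
#'   with \code{marker}, \code{recessive_allele}, \code{estimate} (log-odds
#'   of sterility for the recessive homozygote), \code{p_value},
#'   \code{separation}, \code{method}, \code{n_used}.
#' @export
single_marker_scan <- function(G, y, map = NULL,
                               coding = c("recessive", "additive")) {
  coding <- match.arg(coding)
  y <- as.integer(y)
  if (length(unique(stats::na.omit(y))) < 2L)
    stop("phenotype is constant; association is undefined", call. = FALSE)
  sterile <- 1L - y   # model P(sterile)
  rows <- list()
  for (m in colnames(G)) {
    al <- if (!is.null(map)) marker_alleles(map, m) else
      marker_alleles_from_calls(G[, m])
    if (length(al) < 2L) {
      warning("marker ", m, " is monomorphic; skipped", call. = FALSE)
      next
    }
    fits <- list()
    for (rec in al) {
      x <- if (coding == "recessive") recessive_encode(G[, m], rec, al)
      else {
        parts <- strsplit(G[, m], "/", fixed = TRUE)
        d <- vapply(parts, function(p) sum(p == rec), 0L)
        d[G[, m] == "./." | is.na(G[, m])] <- NA_integer_
        d
      }
      keep <- !is.na(x)
      if (sum(x[keep]) == 0L) {
        warning("marker ", m, ": no ", rec, "-homozygotes; orientation ",
                "dropped", call. = FALSE)
        next
      }
      if (length(unique(x[keep])) < 2L) next
      tab <- ind_pheno_table(as.integer(x > if (coding == "recessive") 0L
                                        else 1L), sterile)
      sep <- any(tab == 0L)
      if (sep) {
        f <- firth_logistic(x[keep], sterile[keep])
        fits[[rec]] <- list(rec = rec, est = f$coef[2], p = f$p_value,
                            sep = TRUE, method = "firth",
                            n = sum(keep))
      } else {
        fit <- stats::glm(sterile[keep] ~ x[keep], family = stats::binomial())
        p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
        fits[[rec]] <- list(rec = rec, est = unname(stats::coef(fit)[2]),
                            p = p, sep = FALSE, method = "standard",
                            n = sum(keep))
      }
    }
    if (!length(fits)) next
    best <- fits[[which.min(vapply(fits, function(f) f$p, 0))]]
    rows[[m]] <- data.frame(marker = m, recessive_allele = best$rec,
                            estimate = best$est, p_value = best$p,
                            separation = best$sep, method = best$method,
                            n_used = best$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gms_marker_scan", "data.frame")
  out
}

#' Construct a haplotype rule
#'
#' A haplotype rule lists, for each causal locus, the markers and their
#' recessive-associated alleles; an individual is predicted sterile if and
#' only if it is homozygous for the recessive-associated allele at
#' \emph{every} listed marker of \emph{both} loci.
#'
#' @param ms5,ms6 Named character vectors: marker name -> recessive
#'   allele, one or more markers per locus.
#' @return Object of class \code{"gms_rule"}.
#' @examples
#' published_gms_rule()
#' @export
haplotype_rule <- function(ms5, ms6) {
  chk <- function(x, locus) {
    if (!length(x) || is.null(names(x)) || any(!nzchar(names(x))))
      stop(locus, " needs at least one named marker -> allele entry",
           call. = FALSE)
    if (anyDuplicated(names(x)))
      stop("duplicated marker in ", locus, " rule", call. = FALSE)
    x[order(names(x))]
  }
  r <- structure(list(ms5 = chk(ms5, "ms5"), ms6 = chk(ms6, "ms6")),
                 class = "gms_rule")
  dup <- intersect(names(r$ms5), names(r$ms6))
  if (length(dup))
    stop("marker(s) listed under both loci: ", paste(dup, collapse = ", "),
         call. = FALSE)
  r
}

#' @export
format.gms_rule <- function(x, ...) {
  f <- function(v) paste0(names(v), ":", v, v, collapse = " + ")
  paste0("ms5 { ", f(x$ms5), " } & ms6 { ", f(x$ms6), " }")
}

#' @export
print.gms_rule <- function(x, ...) {
  cat("Haplotype rule (sterile iff homozygous at every marker):\n ",
      format(x), "\n  hash:", rule_hash(x), "\n")
  invisible(x)
}

#' @rdname haplotype_rule
#' @export
rule_hash <- function(rule) {
  fnv1a(paste(c(names(rule$ms5), rule$ms5, names(rule$ms6), rule$ms6),
              collapse = "|"))
}

#' The published four-SNP haplotype rule
#'
#' The validated diagnostic set: TT at MOGH583971 and TT at MOGH582973 call
#' the ms5ms5 genotype; CC at MOGH211275 and GG at MOGH493571 call ms6ms6.
#'
#' @return A \code{\link{haplotype_rule}}.
#' @export
published_gms_rule <- function() {
  haplotype_rule(ms5 = c(MOGH583971 = "T", MOGH582973 = "T"),
                 ms6 = c(MOGH211275 = "C", MOGH493571 = "G"))
}

rule_markers <- function(rule) c(names(rule$ms5), names(rule$ms6))

# Recessive indicator of a whole rule: AND across markers; NA if any call
# missing.
rule_indicator <- function(rule, G, map = NULL) {
  mk <- rule_markers(rule)
  alleles <- c(rule$ms5, rule$ms6)
  if (!all(mk %in% colnames(G)))
    stop("rule marker(s) absent from genotype matrix: ",
         paste(setdiff(mk, colnames(G)), collapse = ", "), call. = FALSE)
  M <- vapply(mk, function(m)
    recessive_encode(G[, m], alleles[[m]],
                     alleles = if (!is.null(map)) marker_alleles(map, m)),
    integer(nrow(G)))
  M <- matrix(M, nrow = nrow(G))
  apply(M, 1L, function(v) if (anyNA(v)) NA_integer_ else
    as.integer(all(v == 1L)))
}

#' Evaluate a haplotype rule against observed phenotypes
#'
#' Predicts sterility from the rule, cross-tabulates prediction against the
#' observed binary phenotype (sterile is the positive class), and reports
#' predictability (overall accuracy), sensitivity, specificity, and a
#' two-sided Fisher exact p for the 2 x 2 table.  Individuals with a
#' missing call at any rule marker are excluded and counted.
#'
#' @param rule A \code{\link{haplotype_rule}}.
#' @param G Character call matrix (individuals x markers).
#' @param y Binary phenotype (1 = fertile, 0 = sterile).
#' @param map Optional marker map for allele validation.
#' @return Object of class \code{"gms_confusion"}: list with \code{TP},
#'   \code{FP}, \code{TN}, \code{FN} (sterile positive), \code{accuracy},
#'   \code{sensitivity}, \code{specificity} (NA when the margin is empty),
#'   \code{exact_test_p}, \code{n_excluded_missing}, \code{n_used},
#'   \code{rule}, \code{rule_hash}.
#' @export
evaluate_ruleset <- function(rule, G, y, map = NULL) {
  stopifnot(inherits(rule, "gms_rule"))
  y <- as.integer(y)
  if (length(y) != nrow(G))
    stop("phenotype length does not match genotype rows", call. = FALSE)
  ind <- rule_indicator(rule, G, map)
  keep <- !is.na(ind) & !is.na(y)
  if (!any(keep))
    stop("no individuals remain after excluding missing calls",
         call. = FALSE)
  pred_sterile <- ind[keep] == 1L
  obs_sterile <- y[keep] == 0L
  TP <- sum(pred_sterile & obs_sterile)
  FP <- sum(pred_sterile & !obs_sterile)
  FN <- sum(!pred_sterile & obs_sterile)
  TN <- sum(!pred_sterile & !obs_sterile)
  confusion_summary(TP, FP, TN, FN,
                    n_excluded_missing = sum(!keep),
                    rule = rule)
}

confusion_summary <- function(TP, FP, TN, FN, n_excluded_missing = 0L,
                              rule = NULL) {
  n <- TP + FP + TN + FN
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = (TP + TN) / n,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    exact_test_p = fisher_exact_2x2(TP, FN, FP, TN),
    n_used = n, n_excluded_missing = n_excluded_missing,
    rule = rule,
    rule_hash = if (!is.null(rule)) rule_hash(rule) else NA_character_),
    class = "gms_confusion")
}

#' @export
print.gms_confusion <- function(x, ...) {
  cat("Haplotype-rule confusion (sterile = positive class):\n")
  tab <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
                dimnames = list(observed = c("sterile", "fertile"),
                                predicted = c("sterile", "fertile")))
  print(tab)
  cat("Same table, fertile as positive class:\n")
  print(tab[2:1, 2:1])
  cat(sprintf(
    "accuracy %.4f  sensitivity %s  specificity %s\nFisher exact p = %s;  %d used, %d excluded (missing calls)\n",
    x$accuracy, format(x$sensitivity, digits = 4),
    format(x$specificity, digits = 4),
    format(x$exact_test_p, digits = 3), x$n_used, x$n_excluded_missing))
  invisible(x)
}

# Enumerate the per-locus marker-subset x orientation combinations of a
# candidate set, as an indicator matrix plus metadata.
locus_combos <- function(G, candidates, markers_per_locus, map) {
  n <- nrow(G)
  base <- list()   # per marker x allele indicator columns
  meta <- list()
  for (m in candidates) {
    al <- if (!is.null(map)) marker_alleles(map, m) else
      marker_alleles_from_calls(G[, m])
    for (a in al) {
      key <- paste0(m, "=", a)
      v <- recessive_encode(G[, m], a, al)
      if (sum(v, na.rm = TRUE) == 0L) next   # degenerate orientation
      base[[key]] <- v
      meta[[key]] <- list(markers = m, alleles = stats::setNames(a, m))
    }
  }
  cols <- base
  info <- meta
  if (markers_per_locus >= 2L && length(candidates) >= 2L) {
    keys <- names(base)
    mk_of <- vapply(info[keys], function(x) x$markers, "")
    for (i in seq_along(keys)) {
      for (j in seq_along(keys)) {
        if (j <= i) next
        if (mk_of[i] == mk_of[j]) next   # same marker, different allele
        ki <- keys[i]; kj <- keys[j]
        v <- base[[ki]] * base[[kj]]
        key <- paste(sort(c(ki, kj)), collapse = "&")
        cols[[key]] <- v
        al <- c(info[[ki]]$alleles, info[[kj]]$alleles)
        al <- al[order(names(al))]
        info[[key]] <- list(markers = names(al), alleles = al)
      }
    }
  }
  if (!length(cols))
    stop("no usable marker orientation among the candidates", call. = FALSE)
  ind <- do.call(cbind, cols)
  colnames(ind) <- names(cols)
  list(ind = ind, info = info)
}

#' Exhaustive cross-locus haplotype scan
#'
#' Enumerates every haplotype rule with up to \code{markers_per_locus}
#' markers per locus (all marker subsets and all recessive-allele
#' orientations) over disjoint ms5 and ms6 candidate sets, evaluates each
#' rule's prediction of sterility, and ranks rules by predictability
#' (overall accuracy, descending), breaking ties by the Fisher exact p
#' (ascending), then by fewer markers, then by marker names.  No
#' multiplicity correction is applied across the enumerated rules -- the
#' selection should be validated on independent material.
#'
#' @param G Character call matrix (individuals x markers).
#' @param y Binary phenotype (1 = fertile, 0 = sterile).
#' @param ms5_candidates,ms6_candidates Disjoint, non-empty marker sets.
#' @param markers_per_locus 1 or 2 markers per locus (default 2).
#' @param map Optional marker map for allele definitions.
#' @param max_rules Combinatorial budget; exceeding it is an error naming
#'   the cap (default 2e5).
#' @return Object of class \code{"gms_scan"}: list with \code{rules} (the
#'   full ranked data frame: markers, alleles, confusion counts, accuracy,
#'   sensitivity, specificity, exact p, n excluded), \code{best} (the
#'   top-ranked \code{\link{haplotype_rule}}), \code{best_confusion}, and
#'   \code{n_rules}.
#' @export
cross_locus_scan <- function(G, y, ms5_candidates, ms6_candidates,
                             markers_per_locus = 2, map = NULL,
                             max_rules = 2e5) {
  y <- as.integer(y)
  stopifnot(length(y) == nrow(G))
  if (!length(ms5_candidates) || !length(ms6_candidates))
    stop("both candidate sets must be non-empty", call. = FALSE)
  if (length(intersect(ms5_candidates, ms6_candidates)))
    stop("candidate sets must be disjoint", call. = FALSE)
  if (!markers_per_locus %in% 1:2)
    stop("markers_per_locus must be 1 or 2", call. = FALSE)
  miss <- setdiff(c(ms5_candidates, ms6_candidates), colnames(G))
  if (length(miss))
    stop("candidate marker(s) absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)

  c5 <- locus_combos(G, ms5_candidates, markers_per_locus, map)
  c6 <- locus_combos(G, ms6_candidates, markers_per_locus, map)
  n_rules <- ncol(c5$ind) * ncol(c6$ind)
  if (n_rules > max_rules)
    stop("scan would evaluate ", n_rules, " rules, exceeding the cap ",
         "max_rules = ", max_rules, call. = FALSE)

  sterile <- as.numeric(y == 0L)
  ok <- !is.na(y)
  M5 <- (!is.na(c5$ind)) * 1; C5 <- c5$ind; C5[is.na(C5)] <- 0
  M6 <- (!is.na(c6$ind)) * 1; C6 <- c6$ind; C6[is.na(C6)] <- 0
  M5 <- M5 * ok; C5 <- C5 * ok
  st5 <- M5 * sterile

  n_valid <- crossprod(M5, M6)
  pred <- crossprod(C5, C6)
  TP <- crossprod(C5 * sterile, C6)
  obs_st <- crossprod(st5, M6)
  FN <- obs_st - TP
  FP <- pred - TP
  TN <- n_valid - TP - FN - FP
  acc <- (TP + TN) / n_valid

  k5 <- vapply(c5$info[colnames(c5$ind)], function(x) length(x$markers), 0L)
  k6 <- vapply(c6$info[colnames(c6$ind)], function(x) length(x$markers), 0L)
  nm <- outer(k5, k6, `+`)

  df <- data.frame(
    ms5_key = rep(colnames(c5$ind), times = ncol(c6$ind)),
    ms6_key = rep(colnames(c6$ind), each = ncol(c5$ind)),
    TP = as.vector(TP), FP = as.vector(FP),
    TN = as.vector(TN), FN = as.vector(FN),
    n_used = as.vector(n_valid),
    n_excluded_missing = nrow(G) - as.vector(n_valid),
    n_markers = as.vector(nm),
    accuracy = as.vector(acc),
    stringsAsFactors = FALSE)
  df$sensitivity <- ifelse(df$TP + df$FN > 0, df$TP / (df$TP + df$FN), NA)
  df$specificity <- ifelse(df$TN + df$FP > 0, df$TN / (df$TN + df$FP), NA)

  # Fisher exact p per unique confusion table (tables repeat heavily)
  key <- paste(df$TP, df$FP, df$TN, df$FN)
  uk <- !duplicated(key)
  pu <- fisher_exact_2x2(df$TP[uk], df$FN[uk], df$FP[uk], df$TN[uk])
  df$exact_test_p <- pu[match(key, key[uk])]

  ord <- order(-df$accuracy, df$exact_test_p, df$n_markers,
               df$ms5_key, df$ms6_key)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  mk_rule <- function(row) {
    i5 <- c5$info[[row$ms5_key]]
    i6 <- c6$info[[row$ms6_key]]
    haplotype_rule(ms5 = i5$alleles, ms6 = i6$alleles)
  }
  best_rule <- mk_rule(df[1, ])
  best_conf <- evaluate_ruleset(best_rule, G, y, map)
  structure(list(rules = df, best = best_rule,
                 best_confusion = best_conf, n_rules = n_rules,
                 markers_per_locus = markers_per_locus),
            class = "gms_scan")
}

#' @export
print.gms_scan <- function(x, n = 5, ...) {
  cat("Cross-locus haplotype scan:", x$n_rules, "rules evaluated\n")
  cat("Top", min(n, nrow(x$rules)), "rules:\n")
  print(utils::head(x$rules[, c("ms5_key", "ms6_key", "accuracy",
                                "exact_test_p", "TP", "FP", "TN", "FN")],
                    n), digits = 6)
  cat("\nSelected rule:\n")
  print(x$best)
  cat("\nNote: rule selection is not corrected for the multiplicity of the",
      "\nsearch; validate the selected rule on held-out material.\n")
  invisible(x)
}

#' @export
summary.gms_scan <- function(object, ...) {
  print(object, n = 10, ...)
  invisible(object$rules)
}
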