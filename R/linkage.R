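# Two-point recombination-fraction estimation for intercross (F2-type)
# codominant marker data, by EM over the double-heterozygote gamete
# ambiguity and, when several families are pooled, over each family's
# unknown linkage phase; plus LOD-based assignment of markers to
# chromosomes via anchor markers.

# 3 x 3 genotype-class probabilities of an F2 intercross at recombination
# fraction r, coupling phase (repulsion is P(r) with r -> 1 - r).
# Genotypes are dosages (0, 1, 2) of the second allele at each marker.
f2_class_probs <- function(r, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  if (phase == "repulsion") r <- 1 - r
  g <- c(`00` = (1 - r) / 2, `11` = (1 - r) / 2,  # parental gametes
         `01` = r / 2, `10` = r / 2)              # recombinant gametes
  ga <- c(0L, 1L, 0L, 1L)  # dosage contribution at marker a
  gb <- c(0L, 1L, 1L, 0L)  # at marker b
  P <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4)
    P[ga[i] + ga[j] + 1L, gb[i] + gb[j] + 1L] <-
      P[ga[i] + ga[j] + 1L, gb[i] + gb[j] + 1L] + g[i] * g[j]
  P
}

# Recombinant-gamete count of each F2 class under coupling; the double
# heterozygote (NA) is a mixture of 0 and 2 resolved in the E step.
.f2_recomb_counts <- matrix(c(0, 1, 2,
                              1, NA, 1,
                              2, 1, 0), 3, 3, byrow = TRUE)

# Per-family 3 x 3 class-count tables from paired dosage calls.
family_count_tables <- function(a, b, family) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  fam <- if (is.null(family)) rep(1L, length(a)) else factor(family[keep])
  lapply(split(seq_along(a), fam), function(idx)
    table(factor(a[idx], 0:2), factor(b[idx], 0:2)))
}

# Observed-data log-likelihood at r: per family, a 50/50 phase mixture.
rf_loglik <- function(r, tables) {
  sum(vapply(tables, function(N) {
    lc <- sum(N * log(pmax(f2_class_probs(r, "coupling"), 1e-300)))
    lr <- sum(N * log(pmax(f2_class_probs(r, "repulsion"), 1e-300)))
    m <- max(lc, lr)
    m + log(0.5 * exp(lc - m) + 0.5 * exp(lr - m))
  }, 0))
}

#' Estimate the recombination fraction from intercross genotypes
#'
#' Maximum-likelihood two-point estimate of the recombination fraction
#' between two codominant biallelic markers scored on F2-type (intercross)
#' individuals.  The estimate is obtained by EM: the double-heterozygote
#' class is a mixture of zero- and two-recombinant gamete configurations,
#' and when \code{family} identifies several independent selfed families the
#' unknown linkage phase of each family is a further latent variable
#' (per-family 50/50 coupling/repulsion mixture); the pooled log-likelihood
#' is the sum of per-family mixture log-likelihoods.  Individuals missing
#' either call are excluded (pairwise deletion).
#'
#' @param calls_a,calls_b Integer dosage calls (0/1/2 copies of the second
#'   allele, NA = missing), one entry per individual.
#' @param family Optional family identifier for pooled multi-family data.
#' @param map_function Map function used to express the estimate in cM.
#' @param tol EM convergence tolerance on |delta r| (default 1e-8).
#' @param max_iter Maximum EM iterations (default 200).
#' @return Object of class \code{"gms_rf"}: \code{r_hat} (in [0, 0.5]),
#'   \code{LOD} (log10 likelihood ratio against r = 0.5), \code{se} (Wald
#'   standard error from the numerical observed information),
#'   \code{n_informative}, \code{map_distance_cM}, \code{map_function},
#'   \code{loglik}, \code{iterations}, \code{converged}.
#' @export
estimate_rf_f2 <- function(calls_a, calls_b, family = NULL,
                           map_function = c("haldane", "kosambi"),
                           tol = 1e-8, max_iter = 200) {
  map_function <- match.arg(map_function)
  stopifnot(length(calls_a) == length(calls_b))
  ok_a <- !is.na(calls_a); ok_b <- !is.na(calls_b)
  if (!any(ok_a) || !any(ok_b))
    stop("all calls missing at a marker", call. = FALSE)
  if (length(unique(calls_a[ok_a])) < 2L ||
      length(unique(calls_b[ok_b])) < 2L)
    stop("monomorphic marker: recombination fraction is not estimable",
         call. = FALSE)
  tables <- family_count_tables(calls_a, calls_b, family)
  # families where either marker is monomorphic carry no linkage
  # information; drop them
  informative <- vapply(tables, function(N)
    sum(rowSums(N) > 0) > 1 && sum(colSums(N) > 0) > 1, TRUE)
  tables <- tables[informative]
  n_inf <- sum(vapply(tables, sum, 0))
  if (n_inf < 2L)
    stop("fewer than 2 informative individuals", call. = FALSE)

  r <- 0.25
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    num <- 0; den <- 0
    for (N in tables) {
      lc <- sum(N * log(pmax(f2_class_probs(r, "coupling"), 1e-300)))
      lr <- sum(N * log(pmax(f2_class_probs(r, "repulsion"), 1e-300)))
      w <- 1 / (1 + exp(lr - lc))   # P(coupling | data, r)
      # expected recombinant gametes in the double-het class: identical
      # under either phase (the two resolving gamete pairs swap roles)
      eh <- 2 * r^2 / ((1 - r)^2 + r^2)
      Rc <- .f2_recomb_counts; Rc[2, 2] <- eh
      Rr <- 2 - .f2_recomb_counts; Rr[2, 2] <- eh
      num <- num + w * sum(N * Rc) + (1 - w) * sum(N * Rr)
      den <- den + 2 * sum(N)
    }
    r_new <- min(max(num / den, 1e-12), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; converged <- TRUE; break }
    r <- r_new
    if (iter >= max_iter) break
  }
  ll_hat <- rf_loglik(r, tables)
  ll_null <- rf_loglik(0.5, tables)
  lod <- max((ll_hat - ll_null) / log(10), 0)
  # Wald SE from numerical observed information of the mixture likelihood
  h <- 1e-4
  r0 <- min(max(r, h), 0.5 - h)
  d2 <- (rf_loglik(r0 + h, tables) - 2 * rf_loglik(r0, tables) +
           rf_loglik(r0 - h, tables)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  dist <- if (r < 0.5) map_distance(r, map_function) else Inf
  structure(list(r_hat = r, LOD = lod, se = se, n_informative = n_inf,
                 map_distance_cM = dist, map_function = map_function,
                 loglik = ll_hat, iterations = iter, converged = converged,
                 n_families = length(tables)),
            class = "gms_rf")
}

#' @export
print.gms_rf <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Two-point linkage: r = %s (SE %s), LOD = %s\n  %d informative individuals in %d family(ies); %s cM (%s)\n",
    format(x$r_hat, digits = digits),
    format(x$se, digits = 3),
    format(x$LOD, digits = digits), x$n_informative, x$n_families,
    format(x$map_distance_cM, digits = digits), x$map_function))
  invisible(x)
}

#' Assign markers to chromosomes via anchor markers
#'
#' Each new marker is tested for two-point linkage against every anchor
#' marker of known chromosome; it is assigned to the chromosome of its
#' maximum-LOD anchor if that LOD reaches the threshold, and is otherwise
#' left unassigned.  Ties are broken by the smaller estimated recombination
#' fraction, then by anchor name order.
#'
#' @param dosages Integer dosage matrix (individuals x markers; 0/1/2/NA)
#'   containing both the new markers and the anchors.
#' @param anchors Named character vector: anchor marker name -> chromosome.
#' @param new_markers Markers to assign (default: all non-anchor columns).
#' @param family Optional family identifier passed to
#'   \code{\link{estimate_rf_f2}}.
#' @param lod_threshold Minimum LOD for assignment (default 3).
#' @return Data frame: \code{marker}, \code{chromosome} (or \code{NA} if
#'   unassigned), \code{anchor}, \code{r_hat}, \code{LOD}.
#' @export
assign_to_anchor <- function(dosages, anchors,
                             new_markers = setdiff(colnames(dosages),
                                                   names(anchors)),
                             family = NULL, lod_threshold = 3) {
  stopifnot(length(anchors) >= 1, !is.null(names(anchors)))
  if (!all(names(anchors) %in% colnames(dosages)))
    stop("anchor marker(s) absent from the dosage matrix", call. = FALSE)
  anchors <- anchors[order(names(anchors))]
  rows <- lapply(new_markers, function(m) {
    fits <- lapply(names(anchors), function(a) {
      if (identical(a, m))
        return(list(r_hat = 0, LOD = Inf))
      tryCatch(estimate_rf_f2(dosages[, m], dosages[, a], family = family),
               error = function(e) list(r_hat = NA_real_, LOD = -Inf))
    })
    lods <- vapply(fits, function(f) f$LOD, 0)
    rhats <- vapply(fits, function(f) f$r_hat, 0)
    ord <- order(-lods, rhats, names(anchors))
    best <- ord[1]
    assigned <- is.finite(lods[best]) && lods[best] >= lod_threshold ||
      is.infinite(lods[best]) && lods[best] > 0
    data.frame(marker = m,
               chromosome = if (assigned)
                 unname(anchors[best]) else NA_character_,
               anchor = names(anchors)[best],
               r_hat = rhats[best], LOD = lods[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert diploid string calls to allele dosages
#'
#' @param calls Character call matrix ("C/T" style, \code{"./."} missing).
#' @param map A \code{\link{marker_map}} defining each marker's alleles;
#'   dosage counts copies of \code{allele2}.
#' @return Integer dosage matrix with NA for missing.
#' @export
calls_to_dosage <- function(calls, map) {
  out <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  for (m in colnames(calls)) {
    al <- marker_alleles(map, m)
    parts <- strsplit(calls[, m], "/", fixed = TRUE)
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, `[`, "", 2L)
    known <- a1 %in% al & a2 %in% al
    bad <- !known & !(a1 == "." | a2 == ".")
    if (any(bad))
      stop("allele(s) not in marker definition for ", m, ": ",
           paste(unique(calls[bad, m]), collapse = ", "), call. = FALSE)
    out[known, m] <- (a1[known] == al[2]) + (a2[known] == al[2])
  }
  out
}
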