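# Readers and writers for the exchange formats: genotype TSV (primary) and
# minimal VCF, phenotype CSV, marker-map TSV, and haplotype-ruleset JSON.
# Every writer stamps a deterministic header (tool version, config hash,
# seed) so outputs are traceable and byte-reproducible under a fixed seed.

output_header <- function(comment = "#", seed = NULL, extra = NULL) {
  paste0(comment, " gmshap v", pkg_version_string(),
         if (!is.null(seed)) paste0("; seed=", seed),
         if (!is.null(extra)) paste0("; ", extra))
}

#' Read and write genotype matrices
#'
#' The primary dialect is a TSV with individuals in rows and markers in
#' columns; the first column is the individual id and calls are unphased
#' diploid allele pairs ("C/T"), with \code{"./."} for missing.  Lines
#' starting with \code{#} are header comments.  Reading normalizes each
#' call to alphabetical allele order.  A minimal VCF dialect (one record
#' per marker, GT-only, unphased diploid) is also supported; reading VCF
#' requires the \pkg{vcfR} package.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param map Optional \code{\link{marker_map}}; when supplied, observed
#'   alleles are validated against it.
#' @return \code{read_genotypes}: a character call matrix with individual
#'   ids as row names.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path, map))
  lines <- readLines(path)
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2L)
    stop("genotype file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  markers <- header[-1]
  n <- length(body) - 1L
  out <- matrix(NA_character_, n, length(markers),
                dimnames = list(NULL, markers))
  ids <- character(n)
  for (i in seq_len(n)) {
    ln <- body[i + 1L]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("malformed genotype row at line ", ln, " of ", path,
           " (expected ", length(header), " fields, got ", length(f), ")",
           call. = FALSE)
    ids[i] <- f[1]
    out[i, ] <- f[-1]
  }
  rownames(out) <- ids
  normalize_calls(out, map, path)
}

normalize_calls <- function(calls, map = NULL, path = "<calls>") {
  norm <- function(v) {
    p <- strsplit(v, "/", fixed = TRUE)
    bad <- lengths(p) != 2L
    if (any(bad))
      stop("malformed call(s) in ", path, ": ",
           paste(utils::head(unique(v[bad]), 3), collapse = ", "),
           call. = FALSE)
    a1 <- vapply(p, `[`, "", 1L)
    a2 <- vapply(p, `[`, "", 2L)
    miss <- a1 == "." | a2 == "."
    out <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
    out[miss] <- "./."
    out
  }
  out <- apply(calls, 2L, norm)
  out <- matrix(out, nrow = nrow(calls), dimnames = dimnames(calls))
  if (!is.null(map)) {
    for (m in intersect(colnames(out), map$name)) {
      al <- marker_alleles(map, m)
      obs <- setdiff(unique(unlist(strsplit(out[, m], "/", fixed = TRUE))),
                     c(".", al))
      if (length(obs))
        stop("unknown allele(s) ", paste(obs, collapse = ", "),
             " at marker ", m, " in ", path, call. = FALSE)
    }
  }
  out
}

#' @rdname read_genotypes
#' @param calls Character call matrix to write.
#' @param seed Seed recorded in the output header.
#' @param config_note Optional extra header note (e.g. a config hash).
#' @export
write_genotypes <- function(calls, path, format = c("tsv", "vcf"),
                            map = NULL, seed = NULL, config_note = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(write_genotypes_vcf(calls, path, map, seed,
                                                  config_note))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("#", seed, config_note), con)
  writeLines(paste(c("id", colnames(calls)), collapse = "\t"), con)
  writeLines(paste(rownames(calls) %||% seq_len(nrow(calls)),
                   apply(calls, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

read_genotypes_vcf <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  markers <- rownames(gt)
  decode <- function(j) {
    al <- c(ref[j], alt[j])
    g <- gt[j, ]
    out <- rep("./.", length(g))
    okg <- !is.na(g) & grepl("^[01][/|][01]$", g)
    i1 <- as.integer(substr(g[okg], 1, 1)) + 1L
    i2 <- as.integer(substr(g[okg], 3, 3)) + 1L
    out[okg] <- paste0(pmin(al[i1], al[i2]), "/", pmax(al[i1], al[i2]))
    out
  }
  calls <- vapply(seq_along(markers), decode, character(ncol(gt)))
  calls <- matrix(calls, ncol = length(markers),
                  dimnames = list(colnames(gt), markers))
  normalize_calls(calls, map, path)
}

write_genotypes_vcf <- function(calls, path, map = NULL, seed = NULL,
                                config_note = NULL) {
  markers <- colnames(calls)
  al <- lapply(markers, function(m) {
    if (!is.null(map) && m %in% map$name) sort(marker_alleles(map, m))
    else marker_alleles_from_calls(calls[, m])
  })
  chrom <- pos <- rep(".", length(markers))
  if (!is.null(map)) {
    i <- match(markers, map$name)
    chrom <- ifelse(is.na(i), ".", map$chromosome[i])
    pos <- ifelse(is.na(i), "0",
                  as.character(round(map$pos_cM[i] * 1e4)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=gmshap_v", pkg_version_string(),
                      if (!is.null(seed)) paste0(";seed=", seed),
                      if (!is.null(config_note))
                        paste0(";", config_note)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(calls) %||% seq_len(nrow(calls))),
                     collapse = "\t")), con)
  for (j in seq_along(markers)) {
    a <- al[[j]]
    if (length(a) < 2L) a <- c(a, ".")
    enc <- function(call) {
      if (call == "./.") return("./.")
      p <- strsplit(call, "/", fixed = TRUE)[[1]]
      paste0(match(p[1], a) - 1L, "/", match(p[2], a) - 1L)
    }
    writeLines(paste(c(chrom[j], pos[j], markers[j], a[1], a[2], ".",
                       ".", ".", "GT",
                       vapply(calls[, j], enc, "")), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read and write phenotype files
#'
#' Phenotypes are CSV with columns \code{individual_id} and
#' \code{phenotype}, coded 1 for male fertile and 0 for male sterile.
#'
#' @param path File path.
#' @return Named integer vector of phenotypes.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  req <- c("individual_id", "phenotype")
  if (!all(req %in% names(df)))
    stop("phenotype file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- !df$phenotype %in% c(0L, 1L)
  if (any(bad))
    stop("phenotype values must be coded 1 (male fertile) / 0 (male ",
         "sterile); offending value(s): ",
         paste(utils::head(unique(df$phenotype[bad]), 3), collapse = ", "),
         call. = FALSE)
  stats::setNames(as.integer(df$phenotype), df$individual_id)
}

#' @rdname read_phenotypes
#' @param phenotypes Named integer vector (1 fertile / 0 sterile).
#' @param seed,config_note Recorded in the output header.
#' @export
write_phenotypes <- function(phenotypes, path, seed = NULL,
                             config_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("#", seed, config_note), con)
  writeLines("individual_id,phenotype", con)
  writeLines(paste(names(phenotypes), phenotypes, sep = ","), con)
  invisible(path)
}

#' Read and write marker maps
#'
#' Marker-map TSV columns: \code{name}, \code{chromosome}, \code{pos_cM},
#' optionally \code{allele1}, \code{allele2}, \code{recessive_linked},
#' \code{type}.  Positions must be strictly increasing within a chromosome.
#'
#' @param path File path.
#' @return A \code{\link{marker_map}}.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.null(df$allele1)) { df$allele1 <- "A"; df$allele2 <- "B" }
  if (!is.null(df$recessive_linked))
    df$recessive_linked[df$recessive_linked == ""] <- NA_character_
  marker_map(df)
}

#' @rdname read_marker_map
#' @param map A \code{\link{marker_map}} to write.
#' @param seed,config_note Recorded in the output header.
#' @export
write_marker_map <- function(map, path, seed = NULL, config_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("#", seed, config_note), con)
  df <- as.data.frame(unclass(map), stringsAsFactors = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' Read and write haplotype rulesets
#'
#' Ruleset JSON schema: an object with one array per locus, each entry
#' \code{{"marker": name, "recessive_allele": allele}}, plus optional
#' \code{version} and \code{hash} fields.  The shipped fixture
#' \code{system.file("extdata", "gms_haplotype_ruleset.json", package =
#' "gmshap")} carries the published four-SNP set.
#'
#' @param path File path.
#' @return A \code{\link{haplotype_rule}}.
#' @export
read_ruleset <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("ms5", "ms6")
  if (!all(need %in% names(j)))
    stop("ruleset must define both loci: ", paste(need, collapse = ", "),
         call. = FALSE)
  pull <- function(df) {
    if (!all(c("marker", "recessive_allele") %in% names(df)))
      stop("ruleset entries need fields 'marker' and 'recessive_allele'",
           call. = FALSE)
    stats::setNames(as.character(df$recessive_allele),
                    as.character(df$marker))
  }
  rule <- haplotype_rule(pull(j$ms5), pull(j$ms6))
  if (!is.null(j$hash) && !identical(j$hash, rule_hash(rule)))
    warning("ruleset hash mismatch: file says ", j$hash, ", computed ",
            rule_hash(rule), call. = FALSE)
  rule
}

#' @rdname read_ruleset
#' @param rule A \code{\link{haplotype_rule}} to write.
#' @param seed Seed recorded in the file.
#' @export
write_ruleset <- function(rule, path, seed = NULL) {
  stopifnot(inherits(rule, "gms_rule"))
  obj <- list(
    version = pkg_version_string(),
    hash = rule_hash(rule),
    seed = seed,
    ms5 = data.frame(marker = names(rule$ms5),
                     recessive_allele = unname(rule$ms5)),
    ms6 = data.frame(marker = names(rule$ms6),
                     recessive_allele = unname(rule$ms6)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a family segregation-counts CSV
#'
#' Columns: \code{family_id}, \code{fertile}, \code{sterile}.
#'
#' @param path File path.
#' @return Data frame suitable for \code{\link{segregation_report}}.
#' @export
read_family_counts <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  req <- c("family_id", "fertile", "sterile")
  if (!all(req %in% names(df)))
    stop("family counts file needs columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(df$fertile < 0 | df$sterile < 0 |
          df$fertile + df$sterile <= 0))
    stop("family counts must be non-negative with positive totals",
         call. = FALSE)
  df
}
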