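# End-to-end pipeline: simulate -> segregation testing -> linkage ->
# haplotype scan -> prediction, with all artifacts written to disk.
# Deterministic under a fixed seed (byte-identical outputs on rerun).

#' Run the full GMS analysis pipeline
#'
#' Simulates the breeding scheme and diversity panel, tests each sibcross-F2
#' family's segregation ratio, assigns all markers to chromosomes by linkage
#' to the anchor markers, runs the cross-locus haplotype scan on the panel,
#' applies the selected rule back to the panel, and writes every artifact
#' (genotypes, phenotypes, map, segregation report, linkage table, ranked
#' rules, selected ruleset, predictions) under \code{out_dir}.
#'
#' @param out_dir Output directory (created if absent; must not already
#'   contain this run's input files).
#' @param seed Integer master seed.
#' @param cfg A \code{\link{sim_config}} (default: a moderate-size
#'   configuration using the shipped marker map).
#' @param anchors Named chromosome-anchor vector
#'   (default \code{\link{default_anchors}()}).
#' @param top_rules Number of ranked rules to write (default 50).
#' @return Invisibly, a list with the in-memory results (\code{sim},
#'   \code{segregation}, \code{assignment}, \code{scan},
#'   \code{predictions}, \code{files}).
#' @export
run_gms_pipeline <- function(out_dir, seed, cfg = NULL,
                             anchors = default_anchors(),
                             top_rules = 50) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  note <- paste0("config=", config_hash(cfg))
  sim <- simulate_breeding_scheme(cfg)
  map <- cfg$map

  files <- c(genotypes = file.path(out_dir, "panel_genotypes.tsv"),
             phenotypes = file.path(out_dir, "panel_phenotypes.csv"),
             map = file.path(out_dir, "marker_map.tsv"),
             segregation = file.path(out_dir, "segregation.csv"),
             linkage = file.path(out_dir, "linkage_assignment.csv"),
             rules = file.path(out_dir, "scan_rules.csv"),
             ruleset = file.path(out_dir, "selected_ruleset.json"),
             predictions = file.path(out_dir, "predictions.csv"))
  if (any(vapply(files, function(f)
    file.exists(f) && file.access(f, 2) < 0, TRUE)))
    stop("refusing to overwrite a read-only existing output", call. = FALSE)

  write_genotypes(sim$panel_calls, files["genotypes"], map = map,
                  seed = cfg$seed, config_note = note)
  write_phenotypes(stats::setNames(sim$panel$phenotype, sim$panel$id),
                   files["phenotypes"], seed = cfg$seed, config_note = note)
  write_marker_map(map, files["map"], seed = cfg$seed, config_note = note)

  # segregation of the sibcross-F2 families
  fams <- data.frame(
    family_id = sprintf("SC2_%02d", seq_along(sim$sibcross_f2)),
    fertile = vapply(sim$sibcross_f2, function(p)
      sum(p$phenotype == 1L), 0L),
    sterile = vapply(sim$sibcross_f2, function(p)
      sum(p$phenotype == 0L), 0L))
  seg <- segregation_report(fams)
  write_csv_with_header(seg, files["segregation"], seed = cfg$seed,
                        note = note)

  # linkage assignment of all markers to chromosome anchors
  dos <- calls_to_dosage(sim$sibcross_f2_calls, map)
  assignment <- assign_to_anchor(dos, anchors,
                                 family = attr(sim$sibcross_f2_calls,
                                               "family"))
  write_csv_with_header(assignment, files["linkage"], seed = cfg$seed,
                        note = note)

  # cross-locus haplotype scan on the diversity panel
  cand <- split(setdiff(map_marker_names(map), names(anchors)),
                map$chromosome[match(setdiff(map_marker_names(map),
                                             names(anchors)), map$name)])
  scan <- cross_locus_scan(sim$panel_calls, sim$panel$phenotype,
                           ms5_candidates = cand[["A12"]],
                           ms6_candidates = cand[["D12"]],
                           map = map)
  write_csv_with_header(utils::head(scan$rules, top_rules), files["rules"],
                        seed = cfg$seed, note = note)
  write_ruleset(scan$best, files["ruleset"], seed = cfg$seed)

  preds <- classify_individuals(sim$panel_calls, scan$best, map = map)
  preds$rule_hash <- attr(preds, "rule_hash")
  write_csv_with_header(preds, files["predictions"], seed = cfg$seed,
                        note = note)

  invisible(list(sim = sim, segregation = seg, assignment = assignment,
                 scan = scan, predictions = preds, files = files))
}

write_csv_with_header <- function(df, path, seed = NULL, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("#", seed, note), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
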