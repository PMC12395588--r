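# High-level pipeline runners behind the command-line wrapper
# (inst/scripts/lgtsurvey.R). Each writes TSV outputs plus a resolved
# run-metadata JSON so runs are reproducible byte-for-byte.

write_run_meta <- function(dir, meta) {
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# derive a matched null simulation design from an observed tree set:
# same marker count, per-lineage leaf counts from the median across trees
matched_null_config <- function(set, map, seed) {
  counts <- dplyr::bind_rows(lapply(set$tree, function(t) {
    dplyr::count(t$taxa, .data$lineage, .data$group, .data$domain)
  })) |>
    dplyr::filter(.data$lineage != "Unknown") |>
    dplyr::group_by(.data$lineage, .data$group, .data$domain) |>
    dplyr::summarise(n = as.integer(stats::median(.data$n)), .groups = "drop")
  base <- default_lineages()
  lineages <- counts[counts$lineage %in% base$lineage, ]
  if (nrow(lineages) < 4 || !"Eukarya" %in% lineages$lineage) {
    # observed lineages do not cover the default design; fall back to it
    lineages <- base
  } else {
    missing <- base[!base$lineage %in% lineages$lineage, ]
    if (nrow(missing) > 0) lineages <- dplyr::bind_rows(lineages, missing)
  }
  focal_n <- lineages$n[lineages$lineage == "Eukarya"]
  simulation_config(
    n_markers = nrow(set), lineages = lineages,
    focal_size = max(2L, focal_n),
    p_lgt_focal_to_lineage = numeric(0),
    p_lgt_lineage_to_focal = numeric(0),
    p_lgt_lineage_to_donor = tibble(lineage = character(),
                                    donor = character(), p = numeric()),
    p_focal_missing = mean(set$n_focal == 0),
    seed = seed)
}

#' Run the full tree-incongruence scan
#'
#' Loads a directory of Newick gene trees, surveys them
#' ([survey_trees()]), profiles the distance to each target lineage,
#' scores the profiles against matched simulated nulls ([lgt_score()]),
#' infers per-marker transfer direction, and writes
#' `table1_summary.tsv`, `table2_distances.tsv`, `table3_affinity.tsv`,
#' `profiles.tsv`, `lgt_calls.tsv`, `classifications.tsv` and
#' `run_meta.json` into `out_dir`.
#'
#' @param trees_dir Directory of Newick files.
#' @param map_path Lineage-map TSV ([read_lineage_map()]).
#' @param out_dir Output directory (created).
#' @param focal Focal taxon name (default `"Eukarya"`).
#' @param targets Target lineages to profile (default Hodarchaeales and
#'   Njordarchaeales).
#' @param dataset Optional dataset filter (`"RP"` or `"NM"`).
#' @param manifest Optional manifest TSV for [load_tree_set()].
#' @param n_null Number of matched null replicate sets (default 100).
#' @param cfg A [survey_config()].
#' @param seed Seed for the null simulations.
#' @return Invisibly, a list with the survey, profiles and calls.
#' @export
run_tree_scan <- function(trees_dir, map_path, out_dir,
                          focal = "Eukarya",
                          targets = c("Hodarchaeales", "Njordarchaeales"),
                          dataset = NULL, manifest = NULL, n_null = 100,
                          cfg = survey_config(), seed = 1L) {
  map <- read_lineage_map(map_path)
  set <- load_tree_set(trees_dir, map, manifest = manifest)
  if (!is.null(dataset)) {
    keep <- !is.na(set$dataset) & set$dataset == dataset
    if (!any(keep)) abort(paste0("no trees with dataset tag ", dataset))
    set <- set[keep, ]
    class(set) <- c("tree_set", setdiff(class(set), "tree_set"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sv <- survey_trees(set, focal = focal, cfg = cfg)
  cl <- infer_direction(sv, cfg)
  null_cfg <- matched_null_config(set, map, seed = seed)
  calls <- list(); prof_rows <- list()
  for (tg in targets) {
    pr <- distance_profile(set, focal = focal, target = tg, cfg = cfg)
    nulls <- make_null_profiles(null_cfg, target = tg, n_replicates = n_null,
                                focal = focal, cfg = cfg,
                                seed = seed + 10000L)
    calls[[tg]] <- lgt_score(pr, nulls, cfg = cfg)
    prof_rows[[tg]] <- dplyr::mutate(pr$histogram, target = tg,
                                     .before = 1)
  }
  calls <- dplyr::bind_rows(calls)
  calls$n_targets_tested <- length(targets)
  if (cfg$correction == "bonferroni") {
    calls$near_excess_p_adj <- pmin(1, calls$near_excess_p * length(targets))
  }
  readr::write_tsv(sv$table1, file.path(out_dir, "table1_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(sv, distances = TRUE),
                   file.path(out_dir, "table2_distances.tsv"), progress = FALSE)
  readr::write_tsv(sv$affinity, file.path(out_dir, "table3_affinity.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(prof_rows),
                   file.path(out_dir, "profiles.tsv"), progress = FALSE)
  readr::write_tsv(tidy(calls), file.path(out_dir, "lgt_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::select(cl, -"sister_composition", -"distances"),
                   file.path(out_dir, "classifications.tsv"), progress = FALSE)
  write_run_meta(out_dir, list(
    subcommand = "scan-trees", trees_dir = trees_dir, map = map_path,
    focal = focal, targets = targets, dataset = dataset, n_null = n_null,
    seed = seed, config = unclass(cfg),
    n_trees = nrow(set),
    n_skipped = nrow(attr(set, "skipped")),
    rooting_fallbacks = sum(sv$classifications$rooting == "midpoint-fallback")))
  invisible(list(survey = sv, classifications = cl, calls = calls))
}

#' Run the gene-tree simulator and write its outputs
#'
#' @param out_dir Output directory.
#' @param n_markers Number of markers.
#' @param seed Master seed.
#' @param ... Further arguments to [simulation_config()].
#' @return Invisibly, the `lgt_simulation`.
#' @export
run_simulation <- function(out_dir, n_markers = 56, seed = 1L, ...) {
  cfg <- simulation_config(n_markers = n_markers, seed = seed, ...)
  sim <- simulate_gene_trees(cfg)
  write_simulation(sim, out_dir)
  write_run_meta(out_dir, list(subcommand = "simulate",
                               n_markers = n_markers, seed = seed))
  invisible(sim)
}

#' Run the insertion scan on an aligned FASTA
#'
#' @param fasta Aligned protein FASTA.
#' @param focal Character vector of focal taxa, or a path to a one-label
#'   -per-line file.
#' @param out_dir Output directory.
#' @param species_tree Optional Newick path; when given, each block's
#'   carrier pattern is checked with [insertion_parsimony_check()]
#'   (carriers = focal taxa bearing the block).
#' @param ... Further arguments to [find_lineage_insertions()].
#' @return Invisibly, the blocks tibble.
#' @export
run_indel_scan <- function(fasta, focal, out_dir, species_tree = NULL, ...) {
  aln <- read_alignment(fasta)
  if (length(focal) == 1 && file.exists(focal)) {
    focal <- readr::read_lines(focal)
    focal <- trimws(focal[nzchar(trimws(focal))])
  }
  missing <- setdiff(focal, rownames(aln))
  if (length(missing) > 0) {
    abort(paste0("focal taxa absent from alignment: ",
                 paste(missing, collapse = ", ")))
  }
  blocks <- find_lineage_insertions(aln, focal, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- blocks |>
    dplyr::mutate(
      lengths = vapply(.data$lengths, function(l) {
        paste(names(l), l, sep = ":", collapse = ";")
      }, character(1)),
      focal_absent = vapply(.data$focal_absent, paste,
                            character(1), collapse = ";"))
  if (!is.null(species_tree)) {
    st <- ape::read.tree(species_tree)
    flat$min_events <- NA_integer_
    flat$single_gain <- NA
    for (i in seq_len(nrow(blocks))) {
      carriers <- setdiff(names(blocks$lengths[[i]]),
                          blocks$focal_absent[[i]])
      carriers <- intersect(carriers, st$tip.label)
      if (length(carriers) > 0) {
        pc <- insertion_parsimony_check(carriers, st)
        flat$min_events[i] <- pc$min_events
        flat$single_gain[i] <- pc$single_gain
      }
    }
  }
  readr::write_tsv(flat, file.path(out_dir, "insertion_blocks.tsv"),
                   progress = FALSE)
  write_run_meta(out_dir, list(subcommand = "indel-scan", fasta = fasta,
                               n_focal = length(focal),
                               n_blocks = nrow(blocks)))
  invisible(blocks)
}
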