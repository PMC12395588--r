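# Per-tree classification and tree-set aggregation: sister-group census,
# nodal-distance profiles, bimodality scoring, affinity census, direction.

#' Survey configuration
#'
#' Thresholds shared by the survey pipeline. Defaults: collapse internal
#' edges with support < 50 or length < 0.005 substitutions/site; require
#' 4 focal leaves for a placement verdict and 2 leaves for a lineage to
#' receive a distance (a single stray leaf is likelier mis-annotation);
#' root via a DPANN-then-Euryarchaeota outgroup policy with midpoint
#' fallback; distances <= `d_near` (2) count as "close", > `d_far` (4) as
#' "far"; near-excess test at `alpha` 0.05.
#'
#' @param min_support,min_length Weak-edge collapse thresholds
#'   ([collapse_weak_edges()]). Length-based collapsing is skipped, with
#'   a note in the classification, for trees without real lengths.
#' @param min_focal Minimum focal leaves for a sister verdict.
#' @param min_lineage_leaves Minimum leaves for a lineage to be scored.
#' @param rooting_policy Ordered outgroup names for [root_gene_tree()].
#' @param major_share Sister-composition share threshold
#'   ([sister_lineage()]).
#' @param d_near Distances `<= d_near` count toward the near-excess
#'   statistic (sister = 1, near-sister = 2).
#' @param d_far Distances must exceed this for "far" in direction calls.
#' @param alpha Significance level of the near-excess test.
#' @param tabulation `"strict"` credits a lineage only with sister/nested
#'   verdicts; `"loose"` also credits unresolved trees whose nearest
#'   target lies within `d_near`.
#' @param correction Across-target p-value correction: `"none"` (targets
#'   are reported jointly, with the number tested) or `"bonferroni"`.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(min_support = 50, min_length = 0.005,
                          min_focal = 4, min_lineage_leaves = 2,
                          rooting_policy = c("DPANN", "Euryarchaeota"),
                          major_share = 0.2, d_near = 2, d_far = 4,
                          alpha = 0.05, tabulation = c("strict", "loose"),
                          correction = c("none", "bonferroni")) {
  structure(list(
    min_support = min_support, min_length = min_length,
    min_focal = min_focal, min_lineage_leaves = min_lineage_leaves,
    rooting_policy = rooting_policy, major_share = major_share,
    d_near = d_near, d_far = d_far, alpha = alpha,
    tabulation = match.arg(tabulation), correction = match.arg(correction)
  ), class = "survey_config")
}

# collapse + root one tree under a survey config
prepare_tree <- function(tree, cfg) {
  ml <- if (tree$lengths_real) cfg$min_length else 0
  pt <- collapse_weak_edges(tree, min_support = cfg$min_support,
                            min_length = ml)
  root_gene_tree(pt, policy = cfg$rooting_policy)
}

# distances from the focal leaves to every candidate lineage
lineage_distances <- function(prep, focal_leaves, targets, cfg) {
  tx <- prep$taxa
  cand <- tx |>
    dplyr::filter(.data$lineage != "Unknown", .data$domain != "Eukarya") |>
    dplyr::count(.data$lineage, .data$group, name = "n_leaves") |>
    dplyr::filter(.data$n_leaves >= cfg$min_lineage_leaves)
  if (!is.null(targets)) cand <- cand[cand$lineage %in% targets, ]
  out <- cand |>
    dplyr::mutate(distance = NA_integer_, nested = NA)
  if (length(focal_leaves) == 0 || nrow(out) == 0) return(out)
  sets <- node_tip_sets(prep$phy)
  for (i in seq_len(nrow(out))) {
    nd <- nodal_distance(prep, focal_leaves,
                         tx$label[tx$lineage == out$lineage[i]], sets = sets)
    out$distance[i] <- nd$value
    out$nested[i] <- nd$nested
  }
  out
}

#' Classify one gene tree
#'
#' Applies the full per-tree pipeline: collapse weak edges, root by
#' policy, identify the focal clade's sister lineage, measure the nodal
#' distance from the focal clade to each target lineage, and test Asgard
#' (and per-target lineage) monophyly. Monophyly is tested on the
#' uncollapsed topology (it is a bipartition property, invariant to
#' rooting); distances and the sister verdict use the collapsed, rooted
#' tree. Trees lacking the focal clade are still classified
#' (`focal_status = "absent"`) so the zero-focal census can count them.
#'
#' @param tree A [gene_tree()].
#' @param focal Focal taxon name (default `"Eukarya"`).
#' @param targets Lineages to measure distances to, or `NULL` for every
#'   lineage with at least `min_lineage_leaves` leaves.
#' @param cfg A [survey_config()].
#' @return A one-row tibble with scalar columns (`marker_id`, `dataset`,
#'   `n_focal`, `n_unknown`, `focal_status`, `sister_label`, `rooting`,
#'   `asgard_monophyly`, `asgard_monophyly_with_focal`) and list-columns
#'   `sister_composition` and `distances` (tibble `lineage`, `group`,
#'   `n_leaves`, `distance`, `nested`, `monophyletic`).
#' @export
classify_tree <- function(tree, focal = "Eukarya", targets = NULL,
                          cfg = survey_config()) {
  prep <- prepare_tree(tree, cfg)
  classify_prepared(tree, prep, focal, targets, cfg)
}

classify_prepared <- function(tree, prep, focal, targets, cfg) {
  focal_leaves <- taxon_leaves(prep, focal)
  sr <- sister_lineage(prep, focal = if (length(focal_leaves)) focal_leaves
                       else character(0),
                       min_focal = cfg$min_focal,
                       major_share = cfg$major_share)
  dist <- lineage_distances(prep, focal_leaves, targets, cfg)
  if (nrow(dist) > 0) {
    sets0 <- node_tip_sets(tree$phy)
    dist$monophyletic <- vapply(dist$lineage, function(L) {
      is_monophyletic_clade(tree, taxon_leaves(tree, L),
                            sets = sets0)$monophyletic
    }, logical(1))
  } else {
    dist$monophyletic <- logical(0)
  }
  asg <- taxon_leaves(tree, "Asgard")
  asg_mono <- if (length(asg) >= 2) {
    is_monophyletic_clade(tree, asg)$monophyletic
  } else NA
  asg_mono_f <- if (length(asg) >= 2 && length(focal_leaves) > 0) {
    is_monophyletic_clade(tree, c(asg, taxon_leaves(tree, focal)))$monophyletic
  } else asg_mono
  tibble(
    marker_id = tree$marker_id, dataset = tree$dataset,
    n_focal = length(focal_leaves),
    n_unknown = sum(tree$taxa$matched == "none"),
    focal_status = sr$status, sister_label = sr$sister_label,
    rooting = prep$rooting,
    asgard_monophyly = asg_mono, asgard_monophyly_with_focal = asg_mono_f,
    sister_composition = sr$sister_composition,
    distances = list(dist))
}

# position of one lineage relative to its archaeal neighbourhood
affinity_of_lineage <- function(tree, prep, lineage, cfg) {
  leaves <- taxon_leaves(prep, lineage)
  if (length(leaves) < cfg$min_lineage_leaves) return("unresolved_or_missing")
  if (!is_monophyletic_clade(prep, leaves)$monophyletic) {
    return("unresolved_or_missing")
  }
  phy <- prep$phy
  ntip <- length(phy$tip.label)
  sets <- node_tip_sets(phy)
  node <- mrca_node(prep, leaves)
  own <- if (node <= ntip) node else sets[[node]]
  tx <- prep$taxa
  # climb until the surrounding clade holds classified archaeal leaves
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(parent) == 0) return("unresolved_or_missing")
    pool <- setdiff(sets[[parent]], own)
    nb <- tx[pool, ]
    nb <- nb[nb$domain == "Archaea" & nb$lineage != "Unknown" &
               nb$lineage != lineage, ]
    if (nrow(nb) > 0) break
    node <- parent
  }
  shares <- prop.table(table(nb$group))
  kc <- sum(shares[names(shares) %in% c("Korarchaeota", "Crenarchaeota")])
  own_group <- tx$group[match(leaves[1], tx$label)]
  own_share <- sum(shares[names(shares) == own_group])
  if (own_share >= 0.5) return("own_group")
  if (kc >= 0.5) return("kor_cren")
  if (max(shares) >= 0.5) return("other_archaea")
  "unresolved_or_missing"
}

tabulate_positions <- function(classifications, cfg) {
  cl <- classifications |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_focal == 0 ~ "no_focal",
      .data$focal_status == "absent" ~ "too_few_focal",
      .data$focal_status %in% c("unresolved", "paraphyletic_focal") ~ "not_resolved",
      .data$focal_status %in% c("sister", "nested") ~ .data$sister_label,
      TRUE ~ "not_resolved"))
  if (cfg$tabulation == "loose") {
    near <- vapply(seq_len(nrow(cl)), function(i) {
      if (cl$category[i] != "not_resolved" || cl$n_focal[i] < cfg$min_focal) {
        return(NA_character_)
      }
      d <- cl$distances[[i]]
      d <- d[!is.na(d$distance) & d$distance <= cfg$d_near, ]
      if (nrow(d) == 0) return(NA_character_)
      d$lineage[which.min(d$distance)]
    }, character(1))
    cl$category[!is.na(near)] <- near[!is.na(near)]
  }
  cl |>
    dplyr::count(.data$dataset, .data$category) |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(total = rowSums(dplyr::across(-"category"))) |>
    dplyr::arrange(dplyr::desc(.data$total))
}

#' Survey a tree set
#'
#' Runs [classify_tree()] over every marker and aggregates: the
#' position-census table (one category per tree per dataset: the sister
#' or nesting lineage, `not_resolved`, `too_few_focal`, or `no_focal`),
#' a monophyly census (Asgard monophyly with and without the focal clade
#' branching inside), and a lineage-affinity census recording, for each
#' lineage in `affinity_lineages`, whether it branches with its own
#' group, close to Korarchaeota/Crenarchaeota, with other archaea, or is
#' unresolved/missing.
#'
#' @param set A `tree_set`.
#' @inheritParams classify_tree
#' @param affinity_lineages Lineages to census (default Njordarchaeales
#'   against the Hodarchaeales control).
#' @return An object of class `lgt_survey`: list with `classifications`,
#'   `table1` (position census), `monophyly`, `affinity`, `focal`, `cfg`.
#' @export
survey_trees <- function(set, focal = "Eukarya", targets = NULL,
                         affinity_lineages = c("Njordarchaeales",
                                               "Hodarchaeales"),
                         cfg = survey_config()) {
  stopifnot(inherits(set, "tree_set"), nrow(set) >= 1)
  rows <- vector("list", nrow(set))
  aff_rows <- vector("list", nrow(set))
  for (i in seq_len(nrow(set))) {
    tree <- set$tree[[i]]
    prep <- prepare_tree(tree, cfg)
    rows[[i]] <- classify_prepared(tree, prep, focal, targets, cfg)
    if (length(affinity_lineages) > 0) {
      aff_rows[[i]] <- tibble(
        marker_id = tree$marker_id, dataset = tree$dataset,
        lineage = affinity_lineages,
        affinity = vapply(affinity_lineages, function(L) {
          affinity_of_lineage(tree, prep, L, cfg)
        }, character(1)))
    }
  }
  classifications <- dplyr::bind_rows(rows)
  affinity <- if (length(affinity_lineages) > 0) {
    dplyr::bind_rows(aff_rows) |>
      dplyr::count(.data$lineage, .data$dataset, .data$affinity) |>
      tidyr::pivot_wider(names_from = "affinity", values_from = "n",
                         values_fill = 0L)
  } else tibble()
  monophyly <- classifications |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      asgard_monophyletic = sum(.data$asgard_monophyly, na.rm = TRUE),
      asgard_monophyletic_with_focal =
        sum(.data$asgard_monophyly_with_focal, na.rm = TRUE),
      no_focal = sum(.data$n_focal == 0), .groups = "drop")
  structure(list(classifications = classifications,
                 table1 = tabulate_positions(classifications, cfg),
                 monophyly = monophyly, affinity = affinity,
                 focal = focal, cfg = cfg),
            class = "lgt_survey")
}

#' @export
print.lgt_survey <- function(x, ...) {
  cat(sprintf("<lgt_survey: %d trees, focal = %s>\n",
              nrow(x$classifications), x$focal))
  cat("Position census:\n")
  print(x$table1, n = 30)
  invisible(x)
}

#' Nodal-distance profile of one target lineage
#'
#' For every marker, the nodal distance between the focal clade and the
#' target lineage on the collapsed, rooted tree, plus the occurrence
#' histogram over defined distances. Nested and absent cases are counted
#' separately, never folded into the histogram.
#'
#' @param set A `tree_set`.
#' @param target Target lineage name.
#' @inheritParams classify_tree
#' @return An object of class `distance_profile`: `per_marker` tibble
#'   (`marker_id`, `dataset`, `distance`, `nested`, `status`),
#'   `histogram` tibble (`distance`, `n`), `target`, `focal`,
#'   `n_defined`, `n_nested`, `n_absent`.
#' @export
distance_profile <- function(set, focal = "Eukarya", target,
                             cfg = survey_config()) {
  stopifnot(inherits(set, "tree_set"))
  n <- nrow(set)
  distance <- rep(NA_integer_, n); nested <- rep(FALSE, n)
  status <- rep("defined", n)
  for (i in seq_len(n)) {
    tree <- set$tree[[i]]
    fl <- taxon_leaves(tree, focal)
    tl <- taxon_leaves(tree, target)
    if (length(fl) < 1 || length(tl) < cfg$min_lineage_leaves) {
      status[i] <- "absent"
      next
    }
    prep <- prepare_tree(tree, cfg)
    nd <- nodal_distance(prep, fl, tl)
    if (nd$nested) {
      nested[i] <- TRUE; status[i] <- "nested"
    } else {
      distance[i] <- nd$value
    }
  }
  per_marker <- tibble(marker_id = set$marker_id, dataset = set$dataset,
                       distance = distance, nested = nested, status = status)
  histogram <- per_marker |>
    dplyr::filter(!is.na(.data$distance)) |>
    dplyr::count(.data$distance, name = "n") |>
    dplyr::arrange(.data$distance)
  structure(list(per_marker = per_marker, histogram = histogram,
                 target = target, focal = focal,
                 n_defined = sum(status == "defined"),
                 n_nested = sum(nested), n_absent = sum(status == "absent")),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile %s vs %s: %d defined, %d nested, %d absent>\n",
              x$focal, x$target, x$n_defined, x$n_nested, x$n_absent))
  print(x$histogram, n = 20)
  invisible(x)
}

profile_mode <- function(profile) {
  h <- profile$histogram
  if (nrow(h) == 0) return(NA_integer_)
  cand <- h$distance[h$n == max(h$n)]
  max(cand)  # break ties toward the bulk (larger distance)
}

profile_near_count <- function(profile, d_near) {
  sum(profile$histogram$n[profile$histogram$distance <= d_near])
}

#' Generate matched null distance profiles from the simulator
#'
#' Simulates `n_replicates` tree sets under the given configuration with
#' every transfer probability set to zero (taxon sampling, noise and
#' focal-missing rate retained), and profiles each one. These nulls embody
#' the expectation that, absent transfer, the focal clade's distance to
#' any lineage is governed by the species topology and sampling imbalance
#' alone.
#'
#' @param sim_cfg A [simulation_config()] describing the matched design.
#' @param target Target lineage to profile.
#' @param n_replicates Number of null sets (>= 100 recommended).
#' @param focal Focal taxon name.
#' @param cfg A [survey_config()].
#' @param seed Base seed for the null replicates (replicate r uses
#'   `seed + r`).
#' @return A list of `distance_profile` objects.
#' @export
make_null_profiles <- function(sim_cfg, target, n_replicates = 100,
                               focal = "Eukarya", cfg = survey_config(),
                               seed = sim_cfg$seed + 10000L) {
  stopifnot(inherits(sim_cfg, "simulation_config"), n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    cfg0 <- sim_cfg
    cfg0$p_lgt_focal_to_lineage <- numeric(0)
    cfg0$k_lgt_focal_to_lineage <- NULL
    cfg0$p_lgt_lineage_to_focal <- numeric(0)
    cfg0$p_lgt_lineage_to_donor <-
      sim_cfg$p_lgt_lineage_to_donor[0, , drop = FALSE]
    cfg0$seed <- as.integer((seed + r) %% .Machine$integer.max)
    sim <- simulate_gene_trees(cfg0)
    distance_profile(sim$trees, focal = focal, target = target, cfg = cfg)
  })
}

#' Score a distance profile for transfer-driven bimodality
#'
#' Operationalises the visual two-signal reading of a distance profile
#' as a simulation-based near-excess test: the observed number of
#' markers at distance `<= d_near` is compared with the same count in
#' matched no-transfer null profiles. The add-one-smoothed exceedance
#' probability is `(1 + #{null >= observed}) / (1 + n_null)`.
#' Classification: `bimodal_lgt` when the near excess is significant at
#' `alpha` while the histogram mode sits beyond `d_near` (two signals);
#' `sister_like` when the mode itself is `<= d_near`; `unrelated_like`
#' when the near count is null-consistent; `inconclusive` otherwise.
#'
#' @param profile A [distance_profile()].
#' @param nulls A list of null `distance_profile`s (from
#'   [make_null_profiles()]) or a numeric vector of null near counts.
#' @param cfg A [survey_config()] (uses `d_near`, `alpha`).
#' @return A one-row tibble of class `lgt_call`: `target`, `n_defined`,
#'   `n_nested`, `near_count`, `near_excess_p`, `mode`, `classification`,
#'   `n_null`.
#' @export
lgt_score <- function(profile, nulls, cfg = survey_config()) {
  stopifnot(inherits(profile, "distance_profile"))
  if (is.list(nulls)) {
    if (length(nulls) == 0) abort("lgt_score requires a non-empty null set")
    null_near <- vapply(nulls, profile_near_count, numeric(1),
                        d_near = cfg$d_near)
  } else {
    if (length(nulls) == 0) abort("lgt_score requires a non-empty null set")
    null_near <- as.numeric(nulls)
  }
  obs <- profile_near_count(profile, cfg$d_near)
  p <- (1 + sum(null_near >= obs)) / (1 + length(null_near))
  mode <- profile_mode(profile)
  classification <- if (!is.na(mode) && p < cfg$alpha && mode > cfg$d_near) {
    "bimodal_lgt"
  } else if (!is.na(mode) && mode <= cfg$d_near) {
    "sister_like"
  } else if (p >= cfg$alpha) {
    "unrelated_like"
  } else {
    "inconclusive"
  }
  out <- tibble(target = profile$target, n_defined = profile$n_defined,
                n_nested = profile$n_nested, near_count = obs,
                near_excess_p = p, mode = mode,
                classification = classification,
                n_null = length(null_near))
  class(out) <- c("lgt_call", class(out))
  out
}

#' Infer per-marker transfer direction
#'
#' Adds a `direction` column to a survey's classifications. A marker is
#' called `to_prokaryote` (proto-eukaryote gene replacing a prokaryotic
#' lineage's copy) when the focal clade is sister to exactly one lineage
#' while every other scored lineage of that lineage's group lies beyond
#' `d_far`; `to_eukaryote` when the focal clade is nested inside a
#' lineage; `ambiguous` otherwise.
#'
#' @param survey An `lgt_survey`, or its classifications tibble.
#' @param cfg A [survey_config()] (uses `d_far`).
#' @return The classifications tibble with a `direction` column.
#' @export
infer_direction <- function(survey, cfg = survey_config()) {
  cl <- if (inherits(survey, "lgt_survey")) survey$classifications else survey
  cl$direction <- vapply(seq_len(nrow(cl)), function(i) {
    st <- cl$focal_status[i]
    if (st == "nested") return("to_eukaryote")
    if (st != "sister") return("ambiguous")
    lab <- cl$sister_label[i]
    if (grepl("/", lab, fixed = TRUE)) return("ambiguous")
    d <- cl$distances[[i]]
    grp <- d$group[match(lab, d$lineage)]
    if (is.na(grp)) {
      grp <- cl$sister_composition[[i]]$group[
        match(lab, cl$sister_composition[[i]]$lineage)]
    }
    if (is.na(grp)) return("ambiguous")
    others <- d[d$group == grp & d$lineage != lab & !is.na(d$distance), ]
    if (nrow(others) == 0) return("ambiguous")
    if (all(others$distance > cfg$d_far)) "to_prokaryote" else "ambiguous"
  }, character(1))
  cl
}
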