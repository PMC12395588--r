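# Ground-truthed gene-tree simulator. Transfers are modelled purely
# topologically (SPR moves on the expanded species tree): the survey
# consumes topologies, so simulating sequences would test nothing extra.

#' Default lineage table for the simulator
#'
#' Emulates the taxon sampling of a heavily imbalanced archaeal marker
#' dataset: 175 Asgard leaves split over 14 lineages (about half of all
#' archaeal leaves), 72 TACK (split here into Crenarchaeota, Korarchaeota
#' and the BAT cluster), 41 DPANN, 43 Euryarchaeota, and a 14-leaf focal
#' Eukarya clade.
#'
#' @return A tibble: `lineage`, `group`, `domain`, `n`.
#' @export
default_lineages <- function() {
  tibble::tribble(
    ~lineage,              ~group,          ~n,
    "Hodarchaeales",       "Asgard",        20L,
    "Njordarchaeales",     "Asgard",        10L,
    "Gerdarchaeales",      "Asgard",         8L,
    "Heimdallarchaeaceae", "Asgard",        12L,
    "Kariarchaeaceae",     "Asgard",         8L,
    "Wukongarchaeia",      "Asgard",         6L,
    "Lokiarchaeales",      "Asgard",        30L,
    "Helarchaeales",       "Asgard",        10L,
    "Thorarchaeia",        "Asgard",        20L,
    "Baldrarchaeia",       "Asgard",         8L,
    "Hermodarchaeia",      "Asgard",        10L,
    "Odinarchaeia",        "Asgard",         8L,
    "Jordarchaeia",        "Asgard",        10L,
    "Sifarchaeales",       "Asgard",        15L,
    "Korarchaeota",        "Korarchaeota",  12L,
    "Crenarchaeota",       "Crenarchaeota", 30L,
    "BAT",                 "BAT",           30L,
    "DPANN",               "DPANN",         41L,
    "Euryarchaeota",       "Euryarchaeota", 43L,
    "Eukarya",             "Eukarya",       14L
  ) |>
    dplyr::mutate(domain = ifelse(.data$group == "Eukarya", "Eukarya",
                                  "Archaea"))
}

#' Default lineage-level species topology
#'
#' A rooted tree over the lineages of [default_lineages()]: the focal
#' clade branches outside the archaeal radiation (the three-domains
#' configuration; the simulator's "true" null position), DPANN and
#' Euryarchaeota are the deepest archaeal groups, and the Asgard clade
#' follows the two-cluster consensus shape with the Heimdallarchaeia
#' lineages (Hodarchaeales, Njordarchaeales, Gerdarchaeales,
#' Heimdallarchaeaceae, Kariarchaeaceae) plus Wukongarchaeia on one side.
#'
#' @return An [ape::phylo] with one tip per lineage.
#' @export
default_species_topology <- function() {
  asg <- paste0(
    "((Wukongarchaeia,(Hodarchaeales,((Njordarchaeales,Gerdarchaeales),",
    "(Heimdallarchaeaceae,Kariarchaeaceae)))),",
    "(Sifarchaeales,(Jordarchaeia,((Odinarchaeia,(Helarchaeales,Lokiarchaeales)),",
    "(Hermodarchaeia,(Thorarchaeia,Baldrarchaeia))))))")
  nk <- paste0("(Eukarya,(DPANN,(Euryarchaeota,((BAT,(Crenarchaeota,",
               "Korarchaeota)),", asg, "))));")
  ape::read.tree(text = nk)
}

#' Lineage map matching the simulator's leaf-naming scheme
#'
#' One prefix rule per lineage (`"<lineage>_"`), so simulated leaves such
#' as `Hodarchaeales_007` classify without per-leaf records.
#'
#' @param lineages A lineage table as from [default_lineages()].
#' @return A [lineage_map()].
#' @export
simulation_lineage_map <- function(lineages = default_lineages()) {
  lineage_map(rules = tibble(pattern = paste0(lineages$lineage, "_"),
                             domain = lineages$domain,
                             group = lineages$group,
                             lineage = lineages$lineage))
}

#' Build a simulation configuration
#'
#' The defaults are the study conditions the package is designed around:
#' 56 markers over 345 leaves with the taxon imbalance of
#' [default_lineages()], a minority of markers carrying a transfer event,
#' 3 random NNI moves of topological noise per tree, and a small
#' probability that a marker lacks the focal clade entirely.
#'
#' Event semantics follow the direction of gene replacement: a transfer
#' from the proto-eukaryotic stem into a lineage
#' (`p_lgt_focal_to_lineage` / `k_lgt_focal_to_lineage`) makes that
#' lineage's sequence eukaryote-like, so the recipient lineage is
#' regrafted onto the focal clade's stem (focal sister to recipient,
#' everything else far). A transfer from a lineage into the
#' proto-eukaryotic stem (`p_lgt_lineage_to_focal`) regrafts the focal
#' clade onto an edge strictly inside the recipient lineage's clade
#' (focal nested). A prokaryote-to-prokaryote replacement
#' (`p_lgt_lineage_to_donor`) regrafts the recipient lineage onto the
#' donor group's stem.
#'
#' @param n_markers Number of gene trees (default 56).
#' @param lineages Lineage table (`lineage`, `group`, `domain`, `n`).
#' @param species_topology Rooted lineage-level [ape::phylo].
#' @param focal_size Number of focal-clade leaves (default 14).
#' @param p_lgt_focal_to_lineage Named probabilities, per recipient
#'   lineage, that a marker carries a focal-to-lineage transfer.
#' @param k_lgt_focal_to_lineage Optional named integer counts: exactly
#'   this many markers (sampled without replacement) carry the event;
#'   overrides the probabilities for the named lineages.
#' @param p_lgt_lineage_to_focal Named probabilities per donor lineage of
#'   a lineage-to-focal (nesting) transfer.
#' @param p_lgt_lineage_to_donor Data frame `lineage`, `donor`, `p` of
#'   prokaryote-to-prokaryote replacement rates.
#' @param nni_noise Random NNI moves per gene tree (default 3), applied
#'   to internal edges not adjacent to event regraft points.
#' @param length_mean,length_sd Mean and sd (substitutions/site) of the
#'   log-normal branch-length model.
#' @param p_focal_missing Probability a marker lacks the focal clade.
#' @param dataset Dataset tag stamped on the simulated markers.
#' @param seed Master seed; all per-marker randomness derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_markers = 56,
                              lineages = default_lineages(),
                              species_topology = default_species_topology(),
                              focal_size = 14,
                              p_lgt_focal_to_lineage =
                                c(Hodarchaeales = 5 / 56, Njordarchaeales = 6 / 56),
                              k_lgt_focal_to_lineage = NULL,
                              p_lgt_lineage_to_focal =
                                c(Lokiarchaeales = 1 / 56, Helarchaeales = 1 / 56),
                              p_lgt_lineage_to_donor = tibble::tribble(
                                ~lineage, ~donor, ~p,
                                "Njordarchaeales", "Korarchaeota", 0.17,
                                "Njordarchaeales", "Crenarchaeota", 0.17,
                                "Hodarchaeales", "Korarchaeota", 0.03,
                                "Hodarchaeales", "Crenarchaeota", 0.03),
                              nni_noise = 3,
                              length_mean = 0.06,
                              length_sd = 0.06,
                              p_focal_missing = 4 / 113,
                              dataset = "NM",
                              seed = 1L) {
  lineages <- as_tibble(lineages)
  stopifnot(all(c("lineage", "group", "domain", "n") %in% names(lineages)),
            all(lineages$n >= 1), n_markers >= 1, focal_size >= 1,
            nni_noise >= 0, length_mean > 0, length_sd >= 0)
  lineages$n[lineages$lineage == "Eukarya"] <- as.integer(focal_size)
  tips <- species_topology$tip.label
  if (!setequal(tips, lineages$lineage)) {
    abort("species_topology tips must match the lineage table exactly")
  }
  probs <- c(p_lgt_focal_to_lineage, p_lgt_lineage_to_focal,
             p_lgt_lineage_to_donor$p, p_focal_missing)
  if (any(probs < 0 | probs > 1)) abort("all LGT probabilities must be in [0, 1]")
  chk <- function(x, what) {
    bad <- setdiff(x, lineages$lineage)
    if (length(bad)) abort(paste0("unknown ", what, ": ", paste(bad, collapse = ", ")))
  }
  chk(names(p_lgt_focal_to_lineage), "focal_to_lineage recipient")
  chk(names(p_lgt_lineage_to_focal), "lineage_to_focal donor")
  chk(p_lgt_lineage_to_donor$lineage, "lineage_to_donor recipient")
  chk(p_lgt_lineage_to_donor$donor, "lineage_to_donor donor")
  if (!is.null(k_lgt_focal_to_lineage)) {
    chk(names(k_lgt_focal_to_lineage), "k_lgt recipient")
    if (any(k_lgt_focal_to_lineage < 0) || sum(k_lgt_focal_to_lineage) > n_markers) {
      abort("k_lgt_focal_to_lineage counts must be >= 0 and sum to <= n_markers")
    }
  }
  sdlog <- if (length_sd == 0) 0 else sqrt(log(1 + (length_sd / length_mean)^2))
  structure(list(
    n_markers = as.integer(n_markers), lineages = lineages,
    species_topology = species_topology, focal_size = as.integer(focal_size),
    p_lgt_focal_to_lineage = p_lgt_focal_to_lineage,
    k_lgt_focal_to_lineage = k_lgt_focal_to_lineage,
    p_lgt_lineage_to_focal = p_lgt_lineage_to_focal,
    p_lgt_lineage_to_donor = as_tibble(p_lgt_lineage_to_donor),
    nni_noise = as.integer(nni_noise),
    length_meanlog = log(length_mean) - sdlog^2 / 2, length_sdlog = sdlog,
    p_focal_missing = p_focal_missing, dataset = dataset,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

one_tip_phylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = 1, Nnode = 1L, root.edge = 1),
            class = "phylo")
}

# detach `tip` and reattach it as sister to `target` (both tip labels)
move_tip_sister <- function(phy, tip, target) {
  back <- ape::drop.tip(phy, tip)
  back$edge.length <- rep(1, nrow(back$edge))
  out <- ape::bind.tree(back, one_tip_phylo(tip),
                        where = match(target, back$tip.label), position = 0.5)
  ape::collapse.singles(out)  # the 1-tip subtree's root is a degree-2 node
}

# splice per-lineage subtrees into the lineage-level topology
expand_lineage_tree <- function(ltree, counts) {
  ltree$edge.length <- NULL
  nk <- ape::write.tree(ltree)
  for (nm in names(counts)) {
    n <- counts[[nm]]
    lab <- sprintf("%s_%03d", nm, seq_len(n))
    sub <- if (n == 1) lab else {
      s <- ape::write.tree(ape::rcoal(n, tip.label = lab))
      sub(";$", "", s)
    }
    nk <- sub(paste0("([(,])", nm, "([,:)])"), paste0("\\1", sub, "\\2"), nk)
  }
  phy <- ape::read.tree(text = nk)
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

# regraft the clade of `clade_tips` onto a random internal edge strictly
# inside the clade spanned by `recipient_tips`; returns NULL if impossible
regraft_inside <- function(phy, clade_tips, recipient_tips) {
  sub <- ape::keep.tip(phy, clade_tips)
  sub$root.edge <- 1
  back <- ape::drop.tip(phy, clade_tips)
  back$edge.length <- rep(1, nrow(back$edge))
  ntip <- length(back$tip.label)
  ridx <- match(recipient_tips, back$tip.label)
  if (anyNA(ridx) || length(ridx) < 3) return(NULL)
  rmrca <- ape::getMRCA(back, ridx)
  sets <- node_tip_sets(back)
  cand <- which(vapply(seq_along(sets), function(v) {
    v > ntip && v != rmrca && all(sets[[v]] %in% ridx)
  }, logical(1)))
  if (length(cand) == 0) return(NULL)
  at <- cand[sample.int(length(cand), 1)]
  ape::bind.tree(back, sub, where = at, position = 0.5)
}

# k random NNI moves avoiding edges incident to `protect` (ape node ids)
apply_random_nni <- function(phy, k, protect = integer(0)) {
  if (k <= 0) return(phy)
  ntip <- length(phy$tip.label)
  for (r in seq_len(k)) {
    E <- phy$edge
    cand <- which(E[, 2] > ntip & !(E[, 1] %in% protect) &
                    !(E[, 2] %in% protect))
    if (length(cand) == 0) break
    i <- cand[sample.int(length(cand), 1)]
    u <- E[i, 1]; v <- E[i, 2]
    vrows <- which(E[, 1] == v)
    urows <- which(E[, 1] == u & E[, 2] != v)
    if (length(vrows) == 0 || length(urows) == 0) next
    ri <- vrows[sample.int(length(vrows), 1)]
    rj <- urows[sample.int(length(urows), 1)]
    phy$edge[ri, 1] <- u
    phy$edge[rj, 1] <- v
  }
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a ground-truthed gene-tree set
#'
#' For each marker: clone the lineage-level species topology; apply any
#' transfer events as SPR moves (see [simulation_config()] for the event
#' semantics); expand every lineage tip into a random coalescent subtree
#' of its configured size; apply `nni_noise` random NNI moves away from
#' event regraft points; optionally delete the focal clade; draw
#' log-normal branch lengths. Each marker gets at most one
#' focal-placement event and at most one relocation per recipient
#' lineage; conflicting draws are resolved uniformly at random and only
#' the applied event is recorded as truth.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `lgt_simulation`: `trees` (a `tree_set`),
#'   `truth` (tibble: `marker_id`, `event`, `recipient`, `donor`,
#'   `direction_truth`, `focal_missing`), `map` (the matching
#'   [lineage_map()]), and `config`.
#' @export
simulate_gene_trees <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_markers
  marker_ids <- sprintf("S%03d", seq_len(n))
  counts <- stats::setNames(cfg$lineages$n, cfg$lineages$lineage)
  map <- simulation_lineage_map(cfg$lineages)

  # --- draw all events under the master seed ---------------------------
  focal_missing <- stats::runif(n) < cfg$p_focal_missing
  focal_events <- rep(NA_character_, n)   # recipient lineage, or NA
  nested_events <- rep(NA_character_, n)  # donor lineage, or NA
  if (!is.null(cfg$k_lgt_focal_to_lineage)) {
    pool <- which(!focal_missing)
    for (nm in names(cfg$k_lgt_focal_to_lineage)) {
      k <- cfg$k_lgt_focal_to_lineage[[nm]]
      if (k == 0) next
      if (k > length(pool)) abort("not enough focal-bearing markers for k_lgt counts")
      pick <- pool[sample.int(length(pool), k)]
      focal_events[pick] <- nm
      pool <- setdiff(pool, pick)
    }
  } else {
    for (i in which(!focal_missing)) {
      hits <- names(cfg$p_lgt_focal_to_lineage)[
        stats::runif(length(cfg$p_lgt_focal_to_lineage)) <
          cfg$p_lgt_focal_to_lineage]
      if (length(hits) > 0) focal_events[i] <- hits[sample.int(length(hits), 1)]
    }
  }
  for (i in which(!focal_missing & is.na(focal_events))) {
    hits <- names(cfg$p_lgt_lineage_to_focal)[
      stats::runif(length(cfg$p_lgt_lineage_to_focal)) <
        cfg$p_lgt_lineage_to_focal]
    if (length(hits) > 0) nested_events[i] <- hits[sample.int(length(hits), 1)]
  }
  donor_events <- vector("list", n)
  pd <- cfg$p_lgt_lineage_to_donor
  if (nrow(pd) > 0) {
    for (i in seq_len(n)) {
      hit <- which(stats::runif(nrow(pd)) < pd$p)
      if (length(hit) > 0) {
        ev <- pd[hit, c("lineage", "donor")]
        # one relocation per recipient lineage; focal event wins a conflict
        ev <- ev[!duplicated(ev$lineage), , drop = FALSE]
        ev <- ev[!(ev$lineage %in% c(focal_events[i], nested_events[i])), ,
                 drop = FALSE]
        if (nrow(ev) > 0) donor_events[[i]] <- ev
      }
    }
  }
  marker_seeds <- sample.int(.Machine$integer.max - 1L, n)

  # --- build each marker's tree ---------------------------------------
  trees <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(marker_seeds[i])
    ltree <- cfg$species_topology
    if (!is.na(focal_events[i])) {
      ltree <- move_tip_sister(ltree, focal_events[i], "Eukarya")
    }
    dev <- donor_events[[i]]
    if (!is.null(dev)) {
      for (j in seq_len(nrow(dev))) {
        ltree <- move_tip_sister(ltree, dev$lineage[j], dev$donor[j])
      }
    }
    phy <- expand_lineage_tree(ltree, counts)
    nested_ok <- FALSE
    if (!is.na(nested_events[i])) {
      euk <- grep("^Eukarya_", phy$tip.label, value = TRUE)
      rec <- grep(paste0("^", nested_events[i], "_"), phy$tip.label, value = TRUE)
      res <- regraft_inside(phy, euk, rec)
      if (!is.null(res)) { phy <- res; nested_ok <- TRUE }
    }
    # protect event attachment regions from NNI noise
    protect <- integer(0)
    prot_groups <- list()
    if (!is.na(focal_events[i]) || nested_ok) {
      prot_groups <- c(prot_groups, list("Eukarya"))
    }
    if (!is.null(dev)) prot_groups <- c(prot_groups, as.list(dev$lineage))
    for (g in prot_groups) {
      tipsg <- grep(paste0("^", g, "_"), phy$tip.label)
      if (length(tipsg) >= 2) {
        mg <- ape::getMRCA(phy, tipsg)
        pg <- phy$edge[phy$edge[, 2] == mg, 1]
        protect <- c(protect, mg, pg)
      }
    }
    phy <- apply_random_nni(phy, cfg$nni_noise, protect = protect)
    if (focal_missing[i]) {
      phy <- ape::drop.tip(phy, grep("^Eukarya_", phy$tip.label, value = TRUE))
    }
    phy$edge.length <- stats::rlnorm(nrow(phy$edge), cfg$length_meanlog,
                                     cfg$length_sdlog)
    trees[[i]] <- gene_tree(phy, marker_id = marker_ids[i],
                            dataset = cfg$dataset, map = map)
    truth_rows[[i]] <- tibble(
      marker_id = marker_ids[i],
      event = if (focal_missing[i]) "none"
              else if (!is.na(focal_events[i])) "focal_to_lineage"
              else if (nested_ok) "lineage_to_focal"
              else "none",
      recipient = if (!focal_missing[i] && !is.na(focal_events[i]))
        focal_events[i] else if (nested_ok) "Eukarya" else NA_character_,
      donor = if (nested_ok) nested_events[i] else NA_character_,
      direction_truth = if (focal_missing[i]) NA_character_
                        else if (!is.na(focal_events[i])) "to_prokaryote"
                        else if (nested_ok) "to_eukaryote" else NA_character_,
      donor_swaps = list(if (is.null(dev)) tibble(lineage = character(),
                                                  donor = character()) else dev),
      focal_missing = focal_missing[i])
  }
  structure(list(trees = tree_set(trees, provenance = "simulate_gene_trees"),
                 truth = dplyr::bind_rows(truth_rows),
                 map = map, config = cfg),
            class = "lgt_simulation")
}

#' Write a simulation to disk
#'
#' Writes the Newick files and manifest ([write_tree_set()]), the lineage
#' map (`lineage_map.tsv`) and the truth table (`truth.tsv`, with
#' prokaryote-to-prokaryote swaps flattened to `"recipient>donor"`
#' strings) into `dir`.
#'
#' @param sim An `lgt_simulation` from [simulate_gene_trees()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lgt_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree_set(sim$trees, dir)
  write_lineage_map(sim$map, file.path(dir, "lineage_map.tsv"))
  flat <- sim$truth |>
    dplyr::mutate(donor_swaps = vapply(.data$donor_swaps, function(d) {
      if (nrow(d) == 0) "" else paste(d$lineage, d$donor, sep = ">", collapse = ";")
    }, character(1)))
  readr::write_tsv(flat, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Simulate an alignment with a planted lineage-specific insertion
#'
#' Builds a conserved protein backbone alignment and inserts, at a shared
#' anchor column, a focal-only block whose per-taxon length is drawn from
#' `insertion_len` (emulating observed 9-13 and 6-9 residue
#' lineage-specific insertions; shorter copies are left-aligned and
#' gap-padded within the block). Non-focal taxa are gapped across the
#' whole block.
#'
#' @param n_focal,n_other Number of insertion-carrying and other taxa.
#' @param length Backbone alignment length in columns (before insertion).
#' @param insertion_len Integer vector of allowed per-taxon insertion
#'   lengths (default `9:13`).
#' @param flank_conservation Probability that a backbone residue matches
#'   its column's modal residue (1.0 = fully conserved backbone).
#' @param anchor Backbone column after which the block is inserted
#'   (default: middle column).
#' @param seed Random seed.
#' @return A list of class `insertion_sim`: `alignment` (character
#'   matrix, rows = taxa), `focal` (labels), and `truth` (`start0`,
#'   `end0` half-open block columns, `lengths` named per-taxon vector).
#' @export
simulate_insertion_alignment <- function(n_focal = 6, n_other = 20,
                                         length = 120, insertion_len = 9:13,
                                         flank_conservation = 0.95,
                                         anchor = NULL, seed = 1) {
  stopifnot(n_focal >= 1, n_other >= 1, length >= 20,
            all(insertion_len >= 1),
            flank_conservation >= 0, flank_conservation <= 1)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(anchor)) anchor <- floor(length / 2)
  w <- max(insertion_len)
  if (anchor < 1 || anchor > length - 1) abort("anchor outside the backbone")
  taxa <- c(sprintf("INS_%02d", seq_len(n_focal)),
            sprintf("REF_%02d", seq_len(n_other)))
  nt <- length(taxa)
  modal <- sample(aa, length, replace = TRUE)
  back <- matrix(rep(modal, each = nt), nrow = nt)
  flip <- matrix(stats::runif(nt * length) > flank_conservation, nrow = nt)
  if (any(flip)) {
    back[flip] <- sample(aa, sum(flip), replace = TRUE)
  }
  lens <- sample(rep(insertion_len, length.out = max(n_focal, length(insertion_len))),
                 n_focal)
  block <- matrix("-", nrow = nt, ncol = w)
  for (i in seq_len(n_focal)) {
    block[i, seq_len(lens[i])] <- sample(aa, lens[i], replace = TRUE)
  }
  mat <- cbind(back[, seq_len(anchor), drop = FALSE], block,
               back[, (anchor + 1):length, drop = FALSE])
  rownames(mat) <- taxa
  structure(list(alignment = mat, focal = taxa[seq_len(n_focal)],
                 truth = list(start0 = anchor, end0 = anchor + w,
                              lengths = stats::setNames(lens, taxa[seq_len(n_focal)]))),
            class = "insertion_sim")
}
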