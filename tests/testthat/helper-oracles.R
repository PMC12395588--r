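# Brute-force oracles, independent of the package's traversal code:
# adjacency lists + breadth-first search over the edge matrix only.

oracle_adjacency <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_path <- function(phy, from, to) {
  adj <- oracle_adjacency(phy)
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w) }
    }
  }
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

# tips reachable from `node` without crossing `block`
oracle_side_tips <- function(phy, node, block) {
  adj <- oracle_adjacency(phy)
  ntip <- length(phy$tip.label)
  seen <- rep(FALSE, length(adj)); seen[c(node, block)] <- TRUE
  queue <- node; out <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v <= ntip) out <- c(out, v)
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  sort(out)
}

# all unrooted bipartitions (one side each), via edge deletion + BFS
oracle_bipartitions <- function(phy) {
  lapply(seq_len(nrow(phy$edge)), function(i) {
    oracle_side_tips(phy, phy$edge[i, 2], phy$edge[i, 1])
  })
}

oracle_monophyletic <- function(phy, tip_idx) {
  ntip <- length(phy$tip.label)
  q <- sort(tip_idx)
  if (length(q) <= 1 || length(q) == ntip) return(TRUE)
  for (side in oracle_bipartitions(phy)) {
    if (identical(side, q) ||
        identical(sort(setdiff(seq_len(ntip), side)), q)) return(TRUE)
  }
  FALSE
}

# MRCA on a rooted tree: last common element of the root paths
oracle_mrca <- function(phy, tip_idx) {
  root <- length(phy$tip.label) + 1L
  paths <- lapply(tip_idx, function(t) oracle_path(phy, root, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# nodal distance: internal nodes strictly between the two MRCAs, or nested
oracle_nodal_distance <- function(phy, tips_a, tips_b) {
  a <- if (length(tips_a) == 1) tips_a else oracle_mrca(phy, tips_a)
  b <- if (length(tips_b) == 1) tips_b else oracle_mrca(phy, tips_b)
  root <- length(phy$tip.label) + 1L
  pa <- oracle_path(phy, root, a)
  pb <- oracle_path(phy, root, b)
  if (a %in% pb || b %in% pa) return(list(value = NA_integer_, nested = TRUE))
  p <- oracle_path(phy, a, b)
  list(value = length(p) - 2L, nested = FALSE)
}

# sibling leaf set of a monophyletic clade on a rooted tree
oracle_sibling_tips <- function(phy, tip_idx) {
  m <- if (length(tip_idx) == 1) tip_idx else oracle_mrca(phy, tip_idx)
  root <- length(phy$tip.label) + 1L
  if (m == root) return(NULL)
  parent <- phy$edge[phy$edge[, 2] == m, 1]
  sibs <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], m)
  sort(unlist(lapply(sibs, function(s) oracle_side_tips(phy, s, parent))))
}

# exhaustive Fitch: minimise changes over all ancestral 0/1 labelings
oracle_fitch <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  tipst <- as.integer(states[phy$tip.label])
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(tipst, as.integer(intToBits(mask)[seq_len(nint)]))
    ch <- sum(lab[phy$edge[, 1]] != lab[phy$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# random gene tree over a small synthetic taxonomy
random_mapped_tree <- function(n = 30, n_lineages = 5, seed = NULL,
                               marker_id = "R1") {
  if (!is.null(seed)) set.seed(seed)
  lins <- paste0("L", seq_len(n_lineages))
  map <- lineage_map(rules = tibble::tibble(
    pattern = paste0(lins, "_"), domain = "Archaea", group = "G1",
    lineage = lins))
  phy <- ape::rtree(n)
  phy$tip.label <- sprintf("%s_%02d", sample(lins, n, replace = TRUE),
                           seq_len(n))
  phy$node.label <- NULL
  gene_tree(phy, marker_id = marker_id, map = map)
}

toy_map <- function() {
  lineage_map(
    records = tibble::tibble(
      label = c("E1", "E2", "E3", "E4"),
      domain = "Eukarya", group = "Eukarya", lineage = "Eukarya"),
    rules = tibble::tibble(
      pattern = c("H_", "N_", "L_", "K_", "D_", "Y_"),
      domain = "Archaea",
      group = c("Asgard", "Asgard", "Asgard", "Korarchaeota", "DPANN",
                "Euryarchaeota"),
      lineage = c("Hodarchaeales", "Njordarchaeales", "Lokiarchaeales",
                  "Korarchaeota", "DPANN", "Euryarchaeota")))
}

# small fully-labelled example: focal (E1..E4) sister to Hodarchaeales,
# DPANN outgroup available for rooting
toy_tree <- function(newick = NULL, marker_id = "toy") {
  if (is.null(newick)) {
    newick <- paste0("(((E1:1,(E2:1,(E3:1,E4:1):1):1):1,(H_1:1,H_2:1):1):1,",
                     "(((N_1:1,N_2:1):1,(L_1:1,L_2:1):1):1,",
                     "((K_1:1,K_2:1):1,((Y_1:1,Y_2:1):1,(D_1:1,D_2:1):1):1):1):1);")
  }
  read_gene_tree(newick, marker_id = marker_id, dataset = "NM",
                 map = toy_map())
}

# a cached bank of matched null distance profiles, shared across tests
null_bank_env <- new.env(parent = emptyenv())

null_profile_bank <- function(target = "Hodarchaeales", n = 101,
                              n_markers = 56) {
  key <- paste(target, n, n_markers, sep = "|")
  if (!is.null(null_bank_env[[key]])) return(null_bank_env[[key]])
  cfg0 <- simulation_config(
    n_markers = n_markers,
    p_lgt_focal_to_lineage = numeric(0),
    p_lgt_lineage_to_focal = numeric(0),
    p_lgt_lineage_to_donor = tibble::tibble(
      lineage = character(), donor = character(), p = numeric()),
    seed = 777L)
  bank <- make_null_profiles(cfg0, target = target, n_replicates = n,
                             seed = 20000L)
  null_bank_env[[key]] <- bank
  bank
}

expect_valid_phylo <- function(phy) {
  msgs <- utils::capture.output(ape::checkValidPhylo(phy))
  testthat::expect_false(any(grepl("FATAL|MODERATE", msgs)))
}
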