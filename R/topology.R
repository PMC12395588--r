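# Core topological queries: monophyly, weak-edge collapsing, rooting, MRCA,
# nodal distance, sister-group classification.

# tip index sets per node, postorder accumulation; node ids are ape ids
# (tips 1..ntip, internals ntip+1..ntip+Nnode)
node_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    p <- eo[i, 1]; ch <- eo[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

tip_indices <- function(tree, labels) {
  idx <- match(labels, tree$phy$tip.label)
  if (anyNA(idx)) {
    abort(paste0("labels absent from tree '", tree$marker_id, "': ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Leaves of a gene tree belonging to a named taxon
#'
#' Matches `name` against the `lineage`, `group` and `domain` columns of
#' the tree's taxon classification (any hit counts), so `"Eukarya"`,
#' `"Asgard"` or `"Hodarchaeales"` all work.
#'
#' @param tree A [gene_tree()].
#' @param name Lineage, group or domain name.
#' @return Character vector of matching leaf labels (possibly empty).
#' @export
taxon_leaves <- function(tree, name) {
  tx <- tree$taxa
  tx$label[tx$lineage == name | tx$group == name | tx$domain == name]
}

#' Test monophyly of a leaf set (rooting-invariant)
#'
#' A set is monophyletic on an unrooted tree iff it forms one side of the
#' bipartition induced by a single edge. Singleton queries and the full
#' leaf set are monophyletic by convention. When the query is not
#' monophyletic, intruders are the extra leaves inside the smallest clade
#' (either side of any edge) containing the query.
#'
#' @param tree A [gene_tree()] (rooted or unrooted).
#' @param query Character vector of leaf labels (subset of the tree's
#'   leaves), or an integer vector of tip indices.
#' @return A list: `query`, `monophyletic`, `witness_node` (ape id of the
#'   node whose stem edge separates query from rest; `NA` if none or if
#'   the split is only realised on the complement side), and `intruders`
#'   (character vector, empty iff monophyletic).
#' @export
is_monophyletic_clade <- function(tree, query, sets = NULL) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  q <- if (is.numeric(query)) as.integer(query) else tip_indices(tree, query)
  if (length(q) == 0) abort("empty monophyly query")
  qlab <- phy$tip.label[q]
  inq <- rep(FALSE, ntip); inq[q] <- TRUE
  if (length(q) == 1 || length(q) == ntip) {
    return(list(query = qlab, monophyletic = TRUE,
                witness_node = if (length(q) == 1) q else NA_integer_,
                intruders = character(0)))
  }
  if (is.null(sets)) sets <- node_tip_sets(phy)
  nq <- length(q)
  witness <- NA_integer_
  # a clade (in the unrooted sense) is each node's tip set or its complement
  best <- NULL; best_size <- ntip + 1L
  for (v in seq_along(sets)) {
    s <- sets[[v]]
    ns <- length(s)
    hits <- sum(inq[s])
    if (hits == nq) {                       # node's clade contains the query
      if (ns == nq) witness <- v
      if (ns < best_size) { best <- s; best_size <- ns }
    } else if (hits == 0L) {                # complement side contains it
      if ((ntip - ns) == nq && is.na(witness)) witness <- v
      if ((ntip - ns) < best_size) {
        best <- setdiff(seq_len(ntip), s); best_size <- ntip - ns
      }
    }
  }
  mono <- best_size == nq
  intr <- if (mono) character(0) else phy$tip.label[setdiff(best, q)]
  list(query = qlab, monophyletic = mono,
       witness_node = if (mono) witness else NA_integer_,
       intruders = intr)
}

# contract the stem edges of the given internal nodes into polytomies
contract_edges <- function(phy, nodes) {
  if (length(nodes) == 0) return(phy)
  ntip <- length(phy$tip.label)
  nodes <- nodes[nodes > ntip]
  if (length(nodes) == 0) return(phy)
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
  ntot <- ntip + phy$Nnode
  map <- seq_len(ntot)
  drop_child <- logical(ntot); drop_child[nodes] <- TRUE
  E <- phy$edge
  for (i in seq_len(nrow(E))) {
    ch <- E[i, 2]
    if (ch > ntip && drop_child[ch]) map[ch] <- map[E[i, 1]]
  }
  keep <- !drop_child[E[, 2]]
  E2 <- cbind(map[E[keep, 1]], E[keep, 2])
  len2 <- phy$edge.length[keep]
  old_int <- sort(unique(c(E2[E2 > ntip])))
  new_id <- integer(ntot)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[old_int] <- ntip + seq_along(old_int)
  out <- list(edge = cbind(new_id[E2[, 1]], new_id[E2[, 2]]),
              tip.label = phy$tip.label,
              Nnode = length(old_int))
  if (!is.null(phy$edge.length)) out$edge.length <- len2
  if (!is.null(phy$node.label)) out$node.label <- phy$node.label[old_int - ntip]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Collapse weakly supported or very short internal edges
#'
#' Operationalises the visual judgement that a node is "unresolved": every
#' internal edge with support below `min_support` or length below
#' `min_length` is contracted into a polytomy. The leaf set is unchanged;
#' contracting every internal edge yields a valid star tree.
#'
#' @param tree A [gene_tree()].
#' @param min_support Support threshold (same scale as the tree's node
#'   labels, conventionally 0-100). Edges whose child node has a numeric
#'   support below this are contracted. Use 0 to disable.
#' @param min_length Branch-length threshold in substitutions/site.
#'   Requires real branch lengths; an error is raised if the source tree
#'   had none (pass `min_length = 0` for topology-only input).
#' @return A [gene_tree()] with the contracted topology.
#' @export
collapse_weak_edges <- function(tree, min_support = 50, min_length = 0.005) {
  stopifnot(inherits(tree, "gene_tree"), min_support >= 0, min_length >= 0)
  if (min_length > 0 && !tree$lengths_real) {
    abort(sprintf("tree '%s' has no real branch lengths; length-based collapsing refused (set min_length = 0)",
                  tree$marker_id))
  }
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  sup <- node_supports(tree)
  root <- ntip + 1L
  kill <- integer(0)
  E <- phy$edge
  internal_child <- E[, 2] > ntip
  for (i in which(internal_child)) {
    ch <- E[i, 2]
    weak <- FALSE
    s <- sup[ch - ntip]
    if (min_support > 0 && !is.na(s) && s < min_support) weak <- TRUE
    if (min_length > 0 && phy$edge.length[i] < min_length) weak <- TRUE
    if (weak) kill <- c(kill, ch)
  }
  out <- tree
  out$phy <- contract_edges(phy, kill)
  out
}

#' Root a gene tree by an ordered outgroup policy
#'
#' The root is placed on the stem edge of the first policy group that is
#' present (>= 1 leaf, but not all leaves) and monophyletic on the
#' unrooted tree; if no policy group qualifies, the tree is midpoint
#' rooted on path lengths. The rooting actually used is recorded in the
#' returned object and propagated into downstream reports.
#'
#' @param tree A [gene_tree()] with >= 4 leaves.
#' @param policy Character vector of group (or lineage/domain) names,
#'   tried in order.
#' @return A rooted [gene_tree()]; `$rooting` is `"outgroup:<name>"` or
#'   `"midpoint-fallback"`.
#' @export
root_gene_tree <- function(tree, policy = c("DPANN", "Euryarchaeota")) {
  stopifnot(inherits(tree, "gene_tree"))
  if (length(policy) == 0) abort("rooting policy must be non-empty")
  phy <- tree$phy
  if (length(phy$tip.label) < 4) {
    abort(sprintf("tree '%s' has fewer than 4 leaves; refusing to root",
                  tree$marker_id))
  }
  for (g in policy) {
    out_leaves <- taxon_leaves(tree, g)
    n <- length(out_leaves)
    if (n == 0 || n == length(phy$tip.label)) next
    if (is_monophyletic_clade(tree, out_leaves)$monophyletic) {
      rooted <- ape::root(phy, outgroup = out_leaves, resolve.root = TRUE)
      tree$phy <- rooted
      tree$rooted <- TRUE
      tree$rooting <- paste0("outgroup:", g)
      return(tree)
    }
  }
  tree$phy <- suppressWarnings(suppressMessages(phangorn::midpoint(phy)))
  tree$rooted <- TRUE
  tree$rooting <- "midpoint-fallback"
  tree
}

#' Remove the root of a gene tree
#'
#' @param tree A rooted [gene_tree()].
#' @return The unrooted tree (basal polytomy), with rooting cleared.
#' @export
unroot_gene_tree <- function(tree) {
  tree$phy <- ape::unroot(tree$phy)
  tree$rooted <- FALSE
  tree$rooting <- NA_character_
  tree
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree A rooted [gene_tree()].
#' @param query Leaf labels (a single label returns that tip's index).
#' @return An ape node id.
#' @export
mrca_node <- function(tree, query) {
  if (!tree$rooted) abort("mrca_node requires a rooted tree")
  idx <- tip_indices(tree, query)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree$phy, idx)
}

#' Nodal distance between two clades
#'
#' The number of internal nodes strictly between the MRCAs of the two
#' sets: `value = (edges on the MRCA path) - 1`, so sister clades score 1
#' and polytomy nodes on the path count once. If one MRCA is an ancestor
#' of (or equal to) the other, the pair is flagged `nested` and no integer
#' distance is defined - nesting is a distinct transfer signal, not a
#' small distance.
#'
#' @param tree A rooted [gene_tree()].
#' @param set_a,set_b Disjoint leaf-label sets, both present in the tree.
#' @return A list: `value` (integer or `NA` when nested), `nested`
#'   (logical), `path_nodes` (ape ids strictly between the MRCAs).
#' @export
nodal_distance <- function(tree, set_a, set_b, sets = NULL) {
  if (!tree$rooted) abort("nodal_distance requires a rooted tree")
  if (length(intersect(set_a, set_b)) > 0) {
    abort("nodal_distance: leaf sets overlap")
  }
  ia <- tip_indices(tree, set_a)
  ib <- tip_indices(tree, set_b)
  a <- if (length(ia) == 1) ia else ape::getMRCA(tree$phy, ia)
  b <- if (length(ib) == 1) ib else ape::getMRCA(tree$phy, ib)
  if (a == b) return(list(value = NA_integer_, nested = TRUE, path_nodes = integer(0)))
  if (is.null(sets)) sets <- node_tip_sets(tree$phy)
  if (all(ib %in% sets[[a]]) || all(ia %in% sets[[b]])) {
    return(list(value = NA_integer_, nested = TRUE, path_nodes = integer(0)))
  }
  path <- ape::nodepath(tree$phy, a, b)
  list(value = length(path) - 2L, nested = FALSE,
       path_nodes = path[-c(1L, length(path))])
}

#' Identify the sister lineage of a focal clade
#'
#' Classifies the focal clade's position in a rooted (and usually
#' weak-edge-collapsed) gene tree, reproducing the per-tree verdicts of a
#' sister-group census: `absent` (fewer than `min_focal` focal leaves),
#' `paraphyletic_focal`, `sister` (to one lineage, or to two lineages each
#' holding at least `major_share` of the sibling's classified leaves, with
#' a joined label such as `"Njordarchaeales/Gerdarchaeales"`), `nested`
#' (the sibling is a strict subset of one lineage whose smallest
#' containing clade also contains the focal MRCA's parent), or
#' `unresolved` (three or more major lineages, a mixed-group polytomy at
#' the parent, or no lineage reaching `major_share`).
#'
#' Unknown-classified leaves are excluded from all lineage shares.
#'
#' @param tree A rooted [gene_tree()].
#' @param focal Focal leaf labels, or a single taxon name resolved via
#'   [taxon_leaves()] (default `"Eukarya"`).
#' @param min_focal Minimum focal leaves for a verdict (default 4; trees
#'   with only two or three focal leaves are too thin to place).
#' @param major_share Minimum share of classified sibling leaves for a
#'   lineage to count as a major sister component (default 0.2).
#' @return A one-row tibble: `status`, `sister_label`, `n_focal`,
#'   `rooting_used`, and `sister_composition` (list-column tibble of
#'   `lineage`, `group`, `n`).
#' @export
sister_lineage <- function(tree, focal = "Eukarya", min_focal = 4,
                           major_share = 0.2) {
  if (!tree$rooted) abort("sister_lineage requires a rooted tree")
  fl <- if (length(focal) == 1 && !(focal %in% tree$phy$tip.label)) {
    taxon_leaves(tree, focal)
  } else focal
  empty_comp <- list(tibble(lineage = character(), group = character(),
                            n = integer()))
  res <- function(status, label = NA_character_, comp = empty_comp) {
    tibble(status = status, sister_label = label, n_focal = length(fl),
           rooting_used = tree$rooting, sister_composition = comp)
  }
  if (length(fl) < min_focal) return(res("absent"))
  mono <- is_monophyletic_clade(tree, fl)
  if (!mono$monophyletic) return(res("paraphyletic_focal"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  m <- mrca_node(tree, fl)
  root <- ntip + 1L
  if (m == root) return(res("unresolved"))
  E <- phy$edge
  p <- E[E[, 2] == m, 1]
  sib_nodes <- E[E[, 1] == p & E[, 2] != m, 2]
  sets <- node_tip_sets(phy)
  sib_tips <- unique(unlist(sets[sib_nodes]))
  tx <- tree$taxa[sib_tips, ]
  cls <- tx[tx$lineage != "Unknown", ]
  comp <- cls |>
    dplyr::count(.data$lineage, .data$group, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$lineage)
  if (nrow(comp) == 0) return(res("unresolved"))
  # mixed-group polytomy at the parent
  if (length(sib_nodes) >= 3 && length(unique(cls$group)) >= 2) {
    return(res("unresolved", comp = list(comp)))
  }
  major <- comp[comp$n / sum(comp$n) >= major_share, ]
  if (nrow(major) == 0 || nrow(major) >= 3) {
    return(res("unresolved", comp = list(comp)))
  }
  if (nrow(major) == 1 && nrow(comp) == 1) {
    # single-lineage sibling: sister, or focal nested inside that lineage
    lin <- comp$lineage[1]
    lin_tips <- which(tree$taxa$lineage == lin)
    extra <- setdiff(lin_tips, sib_tips)
    if (length(extra) > 0) {
      ml <- ape::getMRCA(phy, lin_tips)
      if (!is.null(ml) && all(sets[[p]] %in% sets[[ml]])) {
        return(res("nested", label = lin, comp = list(comp)))
      }
    }
    return(res("sister", label = lin, comp = list(comp)))
  }
  if (nrow(major) == 1) {
    return(res("sister", label = major$lineage[1], comp = list(comp)))
  }
  res("sister", label = paste(major$lineage, collapse = "/"),
      comp = list(comp))
}
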