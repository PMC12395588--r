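#' Construct a gene-tree object
#'
#' A `gene_tree` pairs one marker's (usually unrooted) topology with its
#' per-leaf taxonomic classification, a marker identifier and a dataset tag
#' (`"RP"` ribosomal / `"NM"` non-ribosomal). Trees are stored unrooted by
#' convention; rooting is an explicit, recorded operation
#' ([root_gene_tree()]) because the survey's conclusions depend on it.
#'
#' @param phy An [ape::phylo] object with >= 3 uniquely-labelled leaves.
#' @param marker_id Marker identifier (e.g. `"M037"`).
#' @param dataset `"RP"`, `"NM"`, or `NA`.
#' @param map A [lineage_map()] used to classify the leaf labels.
#' @return A `gene_tree`: list with elements `phy`, `marker_id`, `dataset`,
#'   `taxa` (tibble from [classify_taxa()]), `lengths_real` (FALSE when the
#'   source had no branch lengths and unit lengths were substituted),
#'   `rooted`, `rooting` and `focal_absent` (no Eukarya-classified leaf).
#' @export
gene_tree <- function(phy, marker_id, dataset = NA_character_, map) {
  stopifnot(inherits(phy, "phylo"))
  if (length(phy$tip.label) < 3) {
    abort(sprintf("gene tree '%s' has %d leaves; need at least 3",
                  marker_id, length(phy$tip.label)))
  }
  if (anyDuplicated(phy$tip.label)) {
    abort(sprintf("gene tree '%s' has duplicate leaf labels", marker_id))
  }
  lengths_real <- !is.null(phy$edge.length)
  if (!lengths_real) phy$edge.length <- rep(1, nrow(phy$edge))
  # an unstated length (e.g. on a collapsed redundant node) adds no path
  phy$edge.length[is.na(phy$edge.length)] <- 0
  if (any(phy$edge.length < 0)) {
    abort(sprintf("gene tree '%s' has negative branch lengths", marker_id))
  }
  taxa <- classify_taxa(phy$tip.label, map)
  structure(list(
    phy = phy,
    marker_id = as.character(marker_id),
    dataset = as.character(dataset),
    taxa = taxa,
    lengths_real = lengths_real,
    rooted = FALSE,
    rooting = NA_character_,
    focal_absent = !any(taxa$domain == "Eukarya")
  ), class = "gene_tree")
}

#' Read one Newick gene tree
#'
#' Supports are taken from internal node labels when those are numeric;
#' non-numeric labels are kept as clade names and support is treated as
#' absent. Square-bracket comments are stripped before parsing.
#'
#' @param newick A Newick string, or a path to a file holding one tree.
#' @param marker_id Marker identifier.
#' @param dataset `"RP"`, `"NM"`, or `NA`.
#' @param map A [lineage_map()].
#' @return A [gene_tree()].
#' @export
read_gene_tree <- function(newick, marker_id, dataset = NA_character_, map) {
  txt <- if (length(newick) == 1 && !grepl("(", newick, fixed = TRUE) &&
             file.exists(newick)) {
    paste(readr::read_lines(newick), collapse = "")
  } else {
    paste(newick, collapse = "")
  }
  txt <- gsub("\\[[^]]*\\]", "", txt)  # bracket comments
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo")) {
    abort(sprintf("could not parse Newick for marker '%s'", marker_id))
  }
  phy <- ape::collapse.singles(phy)  # tolerate redundant parentheses
  gene_tree(phy, marker_id = marker_id, dataset = dataset, map = map)
}

#' Node support values of a gene tree
#'
#' Numeric internal node labels, in internal-node order; `NA` where the
#' label is absent or non-numeric.
#'
#' @param tree A [gene_tree()].
#' @return Numeric vector of length `phy$Nnode`.
#' @export
node_supports <- function(tree) {
  phy <- tree$phy
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree %s [%s]: %d leaves (%d Eukarya, %d Unknown)%s%s>\n",
              x$marker_id, x$dataset, length(x$phy$tip.label),
              sum(x$taxa$domain == "Eukarya"),
              sum(x$taxa$matched == "none"),
              if (x$rooted) paste0(", rooted: ", x$rooting) else ", unrooted",
              if (x$lengths_real) "" else ", unit lengths"))
  invisible(x)
}

#' Load a directory of Newick gene trees as a tree set
#'
#' Files with extensions `.nwk`, `.tree`, `.treefile` or `.newick` are
#' read; an optional manifest assigns `marker_id` and `dataset` per file
#' (otherwise the marker id is the file stem and the dataset is guessed
#' from a leading `RP`/`NM` in the stem). Unreadable files are recorded as
#' skipped markers, not errors. Ordering is deterministic by `marker_id`,
#' independent of file-system order.
#'
#' @param dir Directory of Newick files (one tree per file).
#' @param map A [lineage_map()].
#' @param manifest Optional path to a TSV with columns
#'   `marker_id`, `dataset`, `filename`.
#' @return A `tree_set`: tibble with one row per marker (`marker_id`,
#'   `dataset`, `n_leaves`, `n_focal`, `n_unknown`, `focal_absent`, `tree`
#'   list-column) plus attributes `provenance` and `skipped` (tibble of
#'   file, reason).
#' @export
load_tree_set <- function(dir, map, manifest = NULL) {
  if (!dir.exists(dir)) abort(paste0("tree directory not found: ", dir))
  files <- list.files(dir, pattern = "\\.(nwk|tree|treefile|newick)$",
                      full.names = TRUE)
  if (!is.null(manifest)) {
    man <- readr::read_tsv(manifest, show_col_types = FALSE,
                           comment = "#", progress = FALSE)
    need <- c("marker_id", "dataset", "filename")
    if (!all(need %in% names(man))) {
      abort("manifest must have columns marker_id, dataset, filename")
    }
    files <- file.path(dir, man$filename)
    ids <- as.character(man$marker_id)
    datasets <- as.character(man$dataset)
  } else {
    stems <- sub("\\.[^.]*$", "", basename(files))
    ids <- stems
    datasets <- ifelse(grepl("^RP", stems), "RP",
                       ifelse(grepl("^NM", stems), "NM", NA_character_))
  }
  if (length(files) == 0) abort(paste0("no Newick files found in ", dir))
  trees <- vector("list", length(files))
  skipped <- list()
  for (i in seq_along(files)) {
    gt <- tryCatch(
      read_gene_tree(files[i], marker_id = ids[i], dataset = datasets[i],
                     map = map),
      error = function(e) e)
    if (inherits(gt, "error")) {
      skipped[[length(skipped) + 1]] <-
        tibble(file = basename(files[i]), reason = conditionMessage(gt))
    } else {
      trees[[i]] <- gt
    }
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  if (length(trees) == 0) abort(paste0("no readable trees in ", dir))
  tree_set(trees,
           provenance = paste0("directory: ", normalizePath(dir)),
           skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
             tibble(file = character(), reason = character()))
}

#' Assemble gene trees into a tree set
#'
#' @param trees A list of [gene_tree()] objects with unique marker ids.
#' @param provenance Free-text source description.
#' @param skipped Optional tibble of skipped inputs (`file`, `reason`).
#' @return A `tree_set` tibble; see [load_tree_set()].
#' @export
tree_set <- function(trees, provenance = "in-memory",
                     skipped = tibble(file = character(), reason = character())) {
  ids <- vapply(trees, function(t) t$marker_id, character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate marker_id in tree set: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ord <- order(ids)
  trees <- trees[ord]
  out <- tibble(
    marker_id = ids[ord],
    dataset = vapply(trees, function(t) t$dataset, character(1)),
    n_leaves = vapply(trees, function(t) length(t$phy$tip.label), integer(1)),
    n_focal = vapply(trees, function(t) sum(t$taxa$domain == "Eukarya"), integer(1)),
    n_unknown = vapply(trees, function(t) sum(t$taxa$matched == "none"), integer(1)),
    focal_absent = vapply(trees, function(t) t$focal_absent, logical(1)),
    tree = trees
  )
  attr(out, "provenance") <- provenance
  attr(out, "skipped") <- skipped
  class(out) <- c("tree_set", class(out))
  out
}

#' Write a tree set as Newick files plus a manifest
#'
#' @param set A `tree_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes one `<marker_id>.nwk` per tree and
#'   `manifest.tsv` (`marker_id`, `dataset`, `filename`).
#' @export
write_tree_set <- function(set, dir) {
  stopifnot(inherits(set, "tree_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- paste0(set$marker_id, ".nwk")
  for (i in seq_len(nrow(set))) {
    ape::write.tree(set$tree[[i]]$phy, file = file.path(dir, fn[i]))
  }
  readr::write_tsv(tibble(marker_id = set$marker_id, dataset = set$dataset,
                          filename = fn),
                   file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(dir)
}
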