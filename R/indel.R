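# Lineage-specific insertion detection in protein alignments, plus a
# Fitch presence/absence parsimony check of insertion history.

#' Read an aligned FASTA file as a character matrix
#'
#' @param path Aligned FASTA (protein). All sequences must have equal
#'   length; ragged input is an error.
#' @return Character matrix, one row per taxon (rownames = labels), one
#'   column per alignment column.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) abort(paste0("no sequences in ", path))
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1) {
    abort(paste0("sequences in ", path, " have unequal lengths (",
                 paste(range(w), collapse = "-"), "): not an alignment"))
  }
  mat <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(mat) <- sub("\\s.*$", "", names(ss))
  toupper(mat)
}

#' Write a character-matrix alignment as FASTA
#'
#' @param mat Character matrix with taxon rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(mat, path) {
  ss <- Biostrings::AAStringSet(apply(mat, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

GAP_CHARS <- c("-", ".")

# modal-residue fraction among non-gap characters, per column
column_conservation <- function(mat, cols) {
  vapply(cols, function(j) {
    x <- mat[, j]
    x <- x[!(x %in% GAP_CHARS)]
    if (length(x) == 0) return(0)
    max(table(x)) / length(x)
  }, numeric(1))
}

#' Find lineage-specific insertion blocks in an alignment
#'
#' Scans for maximal runs of at least `min_len` consecutive columns in
#' which the fraction of focal taxa carrying a residue is at least
#' `presence` while the fraction of other taxa carrying a residue is at
#' most `absence`. A run is reported only when the mean column
#' conservation (modal-residue fraction among non-gap characters) of the
#' `flank_w` columns on each side reaches `min_flank_cons` - the
#' hallmark of an insertion in an otherwise conserved region. Per-taxon
#' residue lengths inside each block are reported so variable-length
#' insertions (e.g. 9-13 or 6-9 residues) are visible, and focal taxa
#' lacking the block (fewer than half its columns occupied) are listed
#' as explicit exceptions, never silently averaged away.
#'
#' @param aln Character matrix (see [read_alignment()]) or a path.
#' @param focal Character vector of insertion-carrying taxa (a strict,
#'   non-empty subset of the alignment's rows).
#' @param min_len Minimum block width in columns (default 5).
#' @param presence Minimum focal residue fraction per column (default 0.9).
#' @param absence Maximum non-focal residue fraction per column
#'   (default 0.1).
#' @param flank_w Flank width in columns (default 5).
#' @param min_flank_cons Minimum mean flank conservation (default 0.8).
#' @return A tibble, one row per block, sorted by start: `start0`/`end0`
#'   (0-based half-open), `start1`/`end1` (1-based inclusive), `width`,
#'   `focal_present_fraction`, `other_present_fraction`,
#'   `flank_conservation`, `lengths` (list-column: named per-taxon
#'   residue counts), `focal_absent` (list-column: focal taxa lacking
#'   the block).
#' @export
find_lineage_insertions <- function(aln, focal, min_len = 5,
                                    presence = 0.9, absence = 0.1,
                                    flank_w = 5, min_flank_cons = 0.8) {
  if (is.character(aln) && !is.matrix(aln)) aln <- read_alignment(aln)
  if (min_len < 1) abort("min_len must be >= 1")
  taxa <- rownames(aln)
  if (is.null(taxa)) abort("alignment matrix must have taxon rownames")
  missing <- setdiff(focal, taxa)
  if (length(missing) > 0) {
    abort(paste0("focal taxa absent from alignment: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(focal) == 0) abort("focal set is empty")
  if (length(focal) == length(taxa)) {
    abort("focal set must be a strict subset of the alignment's taxa")
  }
  isf <- taxa %in% focal
  res <- !(aln %in% GAP_CHARS)
  dim(res) <- dim(aln)
  f_frac <- colMeans(res[isf, , drop = FALSE])
  o_frac <- colMeans(res[!isf, , drop = FALSE])
  # core columns satisfy both thresholds; a core run of >= min_len is then
  # extended over the surrounding others-absent zone, so the ragged tail of
  # a variable-length insertion stays inside its block
  core <- f_frac >= presence & o_frac <= absence
  zone <- o_frac <= absence & f_frac > 0
  runs <- rle(zone)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- list()
  nc <- ncol(aln)
  for (k in keep) {
    s <- starts[k]; e <- ends[k]
    cruns <- rle(core[s:e])
    if (!any(cruns$values & cruns$lengths >= min_len)) next
    lf <- max(1, s - flank_w):(s - 1)
    rf <- (e + 1):min(nc, e + flank_w)
    if (s == 1 || e == nc) next  # block touching an edge has no flank
    fc <- mean(column_conservation(aln, c(lf, rf)))
    if (fc < min_flank_cons) next
    block <- res[isf, s:e, drop = FALSE]
    lens <- rowSums(block)
    names(lens) <- taxa[isf]
    absent_focal <- names(lens)[lens < (e - s + 1) / 2]
    out[[length(out) + 1]] <- tibble(
      start0 = s - 1L, end0 = e, start1 = s, end1 = e,
      width = e - s + 1L,
      focal_present_fraction = mean(f_frac[s:e]),
      other_present_fraction = mean(o_frac[s:e]),
      flank_conservation = fc,
      lengths = list(lens),
      focal_absent = list(absent_focal))
  }
  if (length(out) == 0) {
    return(tibble(start0 = integer(), end0 = integer(), start1 = integer(),
                  end1 = integer(), width = integer(),
                  focal_present_fraction = numeric(),
                  other_present_fraction = numeric(),
                  flank_conservation = numeric(),
                  lengths = list(), focal_absent = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start0)
}

# Fitch small parsimony for a binary character on a rooted tree;
# postorder edge traversal so child state sets are complete when merged
fitch_count <- function(phy, states) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[[phy$tip.label[i]]]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  changes <- 0L
  for (i in seq_len(nrow(eo))) {
    p <- eo[i, 1]; ch <- eo[i, 2]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- intersect(sets[[p]], sets[[ch]])
      if (length(inter) > 0) {
        sets[[p]] <- inter
      } else {
        sets[[p]] <- union(sets[[p]], sets[[ch]])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Parsimony check of an insertion's presence pattern on a species tree
#'
#' Counts the minimum number of gain/loss events (Fitch small parsimony,
#' unit costs) needed to explain which lineages carry an insertion, and
#' reports whether the pattern is a single clean gain, i.e. whether the
#' carriers are monophyletic on the supplied tree.
#'
#' @param carriers Character vector of carrier lineage names.
#' @param species_tree A rooted [ape::phylo] over lineages (tips must
#'   include every carrier).
#' @return A one-row tibble: `n_carriers`, `min_events`,
#'   `single_gain` (TRUE iff one event suffices), `carriers_monophyletic`.
#' @export
insertion_parsimony_check <- function(carriers, species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  tips <- species_tree$tip.label
  missing <- setdiff(carriers, tips)
  if (length(missing) > 0) {
    abort(paste0("carrier lineages missing from species tree: ",
                 paste(missing, collapse = ", ")))
  }
  states <- stats::setNames(ifelse(tips %in% carriers, "1", "0"), tips)
  n_events <- if (length(unique(states)) == 1) {
    if (all(states == "1")) 1L else 0L  # all carriers: one gain at the root
  } else {
    fitch_count(species_tree, states)
  }
  mono <- if (length(carriers) == 0) {
    NA
  } else if (length(carriers) == length(tips)) {
    TRUE
  } else {
    tmp <- gene_tree(species_tree, marker_id = "species",
                     map = lineage_map())
    is_monophyletic_clade(tmp, carriers)$monophyletic
  }
  tibble(n_carriers = length(carriers), min_events = n_events,
         single_gain = n_events <= 1L && length(carriers) > 0,
         carriers_monophyletic = mono)
}
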