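small_lineages <- function() {
  dplyr::mutate(default_lineages(),
                n = ifelse(.data$lineage == "Eukarya", 4L, 3L))
}

test_that("identical config and seed give byte-identical output", {
  cfg <- simulation_config(n_markers = 5, lineages = small_lineages(),
                           focal_size = 4, seed = 99)
  a <- simulate_gene_trees(cfg)
  b <- simulate_gene_trees(cfg)
  expect_identical(lapply(a$trees$tree, function(t) ape::write.tree(t$phy)),
                   lapply(b$trees$tree, function(t) ape::write.tree(t$phy)))
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 100L
  c2 <- simulate_gene_trees(cfg2)
  expect_false(identical(ape::write.tree(a$trees$tree[[1]]$phy),
                         ape::write.tree(c2$trees$tree[[1]]$phy)))
})

test_that("without events or noise, gene trees mirror the species topology", {
  cfg <- simulation_config(
    n_markers = 4, p_lgt_focal_to_lineage = numeric(0),
    p_lgt_lineage_to_focal = numeric(0),
    p_lgt_lineage_to_donor = tibble::tibble(lineage = character(),
                                            donor = character(), p = numeric()),
    nni_noise = 0, p_focal_missing = 0, seed = 31)
  sim <- simulate_gene_trees(cfg)
  lins <- cfg$lineages$lineage
  for (i in 1:4) {
    tr <- sim$trees$tree[[i]]
    for (L in lins) {
      expect_true(is_monophyletic_clade(tr, taxon_leaves(tr, L))$monophyletic)
    }
    # focal placement matches the species tree: the oracle distances on the
    # expanded tree equal the package's on the rooted tree
    r <- root_gene_tree(tr)
    for (L in c("Hodarchaeales", "Njordarchaeales")) {
      got <- nodal_distance(r, taxon_leaves(r, "Eukarya"),
                            taxon_leaves(r, L))
      ora <- oracle_nodal_distance(
        r$phy, match(taxon_leaves(r, "Eukarya"), r$phy$tip.label),
        match(taxon_leaves(r, L), r$phy$tip.label))
      expect_equal(got$value, ora$value)
    }
    expect_equal(sim$truth$event[i], "none")
  }
})

test_that("forced transfer events plant the advertised signature", {
  # every marker transferred: focal sister to recipient at distance 1
  cfg <- simulation_config(n_markers = 3,
                           p_lgt_focal_to_lineage = c(Njordarchaeales = 1),
                           p_lgt_lineage_to_focal = numeric(0),
                           nni_noise = 0, p_focal_missing = 0, seed = 8)
  sim <- simulate_gene_trees(cfg)
  expect_true(all(sim$truth$event == "focal_to_lineage"))
  expect_true(all(sim$truth$recipient == "Njordarchaeales"))
  for (tr in sim$trees$tree) {
    r <- root_gene_tree(tr)
    expect_equal(nodal_distance(r, taxon_leaves(r, "Eukarya"),
                                taxon_leaves(r, "Njordarchaeales"))$value, 1)
  }
})

test_that("event realism holds before noise for every recorded event", {
  cfg <- simulation_config(n_markers = 30, lineages = small_lineages(),
                           focal_size = 4,
                           p_lgt_focal_to_lineage = c(Hodarchaeales = 0.3,
                                                      Njordarchaeales = 0.2),
                           nni_noise = 0, p_focal_missing = 0, seed = 13)
  sim <- simulate_gene_trees(cfg)
  ev <- sim$truth[sim$truth$event == "focal_to_lineage", ]
  expect_gt(nrow(ev), 0)
  for (j in seq_len(nrow(ev))) {
    tr <- sim$trees$tree[[match(ev$marker_id[j], sim$trees$marker_id)]]
    r <- root_gene_tree(tr)
    expect_equal(nodal_distance(r, taxon_leaves(r, "Eukarya"),
                                taxon_leaves(r, ev$recipient[j]))$value, 1)
  }
})

test_that("transferred-marker counts follow the configured binomial rate", {
  p <- 5 / 56
  tiny <- dplyr::mutate(default_lineages(),
                        n = ifelse(.data$lineage == "Eukarya", 2L, 1L))
  counts <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_markers = 56, lineages = tiny, focal_size = 2,
                             p_lgt_focal_to_lineage = c(Hodarchaeales = p),
                             p_lgt_lineage_to_focal = numeric(0),
                             p_focal_missing = 0, nni_noise = 0, seed = s)
    # event drawing is independent of tree size; count from the truth table
    sum(simulate_gene_trees(cfg)$truth$event == "focal_to_lineage")
  }, numeric(1))
  se_mean <- sqrt(56 * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - 56 * p), 3 * se_mean)
  expect_true(stats::sd(counts) > 0)
})

test_that("focal-missing markers lack the focal clade and carry no event", {
  cfg <- simulation_config(n_markers = 12, lineages = small_lineages(),
                           focal_size = 4, p_focal_missing = 0.5, seed = 4)
  sim <- simulate_gene_trees(cfg)
  miss <- sim$truth$focal_missing
  expect_gt(sum(miss), 0)
  for (i in which(miss)) {
    expect_true(sim$trees$tree[[i]]$focal_absent)
    expect_equal(sim$truth$event[i], "none")
  }
  for (i in which(!miss)) expect_false(sim$trees$tree[[i]]$focal_absent)
})

test_that("insertion alignments plant the block they record", {
  # fixed length 9
  s1 <- simulate_insertion_alignment(n_focal = 6, n_other = 20,
                                     insertion_len = 9, seed = 2)
  expect_equal(s1$truth$end0 - s1$truth$start0, 9)
  blk <- s1$alignment[, (s1$truth$start0 + 1):s1$truth$end0]
  expect_true(all(blk[s1$focal, ] != "-"))
  expect_true(all(blk[setdiff(rownames(s1$alignment), s1$focal), ] == "-"))
  # variable 9-13: per-taxon lengths span the range
  s2 <- simulate_insertion_alignment(n_focal = 8, n_other = 20,
                                     insertion_len = 9:13, seed = 5)
  expect_true(all(s2$truth$lengths >= 9 & s2$truth$lengths <= 13))
  expect_gt(length(unique(s2$truth$lengths)), 1)
  # fully conserved flanks
  s3 <- simulate_insertion_alignment(flank_conservation = 1, seed = 3)
  backbone <- s3$alignment[, seq_len(s3$truth$start0)]
  expect_true(all(apply(backbone, 2, function(x) length(unique(x)) == 1)))
  # determinism
  expect_identical(simulate_insertion_alignment(seed = 11),
                   simulate_insertion_alignment(seed = 11))
})
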