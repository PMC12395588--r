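test_that("weak-edge collapsing contracts exactly the flagged edges", {
  m <- toy_map()
  # all supports strong: unchanged
  gt <- read_gene_tree("(((E1:1,E2:1)100:1,E3:1)100:1,(H_1:1,H_2:1)100:1);",
                       "C1", "NM", m)
  expect_equal(collapse_weak_edges(gt, 50, 0)$phy$Nnode, gt$phy$Nnode)
  # one weak edge -> polytomy of degree 4
  gt2 <- read_gene_tree("(((E1:1,E2:1)30:1,E3:1)90:1,(H_1:1,H_2:1)90:1);",
                        "C2", "NM", m)
  cc <- collapse_weak_edges(gt2, 50, 0)
  expect_equal(cc$phy$Nnode, gt2$phy$Nnode - 1)
  tab <- table(cc$phy$edge[, 1])
  expect_true(any(tab == 3))  # E1,E2,E3 now share a parent with the H clade edge
  expect_setequal(cc$phy$tip.label, gt2$phy$tip.label)
  # collapsing everything yields a valid star tree
  star <- collapse_weak_edges(gt2, 101, 0)
  expect_equal(star$phy$Nnode, 1)
  expect_valid_phylo(star$phy)
  # length-based collapse refused without real lengths
  gt3 <- read_gene_tree("((E1,E2),(H_1,H_2),E3);", "C3", "NM", m)
  expect_false(gt3$lengths_real)
  expect_error(collapse_weak_edges(gt3, 0, 0.005), "refused")
})

test_that("length-based collapse agrees with di2multi and is monotone", {
  set.seed(42)
  for (rep in 1:10) {
    gt <- random_mapped_tree(20)
    prev_internal <- Inf
    for (thr in c(0.1, 0.5, 1, 2)) {
      cc <- collapse_weak_edges(gt, 0, thr)
      expect_valid_phylo(cc$phy)
      # oracle: ape's own polytomy reducer on the same threshold
      ref <- ape::di2multi(gt$phy, tol = thr - 1e-9)
      expect_equal(suppressMessages(suppressWarnings(phangorn::RF.dist(cc$phy, ref))), 0)
      n_int <- sum(cc$phy$edge[, 2] > length(cc$phy$tip.label))
      expect_lte(n_int, prev_internal)
      prev_internal <- n_int
    }
  }
})

test_that("monophyly is bipartition-based and matches the brute-force oracle", {
  m <- toy_map()
  gt <- read_gene_tree("((E1,E2),(H_1,H_2),(L_1,L_2));", "U1", "NM", m)
  expect_true(is_monophyletic_clade(gt, c("E1", "E2"))$monophyletic)
  bad <- is_monophyletic_clade(gt, c("E1", "H_1"))
  expect_false(bad$monophyletic)
  expect_setequal(bad$intruders, c("E2", "H_2"))
  expect_true(is_monophyletic_clade(gt, gt$phy$tip.label)$monophyletic)
  expect_true(is_monophyletic_clade(gt, "E1")$monophyletic)
  expect_error(is_monophyletic_clade(gt, c("E1", "ZZ")), "ZZ")
  # randomised comparison against edge-deletion BFS
  set.seed(7)
  for (rep in 1:25) {
    gt <- random_mapped_tree(15)
    q <- sample(15, sample(2:8, 1))
    got <- is_monophyletic_clade(gt, gt$phy$tip.label[q])
    expect_equal(got$monophyletic, oracle_monophyletic(gt$phy, q))
  }
})

test_that("rooting follows the policy, records fallbacks, and round-trips", {
  gt <- toy_tree()
  r <- root_gene_tree(gt, c("DPANN", "Euryarchaeota"))
  expect_equal(r$rooting, "outgroup:DPANN")
  expect_true(r$rooted)
  # the DPANN pair sits immediately under the root
  sets <- lgtsurvey:::node_tip_sets(r$phy)
  root_kids <- r$phy$edge[r$phy$edge[, 1] == length(r$phy$tip.label) + 1, 2]
  kid_sets <- lapply(root_kids, function(k) sort(r$phy$tip.label[sets[[k]]]))
  expect_true(list(c("D_1", "D_2")) %in% kid_sets ||
                any(vapply(kid_sets, identical, logical(1), c("D_1", "D_2"))))
  # no policy group present -> midpoint fallback, recorded
  r2 <- root_gene_tree(gt, c("Bacteria"))
  expect_equal(r2$rooting, "midpoint-fallback")
  # root + unroot preserves the bipartition set
  expect_equal(phangorn::RF.dist(unroot_gene_tree(r)$phy,
                                 ape::unroot(gt$phy)), 0)
  m <- toy_map()
  expect_error(root_gene_tree(
    read_gene_tree("(E1,E2,E3);", "t", "NM", m)), "4 leaves")
})

test_that("MRCA matches root-path intersection on random trees", {
  gt <- toy_tree()
  r <- root_gene_tree(gt)
  expect_equal(mrca_node(r, "E1"), match("E1", r$phy$tip.label))
  pair <- mrca_node(r, c("D_1", "D_2"))
  expect_equal(pair, ape::getMRCA(r$phy, c("D_1", "D_2")))
  set.seed(11)
  for (rep in 1:25) {
    gt <- random_mapped_tree(20)
    gt$rooted <- TRUE  # ape::rtree trees are rooted
    q <- sample(20, sample(2:6, 1))
    expect_equal(mrca_node(gt, gt$phy$tip.label[q]), oracle_mrca(gt$phy, q))
  }
})

test_that("nodal distance scores sisters 1, flags nesting, and is symmetric", {
  m <- toy_map()
  gt <- read_gene_tree(
    "(((E1:1,E2:1):1,(H_1:1,H_2:1):1):1,((N_1:1,N_2:1):1,(L_1:1,L_2:1):1):1);",
    "D1", "NM", m)
  gt$rooted <- TRUE
  euk <- c("E1", "E2")
  expect_equal(nodal_distance(gt, euk, c("H_1", "H_2"))$value, 1)
  d <- nodal_distance(gt, euk, c("N_1", "N_2"))
  expect_equal(d$value, 3)
  expect_length(d$path_nodes, 3)
  # symmetry
  expect_equal(nodal_distance(gt, c("N_1", "N_2"), euk)$value, 3)
  # ancestor case: an interleaved set whose MRCA contains the other's
  nested <- nodal_distance(gt, c("E1", "H_1"), c("E2"))
  expect_true(nested$nested)
  expect_true(is.na(nested$value))
  expect_error(nodal_distance(gt, euk, c("E1", "H_1")), "overlap")
})

test_that("sister classification covers sister, nested, joint and unresolved", {
  r <- root_gene_tree(toy_tree())
  sr <- sister_lineage(r)
  expect_equal(sr$status, "sister")
  expect_equal(sr$sister_label, "Hodarchaeales")
  expect_equal(sr$rooting_used, "outgroup:DPANN")
  # nested: focal splits the Lokiarchaeales clade
  nest <- root_gene_tree(toy_tree(paste0(
    "(((L_1:1,L_2:1):1,((E1:1,(E2:1,(E3:1,E4:1):1):1):1,",
    "(L_3:1,L_4:1):1):1):1,(D_1:1,D_2:1):1);")))
  sn <- sister_lineage(nest)
  expect_equal(sn$status, "nested")
  expect_equal(sn$sister_label, "Lokiarchaeales")
  # joint sister: sibling split between two lineages above the 20% floor
  joint <- root_gene_tree(toy_tree(paste0(
    "(((E1:1,(E2:1,(E3:1,E4:1):1):1):1,((H_1:1,H_2:1):1,(N_1:1,N_2:1):1):1):1,",
    "(D_1:1,D_2:1):1);")))
  sj <- sister_lineage(joint)
  expect_equal(sj$status, "sister")
  expect_true(sj$sister_label %in% c("Hodarchaeales/Njordarchaeales",
                                     "Njordarchaeales/Hodarchaeales"))
  # mixed polytomy parent -> unresolved
  poly <- root_gene_tree(toy_tree(paste0(
    "(((E1:1,(E2:1,(E3:1,E4:1):1):1):1,(H_1:1,H_2:1):1,(L_1:1,L_2:1):1,",
    "(K_1:1,K_2:1):1):1,(D_1:1,D_2:1):1);")))
  expect_equal(sister_lineage(poly)$status, "unresolved")
  # too few focal leaves
  few <- root_gene_tree(toy_tree(paste0(
    "(((E1:1,(H_1:1,H_2:1):1):1,(L_1:1,L_2:1):1):1,(D_1:1,D_2:1):1);")))
  expect_equal(sister_lineage(few)$status, "absent")
  # paraphyletic focal
  para <- root_gene_tree(toy_tree(paste0(
    "(((E1:1,(H_1:1,(E2:1,(E3:1,E4:1):1):1):1):1,(L_1:1,L_2:1):1):1,",
    "(D_1:1,D_2:1):1);")))
  expect_equal(sister_lineage(para)$status, "paraphyletic_focal")
})

test_that("sister status and unit nodal distance coincide on resolved trees", {
  set.seed(5)
  cfg <- simulation_config(n_markers = 8,
                           k_lgt_focal_to_lineage = c(Hodarchaeales = 4),
                           p_lgt_focal_to_lineage = numeric(0),
                           p_focal_missing = 0, seed = 5)
  sim <- simulate_gene_trees(cfg)
  scfg <- survey_config(min_support = 0, min_length = 0)  # keep trees binary
  for (i in seq_len(8)) {
    prep <- lgtsurvey:::prepare_tree(sim$trees$tree[[i]], scfg)
    sr <- sister_lineage(prep)
    if (sr$status == "sister" && !grepl("/", sr$sister_label)) {
      d <- nodal_distance(prep, taxon_leaves(prep, "Eukarya"),
                          taxon_leaves(prep, sr$sister_label))
      expect_equal(d$value, 1)
    }
  }
})

test_that("harsher collapsing never upgrades a verdict toward sister", {
  # supports chosen so higher thresholds progressively dissolve the
  # focal region; uncertainty must be monotone in the threshold
  nk <- paste0("(((E1:1,(E2:1,(E3:1,E4:1)95:1)95:1)40:1,(H_1:1,H_2:1)80:1)30:1,",
               "((L_1:1,L_2:1)85:1,(D_1:1,D_2:1)90:1)70:1);")
  gt <- toy_tree(nk)
  rank <- c(sister = 1, nested = 1, unresolved = 2, paraphyletic_focal = 2,
            absent = 2)
  prev <- 0
  for (thr in c(0, 35, 55, 75, 85, 99)) {
    prep <- root_gene_tree(collapse_weak_edges(gt, thr, 0))
    st <- sister_lineage(prep)$status
    expect_gte(rank[[st]], prev)
    prev <- max(prev, rank[[st]])
  }
})
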