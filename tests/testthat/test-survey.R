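test_that("per-tree classification reports sister labels and absent focal", {
  cl <- classify_tree(toy_tree(), cfg = survey_config(min_length = 0))
  expect_equal(cl$focal_status, "sister")
  expect_equal(cl$sister_label, "Hodarchaeales")
  expect_equal(cl$n_focal, 4)
  d <- cl$distances[[1]]
  expect_equal(d$distance[d$lineage == "Hodarchaeales"], 1)
  expect_true(all(d$n_leaves >= 2))
  # tree without the focal clade still classifies, as absent
  m <- toy_map()
  nofocal <- read_gene_tree(
    "(((H_1:1,H_2:1):1,(L_1:1,L_2:1):1):1,(D_1:1,D_2:1):1);", "NF", "NM", m)
  cl0 <- classify_tree(nofocal, cfg = survey_config(min_length = 0))
  expect_equal(cl0$focal_status, "absent")
  expect_equal(cl0$n_focal, 0)
})

test_that("survey categories are exhaustive and sum to the tree count", {
  cfg <- simulation_config(n_markers = 16,
                           k_lgt_focal_to_lineage = c(Hodarchaeales = 2),
                           p_lgt_focal_to_lineage = numeric(0),
                           p_lgt_lineage_to_focal = c(Lokiarchaeales = 0.2),
                           p_focal_missing = 0.15, seed = 20)
  sim <- simulate_gene_trees(cfg)
  sv <- survey_trees(sim$trees)
  expect_equal(sum(sv$table1$total), 16)
  expect_equal(sum(sv$table1$NM), 16)
  # every simulated transfer appears as the matching census category
  planted <- sim$truth$marker_id[sim$truth$event == "focal_to_lineage"]
  got <- sv$classifications
  expect_true(all(got$sister_label[got$marker_id %in% planted] ==
                    "Hodarchaeales"))
  g <- glance(sv)
  expect_equal(g$n_trees, 16)
  expect_equal(g$n_no_focal, sum(sim$truth$focal_missing))
  # tidy shapes
  expect_true(all(c("marker_id", "focal_status") %in% names(tidy(sv))))
  long <- tidy(sv, distances = TRUE)
  expect_true(all(c("lineage", "distance", "nested") %in% names(long)))
})

test_that("affinity census recovers donor-swap rates within binomial noise", {
  q <- 0.4
  n <- 40
  cfg <- simulation_config(
    n_markers = n, p_lgt_focal_to_lineage = numeric(0),
    p_lgt_lineage_to_focal = numeric(0),
    p_lgt_lineage_to_donor = tibble::tibble(
      lineage = "Njordarchaeales", donor = "Korarchaeota", p = q),
    p_focal_missing = 0, seed = 77)
  sim <- simulate_gene_trees(cfg)
  sv <- survey_trees(sim$trees,
                     affinity_lineages = c("Njordarchaeales", "Hodarchaeales"))
  aff <- sv$affinity
  kc <- aff$kor_cren[aff$lineage == "Njordarchaeales"]
  expect_lt(abs(kc / n - q), 3 * sqrt(q * (1 - q) / n))
  # row sums cover every tree containing the lineage
  row_tot <- rowSums(aff[, setdiff(names(aff), c("lineage", "dataset"))])
  expect_true(all(row_tot == n))
  # the control lineage stays overwhelmingly with its own group
  hod_own <- aff$own_group[aff$lineage == "Hodarchaeales"]
  expect_gt(hod_own / n, 0.8)
})

test_that("distance profiles and the near-excess score behave at the extremes", {
  # all markers transferred: histogram mass entirely at 1 -> sister_like
  cfg <- simulation_config(n_markers = 6,
                           p_lgt_focal_to_lineage = c(Hodarchaeales = 1),
                           p_lgt_lineage_to_focal = numeric(0),
                           nni_noise = 0, p_focal_missing = 0, seed = 2)
  sim <- simulate_gene_trees(cfg)
  pr <- distance_profile(sim$trees, target = "Hodarchaeales")
  expect_equal(pr$histogram$distance, 1L)
  expect_equal(pr$histogram$n, 6L)
  expect_equal(sum(pr$histogram$n), pr$n_defined)
  call <- lgt_score(pr, nulls = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
                    cfg = survey_config())
  expect_equal(call$classification, "sister_like")
  # a far-mode profile with a clear near excess -> bimodal_lgt
  cfg2 <- simulation_config(n_markers = 20,
                            k_lgt_focal_to_lineage = c(Hodarchaeales = 4),
                            p_lgt_focal_to_lineage = numeric(0),
                            p_focal_missing = 0, seed = 3)
  pr2 <- distance_profile(simulate_gene_trees(cfg2)$trees,
                          target = "Hodarchaeales")
  call2 <- lgt_score(pr2, nulls = rep(c(0, 1), 20), cfg = survey_config())
  expect_equal(call2$classification, "bimodal_lgt")
  expect_lt(call2$near_excess_p, 0.05)
  expect_gt(call2$mode, 2)
  # null-like profile scored against its own kind -> not bimodal
  cfg0 <- cfg2
  cfg0$k_lgt_focal_to_lineage <- NULL
  pr0 <- distance_profile(simulate_gene_trees(cfg0)$trees,
                          target = "Hodarchaeales")
  call0 <- lgt_score(pr0, nulls = rep(c(0, 1), 20), cfg = survey_config())
  expect_true(call0$classification %in% c("unrelated_like", "inconclusive"))
  expect_error(lgt_score(pr0, nulls = numeric(0)), "null")
})

test_that("direction calls follow the sister-and-far / nested rules", {
  scfg <- survey_config()
  # stem transfer: sister to one lineage, everything else far
  cfg <- simulation_config(n_markers = 4,
                           p_lgt_focal_to_lineage = c(Njordarchaeales = 1),
                           p_lgt_lineage_to_focal = numeric(0),
                           nni_noise = 0, p_focal_missing = 0, seed = 6)
  sim <- simulate_gene_trees(cfg)
  sv <- survey_trees(sim$trees, affinity_lineages = character(0))
  dir <- infer_direction(sv, scfg)
  expect_true(all(dir$direction == "to_prokaryote"))
  # nested transfer
  cfg2 <- simulation_config(n_markers = 4, p_lgt_focal_to_lineage = numeric(0),
                            p_lgt_lineage_to_focal = c(Lokiarchaeales = 1),
                            nni_noise = 0, p_focal_missing = 0, seed = 6)
  sv2 <- survey_trees(simulate_gene_trees(cfg2)$trees,
                      affinity_lineages = character(0))
  dir2 <- infer_direction(sv2, scfg)
  expect_true(all(dir2$direction == "to_eukaryote"))
  # joint sister -> ambiguous
  joint <- root_gene_tree(toy_tree(paste0(
    "(((E1:1,(E2:1,(E3:1,E4:1):1):1):1,((H_1:1,H_2:1):1,(N_1:1,N_2:1):1):1):1,",
    "(D_1:1,D_2:1):1);")))
  cl <- classify_tree(unroot_gene_tree(joint), cfg = survey_config(min_length = 0))
  expect_equal(infer_direction(cl, scfg)$direction, "ambiguous")
})

test_that("plot methods return ggplot objects", {
  cfg <- simulation_config(n_markers = 5, seed = 12)
  sim <- simulate_gene_trees(cfg)
  pr <- distance_profile(sim$trees, target = "Hodarchaeales")
  expect_s3_class(autoplot(pr), "ggplot")
  sv <- survey_trees(sim$trees, targets = "Hodarchaeales",
                     affinity_lineages = character(0))
  expect_s3_class(autoplot(sv), "ggplot")
})
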