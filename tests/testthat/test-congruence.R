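halo_ref <- function() {
  load_archaea_fixture()$ref_tree
}

test_that("induced subtree suppresses degree-2 nodes and keeps ages", {
  ref <- halo_ref()
  # two taxa: a single cherry with the original MRCA age
  ind2 <- induced_subtree(ref, c("Halobacterium", "Haloferax"))
  expect_equal(length(ind2$phylo$tip.label), 2L)
  expect_equal(max(ind2$node_ages), 1.8)   # Halobacteriales crown
  # Halobacterium stays basal in the restricted Halobacteriales
  ind <- induced_subtree(ref, c("Halobacterium", "Natronomonas",
                                "Haloferax", "Haloarcula"))
  r <- lgtrates:::root_node(ind$phylo)
  kids <- ind$phylo$edge[ind$phylo$edge[, 1] == r, 2]
  basal <- ind$phylo$tip.label[kids[kids <= 4]]
  expect_true("Halobacterium" %in% basal)
  # restriction to the full leaf set is the identity on topology
  all_ind <- induced_subtree(ref, ref$phylo$tip.label)
  expect_true(ape::all.equal.phylo(all_ind$phylo, ref$phylo,
                                   use.edge.length = FALSE))
  expect_error(induced_subtree(ref, c("Halobacterium", "nope")), "unknown taxa")
})

test_that("identical trees yield no supported conflict", {
  ref <- halo_ref()
  taxa <- c("Halobacterium", "Natronomonas", "Haloferax", "Haloarcula")
  ind <- induced_subtree(ref, taxa)$phylo
  ind$tip.label <- paste0("x|", ind$tip.label)
  gt <- gene_tree(ind, support_primary = rep(100, ind$Nnode), gene_name = "x")
  expect_equal(nrow(supported_conflicts(gt, ref)), 0L)
})

test_that("an SPR-regrafted clade is flagged at its support level", {
  ref <- parse_tree(
    "((((t1:1,t2:1):1,t3:2):1,t4:3):1,(t5:2,(t6:1.5,(t7:1,t8:1):0.5):0.5):2);",
    time_scaled = TRUE)
  # t1 regrafted next to t7/t8, conflict branches at support 99
  gt <- parse_tree(paste0(
    "(((g|t2:1,g|t3:1)99:1,g|t4:1)99:1,",
    "(g|t5:1,(g|t6:1,(g|t1:1,(g|t7:1,g|t8:1)99:1)99:1)99:1)99:1);"),
    type = "gene", gene_name = "g")
  sc <- supported_conflicts(gt, ref)
  expect_gt(nrow(sc), 0L)
  expect_true(all(sc$support >= 99))
  # every reported conflict is confirmed incompatible by the graph oracle
  ind <- induced_subtree(ref, paste0("t", 1:8))$phylo
  for (side in sc$bipartition)
    expect_false(oracle_split_compatible(side, ind))
  # raising the threshold above the supports silences the conflict
  expect_equal(nrow(supported_conflicts(gt, ref, threshold = 99.5)), 0L)
})

test_that("alternative rooting: compatible unrooted, different basal split", {
  ref <- halo_ref()
  # unrooted topology matches the reference restriction, but the clade is
  # rooted between the (Haloferax,Haloarcula)-cherry and the rest
  gt_alt <- parse_tree(paste0("((g|Haloferax:1,g|Haloarcula:1)60:1,",
                              "(g|Natronomonas:1,g|Halobacterium:1)50:1);"),
                       type = "gene", gene_name = "g")
  expect_true(alternative_rooting(gt_alt, ref))
  expect_equal(assess_clade(gt_alt, ref)$verdict, "alternative_rooting")

  # rooted exactly as the reference: not an alternative rooting
  gt_same <- parse_tree(paste0("(g|Halobacterium:1,(g|Natronomonas:1,",
                               "(g|Haloferax:1,g|Haloarcula:1)95:1)95:1);"),
                        type = "gene", gene_name = "g")
  expect_false(alternative_rooting(gt_same, ref))
  expect_equal(assess_clade(gt_same, ref)$verdict, "congruent")

  # unrooted-incompatible at high support: supported_conflict wins and
  # alternative_rooting is FALSE (verdict exclusivity)
  gt_conf <- parse_tree(paste0("(g|Haloferax:1,(g|Natronomonas:1,",
                               "(g|Halobacterium:1,g|Haloarcula:1)95:1)60:1);"),
                        type = "gene", gene_name = "g")
  expect_false(alternative_rooting(gt_conf, ref))
  expect_equal(assess_clade(gt_conf, ref)$verdict, "supported_conflict")
})

test_that("verdicts: unresolved on small or unsupported clades", {
  ref <- halo_ref()
  # < 4 shared taxa
  gt3 <- parse_tree("(g|Haloferax:1,(g|Natronomonas:1,g|Halobacterium:1)90:1);",
                    type = "gene", gene_name = "g")
  expect_equal(assess_clade(gt3, ref)$verdict, "unresolved")
  # >= 4 taxa but every support below threshold
  gt_low <- parse_tree(paste0("(g|Haloferax:1,(g|Natronomonas:1,",
                              "(g|Halobacterium:1,g|Haloarcula:1)40:1)40:1);"),
                       type = "gene", gene_name = "g")
  expect_equal(assess_clade(gt_low, ref)$verdict, "unresolved")
})

test_that("paralog copies collapse to one taxon occurrence", {
  ref <- halo_ref()
  # two copies of Haloferax on one side; topology otherwise congruent
  gt <- parse_tree(paste0("(g|Halobacterium:1,(g|Natronomonas:1,",
                          "((g|Haloferax__1:1,g|Haloferax__2:1)99:1,",
                          "g|Haloarcula:1)99:1)99:1);"),
                   type = "gene", gene_name = "g")
  expect_equal(nrow(supported_conflicts(gt, ref)), 0L)
  expect_equal(assess_clade(gt, ref)$verdict, "congruent")
})

test_that("threshold is monotone and verdicts ignore leaf rotation", {
  set.seed(31)
  for (k in 1:10) {
    ref <- random_dated_tree(6)
    gph <- ape::rtree(6)
    gph$node.label <- NULL
    gph$tip.label <- paste0("g|", sample(ref$phylo$tip.label))
    gt <- gene_tree(gph, support_primary = round(runif(gph$Nnode, 40, 100)),
                    gene_name = "g")
    v70 <- nrow(supported_conflicts(gt, ref, threshold = 70))
    v90 <- nrow(supported_conflicts(gt, ref, threshold = 90))
    expect_lte(v90, v70)
    # rotation invariance
    rot <- gt
    rot$phylo <- ape::rotateConstr(gph, sample(gph$tip.label))
    st_old <- lgtrates:::subtended_taxa(gph)
    st_new <- lgtrates:::subtended_taxa(rot$phylo)
    n <- 6L
    perm <- match(
      vapply(st_new[(n + 1):(n + rot$phylo$Nnode)],
             function(s) paste(sort(s), collapse = "|"), ""),
      vapply(st_old[(n + 1):(n + gph$Nnode)],
             function(s) paste(sort(s), collapse = "|"), ""))
    rot$support_primary <- gt$support_primary[perm]
    expect_equal(nrow(supported_conflicts(rot, ref)), v70)
  }
})

test_that("fully permuted leaves with full support conflict strongly", {
  set.seed(17)
  hits <- 0
  for (k in 1:10) {
    ref <- random_dated_tree(8)
    gph <- ref$phylo
    gph$tip.label <- paste0("g|", sample(gph$tip.label))
    gt <- gene_tree(gph, support_primary = rep(100, gph$Nnode),
                    gene_name = "g")
    if (nrow(supported_conflicts(gt, ref)) > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
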