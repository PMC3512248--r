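# 4-taxon workhorse: ((A,B),(C,D)) with known ages
chrono_fixture <- function() {
  ph <- ape::read.tree(text = "((A:0.02,B:0.02):0.02,(C:0.03,D:0.03):0.01);")
  ages <- c(0, 0, 0, 0, 2, 1, 1.5)   # root 2, AB crown 1, CD crown 1.5
  dated_tree(ph, node_ages = ages)
}

test_that("pl_objective matches a hand-computed value", {
  tr <- chrono_fixture()
  ages <- tr$node_ages
  rates <- rep(0.02, 6)
  L <- 1000
  # by hand: Poisson kernel sum(x log mu - mu) with x = len * L,
  # mu = rate * duration * L; clock rates give zero penalty
  ph <- tr$phylo
  dur <- ages[ph$edge[, 1]] - ages[ph$edge[, 2]]
  x <- ph$edge.length * L
  mu <- rates * dur * L
  by_hand <- sum(x * log(mu)) - sum(mu)
  expect_equal(pl_objective(tr, ages, rates, lambda = 7, sites = L), by_hand,
               tolerance = 1e-10)

  # penalty term: perturb one child rate r relative to its parent rate
  rates2 <- rates; rates2[2] <- 0.03
  parent_edge <- match(ph$edge[, 1], ph$edge[, 2])
  pen <- sum((rates2[!is.na(parent_edge)] -
              rates2[parent_edge[!is.na(parent_edge)]])^2) +
    var(rates2[is.na(parent_edge)])
  mu2 <- rates2 * dur * L
  expect_equal(pl_objective(tr, ages, rates2, lambda = 7, sites = L),
               sum(x * log(mu2)) - sum(mu2) - 7 * pen, tolerance = 1e-10)

  # zero-duration branch with nonzero length is an impossible point
  ages0 <- ages; ages0[6] <- 0
  expect_equal(pl_objective(tr, ages0, rates, lambda = 7), -Inf)
})

test_that("constraint propagation tightens and detects conflicts", {
  tr <- chrono_fixture()
  tr$clade_labels <- list(AB = c("A", "B"), CD = c("C", "D"))
  cons <- data.frame(clade = c("root", "AB"), min_age = c(2.7, NA),
                     max_age = c(3.8, 1.0))
  b <- propagate_constraints(tr, cons)
  ab <- resolve_clade(tr, "AB")
  expect_equal(unname(b[ab, ]), c(0, 1.0))
  r <- lgtrates:::root_node(tr$phylo)
  expect_equal(unname(b[r, ]), c(2.7, 3.8))
  # a child max also caps its descendants, an ancestor min floors nothing here
  cons2 <- data.frame(clade = c("AB", "root"), min_age = c(3.0, NA),
                      max_age = c(NA, 2.32))
  expect_error(propagate_constraints(tr, cons2), "constraint-conflict")
  # no constraints: no absolute scale, dating refuses
  none <- data.frame(clade = character(), min_age = numeric(),
                     max_age = numeric())
  ph <- tr$phylo
  expect_error(date_tree(dated_tree(ph), none), "no finite maximum")
})

test_that("strict-clock simulations are dated within 1% (root fixed)", {
  cfg <- sim_config(n_taxa = 8, seed = 5)
  tr <- simulate_reference_tree(cfg)
  r_true <- 0.02
  ph <- tr$phylo
  ph$edge.length <- r_true * branch_durations(tr)
  undated <- dated_tree(ph)
  cons <- data.frame(clade = "root", min_age = root_age(tr),
                     max_age = root_age(tr))
  for (lambda in c(1, 100)) {
    chr <- date_tree(undated, cons, lambda = lambda, restarts = 2)
    internal <- (length(ph$tip.label) + 1):(length(ph$tip.label) + ph$Nnode)
    rel <- abs(chr$node_ages[internal] - tr$node_ages[internal]) /
      tr$node_ages[internal]
    expect_lt(max(rel), 0.01)
    expect_equal(mean(chr$rates), r_true, tolerance = 0.01)
    # a common rate is only forced as lambda grows
    if (lambda >= 100) expect_lt(max(chr$rates) / min(chr$rates), 1.01)
  }
})

test_that("constraints are respected on the dated tree", {
  cfg <- sim_config(n_taxa = 6, seed = 9)
  tr <- simulate_reference_tree(cfg)
  ph <- tr$phylo
  ph$edge.length <- 0.02 * branch_durations(tr) *
    exp(rnorm(nrow(ph$edge), 0, 0.2))   # mild rate variation
  undated <- dated_tree(ph)
  # pick a real clade to constrain
  st <- lgtrates:::subtended_taxa(ph)
  internal <- (length(ph$tip.label) + 1):(length(ph$tip.label) + ph$Nnode)
  v <- internal[which(lengths(st[internal]) %in% 2:3)[1]]
  undated$clade_labels <- list(X = st[[v]])
  cons <- data.frame(clade = c("root", "X"), min_age = c(2.7, NA),
                     max_age = c(3.8, 2.32))
  chr <- date_tree(undated, cons, restarts = 2)
  expect_gte(chr$node_ages[lgtrates:::root_node(ph)], 2.7)
  expect_lte(chr$node_ages[lgtrates:::root_node(ph)], 3.8)
  expect_lte(chr$node_ages[v], 2.32)
  # strict parent > child ordering everywhere
  expect_true(all(branch_durations(chr) > 0))
})

test_that("rescaling branch lengths rescales rates, not ages (clock data)", {
  cfg <- sim_config(n_taxa = 6, seed = 11)
  tr <- simulate_reference_tree(cfg)
  ph <- tr$phylo
  ph$edge.length <- 0.02 * branch_durations(tr)
  cons <- data.frame(clade = "root", min_age = root_age(tr),
                     max_age = root_age(tr))
  c1 <- date_tree(dated_tree(ph), cons, restarts = 2)
  ph2 <- ph; ph2$edge.length <- ph$edge.length * 3
  c2 <- date_tree(dated_tree(ph2), cons, restarts = 2)
  expect_equal(c2$node_ages, c1$node_ages, tolerance = 0.01)
  expect_equal(mean(c2$rates) / mean(c1$rates), 3, tolerance = 0.02)
})

test_that("large lambda forces a common rate on clock-like data", {
  cfg <- sim_config(n_taxa = 8, seed = 13)
  tr <- simulate_reference_tree(cfg)
  ph <- tr$phylo
  ph$edge.length <- 0.02 * branch_durations(tr)
  cons <- data.frame(clade = "root", min_age = 3.0, max_age = 3.8)
  chr <- date_tree(dated_tree(ph), cons, lambda = 1e4, restarts = 2)
  expect_lt(max(chr$rates) / min(chr$rates), 1.01)
})

test_that("a pre-dated tree bypasses dating entirely", {
  fx <- load_archaea_fixture()
  expect_false(is.null(fx$ref_tree$node_ages))
  expect_equal(root_age(fx$ref_tree), 3.5)
  # fixture ages already satisfy the transcribed constraint table
  b <- propagate_constraints(fx$ref_tree, fx$constraints)
  expect_true(all(fx$ref_tree$node_ages >= b[, "lo"] - 1e-9 &
                  fx$ref_tree$node_ages <= b[, "hi"] + 1e-9))
})
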