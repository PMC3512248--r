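# Independent oracles and small builders used across the suite.

# exhaustive-enumeration likelihood for the binary one-rate Mk model:
# sum over all internal-state assignments of prior * product of transition
# probabilities (the definition the pruning algorithm must reproduce)
enum_mk1_loglik <- function(tree, tips, q, prior = 0.5) {
  ph <- tree$phylo
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  dur <- branch_durations(tree)
  states <- as.integer(tips[ph$tip.label])
  internals <- (n + 1):N
  tot <- 0
  for (mask in 0:(2^length(internals) - 1)) {
    s <- numeric(N)
    s[1:n] <- states
    s[internals] <- bitwAnd(bitwShiftR(mask, seq_along(internals) - 1), 1)
    p <- if (s[n + 1] == 1) prior else 1 - prior
    for (e in seq_len(nrow(ph$edge))) {
      P <- mk1_transition(q, dur[e])
      p <- p * P[s[ph$edge[e, 1]] + 1, s[ph$edge[e, 2]] + 1]
    }
    tot <- tot + p
  }
  log(tot)
}

# enumeration-based marginal P(state 1) per node
enum_mk1_marginal <- function(tree, tips, q, prior = 0.5) {
  ph <- tree$phylo
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  dur <- branch_durations(tree)
  states <- as.integer(tips[ph$tip.label])
  internals <- (n + 1):N
  w <- matrix(0, N, 2)
  for (mask in 0:(2^length(internals) - 1)) {
    s <- numeric(N)
    s[1:n] <- states
    s[internals] <- bitwAnd(bitwShiftR(mask, seq_along(internals) - 1), 1)
    p <- if (s[n + 1] == 1) prior else 1 - prior
    for (e in seq_len(nrow(ph$edge))) {
      P <- mk1_transition(q, dur[e])
      p <- p * P[s[ph$edge[e, 1]] + 1, s[ph$edge[e, 2]] + 1]
    }
    for (v in 1:N) w[v, s[v] + 1] <- w[v, s[v] + 1] + p
  }
  w[, 2] / rowSums(w)
}

# split-vs-tree compatibility oracle: the split's two sides must span
# edge-disjoint subtrees of the reference (checked on the tree graph),
# independent of the pairwise-bipartition test used by the package
oracle_split_compatible <- function(side, ph) {
  leaves <- ph$tip.label
  g <- igraph::graph_from_edgelist(ph$edge, directed = FALSE)
  steiner_edges <- function(tips) {
    ids <- match(tips, leaves)
    es <- integer(0)
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1)) {
        p <- igraph::shortest_paths(g, ids[i], ids[j],
                                    output = "epath")$epath[[1]]
        es <- union(es, as.integer(p))
      }
    }
    es
  }
  length(intersect(steiner_edges(side),
                   steiner_edges(setdiff(leaves, side)))) == 0
}

random_dated_tree <- function(n) {
  ph <- ape::rtree(n)
  ph$node.label <- NULL
  dated_tree(ph)
}

# simulate a bundle, run the full-route pipeline, return truth + counts
sim_and_detect <- function(cfg, linkage = FALSE) {
  tr <- simulate_reference_tree(cfg)
  hist <- simulate_gene_history(tr, cfg)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write.table(data.frame(taxon = rownames(hist$presence), hist$presence,
                         check.names = FALSE),
              file.path(d, "pm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(write_newick(tr), file.path(d, "ref.nwk"))
  gfiles <- character(0)
  for (g in names(hist$gene_trees)) {
    f <- file.path(d, paste0(g, ".nwk"))
    writeLines(write_newick(hist$gene_trees[[g]]), f)
    gfiles <- c(gfiles, f)
  }
  lfile <- NULL
  if (linkage) {
    lfile <- file.path(d, "linkage.tsv")
    write.table(as.data.frame(hist$linkage), lfile, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfgp <- pipeline_config(ref_tree = file.path(d, "ref.nwk"),
                          presence = file.path(d, "pm.tsv"),
                          gene_trees = as.list(gfiles), linkage = lfile)
  res <- suppressWarnings(run_pipeline(cfgp))
  list(tree = tr, history = hist, result = res,
       true_gains = nrow(hist$gains),
       counts = event_counts(res$event_set))
}

fixture_events <- function() {
  cfg <- pipeline_config(
    clade_table = archaea_fixture("clades.tsv"),
    linkage = archaea_fixture("linkage.tsv"),
    dup_flags = archaea_fixture("dup_flags.tsv"),
    categories = archaea_fixture("categories.tsv"))
  run_pipeline(cfg)
}
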