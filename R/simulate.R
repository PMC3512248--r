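## Synthetic data: birth-death reference trees and gene histories with
## implanted transfers, losses, tandem linkage and degraded supports, so the
## whole detection pipeline can be exercised against a known truth.

#' Simulation configuration
#'
#' Defaults describe the data regime the detector targets: a ~3.5 Gy old
#' domain with rare gene gains (a handful of transfers per gene over the whole
#' tree) and optional losses.
#'
#' @param n_taxa number of surviving taxa (>= 4).
#' @param birth,death per-lineage rates per Gy.
#' @param root_age crown age in Ga (default 3.5, the assumed age of the
#'   archaeal domain).
#' @param gamma per-gene transfer rate: expected gains across the whole tree
#'   per Gy of crown span.
#' @param loss_rate per-lineage loss rate per Gy after a gain.
#' @param n_genes number of genes to simulate.
#' @param n_linkage_groups number of gene pairs sharing gain events
#'   (tandem/operonic pairs).
#' @param support_noise support degradation level in [0,1].
#' @param seed RNG seed, recorded in all outputs.
#' @param n_gains optional exact number of gains per gene (overrides the
#'   Poisson draw; used when a test conditions on a gain count).
#' @param max_clade_frac largest fraction of taxa a single recipient clade may
#'   span (default 0.2). Transfer recipients in the emulated regime are minor
#'   clades of the domain (the largest real recipient order is about a tenth
#'   of the sampled taxa); a trait blanketing most of the tree is outside the
#'   regime the detector targets.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_taxa = 32, birth = 1.0, death = 0.2, root_age = 3.5,
                       gamma = 0.6, loss_rate = 0, n_genes = 1,
                       n_linkage_groups = 0, support_noise = 0, seed = 1,
                       n_gains = NULL, max_clade_frac = 0.2) {
  stopifnot(n_taxa >= 4, birth >= 0, death >= 0, root_age > 0, gamma >= 0,
            loss_rate >= 0, support_noise >= 0, support_noise <= 1)
  structure(list(n_taxa = n_taxa, birth = birth, death = death,
                 root_age = root_age, gamma = gamma, loss_rate = loss_rate,
                 n_genes = n_genes, n_linkage_groups = n_linkage_groups,
                 support_noise = support_noise, seed = seed,
                 n_gains = n_gains, max_clade_frac = max_clade_frac),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Simulate a dated birth-death reference tree
#'
#' A birth-death tree conditioned on the number of survivors (via
#' \code{ape::rphylo}), rescaled so the crown sits at \code{root_age}; the
#' result is ultrametric with node ages filled in and taxa labelled
#' \code{t1..tn}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{dated_tree}.
#' @export
simulate_reference_tree <- function(config) {
  with_seed(config$seed, {
    ph <- NULL
    for (try in 1:25) {
      ph <- tryCatch(ape::rphylo(config$n_taxa, config$birth, config$death,
                                 fossils = FALSE),
                     error = function(e) NULL)
      if (!is.null(ph)) break
    }
    if (is.null(ph))
      stop("birth-death simulation failed after 25 attempts ",
           "(death rate too high?)")
    depth <- max(ape::node.depth.edgelength(ph))
    ph$edge.length <- ph$edge.length * config$root_age / depth
    ph$tip.label <- paste0("t", seq_len(config$n_taxa))
    dated_tree(ph, node_ages = ages_from_lengths(ph))
  })
}

#' Simulate gene histories on a dated tree
#'
#' Gains are a Poisson process over the tree: the number of gains is
#' Poisson(\code{gamma * root_age}) and each gain lands on an edge with
#' probability proportional to its duration, at a uniform time along it.
#' Gains of one gene are constrained to disjoint subtrees (a gain nested
#' inside an already-carrying clade is unobservable in presence/absence data,
#' so it is not generated). Losses then prune carrier subtrees at rate
#' \code{loss_rate} per lineage per Gy. Genes in a linkage group share their
#' gain events and are recorded as adjacent (gap 0) in every carrier taxon.
#'
#' Gene trees are constructed, not sequence-simulated: each gain clade is the
#' induced reference subtree of its carriers; multiple gain clades are strung
#' along a pectinate backbone (mimicking independently acquired, externally
#' rooted copies), with all supports 100 before optional degradation.
#'
#' @param tree a \code{dated_tree} (typically from
#'   \code{\link{simulate_reference_tree}}).
#' @param config a \code{\link{sim_config}}.
#' @return a \code{true_history}: list with \code{gains} (data.frame: gene,
#'   edge child node, time, list column taxa), \code{presence}
#'   (taxa x genes matrix), \code{gene_trees} (named list of
#'   \code{gene_tree}), \code{linkage} (\code{linkage_table}), \code{config}.
#' @export
simulate_gene_history <- function(tree, config) {
  with_seed(config$seed + 1L, {
    ph <- tree$phylo
    dur <- branch_durations(tree)
    st <- subtended_taxa(ph)
    genes <- paste0("g", seq_len(config$n_genes))
    # linkage groups: pair 2k-1 with 2k
    group_of <- seq_len(config$n_genes)
    if (config$n_linkage_groups > 0) {
      for (k in seq_len(config$n_linkage_groups)) {
        a <- 2 * k - 1; b <- 2 * k
        if (b <= config$n_genes) group_of[b] <- group_of[a]
      }
    }
    gains <- data.frame(gene = character(), child = integer(),
                        time = numeric(), stringsAsFactors = FALSE)
    gains$taxa <- list()
    presence <- matrix(0L, length(ph$tip.label), length(genes),
                       dimnames = list(ph$tip.label, genes))
    linkage_rows <- list()
    gene_trees <- list()

    for (grp in unique(group_of)) {
      members <- genes[group_of == grp]
      n_gain <- if (!is.null(config$n_gains)) config$n_gains
                else rpois(1, config$gamma * root_age(tree))
      chosen <- integer(0)
      tries <- 0
      while (length(chosen) < n_gain && tries < 500) {
        tries <- tries + 1
        e <- sample.int(nrow(ph$edge), 1, prob = dur)
        ch <- ph$edge[e, 2]
        clade <- st[[ch]]
        if (length(clade) > config$max_clade_frac * length(ph$tip.label))
          next
        overlap <- any(vapply(chosen, function(c2)
          length(intersect(st[[ph$edge[c2, 2]]], clade)) > 0, TRUE))
        if (!overlap) chosen <- c(chosen, e)
      }
      carriers_by_gain <- list()
      for (e in chosen) {
        ch <- ph$edge[e, 2]
        t_gain <- tree$node_ages[ph$edge[e, 1]] - runif(1) * dur[e]
        clade_taxa <- st[[ch]]
        # losses: prune tips from the clade
        keep <- clade_taxa
        if (config$loss_rate > 0) {
          keep <- apply_losses(tree, ch, t_gain, config$loss_rate)
        }
        if (!length(keep)) next
        carriers_by_gain[[length(carriers_by_gain) + 1L]] <- keep
        for (g in members) {
          gains[nrow(gains) + 1L, c("gene", "child", "time")] <-
            list(g, ch, t_gain)
          gains$taxa[[nrow(gains)]] <- clade_taxa
          presence[keep, g] <- 1L
        }
      }
      for (g in members) {
        if (length(carriers_by_gain))
          gene_trees[[g]] <- build_gene_tree(tree, g, carriers_by_gain)
      }
      if (length(members) > 1) {
        carr <- rownames(presence)[presence[, members[1]] == 1L]
        for (tx in carr) for (j in 2:length(members)) {
          linkage_rows[[length(linkage_rows) + 1L]] <- data.frame(
            taxon = tx, copy_a = paste0(members[1], "|", tx),
            copy_b = paste0(members[j], "|", tx), gap_orfs = 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    linkage <- if (length(linkage_rows))
      linkage_table(do.call(rbind, linkage_rows))
    else linkage_table(data.frame(taxon = character(), copy_a = character(),
                                  copy_b = character(), gap_orfs = integer()))
    if (config$support_noise > 0) {
      for (g in names(gene_trees))
        gene_trees[[g]] <- degrade_supports(gene_trees[[g]],
                                            config$support_noise,
                                            seed = config$seed + 97L)
    }
    structure(list(gains = gains, presence = presence,
                   gene_trees = gene_trees, linkage = linkage,
                   config = config), class = "true_history")
  })
}

## losses as a Poisson pruning process below the gain point
apply_losses <- function(tree, gain_node, t_gain, mu) {
  ph <- tree$phylo
  lost_below <- rep(FALSE, length(tree$node_ages))
  keep <- character(0)
  # walk edges below gain_node root-down; a loss on an edge kills its subtree
  desc_edges <- which_edges_below(ph, gain_node)
  ord <- desc_edges[order(-tree$node_ages[ph$edge[desc_edges, 1]])]
  for (e in ord) {
    p <- ph$edge[e, 1]; ch <- ph$edge[e, 2]
    if (lost_below[p]) { lost_below[ch] <- TRUE; next }
    top <- if (p == gain_node) min(t_gain, tree$node_ages[p]) else tree$node_ages[p]
    span <- max(top - tree$node_ages[ch], 0)
    if (rpois(1, mu * span) > 0) lost_below[ch] <- TRUE
  }
  n <- length(ph$tip.label)
  tips <- if (gain_node <= n) gain_node else
    which(ph$tip.label %in% subtended_taxa(ph)[[gain_node]])
  ph$tip.label[tips[!lost_below[tips]]]
}

which_edges_below <- function(ph, node) {
  below <- logical(length(ph$tip.label) + ph$Nnode)
  below[node] <- TRUE
  res <- integer(0)
  for (i in rev(ape::postorder(ph))) {   # root-down
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    if (below[p]) { below[ch] <- TRUE; res <- c(res, i) }
  }
  res
}

## gene tree: gain clades (induced reference subtrees) on a pectinate backbone
build_gene_tree <- function(tree, gene, carriers_by_gain) {
  newicks <- vapply(seq_along(carriers_by_gain), function(i) {
    taxa <- carriers_by_gain[[i]]
    if (length(taxa) == 1) paste0(gene, "|", taxa, ":1")
    else {
      sub <- induced_subtree(tree, taxa)$phylo
      sub$edge.length <- rep(1, nrow(sub$edge))
      sub$tip.label <- paste0(gene, "|", sub$tip.label)
      txt <- ape::write.tree(sub)
      sub("; *$", "", txt)
    }
  }, "")
  txt <- newicks[1]
  if (length(newicks) > 1) {
    for (i in 2:length(newicks))
      txt <- paste0("(", txt, ",", newicks[i], "):1")
  } else if (length(carriers_by_gain[[1]]) == 1) {
    txt <- paste0("(", txt, ")")   # 1-copy gene: trivial 1-tip tree
  }
  ph <- ape::read.tree(text = paste0(txt, ";"))
  gene_tree(ph, gene_name = gene,
            support_primary = rep(100, ph$Nnode), rooted = TRUE)
}

#' Degrade branch supports stochastically
#'
#' Supports are resampled downward: \code{s' = (1 - noise) * s + noise * U}
#' with \code{U ~ Uniform(0, 50)}. Noise 0 is the identity; noise 1 leaves
#' every support below the 70 threshold. Topology is unchanged.
#'
#' @param gene a \code{gene_tree} with supports present.
#' @param noise level in [0,1].
#' @param seed RNG seed.
#' @return the gene tree with degraded supports.
#' @export
degrade_supports <- function(gene, noise, seed = 1) {
  stopifnot(noise >= 0, noise <= 1)
  if (noise == 0) return(gene)
  with_seed(seed, {
    nn <- gene$phylo$Nnode
    u <- runif(nn, 0, 50)
    for (tr in c("support_primary", "support_secondary")) {
      s <- gene[[tr]]
      keep <- !is.na(s)
      s[keep] <- (1 - noise) * s[keep] + noise * u[keep]
      gene[[tr]] <- s
    }
    gene
  })
}

#' Regenerate a presence matrix from a true history
#'
#' Deterministic consequence of the recorded gains and the loss-pruned
#' carrier sets; used as a consistency check on the generator.
#'
#' @param tree the reference \code{dated_tree}.
#' @param history a \code{true_history}.
#' @return taxa x genes integer matrix.
#' @export
presence_from_history <- function(tree, history) {
  ph <- tree$phylo
  genes <- colnames(history$presence)
  m <- matrix(0L, length(ph$tip.label), length(genes),
              dimnames = list(ph$tip.label, genes))
  for (i in seq_len(nrow(history$gains))) {
    g <- history$gains$gene[i]
    carriers <- intersect(history$gains$taxa[[i]],
                          rownames(history$presence)[history$presence[, g] == 1L])
    m[carriers, g] <- 1L
  }
  m
}

#' Write a simulated input bundle to a directory
#'
#' Emits the reference tree (Newick), presence matrix, per-gene trees,
#' linkage table and a truth TSV, i.e. everything \code{\link{run_pipeline}}
#' needs plus the answer key.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the \code{true_history}.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_reference_tree(config)
  hist <- simulate_gene_history(tree, config)
  writeLines(write_newick(tree), file.path(dir, "ref_tree.nwk"))
  pm <- data.frame(taxon = rownames(hist$presence), hist$presence,
                   check.names = FALSE)
  write.table(pm, file.path(dir, "presence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in names(hist$gene_trees))
    writeLines(write_newick(hist$gene_trees[[g]]),
               file.path(dir, paste0(g, ".nwk")))
  write.table(as.data.frame(hist$linkage), file.path(dir, "linkage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(gene = hist$gains$gene,
                      taxa = vapply(hist$gains$taxa, paste, "", collapse = ","),
                      time = hist$gains$time)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(as.character(config$seed), file.path(dir, "seed.txt"))
  invisible(hist)
}
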