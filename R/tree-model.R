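## Core tree containers. Both classes wrap an ape "phylo" object; node indexing
## follows ape conventions (tips 1..n, internals n+1..n+Nnode, root = n+1).

#' Construct a dated reference tree
#'
#' A \code{dated_tree} is a rooted tree over taxon labels carrying optional
#' substitution branch lengths (on the embedded \code{phylo}), optional node
#' ages in Ga (billions of years before present), per-internal-node support
#' values on a 0--100 scale (up to two tracks, e.g. parsimony bootstrap and
#' Bayesian posterior), and named clade labels.
#'
#' @param phylo a rooted \code{ape::phylo} object with unique tip labels.
#' @param node_ages numeric vector of ages (Ga) indexed by ape node number
#'   (length \code{Ntip + Nnode}), or \code{NULL} if the tree is undated.
#' @param support_primary,support_secondary numeric vectors of length
#'   \code{Nnode} on a 0--100 scale (\code{NA} allowed).
#' @param clade_labels named list mapping clade names to character vectors of
#'   taxon labels.
#' @return an object of class \code{dated_tree}.
#' @export
dated_tree <- function(phylo, node_ages = NULL, support_primary = NULL,
                       support_secondary = NULL, clade_labels = list()) {
  stopifnot(inherits(phylo, "phylo"))
  if (anyDuplicated(phylo$tip.label))
    stop("validation error: duplicate leaf labels: ",
         paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phylo)) stop("reference tree must be rooted")
  n <- length(phylo$tip.label)
  nn <- phylo$Nnode
  if (is.null(support_primary)) support_primary <- rep(NA_real_, nn)
  if (is.null(support_secondary)) support_secondary <- rep(NA_real_, nn)
  check_supports(support_primary)
  check_supports(support_secondary)
  if (!is.null(node_ages)) {
    stopifnot(length(node_ages) == n + nn)
    check_age_order(phylo, node_ages)
  }
  obj <- structure(list(
    phylo = phylo, node_ages = node_ages,
    support_primary = support_primary, support_secondary = support_secondary,
    clade_labels = clade_labels), class = "dated_tree")
  obj
}

check_supports <- function(s) {
  bad <- !is.na(s) & (s < 0 | s > 100)
  if (any(bad)) stop("validation error: support values outside [0,100]")
  invisible(TRUE)
}

check_age_order <- function(phylo, ages) {
  e <- phylo$edge
  ok <- is.na(ages[e[, 1]]) | is.na(ages[e[, 2]]) |
    ages[e[, 1]] >= ages[e[, 2]] - 1e-9
  if (!all(ok)) stop("validation error: an internal node is younger than its child")
  invisible(TRUE)
}

#' Construct a gene tree
#'
#' A \code{gene_tree} is a (possibly unrooted) tree over gene-copy identifiers
#' with per-internal-branch supports and a mapping from copies to taxa of a
#' companion reference tree. Copies whose taxon is not in the reference tree
#' should be flagged via \code{outgroup}.
#'
#' @param phylo an \code{ape::phylo} over copy identifiers.
#' @param copy_to_taxon named character vector: copy id -> taxon label. When
#'   \code{NULL}, copy ids are taken as taxon labels after stripping a leading
#'   \code{"<gene>|"} prefix and/or a trailing \code{"__<k>"} copy suffix.
#' @param gene_name gene name string.
#' @param support_primary,support_secondary supports (0--100) per internal node.
#' @param rooted logical; whether the rooting is meaningful.
#' @param outgroup character vector of copy ids flagged as outgroup.
#' @return an object of class \code{gene_tree}.
#' @export
gene_tree <- function(phylo, copy_to_taxon = NULL, gene_name = "gene",
                      support_primary = NULL, support_secondary = NULL,
                      rooted = ape::is.rooted(phylo), outgroup = character()) {
  stopifnot(inherits(phylo, "phylo"))
  if (anyDuplicated(phylo$tip.label))
    stop("validation error: duplicate copy identifiers")
  nn <- phylo$Nnode
  if (is.null(support_primary)) support_primary <- rep(NA_real_, nn)
  if (is.null(support_secondary)) support_secondary <- rep(NA_real_, nn)
  check_supports(support_primary)
  check_supports(support_secondary)
  if (is.null(copy_to_taxon)) {
    # default conventions: "<gene>|<taxon>" or "<taxon>__<k>" copy ids
    taxa <- sub("^[^|]*\\|", "", sub("__[0-9]+$", "", phylo$tip.label))
    copy_to_taxon <- setNames(taxa, phylo$tip.label)
  }
  missing <- setdiff(phylo$tip.label, names(copy_to_taxon))
  if (length(missing))
    stop("validation error: copies without taxon mapping: ",
         paste(missing, collapse = ", "))
  structure(list(
    phylo = phylo, copy_to_taxon = copy_to_taxon, gene_name = gene_name,
    support_primary = support_primary, support_secondary = support_secondary,
    rooted = rooted, outgroup = outgroup), class = "gene_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree:", length(x$phylo$tip.label), "taxa,",
      x$phylo$Nnode, "internal nodes",
      if (!is.null(x$node_ages)) sprintf("(root age %.3g Ga)", root_age(x)) else "(undated)",
      "\n")
  if (length(x$clade_labels))
    cat("  clade labels:", paste(names(x$clade_labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree", shQuote(x$gene_name), ":", length(x$phylo$tip.label),
      "copies over", length(unique(x$copy_to_taxon[x$phylo$tip.label])),
      "taxa;", if (x$rooted) "rooted" else "unrooted", "\n")
  invisible(x)
}

root_node <- function(phylo) length(phylo$tip.label) + 1L

#' Root age of a dated tree
#' @param tree a \code{dated_tree} with node ages.
#' @return root age in Ga.
#' @export
root_age <- function(tree) {
  if (is.null(tree$node_ages)) stop("tree is undated")
  tree$node_ages[root_node(tree$phylo)]
}

#' Per-edge durations (Gy) of a dated tree
#'
#' Durations are computed from node ages when available, otherwise taken from
#' the embedded branch lengths. Operations needing time-scaled branches fail
#' loudly if neither is present.
#'
#' @param tree a \code{dated_tree}.
#' @return numeric vector parallel to \code{tree$phylo$edge}.
#' @export
branch_durations <- function(tree) {
  ph <- tree$phylo
  if (!is.null(tree$node_ages))
    return(tree$node_ages[ph$edge[, 1]] - tree$node_ages[ph$edge[, 2]])
  if (!is.null(ph$edge.length)) return(ph$edge.length)
  stop("tree has neither node ages nor branch lengths")
}

## node ages from a time-scaled phylo (branch lengths in Ga); tips of an
## ultrametric tree sit at age 0, otherwise at root_depth - depth.
ages_from_lengths <- function(phylo) {
  if (is.null(phylo$edge.length)) stop("tree has no branch lengths")
  n <- length(phylo$tip.label)
  depth <- numeric(n + phylo$Nnode)
  ord <- rev(ape::postorder(phylo))   # root-down edge order
  for (i in ord) {
    p <- phylo$edge[i, 1]; ch <- phylo$edge[i, 2]
    depth[ch] <- depth[p] + phylo$edge.length[i]
  }
  max(depth) - depth
}

## tip indices subtended by each node (list over all node ids)
subtended_tips <- function(phylo) {
  n <- length(phylo$tip.label)
  res <- vector("list", n + phylo$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  for (i in ape::postorder(phylo)) {
    p <- phylo$edge[i, 1]; ch <- phylo$edge[i, 2]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

## taxa subtended by each node
subtended_taxa <- function(phylo) {
  lapply(subtended_tips(phylo), function(i) phylo$tip.label[i])
}

#' Resolve a clade name to a node of the reference tree
#'
#' Clade names resolve through \code{clade_labels} (or \code{"root"}); the node
#' returned is the MRCA of the labelled taxa.
#'
#' @param tree a \code{dated_tree}.
#' @param clade_name name present in \code{tree$clade_labels} or \code{"root"}.
#' @return ape node number.
#' @export
resolve_clade <- function(tree, clade_name) {
  ph <- tree$phylo
  if (identical(clade_name, "root")) return(root_node(ph))
  taxa <- tree$clade_labels[[clade_name]]
  if (is.null(taxa))
    stop("validation error: unknown clade name: ", clade_name)
  taxa <- intersect(taxa, ph$tip.label)
  if (length(taxa) == 0L)
    stop("validation error: clade ", clade_name, " has no taxa in the tree")
  if (length(taxa) == 1L) return(match(taxa, ph$tip.label))
  ape::getMRCA(ph, taxa)
}
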