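## Gene-tree / reference-tree congruence. A gene clade is "congruent" when its
## topology is compatible with the reference restricted to the same taxa,
## a "supported conflict" when a branch with support >= threshold (default 70,
## satisfied by either bootstrap or posterior track) implies an incompatible
## bipartition, and "alternatively rooted" when the unrooted topology matches
## but the basal lineage differs from the reference (the signature of
## acquisition from an external donor).

#' Restrict the reference tree to a taxon subset
#'
#' Degree-2 nodes are suppressed; node ages of retained nodes are preserved
#' (each induced internal node keeps the age of the original MRCA of its
#' descendant taxa), so relative ages survive the restriction.
#'
#' @param ref a \code{dated_tree}.
#' @param taxa character vector, subset of the reference leaf set.
#' @return a \code{dated_tree} over \code{taxa}.
#' @export
induced_subtree <- function(ref, taxa) {
  ph <- ref$phylo
  unknown <- setdiff(taxa, ph$tip.label)
  if (length(unknown))
    stop("validation error: unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa")
  sub <- ape::keep.tip(ph, taxa)
  ages <- NULL
  if (!is.null(ref$node_ages)) {
    n2 <- length(sub$tip.label)
    ages <- numeric(n2 + sub$Nnode)
    ages[seq_len(n2)] <- ref$node_ages[match(sub$tip.label, ph$tip.label)]
    st <- subtended_taxa(sub)
    for (v in (n2 + 1L):(n2 + sub$Nnode)) {
      orig <- ape::getMRCA(ph, st[[v]])
      ages[v] <- ref$node_ages[orig]
    }
  }
  dated_tree(sub, node_ages = ages, clade_labels = ref$clade_labels)
}

## --- bipartition / cluster machinery -------------------------------------

## unrooted splits of a phylo as a list of taxon-label vectors (side below
## each internal edge), deduplicated and trivial splits dropped
tree_splits <- function(ph) {
  n <- length(ph$tip.label)
  st <- subtended_taxa(ph)
  sides <- list()
  for (i in seq_len(nrow(ph$edge))) {
    ch <- ph$edge[i, 2]
    if (ch <= n) next
    side <- st[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    sides[[length(sides) + 1L]] <- side
  }
  keys <- vapply(sides, function(s) paste(sort(s), collapse = "|"), "")
  comp_keys <- vapply(sides, function(s)
    paste(sort(setdiff(ph$tip.label, s)), collapse = "|"), "")
  canon <- ifelse(keys < comp_keys, keys, comp_keys)
  sides[!duplicated(canon)]
}

#' Test compatibility of two bipartitions on a common leaf set
#'
#' Splits A|A' and B|B' are incompatible iff all four pairwise intersections
#' are nonempty.
#'
#' @param a,b character vectors (one side of each split).
#' @param leaves full leaf set.
#' @return logical.
#' @export
splits_compatible <- function(a, b, leaves) {
  a2 <- setdiff(leaves, a); b2 <- setdiff(leaves, b)
  !(length(intersect(a, b)) && length(intersect(a, b2)) &&
    length(intersect(a2, b)) && length(intersect(a2, b2)))
}

## split vs whole tree: compatible iff pairwise-compatible with every tree
## split (tree splits are jointly compatible, so pairwise suffices)
split_in_tree_compatible <- function(side, ph) {
  leaves <- ph$tip.label
  for (s in tree_splits(ph))
    if (!splits_compatible(side, s, leaves)) return(FALSE)
  TRUE
}

## rooted clusters (taxon sets of internal nodes, excluding root/full set)
tree_clusters <- function(ph) {
  n <- length(ph$tip.label)
  st <- subtended_taxa(ph)
  out <- list()
  for (v in (n + 1L):(n + ph$Nnode)) {
    if (length(st[[v]]) >= n) next
    if (length(st[[v]]) < 2) next
    out[[length(out) + 1L]] <- st[[v]]
  }
  out
}

cluster_compatible <- function(cl, ref_clusters) {
  for (rc in ref_clusters) {
    i <- length(intersect(cl, rc))
    if (i > 0 && i < length(cl) && i < length(rc)) return(FALSE)
  }
  TRUE
}

## effective support per internal node: max over the two tracks
effective_support <- function(gt) {
  pmax(ifelse(is.na(gt$support_primary), -Inf, gt$support_primary),
       ifelse(is.na(gt$support_secondary), -Inf, gt$support_secondary))
}

## map a set of gene-tree copies to reference taxa (in-domain only)
copies_taxa <- function(gt, copies, ref) {
  tx <- unique(unname(gt$copy_to_taxon[copies]))
  intersect(tx, ref$phylo$tip.label)
}

#' Supported conflicts between a gene tree and the reference
#'
#' Returns every gene-tree bipartition (taxon space, paralogs collapsed to one
#' occurrence) carried by a branch with support >= \code{threshold} that is
#' incompatible with the reference tree restricted to the shared taxa. With
#' \code{rooted = TRUE} the comparison uses rooted clusters instead of
#' unrooted splits (so a mis-rooted but unrooted-compatible clade can
#' conflict).
#'
#' @param gene a \code{gene_tree}.
#' @param ref a \code{dated_tree}.
#' @param threshold support threshold in percent (default 70; a posterior of
#'   0.70 stored as 70 passes).
#' @param rooted compare as rooted trees (default FALSE).
#' @return data.frame with list column \code{bipartition} and column
#'   \code{support}; empty when no supported conflict. Attribute
#'   \code{shared_taxa} carries the taxa compared.
#' @export
supported_conflicts <- function(gene, ref, threshold = 70, rooted = FALSE) {
  gph <- gene$phylo
  n <- length(gph$tip.label)
  shared <- copies_taxa(gene, gph$tip.label, ref)
  empty <- data.frame(support = numeric(0))
  empty$bipartition <- list()
  attr(empty, "shared_taxa") <- shared
  if (length(shared) < 4) {
    attr(empty, "insufficient") <- TRUE
    return(empty)
  }
  ind <- induced_subtree(ref, shared)
  ref_splits <- tree_splits(ind$phylo)
  ref_clusters <- if (rooted) tree_clusters(ind$phylo) else NULL
  sup <- effective_support(gene)
  st <- subtended_taxa(gph)
  hits <- list(); hit_sup <- numeric(0)
  seen <- character(0)
  for (i in seq_len(nrow(gph$edge))) {
    ch <- gph$edge[i, 2]
    if (ch <= n) next
    s <- sup[ch - n]
    if (!is.finite(s) || s < threshold) next
    below <- copies_taxa(gene, st[[ch]], ref)
    below <- intersect(below, shared)
    above <- setdiff(shared, below)
    straddle <- intersect(
      copies_taxa(gene, setdiff(gph$tip.label, st[[ch]]), ref), below)
    if (length(straddle)) next            # paralog straddles the split
    if (length(below) < 2 || length(above) < (if (rooted) 1 else 2)) next
    key <- paste(sort(below), collapse = "|")
    if (key %in% seen) next
    conflict <- if (rooted) !cluster_compatible(below, ref_clusters)
                else !split_in_tree_compatible(below, ind$phylo)
    if (conflict) {
      seen <- c(seen, key)
      hits[[length(hits) + 1L]] <- below
      hit_sup <- c(hit_sup, s)
    }
  }
  out <- data.frame(support = hit_sup)
  out$bipartition <- hits
  attr(out, "shared_taxa") <- shared
  out
}

#' Detect an alternatively rooted gene clade
#'
#' TRUE iff the clade, treated as unrooted, is compatible with the reference
#' restricted to its taxa, while its rooted basal split differs from the
#' reference basal split. No support threshold is applied: the evidence is
#' positional.
#'
#' @param gene_clade a rooted \code{gene_tree} for the clade (>= 3 taxa after
#'   mapping copies).
#' @param ref a \code{dated_tree}.
#' @return logical.
#' @export
alternative_rooting <- function(gene_clade, ref) {
  gph <- gene_clade$phylo
  taxa <- copies_taxa(gene_clade, gph$tip.label, ref)
  if (length(taxa) < 3) return(FALSE)
  if (!gene_clade$rooted) return(FALSE)
  ind <- induced_subtree(ref, taxa)
  # unrooted compatibility of every gene split
  st <- subtended_taxa(gph)
  n <- length(gph$tip.label)
  for (i in seq_len(nrow(gph$edge))) {
    ch <- gph$edge[i, 2]
    if (ch <= n) next
    below <- intersect(copies_taxa(gene_clade, st[[ch]], ref), taxa)
    straddle <- intersect(
      copies_taxa(gene_clade, setdiff(gph$tip.label, st[[ch]]), ref), below)
    if (length(straddle)) next
    if (length(below) < 2 || length(below) > length(taxa) - 2) next
    if (!split_in_tree_compatible(below, ind$phylo)) return(FALSE)
  }
  !identical(basal_partition(gph, function(copies)
               copies_taxa(gene_clade, copies, ref)),
             basal_partition(ind$phylo, identity))
}

## canonical basal split: sorted sides of the root, as a sorted key
basal_partition <- function(ph, map) {
  r <- root_node(ph)
  kids <- ph$edge[ph$edge[, 1] == r, 2]
  st <- subtended_taxa(ph)
  sides <- lapply(kids, function(v) sort(unique(map(st[[v]]))))
  sides <- sides[vapply(sides, length, 1L) > 0]
  keys <- sort(vapply(sides, paste, "", collapse = "|"))
  paste(keys, collapse = " // ")
}

#' Assess a gene-tree clade against the reference
#'
#' Verdicts, in precedence order: \code{supported_conflict} (a branch with
#' support >= threshold implies an incompatible bipartition),
#' \code{alternative_rooting} (unrooted-compatible, mis-rooted),
#' \code{congruent}; \code{unresolved} when fewer than 4 shared taxa or no
#' support values exist. Multiple copies of one taxon are collapsed for the
#' compatibility test.
#'
#' @param gene a \code{gene_tree}.
#' @param ref a \code{dated_tree}.
#' @param copies copy ids forming the (monophyletic) clade; default all.
#' @param threshold support threshold (percent).
#' @param clade_id identifier carried through to the result.
#' @return a one-row data.frame of class \code{clade_assessment}: gene, clade,
#'   verdict, max_conflict_support, n_shared_taxa, plus a list column
#'   \code{taxa}.
#' @export
assess_clade <- function(gene, ref, copies = gene$phylo$tip.label,
                         threshold = 70, clade_id = "clade1") {
  stopifnot(all(copies %in% gene$phylo$tip.label))
  sub <- if (length(copies) < length(gene$phylo$tip.label) && length(copies) >= 2)
    restrict_gene_tree(gene, copies) else gene
  taxa <- copies_taxa(gene, copies, ref)
  has_support <- any(is.finite(effective_support(gene)))
  verdict <- NULL
  max_sup <- NA_real_
  conflicts <- NULL
  if (length(taxa) < 4 || !has_support) {
    verdict <- "unresolved"
  } else {
    conflicts <- supported_conflicts(sub, ref, threshold,
                                     rooted = isTRUE(sub$rooted))
    any_supported <- any(effective_support(sub) >= threshold, na.rm = TRUE)
    if (nrow(conflicts)) {
      verdict <- "supported_conflict"
      max_sup <- max(conflicts$support)
    } else if (isTRUE(sub$rooted) && length(taxa) >= 3 &&
               alternative_rooting(sub, ref)) {
      # positional evidence: no support threshold applies here
      verdict <- "alternative_rooting"
    } else if (any_supported) {
      verdict <- "congruent"
    } else {
      # nothing in the clade reaches the support threshold: the gene tree
      # can neither confirm nor contradict the reference
      verdict <- "unresolved"
    }
  }
  out <- data.frame(gene = gene$gene_name, clade = clade_id, verdict = verdict,
                    max_conflict_support = max_sup,
                    n_shared_taxa = length(taxa), stringsAsFactors = FALSE)
  out$taxa <- list(taxa)
  attr(out, "conflicts") <- conflicts
  class(out) <- c("clade_assessment", class(out))
  out
}

## keep a subset of copies, preserving supports on surviving internal nodes
restrict_gene_tree <- function(gene, copies) {
  ph <- gene$phylo
  n <- length(ph$tip.label)
  sub <- ape::keep.tip(ph, copies)
  # map surviving internal nodes by descendant copy set
  st_old <- subtended_taxa(ph)
  key_old <- vapply(st_old, function(s)
    paste(sort(intersect(s, copies)), collapse = "|"), "")
  st_new <- subtended_taxa(sub)
  n2 <- length(sub$tip.label)
  sp <- rep(NA_real_, sub$Nnode); ss <- rep(NA_real_, sub$Nnode)
  for (v in (n2 + 1L):(n2 + sub$Nnode)) {
    key <- paste(sort(st_new[[v]]), collapse = "|")
    old <- which(key_old == key)
    old <- old[old > n]
    if (length(old)) {
      sp[v - n2] <- gene$support_primary[old[1] - n]
      ss[v - n2] <- gene$support_secondary[old[1] - n]
    }
  }
  gene_tree(sub, copy_to_taxon = gene$copy_to_taxon, gene_name = gene$gene_name,
            support_primary = sp, support_secondary = ss,
            rooted = gene$rooted, outgroup = intersect(gene$outgroup, copies))
}
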