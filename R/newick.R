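## Newick I/O. Parsing is backed by ape::read.tree after a light pre-pass that
## (a) checks parenthesis structure so malformed input gets a character offset,
## and (b) rewrites square-bracket branch comments carrying support values into
## internal node labels. Two support tracks per branch are accepted, written as
## "primary/secondary" (e.g. MP bootstrap above / Bayesian posterior below a
## branch); a pre-existing node label always wins over a comment.

#' Parse a Newick string into a reference or gene tree
#'
#' Supports may sit in internal node labels (\code{(A,B)95:1}) or in bracket
#' comments after the closing parenthesis or branch length
#' (\code{(A,B)[95]:1}, \code{(A,B):1[95]}); node labels take precedence.
#' A label of the form \code{"x"} or \code{"x/y"} is read as one or two
#' support tracks; any support track whose values all lie in [0,1] is taken to
#' be on the probability scale and multiplied by 100 (idempotent). Non-numeric
#' internal labels are kept as clade labels (reference trees).
#'
#' @param text Newick string (single tree, terminating \code{;} optional).
#' @param type \code{"reference"} (returns \code{\link{dated_tree}}) or
#'   \code{"gene"} (returns \code{\link{gene_tree}}).
#' @param support_convention \code{"auto"} (default, node label wins),
#'   \code{"branch_label"} (node labels only) or \code{"node_comment"}
#'   (bracket comments only).
#' @param time_scaled if \code{TRUE} and branch lengths are present on a
#'   reference tree, they are read as Ga and node ages are filled in.
#' @param ages_in_ma if \code{TRUE}, time-scaled input lengths are in Ma and
#'   divided by 1000 (ages are kept in Ga internally).
#' @param ... passed to \code{\link{gene_tree}} for \code{type = "gene"}
#'   (e.g. \code{gene_name}, \code{copy_to_taxon}).
#' @return a \code{dated_tree} or \code{gene_tree}.
#' @export
parse_tree <- function(text, type = c("reference", "gene"),
                       support_convention = c("auto", "branch_label", "node_comment"),
                       time_scaled = FALSE, ages_in_ma = FALSE, ...) {
  type <- match.arg(type)
  support_convention <- match.arg(support_convention)
  text <- gsub("[[:space:]]", "", paste(text, collapse = ""))
  if (!nzchar(text)) stop("parse error: empty Newick string")
  if (!grepl(";$", text)) text <- paste0(text, ";")
  check_parens(text)
  if (support_convention != "branch_label") text <- comments_to_labels(text)
  else text <- gsub("\\[[^]]*\\]", "", text)
  ph <- ape::read.tree(text = text)
  if (is.null(ph)) stop("parse error: ape could not read the Newick string")
  if (length(ph$tip.label) > 1) ph <- ape::collapse.singles(ph)
  if (anyDuplicated(ph$tip.label))
    stop("validation error: duplicate leaf labels: ",
         paste(unique(ph$tip.label[duplicated(ph$tip.label)]), collapse = ", "))
  sup <- split_node_labels(ph)
  if (type == "reference") {
    if (ages_in_ma && !is.null(ph$edge.length))
      ph$edge.length <- ph$edge.length / 1000
    ages <- NULL
    if (time_scaled) {
      if (is.null(ph$edge.length)) stop("time_scaled = TRUE but tree has no branch lengths")
      ages <- ages_from_lengths(ph)
    }
    dated_tree(ph, node_ages = ages, support_primary = sup$primary,
               support_secondary = sup$secondary, clade_labels = sup$clade_labels)
  } else {
    gene_tree(ph, support_primary = sup$primary,
              support_secondary = sup$secondary, ...)
  }
}

## parenthesis sanity scan; reports 1-based character offset of the problem
check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("parse error: unbalanced ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("parse error: ", depth, " unclosed '(' at character offset ",
         nchar(text))
  invisible(TRUE)
}

## rewrite ")[c]" / "):len[c]" into internal node labels; a node label already
## present wins and the comment is dropped. Tip comments are discarded.
comments_to_labels <- function(text) {
  # comment directly after ')' with no label: promote
  text <- gsub("\\)\\[([^]]*)\\]", ")\\1", text)
  # comment after an internal branch length: ")(label)?:len[c]"
  repeat {
    new <- sub("\\)((?:[^][(),:;]*)?)(:[0-9eE.+-]+)\\[([^]]*)\\]",
               ")\\1__CMT\\3__\\2", text)
    if (identical(new, text)) break
    text <- new
  }
  # promoted comments: keep only when no label preceded them
  repeat {
    new <- sub("\\)__CMT([^_]*)__", ")\\1", text)  # bare comment -> label
    if (identical(new, text)) break
    text <- new
  }
  text <- gsub("__CMT[^_]*__", "", text)           # label present: drop comment
  # remaining comments (tips, metadata): strip
  text <- gsub("\\[[^]]*\\]", "", text)
  # sanitize comment-derived labels like &support=95 -> 95
  text
}

## split ape node labels into support tracks and clade labels
split_node_labels <- function(ph) {
  nn <- ph$Nnode
  primary <- rep(NA_real_, nn)
  secondary <- rep(NA_real_, nn)
  clade_labels <- list()
  labs <- ph$node.label
  if (!is.null(labs)) {
    for (i in seq_len(nn)) {
      lab <- labs[i]
      if (is.na(lab) || !nzchar(lab)) next
      lab2 <- gsub("&(support|prob|posterior)=", "", lab)
      parts <- strsplit(lab2, "/", fixed = TRUE)[[1]]
      nums <- suppressWarnings(as.numeric(parts))
      if (length(nums) >= 1 && !anyNA(nums)) {
        primary[i] <- nums[1]
        if (length(nums) >= 2) secondary[i] <- nums[2]
      } else {
        node <- length(ph$tip.label) + i
        clade_labels[[lab]] <- ph$tip.label[subtended_tips(ph)[[node]]]
      }
    }
  }
  list(primary = normalize_supports(primary),
       secondary = normalize_supports(secondary),
       clade_labels = clade_labels)
}

#' Normalize a support track to the 0--100 scale
#'
#' If every non-missing value of the track lies in [0,1], values are treated as
#' probabilities and multiplied by 100. The operation is idempotent.
#'
#' @param s numeric vector of supports.
#' @return numeric vector on a 0--100 scale.
#' @export
normalize_supports <- function(s) {
  v <- s[!is.na(s)]
  if (length(v) && all(v >= 0) && all(v <= 1)) s <- s * 100
  check_supports(s)
  s
}

#' Serialize a tree to Newick
#'
#' Writes supports back as internal node labels (\code{"p"} or \code{"p/s"});
#' clade labels of a reference tree are written for nodes without supports.
#' \code{parse_tree(write_newick(x))} round-trips topology, branch lengths and
#' supports.
#'
#' @param tree a \code{dated_tree} or \code{gene_tree}.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ph <- tree$phylo
  nn <- ph$Nnode
  labs <- character(nn)
  for (i in seq_len(nn)) {
    p <- tree$support_primary[i]; s <- tree$support_secondary[i]
    if (!is.na(p) && !is.na(s)) labs[i] <- paste0(format(p, digits = digits), "/",
                                                  format(s, digits = digits))
    else if (!is.na(p)) labs[i] <- format(p, digits = digits)
  }
  if (inherits(tree, "dated_tree") && length(tree$clade_labels)) {
    st <- subtended_taxa(ph)
    n <- length(ph$tip.label)
    for (nm in names(tree$clade_labels)) {
      want <- sort(tree$clade_labels[[nm]])
      for (i in seq_len(nn)) {
        if (nzchar(labs[i])) next
        if (identical(sort(st[[n + i]]), want)) { labs[i] <- nm; break }
      }
    }
  }
  ph$node.label <- labs
  ape::write.tree(ph, digits = digits)
}

#' Read a reference tree from a Newick file
#' @param path file path.
#' @param ... passed to \code{\link{parse_tree}}.
#' @return a \code{dated_tree}.
#' @export
read_ref_tree <- function(path, ...) {
  parse_tree(readLines(path, warn = FALSE), type = "reference", ...)
}

#' Read a gene tree from a Newick file
#' @param path file path.
#' @param ... passed to \code{\link{parse_tree}} / \code{\link{gene_tree}}.
#' @return a \code{gene_tree}.
#' @export
read_gene_tree <- function(path, ...) {
  parse_tree(readLines(path, warn = FALSE), type = "gene", ...)
}
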