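## Transfer-event bookkeeping: raw events from ASR gains + clade assessments,
## linkage collapsing (operonic genes move in one transfer), duplication
## ambiguity flags (min/max counts), event dating, and rates per billion years.

#' Build a transfer event set
#'
#' @param events data.frame with columns \code{event_id}, \code{evidence},
#'   \code{ambiguity} (\code{"firm"} or \code{"possible_duplication"}),
#'   \code{dup_family} (NA for unflagged), \code{age_lo}, \code{age_hi}, and
#'   list columns \code{genes}, \code{taxa}, \code{copies}.
#' @param domain_age age span of the domain in Gy (default 3.5).
#' @return object of class \code{transfer_event_set}.
#' @export
transfer_event_set <- function(events, domain_age = 3.5) {
  needed <- c("event_id", "evidence", "ambiguity")
  stopifnot(all(needed %in% names(events)))
  stopifnot(all(events$ambiguity %in% c("firm", "possible_duplication")))
  structure(list(events = events, domain_age = domain_age),
            class = "transfer_event_set")
}

#' @export
print.transfer_event_set <- function(x, ...) {
  cnt <- event_counts(x)
  cat("transfer_event_set:", nrow(x$events), "events (min", cnt["min"],
      "/ max", cnt["max"], "), domain age", x$domain_age, "Gy\n")
  invisible(x)
}

empty_events <- function() {
  df <- data.frame(event_id = character(), evidence = character(),
                   ambiguity = character(), dup_family = character(),
                   age_lo = numeric(), age_hi = numeric(),
                   stringsAsFactors = FALSE)
  df$genes <- list(); df$taxa <- list(); df$copies <- list()
  df
}

taxa_key <- function(taxa) paste(sort(unique(taxa)), collapse = "|")

#' Propose raw transfer events from gains and clade assessments
#'
#' One raw event per (gene, clade) where an ancestral-state gain edge subtends
#' the clade's taxa and the clade's verdict is \code{supported_conflict},
#' \code{alternative_rooting}, or congruent/unresolved with a restricted
#' taxonomic distribution (the latter admitted as
#' \code{taxonomic_restriction} evidence when
#' \code{allow_taxonomic_restriction} is TRUE). A clade congruent with the
#' reference and spanning the whole domain yields no event. Gain edges with no
#' overlapping assessed clade are emitted with evidence \code{asr_gain} and a
#' warning: ASR-only evidence, reported in an unconfirmed tier and excluded
#' from minimum counts.
#'
#' @param gains data.frame of candidate gain edges per gene
#'   (\code{\link{candidate_gain_edges}} output plus a \code{gene} column), or
#'   NULL when no ASR was run.
#' @param assessments a data.frame of stacked \code{\link{assess_clade}} rows
#'   (columns gene, clade, verdict, list column taxa).
#' @param ref the reference \code{dated_tree} (to know the full taxon set).
#' @param copies_of optional function(gene, taxa) returning the copy ids of a
#'   clade (used for linkage collapsing); default pastes gene and taxon.
#' @param allow_taxonomic_restriction admit restricted congruent clades.
#' @return data.frame of raw events (see \code{\link{transfer_event_set}}).
#' @export
propose_events <- function(gains, assessments, ref,
                           copies_of = NULL,
                           allow_taxonomic_restriction = TRUE) {
  if (is.null(copies_of))
    copies_of <- function(gene, taxa) paste(gene, taxa, sep = ".")
  all_taxa <- ref$phylo$tip.label
  ev <- empty_events()
  add <- function(gene, taxa, evidence, copies) {
    k <- nrow(ev) + 1L
    ev[k, c("event_id", "evidence", "ambiguity")] <<-
      list(sprintf("ev%03d", k), evidence, "firm")
    ev$dup_family[k] <<- NA_character_
    ev$age_lo[k] <<- NA_real_; ev$age_hi[k] <<- NA_real_
    ev$genes[[k]] <<- gene; ev$taxa[[k]] <<- sort(unique(taxa))
    ev$copies[[k]] <<- copies
  }
  matched_gain <- logical(if (is.null(gains)) 0 else nrow(gains))
  if (!is.null(assessments) && nrow(assessments)) {
    for (i in seq_len(nrow(assessments))) {
      a <- assessments[i, ]
      taxa <- a$taxa[[1]]
      if (!length(taxa)) next
      gene_gains <- if (is.null(gains)) NULL else
        gains[gains$gene == a$gene, , drop = FALSE]
      sub_idx <- if (is.null(gene_gains) || !nrow(gene_gains)) integer(0) else
        which(vapply(gene_gains$taxa, function(g)
          all(taxa %in% g), TRUE))
      has_gain <- length(sub_idx) > 0
      if (has_gain && !is.null(gains))
        matched_gain[which(gains$gene == a$gene)[sub_idx]] <- TRUE
      evidence <- NULL
      if (a$verdict == "supported_conflict") evidence <- "supported_conflict"
      else if (a$verdict == "alternative_rooting") evidence <- "alternative_rooting"
      else if (a$verdict == "congruent") {
        restricted <- length(setdiff(all_taxa, taxa)) > 0
        if (allow_taxonomic_restriction && restricted && has_gain)
          evidence <- "taxonomic_restriction"
      } else if (a$verdict == "unresolved" && has_gain) {
        small <- !is.null(a$n_shared_taxa) && a$n_shared_taxa < 4
        restricted <- length(setdiff(all_taxa, taxa)) > 0
        if (small && restricted && allow_taxonomic_restriction) {
          # too few taxa for a topology test; restricted distribution plus an
          # ASR gain is the accepted evidence for such clades
          evidence <- "taxonomic_restriction"
        } else {
          # gene tree uninformative: ASR-only tier, excluded from min counts
          evidence <- "asr_gain"
        }
      }
      if (!is.null(evidence))
        add(a$gene, taxa, evidence, copies_of(a$gene, taxa))
    }
  }
  if (!is.null(gains) && nrow(gains)) {
    for (i in which(!matched_gain)) {
      g <- gains[i, ]
      covered <- any(vapply(seq_len(nrow(ev)), function(k)
        identical(ev$genes[[k]], g$gene) &&
          all(g$taxa[[1]] %in% ev$taxa[[k]]), TRUE))
      if (covered) next
      warning("gain edge for gene ", g$gene,
              " has no overlapping assessed clade; emitting ASR-only event")
      add(g$gene, g$taxa[[1]], "asr_gain", copies_of(g$gene, g$taxa[[1]]))
    }
  }
  ev
}

#' Collapse genomically linked events
#'
#' Events merge (transitively) when their recipient clades are identical and
#' at least one taxon shows a member copy of one event linked to a member copy
#' of the other with \code{gap_orfs <= max_gap_orfs}: two genes moving in one
#' operon were acquired in a single transfer. Counts are non-increasing; the
#' operation is idempotent and invariant to event order.
#'
#' @param events raw event data.frame (or a \code{transfer_event_set}).
#' @param linkage a \code{linkage_table}.
#' @param max_gap_orfs maximum intervening ORFs for two copies to count as
#'   linked (default 1, so copies separated by a single ORF still collapse).
#' @param domain_age domain age span in Gy for the resulting set.
#' @return a \code{transfer_event_set}.
#' @export
collapse_linked <- function(events, linkage, max_gap_orfs = 1,
                            domain_age = 3.5) {
  if (inherits(events, "transfer_event_set")) {
    domain_age <- events$domain_age
    events <- events$events
  }
  n <- nrow(events)
  if (n == 0)
    return(transfer_event_set(events, domain_age))
  link <- linkage[linkage$gap_orfs <= max_gap_orfs, , drop = FALSE]
  # union-find over events
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  keys <- vapply(events$taxa, taxa_key, "")
  if (nrow(link)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (keys[i] != keys[j]) next
      ci <- events$copies[[i]]; cj <- events$copies[[j]]
      hit <- (link$copy_a %in% ci & link$copy_b %in% cj) |
             (link$copy_a %in% cj & link$copy_b %in% ci)
      if (any(hit)) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), comp)
  ord <- order(vapply(groups, min, 1L))
  groups <- groups[ord]
  out <- empty_events()
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    first <- idx[1]
    out[k, c("event_id", "evidence", "ambiguity")] <-
      list(sprintf("E%03d", k), events$evidence[first],
           if (any(events$ambiguity[idx] == "firm")) "firm"
           else "possible_duplication")
    fam <- events$dup_family[idx]
    out$dup_family[k] <- if (all(is.na(fam))) NA_character_ else fam[!is.na(fam)][1]
    out$age_lo[k] <- events$age_lo[first]; out$age_hi[k] <- events$age_hi[first]
    out$genes[[k]] <- sort(unique(unlist(events$genes[idx])))
    out$taxa[[k]] <- events$taxa[[first]]
    out$copies[[k]] <- sort(unique(unlist(events$copies[idx])))
  }
  transfer_event_set(out, domain_age)
}

#' Apply duplication-ambiguity flags
#'
#' Flags mark events whose gene may stem from an ancestral duplication of a
#' sister clade's gene rather than an independent transfer. Flagged events
#' count only toward the maximum; each duplication family is guaranteed one
#' contribution to the minimum (its firm anchor if present, otherwise one
#' representative).
#'
#' @param event_set a \code{transfer_event_set}.
#' @param flags data.frame with columns \code{gene}, \code{family},
#'   \code{flagged} (logical; FALSE rows declare a family's firm anchor) and
#'   optionally \code{clade} matched against event copies.
#' @return the event set with \code{ambiguity} and \code{dup_family} updated.
#' @export
apply_duplication_flags <- function(event_set, flags) {
  ev <- event_set$events
  if (is.null(flags) || !nrow(flags)) return(event_set)
  if (!"flagged" %in% names(flags)) flags$flagged <- TRUE
  for (i in seq_len(nrow(flags))) {
    hit <- vapply(seq_len(nrow(ev)), function(k) {
      ok <- flags$gene[i] %in% ev$genes[[k]]
      if (ok && "clade" %in% names(flags) && !is.na(flags$clade[i]))
        ok <- any(grepl(paste0("\\.", flags$clade[i], "$"),
                        ev$copies[[k]])) ||
          flags$clade[i] %in% ev$copies[[k]]
      ok
    }, TRUE)
    if (!any(hit))
      stop("validation error: duplication flag for gene ", flags$gene[i],
           " matches no event")
    ev$dup_family[hit] <- flags$family[i]
    if (isTRUE(as.logical(flags$flagged[i])))
      ev$ambiguity[hit] <- "possible_duplication"
  }
  transfer_event_set(ev, event_set$domain_age)
}

#' Minimum and maximum event counts
#'
#' min = firm events (excluding the unconfirmed, ASR-only tier), plus one
#' representative for any duplication family with no firm member;
#' max = all events.
#'
#' @param event_set a \code{transfer_event_set} (or its events data.frame).
#' @return named numeric vector \code{c(min=, max=)}.
#' @export
event_counts <- function(event_set) {
  ev <- if (inherits(event_set, "transfer_event_set")) event_set$events
        else event_set
  # ASR-only (unconfirmed-tier) events never count toward the minimum
  firm <- sum(ev$ambiguity == "firm" & ev$evidence != "asr_gain")
  flagged <- ev$ambiguity == "possible_duplication"
  # a family wholly made of flagged events still represents at least one
  # transfer: it contributes 1 to the minimum
  fams <- unique(ev$dup_family[flagged & !is.na(ev$dup_family)])
  orphan <- sum(vapply(fams, function(f)
    !any(ev$ambiguity == "firm" & !is.na(ev$dup_family) & ev$dup_family == f),
    TRUE))
  c(min = firm + orphan, max = nrow(ev))
}

#' Attach age intervals to events
#'
#' Each event's interval is [age of the recipient clade's crown node, age of
#' that node's parent] on the chronogram: the transfer happened somewhere on
#' the stem branch.
#'
#' @param event_set a \code{transfer_event_set}.
#' @param chronogram a dated \code{dated_tree} covering the recipient taxa.
#' @return the event set with \code{age_lo}/\code{age_hi} filled (Ga).
#' @export
date_events <- function(event_set, chronogram) {
  if (is.null(chronogram$node_ages)) stop("chronogram has no node ages")
  ph <- chronogram$phylo
  st <- subtended_taxa(ph)
  parent <- rep(NA_integer_, length(st))
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  ev <- event_set$events
  for (k in seq_len(nrow(ev))) {
    taxa <- intersect(ev$taxa[[k]], ph$tip.label)
    if (length(taxa) == 0) next
    v <- if (length(taxa) == 1) match(taxa, ph$tip.label)
         else ape::getMRCA(ph, taxa)
    if (!setequal(st[[v]], taxa))
      stop("validation error: recipient clade of event ", ev$event_id[k],
           " is not monophyletic in the reference tree (taxa: ",
           paste(taxa, collapse = ", "), ")")
    ev$age_lo[k] <- chronogram$node_ages[v]
    ev$age_hi[k] <- if (is.na(parent[v])) chronogram$node_ages[v]
                    else chronogram$node_ages[parent[v]]
  }
  transfer_event_set(ev, event_set$domain_age)
}

#' Round half away from zero
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values (0.05 at 1 digit rounds to 0.1, not 0.0).
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Lateral transfer rate
#'
#' Events per billion years over the age span of the domain, rounded to one
#' decimal (half away from zero).
#'
#' @param n_events event count (>= 0).
#' @param domain_age domain age span in Gy (> 0), default 3.5.
#' @return rate in events per Gy.
#' @export
transfer_rate <- function(n_events, domain_age = 3.5) {
  if (any(domain_age <= 0)) stop("domain error: domain_age must be positive")
  if (any(n_events < 0)) stop("domain error: negative event count")
  round_half_up(n_events / domain_age, 1)
}
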