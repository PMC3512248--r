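## Configuration-driven orchestration. Two input routes feed the event engine:
## (a) a clade table transcribing per-gene monophyletic clades directly
##     (clade_table route, used by the bundled study fixtures), and
## (b) reference tree + presence matrix + gene trees, run through Mk1 ASR and
##     congruence assessment (full route, used on simulated bundles).
## Both then pass through linkage collapsing, duplication flags, optional
## dating, and category summaries.

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults: \code{support_threshold} (70),
#'   \code{present_threshold} (0.7), \code{absent_threshold} (0.3),
#'   \code{max_gap_orfs} (1), \code{domain_age} (3.5 Gy),
#'   \code{allow_taxonomic_restriction} (TRUE), \code{seed} (1), and the
#'   input paths (\code{ref_tree}, \code{presence}, \code{gene_trees},
#'   \code{clade_table}, \code{linkage}, \code{dup_flags},
#'   \code{categories}, \code{clade_labels}, \code{constraints}).
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  modifyList(list(
    support_threshold = 70, present_threshold = 0.7, absent_threshold = 0.3,
    max_gap_orfs = 1, domain_age = 3.5, allow_taxonomic_restriction = TRUE,
    skip_dating = TRUE, seed = 1,
    ref_tree = NULL, presence = NULL, gene_trees = NULL, clade_table = NULL,
    linkage = NULL, dup_flags = NULL, categories = NULL, clade_labels = NULL,
    constraints = NULL), list(...))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; relative input paths resolve against its directory.
#' @return config list as from \code{\link{pipeline_config}}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("ref_tree", "presence", "clade_table", "linkage", "dup_flags",
                "categories", "clade_labels", "constraints")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  }
  if (!is.null(cfg$gene_trees))
    cfg$gene_trees <- vapply(cfg$gene_trees, function(p)
      if (file.exists(p)) p else file.path(base, p), "")
  do.call(pipeline_config, cfg)
}

#' Read a clade table (one row per gene clade)
#'
#' Columns: \code{gene}, \code{clade_id}, \code{taxa} (comma-separated),
#' optional \code{evidence}. Each row is a confirmed monophyletic gene clade,
#' i.e. one raw transfer event before linkage collapsing; copies are
#' identified as \code{"<gene>.<clade_id>"} for linkage lookup.
#'
#' @param path delimited text file.
#' @return data.frame of raw events.
#' @export
read_clade_table <- function(path) {
  df <- read_delim_auto(path)
  ev <- empty_events()
  for (i in seq_len(nrow(df))) {
    k <- nrow(ev) + 1L
    ev[k, c("event_id", "evidence", "ambiguity")] <-
      list(paste0(df$gene[i], ".", df$clade_id[i]),
           if (!is.null(df$evidence)) df$evidence[i] else "supported_conflict",
           "firm")
    ev$dup_family[k] <- NA_character_
    ev$age_lo[k] <- NA_real_; ev$age_hi[k] <- NA_real_
    ev$genes[[k]] <- df$gene[i]
    ev$taxa[[k]] <- sort(trimws(strsplit(df$taxa[i], ",")[[1]]))
    ev$copies[[k]] <- paste0(df$gene[i], ".", df$clade_id[i])
  }
  ev
}

#' Read a gene-to-category map
#' @param path delimited text with columns gene, category and optional group.
#' @return data.frame.
#' @export
read_categories <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1:2] <- c("gene", "category")
  df
}

#' Read duplication-ambiguity flags
#' @param path delimited text with columns gene, clade, family, flagged (0/1).
#' @return data.frame.
#' @export
read_dup_flags <- function(path) {
  df <- read_delim_auto(path)
  df$flagged <- as.logical(as.integer(df$flagged))
  df
}

#' Run the full detection pipeline
#'
#' @param config list from \code{\link{pipeline_config}} or
#'   \code{\link{read_config}}.
#' @return list with \code{event_set} (a \code{transfer_event_set}),
#'   \code{summary} (category table from \code{\link{write_summary}}),
#'   \code{log} (character vector of per-decision lines), and for the full
#'   route \code{asr} and \code{assessments}.
#' @export
run_pipeline <- function(config) {
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  asr_results <- NULL; assessments <- NULL

  if (!is.null(config$clade_table)) {
    raw <- read_clade_table(config$clade_table)
    say("clade_table route: ", nrow(raw), " raw events from ",
        config$clade_table)
  } else if (!is.null(config$ref_tree) && !is.null(config$presence)) {
    ref <- read_ref_tree(config$ref_tree, time_scaled = TRUE)
    if (!is.null(config$clade_labels))
      ref$clade_labels <- read_clade_labels(config$clade_labels)
    pm <- read_presence_matrix(config$presence)
    gene_trees <- list()
    if (!is.null(config$gene_trees)) {
      for (p in config$gene_trees) {
        g <- sub("\\.nwk$", "", basename(p))
        gene_trees[[g]] <- read_gene_tree(p, gene_name = g)
      }
    }
    res <- detect_events(ref, pm, gene_trees, config)
    raw <- res$raw
    asr_results <- res$asr
    assessments <- res$assessments
    log <- c(log, res$log)
  } else if (is.null(config$clade_table) && is.null(config$presence)) {
    raw <- empty_events()
    say("no inputs: empty event list")
  } else stop("config must provide either clade_table or ref_tree+presence")

  linkage <- if (!is.null(config$linkage)) read_linkage_table(config$linkage)
    else linkage_table(data.frame(taxon = character(), copy_a = character(),
                                  copy_b = character(), gap_orfs = integer()))
  es <- collapse_linked(raw, linkage, max_gap_orfs = config$max_gap_orfs,
                        domain_age = config$domain_age)
  say("linkage collapsing: ", nrow(raw), " raw events -> ",
      nrow(es$events), " events")
  if (!is.null(config$dup_flags)) {
    flags <- read_dup_flags(config$dup_flags)
    es <- apply_duplication_flags(es, flags)
    say("duplication flags applied: ", sum(flags$flagged), " events flagged")
  }
  cnt <- event_counts(es)
  say("event counts: min ", cnt["min"], " max ", cnt["max"])

  categories <- if (!is.null(config$categories))
    read_categories(config$categories) else NULL
  summary <- write_summary(es, categories, domain_age = config$domain_age)
  list(event_set = es, summary = summary, log = log,
       asr = asr_results, assessments = assessments)
}

## full route: ASR per gene, clade assessment of each gain, raw events
detect_events <- function(ref, pm, gene_trees, config) {
  log <- character(0)
  gains_all <- NULL
  assessments <- NULL
  asr_results <- list()
  for (g in colnames(pm)) {
    tips <- setNames(pm[, g], rownames(pm))
    if (all(tips == 0)) {
      log <- c(log, paste0(g, ": gene absent everywhere; 0 gains"))
      next
    }
    asr <- marginal_asr(ref, tips,
                        present_threshold = config$present_threshold,
                        absent_threshold = config$absent_threshold)
    asr_results[[g]] <- asr
    gains <- candidate_gain_edges(asr)
    log <- c(log, paste0(g, ": q=", signif(asr$q, 3), ", ",
                         nrow(gains), " candidate gain edge(s)"))
    if (nrow(gains)) {
      gains$gene <- g
      gains_all <- rbind(gains_all, gains)
    }
    gt <- gene_trees[[g]]
    if (!is.null(gt) && nrow(gains)) {
      for (i in seq_len(nrow(gains))) {
        carrier_taxa <- intersect(gains$taxa[[i]],
                                  rownames(pm)[pm[, g] == 1L])
        copies <- names(gt$copy_to_taxon)[gt$copy_to_taxon %in% carrier_taxa]
        if (length(copies) < 1) next
        # a gain region may span several independently acquired gene-tree
        # clades: assess each maximal monophyletic group separately
        groups <- maximal_mono_groups(gt, copies)
        for (j in seq_along(groups)) {
          grp <- groups[[j]]
          grp_taxa <- sort(unique(unname(gt$copy_to_taxon[grp])))
          a <- if (length(grp) >= 2)
            assess_clade(gt, ref, grp, threshold = config$support_threshold,
                         clade_id = paste0(g, ".gain", i, ".", j))
          else {
            out <- data.frame(gene = g, clade = paste0(g, ".gain", i, ".", j),
                              verdict = "unresolved",
                              max_conflict_support = NA_real_,
                              n_shared_taxa = length(grp_taxa),
                              stringsAsFactors = FALSE)
            out$taxa <- list(grp_taxa)
            out
          }
          a$taxa <- list(grp_taxa)
          log <- c(log, paste0(g, " clade ", a$clade, ": verdict ", a$verdict))
          assessments <- rbind(assessments, a)
        }
      }
    }
  }
  copies_of <- function(gene, taxa) {
    gt <- gene_trees[[gene]]
    if (is.null(gt)) return(paste(gene, taxa, sep = "."))
    names(gt$copy_to_taxon)[gt$copy_to_taxon %in% taxa]
  }
  raw <- propose_events(gains_all, assessments, ref, copies_of = copies_of,
                        allow_taxonomic_restriction =
                          config$allow_taxonomic_restriction)
  list(raw = raw, asr = asr_results, assessments = assessments, log = log)
}

is_monophyletic_copies <- function(gt, copies) {
  ph <- gt$phylo
  if (length(copies) >= length(ph$tip.label) || length(copies) == 1)
    return(TRUE)
  v <- ape::getMRCA(ph, copies)
  setequal(subtended_taxa(ph)[[v]], copies)
}

## decompose a copy set into maximal groups monophyletic in the gene tree
maximal_mono_groups <- function(gt, copies) {
  ph <- gt$phylo
  if (is_monophyletic_copies(gt, copies)) return(list(copies))
  st <- subtended_taxa(ph)
  n <- length(ph$tip.label)
  parent <- rep(NA_integer_, n + ph$Nnode)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  inset <- vapply(st, function(s) all(s %in% copies), TRUE)
  groups <- list()
  for (v in seq_along(inset)) {
    if (!inset[v]) next
    if (!length(intersect(st[[v]], copies))) next
    if (!is.na(parent[v]) && inset[parent[v]]) next  # not maximal
    grp <- intersect(st[[v]], copies)
    if (length(grp)) groups[[length(groups) + 1L]] <- grp
  }
  groups
}

#' Category summary table
#'
#' One row per category (and per group of categories when a \code{group}
#' column is present), with minimum/maximum event counts and transfer rates.
#' An event belongs to a category when any gene of its gene group maps there.
#' Ranges render ASCII style (\code{"12-14"}, \code{"3.4-4.0"}).
#'
#' @param event_set a \code{transfer_event_set}.
#' @param categories data.frame (gene, category, optional group) or NULL for
#'   a single overall row.
#' @param domain_age Gy (default from the event set).
#' @return data.frame: category, group, n_min, n_max, rate_min, rate_max,
#'   n_display, rate_display.
#' @export
write_summary <- function(event_set, categories = NULL,
                          domain_age = event_set$domain_age) {
  ev <- event_set$events
  rows <- list()
  cat_count <- function(idx) event_counts(ev[idx, , drop = FALSE])
  mk_row <- function(name, group, cnt) {
    data.frame(category = name, group = group,
               n_min = unname(cnt["min"]), n_max = unname(cnt["max"]),
               rate_min = transfer_rate(cnt["min"], domain_age),
               rate_max = transfer_rate(cnt["max"], domain_age),
               stringsAsFactors = FALSE)
  }
  if (is.null(categories)) {
    rows[[1]] <- mk_row("all", NA_character_, cat_count(seq_len(nrow(ev))))
  } else {
    if (!"group" %in% names(categories)) categories$group <- NA_character_
    for (cat in unique(categories$category)) {
      genes <- categories$gene[categories$category == cat]
      idx <- which(vapply(ev$genes, function(g) any(g %in% genes), TRUE))
      grp <- categories$group[categories$category == cat][1]
      rows[[length(rows) + 1L]] <- mk_row(cat, grp, cat_count(idx))
    }
    df <- do.call(rbind, rows)
    for (grp in unique(df$group[!is.na(df$group)])) {
      member <- df[!is.na(df$group) & df$group == grp & !grepl("^Total ", df$category), ]
      cnt <- c(min = sum(member$n_min), max = sum(member$n_max))
      rows[[length(rows) + 1L]] <- mk_row(paste0("Total ", grp), grp, cnt)
    }
  }
  df <- do.call(rbind, rows)
  fmt_rate <- function(x) formatC(x, format = "f", digits = 1)
  df$n_display <- ifelse(df$n_min == df$n_max, as.character(df$n_min),
                         paste0(df$n_min, "-", df$n_max))
  df$rate_display <- ifelse(df$n_min == df$n_max, fmt_rate(df$rate_min),
                            paste0(fmt_rate(df$rate_min), "-",
                                   fmt_rate(df$rate_max)))
  rownames(df) <- NULL
  df
}

#' Write pipeline outputs to a directory
#'
#' Emits \code{events.tsv} (event id, genes, recipient taxa, evidence,
#' ambiguity, age interval), \code{summary.tsv} and \code{log.txt}. Re-running
#' with the same config yields byte-identical files.
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- result$event_set$events
  flat <- data.frame(
    event_id = ev$event_id,
    genes = vapply(ev$genes, paste, "", collapse = ","),
    taxa = vapply(ev$taxa, paste, "", collapse = ","),
    evidence = ev$evidence, ambiguity = ev$ambiguity,
    age_lo = ev$age_lo, age_hi = ev$age_hi, stringsAsFactors = FALSE)
  p1 <- file.path(dir, "events.tsv")
  write.table(flat, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "summary.tsv")
  write.table(result$summary, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "log.txt")
  writeLines(result$log, p3)
  invisible(c(p1, p2, p3))
}
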