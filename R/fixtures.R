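## Bundled study fixtures: delimited-text transcriptions of the per-gene
## monophyletic clade lists, genomic linkage statements and duplication
## ambiguities for metabolic genes across the cultured Crenarchaeota and
## Euryarchaeota, plus an explicitly synthetic ~33-taxon dated reference tree
## standing in for the (undeposited) genome chronogram.

#' Path to a bundled archaeal fixture file
#' @param file file name under \code{extdata/archaea}, or \code{""} to list.
#' @return file path.
#' @export
archaea_fixture <- function(file = "") {
  system.file("extdata", "archaea", file, package = "lgtrates",
              mustWork = nzchar(file))
}

#' Load the archaeal study fixture bundle
#'
#' @return list with \code{ref_tree} (synthetic \code{dated_tree} with clade
#'   labels), \code{clades} (raw event table), \code{linkage},
#'   \code{dup_flags}, \code{categories}, \code{clade_labels},
#'   \code{constraints}, \code{cox_presence} (presence matrix for the
#'   cytochrome oxidase character on the synthetic tree).
#' @export
load_archaea_fixture <- function() {
  labels <- read_clade_labels(archaea_fixture("clade_labels.tsv"))
  ref <- read_ref_tree(archaea_fixture("ref_tree_synthetic.nwk"),
                       time_scaled = TRUE)
  ref$clade_labels <- modifyList(ref$clade_labels, labels)
  list(
    ref_tree = ref,
    clades = read_clade_table(archaea_fixture("clades.tsv")),
    linkage = read_linkage_table(archaea_fixture("linkage.tsv")),
    dup_flags = read_dup_flags(archaea_fixture("dup_flags.tsv")),
    categories = read_categories(archaea_fixture("categories.tsv")),
    clade_labels = labels,
    constraints = read_age_constraints(archaea_fixture("constraints.tsv")),
    cox_presence = read_presence_matrix(archaea_fixture("cox_presence.tsv")))
}

#' Run the event engine on the bundled fixtures
#'
#' Collapses the transcribed clade events over the transcribed linkage table
#' and applies the duplication flags; this is the computation behind the
#' domain-wide transfer-rate table.
#'
#' @return a \code{run_pipeline} result list.
#' @export
run_archaea_fixture <- function() {
  cfg <- pipeline_config(
    clade_table = archaea_fixture("clades.tsv"),
    linkage = archaea_fixture("linkage.tsv"),
    dup_flags = archaea_fixture("dup_flags.tsv"),
    categories = archaea_fixture("categories.tsv"))
  run_pipeline(cfg)
}

#' Count fixture events restricted to a labelled clade
#'
#' @param event_set a \code{transfer_event_set}.
#' @param taxa taxon set of the clade (events whose recipients all fall
#'   inside it are counted).
#' @param genes optional gene filter (any overlap of the gene group counts).
#' @return named vector \code{c(min=, max=)}.
#' @export
count_events_in <- function(event_set, taxa = NULL, genes = NULL) {
  ev <- event_set$events
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(taxa))
    keep <- keep & vapply(ev$taxa, function(t) all(t %in% taxa), TRUE)
  if (!is.null(genes))
    keep <- keep & vapply(ev$genes, function(g) any(g %in% genes), TRUE)
  event_counts(ev[keep, , drop = FALSE])
}
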