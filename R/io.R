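## Delimited-text readers. TSV is the default; comma-separated files are
## auto-detected from the header line.

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (length(first) && grepl("\t", first)) "\t"
         else if (length(first) && grepl(",", first)) ","
         else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "#",
             blank.lines.skip = TRUE)
}

#' Read a taxon-by-gene presence/absence matrix
#'
#' Expects a header row of gene names and a first column of taxon labels.
#' Every cell must be exactly 0 or 1 (absence/presence of the gene in the
#' genome); anything else is a validation error naming the offending cell.
#'
#' @param path delimited text file (TSV or CSV).
#' @return an integer matrix with taxa as rownames and genes as colnames,
#'   of class \code{presence_matrix}.
#' @export
read_presence_matrix <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 1L) stop("validation error: presence matrix has no columns")
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa)) stop("validation error: duplicate taxa in presence matrix")
  genes <- colnames(df)[-1]
  m <- matrix(0L, nrow = length(taxa), ncol = length(genes),
              dimnames = list(taxa, genes))
  for (j in seq_along(genes)) {
    v <- df[[j + 1]]
    vi <- suppressWarnings(as.integer(v))
    bad <- which(is.na(vi) | !(vi %in% c(0L, 1L)) | vi != as.numeric(v))
    if (length(bad))
      stop("validation error: non-binary cell at row ", taxa[bad[1]],
           ", column ", genes[j], " (value '", v[bad[1]], "')")
    m[, j] <- vi
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Read a genomic linkage (adjacency) table
#'
#' One record per adjacency: \code{taxon}, \code{copy_a}, \code{copy_b},
#' \code{gap_orfs} (number of intervening open reading frames, >= 0).
#' The symmetric closure is applied: (a,b) and (b,a) records are deduplicated.
#'
#' @param path delimited text file; an empty file yields an empty table.
#' @param known_copies optional character vector; records referring to copies
#'   outside it raise a validation error.
#' @return a data.frame of class \code{linkage_table}.
#' @export
read_linkage_table <- function(path, known_copies = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
  if (length(txt) <= 1L) {
    df <- data.frame(taxon = character(), copy_a = character(),
                     copy_b = character(), gap_orfs = integer())
    class(df) <- c("linkage_table", class(df))
    return(df)
  }
  df <- read_delim_auto(path)
  names(df)[1:4] <- c("taxon", "copy_a", "copy_b", "gap_orfs")
  linkage_table(df, known_copies = known_copies)
}

#' Build a validated linkage table from a data.frame
#' @param df data.frame with columns taxon, copy_a, copy_b, gap_orfs.
#' @param known_copies optional namespace of valid copy ids.
#' @return a \code{linkage_table}.
#' @export
linkage_table <- function(df, known_copies = NULL) {
  df$gap_orfs <- as.integer(df$gap_orfs)
  if (any(is.na(df$gap_orfs)) || any(df$gap_orfs < 0))
    stop("validation error: gap_orfs must be a nonnegative integer")
  if (!is.null(known_copies)) {
    unk <- setdiff(c(df$copy_a, df$copy_b), known_copies)
    if (length(unk))
      stop("validation error: unknown copy id(s) in linkage table: ",
           paste(unk, collapse = ", "))
  }
  cp <- canonical_pair(df$copy_a, df$copy_b)
  df$copy_a <- cp$a; df$copy_b <- cp$b
  df <- df[!duplicated(df[c("taxon", "copy_a", "copy_b")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("linkage_table", class(df)))
  df
}

#' Read a node-age constraint table
#'
#' Columns: \code{clade} (resolvable against the reference tree's clade labels,
#' or \code{"root"}), \code{min_age}, \code{max_age} in Ga (\code{NA} for an
#' unconstrained side). \code{min_age <= max_age} is required when both are set.
#'
#' @param path delimited text file.
#' @return data.frame with columns clade, min_age, max_age.
#' @export
read_age_constraints <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1:3] <- c("clade", "min_age", "max_age")
  df$min_age <- suppressWarnings(as.numeric(df$min_age))
  df$max_age <- suppressWarnings(as.numeric(df$max_age))
  bad <- !is.na(df$min_age) & !is.na(df$max_age) & df$min_age > df$max_age
  if (any(bad))
    stop("validation error: min_age > max_age for clade ",
         paste(df$clade[bad], collapse = ", "))
  df
}

#' Read clade label definitions
#'
#' Two columns: \code{clade}, \code{taxa} (comma-separated taxon labels).
#'
#' @param path delimited text file.
#' @return named list of character vectors.
#' @export
read_clade_labels <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1:2] <- c("clade", "taxa")
  setNames(lapply(strsplit(df$taxa, ","), trimws), df$clade)
}
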