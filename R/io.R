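#' Write a table as deterministic TSV
#'
#' UTF-8, LF line endings, numeric columns serialized with 9 significant
#' digits, so repeated runs with the same inputs produce byte-identical
#' files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) {
      formatC(col, digits = 9, format = "g")
    } else if (is.logical(col)) {
      ifelse(col, "TRUE", "FALSE")
    } else {
      ifelse(is.na(col), "NA", as.character(col))
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] or an external export
#'
#' @param path Input path.
#' @param required Character vector of column names that must be present.
#' @return Data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
    }
  }
  df
}

#' Read a gene-annotation table
#'
#' Tab-separated IMG/M-style export with one row per gene:
#' `genome_id`, `gene_id`, `cog_id`, `cog_category` (one or more COG
#' functional-category letters), `ko_id`, `symbol`. Empty fields read as
#' `NA`.
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, required = c("genome_id", "gene_id"))
  for (col in c("cog_id", "cog_category", "ko_id", "symbol")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  if (anyDuplicated(df[c("genome_id", "gene_id")])) {
    stop(path, ": gene_id values must be unique within a genome")
  }
  df
}

#' Write a gene-annotation table
#'
#' @param annotations Annotation data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("genome_id", "gene_id", "cog_id", "cog_category", "ko_id",
            "symbol")
  write_tsv(annotations[intersect(cols, names(annotations))], path)
}

#' Presence matrix as a flat table
#'
#' @param matrix A `presence_matrix`.
#' @return Data frame `genome_id`, `set_name`, `member`, `present`.
#' @export
presence_table <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  out <- expand.grid(genome_id = matrix$genomes,
                     idx = seq_len(nrow(matrix$markers)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$set_name <- matrix$markers$set_name[out$idx]
  out$member <- matrix$markers$member[out$idx]
  out$present <- matrix$presence[cbind(match(out$genome_id, matrix$genomes),
                                       out$idx)]
  out$idx <- NULL
  out[order(match(out$genome_id, matrix$genomes)), , drop = FALSE]
}
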