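#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character sequences. Line wrapping is irrelevant to the parse; an empty
#' file yields an empty list; duplicate ids raise a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named list of uppercase sequence strings (names are the ids up to
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    warning("duplicate FASTA ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  setNames(as.list(toupper(as.character(set))), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Tabular report carrier
#'
#' A plain data frame plus a caption, used for every table-shaped output of
#' the pipeline (genome summaries, gene partitions, tRNA matrices, DCJ
#' matrices).
#'
#' @param df A data frame.
#' @param caption One-line description of the table.
#' @return The data frame with class `report_table` and a `caption` attribute.
#' @export
report_table <- function(df, caption = "") {
  stopifnot(is.data.frame(df))
  structure(df, caption = caption, class = c("report_table", class(df)))
}

#' Write a report table as TSV
#'
#' Tab-separated, header row, newline-terminated, no quoting or row names;
#' the caption (when present) goes in a leading `#` comment line.
#'
#' @param table A data frame or [report_table()].
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cap <- attr(table, "caption")
  if (!is.null(cap) && nzchar(cap)) writeLines(paste0("# ", cap), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data frame (comment lines skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
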