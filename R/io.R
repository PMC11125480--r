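#' Read a gene-by-sample fragment count matrix
#'
#' TSV with gene identifiers in the first column and one column per sample.
#'
#' @param path TSV file.
#' @return Integer-valued matrix, genes in rows.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]]))
    stop("duplicate gene_id in count matrix: ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "double"
  m
}

#' Read sample group labels
#'
#' TSV with columns `sample_id` and `group` (`case` / `control`).
#'
#' @param path TSV file.
#' @return Named character vector of group labels.
#' @export
read_group_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stop("group-label file needs columns sample_id, group: ", path)
  bad <- setdiff(unique(d$group), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "))
  setNames(d$group, d$sample_id)
}

#' Read per-sample library sizes (total mapped fragments)
#'
#' TSV with columns `sample_id` and `library_size`.
#'
#' @param path TSV file.
#' @return Named numeric vector.
#' @export
read_library_sizes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "library_size") %in% names(d)))
    stop("library-size file needs columns sample_id, library_size: ", path)
  setNames(as.numeric(d$library_size), d$sample_id)
}

#' Construct a coding-potential tool call table
#'
#' A `ToolCallTable` records, for one external coding-potential predictor
#' (e.g. CPC2, LGC, CNCI or CPAT run outside this package), a
#' coding/noncoding label per transcript.
#'
#' @param tool_name Name of the predictor.
#' @param calls Named character vector, transcript_id -> "coding" or
#'   "noncoding".
#' @return A `ToolCallTable`.
#' @export
tool_call_table <- function(tool_name, calls) {
  stopifnot(is.character(tool_name), length(tool_name) == 1)
  bad <- setdiff(unique(calls), c("coding", "noncoding"))
  if (length(bad))
    stop("tool call labels must be coding/noncoding; found: ",
         paste(bad, collapse = ", "))
  if (is.null(names(calls)) || anyDuplicated(names(calls)))
    stop("calls must be uniquely named by transcript_id")
  structure(list(tool_name = tool_name, calls = calls),
            class = "ToolCallTable")
}

#' @export
print.ToolCallTable <- function(x, ...) {
  cat("ToolCallTable '", x$tool_name, "': ", length(x$calls),
      " transcripts (", sum(x$calls == "noncoding"), " noncoding)\n",
      sep = "")
  invisible(x)
}

#' Read a coding-potential call table
#'
#' TSV with columns `transcript_id` and `label`.
#'
#' @param path TSV file.
#' @param tool_name Predictor name; defaults to the file name.
#' @return A [tool_call_table()].
#' @export
read_tool_calls <- function(path, tool_name = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "label") %in% names(d)))
    stop("tool-call file needs columns transcript_id, label: ", path)
  if (is.null(tool_name))
    tool_name <- sub("\\.[^.]*$", "", basename(path))
  tool_call_table(tool_name, setNames(d$label, d$transcript_id))
}

#' Read a TF catalogue (one gene symbol per line)
#'
#' @param path Text file.
#' @return Character vector of TF gene symbols.
#' @export
read_tf_catalogue <- function(path) {
  x <- readLines(path)
  x <- trimws(x[nzchar(trimws(x))])
  unique(x)
}

#' Read annotated TF-target pairs
#'
#' TSV with columns `tf`, `target`, `source_db` — one row per
#' database-supported regulatory pair.
#'
#' @param path TSV file.
#' @return data.frame with columns tf, target, source_db.
#' @export
read_tf_targets <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target", "source_db") %in% names(d)))
    stop("TF-target file needs columns tf, target, source_db: ", path)
  d[, c("tf", "target", "source_db")]
}

#' Read term -> gene sets from a GMT file
#'
#' @param path GMT file (term, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a differential-expression table
#'
#' @param de data.frame as returned by [differential_expression()].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
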