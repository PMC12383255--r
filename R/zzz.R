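.datatable.aware <- TRUE

#' Read a gene set from a plain-text or GMT file
#'
#' Plain text: one gene symbol per line. GMT: tab-separated, set name,
#' description, then symbols; every line yields one named set.
#'
#' @param path file path.
#' @param format `"auto"` (GMT if the extension is .gmt), `"text"` or
#'   `"gmt"`.
#' @return For text, a character vector; for GMT, a named list of character
#'   vectors.
#' @export
read_gene_set <- function(path, format = c("auto", "text", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
      else "text"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "text") return(trimws(lines))
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`,
                        character(1), 1L)
  sets
}

#' Read a regulator weight matrix from TSV
#'
#' Rows are transcription factors, columns targets; the first column holds
#' factor ids. This is the import path for weight matrices produced by
#' external inference tools.
#'
#' @param path TSV file path.
#' @return Numeric matrix (factors x targets) with attribute
#'   `provenance = "external"`.
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("weights must be finite and non-negative")
  attr(m, "provenance") <- "external"
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
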