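#' Single-cell count matrix container
#'
#' Light S3 container for a sparse cells x genes matrix of raw UMI counts
#' together with its cell and gene identifiers. All pipeline stages consume
#' and return this representation; the on-disk orientation (10x files are
#' genes x cells) is normalised to cells x genes on read.
#'
#' @param counts sparse or dense non-negative integer matrix, cells x genes.
#' @param cell_ids character vector of unique cell barcodes, one per row.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @return An object of class `sc_counts`: a list with elements `counts`
#'   (a `dgCMatrix`, cells x genes, dimnames set), `cell_ids` and `gene_ids`.
#' @export
sc_counts <- function(counts, cell_ids = rownames(counts),
                      gene_ids = colnames(counts)) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required when the matrix has no dimnames")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids),
         " cell_ids")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids),
         " gene_ids")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    if (any(x != round(x))) stop("counts must be integer-valued")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "sc_counts")
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' @export
print.sc_counts <- function(x, ...) {
  cat("sc_counts: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes, ", length(x$counts@x), " non-zero entries\n", sep = "")
  invisible(x)
}

#' Subset an sc_counts object by cells and/or genes
#'
#' @param x an `sc_counts` object.
#' @param i,j cell and gene indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always an `sc_counts`.
#' @export
`[.sc_counts` <- function(x, i, j, ..., drop = FALSE) {
  m <- x$counts
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  sc_counts(m)
}

#' Read a 10x-style count matrix triplet
#'
#' Reads a Matrix Market coordinate file together with its barcode and
#' feature annotation files and returns a cells x genes [sc_counts] object.
#' Orientation on disk may be either genes x cells (the 10x convention) or
#' cells x genes; it is disambiguated by matching the matrix dimensions
#' against the lengths of the two annotation files. If both orientations are
#' consistent (a square matrix with equally long annotation files) the read
#' is refused as ambiguous.
#'
#' @param matrix_path path to the Matrix Market (.mtx) coordinate file.
#' @param barcodes_path path to the barcodes file (one cell id per line;
#'   only the first tab-separated field is used).
#' @param features_path path to the features file (one gene symbol per line;
#'   only the first tab-separated field is used).
#' @return An [sc_counts] object, cells x genes.
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path) {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"),
                               "CsparseMatrix"), "generalMatrix")
  if (length(m@x) && any(m@x != round(m@x)))
    stop("non-integer entries in ", matrix_path)
  if (length(m@x) && any(m@x < 0))
    stop("negative entries in ", matrix_path)
  read_first_field <- function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  }
  barcodes <- read_first_field(barcodes_path)
  features <- read_first_field(features_path)
  gxc <- nrow(m) == length(features) && ncol(m) == length(barcodes)
  cxg <- nrow(m) == length(barcodes) && ncol(m) == length(features)
  if (gxc && cxg && length(barcodes) != length(features)) gxc <- FALSE
  if (gxc && cxg)
    stop("ambiguous orientation: matrix is square and annotation files are ",
         "equally long")
  if (!gxc && !cxg) {
    bad <- if (nrow(m) %in% c(length(features), length(barcodes)) ||
               ncol(m) == length(features)) barcodes_path else features_path
    if (!(length(barcodes) %in% dim(m))) bad <- barcodes_path
    else if (!(length(features) %in% dim(m))) bad <- features_path
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " do not match annotation file ", bad,
         " (", length(barcodes), " barcodes, ", length(features),
         " features)")
  }
  if (gxc) m <- Matrix::t(m)
  sc_counts(m, cell_ids = barcodes, gene_ids = features)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` into `out_dir`,
#' using the 10x genes x cells on-disk orientation. The round trip through
#' [read_counts()] is lossless.
#'
#' @param matrix an [sc_counts] object.
#' @param out_dir output directory, created if absent.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_counts <- function(matrix, out_dir) {
  stopifnot(inherits(matrix, "sc_counts"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             features = file.path(out_dir, "features.tsv"))
  Matrix::writeMM(Matrix::t(matrix$counts), paths[["matrix"]])
  writeLines(matrix$cell_ids, paths[["barcodes"]])
  writeLines(matrix$gene_ids, paths[["features"]])
  invisible(paths)
}
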