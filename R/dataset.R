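#' Construct a single-cell dataset container
#'
#' A light container for one modality's cell-by-feature matrix together with
#' cell identifiers, feature (gene) identifiers, a dataset id used to select
#' decoder branches, and optional per-cell type annotations.
#'
#' @param matrix Numeric cell-by-gene matrix (base `matrix` or a
#'   `Matrix::sparseMatrix`). Rows are cells, columns genes. All entries must
#'   be finite and non-negative.
#' @param dataset_id Single string naming the dataset (e.g. `"rna"`,
#'   `"atac"`). Used to register decoder branches in the model.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   the matrix rownames (generated if absent).
#' @param gene_ids Character vector of gene identifiers; defaults to the
#'   matrix colnames (generated if absent).
#' @param cell_types Optional character vector of per-cell type labels.
#'
#' @return An object of class `sc_dataset`: a list with elements `matrix`,
#'   `cell_ids`, `gene_ids`, `dataset_id` and `cell_types`.
#' @export
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5)
#' ds <- sc_dataset(m, "rna")
#' ds
sc_dataset <- function(matrix, dataset_id,
                       cell_ids = rownames(matrix),
                       gene_ids = colnames(matrix),
                       cell_types = NULL) {
  if (!(is.matrix(matrix) || methods::is(matrix, "sparseMatrix")))
    stop("`matrix` must be a base matrix or a sparse Matrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(matrix)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(matrix)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(matrix))
    stop("length(cell_ids) must equal nrow(matrix)")
  if (length(gene_ids) != ncol(matrix))
    stop("length(gene_ids) must equal ncol(matrix)")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids within a dataset are not allowed")
  if (!is.character(dataset_id) || length(dataset_id) != 1L || is.na(dataset_id))
    stop("`dataset_id` must be a single string")
  vals <- if (methods::is(matrix, "sparseMatrix")) matrix@x else matrix
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    stop("matrix entries must be finite and >= 0")
  if (!is.null(cell_types)) {
    cell_types <- as.character(cell_types)
    if (length(cell_types) != nrow(matrix))
      stop("length(cell_types) must equal nrow(matrix)")
  }
  rownames(matrix) <- cell_ids
  colnames(matrix) <- gene_ids
  structure(
    list(matrix = matrix, cell_ids = cell_ids, gene_ids = gene_ids,
         dataset_id = dataset_id, cell_types = cell_types),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset '%s'> %d cells x %d genes%s\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$cell_types)) "" else
                sprintf(", %d cell types", length(unique(x$cell_types)))))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$matrix)

# internal: subset cells/genes keeping metadata aligned
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  m <- ds$matrix
  ct <- ds$cell_types
  if (!is.null(cells)) {
    m <- m[cells, , drop = FALSE]
    if (!is.null(ct)) ct <- ct[cells]
  }
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  sc_dataset(m, ds$dataset_id, rownames(m), colnames(m), ct)
}

# internal: dense numeric copy of the data matrix
dense_matrix <- function(ds) as.matrix(ds$matrix)

#' Read a cell-by-gene matrix from disk
#'
#' Supports MatrixMarket triplets (`matrix.mtx` with `barcodes.tsv` /
#' `features.tsv` sidecars, genes in rows as written by common pipelines) and
#' dense CSV/TSV tables (cells in rows, header row of gene ids, first column
#' of cell ids).
#'
#' @param path Path to a `.mtx`, `.csv` or `.tsv`/`.txt` file.
#' @param dataset_id Dataset id to attach (see [sc_dataset()]).
#' @param cell_types Optional cell-type labels, or a path to a one-column
#'   text file with one label per cell.
#' @return An [sc_dataset()].
#' @export
read_cell_matrix <- function(path, dataset_id, cell_types = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    bc <- file.path(dir, "barcodes.tsv")
    ft <- file.path(dir, "features.tsv")
    if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
    genes <- if (file.exists(ft)) utils::read.table(ft, sep = "\t",
                                                    stringsAsFactors = FALSE)[, 1]
             else paste0("gene", seq_len(nrow(m)))
    cells <- if (file.exists(bc)) utils::read.table(bc, sep = "\t",
                                                    stringsAsFactors = FALSE)[, 1]
             else paste0("cell", seq_len(ncol(m)))
    m <- Matrix::t(m)  # stored genes x cells; we use cells x genes
    m <- methods::as(m, "CsparseMatrix")
    rownames(m) <- cells
    colnames(m) <- genes
  } else if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
  } else {
    stop("unsupported input format '", ext, "' (use mtx, csv or tsv)")
  }
  if (is.character(cell_types) && length(cell_types) == 1L &&
      file.exists(cell_types)) {
    cell_types <- utils::read.table(cell_types, stringsAsFactors = FALSE)[, 1]
  }
  sc_dataset(m, dataset_id, cell_types = cell_types)
}

#' Write a cell-by-gene matrix to disk
#'
#' Mirrors the reader formats: `"mtx"` writes `<prefix>.mtx` (genes x cells)
#' plus `barcodes.tsv` / `features.tsv` sidecars; `"csv"`/`"tsv"` write a
#' dense table with cells in rows.
#'
#' @param ds An [sc_dataset()].
#' @param path Output file path (for `"mtx"`, sidecars are written next to it).
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`; default inferred from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
write_cell_matrix <- function(ds, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(Matrix::t(ds$matrix),
                                               sparse = TRUE), "generalMatrix"),
                    path)
    dir <- dirname(path)
    utils::write.table(ds$cell_ids, file.path(dir, "barcodes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(ds$gene_ids, file.path(dir, "features.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else if (format %in% c("csv", "tsv", "txt")) {
    sep <- if (format == "csv") "," else "\t"
    m <- dense_matrix(ds)
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported output format '", format, "'")
  }
  invisible(path)
}
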