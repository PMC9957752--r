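#' Read a genes-by-libraries expression table with its annotation
#'
#' The expression table is TSV with gene ids in the first column and one
#' numeric column per library; the annotation table is TSV with columns
#' `gene_id`, `length_kb` and `biotype` (and optionally `isoform_group`).
#' Every gene must be annotated; duplicate gene ids and non-numeric cells are
#' format errors.
#'
#' @param path expression TSV path.
#' @param annotation_path annotation TSV path.
#' @return named list of `ExpressionLibrary`, one per column.
#' @export
read_expression_table <- function(path, annotation_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs gene ids plus >= 1 library")
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !is.na(tab[[j]]))
    if (length(bad) || anyNA(tab[[j]]))
      stop("non-numeric or missing value in column '", names(tab)[j],
           "', row ", c(bad, which(is.na(tab[[j]])))[1L])
    tab[[j]] <- v
  }
  ann <- read_gene_annotation(annotation_path)
  missing <- setdiff(gene_ids, ann$gene_id)
  if (length(missing))
    stop("unannotated gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ann <- ann[match(gene_ids, ann$gene_id), , drop = FALSE]
  libs <- lapply(names(tab)[-1L], function(lib_id)
    expression_library(lib_id, gene_ids, tab[[lib_id]], ann$length_kb,
                       ann$biotype,
                       if ("isoform_group" %in% names(ann))
                         ann$isoform_group else NULL))
  names(libs) <- names(tab)[-1L]
  libs
}

#' Write libraries as one genes-by-libraries TSV
#'
#' All libraries must share one gene universe (same order).
#'
#' @param libs list of `ExpressionLibrary`.
#' @param path output TSV path.
#' @export
write_expression_table <- function(libs, path) {
  ids <- libs[[1L]]$gene_ids
  for (lib in libs)
    if (!identical(lib$gene_ids, ids))
      stop("libraries do not share one gene universe")
  mat <- vapply(libs, function(l) l$raw_counts, numeric(length(ids)))
  df <- data.frame(gene_id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", vapply(libs, `[[`, character(1L), "library_id"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the gene annotation TSV (gene_id, length_kb, biotype)
#'
#' @param path annotation TSV path.
#' @return data.frame with `gene_id`, `length_kb`, `biotype` (and any extra
#'   columns, e.g. `isoform_group`).
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_kb", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  ann$length_kb <- as.numeric(ann$length_kb)
  ann
}

#' @rdname read_gene_annotation
#' @param lib an `ExpressionLibrary` whose annotation is written.
#' @export
write_gene_annotation <- function(lib, path) {
  df <- data.frame(gene_id = lib$gene_ids, length_kb = lib$length_kb,
                   biotype = lib$biotype, stringsAsFactors = FALSE)
  if (!is.null(lib$isoform_group)) df$isoform_group <- lib$isoform_group
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write marker-set files (one gene id per line, file per cell type)
#'
#' @param dir directory of marker files; each file's basename (without
#'   extension) is the cell-type label.
#' @return named list of character vectors of gene ids.
#' @export
read_marker_sets <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0) stop("no marker files in ", dir)
  sets <- lapply(files, function(f) readLines(f, warn = FALSE))
  names(sets) <- sub("\\.[^.]*$", "", basename(files))
  lapply(sets, function(g) g[nzchar(g)])
}

#' @rdname read_marker_sets
#' @param sets named list of gene-id vectors (or `MarkerSet`s).
#' @export
write_marker_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in names(sets)) {
    genes <- if (inherits(sets[[ct]], "MarkerSet")) sets[[ct]]$genes
             else sets[[ct]]
    writeLines(genes, file.path(dir, paste0(ct, ".txt")))
  }
  invisible(dir)
}

#' Read a sparse MatrixMarket expression matrix with name sidecars
#'
#' Coordinate-format MTX (1-based indices) plus one gene id per line and one
#' sample id per line in the sidecar files.  Dimension mismatches between the
#' MTX header and the name files are format errors.
#'
#' @param mtx_path MTX file path.
#' @param rownames_path,colnames_path sidecar files with one name per line.
#' @return dense numeric matrix with gene rownames and sample colnames.
#' @export
read_sparse_matrix <- function(mtx_path, rownames_path, colnames_path) {
  m <- Matrix::readMM(mtx_path)
  rn <- readLines(rownames_path, warn = FALSE)
  cn <- readLines(colnames_path, warn = FALSE)
  if (nrow(m) != length(rn))
    stop("MTX has ", nrow(m), " rows but ", length(rn), " row names")
  if (ncol(m) != length(cn))
    stop("MTX has ", ncol(m), " columns but ", length(cn), " column names")
  m <- as.matrix(m)
  dimnames(m) <- list(rn, cn)
  m
}

#' @rdname read_sparse_matrix
#' @param mat numeric matrix with dimnames to write.
#' @export
write_sparse_matrix <- function(mat, mtx_path, rownames_path, colnames_path) {
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), mtx_path)
  writeLines(rownames(mat), rownames_path)
  writeLines(colnames(mat), colnames_path)
  invisible(mtx_path)
}

#' Read / write a cohort sample sheet (sample_id, stage, group)
#'
#' @param path sample-sheet TSV path.
#' @return data.frame with at least `sample_id` and `stage`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample sheet lacks sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' @rdname read_sample_sheet
#' @param samples data.frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
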