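#' Construct an expression library
#'
#' An `ExpressionLibrary` holds one RNA-seq library's raw read counts together
#' with the per-gene annotation needed for downstream normalization: transcript
#' length in kilobases and a biotype class.  Before isoform collapsing the rows
#' are transcripts and `isoform_group` records which gene each transcript
#' belongs to; after collapsing there is one row per gene.
#'
#' @param library_id single character label for the library.
#' @param gene_ids character vector of unique gene (or transcript) identifiers.
#' @param raw_counts numeric vector of nonnegative read counts, one per gene.
#' @param length_kb numeric vector of positive transcript lengths in kb.
#' @param biotype character vector of biotype labels (e.g. `"protein_coding"`,
#'   `"rRNA"`, `"Mt_rRNA"`, `"miRNA"`).
#' @param isoform_group optional character vector grouping transcripts into
#'   genes; `NULL` once each row is already one gene.
#' @return an object of class `ExpressionLibrary`.
#' @seealso [to_molecule_counts()], [filter_extraneous()], [collapse_isoforms()]
#' @export
expression_library <- function(library_id, gene_ids, raw_counts, length_kb,
                               biotype = NULL, isoform_group = NULL) {
  stopifnot(is.character(library_id), length(library_id) == 1L)
  gene_ids <- as.character(gene_ids)
  n <- length(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(raw_counts) != n || length(length_kb) != n)
    stop("raw_counts and length_kb must have one entry per gene")
  if (any(!is.finite(raw_counts)) || any(raw_counts < 0))
    stop("raw_counts must be finite and nonnegative")
  bad_len <- which(!is.finite(length_kb) | length_kb <= 0)
  if (length(bad_len))
    stop("nonpositive transcript length for gene(s): ",
         paste(gene_ids[utils::head(bad_len, 5L)], collapse = ", "))
  if (is.null(biotype)) biotype <- rep("protein_coding", n)
  if (length(biotype) != n) stop("biotype must have one entry per gene")
  if (!is.null(isoform_group)) {
    isoform_group <- as.character(isoform_group)
    if (length(isoform_group) != n)
      stop("isoform_group must have one entry per transcript")
  }
  structure(
    list(library_id = library_id,
         gene_ids = gene_ids,
         raw_counts = stats::setNames(as.numeric(raw_counts), gene_ids),
         length_kb = stats::setNames(as.numeric(length_kb), gene_ids),
         biotype = stats::setNames(as.character(biotype), gene_ids),
         isoform_group = if (is.null(isoform_group)) NULL else
           stats::setNames(isoform_group, gene_ids)),
    class = "ExpressionLibrary")
}

#' @export
print.ExpressionLibrary <- function(x, ...) {
  cat(sprintf("ExpressionLibrary '%s': %d genes, %.0f reads\n",
              x$library_id, length(x$gene_ids), sum(x$raw_counts)))
  invisible(x)
}

# internal constructor for a normalized profile; users obtain one through
# to_molecule_counts() / renormalize()
new_normalized_profile <- function(library_id, molecule_counts,
                                   normalization_mode = "none") {
  total <- sum(molecule_counts)
  if (total <= 0) stop("library '", library_id, "' has no expression")
  structure(
    list(library_id = library_id,
         gene_ids = names(molecule_counts),
         molecule_counts = molecule_counts,
         total_molecules = total,
         fractions = molecule_counts / total,
         normalization_mode = normalization_mode),
    class = "NormalizedProfile")
}

#' @export
print.NormalizedProfile <- function(x, ...) {
  cat(sprintf("NormalizedProfile '%s': %d genes, mode=%s, total=%.4g\n",
              x$library_id, length(x$gene_ids), x$normalization_mode,
              x$total_molecules))
  invisible(x)
}

#' Construct a cohort expression matrix
#'
#' A `CohortMatrix` couples a genes-by-samples expression matrix with a sample
#' sheet carrying an ordinal stage label and/or a two-level group label, plus
#' an optional ground-truth record when the matrix was simulated.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param samples data.frame with at least `sample_id`; columns `stage`
#'   (ordinal label) and `group` are used by downstream stages.
#' @param truth optional list recording the generating ground truth.
#' @return an object of class `CohortMatrix`.
#' @export
cohort_matrix <- function(expr, samples, truth = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression matrix")
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples))
    stop("samples must be a data.frame with a sample_id column")
  if (!identical(as.character(samples$sample_id), colnames(expr)))
    stop("samples$sample_id must match the matrix columns in order")
  if (any(!is.finite(expr)))
    stop("expression matrix contains non-finite values")
  structure(list(expr = expr, samples = samples, truth = truth),
            class = "CohortMatrix")
}

#' @export
print.CohortMatrix <- function(x, ...) {
  cat(sprintf("CohortMatrix: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  if ("stage" %in% names(x$samples))
    cat("  stages:", paste(unique(as.character(x$samples$stage)),
                           collapse = ", "), "\n")
  invisible(x)
}

# check that a list of profiles (and optionally a tissue profile) share one
# gene universe, in identical order
check_shared_universe <- function(profiles, tissue = NULL) {
  ids <- lapply(profiles, function(p) p$gene_ids)
  if (!is.null(tissue)) ids <- c(ids, list(tissue$gene_ids))
  ref <- ids[[1L]]
  ok <- vapply(ids, function(g) identical(g, ref), logical(1L))
  if (!all(ok))
    stop("profiles do not share one gene universe (same genes, same order)")
  invisible(ref)
}
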