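#' Remove extraneous transcripts by biotype
#'
#' Drops genes whose biotype is in the exclusion set (ribosomal RNA,
#' mitochondrial RNA and small RNA classes by default); counts of retained
#' genes are unchanged.  An excluded biotype that does not occur in the
#' library triggers a warning, not an error.
#'
#' @param lib an `ExpressionLibrary`.
#' @param excluded_biotypes character vector of biotype labels to remove.
#' @return the filtered `ExpressionLibrary`.
#' @export
filter_extraneous <- function(lib,
                              excluded_biotypes = c("rRNA", "Mt_rRNA",
                                                    "Mt_tRNA", "miRNA",
                                                    "snoRNA", "snRNA")) {
  stopifnot(inherits(lib, "ExpressionLibrary"))
  if (length(excluded_biotypes) == 0) return(lib)
  unknown <- setdiff(excluded_biotypes, unique(lib$biotype))
  if (length(unknown))
    warning("excluded biotype(s) not present in library: ",
            paste(unknown, collapse = ", "))
  keep <- !(lib$biotype %in% excluded_biotypes)
  subset_library(lib, keep)
}

# row subset preserving all parallel fields
subset_library <- function(lib, keep) {
  expression_library(lib$library_id,
                     lib$gene_ids[keep],
                     lib$raw_counts[keep],
                     lib$length_kb[keep],
                     lib$biotype[keep],
                     if (is.null(lib$isoform_group)) NULL else
                       lib$isoform_group[keep])
}

#' Collapse multi-transcript genes to their most abundant isoform
#'
#' Within each isoform group the transcript with the largest raw count in this
#' library is retained and relabelled with the group (gene) id.  Ties are
#' broken by the lexicographically smallest transcript id so the choice is
#' deterministic.  A library without `isoform_group` is returned unchanged.
#'
#' @param lib an `ExpressionLibrary` with `isoform_group` populated.
#' @return an `ExpressionLibrary` with one row per gene, sorted by gene id.
#' @export
collapse_isoforms <- function(lib) {
  stopifnot(inherits(lib, "ExpressionLibrary"))
  if (is.null(lib$isoform_group)) return(lib)
  ord <- order(lib$isoform_group, -lib$raw_counts, lib$gene_ids)
  keep <- ord[!duplicated(lib$isoform_group[ord])]
  keep <- keep[order(lib$isoform_group[keep])]
  expression_library(lib$library_id,
                     gene_ids = lib$isoform_group[keep],
                     raw_counts = lib$raw_counts[keep],
                     length_kb = lib$length_kb[keep],
                     biotype = lib$biotype[keep],
                     isoform_group = NULL)
}

#' Convert read counts to molecule counts (reads/kb)
#'
#' Divides each gene's raw read count by its transcript length in kilobases,
#' yielding a length-normalized abundance, and derives each gene's
#' transcriptome fraction (its share of the library's total molecules).
#'
#' @param lib an `ExpressionLibrary` (one row per gene).
#' @return a `NormalizedProfile` with `molecule_counts`, `total_molecules` and
#'   `fractions`.
#' @export
to_molecule_counts <- function(lib) {
  stopifnot(inherits(lib, "ExpressionLibrary"))
  bad <- which(lib$length_kb <= 0)
  if (length(bad))
    stop("nonpositive transcript length for gene(s): ",
         paste(lib$gene_ids[utils::head(bad, 5L)], collapse = ", "))
  new_normalized_profile(lib$library_id, lib$raw_counts / lib$length_kb)
}

#' Linearly renormalize a profile
#'
#' `mode = "total"` divides by the library total so values become
#' transcriptome fractions (idempotent); `mode = "median"` divides by the
#' median over genes with nonzero expression, the scaling used for
#' cross-cell-type expression displays.  Both rescalings are linear, so
#' per-gene transcriptome fractions — and therefore the downstream
#' marker-ratio estimator — are unchanged.
#'
#' @param profile a `NormalizedProfile`.
#' @param mode `"total"` or `"median"`.
#' @return the rescaled `NormalizedProfile`.
#' @export
renormalize <- function(profile, mode = c("total", "median")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "NormalizedProfile"))
  values <- profile$molecule_counts
  if (all(values == 0)) stop("all-zero library cannot be normalized")
  scaled <- switch(mode,
    total = values / sum(values),
    median = {
      med <- stats::median(values[values > 0])
      values / med
    })
  new_normalized_profile(profile$library_id, scaled, normalization_mode = mode)
}
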