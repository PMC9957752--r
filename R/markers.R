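#' Derive cell-type-exclusive marker sets from reference profiles
#'
#' A gene is a marker of cell type `c` when its transcriptome fraction there
#' is at least `min_own_fraction` (and strictly positive) and its fraction in
#' every other type is at most `max_other_relative` times the own-type
#' fraction.  With `max_other_relative < 1` the resulting sets are disjoint
#' across types.  Specificity is the ratio of own-type fraction to the largest
#' other-type fraction (`Inf` for a perfectly exclusive gene).
#'
#' @param profiles named list of `NormalizedProfile`, one per cell type, on a
#'   shared gene universe.
#' @param min_own_fraction minimum transcriptome fraction in the marker's own
#'   type; the default 1e-5 corresponds to a solidly detected transcript in a
#'   deep library.
#' @param max_other_relative maximum fraction in any other type, relative to
#'   the own-type fraction.
#' @param min_markers minimum surviving markers per type; fewer is an error
#'   naming the deficient type, because the averaged ratio estimator needs
#'   several markers for stability.
#' @return named list of `MarkerSet` objects (fields `cell_type`, `genes`,
#'   `specificity`).
#' @export
find_cell_specific_genes <- function(profiles, min_own_fraction = 1e-5,
                                     max_other_relative = 0.05,
                                     min_markers = 5) {
  if (length(profiles) < 2) stop("need profiles for >= 2 cell types")
  if (is.null(names(profiles))) stop("profiles must be named by cell type")
  genes <- check_shared_universe(profiles)
  frac <- vapply(profiles, function(p) p$fractions, numeric(length(genes)))
  rownames(frac) <- genes

  sets <- lapply(names(profiles), function(ct) {
    own <- frac[, ct]
    other <- frac[, setdiff(colnames(frac), ct), drop = FALSE]
    other_max <- apply(other, 1L, max)
    pass <- own > 0 & own >= min_own_fraction &
      other_max <= max_other_relative * own
    structure(list(cell_type = ct,
                   genes = genes[pass],
                   specificity = ifelse(other_max[pass] > 0,
                                        own[pass] / other_max[pass], Inf)),
              class = "MarkerSet")
  })
  names(sets) <- names(profiles)
  deficit <- names(sets)[vapply(sets, function(s) length(s$genes),
                                integer(1L)) < min_markers]
  if (length(deficit))
    stop("fewer than ", min_markers, " markers for cell type(s): ",
         paste(deficit, collapse = ", "))
  sets
}

#' @export
print.MarkerSet <- function(x, ...) {
  cat(sprintf("MarkerSet '%s': %d genes (min specificity %.3g)\n",
              x$cell_type, length(x$genes),
              if (length(x$specificity)) min(x$specificity) else NA))
  invisible(x)
}

#' Rank candidate surrogate libraries by correlation with whole tissue
#'
#' For cell types lacking a tissue-derived reference, candidate libraries
#' from other sources are ranked by the Pearson correlation of their
#' expression with a whole-tissue profile; the top-ranked candidate is the
#' surrogate.  By default the correlation is computed on
#' `log2(1 + 1e6 * fraction)` values so a handful of very abundant genes does
#' not dominate; `log_transform = FALSE` gives plain linear-scale Pearson.
#'
#' @param candidates named list of `NormalizedProfile` candidates.
#' @param whole_tissue a `NormalizedProfile` on the same gene universe.
#' @param log_transform correlate log-transformed fractions (default) or raw
#'   fractions.
#' @return data.frame (`candidate`, `r`, `n_genes`) sorted by decreasing `r`;
#'   a zero-variance candidate gets `r = NA` and is ranked last with a
#'   warning.
#' @export
select_surrogate_library <- function(candidates, whole_tissue,
                                     log_transform = TRUE) {
  if (length(candidates) == 0) stop("need at least one candidate")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  check_shared_universe(candidates, whole_tissue)
  xf <- function(v) if (log_transform) log2(1 + 1e6 * v) else v
  y <- xf(whole_tissue$fractions)
  r <- vapply(candidates, function(p) {
    x <- xf(p$fractions)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1L))
  if (anyNA(r))
    warning("zero-variance candidate(s) ranked last: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  out <- data.frame(candidate = names(candidates), r = unname(r),
                    n_genes = length(whole_tissue$gene_ids),
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$candidate, na.last = TRUE), , drop = FALSE]
}
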