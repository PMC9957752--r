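#' Marker-ratio of tissue to cell-type transcriptome fraction
#'
#' For a gene expressed exclusively in one cell type, the ratio of its
#' transcriptome fraction in whole tissue (t_L/T_L) to its fraction in the
#' pure cell-type library (t_C/T_C) equals that cell type's transcriptome
#' fraction within the tissue.  Because both quantities are fractions of
#' their own library totals, the ratio is invariant to any linear rescaling
#' of either library (the totals cancel).
#'
#' A marker with zero expression in the *tissue* returns ratio 0 — the cell
#' type may simply be absent — but zero (or missing) expression in the cell
#' profile invalidates the marker, since a marker must be expressed in its own
#' type.
#'
#' @param gene gene id present in both profiles.
#' @param tissue whole-tissue `NormalizedProfile`.
#' @param cell cell-type `NormalizedProfile`.
#' @return the scalar ratio (t_L/T_L) / (t_C/T_C).
#' @export
marker_ratio <- function(gene, tissue, cell) {
  stopifnot(inherits(tissue, "NormalizedProfile"),
            inherits(cell, "NormalizedProfile"))
  if (!gene %in% tissue$gene_ids)
    stop("gene '", gene, "' absent from tissue profile")
  if (!gene %in% cell$gene_ids || cell$fractions[[gene]] <= 0)
    stop("invalid marker '", gene,
         "': zero or missing expression in cell profile '",
         cell$library_id, "'")
  unname(tissue$fractions[[gene]] / cell$fractions[[gene]])
}

#' Estimate a cell type's transcriptome fraction from its markers
#'
#' Computes the marker ratio for every gene in the marker set and averages
#' them (mean by default; median available for robustness).  Markers invalid
#' in the cell profile are skipped and listed.  The average is clipped to
#' [0, 1] with a warning; the raw per-marker ratios are always preserved.
#'
#' @param markers a `MarkerSet`.
#' @param tissue whole-tissue `NormalizedProfile`.
#' @param cell the marker set's cell-type `NormalizedProfile`.
#' @param average `"mean"` or `"median"`.
#' @return a `CellFractionEstimate`: list with `cell_type`, `fraction`,
#'   `per_marker_ratios` (data.frame gene/ratio), `n_markers`, `dispersion`
#'   (sd of ratios), `skipped` and `clipped`.
#' @export
estimate_cell_fraction <- function(markers, tissue, cell,
                                   average = c("mean", "median")) {
  average <- match.arg(average)
  stopifnot(inherits(markers, "MarkerSet"))
  ratios <- numeric(0)
  skipped <- character(0)
  for (g in markers$genes) {
    r <- tryCatch(marker_ratio(g, tissue, cell), error = function(e) NA_real_)
    if (is.na(r)) skipped <- c(skipped, g) else ratios[g] <- r
  }
  if (length(ratios) == 0)
    stop("no valid marker for cell type '", markers$cell_type, "'")
  raw <- switch(average, mean = mean(ratios), median = stats::median(ratios))
  clipped <- raw < 0 || raw > 1
  if (clipped)
    warning("estimated fraction ", format(raw), " for '", markers$cell_type,
            "' clipped to [0,1]")
  structure(
    list(cell_type = markers$cell_type,
         fraction = min(max(raw, 0), 1),
         per_marker_ratios = data.frame(gene = names(ratios),
                                        ratio = unname(ratios),
                                        stringsAsFactors = FALSE),
         n_markers = length(ratios),
         dispersion = stats::sd(ratios),
         average = average,
         skipped = skipped,
         clipped = clipped),
    class = "CellFractionEstimate")
}

#' @export
print.CellFractionEstimate <- function(x, ...) {
  cat(sprintf("CellFractionEstimate '%s': %.4g (%s of %d markers, sd %.3g)\n",
              x$cell_type, x$fraction, x$average, x$n_markers, x$dispersion))
  invisible(x)
}

#' Sum nonparenchymal fractions and obtain the hepatocyte fraction
#'
#' The per-type transcriptome fractions of all nonparenchymal cell (NPC)
#' types are summed, and the hepatocyte (parenchymal) fraction is the
#' remainder of the whole-tissue transcriptome: 1 minus the NPC sum.  The
#' subtraction route exists because isolated-hepatocyte libraries are
#' unreliable references (isolation strongly induces reactive genes), so
#' hepatocytes are deliberately not estimated from their own markers.
#'
#' @param estimates list of `CellFractionEstimate` for the non-hepatocyte
#'   types (may be empty); duplicate cell types are an error.
#' @param tolerance NPC sums above `1 + tolerance` trigger an inconsistency
#'   warning.
#' @return list with `npc_fraction`, `hepatocyte_fraction` (clipped to [0,1]
#'   with a warning when needed) and `clipped`.
#' @export
estimate_npc_and_hepatocyte <- function(estimates, tolerance = 0.05) {
  types <- vapply(estimates, function(e) e$cell_type, character(1L))
  if (anyDuplicated(types))
    stop("duplicate cell types in estimates: ",
         paste(unique(types[duplicated(types)]), collapse = ", "))
  npc <- sum(vapply(estimates, function(e) e$fraction, numeric(1L)))
  hep <- 1 - npc
  clipped <- FALSE
  if (npc > 1 + tolerance)
    warning("NPC fraction ", format(npc),
            " exceeds 1; hepatocyte fraction clipped to 0")
  if (hep < 0 || hep > 1) {
    if (hep < 0 && npc <= 1 + tolerance)
      warning("hepatocyte fraction ", format(hep), " clipped to [0,1]")
    hep <- min(max(hep, 0), 1)
    clipped <- TRUE
  }
  list(npc_fraction = npc, hepatocyte_fraction = hep, clipped = clipped)
}

#' Apportion one gene's tissue expression across cell types
#'
#' Splits the total tissue expression of a (possibly multi-cell-type) gene
#' into per-type contributions: type `c` contributes
#' `f_c * fraction_c(gene) / fraction_tissue(gene)`, where `f_c` is the
#' type's estimated transcriptome fraction.  Whatever is not attributed to a
#' profiled type is the residual; with
#' `residual_policy = "assign_hepatocyte"` the residual is credited to
#' hepatocytes, the profiled-reference-free type, instead of being reported.
#' Contributions plus residual always sum to 1.
#'
#' @param gene gene id with nonzero tissue fraction.
#' @param estimates list of `CellFractionEstimate` (the `f_c`).
#' @param cell_profiles named list of `NormalizedProfile` covering every
#'   estimated type.
#' @param tissue whole-tissue `NormalizedProfile`.
#' @param residual_policy `"report"` or `"assign_hepatocyte"`.
#' @return an `ApportionmentRow`: list with `gene`, `per_type_contribution`
#'   (named numeric), `residual` and `inconsistent` (TRUE when contributions
#'   exceed 1 by more than 0.05).
#' @export
apportion_gene <- function(gene, estimates, cell_profiles, tissue,
                           residual_policy = c("report",
                                               "assign_hepatocyte")) {
  residual_policy <- match.arg(residual_policy)
  if (!gene %in% tissue$gene_ids || tissue$fractions[[gene]] <= 0)
    stop("gene '", gene, "' absent from or unexpressed in the tissue profile")
  frac_l <- tissue$fractions[[gene]]
  types <- vapply(estimates, function(e) e$cell_type, character(1L))
  missing_prof <- setdiff(types, names(cell_profiles))
  if (length(missing_prof))
    stop("no cell profile for type(s): ", paste(missing_prof, collapse = ", "))
  contrib <- vapply(estimates, function(e) {
    p <- cell_profiles[[e$cell_type]]
    fg <- if (gene %in% p$gene_ids) p$fractions[[gene]] else 0
    e$fraction * fg / frac_l
  }, numeric(1L))
  names(contrib) <- types
  residual <- 1 - sum(contrib)
  inconsistent <- sum(contrib) > 1 + 0.05
  if (inconsistent)
    warning("contributions for gene '", gene, "' sum to ",
            format(sum(contrib)), " > 1")
  if (residual_policy == "assign_hepatocyte" &&
      !"hepatocyte" %in% names(contrib)) {
    contrib <- c(contrib, hepatocyte = residual)
    residual <- 0
  }
  structure(list(gene = gene, per_type_contribution = contrib,
                 residual = residual, inconsistent = inconsistent),
            class = "ApportionmentRow")
}

#' @export
print.ApportionmentRow <- function(x, ...) {
  cat(sprintf("ApportionmentRow '%s': %s; residual %.3g\n", x$gene,
              paste(sprintf("%s=%.3g", names(x$per_type_contribution),
                            x$per_type_contribution), collapse = ", "),
              x$residual))
  invisible(x)
}

#' Full deconvolution of a whole-tissue profile
#'
#' Convenience wrapper: estimates each marker set's cell-type fraction,
#' derives the NPC sum and the hepatocyte fraction by subtraction, and
#' optionally apportions a list of genes across cell types.
#'
#' @param tissue whole-tissue `NormalizedProfile`.
#' @param cell_profiles named list of cell-type `NormalizedProfile`s.
#' @param marker_sets named list of `MarkerSet`s (one per profiled type).
#' @param average averaging mode passed to [estimate_cell_fraction()].
#' @param apportion optional character vector of genes to apportion (credited
#'   residuals go to hepatocytes).
#' @return list with `fractions` (data.frame cell_type/fraction/n_markers/
#'   dispersion/clipped, including the hepatocyte row), `npc_fraction`,
#'   `hepatocyte_fraction`, `estimates` and, if requested, `apportionment`
#'   (data.frame with one contribution column per type plus residual).
#' @export
deconvolve_tissue <- function(tissue, cell_profiles, marker_sets,
                              average = c("mean", "median"),
                              apportion = NULL) {
  average <- match.arg(average)
  stopifnot(all(names(marker_sets) %in% names(cell_profiles)))
  estimates <- lapply(names(marker_sets), function(ct)
    estimate_cell_fraction(marker_sets[[ct]], tissue, cell_profiles[[ct]],
                           average = average))
  nh <- estimate_npc_and_hepatocyte(estimates)
  tab <- data.frame(
    cell_type = c(vapply(estimates, `[[`, character(1L), "cell_type"),
                  "hepatocyte"),
    fraction = c(vapply(estimates, `[[`, numeric(1L), "fraction"),
                 nh$hepatocyte_fraction),
    n_markers = c(vapply(estimates, `[[`, integer(1L), "n_markers"), NA),
    dispersion = c(vapply(estimates, `[[`, numeric(1L), "dispersion"), NA),
    clipped = c(vapply(estimates, `[[`, logical(1L), "clipped"), nh$clipped),
    stringsAsFactors = FALSE)
  out <- list(fractions = tab, npc_fraction = nh$npc_fraction,
              hepatocyte_fraction = nh$hepatocyte_fraction,
              estimates = estimates)
  if (!is.null(apportion)) {
    rows <- lapply(apportion, function(g)
      apportion_gene(g, estimates, cell_profiles, tissue,
                     residual_policy = "assign_hepatocyte"))
    types <- names(rows[[1L]]$per_type_contribution)
    ap <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(c(r$per_type_contribution,
                              residual = r$residual)))))
    ap <- cbind(data.frame(gene = apportion, stringsAsFactors = FALSE), ap)
    out$apportionment <- ap
  }
  out
}
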