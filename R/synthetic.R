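#' Simulate a panel of cell-type reference libraries with known markers
#'
#' Builds a shared gene universe in which most genes are expressed in every
#' cell type at independent log-normal levels ("shared" genes) while a reserved
#' block of genes is expressed in exactly one cell type ("exclusive markers",
#' emulating abundant cell-identity genes such as albumin in hepatocytes).
#' Expression is on the molecule-count (reads/kb) scale; transcript lengths
#' are drawn uniformly in [0.5, 10] kb so that the reads-to-molecules
#' conversion is exercised nontrivially downstream.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_genes total genes in the universe.
#' @param n_markers_per_type exclusive markers reserved for each type;
#'   `n_markers_per_type * n_cell_types` must be below `n_genes`.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param shared_meanlog,marker_meanlog,sdlog log-normal parameters of shared
#'   and marker expression on the reads/kb scale.  Markers default to a higher
#'   mean because cell-identity genes are typically among the most abundant
#'   transcripts of their cell type.
#' @return a `ReferenceSet`: list with `cell_types`, `profiles` (named list of
#'   `NormalizedProfile`), `marker_truth` (named list of exclusive marker ids
#'   per type), `shared_genes`, `length_kb`, `biotype` and `seed`.
#' @export
make_reference_set <- function(n_cell_types, n_genes, n_markers_per_type,
                               seed, shared_meanlog = 2, marker_meanlog = 4,
                               sdlog = 1) {
  if (n_cell_types < 2) stop("need at least 2 cell types")
  if (n_markers_per_type < 1) stop("n_markers_per_type must be >= 1")
  if (n_markers_per_type * n_cell_types >= n_genes)
    stop("n_markers_per_type * n_cell_types must be < n_genes")
  set.seed(seed)
  cell_types <- paste0("type", seq_len(n_cell_types))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  length_kb <- stats::setNames(stats::runif(n_genes, 0.5, 10), gene_ids)
  marker_idx <- sample.int(n_genes, n_markers_per_type * n_cell_types)
  marker_truth <- split(gene_ids[marker_idx],
                        rep(cell_types, each = n_markers_per_type))
  marker_truth <- marker_truth[cell_types]
  shared_genes <- setdiff(gene_ids, gene_ids[marker_idx])

  expr <- matrix(0, n_genes, n_cell_types,
                 dimnames = list(gene_ids, cell_types))
  for (ct in cell_types) {
    expr[shared_genes, ct] <- stats::rlnorm(length(shared_genes),
                                            shared_meanlog, sdlog)
    expr[marker_truth[[ct]], ct] <- stats::rlnorm(n_markers_per_type,
                                                  marker_meanlog, sdlog)
  }
  profiles <- lapply(cell_types, function(ct)
    new_normalized_profile(ct, expr[, ct]))
  names(profiles) <- cell_types
  structure(
    list(cell_types = cell_types, profiles = profiles,
         marker_truth = marker_truth, shared_genes = shared_genes,
         length_kb = length_kb,
         biotype = stats::setNames(rep("protein_coding", n_genes), gene_ids),
         seed = seed),
    class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf(
    "ReferenceSet: %d cell types, %d genes (%d exclusive markers), seed %d\n",
    length(x$cell_types), length(x$length_kb),
    sum(lengths(x$marker_truth)), x$seed))
  invisible(x)
}

#' Mix reference profiles into a whole-tissue library of known composition
#'
#' Forms the convex combination of the reference transcriptome-fraction
#' vectors with the given per-type weights, converts expected molecule counts
#' back to expected read counts using each gene's transcript length, scales to
#' the requested depth, and optionally resamples each gene's reads from a
#' Poisson distribution.  The weights are the ground-truth transcriptome
#' fractions that the deconvolution stage estimates.
#'
#' @param refs a `ReferenceSet` from [make_reference_set()].
#' @param fractions numeric vector of per-type transcriptome fractions, in the
#'   order of `refs$cell_types` (or named by them); must sum to 1 within 1e-9.
#' @param depth total read count of the mixed library.
#' @param noise `"none"` (expected counts, exact reals) or `"poisson"`
#'   (integer counts resampled per gene).
#' @param seed integer seed used when `noise = "poisson"`.
#' @return list with `library` (an `ExpressionLibrary`) and `truth` (list with
#'   `fractions`, `depth`, `seed`).
#' @export
mix_whole_tissue <- function(refs, fractions, depth = 1e6,
                             noise = c("none", "poisson"), seed = 0L) {
  noise <- match.arg(noise)
  stopifnot(inherits(refs, "ReferenceSet"))
  if (!is.null(names(fractions))) fractions <- fractions[refs$cell_types]
  if (length(fractions) != length(refs$cell_types))
    stop("need one fraction per cell type")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (depth <= 0) stop("depth must be positive")
  names(fractions) <- refs$cell_types

  frac_mat <- vapply(refs$profiles, function(p) p$fractions,
                     numeric(length(refs$length_kb)))
  mix_frac <- as.numeric(frac_mat %*% fractions)     # sums to 1 exactly
  expected_reads <- mix_frac * refs$length_kb
  expected_reads <- expected_reads / sum(expected_reads) * depth
  counts <- if (noise == "poisson") {
    set.seed(seed)
    stats::rpois(length(expected_reads), expected_reads)
  } else expected_reads
  lib <- expression_library(
    library_id = "whole_tissue",
    gene_ids = names(refs$length_kb),
    raw_counts = counts,
    length_kb = refs$length_kb,
    biotype = refs$biotype)
  list(library = lib,
       truth = list(fractions = fractions, depth = depth, seed = seed))
}

#' Simulate a two-condition count matrix with planted differential genes
#'
#' Each gene has a log-normal baseline Poisson rate; planted "up" genes have
#' their rate multiplied by `2^effect_log2fc` in the reference group (the
#' intact/control condition) and "down" genes divided by the same factor, so
#' the expected log2 fold change of reference over the comparison group is
#' exactly `+/- effect_log2fc`.  Identities of planted genes are recorded as
#' ground truth.  An effect of exactly 0 yields a null matrix with no planted
#' genes.
#'
#' @param n_genes,n_samples_per_group matrix dimensions.
#' @param n_up,n_down numbers of planted up-/down-regulated genes
#'   (`n_up + n_down < n_genes`).
#' @param effect_log2fc planted absolute log2 fold change (>= 0; negative is
#'   an error, 0 plants nothing).
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal parameters of the baseline
#'   Poisson rates.
#' @return a `CohortMatrix` with groups `"reference"` and `"comparison"` and
#'   `truth = list(up_genes, down_genes, effect_log2fc, seed)`.
#' @export
make_two_condition_matrix <- function(n_genes, n_samples_per_group, n_up,
                                      n_down, effect_log2fc, seed,
                                      base_meanlog = 4, base_sdlog = 1) {
  if (effect_log2fc < 0) stop("effect_log2fc must be nonnegative")
  if (n_up + n_down >= n_genes) stop("n_up + n_down must be < n_genes")
  if (n_samples_per_group < 2) stop("need >= 2 samples per group")
  set.seed(seed)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  lambda <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  if (effect_log2fc > 0) {
    planted <- sample.int(n_genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- planted[n_up + seq_len(n_down)]
  } else {
    up <- down <- integer(0)
  }
  lam_ref <- lambda
  lam_ref[up] <- lambda[up] * 2^effect_log2fc
  lam_ref[down] <- lambda[down] / 2^effect_log2fc

  n <- n_samples_per_group
  counts <- cbind(
    matrix(stats::rpois(n_genes * n, lam_ref), n_genes, n),
    matrix(stats::rpois(n_genes * n, lambda), n_genes, n))
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("ref_%02d", seq_len(n)),
                        sprintf("cmp_%02d", seq_len(n)))
  samples <- data.frame(
    sample_id = colnames(counts),
    group = rep(c("reference", "comparison"), each = n),
    stage = NA_character_,
    stringsAsFactors = FALSE)
  cohort_matrix(counts, samples,
                truth = list(up_genes = gene_ids[up],
                             down_genes = gene_ids[down],
                             effect_log2fc = effect_log2fc, seed = seed))
}

#' Simulate a staged bulk cohort with a declining signature
#'
#' Generates per-sample expression on the log2 scale: signature genes (and one
#' designated sentinel gene that mimics a single-gene stage biomarker) start
#' from gene-specific baselines and lose `stage_effect` log2 units of mean
#' expression per stage step; background genes carry no trend.  Gaussian noise
#' of standard deviation `noise_sd` is added on the log2 scale and values are
#' mapped back through `2^x - 1`.
#'
#' @param n_per_stage integer vector of samples per stage, ordered from the
#'   healthiest stage; names are used as stage labels (default `stage1..k`).
#' @param signature_genes nonempty character vector of signature gene ids.
#' @param stage_effect per-stage decrement of mean log2 expression of the
#'   signature genes and the sentinel gene.
#' @param noise_sd standard deviation of log2-scale noise.
#' @param seed integer seed.
#' @param n_background number of untrended background genes.
#' @param sentinel_gene id of the single trended biomarker gene.
#' @return a `CohortMatrix` whose `samples$stage` is an ordered factor and
#'   whose `truth` records the planted genes and effect.
#' @export
make_staged_cohort <- function(n_per_stage, signature_genes, stage_effect,
                               noise_sd, seed, n_background = 500,
                               sentinel_gene = "sentinel") {
  if (length(n_per_stage) < 2) stop("need at least 2 stages")
  if (length(signature_genes) == 0) stop("signature gene list is empty")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  stages <- names(n_per_stage)
  if (is.null(stages)) stages <- paste0("stage", seq_along(n_per_stage))
  bg <- sprintf("bg%05d", seq_len(n_background))
  genes <- unique(c(signature_genes, sentinel_gene, bg))
  trended <- unique(c(signature_genes, sentinel_gene))
  n_samples <- sum(n_per_stage)
  stage_idx <- rep(seq_along(stages) - 1L, n_per_stage)

  base <- stats::setNames(stats::rnorm(length(genes), mean = 6, sd = 1), genes)
  logex <- matrix(base, length(genes), n_samples,
                  dimnames = list(genes, sprintf("s%04d", seq_len(n_samples))))
  logex[trended, ] <- logex[trended, ] -
    matrix(stage_effect * stage_idx, length(trended), n_samples, byrow = TRUE)
  logex <- logex + matrix(stats::rnorm(length(logex), 0, noise_sd),
                          nrow(logex), ncol(logex))
  expr <- pmax(2^logex - 1, 0)
  samples <- data.frame(
    sample_id = colnames(expr),
    stage = factor(stages[stage_idx + 1L], levels = stages, ordered = TRUE),
    group = stages[stage_idx + 1L],
    stringsAsFactors = FALSE)
  cohort_matrix(expr, samples,
                truth = list(signature_genes = signature_genes,
                             sentinel_gene = sentinel_gene,
                             stage_effect = stage_effect,
                             noise_sd = noise_sd, seed = seed))
}
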