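#' Fisher-exact enrichment of the overlap between two gene sets
#'
#' Tests whether two gene sets drawn from a common universe share more genes
#' than expected by chance.  The one-sided enrichment p-value is the
#' hypergeometric upper tail P(X >= n_shared) of the 2x2 table; the odds
#' ratio is the sample odds ratio of the table without continuity
#' correction.
#'
#' @param set_a,set_b character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector defining the background gene universe.
#' @return an `OverlapResult`: list with `n_universe`, `n_a`, `n_b`,
#'   `n_shared`, `odds_ratio`, `p_value`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  stray <- setdiff(union(set_a, set_b), universe)
  if (length(stray))
    stop("gene(s) outside the universe: ",
         paste(utils::head(stray, 10L), collapse = ", "))
  n <- length(universe)
  na <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  # 2x2 table: shared | a only / b only | neither
  b <- na - k; c_ <- nb - k; d <- n - na - nb + k
  p <- stats::phyper(k - 1, na, n - na, nb, lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (k * d == 0) NaN else Inf
  } else (k * d) / (b * c_)
  structure(list(n_universe = n, n_a = na, n_b = nb, n_shared = k,
                 odds_ratio = or, p_value = p),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "OverlapResult: %d shared of %d x %d in universe %d (OR %.3g, p %.3g)\n",
    x$n_shared, x$n_a, x$n_b, x$n_universe, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Global expression concordance between two datasets
#'
#' Pearson correlation of matched per-gene expression vectors from two
#' datasets, by default after a log2(x + 1) transform so the statistic is not
#' dominated by a few very abundant genes.  Vectors may be named; when both
#' are, they are matched on gene id (intersection).
#'
#' @param expr_a,expr_b numeric vectors of per-gene values.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return list with `r`, `p` (t-distribution p-value of the correlation),
#'   `n_genes`.
#' @export
pearson_concordance <- function(expr_a, expr_b,
                                transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (!is.null(names(expr_a)) && !is.null(names(expr_b))) {
    shared <- intersect(names(expr_a), names(expr_b))
    expr_a <- expr_a[shared]; expr_b <- expr_b[shared]
  }
  if (length(expr_a) != length(expr_b))
    stop("vectors must be matched on gene id")
  if (length(expr_a) < 3) stop("need >= 3 shared genes")
  if (transform == "log2p1") {
    if (any(expr_a < 0) || any(expr_b < 0))
      stop("log2p1 transform requires nonnegative values")
    expr_a <- log2(expr_a + 1); expr_b <- log2(expr_b + 1)
  }
  if (stats::sd(expr_a) == 0 || stats::sd(expr_b) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(expr_a, expr_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = length(expr_a))
}
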