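#' Rank genes by differential expression between two groups
#'
#' Per-gene Welch t-test on log2(CPM + 1) values with Benjamini-Hochberg
#' q-values.  The log2 fold change is the difference of group means on the
#' log2(CPM + 1) scale, reference minus comparison, so positive values are
#' up in the reference condition.  This built-in test keeps the synthetic
#' pipeline closed; it is a simple location test, not a negative-binomial
#' count model.
#'
#' @param cm a `CohortMatrix` with a two-level `group` column.
#' @param ref_group the group treated as reference (default: the first group
#'   in the sample sheet).
#' @return data.frame (`gene`, `log2fc`, `p`, `q`).
#' @export
de_rank <- function(cm, ref_group = NULL) {
  stopifnot(inherits(cm, "CohortMatrix"))
  grp <- as.character(cm$samples$group)
  lv <- unique(grp)
  if (length(lv) != 2) stop("de_rank needs exactly 2 groups, got ",
                            length(lv))
  if (is.null(ref_group)) ref_group <- lv[1L]
  if (!ref_group %in% lv) stop("unknown reference group '", ref_group, "'")
  if (min(table(grp)) < 2) stop("each group needs >= 2 samples")
  cpm <- t(t(cm$expr) / colSums(cm$expr)) * 1e6
  l <- log2(cpm + 1)
  a <- l[, grp == ref_group, drop = FALSE]
  b <- l[, grp != ref_group, drop = FALSE]
  wt <- welch_rows(a, b)
  q <- stats::p.adjust(wt$p, method = "BH")
  data.frame(gene = rownames(cm$expr), log2fc = wt$diff, p = wt$p, q = q,
             stringsAsFactors = FALSE)
}

# vectorized per-row Welch t-test; rows with zero variance in both groups get
# p = 1 when means agree and p = 0 otherwise
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  list(diff = diff, t = tt, p = p)
}

#' Select an "active-state" signature from differential-expression statistics
#'
#' Keeps genes upregulated in the reference condition at the stated
#' thresholds (log2 fold change at least `min_abs_log2fc` and q at most
#' `max_q`), orders them by ascending q then descending fold change, and
#' optionally truncates to the `top_k` most significant.
#'
#' @param stats data.frame from [de_rank()] (`gene`, `log2fc`, `p`, `q`).
#' @param min_abs_log2fc minimum log2 fold change (reference over comparison).
#' @param max_q maximum BH q-value.
#' @param top_k optional cap on signature size.
#' @return a `SignatureGeneSet`: list with `genes` (ordered), `direction` and
#'   `source_stats`.  An empty qualifying set is an error.
#' @export
derive_signature <- function(stats, min_abs_log2fc = 1, max_q = 0.05,
                             top_k = NULL) {
  stopifnot(is.data.frame(stats),
            all(c("gene", "log2fc", "q") %in% names(stats)))
  keep <- stats$log2fc >= min_abs_log2fc & stats$q <= max_q
  sel <- stats[keep, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no gene passes log2fc >= ", min_abs_log2fc, " and q <= ", max_q)
  sel <- sel[order(sel$q, -sel$log2fc, sel$gene), , drop = FALSE]
  if (!is.null(top_k)) sel <- utils::head(sel, top_k)
  structure(list(genes = sel$gene, direction = "up_in_reference",
                 source_stats = sel),
            class = "SignatureGeneSet")
}

#' @export
print.SignatureGeneSet <- function(x, ...) {
  cat(sprintf("SignatureGeneSet: %d genes, %s\n", length(x$genes),
              x$direction))
  invisible(x)
}

#' Score samples for signature activity
#'
#' The score of a sample is the mean, over signature genes present in the
#' matrix, of that gene's z-scored log2(x + 1) expression across samples — a
#' deliberately simple module-score.  Missing signature genes are reported in
#' a message.  Because the per-gene z-score is taken across samples, the
#' matrix must already be comparable across samples; a warning is raised when
#' sample totals differ by more than 10-fold.
#'
#' @param cm a `CohortMatrix`.
#' @param sig a `SignatureGeneSet` (or plain character vector of gene ids).
#' @param method `"zmean"` (default) or `"rank"`, the mean within-sample
#'   percentile rank of the signature genes.
#' @return a `ScoreTable` data.frame (`sample_id`, `stage`, `score`).
#' @export
score_samples <- function(cm, sig, method = c("zmean", "rank")) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "CohortMatrix"))
  genes <- if (inherits(sig, "SignatureGeneSet")) sig$genes else
    as.character(sig)
  present <- intersect(genes, rownames(cm$expr))
  if (length(present) == 0) stop("no signature gene present in the matrix")
  if (length(present) < length(genes))
    message(length(genes) - length(present),
            " signature gene(s) absent from the matrix")
  totals <- colSums(cm$expr)
  if (max(totals) / max(min(totals), .Machine$double.eps) > 10)
    warning("sample totals differ by > 10x; scores assume a pre-normalized ",
            "matrix")
  l <- log2(cm$expr + 1)
  score <- if (method == "zmean") {
    z <- t(scale(t(l[present, , drop = FALSE])))
    z[is.nan(z)] <- 0          # constant gene across samples carries no signal
    colMeans(z)
  } else {
    pr <- apply(l, 2L, function(col) rank(col) / length(col))
    colMeans(pr[present, , drop = FALSE])
  }
  out <- data.frame(sample_id = cm$samples$sample_id,
                    stage = cm$samples$stage,
                    score = unname(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("ScoreTable", class(out))
  out
}

#' Test for a monotone trend of score across ordinal stages
#'
#' Spearman rank correlation of the per-sample score with the integer stage
#' index, with a two-sided permutation p-value.  When the number of distinct
#' stage-label assignments is at most `n_perm` the permutation null is
#' enumerated exhaustively (exact p); otherwise `n_perm` random permutations
#' are drawn with the add-one correction.
#'
#' @param scores a `ScoreTable` (needs `score` and ordinal `stage`).
#' @param n_perm permutation budget.
#' @param seed seed for the random-permutation fall-back.
#' @return list with `rho`, `p`, `n_perm_used` and `exact` (logical).
#'   Constant scores give `rho = 0`, `p = 1`.
#' @export
stage_trend <- function(scores, n_perm = 10000, seed = 1L) {
  stopifnot(all(c("score", "stage") %in% names(scores)))
  stage <- as.integer(factor(scores$stage,
                             levels = unique(as.character(scores$stage))))
  if (inherits(scores$stage, "factor"))
    stage <- as.integer(scores$stage)
  if (length(unique(stage)) < 2) stop("need >= 2 stages")
  if (min(table(stage)) < 2) stop("need >= 2 samples per stage")
  s <- scores$score
  if (stats::sd(s) == 0) return(list(rho = 0, p = 1, n_perm_used = 0L,
                                     exact = TRUE))
  rho_obs <- stats::cor(s, stage, method = "spearman")
  n_distinct <- multiset_perm_count(table(stage))
  rho_of <- function(st) stats::cor(s, st, method = "spearman")
  if (!is.na(n_distinct) && n_distinct <= n_perm) {
    perms <- multiset_permutations(stage)
    rhos <- vapply(perms, rho_of, numeric(1L))
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    list(rho = rho_obs, p = p, n_perm_used = length(perms), exact = TRUE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm))
      if (abs(rho_of(sample(stage))) >= abs(rho_obs) - 1e-12)
        hits <- hits + 1L
    list(rho = rho_obs, p = (1 + hits) / (1 + n_perm),
         n_perm_used = n_perm, exact = FALSE)
  }
}

# number of distinct permutations of a multiset; NA when it overflows
multiset_perm_count <- function(tab) {
  v <- lfactorial(sum(tab)) - sum(lfactorial(tab))
  if (v > log(.Machine$integer.max)) NA_integer_ else as.integer(round(exp(v)))
}

# all distinct permutations of an integer vector (multiset), as a list
multiset_permutations <- function(x) {
  vals <- sort(unique(x))
  counts <- as.integer(table(factor(x, levels = vals)))
  n <- length(x)
  out <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (i in seq_along(vals)) {
      if (counts[i] > 0L) {
        counts[i] <- counts[i] - 1L
        rec(c(prefix, vals[i]), counts)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  rec(integer(0), counts)
  out
}
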