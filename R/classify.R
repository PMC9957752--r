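#' Split a cohort into training and test sets
#'
#' Reserves about `train_fraction` of the samples for training a logistic
#' regression model and leaves the rest as the test set.  With
#' `stratified = TRUE` (the default) the split preserves the class ratio
#' within one sample per class.  The split is deterministic for a fixed seed
#' and the seed is recorded in the plan.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels class label per sample (two classes).
#' @param train_fraction fraction reserved for training.
#' @param seed integer seed.
#' @param stratified preserve class ratios (default TRUE).
#' @return a `SplitPlan`: list with `train_ids`, `test_ids`,
#'   `train_fraction`, `seed`, `stratified`.
#' @export
split_cohort <- function(sample_ids, labels, train_fraction = 0.25, seed = 1L,
                         stratified = TRUE) {
  n <- length(sample_ids)
  stopifnot(length(labels) == n, n >= 4, train_fraction > 0,
            train_fraction < 1)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  labels <- as.character(labels)
  set.seed(seed)
  if (stratified) {
    if (min(table(labels)) < 2)
      stop("stratified split needs >= 2 samples per class")
    # largest-remainder allocation: total train size is round(f * n) and
    # each class quota is within one sample of f * n_class
    by_class <- split(sample_ids, labels)
    quota <- train_fraction * lengths(by_class)
    k_class <- floor(quota)
    extra <- round(train_fraction * n) - sum(k_class)
    if (extra > 0) {
      give <- order(quota - k_class, decreasing = TRUE)[seq_len(extra)]
      k_class[give] <- k_class[give] + 1L
    }
    k_class <- pmin(pmax(k_class, 1L), lengths(by_class) - 1L)
    train <- unlist(Map(function(ids, k) sample(ids, k), by_class, k_class),
                    use.names = FALSE)
  } else {
    k <- round(train_fraction * n)
    k <- min(max(k, 1L), n - 1L)
    train <- sample(sample_ids, k)
  }
  test <- setdiff(sample_ids, train)
  for (cl in unique(labels)) {
    if (!any(labels[match(train, sample_ids)] == cl) ||
        !any(labels[match(test, sample_ids)] == cl))
      stop("class '", cl, "' absent from train or test set")
  }
  list(train_ids = sort(train), test_ids = sort(test),
       train_fraction = train_fraction, seed = seed, stratified = stratified)
}

#' Fit a univariate logistic regression
#'
#' Maximum-likelihood fit of `P(y = 1 | x) = plogis(intercept + slope * x)`
#' by iteratively reweighted least squares (deviance tolerance 1e-10, at most
#' 100 iterations).  Perfect separation is flagged; the coefficients reached
#' at the iteration cap are still returned.
#'
#' @param x numeric predictor, not constant.
#' @param y binary labels (logical, 0/1, or two-level factor).
#' @return list with `intercept`, `slope`, `converged` and `separation`.
#' @export
fit_univariate_logistic <- function(x, y) {
  y <- as_binary(y)
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (stats::sd(x) == 0) stop("predictor is constant")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("perfect or quasi-perfect separation detected")
  list(intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]),
       converged = fit$converged,
       separation = separation)
}

as_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("labels must have exactly 2 levels")
    return(as.integer(y) - 1L)
  }
  u <- sort(unique(y))
  if (length(u) > 2) stop("labels must have exactly 2 distinct values")
  if (length(u) == 1)                     # callers report the missing class
    return(rep(if (identical(u, 1)) 1L else 0L, length(y)))
  as.integer(y == u[2L])
}

#' ROC curve and AUC for a continuous score
#'
#' Sweeps all distinct score thresholds, accumulates true- and
#' false-positive rates, and integrates the curve by the trapezoidal rule —
#' ties between classes contribute half credit, so the AUC equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric score per sample (higher = more positive-like).
#' @param y binary labels.
#' @return a `RocResult`: list with `auc`, `thresholds`, `tpr`, `fpr`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, y) {
  y <- as_binary(y)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: only one class present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE)   # end of each tie block
  tpr <- c(0, cumsum(ys)[last] / n_pos)
  fpr <- c(0, cumsum(1 - ys)[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc,
                 thresholds = c(Inf, ss[last]),
                 tpr = tpr, fpr = fpr,
                 n_pos = n_pos, n_neg = n_neg),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Single-gene staging classifier with train/test split and ROC
#'
#' Reproduces the full staging protocol for one gene: select the samples in
#' the two stage groups, log2-transform expression, reserve a training
#' fraction for fitting a univariate logistic regression, and evaluate by ROC
#' on the held-out test set.  Both the model-score AUC and the
#' raw-expression AUC are reported; because a univariate logistic model is a
#' monotone transform of its input, they agree up to slope sign.
#'
#' @param cm a `CohortMatrix` with a `stage` column.
#' @param gene gene id to stage on.
#' @param pos_stages,neg_stages stage labels forming the positive (e.g.
#'   advanced fibrosis) and negative classes.
#' @param train_fraction fraction reserved for training (default one
#'   quarter).
#' @param seed split seed.
#' @param positive_low set TRUE when the positive class is expected to have
#'   *lower* expression, to orient the raw-expression ROC; the model AUC is
#'   orientation-free.
#' @return list with `model` (coefficients), `roc_model`, `roc_raw`, `split`,
#'   `n_train`, `n_test`.
#' @export
stage_classifier <- function(cm, gene, pos_stages, neg_stages,
                             train_fraction = 0.25, seed = 1L,
                             positive_low = TRUE) {
  stopifnot(inherits(cm, "CohortMatrix"))
  if (!gene %in% rownames(cm$expr)) stop("gene '", gene, "' not in matrix")
  st <- as.character(cm$samples$stage)
  sel <- st %in% c(pos_stages, neg_stages)
  if (!any(sel)) stop("no sample in the requested stages")
  ids <- cm$samples$sample_id[sel]
  y <- as.integer(st[sel] %in% pos_stages)
  x <- log2(cm$expr[gene, sel] + 1)
  plan <- split_cohort(ids, y, train_fraction = train_fraction, seed = seed)
  tr <- ids %in% plan$train_ids
  model <- fit_univariate_logistic(x[tr], y[tr])
  lin <- model$intercept + model$slope * x[!tr]
  roc_model <- roc_auc(lin, y[!tr])
  roc_raw <- roc_auc(if (positive_low) -x[!tr] else x[!tr], y[!tr])
  list(model = model, roc_model = roc_model, roc_raw = roc_raw,
       split = plan, n_train = sum(tr), n_test = sum(!tr))
}
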