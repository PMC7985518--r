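# DYNAMITE-style TF ranking: a sparse (elastic net) logistic regression on
# condition-contrasted TF-gene scores discriminates up- from down-regulated
# genes; the per-TF coefficients, averaged over outer cross-validation
# folds and normalized to [0,1], rank candidate driver TFs.

#' Build the regression feature matrix from two score matrices
#'
#' Feature entry for gene g and TF t is
#' `log2((treated[g,t] + epsilon) / (control[g,t] + epsilon))` (or the plain
#' difference). Labels are 1 (up) / 0 (down) from the sign of the gene's
#' fold change at the modeled time point; zero fold changes are excluded.
#'
#' @param scores_control,scores_treated `tf_gene_scores` matrices sharing
#'   TF columns.
#' @param labeled_genes data.frame with columns `gene_id` and `log2fc`
#'   (typically the secondary DEGs at the late time point).
#' @param epsilon positive stabilizer for the log ratio (default 1e-3).
#' @param contrast `"ratio"` (default, log2 ratio) or `"difference"`.
#' @return list with `features` (genes x TFs matrix) and `labels`
#'   (named 0/1 vector).
#' @export
build_feature_matrix <- function(scores_control, scores_treated,
                                 labeled_genes, epsilon = 1e-3,
                                 contrast = c("ratio", "difference")) {
  contrast <- match.arg(contrast)
  if (epsilon <= 0) stop("epsilon must be > 0")
  tfs <- intersect(colnames(scores_control), colnames(scores_treated))
  if (length(tfs) == 0L) stop("score matrices share no TF columns")
  lg <- labeled_genes[labeled_genes$log2fc != 0 &
                      !is.na(labeled_genes$log2fc), , drop = FALSE]
  present <- lg$gene_id %in% rownames(scores_control) &
             lg$gene_id %in% rownames(scores_treated)
  if (any(!present)) {
    warning(sum(!present), " labeled gene(s) missing from a score matrix; excluded")
    lg <- lg[present, , drop = FALSE]
  }
  ctl <- scores_control[lg$gene_id, tfs, drop = FALSE]
  trt <- scores_treated[lg$gene_id, tfs, drop = FALSE]
  X <- switch(contrast,
              ratio = log2((trt + epsilon) / (ctl + epsilon)),
              difference = trt - ctl)
  X <- matrix(as.numeric(X), nrow = nrow(X),
              dimnames = list(lg$gene_id, tfs))
  list(features = X,
       labels = stats::setNames(as.integer(lg$log2fc > 0), lg$gene_id))
}

#' Fit the sparse logistic TF classifier
#'
#' Elastic-net-penalized logistic regression (default mixing `alpha = 0.1`)
#' with nested cross-validation: the penalty is chosen per outer fold by
#' inner cross-validation on misclassification error, and the raw TF
#' coefficients are the average over the outer-fold fits. Features are
#' standardized to zero mean / unit variance once before fitting (constant
#' columns become all-zero). Deterministic given `seed`.
#'
#' @param features genes x TFs matrix (from [build_feature_matrix()]).
#' @param labels 0/1 vector aligned with `features` rows.
#' @param alpha elastic-net mixing parameter (default 0.1).
#' @param penalty_grid decreasing lambda grid; default logarithmic over six
#'   decades, `10^seq(1, -5, length.out = 60)`.
#' @param n_outer_folds,n_inner_folds fold counts (defaults 6 and 6).
#' @param seed RNG seed for the fold assignments (mandatory).
#' @return data.frame with columns `tf_name`, `raw_coefficient`, plus
#'   attributes `fold_accuracy` (outer-fold held-out accuracies) and
#'   `seed`.
#' @export
fit_sparse_classifier <- function(features, labels, alpha = 0.1,
                                  penalty_grid = 10^seq(1, -5,
                                                        length.out = 60),
                                  n_outer_folds = 6, n_inner_folds = 6,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory")
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (nrow(features) != length(y)) stop("features/labels size mismatch")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  X <- sweep(features, 2, mu, "-")
  X <- sweep(X, 2, ifelse(sdv > 0, sdv, 1), "/")
  if (all(abs(X) < 1e-12) || all(sdv == 0)) {
    warning("degenerate all-constant feature matrix; all coefficients 0")
    out <- data.frame(tf_name = colnames(features),
                      raw_coefficient = 0, stringsAsFactors = FALSE)
    attr(out, "fold_accuracy") <- rep(NA_real_, n_outer_folds)
    attr(out, "seed") <- seed
    return(out)
  }
  n <- nrow(X)
  set.seed(seed)
  outer_fold <- sample(rep_len(seq_len(n_outer_folds), n))
  inner_seeds <- sample.int(.Machine$integer.max %/% 2L, n_outer_folds)
  coefs <- matrix(0, nrow = ncol(X), ncol = n_outer_folds,
                  dimnames = list(colnames(X), NULL))
  acc <- numeric(n_outer_folds)
  for (f in seq_len(n_outer_folds)) {
    tr <- outer_fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) { acc[f] <- NA_real_; next }
    set.seed(inner_seeds[f])
    foldid <- sample(rep_len(seq_len(n_inner_folds), sum(tr)))
    cvfit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial",
                               alpha = alpha, lambda = penalty_grid,
                               type.measure = "class", foldid = foldid,
                               standardize = FALSE)
    coefs[, f] <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
    pred <- stats::predict(cvfit, newx = X[!tr, , drop = FALSE],
                           s = "lambda.min", type = "class")
    acc[f] <- mean(as.integer(pred) == y[!tr])
  }
  out <- data.frame(tf_name = colnames(features),
                    raw_coefficient = rowMeans(coefs),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fold_accuracy") <- acc
  attr(out, "seed") <- seed
  out
}

#' Normalize coefficients to [0,1] and rank TFs
#'
#' `normalized = |raw| / max(|raw|)` (all zero if every raw coefficient is
#' zero); rank by descending normalized value, ties broken by TF name.
#'
#' @param raw_importances data.frame from [fit_sparse_classifier()]
#'   (columns `tf_name`, `raw_coefficient`).
#' @return data.frame with columns `tf_name`, `raw_coefficient`,
#'   `normalized_coefficient`, `rank`.
#' @export
normalize_and_rank <- function(raw_importances) {
  if (nrow(raw_importances) == 0L) stop("no coefficients to normalize")
  raw <- raw_importances$raw_coefficient
  mx <- max(abs(raw))
  norm <- if (mx > 0) abs(raw) / mx else rep(0, length(raw))
  ord <- order(-norm, raw_importances$tf_name)
  out <- raw_importances
  out$normalized_coefficient <- norm
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out[ord, , drop = FALSE]
}
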