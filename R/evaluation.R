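# Classification metrics (threshold-based and threshold-free) and the
# baseline comparison harness. Positive class = 1 (non-LTS, poor prognosis).

auc_rank <- function(y, p) {
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(p)  # midranks handle ties
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision by step integration: sum over distinct score thresholds
# (descending) of precision * recall increment.
aupr_step <- function(y, p) {
  P <- sum(y == 1)
  if (P == 0 || P == length(y)) return(NA_real_)
  o <- order(p, decreasing = TRUE)
  ys <- y[o]; ps <- p[o]
  grp_end <- cumsum(rle(ps)$lengths)  # last index of each distinct score
  tp <- cumsum(ys)[grp_end]
  fp <- (grp_end) - tp
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics report
#'
#' Threshold-based metrics (accuracy, precision, recall, F1 and the
#' confusion counts) at the given probability cutoff, plus threshold-free
#' ROC AUC (midrank convention, so constant scores give 0.5) and AUPR
#' (average precision by step interpolation, declared in the report).
#' Positive class = 1 (non-LTS).
#'
#' @param y 0/1 labels; @param p probabilities of class 1.
#' @param threshold decision cutoff (default 0.5; predictions are `p >=
#'   threshold`).
#' @return class `metrics_report`: accuracy, auc, aupr, f1, precision,
#'   recall, tp/fp/tn/fn, threshold, aupr_convention.
#' @export
compute_metrics <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) config_error("label/probability length mismatch")
  if (length(unique(y)) < 2)
    warning("only one class present; AUC and AUPR are undefined")
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = (tp + tn) / length(y),
                 auc = auc_rank(y, p), aupr = aupr_step(y, p),
                 f1 = f1, precision = precision, recall = recall,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 threshold = threshold,
                 aupr_convention = "step interpolation (average precision)"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  AUC %.3f  AUPR %.3f  F1 %.3f  precision %.3f  recall %.3f\n",
              x$accuracy, x$auc, x$aupr, x$f1, x$precision, x$recall))
  cat(sprintf("confusion @%.2f: TP %d  FP %d  TN %d  FN %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

metrics_row <- function(model_name, m) {
  data.frame(model = model_name, accuracy = m$accuracy, auc = m$auc,
             aupr = m$aupr, f1 = m$f1, precision = m$precision,
             recall = m$recall, stringsAsFactors = FALSE)
}

#' Evaluate a trained sparse model on a cohort partition
#'
#' @param model a `sparse_model`; @param features,labels full cohort data;
#' @param ids sample ids of the partition to score; @param threshold cutoff.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, features, labels, ids, threshold = 0.5) {
  p <- forward(model, features[ids, , drop = FALSE])$combined
  compute_metrics(labels[ids], p, threshold)
}

#' Run the baseline model comparison
#'
#' Fits five classical families on identical training data and scores the
#' identical test set with the same binary feature matrix the network
#' consumes: L2 logistic regression (glmnet ridge), linear and RBF support
#' vector machines (in-package primal squared-hinge minimizers; the RBF
#' kernel uses the "scale" bandwidth 1/(p * var(X))), a CART-style decision
#' tree, and a random forest (bagged trees with per-split feature
#' subsampling). A family whose training fold is single-class is skipped
#' with a warning.
#'
#' @param features samples x features binary matrix with sample-id rownames.
#' @param labels named 0/1 vector.
#' @param split list with `train` and `test` id vectors.
#' @param seed seed for the stochastic learners.
#' @param models subset of the baseline names to run.
#' @return data.frame, one row per model, with the metric columns of
#'   [compute_metrics()].
#' @export
run_baselines <- function(features, labels, split, seed = 1L,
                          models = c("logistic_l2", "svm_linear", "svm_rbf",
                                     "random_forest", "decision_tree")) {
  Xtr <- features[split$train, , drop = FALSE]; ytr <- labels[split$train]
  Xte <- features[split$test, , drop = FALSE]; yte <- labels[split$test]
  if (length(unique(ytr)) < 2) {
    warning("single-class training fold; all baselines skipped")
    return(data.frame())
  }
  out <- list()
  for (m in models) {
    set.seed(seed)
    p <- switch(m,
      logistic_l2 = {
        fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                              lambda = 1 / nrow(Xtr))
        as.vector(predict(fit, Xte, type = "response"))
      },
      svm_linear = {
        fit <- fit_linear_svm(Xtr, ytr)
        plogis(as.vector(Xte %*% fit$w + fit$b))
      },
      svm_rbf = {
        fit <- fit_rbf_svm(Xtr, ytr)
        plogis(predict_rbf_svm(fit, Xte))
      },
      decision_tree = {
        tree <- fit_tree(Xtr, ytr, max_depth = 12, min_node = 2)
        predict_tree(tree, Xte)
      },
      random_forest = {
        fit <- fit_forest(Xtr, ytr, n_trees = 100, max_depth = 12)
        predict_forest(fit, Xte)
      },
      config_error(sprintf("unknown baseline '%s'", m)))
    out[[m]] <- metrics_row(m, compute_metrics(yte, p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- primal squared-hinge SVMs (no SVM library is available offline) ----

squared_hinge_obj <- function(theta, X, ys, lambda, kernel = NULL) {
  w <- theta[-length(theta)]; b <- theta[length(theta)]
  f <- as.vector(X %*% w) + b
  m <- pmax(0, 1 - ys * f)
  reg <- if (is.null(kernel)) lambda / 2 * sum(w^2) else lambda / 2 * sum(w * (kernel %*% w))
  reg + mean(m^2)
}

squared_hinge_grad <- function(theta, X, ys, lambda, kernel = NULL) {
  w <- theta[-length(theta)]; b <- theta[length(theta)]
  f <- as.vector(X %*% w) + b
  m <- pmax(0, 1 - ys * f)
  gf <- -2 * ys * m / nrow(X)
  gw <- as.vector(crossprod(X, gf)) +
    if (is.null(kernel)) lambda * w else lambda * as.vector(kernel %*% w)
  c(gw, sum(gf))
}

fit_linear_svm <- function(X, y, C = 1) {
  ys <- ifelse(y == 1, 1, -1)
  lambda <- 1 / (C * nrow(X))
  opt <- stats::optim(numeric(ncol(X) + 1), squared_hinge_obj, squared_hinge_grad,
                      X = X, ys = ys, lambda = lambda, method = "L-BFGS-B",
                      control = list(maxit = 200))
  list(w = opt$par[-length(opt$par)], b = opt$par[length(opt$par)])
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_rbf_svm <- function(X, y, C = 1) {
  gamma <- 1 / (ncol(X) * max(var(as.vector(X)), .Machine$double.eps))
  K <- rbf_kernel(X, X, gamma)
  ys <- ifelse(y == 1, 1, -1)
  lambda <- 1 / (C * nrow(X))
  opt <- stats::optim(numeric(nrow(X) + 1), squared_hinge_obj, squared_hinge_grad,
                      X = K, ys = ys, lambda = lambda, kernel = K,
                      method = "L-BFGS-B", control = list(maxit = 150))
  list(alpha = opt$par[-length(opt$par)], b = opt$par[length(opt$par)],
       gamma = gamma, Xtr = X)
}

predict_rbf_svm <- function(fit, X) {
  as.vector(rbf_kernel(X, fit$Xtr, fit$gamma) %*% fit$alpha) + fit$b
}

# ---- CART-style tree / bagged forest for binary features ----

gini_split <- function(X, y, feat_idx) {
  n <- length(y)
  n1 <- colSums(X[, feat_idx, drop = FALSE])
  p1 <- as.vector(crossprod(X[, feat_idx, drop = FALSE], y))
  n0 <- n - n1; p0 <- sum(y) - p1
  g <- function(pos, tot) ifelse(tot > 0, 2 * (pos / tot) * (1 - pos / tot), 0)
  impurity <- (n1 * g(p1, n1) + n0 * g(p0, n0)) / n
  valid <- n1 > 0 & n0 > 0
  impurity[!valid] <- Inf
  list(feature = feat_idx[which.min(impurity)], impurity = min(impurity))
}

fit_tree <- function(X, y, max_depth = 12, min_node = 2, mtry = NULL) {
  grow <- function(idx, depth) {
    ys <- y[idx]
    prob <- mean(ys)
    if (depth >= max_depth || length(idx) < min_node || prob %in% c(0, 1))
      return(list(leaf = TRUE, prob = prob))
    feats <- if (is.null(mtry)) seq_len(ncol(X)) else
      sample(ncol(X), min(mtry, ncol(X)))
    parent_gini <- 2 * prob * (1 - prob)
    sp <- gini_split(X[idx, , drop = FALSE], ys, feats)
    if (!is.finite(sp$impurity) || sp$impurity >= parent_gini - 1e-12)
      return(list(leaf = TRUE, prob = prob))
    left <- idx[X[idx, sp$feature] == 0]
    right <- idx[X[idx, sp$feature] == 1]
    list(leaf = FALSE, feature = sp$feature,
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  grow(seq_len(nrow(X)), 0)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {out[idx] <<- node$prob; return()}
    on <- X[idx, node$feature] == 1
    walk(node$left, idx[!on]); walk(node$right, idx[on])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

fit_forest <- function(X, y, n_trees = 100, max_depth = 12) {
  mtry <- max(1, floor(sqrt(ncol(X))))
  lapply(seq_len(n_trees), function(b) {
    idx <- sample(nrow(X), replace = TRUE)
    fit_tree(X[idx, , drop = FALSE], y[idx], max_depth = max_depth,
             min_node = 1, mtry = mtry)
  })
}

predict_forest <- function(forest, X) {
  rowMeans(vapply(forest, function(tr) predict_tree(tr, X), numeric(nrow(X))))
}
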