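# Cost-asymmetric linear SVM via dual coordinate descent (L1 hinge).
# The bias is learned through an augmented constant feature, so `w` has
# length ncol(X) and `b` is the augmented weight.

fit_binary_svm <- function(X, y, cpos, cneg, seed = 1L,
                           eps = 0.1, max_iter = 1000L) {
  stopifnot(is.logical(y), length(y) == nrow(X))
  if (all(y) || all(!y))
    return(list(w = numeric(ncol(X)), b = if (all(y)) 1 else -1,
                degenerate = TRUE))
  Xa <- cbind(X, 1)
  Xt <- methods::as(Matrix::t(Xa), "CsparseMatrix")
  yv <- ifelse(y, 1, -1)
  Ci <- ifelse(y, cpos, cneg)
  w <- .dcd_svm_fit(Xt@i, Xt@p, Xt@x, ncol(Xa), yv, Ci,
                    eps, max_iter, as.integer(seed))
  list(w = w[seq_len(ncol(X))], b = w[ncol(Xa)], degenerate = FALSE)
}

svm_decision <- function(fit, X) {
  if (isTRUE(fit$degenerate)) return(rep(fit$b, nrow(X)))
  as.numeric(X %*% fit$w) + fit$b
}

binary_f1 <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Grid search over (C+, C-) by document-level cross-validation, maximizing
# the binary F-score of the positive class; ties resolved by grid order
# (deterministic).  `folds` is an integer vector of fold ids per row.
select_costs <- function(X, y, folds, cpos_grid, cneg_grid, seed = 1L) {
  best <- list(f1 = -1, cpos = cpos_grid[1], cneg = cneg_grid[1])
  fold_ids <- sort(unique(folds))
  for (cp in cpos_grid) for (cn in cneg_grid) {
    tp <- fp <- fn <- 0L
    for (fd in fold_ids) {
      tr <- folds != fd; te <- !tr
      if (!any(y[tr]) || !any(te)) next
      fit <- fit_binary_svm(X[tr, , drop = FALSE], y[tr], cp, cn, seed)
      pred <- svm_decision(fit, X[te, , drop = FALSE]) > 0
      tp <- tp + sum(pred & y[te])
      fp <- fp + sum(pred & !y[te])
      fn <- fn + sum(!pred & y[te])
    }
    f1 <- if (tp == 0L) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn); 2 * p * r / (p + r)
    }
    if (f1 > best$f1 + 1e-12) best <- list(f1 = f1, cpos = cp, cneg = cn)
  }
  best
}
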