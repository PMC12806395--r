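# L1-penalised (multinomial) logistic node models. The solver is glmnet,
# whose objective -(1/N) loglik + lambda * sum|beta| with unpenalised
# intercepts is exactly the penalised likelihood used here; models are
# stored in a solver-independent m x K coefficient form.

#' Fit an L1-penalised logistic model at a fixed penalty
#'
#' Class-k probabilities follow the softmax model
#' \deqn{Pr(G=k|x) = e^{\beta_{0k} + \beta_k^T x} / \sum_l e^{\beta_{0l} + \beta_l^T x}}
#' and coefficients minimise the penalised negative log-likelihood with an
#' L1 penalty \eqn{\lambda \sum |\beta|} over all slope entries (intercepts
#' unpenalised).
#'
#' @param X numeric sample-by-feature matrix (finite values).
#' @param y labels with K >= 2 levels, every level present.
#' @param lambda penalty weight (>= 0).
#' @return an object of class \code{sparse_model}: \code{classes},
#'   \code{coefficients} (features x classes), \code{intercepts},
#'   \code{lambda}, \code{features}.
#' @export
fit_lasso_logistic <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- factor(as.character(y))
  if (nlevels(y) < 2) stop("y must have at least two classes")
  if (any(table(y) == 0)) stop("every class must be present in y")
  if (lambda < 0) stop("lambda must be >= 0")
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  # warm-start path ending exactly at the requested lambda
  lmax <- max(lambda_grid(X, y, nlambda = 3), lambda * 1.001)
  path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-5)), length.out = 20))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = fam, lambda = path,
                        standardize = FALSE, maxit = 300000)
  new_sparse_model(fit, lambda, levels(y), colnames(X))
}

new_sparse_model <- function(fit, lambda, classes, features) {
  # extract at the exact path position when present; interpolate otherwise
  idx <- which(abs(fit$lambda - lambda) <= 1e-12 * max(1, lambda))
  cf <- if (length(idx) == 1) suppressWarnings(coef(fit, s = fit$lambda[idx]))
        else suppressWarnings(coef(fit, s = lambda))
  K <- length(classes)
  m <- length(features)
  B <- matrix(0, m, K, dimnames = list(features, classes))
  b0 <- setNames(numeric(K), classes)
  if (is.list(cf)) {  # multinomial: one sparse column per class
    for (k in seq_len(K)) {
      col <- as.matrix(cf[[k]])
      b0[k] <- col[1]
      B[, k] <- col[-1]
    }
  } else {            # binomial: log-odds of the second level vs the first
    col <- as.matrix(cf)
    b0[2] <- col[1]
    B[, 2] <- col[-1]
  }
  structure(list(classes = classes, coefficients = B, intercepts = b0,
                 lambda = lambda, features = features),
            class = "sparse_model")
}

#' @export
#' @method print sparse_model
print.sparse_model <- function(x, ...) {
  cat(sprintf("<sparse_model> %d classes (%s), %d features, lambda=%.4g, %d selected\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              length(x$features), x$lambda, length(selected_features(x))))
  invisible(x)
}

#' Class probabilities from a sparse logistic model
#'
#' Softmax of the per-class linear scores; rows sum to 1.
#'
#' @param model a \code{sparse_model}.
#' @param X sample-by-feature matrix whose columns match the model features.
#' @return probability matrix, one column per class.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), model$features)) {
    if (is.null(colnames(X)) || !all(model$features %in% colnames(X)))
      stop("feature names of X do not match the model")
    X <- X[, model$features, drop = FALSE]
  }
  scores <- sweep(X %*% model$coefficients, 2, model$intercepts, "+")
  scores <- scores - apply(scores, 1, max)   # shift invariance, avoids overflow
  e <- exp(scores)
  p <- e / rowSums(e)
  colnames(p) <- model$classes
  rownames(p) <- rownames(X)
  p
}

#' @export
#' @method predict sparse_model
predict.sparse_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "class") object$classes[max.col(p, "first")] else p
}

#' Features with a nonzero coefficient
#'
#' @param model a \code{sparse_model}.
#' @param tol absolute tolerance below which a coefficient counts as zero.
#' @return character vector of selected feature names.
#' @export
selected_features <- function(model, tol = 1e-8) {
  model$features[rowSums(abs(model$coefficients) > tol) > 0]
}

#' Penalised negative log-likelihood of a sparse logistic model
#'
#' The fitting objective: mean negative log-likelihood plus
#' \eqn{\lambda \sum |\beta|} over slope entries.
#'
#' @param model a \code{sparse_model}.
#' @param X,y data the objective is evaluated on.
#' @param lambda penalty (default the model's own).
#' @return a single number.
#' @export
lasso_objective <- function(model, X, y, lambda = model$lambda) {
  p <- predict_proba(model, X)
  idx <- cbind(seq_along(y), match(as.character(y), model$classes))
  -mean(log(pmax(p[idx], 1e-300))) + lambda * sum(abs(model$coefficients))
}

#' Default descending lambda grid
#'
#' Log-spaced points from the smallest penalty that zeroes all slope
#' coefficients down a fixed number of decades. The maximal lambda follows
#' from the stationarity condition of the L1-penalised likelihood at the
#' intercept-only solution: \eqn{\lambda_{max} = \max_{j,k} |x_j'(y_k -
#' \bar p_k)| / N} with \eqn{\bar p_k} the class frequencies.
#'
#' @param X,y training data.
#' @param nlambda number of grid points (default 50).
#' @param decades decades spanned below the maximal lambda (default 4).
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, nlambda = 50, decades = 4) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  n <- nrow(X)
  Yind <- outer(as.integer(y), seq_len(nlevels(y)), function(a, b) (a == b) + 0)
  resid <- sweep(Yind, 2, colMeans(Yind), "-")
  lmax <- max(abs(crossprod(X, resid))) / n
  if (lmax <= 0) lmax <- 1e-3   # degenerate: constant features
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  small <- names(which(table(y) < folds))
  if (length(small))
    stop("class(es) with fewer samples than folds: ", paste(small, collapse = ", "))
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

macro_ovr_auroc <- function(y, proba) {
  classes <- colnames(proba)
  aucs <- vapply(classes, function(cl) {
    yt <- as.integer(y == cl)
    if (!any(yt == 1) || all(yt == 1)) return(NA_real_)
    roc_curve_auc(yt, proba[, cl])$auc
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Cross-validated lambda selection
#'
#' Stratified k-fold cross-validation; the per-lambda score is the mean
#' held-out macro one-vs-rest ROC area; the chosen lambda is the smallest
#' lambda attaining the maximal score. When \code{balance = TRUE} the
#' training folds are SMOTE-balanced inside each CV round while held-out
#' folds stay untouched, so synthetic samples never leak into the
#' validation side.
#'
#' @param X,y training data.
#' @param grid descending lambda grid (default \code{\link{lambda_grid}}).
#' @param folds fold count (default 5).
#' @param seed fold-assignment seed.
#' @param nlambda,decades grid construction parameters when \code{grid} is
#'   not supplied.
#' @param balance SMOTE-balance each training fold (default FALSE).
#' @param smote_k SMOTE neighbour count when balancing.
#' @return an object of class \code{cv_result}: \code{grid}, \code{score}
#'   per lambda, \code{lambda} (chosen), \code{seed}.
#' @export
cv_select_lambda <- function(X, y, grid = NULL, folds = 5, seed = 1L,
                             nlambda = 50, decades = 4, balance = FALSE,
                             smote_k = 5) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  if (is.null(grid)) grid <- lambda_grid(X, y, nlambda, decades)
  grid <- sort(grid, decreasing = TRUE)
  if (!length(grid)) stop("empty lambda grid")
  if (folds < 2) stop("folds must be >= 2")
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fold <- stratified_folds(y, folds, seed)
  scores <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (balance) {
      bal <- smote_balance(Xtr, as.character(ytr), k = smote_k,
                           seed = seed + 1000L * f)
      Xtr <- bal$features; ytr <- factor(bal$labels, levels = levels(y))
    }
    fit <- glmnet::glmnet(Xtr, ytr, family = fam,
                          lambda = grid, standardize = FALSE, maxit = 300000)
    pr <- predict(fit, X[!tr, , drop = FALSE], s = grid, type = "response")
    for (l in seq_along(grid)) {
      p <- if (fam == "multinomial") pr[, , l] else
        cbind(1 - pr[, l], pr[, l])
      colnames(p) <- levels(y)
      scores[f, l] <- macro_ovr_auroc(as.character(y[!tr]), p)
    }
  }
  mean_score <- colMeans(scores)
  best <- which(mean_score == max(mean_score))
  chosen <- min(grid[best])   # minimal lambda among the argmax set
  structure(list(grid = grid, score = mean_score, lambda = chosen,
                 folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d lambdas, %d folds; chosen lambda=%.4g (CV macro auROC %.4f)\n",
              length(x$grid), x$folds, x$lambda, max(x$score)))
  invisible(x)
}
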