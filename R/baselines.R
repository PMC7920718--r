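# Reference classifiers behind one fit/predict contract: RBF soft-margin
# SVM (deterministic SMO solver), K-nearest neighbors, linear discriminant
# analysis, and batch-gradient-descent logistic regression. All operate on
# standardized trial features with binary walk/idle labels; "walk" is the
# positive class.

#' Baseline classifier specification
#'
#' Defaults follow the comparison setup: SVM with RBF kernel, gamma 1,
#' C 2 and class weight 1.05 on the positive (walk) class; KNN with k = 5;
#' LDA with empirical priors; logistic regression fitted by batch gradient
#' descent with learning rate 0.01 for 300 iterations from zero weights.
#'
#' @param name One of `"svm"`, `"knn"`, `"lda"`, `"lr"`.
#' @param ... Named parameter overrides (svm: `gamma`, `C`, `weight`,
#'   `positive`; knn: `k`; lr: `alpha`, `iters`).
#' @export
baseline_spec <- function(name = c("svm", "knn", "lda", "lr"), ...) {
  name <- match.arg(name)
  params <- switch(name,
    svm = list(gamma = 1, C = 2, weight = 1.05, positive = "walk"),
    knn = list(k = 5),
    lda = list(),
    lr = list(alpha = 0.01, iters = 300)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0) {
    stop("unknown ", name, " parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(dots)] <- dots
  structure(list(name = name, params = params), class = "baseline_spec")
}

#' Fit a baseline classifier on a training fold and predict a test fold
#'
#' All four classifiers are deterministic given the data and spec: the SVM
#' dual is solved by maximal-violating-pair SMO, KNN and LDA have no
#' randomness, and LR starts from zero weights.
#'
#' @param spec A [baseline_spec()].
#' @param train,test `trial_feature_set`s (standardized; fit the transform
#'   on `train` only).
#' @return Character vector of predicted labels for `test`.
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "baseline_spec"),
            inherits(train, "trial_feature_set"))
  if (length(unique(train$y)) < 2) {
    stop("training fold contains a single class; cannot fit '",
         spec$name, "'", call. = FALSE)
  }
  Xtr <- train$X; ytr <- train$y
  Xte <- if (inherits(test, "trial_feature_set")) test$X else as.matrix(test)
  switch(spec$name,
         svm = svm_rbf_predict(Xtr, ytr, Xte, spec$params),
         knn = knn_predict(Xtr, ytr, Xte, spec$params$k),
         lda = lda_predict(Xtr, ytr, Xte),
         lr = lr_predict(Xtr, ytr, Xte, spec$params$alpha, spec$params$iters))
}

rbf_kernel <- function(A, B, gamma) {
  # exp(-gamma * ||a - b||^2), rows of A vs rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Deterministic SMO for the soft-margin SVM dual with per-sample C
# (class weighting). Working-set selection: maximal violating pair.
svm_smo <- function(K, y, Cvec, tol = 1e-6, max_iter = 50000L) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)  # gradient of 1/2 a'Qa - sum(a), Q = yy'K
  for (iter in seq_len(max_iter)) {
    yg <- -y * grad
    up <- (y > 0 & alpha < Cvec) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < Cvec)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(low)[which.min(yg[low])]
    if (yg[i] - yg[j] < tol) break
    # analytic step on the (i, j) pair
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 0) quad <- 1e-12
    delta <- (yg[i] - yg[j]) / quad
    # max feasible step along (y_i at i, -y_j at j) in alpha
    step_max_i <- if (y[i] > 0) Cvec[i] - alpha[i] else alpha[i]
    step_max_j <- if (y[j] > 0) alpha[j] else Cvec[j] - alpha[j]
    delta <- min(delta, step_max_i, step_max_j)
    if (delta <= 0) break
    alpha[i] <- alpha[i] + y[i] * delta
    alpha[j] <- alpha[j] - y[j] * delta
    grad <- grad + delta * y * (K[, i] - K[, j])
  }
  yg <- -y * grad
  up <- (y > 0 & alpha < Cvec) | (y < 0 & alpha > 0)
  low <- (y > 0 & alpha > 0) | (y < 0 & alpha < Cvec)
  # for any free SV, b = y_i - sum_j alpha_j y_j K_ij = yg_i at optimum
  b <- (max(yg[up]) + min(yg[low])) / 2
  list(alpha = alpha, b = b)
}

svm_rbf_predict <- function(Xtr, ytr, Xte, params) {
  classes <- sort(unique(ytr))
  pos <- if (params$positive %in% classes) params$positive else classes[2]
  y <- ifelse(ytr == pos, 1, -1)
  Cvec <- ifelse(y > 0, params$C * params$weight, params$C)
  K <- rbf_kernel(Xtr, Xtr, params$gamma)
  fit <- svm_smo(K, y, Cvec)
  Kte <- rbf_kernel(Xte, Xtr, params$gamma)
  f <- as.numeric(Kte %*% (fit$alpha * y)) + fit$b
  ifelse(f >= 0, pos, setdiff(classes, pos)[1])
}

knn_predict <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  an <- rowSums(Xte^2); bn <- rowSums(Xtr^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(Xte, Xtr)
  apply(d2, 1, function(d) {
    nb <- ytr[order(d)[seq_len(k)]]
    tab <- table(nb)
    names(tab)[which.max(tab)]  # first max: deterministic on vote ties
  })
}

# Two-class LDA with pooled covariance and empirical priors; pseudoinverse
# fallback when the pooled covariance is singular.
lda_predict <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  n <- nrow(Xtr)
  mus <- lapply(classes, function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  ns <- vapply(classes, function(cl) sum(ytr == cl), numeric(1))
  Sp <- Reduce(`+`, lapply(seq_along(classes), function(i) {
    Xc <- Xtr[ytr == classes[i], , drop = FALSE]
    crossprod(sweep(Xc, 2, mus[[i]]))
  })) / (n - length(classes))
  Sinv <- tryCatch(solve(Sp), error = function(e) {
    sv <- svd(Sp)
    pos <- sv$d > max(dim(Sp)) * .Machine$double.eps * sv$d[1]
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  disc <- vapply(seq_along(classes), function(i) {
    w <- Sinv %*% mus[[i]]
    as.numeric(Xte %*% w) - 0.5 * sum(mus[[i]] * w) + log(ns[i] / n)
  }, numeric(nrow(Xte)))
  disc <- rbind(disc)
  classes[apply(disc, 1, which.max)]
}

# Batch gradient descent on the mean logistic loss, zero initialization,
# no regularization; intercept included.
lr_fit <- function(Xtr, y01, alpha, iters) {
  Xb <- cbind(1, Xtr)
  w <- numeric(ncol(Xb))
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-as.numeric(Xb %*% w)))
    w <- w - alpha * as.numeric(crossprod(Xb, p - y01)) / nrow(Xb)
  }
  w
}

lr_predict <- function(Xtr, ytr, Xte, alpha, iters) {
  classes <- sort(unique(ytr))
  pos <- if ("walk" %in% classes) "walk" else classes[2]
  w <- lr_fit(Xtr, as.numeric(ytr == pos), alpha, iters)
  p <- 1 / (1 + exp(-as.numeric(cbind(1, Xte) %*% w)))
  ifelse(p >= 0.5, pos, setdiff(classes, pos)[1])
}
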