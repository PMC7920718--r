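# Class-dependent sparse representation classification (cdSRC): per-class
# orthogonal matching pursuit (cdOMP) reconstruction residuals fused with
# class-dependent K-nearest-neighbor (cdKNN) mean distances.

#' cdSRC hyperparameters
#'
#' @param sparsity Maximum OMP support size (default 10).
#' @param lambda Fusion weight on the normalized cdKNN distance (default
#'   0.05): fused score `s_c = r~_c + lambda * d~_c`, predicted class is the
#'   argmin.
#' @param K Neighbor count for cdKNN (default 5).
#' @export
cdsrc_params <- function(sparsity = 10, lambda = 0.05, K = 5) {
  stopifnot(sparsity >= 1, lambda >= 0, K >= 1)
  structure(list(sparsity = sparsity, lambda = lambda, K = K),
            class = "cdsrc_params")
}

# Least-squares coefficients of x on the columns Phi; pseudoinverse fallback
# for rank-deficient supports.
ls_coef <- function(Phi, x) {
  qrd <- qr(Phi)
  if (qrd$rank < ncol(Phi)) {
    sv <- svd(Phi)
    pos <- sv$d > max(dim(Phi)) * .Machine$double.eps * sv$d[1]
    return(sv$v[, pos, drop = FALSE] %*%
             ((crossprod(sv$u[, pos, drop = FALSE], x)) / sv$d[pos]))
  }
  qr.coef(qrd, x)
}

#' Class-dependent orthogonal matching pursuit
#'
#' Greedy sparse coding of `x` against one class's dictionary: initialize
#' the residual `e0 = x`; at each step select the unselected atom with the
#' largest absolute inner product with the current residual (ties broken by
#' lowest column index), recompute the orthogonal projector onto the span
#' of the selected atoms `P = Phi (Phi' Phi)^-1 Phi'`, and update
#' `e <- (I - P) e`. Stops when the support reaches `sparsity`, the
#' residual norm drops to `tol`, or all remaining inner products are zero.
#'
#' @param x Feature vector.
#' @param D Dictionary matrix, atoms as columns.
#' @param sparsity Maximum support size.
#' @param tol Residual-norm stopping tolerance (default 1e-10).
#' @return List: `support` (ordered atom indices), `coefficients`
#'   (least-squares weights on the final support), `residual_norm`,
#'   `residual_path` (norm after each iteration, non-increasing), and the
#'   final `residual` vector.
#' @export
cd_omp <- function(x, D, sparsity, tol = 1e-10) {
  stopifnot(all(is.finite(x)), is.matrix(D), ncol(D) >= 1,
            length(x) == nrow(D), sparsity >= 1)
  x <- as.numeric(x)
  e <- x
  support <- integer(0)
  path <- numeric(0)
  beta <- numeric(0)
  repeat {
    ip <- abs(as.numeric(crossprod(D, e)))
    ip[support] <- -Inf
    j <- which.max(ip)        # first maximum = lowest index on ties
    if (!is.finite(ip[j]) || ip[j] == 0) break
    support <- c(support, j)
    Phi <- D[, support, drop = FALSE]
    beta <- ls_coef(Phi, x)
    e <- x - as.numeric(Phi %*% beta)
    path <- c(path, sqrt(sum(e^2)))
    if (length(support) >= sparsity || path[length(path)] <= tol) break
  }
  list(support = support, coefficients = as.numeric(beta),
       residual_norm = if (length(path)) path[length(path)] else sqrt(sum(x^2)),
       residual_path = path, residual = e)
}

#' Class-dependent KNN distance
#'
#' Mean of the `K` smallest Euclidean distances from `x` to one class's
#' training vectors (`K` clipped to the class size).
#'
#' @param x Feature vector.
#' @param class_train Matrix with training vectors as columns.
#' @param K Neighbor count.
#' @return Scalar distance.
#' @export
cd_knn_distance <- function(x, class_train, K) {
  stopifnot(is.matrix(class_train), ncol(class_train) >= 1, K >= 1)
  d <- sqrt(colSums((class_train - as.numeric(x))^2))
  mean(sort(d)[seq_len(min(K, length(d)))])
}

#' Fit a class dictionary for cdSRC
#'
#' Stores, per class, the training feature vectors both raw (for cdKNN)
#' and as unit l2-norm columns (for cdOMP), plus the column norms. Classes
#' are ordered by `sort(unique(y))`; ties in classification resolve to the
#' earlier class in this order.
#'
#' @param train A `trial_feature_set` (standardize first; see
#'   [standardize_features()]).
#' @param params A [cdsrc_params()].
#' @return A `cdsrc_model`.
#' @export
cdsrc_fit <- function(train, params = cdsrc_params()) {
  stopifnot(inherits(train, "trial_feature_set"))
  classes <- sort(unique(train$y))
  need <- max(params$sparsity, params$K)
  dicts <- lapply(classes, function(cl) {
    Xc <- t(train$X[train$y == cl, , drop = FALSE])  # features x trials
    if (ncol(Xc) < need) {
      stop("class '", cl, "' has ", ncol(Xc), " trials; cdSRC needs at least ",
           need, " (max of sparsity and K)", call. = FALSE)
    }
    nrm <- sqrt(colSums(Xc^2))
    if (any(nrm == 0)) {
      stop("class '", cl, "' contains an all-zero training vector; cannot ",
           "normalize dictionary column", call. = FALSE)
    }
    list(raw = Xc, normalized = sweep(Xc, 2, nrm, "/"), norms = nrm)
  })
  names(dicts) <- classes
  structure(list(classes = classes, dicts = dicts, params = params,
                 p = ncol(train$X), format_version = 1L),
            class = "cdsrc_model")
}

cdsrc_score_one <- function(x, model) {
  p <- model$params
  r <- vapply(model$dicts, function(d) {
    cd_omp(x, d$normalized, p$sparsity)$residual_norm
  }, numeric(1))
  # residuals at numerical-noise level are exact reconstructions; clamp so
  # their ratios don't inject rounding noise into the fused score
  r[r <= 1e-8 * max(1, sqrt(sum(x^2)))] <- 0
  dd <- vapply(model$dicts, function(d) {
    cd_knn_distance(x, d$raw, p$K)
  }, numeric(1))
  norm_sum <- function(v) if (sum(v) == 0) rep(1 / length(v), length(v)) else v / sum(v)
  s <- norm_sum(r) + p$lambda * norm_sum(dd)
  names(s) <- model$classes
  s
}

#' Predict with a cdSRC model
#'
#' For each row of `newdata$X`, computes per-class cdOMP residual norms and
#' cdKNN distances, normalizes each across classes to unit sum (all-zero
#' vectors normalize to uniform), fuses as `s_c = r~_c + lambda * d~_c`,
#' and predicts the class with the smallest fused score (ties go to the
#' first class in the model's class order).
#'
#' @param object A `cdsrc_model`.
#' @param newdata A `trial_feature_set` standardized with the training
#'   transform, or a numeric matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels, with a `"scores"`
#'   attribute (rows = samples, columns = classes, fused scores).
#' @export
predict.cdsrc_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "trial_feature_set")) newdata$X else as.matrix(newdata)
  if (ncol(X) != object$p) {
    stop("feature dimension ", ncol(X), " does not match dictionary (",
         object$p, ")", call. = FALSE)
  }
  scores <- t(apply(X, 1, cdsrc_score_one, model = object))
  labels <- object$classes[apply(scores, 1, which.min)]
  attr(labels, "scores") <- scores
  labels
}

#' Save / load a cdSRC model as portable JSON
#'
#' @param model A `cdsrc_model`.
#' @param path File path.
#' @export
cdsrc_save <- function(model, path) {
  obj <- list(format_version = model$format_version,
              classes = model$classes, p = model$p,
              params = unclass(model$params),
              dicts = lapply(model$dicts, function(d)
                list(raw = d$raw, norms = d$norms)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname cdsrc_save
#' @export
cdsrc_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dicts <- lapply(obj$dicts, function(d) {
    raw <- as.matrix(d$raw)
    list(raw = raw, normalized = sweep(raw, 2, d$norms, "/"),
         norms = d$norms)
  })
  structure(list(classes = obj$classes, dicts = dicts,
                 params = do.call(cdsrc_params, as.list(obj$params)),
                 p = obj$p, format_version = obj$format_version),
            class = "cdsrc_model")
}
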