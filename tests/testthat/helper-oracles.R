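# Independent oracles and small fixture builders shared across the suite.
# Every oracle re-derives its answer by a different route than the package
# code it checks (normal equations instead of QR, brute-force sorting,
# closed-form analog response, exact sign-pattern enumeration).

# Wrap a plain matrix + labels as a trial_feature_set.
make_fset <- function(X, y) {
  structure(list(X = as.matrix(X), y = y,
                 feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X))),
                 window = window_spec(), codes = "M"),
            class = "trial_feature_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# From-scratch OMP: re-solves the normal equations Phi'Phi b = Phi'x at
# every iteration (no QR, no projector reuse).
oracle_omp <- function(x, D, sparsity, tol = 1e-10) {
  e <- x; support <- integer(0); path <- numeric(0)
  repeat {
    ip <- abs(t(D) %*% e)
    ip[support] <- -Inf
    j <- which.max(ip)
    if (ip[j] <= 0) break
    support <- c(support, j)
    Phi <- D[, support, drop = FALSE]
    G <- t(Phi) %*% Phi
    b <- solve(G, t(Phi) %*% x)
    e <- x - Phi %*% b
    path <- c(path, sqrt(sum(e^2)))
    if (length(support) >= sparsity || path[length(path)] <= tol) break
  }
  list(support = support, residual_path = path)
}

# Brute-force cdKNN distance: all pairwise distances, full sort, average.
oracle_knn_dist <- function(x, M, K) {
  d <- apply(M, 2, function(col) sqrt(sum((col - x)^2)))
  mean(sort(d)[seq_len(min(K, length(d)))])
}

# Closed-form squared magnitude of the analog first-order band-pass
# Butterworth applied forward-backward: |H(j 2 pi f)|^2 with
# H(s) = B s / (s^2 + B s + w0^2), B = wh - wl, w0^2 = wl wh.
analog_bp_gain_fb <- function(f, low, high) {
  w <- 2 * pi * f; wl <- 2 * pi * low; wh <- 2 * pi * high
  B <- wh - wl; w0sq <- wl * wh
  (B * w)^2 / ((w0sq - w^2)^2 + (B * w)^2)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# on the average ranks of |d| (handles ties via midranks).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ew <- sum(r) / 2
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
  }, numeric(1))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
}

# Friedman chi-square by the rank-sum formula (no ties assumed):
# 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1), Rj = column rank sums.
oracle_friedman_stat <- function(m) {
  rk <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(rk)^2) - 3 * n * (k + 1)
}

# RMS of the central portion of a signal (transient-free region).
central_rms <- function(x, frac = 0.5) {
  n <- length(x)
  i0 <- floor(n * (1 - frac) / 2) + 1
  sqrt(mean(x[i0:(i0 + floor(n * frac) - 1)]^2))
}

# Build a hemo_recording directly from hbo/hbr matrices and a schedule.
make_hemo <- function(hbo, hbr, schedule) {
  structure(list(sample_rate = schedule$sample_rate, hbo = hbo, hbr = hbr,
                 channel_ids = sprintf("ch%02d", seq_len(nrow(hbo))),
                 schedule = schedule, ground_truth = NULL),
            class = "hemo_recording")
}
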