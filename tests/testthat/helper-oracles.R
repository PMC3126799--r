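# Independent oracles used to verify the package's core computations.

# mean pairwise cosine by explicit double loop
bruteReproducibility <- function(X) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- acc + sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  2 * acc / (n * (n - 1))
}

bruteAverageNorm <- function(X) {
  mean(apply(X, 1, function(v) sqrt(sum(v^2))))
}

# minimum L1 norm subject to ||Aw - y||_inf <= eps by vertex enumeration:
# a vertex has support size k with k residual constraints active at +-eps
bruteL1Ineq <- function(A, y, eps) {
  m <- nrow(A); n <- ncol(A)
  if (max(abs(y)) <= eps + 1e-12) return(0)
  best <- Inf
  for (k in seq_len(min(m, n))) {
    supports <- utils::combn(n, k, simplify = FALSE)
    actives <- utils::combn(m, k, simplify = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    for (S in supports) for (E in actives) {
      M <- A[E, S, drop = FALSE]
      if (abs(det(M)) < 1e-10) next
      for (si in seq_len(nrow(signs))) {
        w <- solve(M, y[E] + eps * signs[si, ])
        r <- A[, S, drop = FALSE] %*% w - y
        if (max(abs(r)) <= eps + 1e-7) best <- min(best, sum(abs(w)))
      }
    }
  }
  best
}

# minimum L1 norm subject to Aw = y by support enumeration
bruteL1Eq <- function(A, y) {
  m <- nrow(A); n <- ncol(A)
  best <- Inf
  for (k in seq_len(min(m, n))) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      w <- tryCatch(qr.coef(qr(As), y), error = function(e) NULL)
      if (is.null(w) || anyNA(w)) next
      if (max(abs(As %*% w - y)) <= 1e-8) best <- min(best, sum(abs(w)))
    }
  }
  best
}

# exact signed-rank p-values by enumeration of all 2^n sign assignments
bruteWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  picks <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(picks %*% r)
  mu <- sum(r) / 2
  list(statistic = W,
       greater = mean(Ws >= W - 1e-9),
       less = mean(Ws <= W + 1e-9),
       two = min(1, mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)))
}

# repeated-measures F by explicit sum-of-squares decomposition
bruteRmAnovaF <- function(mat) {
  n <- nrow(mat); k <- ncol(mat); g <- mean(mat)
  ssCond <- n * sum((colMeans(mat) - g)^2)
  ssSubj <- k * sum((rowMeans(mat) - g)^2)
  ssErr <- sum((mat - g)^2) - ssCond - ssSubj
  (ssCond / (k - 1)) / (ssErr / ((k - 1) * (n - 1)))
}
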