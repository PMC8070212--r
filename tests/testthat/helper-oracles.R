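# Independent oracle implementations, written from first principles and kept
# separate from the package code paths they check.

# negative-binomial GLM (log link, known theta) by hand-rolled IRLS on the
# normal equations; no glm.fit machinery.
irls_nb_oracle <- function(y, x, offset, theta, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.5) - mean(offset), rep(0, ncol(x) - 1))
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta) + offset
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)          # 1 / (V(mu) * g'(mu)^2), V = mu + mu^2/theta
    z <- (eta - offset) + (y - mu) / mu # working response minus offset
    xtwx <- t(x) %*% (w * x)
    xtwz <- t(x) %*% (w * z)
    beta_new <- drop(solve(xtwx, xtwz))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(x %*% beta) + offset
  mu <- exp(eta)
  w <- mu / (1 + mu / theta)
  list(coefficients = beta, cov = solve(t(x) %*% (w * x)))
}

# polynomial least squares through the raw normal equations
normal_eq_poly <- function(t, y, degree) {
  x <- outer(t, 0:degree, "^")
  solve(t(x) %*% x, t(x) %*% y)[, 1]
}

# two-proportion pooled z statistic, written out
z_two_prop_oracle <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# exhaustive minimum spanning tree over <= 7 nodes: enumerate all edge
# subsets of size n-1, keep connected acyclic ones, return minimal weight
mst_exhaustive_weight <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 7)
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  best <- Inf
  for (subset in utils::combn(m, n - 1, simplify = FALSE)) {
    e <- pairs[, subset, drop = FALSE]
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (j in seq_len(ncol(e))) {
      a <- find(e[1, j]); b <- find(e[2, j])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (!acyclic) next
    w <- sum(d[t(e)])
    if (w < best) best <- w
  }
  best
}
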