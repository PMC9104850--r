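#' Exact t-SNE for small point sets
#'
#' A compact exact (O(n^2) per iteration) t-distributed stochastic neighbor
#' embedding: Gaussian input affinities calibrated per point to the target
#' perplexity by bisection on the bandwidth, symmetrized and normalized;
#' Student-t (df 1) output affinities; gradient descent with momentum and
#' early exaggeration. Intended for the handful of bulk samples plus a
#' centroid this package embeds, not for large matrices.
#'
#' Degenerate inputs are tolerated: points at identical positions get
#' uniform affinities, and perplexities whose entropy target is unreachable
#' saturate at the bisection bounds.
#'
#' @param X points x features numeric matrix.
#' @param perplexity target perplexity (> 0); must satisfy
#'   `perplexity <= (n - 1) / 3`.
#' @param seed integer seed for the random initialization.
#' @param max_iter iterations (default 500).
#' @param eta learning rate (default 100).
#' @return n x 2 coordinate matrix (centered).
#' @export
tsne_exact <- function(X, perplexity = 2, seed = 1, max_iter = 500,
                       eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  .assert(n >= 3, "need at least 3 points")
  .assert(perplexity > 0, "perplexity must be > 0")
  .assert(perplexity <= (n - 1) / 3,
          "perplexity too large for %d points; choose <= %.2f", n, (n - 1) / 3)

  d2 <- as.matrix(dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) {  # all mass collapsed; shrink beta
        hi <- beta; beta <- (lo + hi) / 2; next
      }
      p <- w / sw
      h <- -sum(ifelse(p > 0, p * log(p), 0))   # Shannon entropy (nats)
      if (abs(h - target) < 1e-7) break
      if (h > target) lo <- beta else hi <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    }
    w <- exp(-di * beta)
    p <- if (sum(w) > 0) w / sum(w) else rep(1 / (n - 1), n - 1)
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    qd <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(qd) <- 0
    Q <- pmax(qd / sum(qd), 1e-12)
    W <- (ex * P - Q) * qd
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  dimnames(Y) <- list(rownames(X), c("tsne1", "tsne2"))
  Y
}
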