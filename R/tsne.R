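## Exact t-SNE on a precomputed dissimilarity matrix. O(n^2) per iteration,
## intended for report-scale inputs (n up to a few thousand). Deterministic
## for a fixed seed. Standard ingredients: per-point precision calibrated to
## the target perplexity by bisection, symmetrized input affinities, Student-t
## low-dimensional kernel, early exaggeration and momentum gradient descent.

.tsne <- function(D, perplexity = 30, seed = 1L, n_iter = 400L,
                  momentum = c(0.5, 0.8), exaggeration = 4,
                  exaggerate_until = 100L, eta = 100) {
  n <- nrow(D)
  D2 <- D^2
  log_perp <- log(perplexity)

  ## calibrate conditional affinities row by row
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 10; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - log_perp) < 1e-5) break
      if (h > log_perp) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (beta + hi) / 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- .with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= exaggerate_until) Pex else P
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= exaggerate_until) momentum[1] else momentum[2]
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
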