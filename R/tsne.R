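# Exact t-SNE (quadratic-cost variant), sufficient for the cohort sizes this
# package embeds (a few thousand points). Perplexity calibration by per-point
# bisection on the Gaussian precision; optimization by gradient descent with
# early exaggeration, momentum and adaptive per-coordinate gains.

# Row-normalized conditional affinities at the requested perplexity.
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf; beta_max <- Inf
    Di <- D2[i, -i]
    for (try in seq_len(max_tries)) {
      W <- exp(-Di * beta)
      sumW <- sum(W)
      if (sumW == 0) { W <- rep(1e-12, length(Di)); sumW <- sum(W) }
      H <- log(sumW) + beta * sum(Di * W) / sumW
      if (abs(H - logU) < tol) break
      if (H > logU) {           # entropy too high -> narrow the kernel
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- W / sumW
  }
  P
}

#' Two-dimensional t-SNE embedding
#'
#' Exact (non-approximate) t-Distributed Stochastic Neighbor Embedding of the
#' rows of `X` into 2-D, deterministic for a fixed seed. Early exaggeration
#' (factor 12, first 250 iterations), momentum 0.5 rising to 0.8, and
#' adaptive gains follow the reference optimization schedule.
#'
#' @param X numeric matrix (points x dims), e.g. a latent matrix.
#' @param perplexity effective neighborhood size; must satisfy
#'   `3 * perplexity < n - 1`.
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed integer RNG seed for the initial layout.
#' @param learning_rate gradient step size.
#' @return numeric matrix (n x 2) of embedding coordinates, rownames
#'   preserved.
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 1000, seed = 1,
                       learning_rate = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (3 * perplexity >= n - 1) {
    stop("perplexity too large for n = ", n, " points")
  }
  D2 <- sq_dist_to(X, X)
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  # early exaggeration for the first quarter of the run (capped at 250), so
  # short runs still get a refinement phase
  exag_until <- min(250, max_iter %/% 4)
  Pe <- P * 12

  for (iter in seq_len(max_iter)) {
    Pt <- if (iter <= exag_until) Pe else P
    num <- 1 / (1 + sq_dist_to(Y, Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pt - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    momentum <- if (iter <= exag_until) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("x", "y")
  Y
}
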