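# Independent brute-force oracles for clustering and validity indices.
# These recompute every quantity from its definition with plain loops,
# deliberately sharing no code with the package implementations.

# Ward agglomeration by exhaustive search: at each step evaluate the exact
# increase in total within-cluster sum of squares for every cluster pair and
# merge the minimum (ties: smallest min-id, then max-id). Returns the list of
# partitions indexed by number of clusters (n down to 1).
oracle_ward_partitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- vector("list", n)
  labels <- seq_len(n)
  partitions[[n]] <- labels
  wss <- function(idx) {
    if (length(idx) == 1) return(0)
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; best_cost <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        cost <- wss(c(clusters[[i]], clusters[[j]])) -
          wss(clusters[[i]]) - wss(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    labels <- integer(n)
    for (c_i in seq_along(clusters)) labels[clusters[[c_i]]] <- c_i
    partitions[[length(clusters)]] <- labels
  }
  partitions
}

# Silhouette from the definition, one sample at a time.
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == g]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Davies-Bouldin from the definition.
oracle_davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]))
  scat <- vapply(seq_along(ks), function(gi) {
    M <- X[labels == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2, cent[[gi]])^2)))
  }, 0)
  total <- 0
  for (i in seq_along(ks)) {
    worst <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / dij)
    }
    total <- total + worst
  }
  total / length(ks)
}

# Spherical-Gaussian BIC by direct likelihood summation.
oracle_bic <- function(X, labels) {
  n <- nrow(X); d <- ncol(X)
  ks <- sort(unique(labels))
  k <- length(ks)
  cent <- lapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]))
  rss <- 0
  for (i in seq_len(n)) {
    mu <- cent[[match(labels[i], ks)]]
    rss <- rss + sum((X[i, ] - mu)^2)
  }
  sigma2 <- max(rss / (d * max(n - k, 1)), 1e-9)
  ll <- 0
  for (i in seq_len(n)) {
    mu <- cent[[match(labels[i], ks)]]
    ni <- sum(labels == labels[i])
    ll <- ll + log(ni / n) - d / 2 * log(2 * pi * sigma2) -
      sum((X[i, ] - mu)^2) / (2 * sigma2)
  }
  -2 * ll + (k * d + k) * log(n)
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}
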