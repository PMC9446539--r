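# Squared Euclidean distances from rows of X to rows of C.
sq_dist_to <- function(X, C) {
  # ||x||^2 - 2 x.c + ||c||^2, clamped at 0 against rounding
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

# k-means++ initial centroids (advances the RNG).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- sq_dist_to(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, sq_dist_to(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' k-means clustering of latent representations
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ seeding; the best
#' of `n_restarts` seeded runs by within-cluster sum of squares (inertia) is
#' returned. Iterations stop when assignments stabilize or after `max_iter`
#' rounds. Empty clusters are re-seeded at the point farthest from its
#' centroid.
#'
#' @param H numeric matrix (patients x d).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @param n_restarts number of independent initializations.
#' @param max_iter Lloyd iteration cap per restart.
#' @return a `clustering_solution`: `labels` (1..k), `n_k`, `method`,
#'   `centroids` (k x d), `inertia`, and `inertia_trace` (per-iteration
#'   inertia of the winning restart).
#' @export
kmeans_cluster <- function(H, k, seed = 1, n_restarts = 10, max_iter = 300) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    C <- kmeanspp_init(H, k)
    labels <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- sq_dist_to(H, C)
      new_labels <- max.col(-d2, ties.method = "first")
      trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
      for (j in seq_len(k)) {
        members <- which(new_labels == j)
        if (length(members) == 0) {
          far <- which.max(d2[cbind(seq_len(n), new_labels)])
          new_labels[far] <- j
          members <- far
        }
        C[j, ] <- colMeans(H[members, , drop = FALSE])
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    d2 <- sq_dist_to(H, C)
    inertia <- sum(d2[cbind(seq_len(n), labels)])
    if (is.null(best) || inertia < best$inertia) {
      best <- list(labels = labels, centroids = C, inertia = inertia,
                   inertia_trace = trace)
    }
  }
  structure(list(labels = best$labels, n_k = as.integer(k),
                 method = "kmeans", centroids = best$centroids,
                 inertia = best$inertia, inertia_trace = best$inertia_trace),
            class = "clustering_solution")
}

#' Ward-linkage agglomerative hierarchical clustering
#'
#' Agglomeration from singletons under the Ward criterion (each merge
#' minimizes the increase in total within-cluster variance), computed via
#' [stats::hclust()] with `method = "ward.D2"` on Euclidean distances, and cut
#' at `k` clusters. The merge history (pair merged and linkage height) is
#' retained.
#'
#' @param H numeric matrix (patients x d).
#' @param k number of clusters, `1 <= k <= n`.
#' @return a `clustering_solution` with `labels`, `n_k`, `method`,
#'   `merge_history` (data.frame `a`, `b`, `height` in hclust convention) and
#'   the `hclust` tree.
#' @export
ahc_ward <- function(H, k) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n)
  hc <- stats::hclust(stats::dist(H), method = "ward.D2")
  labels <- as.integer(stats::cutree(hc, k = k))
  structure(list(labels = labels, n_k = as.integer(k), method = "ahc_ward",
                 merge_history = data.frame(a = hc$merge[, 1],
                                            b = hc$merge[, 2],
                                            height = hc$height),
                 tree = hc),
            class = "clustering_solution")
}

#' @export
print.clustering_solution <- function(x, ...) {
  cat("Clustering (", x$method, "), k =", x$n_k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

check_labels <- function(labels, n) {
  labels <- as.integer(as.factor(labels))
  if (length(labels) != n) stop("labels length does not match data")
  labels
}

#' Mean silhouette coefficient
#'
#' For each sample, `(b - a) / max(a, b)` with `a` the mean distance to its
#' own cluster's other members and `b` the smallest mean distance to another
#' cluster; members of singleton clusters contribute 0. Values lie in
#' \[-1, 1\], higher meaning tighter, better-separated clusters.
#'
#' @param H numeric matrix (patients x d).
#' @param labels cluster assignment per row.
#' @param dmat optional precomputed full distance matrix (reused across k).
#' @return scalar mean silhouette.
#' @export
silhouette_score <- function(H, labels, dmat = NULL) {
  H <- as.matrix(H)
  n <- nrow(H)
  labels <- check_labels(labels, n)
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster")
  if (n < 3) stop("silhouette needs n >= 3")
  if (is.null(dmat)) dmat <- as.matrix(stats::dist(H))
  sizes <- tabulate(labels, k)
  member <- matrix(0, n, k)
  member[cbind(seq_len(n), labels)] <- 1
  sums <- dmat %*% member                      # n x k total distance to each cluster
  a <- sums[cbind(seq_len(n), labels)] / pmax(sizes[labels] - 1, 1)
  mean_to <- sweep(sums, 2, sizes, "/")
  mean_to[cbind(seq_len(n), labels)] <- Inf
  b <- apply(mean_to, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of `max_{j != i} (s_i + s_j) / d_ij`, with `s_i` the
#' mean Euclidean distance of members to their centroid and `d_ij` the
#' centroid separation; smaller is better. Coincident centroids yield an
#' infinite index with a warning.
#'
#' @inheritParams silhouette_score
#' @return scalar index, >= 0 (possibly `Inf`).
#' @export
davies_bouldin <- function(H, labels) {
  H <- as.matrix(H)
  labels <- check_labels(labels, nrow(H))
  k <- max(labels)
  if (k < 2) stop("Davies-Bouldin undefined for a single cluster")
  C <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(H[labels == j, , drop = FALSE])
  }))
  s <- vapply(seq_len(k), function(j) {
    mean(sqrt(sq_dist_to(H[labels == j, , drop = FALSE],
                         C[j, , drop = FALSE])))
  }, 0)
  dc <- sqrt(sq_dist_to(C, C))
  R <- outer(s, s, "+") / dc
  diag(R) <- -Inf
  worst <- apply(R, 1, max)
  if (any(!is.finite(worst))) {
    warning("coincident centroids: Davies-Bouldin index is infinite")
  }
  mean(worst)
}

#' BIC of a clustering solution (spherical-Gaussian formulation)
#'
#' Scores the partition as a spherical Gaussian mixture with one pooled
#' variance (the x-means formulation): `-2 log L + p log n` with
#' `p = k d + k` free parameters (k centroids, k - 1 mixing weights, one
#' variance). Lower is better. A variance floor guards degenerate
#' single-point clusters.
#'
#' @param H numeric matrix (patients x d).
#' @param solution a `clustering_solution`, or a label vector.
#' @param var_floor lower bound on the pooled variance.
#' @return scalar BIC.
#' @export
bic_clustering <- function(H, solution, var_floor = 1e-9) {
  H <- as.matrix(H)
  labels <- if (inherits(solution, "clustering_solution")) solution$labels else solution
  labels <- check_labels(labels, nrow(H))
  n <- nrow(H); d <- ncol(H); k <- max(labels)
  C <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(H[labels == j, , drop = FALSE])
  }))
  rss <- sum((H - C[labels, , drop = FALSE])^2)
  sigma2 <- max(rss / (d * max(n - k, 1)), var_floor)
  sizes <- tabulate(labels, k)
  loglik <- sum(sizes * log(sizes)) - n * log(n) -
    n * d / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
  p <- k * d + k
  -2 * loglik + p * log(n)
}

#' Elbow point of a decreasing index curve
#'
#' Picks the k with the greatest curvature, measured by the second forward
#' difference `v[k-1] - 2 v[k] + v[k+1]` over interior points of a curve
#' evaluated on consecutive k; ties break toward smaller k. A curve with no
#' positive curvature (e.g. linear) returns the smallest interior k with a
#' warning that no clear elbow exists.
#'
#' @param values numeric vector of the index at each k.
#' @param k integer vector of the (consecutive) k values; defaults to
#'   `seq_along(values) + 1`.
#' @return the selected k.
#' @export
elbow_point <- function(values, k = seq_along(values) + 1) {
  stopifnot(length(values) == length(k))
  if (length(values) < 3) stop("elbow point needs at least 3 values")
  if (any(diff(k) != 1)) stop("k values must be consecutive")
  i <- 2:(length(values) - 1)
  curv <- values[i - 1] - 2 * values[i] + values[i + 1]
  if (max(curv) <= 1e-12) {
    warning("no clear elbow: curve has no positive curvature")
    return(k[i[1]])
  }
  k[i[which.max(curv)]]
}

#' Cluster-validity-index table and cluster-number selection
#'
#' Computes silhouette, Davies-Bouldin and BIC for each k in `k_range` and
#' each clustering method, then selects k* by majority vote among the
#' preferred method's silhouette argmax, Davies-Bouldin argmin and BIC elbow;
#' when all three disagree the silhouette's choice wins, and remaining ties
#' break toward smaller k.
#'
#' @param H numeric matrix (patients x d).
#' @param k_range integer vector of consecutive candidate k (within
#'   \[2, n - 1\]).
#' @param methods clustering methods to tabulate.
#' @param prefer method whose indices drive the vote.
#' @param seed RNG seed for k-means restarts.
#' @return list with `k_star`, `votes` (named selections of the three
#'   indices), and `cvi_table` (data.frame `k`, `method`, `silhouette`,
#'   `davies_bouldin`, `bic`).
#' @export
select_n_clusters <- function(H, k_range = 2:10,
                              methods = c("ahc_ward", "kmeans"),
                              prefer = "ahc_ward", seed = 1) {
  H <- as.matrix(H)
  n <- nrow(H)
  k_range <- as.integer(k_range)
  if (length(k_range) == 0) stop("empty k range")
  stopifnot(min(k_range) >= 2, max(k_range) <= n - 1, prefer %in% methods)
  dmat <- as.matrix(stats::dist(H))
  tree <- if ("ahc_ward" %in% methods) {
    stats::hclust(stats::as.dist(dmat), method = "ward.D2")
  }
  rows <- list()
  for (method in methods) {
    for (k in k_range) {
      labels <- if (method == "ahc_ward") {
        as.integer(stats::cutree(tree, k = k))
      } else {
        kmeans_cluster(H, k, seed = seed)$labels
      }
      rows[[length(rows) + 1]] <- data.frame(
        k = k, method = method,
        silhouette = silhouette_score(H, labels, dmat = dmat),
        davies_bouldin = davies_bouldin(H, labels),
        bic = bic_clustering(H, labels))
    }
  }
  tab <- do.call(rbind, rows)
  pref <- tab[tab$method == prefer, ]
  pref <- pref[order(pref$k), ]
  votes <- c(silhouette = pref$k[which.max(pref$silhouette)],
             davies_bouldin = pref$k[which.min(pref$davies_bouldin)],
             bic = suppressWarnings(elbow_point(pref$bic, pref$k)))
  counts <- table(votes)
  k_star <- if (max(counts) >= 2) {
    min(as.integer(names(counts)[counts == max(counts)]))
  } else {
    votes[["silhouette"]]
  }
  list(k_star = as.integer(k_star), votes = votes, cvi_table = tab)
}
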