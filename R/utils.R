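#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Match clusters to reference groups by maximum overlap
#'
#' Exhaustive one-to-one assignment (over permutations; intended for small k)
#' maximizing the total contingency-table overlap between cluster labels and
#' reference group labels.
#'
#' @param cluster_labels,group_labels label vectors of equal length.
#' @return data.frame mapping each `cluster` to its matched `group` with the
#'   `overlap` count. When the label sets differ in size, the smaller side is
#'   matched injectively into the larger.
#' @export
match_clusters <- function(cluster_labels, group_labels) {
  tab <- unclass(table(cluster_labels, group_labels))
  transposed <- nrow(tab) > ncol(tab)
  if (transposed) tab <- t(tab)
  r <- nrow(tab); c <- ncol(tab)
  if (r > 8) stop("exhaustive matching supports at most 8 clusters/groups")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  best <- NULL; best_score <- -Inf
  for (p in perms(seq_len(c))) {
    sel <- p[seq_len(r)]
    score <- sum(tab[cbind(seq_len(r), sel)])
    if (score > best_score) { best_score <- score; best <- sel }
  }
  out <- data.frame(cluster = rownames(tab), group = colnames(tab)[best],
                    overlap = tab[cbind(seq_len(r), best)],
                    stringsAsFactors = FALSE)
  if (transposed) names(out)[1:2] <- c("group", "cluster")
  rownames(out) <- NULL
  out[, c("cluster", "group", "overlap")]
}
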