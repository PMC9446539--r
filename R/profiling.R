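#' Presence-rate profile of a patient subset
#'
#' The profile of a subset is the per-code proportion of its patients carrying
#' the code: the column means of the binary sub-matrix, a vector over the full
#' vocabulary in \[0, 1\].
#'
#' @param X binary matrix (patients x D) restricted to the subset, or a
#'   `cohort`.
#' @param vocab the [code_vocabulary()] (taken from the cohort if omitted).
#' @param subset_id label for the subset (cluster or CRG name).
#' @return an object of class `profile`: list with `rates` (named numeric,
#'   length D), `family`, `n_patients`, `subset_id`.
#' @export
compute_profile <- function(X, vocab = NULL, subset_id = NA_character_) {
  if (inherits(X, "cohort")) {
    vocab <- X$vocab
    X <- X$X
  }
  if (!is.matrix(X)) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  stopifnot(inherits(vocab, "code_vocabulary"), ncol(X) == vocab$D)
  if (nrow(X) == 0) stop("cannot profile an empty subset")
  rates <- colMeans(X)
  names(rates) <- vocab$codes
  structure(list(rates = rates, family = vocab_family(vocab),
                 n_patients = nrow(X), subset_id = subset_id, vocab = vocab),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("Profile", if (!is.na(x$subset_id)) paste0("'", x$subset_id, "'"),
      "over", x$n_patients, "patients;",
      sum(x$rates > 0.25), "codes with presence rate > 0.25\n")
  invisible(x)
}

#' Top codes of a profile, per family
#'
#' The `per_family_k` codes with the highest presence rate, separately within
#' the diagnosis and drug families, in descending rate; exact ties break
#' lexicographically by code.
#'
#' @param profile a [compute_profile()] result.
#' @param per_family_k how many codes per family (default 5).
#' @return data.frame with columns `code`, `family`, `rate`.
#' @export
top_codes <- function(profile, per_family_k = 5) {
  stopifnot(inherits(profile, "profile"))
  pick <- function(fam) {
    r <- profile$rates[profile$family == fam]
    r <- r[order(-r, names(r))]
    k <- min(per_family_k, length(r))
    data.frame(code = names(r)[seq_len(k)], family = fam,
               rate = unname(r[seq_len(k)]))
  }
  out <- rbind(pick("diagnosis"), pick("drug"))
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two profiles
#'
#' Computed separately over the diagnosis block and the drug block (the
#' two-value convention used when comparing cluster profiles to CRG
#' profiles), plus the whole-vector value.
#'
#' @param p,q [compute_profile()] results over the same vocabulary.
#' @return named numeric vector `c(diagnosis =, drug =, all =)`.
#' @export
profile_pcc <- function(p, q) {
  stopifnot(inherits(p, "profile"), inherits(q, "profile"),
            identical(names(p$rates), names(q$rates)))
  block_cor <- function(keep) {
    a <- p$rates[keep]; b <- q$rates[keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("profile_pcc: zero-variance block, correlation undefined")
    }
    stats::cor(a, b)
  }
  c(diagnosis = block_cor(p$family == "diagnosis"),
    drug = block_cor(p$family == "drug"),
    all = block_cor(rep(TRUE, length(p$rates))))
}

#' Cluster-versus-group cross-tabulation
#'
#' Counts and within-cluster row percentages of group membership per cluster,
#' the layout used to read clusters against their originating CRGs.
#'
#' @param cluster_labels cluster assignment per patient.
#' @param group_labels group (e.g. CRG) label per patient.
#' @return list with `counts` (clusters x groups matrix), `percent` (row
#'   percentages, full precision), and `cluster_size`.
#' @export
cross_tabulate <- function(cluster_labels, group_labels) {
  if (length(cluster_labels) != length(group_labels)) {
    stop("label vectors must have equal length")
  }
  counts <- table(cluster = cluster_labels, group = group_labels)
  counts <- unclass(counts)
  percent <- 100 * counts / rowSums(counts)
  list(counts = counts, percent = percent, cluster_size = rowSums(counts))
}

#' Per-cluster five-number age summaries
#'
#' Minimum, lower quartile, median, upper quartile and maximum of age within
#' each cluster. Age never enters representation learning or clustering; it
#' is characterization metadata only.
#'
#' @param age numeric ages (or a `cohort`, whose `age` is used).
#' @param cluster_labels cluster assignment per patient.
#' @return data.frame with columns `cluster`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
age_summary <- function(age, cluster_labels) {
  if (inherits(age, "cohort")) age <- age$age
  if (length(age) != length(cluster_labels)) {
    stop("age and labels must have equal length")
  }
  out <- do.call(rbind, lapply(split(age, cluster_labels), function(a) {
    q <- stats::quantile(a, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(n = length(a), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  }))
  out <- cbind(cluster = rownames(out), out)
  rownames(out) <- NULL
  out
}
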