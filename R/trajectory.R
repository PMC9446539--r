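#' Build a simple synthetic patient (one-hot code vector)
#'
#' A simple synthetic patient carries exactly one clinical code: a length-D
#' zero vector with a single 1 at the code's vocabulary position. Encoded and
#' embedded next to real patients, it shows where an isolated code lives in
#' the latent map.
#'
#' @param code a (truncated) vocabulary code, e.g. `"A10BA"` or `"250"`.
#' @param vocab the [code_vocabulary()].
#' @return an object of class `synthetic_patient` with fields `vector`
#'   (integer 0/1, length D), `target_codes`, `kind = "simple"`, `N = 1`,
#'   `id`.
#' @export
make_simple_patient <- function(code, vocab) {
  stopifnot(inherits(vocab, "code_vocabulary"), length(code) == 1)
  j <- match(code, vocab$codes)
  if (is.na(j)) stop("code not in vocabulary: ", code)
  v <- integer(vocab$D)
  names(v) <- vocab$codes
  v[j] <- 1L
  structure(list(vector = v, target_codes = code, kind = "simple", N = 1L,
                 id = paste0("simple_", code)),
            class = "synthetic_patient")
}

#' Build the nested sequence of complex synthetic patients
#'
#' Given target codes ordered by decreasing presence rate in a source cluster
#' (e.g. from [top_codes()]), the i-th complex patient is the indicator of
#' the first `i + 1` codes — the elementwise sum of the corresponding simple
#' patients. Their successive embeddings trace a health-status trajectory as
#' codes accumulate.
#'
#' @param codes ordered character vector of at least 2 distinct vocabulary
#'   codes.
#' @param vocab the [code_vocabulary()].
#' @return list of `synthetic_patient` objects with `N = 2, ..., length(codes)`.
#' @export
make_complex_patients <- function(codes, vocab) {
  stopifnot(inherits(vocab, "code_vocabulary"), length(codes) >= 2)
  if (anyDuplicated(codes)) {
    stop("duplicate target codes: the aggregated vector must stay binary")
  }
  j <- match(codes, vocab$codes)
  if (anyNA(j)) stop("code(s) not in vocabulary: ",
                     paste(codes[is.na(j)], collapse = ", "))
  lapply(2:length(codes), function(N) {
    v <- integer(vocab$D)
    names(v) <- vocab$codes
    v[j[seq_len(N)]] <- 1L
    structure(list(vector = v, target_codes = codes[seq_len(N)],
                   kind = "complex", N = as.integer(N),
                   id = paste0("complex", N, "_", codes[1])),
              class = "synthetic_patient")
  })
}

#' Stack synthetic patients into a binary matrix
#'
#' @param patients list of `synthetic_patient` objects.
#' @return integer matrix (patients x D), rownames = patient ids.
#' @export
synthetic_matrix <- function(patients) {
  stopifnot(length(patients) >= 1,
            all(vapply(patients, inherits, TRUE, "synthetic_patient")))
  X <- do.call(rbind, lapply(patients, `[[`, "vector"))
  rownames(X) <- vapply(patients, `[[`, "", "id")
  X
}

#' Joint 2-D embedding of cohort and synthetic patients
#'
#' Runs a single t-SNE over the row-concatenated latent matrices so the
#' synthetic patients are placed in the same map as the cohort (t-SNE has no
#' native out-of-sample projection; joint fitting is this package's
#' documented choice).
#'
#' @param H_cohort latent matrix of the cohort (n x d).
#' @param H_synth latent matrix of the synthetic patients (m x d, m >= 0).
#' @param perplexity,max_iter,seed passed to [tsne_embed()].
#' @return an object of class `embedding2d`: `coordinates` ((n + m) x 2),
#'   `role` (`"cohort"`/`"synthetic"`), `ids`, `perplexity`, `seed`.
#' @export
embed_joint <- function(H_cohort, H_synth = NULL, perplexity = 30,
                        max_iter = 1000, seed = 1) {
  H_cohort <- as.matrix(H_cohort)
  m <- 0L
  H <- H_cohort
  if (!is.null(H_synth) && nrow(H_synth) > 0) {
    H_synth <- as.matrix(H_synth)
    if (ncol(H_synth) != ncol(H_cohort)) {
      stop("latent widths differ between cohort and synthetic patients")
    }
    m <- nrow(H_synth)
    H <- rbind(H_cohort, H_synth)
  }
  Y <- tsne_embed(H, perplexity = perplexity, max_iter = max_iter, seed = seed)
  structure(list(coordinates = Y,
                 role = rep(c("cohort", "synthetic"),
                            c(nrow(H_cohort), m)),
                 ids = rownames(H),
                 perplexity = perplexity, seed = seed),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat("2-D embedding of", sum(x$role == "cohort"), "cohort and",
      sum(x$role == "synthetic"), "synthetic points (perplexity",
      x$perplexity, ")\n")
  invisible(x)
}

#' Extract an ordered trajectory from a joint embedding
#'
#' Returns the 2-D points of the named synthetic patients in the given order
#' (increasing N for complex patients), ready for arrow plotting.
#'
#' @param embedding an [embed_joint()] result.
#' @param ids character vector of synthetic-point ids, in trajectory order.
#' @return data.frame with columns `id`, `x`, `y`, `step`.
#' @export
extract_trajectory <- function(embedding, ids) {
  stopifnot(inherits(embedding, "embedding2d"))
  synth_ids <- embedding$ids[embedding$role == "synthetic"]
  missing <- setdiff(ids, synth_ids)
  if (length(missing)) {
    stop("unknown synthetic point id(s): ", paste(missing, collapse = ", "))
  }
  j <- match(ids, embedding$ids)
  data.frame(id = ids,
             x = embedding$coordinates[j, 1],
             y = embedding$coordinates[j, 2],
             step = seq_along(ids))
}
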