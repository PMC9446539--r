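# Shared small fixtures, all generated in code.

tiny_vocab <- function() default_vocabulary(n_diagnosis = 60, n_drug = 32)

# Scaled-down three-CRG cohort with the same five latent sub-groups as the
# default case-1 generator, for fast unit tests.
small_case1_cohort <- function(n1 = 400, n2 = 300, n3 = 200, seed = 42,
                               vocab = tiny_vocab()) {
  big <- default_study_specs(1, vocab)
  sizes <- c(n1, n2, n3)
  specs <- lapply(seq_along(big), function(i) {
    s <- big[[i]]
    group_spec(s$crg_label, sizes[i], phenotypes = s$phenotypes,
               age_mean = s$age_mean, age_sd = s$age_sd,
               sex_ratio = s$sex_ratio)
  })
  generate_cohort(specs, vocab, seed = seed)
}

# Minimal hand-built DAE model for forward-map tests.
manual_model <- function(W, b, Wp, bp) {
  structure(list(W = W, b = b, Wp = Wp, bp = bp,
                 config = dae_config(d = nrow(W)),
                 history = NULL, trained = TRUE),
            class = "dae_model")
}

# Gaussian blobs with known labels.
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 7) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      rep(centers[i, ], each = n_per)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Restrict a cohort to one CRG (for guard-clause tests).
cohort_subset_for_tests <- function(co, crg) {
  keep <- which(co$crg == crg)
  out <- list(X = co$X[keep, , drop = FALSE], crg = co$crg[keep],
              subgroup = co$subgroup[keep], age = co$age[keep],
              sex = co$sex[keep], patient_id = co$patient_id[keep],
              vocab = co$vocab, n = length(keep))
  class(out) <- "cohort"
  out
}
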