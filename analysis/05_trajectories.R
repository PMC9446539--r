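# Proof-of-concept health-status trajectories for case 1: one-hot "simple"
# synthetic patients for each cluster's top codes, nested "complex" patients
# aggregating those codes in decreasing presence-rate order, and a joint
# t-SNE embedding of test patients plus synthetic patients. A simple patient
# carrying only ICD9-CM '250' should land in the diabetic cluster and '401'
# in the hypertensive one; late low-relevance codes should barely move the
# complex-patient trajectory.

source("analysis/00_common.R")

split <- cache_get("split_case1")
model <- cache_get("dae_case1")
cl <- cache_get("clusters_case1")
vocab <- split$test$vocab
H_test <- represent(split$test, model)

synth <- list()
for (k in sort(unique(cl$labels))) {
  tc <- top_codes(compute_profile(split$test$X[cl$labels == k, , drop = FALSE],
                                  vocab, subset_id = paste0("C", k)))
  for (fam in c("diagnosis", "drug")) {
    codes <- tc$code[tc$family == fam]
    for (cd in codes) {
      id <- paste0("simple_", cd)
      if (is.null(synth[[id]])) synth[[id]] <- make_simple_patient(cd, vocab)
    }
    for (p in make_complex_patients(codes, vocab)) {
      p$id <- paste0("C", k, "_", fam, "_", p$id)
      synth[[p$id]] <- p
    }
  }
}
cat("built", sum(grepl("^simple", names(synth))), "simple and",
    sum(!grepl("^simple", names(synth))), "complex synthetic patients\n")

H_synth <- represent(synthetic_matrix(unname(synth)), model)
emb <- embed_joint(H_test, H_synth, perplexity = 30, max_iter = 1000,
                   seed = MASTER_SEED + 50)

coords <- data.frame(id = emb$ids, role = emb$role, emb$coordinates)
coords$cluster <- NA_integer_
coords$cluster[seq_len(split$test$n)] <- cl$labels
write_result(coords, "case1_embedding.csv")

trajs <- list()
for (k in sort(unique(cl$labels))) {
  for (fam in c("diagnosis", "drug")) {
    ids <- grep(paste0("^C", k, "_", fam, "_complex"), names(synth),
                value = TRUE)
    ids <- ids[order(vapply(synth[ids], `[[`, 1L, "N"))]
    tr <- extract_trajectory(emb, ids)
    trajs[[length(trajs) + 1]] <- cbind(trajectory = paste0("C", k, "_", fam), tr)
  }
}
write_result(do.call(rbind, trajs), "case1_trajectories.csv")

# where do the lead-code simple patients land, by nearest cluster centroid?
Y <- emb$coordinates
cent <- do.call(rbind, lapply(sort(unique(cl$labels)), function(k) {
  colMeans(Y[seq_len(split$test$n), , drop = FALSE][cl$labels == k, , drop = FALSE])
}))
for (cd in c("250", "401", "V27", "A10BA", "C09AA")) {
  y <- Y[match(paste0("simple_", cd), emb$ids), ]
  near <- which.min(rowSums(sweep(cent, 2, y)^2))
  crg_mix <- table(split$test$crg[cl$labels == near])
  cat(sprintf("simple '%s' -> cluster C%d (dominant %s)\n",
              cd, near, names(which.max(crg_mix))))
}
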