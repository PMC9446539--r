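# Clinical characterization of the clusters on the held-out test subset:
# Ward clustering of the test latent representations at the selected k,
# presence-rate profiles and top-5 codes per cluster, Pearson correlation of
# each cluster's diagnosis/drug profile blocks against each CRG's, the
# cluster-vs-CRG cross-tabulation, per-cluster age summaries, and recovery
# diagnostics against the generator's latent sub-groups (adjusted Rand index
# and matched-profile correlations).

source("analysis/00_common.R")

for (case in 1:2) {
  split <- cache_get(paste0("split_case", case))
  model <- cache_get(paste0("dae_case", case))
  sel <- cache_get(paste0("selection_case", case))
  H_test <- represent(split$test, model)
  cl <- ahc_ward(H_test, sel$k_star)
  cache_put(cl, paste0("clusters_case", case))

  ct <- cross_tabulate(cl$labels, split$test$crg)
  cat(sprintf("\ncase %d: %d test patients in %d clusters\n",
              case, split$test$n, sel$k_star))
  print(cbind(n = ct$cluster_size, round(ct$percent)))

  vocab <- split$test$vocab
  profs <- lapply(sort(unique(cl$labels)), function(k) {
    compute_profile(split$test$X[cl$labels == k, , drop = FALSE], vocab,
                    subset_id = paste0("C", k))
  })
  crgs <- lapply(sort(unique(split$test$crg)), function(g) {
    compute_profile(split$test$X[split$test$crg == g, , drop = FALSE], vocab,
                    subset_id = g)
  })
  pcc <- do.call(rbind, lapply(profs, function(p) {
    do.call(rbind, lapply(crgs, function(q) {
      r <- profile_pcc(p, q)
      data.frame(cluster = p$subset_id, crg = q$subset_id,
                 pcc_diagnosis = round(r[["diagnosis"]], 2),
                 pcc_drug = round(r[["drug"]], 2))
    }))
  }))
  write_result(pcc, sprintf("case%d_cluster_crg_pcc.csv", case))
  write_result(do.call(rbind, lapply(profs, function(p) {
    cbind(cluster = p$subset_id, top_codes(p))
  })), sprintf("case%d_cluster_top_codes.csv", case))
  write_result(age_summary(split$test$age, cl$labels),
               sprintf("case%d_age_summary.csv", case))
  write_result(data.frame(cluster = rownames(ct$counts), ct$counts,
                          check.names = FALSE),
               sprintf("case%d_crosstab.csv", case))

  ari <- adjusted_rand_index(cl$labels, split$test$subgroup)
  matched <- match_clusters(cl$labels, split$test$subgroup)
  cat(sprintf("recovery: ARI = %.3f vs generating sub-groups\n", ari))
  print(matched)
}
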