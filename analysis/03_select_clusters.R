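# Choose the number of clusters on the training latent representations.
# Silhouette, Davies-Bouldin and the spherical-Gaussian BIC are tabulated for
# k = 2..10 under both k-means and Ward agglomerative clustering; the
# selection takes the majority of silhouette argmax, Davies-Bouldin argmin
# and the BIC elbow on the Ward curves. The generating structure is five
# groups for case 1 (healthy, pregnancy, hypertensive, two diabetic
# sub-groups) and six for case 2 (adding the multimorbid group); the index
# curves are flat across the last candidate splits, so the automatic
# majority can settle one below that on some seeds — inspect the CVI table
# and the cross-tabulation at competing k before trusting a borderline k*.

source("analysis/00_common.R")

tables <- list()
for (case in 1:2) {
  split <- cache_get(paste0("split_case", case))
  model <- cache_get(paste0("dae_case", case))
  H <- represent(split$train, model)
  sel <- select_n_clusters(H, 2:10, seed = MASTER_SEED + 40 + case)
  cat(sprintf("case %d: k* = %d  (votes: silhouette %d, Davies-Bouldin %d, BIC elbow %d)\n",
              case, sel$k_star, sel$votes["silhouette"],
              sel$votes["davies_bouldin"], sel$votes["bic"]))
  cache_put(sel, paste0("selection_case", case))
  tables[[case]] <- cbind(case = case, sel$cvi_table)
}
write_result(do.call(rbind, tables), "cvi_table.csv")
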