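# Build the two synthetic case-study cohorts (healthy / hypertensive /
# diabetic, plus multimorbid in case 2), balance them by random
# under-sampling to the minority CRG, and split 75/25 into train and test.
# The printed arithmetic is the design of the study this package emulates:
# balanced sizes 6,498 and 8,664, test sizes 1,625 and 2,166.

source("analysis/00_common.R")

vocab <- default_vocabulary()
cat("Vocabulary:", vocab$D, "features (",
    length(vocab$diagnosis_codes), "diagnosis +",
    length(vocab$drug_codes), "drug )\n\n")

rows <- list()
for (case in 1:2) {
  specs <- default_study_specs(case, vocab)
  cohort <- generate_cohort(specs, vocab, seed = MASTER_SEED + case)
  balanced <- undersample(cohort, seed = MASTER_SEED + 10 + case)
  split <- train_test_split(balanced, 0.75, seed = MASTER_SEED + 20 + case)
  cat(sprintf("case %d: raw n = %d -> balanced n = %d (train %d / test %d)\n",
              case, cohort$n, balanced$n, split$train$n, split$test$n))
  print(table(balanced$crg))
  cat("\n")
  for (g in names(table(cohort$crg))) {
    rows[[length(rows) + 1]] <- data.frame(
      case = case, crg = g,
      n_raw = sum(cohort$crg == g),
      n_balanced = sum(balanced$crg == g),
      n_train = sum(split$train$crg == g),
      n_test = sum(split$test$crg == g))
  }
  cache_put(split, paste0("split_case", case))
  rm(cohort); invisible(gc(FALSE))

  # per-CRG presence-rate profiles with their top-5 codes per family
  tops <- do.call(rbind, lapply(sort(unique(split$test$crg)), function(g) {
    p <- compute_profile(split$test$X[split$test$crg == g, , drop = FALSE],
                         vocab, subset_id = g)
    cbind(crg = g, top_codes(p))
  }))
  write_result(tops, sprintf("case%d_crg_top_codes.csv", case))
}
write_result(do.call(rbind, rows), "cohort_sizes.csv")
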