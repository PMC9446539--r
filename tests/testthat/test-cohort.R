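test_that("default study specs carry the published group sizes and structure", {
  v <- tiny_vocab()
  s1 <- default_study_specs(1, v)
  expect_length(s1, 3)
  expect_equal(vapply(s1, `[[`, 0L, "n_patients"), c(46835L, 12447L, 2166L))
  # five latent groups: the pregnancy bundle spans CRG-1000 and CRG-5192
  expect_length(unique(unlist(lapply(s1, function(s) names(s$phenotypes)))), 5)
  s2 <- default_study_specs(2, v)
  expect_length(s2, 4)
  expect_equal(s2[[4]]$crg_label, "CRG-6144")
  expect_equal(s2[[4]]$n_patients, 3179L)
  expect_length(unique(unlist(lapply(s2, function(s) names(s$phenotypes)))), 6)
  # lead diabetes diagnosis dominates every non-signature code
  d_rates <- s1[[3]]$phenotypes$diabetic_biguanide$rates
  expect_gt(d_rates[["250"]], max(d_rates[setdiff(names(d_rates), c(
    "250", "272", "401", "A10BA", "C10AA", "N02BE"))]))
})

test_that("specs reject a vocabulary missing signature codes", {
  v <- code_vocabulary(c("100", "101", "102"), c("Z01AA", "Z01AB"))
  expect_error(default_study_specs(1, v), "missing from vocabulary")
})

test_that("generation is deterministic and honours degenerate rates", {
  v <- code_vocabulary(c("100", "101"), c("Z01AA", "Z01AB"))
  all0 <- group_spec("G", 20, phenotypes = list(
    p = list(weight = 1, rates = rep(0, 4))), age_mean = 50, age_sd = 5)
  all1 <- group_spec("G", 20, phenotypes = list(
    p = list(weight = 1, rates = rep(1, 4))), age_mean = 50, age_sd = 5)
  expect_true(all(generate_cohort(list(all0), v, seed = 3)$X == 0))
  expect_true(all(generate_cohort(list(all1), v, seed = 3)$X == 1))
  co1 <- small_case1_cohort(seed = 9)
  co2 <- small_case1_cohort(seed = 9)
  expect_identical(co1$X, co2$X)
  expect_identical(co1$age, co2$age)
  expect_false(identical(co1$X, small_case1_cohort(seed = 10)$X))
})

test_that("empirical presence rates calibrate to the generator parameters", {
  v <- tiny_vocab()
  rates <- rep(0.01, v$D)
  rates[match("250", v$codes)] <- 0.8
  spec <- group_spec("G", 5000, phenotypes = list(
    p = list(weight = 1, rates = rates)), age_mean = 60, age_sd = 10)
  co <- generate_cohort(list(spec), v, seed = 5)
  se <- sqrt(0.8 * 0.2 / 5000)
  expect_lt(abs(mean(co$X[, "250"]) - 0.8), 4 * se)
  # >= 99% of columns within 4 binomial SEs of their generating rate
  emp <- colMeans(co$X)
  se_all <- sqrt(pmax(rates * (1 - rates), 1e-12) / 5000)
  ok <- abs(emp - rates) < 4 * se_all | (rates %in% c(0, 1) & emp == rates)
  expect_gte(mean(ok), 0.99)
})

test_that("under-sampling balances to the minority CRG and keeps rows intact", {
  co <- small_case1_cohort(n1 = 120, n2 = 70, n3 = 40, seed = 2)
  bal <- undersample(co, seed = 8)
  expect_equal(as.integer(table(bal$crg)), rep(40L, 3), ignore_attr = TRUE)
  expect_equal(bal$n, 120)
  # every retained row is the unchanged original row
  idx <- match(bal$patient_id, co$patient_id)
  expect_identical(bal$X, co$X[idx, ])
  expect_identical(bal$age, co$age[idx])
  # already balanced: sizes unchanged
  bal2 <- undersample(bal, seed = 9)
  expect_equal(as.integer(table(bal2$crg)), rep(40L, 3), ignore_attr = TRUE)
  expect_error(undersample(cohort_subset_for_tests(co, "CRG-1000")),
               "at least two CRGs")
})


test_that("train/test split is disjoint, exhaustive and uses floor rounding", {
  co <- small_case1_cohort(n1 = 50, n2 = 30, n3 = 20, seed = 3)
  sp <- train_test_split(co, 0.75, seed = 4)
  expect_equal(sp$train$n, floor(0.75 * 100))
  expect_equal(sp$train$n + sp$test$n, co$n)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id), co$patient_id)
  tiny <- cohort_subset_for_tests(co, "CRG-5424")
  tiny4 <- list(X = tiny$X[1:4, ], crg = tiny$crg[1:4],
                subgroup = tiny$subgroup[1:4], age = tiny$age[1:4],
                sex = tiny$sex[1:4], patient_id = tiny$patient_id[1:4],
                vocab = tiny$vocab, n = 4L)
  class(tiny4) <- "cohort"
  sp4 <- train_test_split(tiny4, 0.75, seed = 1)
  expect_equal(c(sp4$train$n, sp4$test$n), c(3L, 1L))
})

test_that("pregnancy sub-phenotype is all female and younger", {
  co <- small_case1_cohort(n1 = 600, n2 = 50, n3 = 50, seed = 6)
  preg <- co$subgroup == "pregnancy"
  expect_gt(sum(preg), 5)
  expect_true(all(co$sex[preg] == "F"))
  expect_lt(median(co$age[preg]), median(co$age[co$subgroup == "hypertensive"]))
})
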