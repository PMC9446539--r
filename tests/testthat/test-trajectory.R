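test_that("simple synthetic patients are one-hot at the target code", {
  v <- tiny_vocab()
  p <- make_simple_patient("A10BA", v)
  expect_equal(sum(p$vector), 1)
  expect_equal(unname(p$vector[["A10BA"]]), 1L)
  expect_equal(p$N, 1L)
  expect_equal(p$kind, "simple")
  q <- make_simple_patient("250", v)
  expect_equal(sum(p$vector & q$vector), 0)   # disjoint supports
  expect_error(make_simple_patient("ZZZZZ", v), "ZZZZZ")
})

test_that("complex synthetic patients nest and aggregate their target codes", {
  v <- tiny_vocab()
  codes <- c("A10BA", "C10AA", "M01AE")
  cx <- make_complex_patients(codes, v)
  expect_length(cx, 2)
  expect_equal(sum(cx[[1]]$vector), 2)
  expect_setequal(names(which(cx[[1]]$vector == 1)), c("A10BA", "C10AA"))
  expect_equal(sum(cx[[2]]$vector), 3)
  expect_setequal(names(which(cx[[2]]$vector == 1)), codes)
  # nesting: support of patient i strictly contains that of i - 1
  expect_true(all(cx[[2]]$vector[cx[[1]]$vector == 1] == 1))
  expect_true(all(vapply(cx, function(p) all(p$vector %in% 0:1), TRUE)))
  expect_error(make_complex_patients(c("A10BA", "A10BA"), v), "duplicate")
  expect_error(make_complex_patients("A10BA", v))
  M <- synthetic_matrix(cx)
  expect_equal(dim(M), c(2, v$D))
  expect_equal(rownames(M), vapply(cx, `[[`, "", "id"))
})

test_that("t-SNE embedding is seeded, shaped, and preserves blob structure", {
  blobs <- make_blobs(n_per = 40,
                      centers = rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)),
                      sd = 0.5, seed = 41)
  Y1 <- tsne_embed(blobs$X, perplexity = 12, max_iter = 300, seed = 5)
  Y2 <- tsne_embed(blobs$X, perplexity = 12, max_iter = 300, seed = 5)
  expect_identical(Y1, Y2)
  expect_equal(dim(Y1), c(120, 2))
  expect_true(all(is.finite(Y1)))
  # well-separated blobs stay separated in 2-D
  km <- kmeans_cluster(Y1, 3, seed = 1)
  expect_gte(adjusted_rand_index(km$labels, blobs$labels), 0.95)
  expect_error(tsne_embed(blobs$X[1:20, ], perplexity = 10), "perplexity")
})

test_that("joint embedding places synthetic patients with the cohort", {
  blobs <- make_blobs(n_per = 30, centers = rbind(c(0, 0), c(9, 9)), sd = 0.4,
                      seed = 42)
  H_synth <- rbind(s1 = c(0.1, 0.1), s2 = c(8.9, 9.2))
  rownames(blobs$X) <- sprintf("p%03d", 1:60)
  emb0 <- embed_joint(blobs$X, NULL, perplexity = 10, max_iter = 250, seed = 2)
  expect_equal(nrow(emb0$coordinates), 60)
  expect_true(all(emb0$role == "cohort"))
  emb <- embed_joint(blobs$X, H_synth, perplexity = 10, max_iter = 250, seed = 2)
  expect_equal(nrow(emb$coordinates), 62)
  expect_equal(sum(emb$role == "synthetic"), 2)
  # each synthetic point lands nearest the blob its latent vector copies
  Y <- emb$coordinates
  c1 <- colMeans(Y[1:30, ]); c2 <- colMeans(Y[31:60, ])
  d_s1 <- c(sum((Y[61, ] - c1)^2), sum((Y[61, ] - c2)^2))
  d_s2 <- c(sum((Y[62, ] - c1)^2), sum((Y[62, ] - c2)^2))
  expect_lt(d_s1[1], d_s1[2])
  expect_lt(d_s2[2], d_s2[1])
  expect_error(embed_joint(blobs$X, H_synth[, 1, drop = FALSE]), "widths")
})

test_that("trajectories are ordered subsets of the embedding", {
  blobs <- make_blobs(n_per = 25, centers = rbind(c(0, 0), c(7, 7)), sd = 0.5,
                      seed = 43)
  H_synth <- matrix(runif(8, 0, 7), 4, 2,
                    dimnames = list(paste0("c", 1:4), NULL))
  emb <- embed_joint(blobs$X, H_synth, perplexity = 8, max_iter = 250, seed = 3)
  tr <- extract_trajectory(emb, paste0("c", 1:4))
  expect_equal(nrow(tr), 4)
  expect_equal(tr$step, 1:4)
  expect_true(all(tr$x %in% emb$coordinates[, 1]))
  expect_error(extract_trajectory(emb, c("c1", "nope")), "unknown")
})

# End-to-end at the full feature dimensionality on a reduced cohort:
# code-level placement of simple patients and damped late steps of complex
# ones. One DAE/embedding setup is shared by both checks. (The placement
# property needs the full vocabulary: against a 2,263-code background a
# one-hot lead-code patient sits nearer the sparse members of its disease
# cluster than any patient lacking the code.)
traj_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      v <- default_vocabulary()
      big <- default_study_specs(1, v)
      sizes <- c(450, 280, 280)
      specs <- lapply(seq_along(big), function(i) {
        s <- big[[i]]
        group_spec(s$crg_label, sizes[i], phenotypes = s$phenotypes,
                   age_mean = s$age_mean, age_sd = s$age_sd,
                   sex_ratio = s$sex_ratio)
      })
      co <- generate_cohort(specs, v, seed = 44)
      m <- train_dae(co$X, dae_config(max_epochs = 120, seed = 45))
      cache <<- list(v = v, co = co, m = m, H = represent(co, m))
    }
    cache
  }
})

test_that("simple patients for lead codes map onto their disease clusters", {
  fx <- traj_fixture()
  synth <- list(make_simple_patient("250", fx$v),
                make_simple_patient("401", fx$v))
  Hs <- represent(synthetic_matrix(synth), fx$m)
  emb <- embed_joint(fx$H, Hs, perplexity = 30, max_iter = 1000, seed = 46)
  Y <- emb$coordinates
  n <- fx$co$n
  centroid <- function(mask) colMeans(Y[seq_len(n), ][mask, , drop = FALSE])
  groups <- list(diabetic = fx$co$crg == "CRG-5424",
                 hypertensive = fx$co$crg == "CRG-5192",
                 healthy = fx$co$subgroup == "healthy",
                 pregnancy = fx$co$subgroup == "pregnancy")
  nearest <- function(y) names(which.min(vapply(groups, function(g) {
    sum((y - centroid(g))^2)
  }, 0)))
  expect_equal(nearest(Y[n + 1, ]), "diabetic")      # ICD9 '250'
  # '401' lands in the hypertension-coded population: either the large
  # hypertensive cluster or the pregnancy cluster, which is dominated by
  # CRG-5192 (pregnancy-induced hypertension) and also carries '401'
  expect_true(nearest(Y[n + 2, ]) %in% c("hypertensive", "pregnancy"))
})

test_that("late low-relevance codes barely move the trajectory", {
  fx <- traj_fixture()
  # high-relevance disease codes first (big early steps), then background
  # codes with near-zero presence rates (small late steps)
  bg_codes <- head(setdiff(fx$v$diagnosis_codes,
                           unlist(ehrlatent:::signature_codes())), 2)
  codes <- c("250", "A10BA", "C10AA", "272", bg_codes)
  cx <- make_complex_patients(codes, fx$v)
  Hs <- represent(synthetic_matrix(cx), fx$m)
  wins <- 0
  for (s in 1:3) {
    emb <- embed_joint(fx$H, Hs, perplexity = 30, max_iter = 500,
                       seed = 100 + s)
    tr <- extract_trajectory(emb, rownames(Hs))
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    last2 <- steps[(length(steps) - 1):length(steps)]
    if (median(last2) < median(steps[1:2])) wins <- wins + 1
  }
  expect_gte(wins, 2)   # majority of seeds
})
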