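test_that("corruption touches the right number of positions", {
  set.seed(1)
  X <- matrix(rbinom(20 * 50, 1, 0.5), 20)
  expect_identical(corrupt(X, "spn", level = 0), X)
  expect_true(all(corrupt(X, "zmn", level = 100) == 0))
  for (nu in c(10, 50)) {
    Xc <- corrupt(X, "zmn", nu)
    changed <- rowSums(Xc != X)
    expect_true(all(changed <= round(nu * 50 / 100)))
    Xc <- corrupt(X, "spn", nu)
    expect_true(all(rowSums(Xc != X) <= round(nu * 50 / 100)))
    expect_true(all(Xc %in% 0:1))
  }
  expect_error(corrupt(matrix(c(0, 2), 1), "spn", 10), "binary")
})

test_that("SPN at full corruption flips a fair coin per feature", {
  set.seed(2)
  D <- 1000
  counts <- replicate(200, sum(corrupt(matrix(0L, 1, D), "spn", 100)))
  expect_lt(abs(mean(counts) - D / 2), 4 * sqrt(D * 0.25) / sqrt(200))
  # single replicate bound from the fair-coin binomial spread
  expect_true(all(abs(counts - 500) < 4 * sqrt(D * 0.25) + 1e-9))
})

test_that("encoder and decoder match hand-computed forward passes", {
  m <- manual_model(W = matrix(c(1, -1), 1), b = 0,
                    Wp = matrix(2, 1, 1), bp = -1)
  expect_equal(unname(encode(c(1, 0), m)[1, 1]), 1)
  expect_equal(unname(encode(c(0, 1), m)[1, 1]), 0)   # ReLU clips -1
  expect_equal(unname(decode(matrix(1), m)[1, 1]), plogis(1))
  z <- manual_model(W = matrix(0, 2, 3), b = c(0, -5),
                    Wp = matrix(0, 3, 2), bp = rep(0, 3))
  expect_true(all(encode(matrix(1, 4, 3), z) == 0))
  expect_true(all(decode(matrix(1, 4, 2), z) == 0.5))
  expect_error(encode(matrix(1, 1, 5), m), "expects")
  expect_error(decode(matrix(1, 1, 3), m), "latent dim")
})

test_that("binary cross-entropy reproduces its closed forms", {
  X <- matrix(rbinom(40, 1, 0.5), 4)
  expect_equal(bce_loss(X, matrix(0.5, 4, 10)), log(2))
  ones <- matrix(1, 3, 5)
  expect_equal(bce_loss(ones, matrix(0.25, 3, 5)), log(4))
  expect_lt(bce_loss(X, pmin(pmax(X, 1e-7), 1 - 1e-7)), 1e-6)
  expect_error(bce_loss(X, matrix(0.5, 2, 2)), "shape")
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  D <- 6; d <- 2; n <- 5
  X <- matrix(rbinom(n * D, 1, 0.5), n)
  Xc <- matrix(rbinom(n * D, 1, 0.5), n)
  model <- manual_model(W = matrix(rnorm(d * D, sd = 0.3), d), b = rnorm(d),
                        Wp = matrix(rnorm(D * d, sd = 0.3), D), bp = rnorm(D))
  g <- ehrlatent:::dae_gradients(model, Xc, X)
  h <- 1e-5
  num_grad <- function(field, i) {
    mp <- model; mm <- model
    mp[[field]][i] <- mp[[field]][i] + h
    mm[[field]][i] <- mm[[field]][i] - h
    (ehrlatent:::dae_gradients(mp, Xc, X)$loss -
       ehrlatent:::dae_gradients(mm, Xc, X)$loss) / (2 * h)
  }
  for (field in c("W", "b", "Wp", "bp")) {
    ga <- g[[paste0("g", sub("^([Wb])", "\\1", field))]]
    idx <- seq_len(min(8, length(ga)))
    num <- vapply(idx, function(i) num_grad(field, i), 0)
    rel <- abs(num - as.vector(ga)[idx]) / pmax(abs(num), abs(as.vector(ga)[idx]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training is seeded, early-stopped, and beats the uninformative predictor", {
  co <- small_case1_cohort(n1 = 450, n2 = 300, n3 = 250, seed = 21)
  cfg <- dae_config(d = 8, max_epochs = 60, seed = 77)
  m1 <- train_dae(co$X, cfg)
  m2 <- train_dae(co$X, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$history, m2$history)
  expect_lt(min(m1$history$val_loss), log(2))
  expect_equal(m1$best_epoch, m1$history$epoch[which.min(m1$history$val_loss)])
  # running best validation loss is non-increasing by construction
  expect_true(all(diff(cummin(m1$history$val_loss)) <= 0))
  expect_true(all(m1$history$lr[-1] <= m1$history$lr[-nrow(m1$history)]))
})

test_that("max_epochs = 0 returns an initialized, untrained model", {
  X <- matrix(rbinom(200, 1, 0.3), 10)
  m <- train_dae(X, dae_config(d = 3, max_epochs = 0, seed = 1))
  expect_false(m$trained)
  expect_equal(nrow(m$history), 0)
  expect_equal(dim(m$W), c(3, 20))
})

test_that("representations are clean-input encodings with ids carried through", {
  co <- small_case1_cohort(n1 = 60, n2 = 40, n3 = 30, seed = 4)
  m <- train_dae(co$X, dae_config(d = 5, max_epochs = 5, seed = 2))
  H <- represent(co, m)
  expect_equal(dim(H), c(co$n, 5))
  expect_equal(rownames(H), co$patient_id)
  # duplicate patients map to identical latent rows
  X2 <- co$X[c(1, 1, 2), ]
  H2 <- represent(X2, m)
  expect_identical(H2[1, ], H2[2, ])
  expect_error(represent(co$X[, 1:10], m), "features")
})

test_that("default configuration matches the study architecture", {
  cfg <- dae_config()
  expect_equal(cfg$d, 20L)
  expect_equal(cfg$noise_type, "spn")
  expect_equal(cfg$noise_level, 10)
})
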