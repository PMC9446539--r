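#' Denoising-autoencoder configuration
#'
#' Defaults follow the study architecture: a single hidden layer of `d = 20`
#' ReLU units, sigmoid output, salt-and-pepper corruption of 10% of the
#' features per sample, trained by mini-batch gradient descent with a
#' reduce-on-plateau learning rate and early stopping.
#'
#' @param d latent dimension (number of hidden units), `d < D`.
#' @param noise_type `"spn"` (salt-and-pepper) or `"zmn"` (zero-masking).
#' @param noise_level percent of features corrupted per sample, in \[0, 100\].
#' @param batch_size mini-batch size.
#' @param learning_rate initial learning rate.
#' @param lr_factor multiplicative learning-rate decay applied after
#'   `lr_patience` epochs without validation improvement.
#' @param lr_patience,stop_patience epochs without validation improvement
#'   before decaying the learning rate / stopping.
#' @param max_epochs training epoch cap.
#' @param validation_fraction fraction of the training matrix held out for
#'   validation-based scheduling and early stopping.
#' @param seed integer RNG seed controlling initialization, shuffling and
#'   corruption.
#' @return an object of class `dae_config`.
#' @export
dae_config <- function(d = 20, noise_type = c("spn", "zmn"), noise_level = 10,
                       batch_size = 128, learning_rate = 0.05,
                       lr_factor = 0.5, lr_patience = 5, stop_patience = 10,
                       max_epochs = 300, validation_fraction = 0.1,
                       seed = 1) {
  noise_type <- match.arg(noise_type)
  stopifnot(d >= 1, noise_level >= 0, noise_level <= 100, batch_size >= 1,
            learning_rate > 0, lr_factor > 0, lr_factor < 1,
            max_epochs >= 0, validation_fraction > 0, validation_fraction < 1)
  structure(list(d = as.integer(d), noise_type = noise_type,
                 noise_level = noise_level, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "dae_config")
}

check_binary <- function(X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!all(X == 0 | X == 1)) stop("input matrix must be binary (0/1)")
  X
}

#' Corrupt a binary batch with masking or salt-and-pepper noise
#'
#' For each sample, a uniformly random subset of `round(level * D / 100)`
#' distinct feature positions is drawn; zero-masking noise (ZMN) forces them
#' to 0, salt-and-pepper noise (SPN) sets each to 0 or 1 by an independent
#' fair coin flip. Remaining positions are untouched. Uses (and advances) the
#' global RNG stream.
#'
#' @param X binary matrix (samples x D) or vector.
#' @param noise_type `"spn"` or `"zmn"`.
#' @param level percent of features corrupted per sample, in \[0, 100\].
#' @return corrupted matrix, same shape as `X`.
#' @export
corrupt <- function(X, noise_type = c("spn", "zmn"), level = 10) {
  noise_type <- match.arg(noise_type)
  stopifnot(level >= 0, level <= 100)
  X <- check_binary(X)
  corrupt_unchecked(X, noise_type, level)
}

#' Encode a batch into the latent space
#'
#' `H = ReLU(X W' + b)` row-wise (encoder weights `W` are d x D).
#'
#' @param X numeric matrix (samples x D).
#' @param model a `dae_model`.
#' @return latent matrix (samples x d).
#' @export
encode <- function(X, model) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$W)) {
    stop("encode: input has ", ncol(X), " columns but model expects ",
         ncol(model$W))
  }
  Z <- X %*% t(model$W)
  Z <- sweep(Z, 2, model$b, "+")
  H <- pmax(Z, 0)
  rownames(H) <- rownames(X)
  H
}

#' Decode latent vectors into reconstruction probabilities
#'
#' `x_hat = sigmoid(H W_dec' + b_dec)`; entries are strictly in (0, 1).
#'
#' @param H numeric matrix (samples x d).
#' @param model a `dae_model`.
#' @return reconstruction matrix (samples x D).
#' @export
decode <- function(H, model) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  if (ncol(H) != model$config$d) {
    stop("decode: input has ", ncol(H), " columns but model latent dim is ",
         model$config$d)
  }
  Z <- H %*% t(model$Wp)
  Z <- sweep(Z, 2, model$bp, "+")
  plogis(Z)
}

#' Binary cross-entropy reconstruction loss
#'
#' Mean over samples and features of
#' `-(x log x_hat + (1 - x) log(1 - x_hat))`, with predictions clipped to
#' `[eps, 1 - eps]`, `eps = 1e-7`. Reported in nats per feature.
#'
#' @param X binary matrix.
#' @param Xhat reconstruction matrix in (0, 1), same shape.
#' @param eps clipping constant.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(X, Xhat, eps = 1e-7) {
  X <- check_binary(X)
  if (!is.matrix(Xhat)) Xhat <- matrix(Xhat, nrow = 1)
  if (!all(dim(X) == dim(Xhat))) stop("bce_loss: shape mismatch")
  P <- pmin(pmax(Xhat, eps), 1 - eps)
  -mean(X * log(P) + (1 - X) * log(1 - P))
}

# Fresh Glorot-uniform model at the given dimensions (advances the RNG).
dae_init <- function(D, d, config) {
  lim <- sqrt(6 / (D + d))
  structure(list(
    W = matrix(runif(d * D, -lim, lim), nrow = d),
    b = numeric(d),
    Wp = matrix(runif(D * d, -lim, lim), nrow = D),
    bp = numeric(D),
    config = config,
    history = data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric(), lr = numeric()),
    trained = FALSE
  ), class = "dae_model")
}

# Loss (mean over samples, summed over features) and analytic gradients for
# reconstructing X_target from corrupted input X_in. Backbone of training and
# of the finite-difference gradient check.
dae_gradients <- function(model, X_in, X_target, eps = 1e-7) {
  n <- nrow(X_in)
  Z1 <- tcrossprod(X_in, model$W)
  Z1 <- Z1 + rep(model$b, each = n)
  H <- pmax(Z1, 0)
  Z2 <- tcrossprod(H, model$Wp)
  P <- plogis(Z2 + rep(model$bp, each = n))
  Pc <- pmin(pmax(P, eps), 1 - eps)
  loss <- -sum(X_target * log(Pc) + (1 - X_target) * log(1 - Pc)) / n
  dZ2 <- (P - X_target) / n               # sigmoid + BCE shortcut
  gWp <- crossprod(dZ2, H)
  gbp <- colSums(dZ2)
  dH <- dZ2 %*% model$Wp
  dZ1 <- dH * (Z1 > 0)
  gW <- crossprod(dZ1, X_in)
  gb <- colSums(dZ1)
  list(loss = loss, gW = gW, gb = gb, gWp = gWp, gbp = gbp)
}

# corrupt() minus the binary re-validation; training validates its input once.
corrupt_unchecked <- function(X, noise_type, level) {
  D <- ncol(X)
  m <- round(level * D / 100)
  if (m == 0) return(X)
  n <- nrow(X)
  cols <- vapply(seq_len(n), function(i) sample.int(D, m), integer(m))
  pos <- cbind(rep(seq_len(n), each = m), as.vector(cols))
  X[pos] <- if (noise_type == "zmn") 0 else rbinom(n * m, 1L, 0.5)
  X
}

#' Train a denoising autoencoder on a binary matrix
#'
#' Mini-batch gradient descent on the binary cross-entropy between the clean
#' input and the reconstruction of its corrupted version. Corruption is
#' resampled freshly for every mini-batch in every epoch. A validation split
#' (with corruption fixed once, so validation denoising loss is comparable
#' across epochs) drives a reduce-on-plateau learning-rate schedule and early
#' stopping; the returned parameters are those with the best validation loss.
#' Fully reproducible for a fixed config seed.
#'
#' @param X binary training matrix (patients x D).
#' @param config a [dae_config()].
#' @return a `dae_model` with encoder/decoder weights, config, per-epoch
#'   `history` (train/validation BCE per feature, learning rate) and
#'   `best_epoch`.
#' @export
train_dae <- function(X, config = dae_config()) {
  X <- check_binary(X)
  storage.mode(X) <- "double"
  n <- nrow(X); D <- ncol(X)
  stopifnot(D > config$d, n >= 2)
  if (n < config$batch_size) {
    config$batch_size <- n
  }
  set.seed(config$seed)
  model <- dae_init(D, config$d, config)
  if (config$max_epochs == 0) return(model)

  n_val <- max(1L, floor(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  Xval <- X[val_idx, , drop = FALSE]
  Xtr <- X[-val_idx, , drop = FALSE]
  ntr <- nrow(Xtr)
  Xval_noisy <- corrupt(Xval, config$noise_type, config$noise_level)

  lr <- config$learning_rate
  best_val <- Inf
  best <- model[c("W", "b", "Wp", "bp")]
  best_epoch <- 0L
  stall <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    epoch_loss <- 0
    n_seen <- 0
    for (start in seq(1, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      Xb_noisy <- corrupt_unchecked(Xb, config$noise_type, config$noise_level)
      g <- dae_gradients(model, Xb_noisy, Xb)
      model$W <- model$W - lr * g$gW
      model$b <- model$b - lr * g$gb
      model$Wp <- model$Wp - lr * g$gWp
      model$bp <- model$bp - lr * g$gbp
      epoch_loss <- epoch_loss + g$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    val_loss <- bce_loss(Xval, decode(encode(Xval_noisy, model), model))
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = epoch_loss / (n_seen * D),
                                val_loss = val_loss, lr = lr)
    if (val_loss < best_val - 1e-7) {
      best_val <- val_loss
      best <- model[c("W", "b", "Wp", "bp")]
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall %% config$lr_patience == 0L) lr <- lr * config$lr_factor
      if (stall >= config$stop_patience) break
    }
  }
  model[c("W", "b", "Wp", "bp")] <- best
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' @export
print.dae_model <- function(x, ...) {
  cat("Denoising autoencoder: D =", ncol(x$W), "-> d =", x$config$d,
      sprintf("(%s, level %g)\n", toupper(x$config$noise_type),
              x$config$noise_level))
  if (x$trained) {
    cat("Trained", nrow(x$history), "epochs; best validation BCE",
        format(min(x$history$val_loss), digits = 4),
        "at epoch", x$best_epoch, "\n")
  } else {
    cat("Untrained (initialized weights only)\n")
  }
  invisible(x)
}

#' Save / load a DAE model as a JSON archive
#'
#' Stores weights, biases, configuration and training history in a single
#' plain-text JSON file at full double precision.
#'
#' @param model a `dae_model`.
#' @param path file path (conventionally `.json`).
#' @return `path` invisibly (writer); a `dae_model` (reader).
#' @export
write_dae_model <- function(model, path) {
  stopifnot(inherits(model, "dae_model"))
  payload <- list(W = model$W, b = model$b, Wp = model$Wp, bp = model$bp,
                  config = unclass(model$config), history = model$history,
                  best_epoch = model$best_epoch, trained = model$trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dae_model
#' @export
read_dae_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(dae_config, p$config[setdiff(names(p$config), character())])
  structure(list(W = p$W, b = p$b, Wp = p$Wp, bp = p$bp, config = cfg,
                 history = as.data.frame(p$history),
                 best_epoch = p$best_epoch, trained = p$trained),
            class = "dae_model")
}

#' Latent representations of a cohort
#'
#' Applies the encoder to the clean (uncorrupted) code matrix; corruption is a
#' training-time regularizer only.
#'
#' @param cohort a `cohort` or a binary matrix with `D` columns.
#' @param model a trained `dae_model`.
#' @return latent matrix (patients x d), rownames carrying patient ids.
#' @export
represent <- function(cohort, model) {
  X <- if (inherits(cohort, "cohort")) cohort$X else cohort
  if (ncol(X) != ncol(model$W)) {
    stop("represent: cohort has ", ncol(X),
         " features but model expects ", ncol(model$W))
  }
  storage.mode(X) <- "double"
  encode(X, model)
}
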