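#' Model configuration for the LSTM autoencoder-regressor
#'
#' Defaults follow the reference training setup: input size 1530,
#' encoder hidden state 256, latent width 128, predictor hidden state
#' 128, one recurrent layer, output size 4, dropout 0.3, learning rate
#' 5e-5, 100 epochs, batch size 8, MSE loss, Adam optimizer.
#'
#' @param input_size Features per window (default 1530).
#' @param encoder_hidden Encoder LSTM hidden width (default 256).
#' @param latent Encoded per-motion width (default 128).
#' @param predictor_hidden Predictor LSTM hidden width (default 128; the
#'   latent dimension is maintained through the predictor).
#' @param num_layers Recurrent layers (only 1 supported, as configured).
#' @param output_size Number of sub-scores (default 4).
#' @param dropout Dropout probability on the predictor output state
#'   (default 0.3; inactive at inference).
#' @param lr Adam learning rate (default 5e-5).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 8).
#' @return List of class `fmaue_modelcfg`.
#' @export
model_config <- function(input_size = 1530, encoder_hidden = 256,
                         latent = 128, predictor_hidden = 128,
                         num_layers = 1, output_size = 4, dropout = 0.3,
                         lr = 5e-5, epochs = 100, batch_size = 8) {
  stopifnot(input_size > 0, encoder_hidden > 0, latent > 0,
            predictor_hidden > 0, num_layers == 1, output_size > 0,
            dropout >= 0, dropout < 1, lr > 0, epochs > 0, batch_size > 0)
  structure(as.list(environment()), class = "fmaue_modelcfg")
}

#' Mixup configuration
#'
#' @param alpha Beta-distribution shape for the mixing weight
#'   `lambda ~ Beta(alpha, alpha)` (default 1, i.e. Uniform(0,1)).
#' @param apply_prob Probability that a training batch is mixed (default
#'   1; set to 0 for the no-mixup ablation arm).
#' @return List of class `fmaue_mixcfg`.
#' @export
mixup_config <- function(alpha = 1, apply_prob = 1) {
  stopifnot(alpha > 0, apply_prob >= 0, apply_prob <= 1)
  structure(list(alpha = alpha, apply_prob = apply_prob),
            class = "fmaue_mixcfg")
}

#' Mixup: convex combination of two samples and their targets
#'
#' `x_hat = lambda * x_i + (1 - lambda) * x_j` and likewise for the
#' targets, elementwise.
#'
#' @param x_i,x_j Numeric arrays of identical shape.
#' @param y_i,y_j Numeric target vectors of identical shape.
#' @param lambda Mixing weight in \[0, 1\].
#' @return List with elements `x` and `y`.
#' @export
#' @examples
#' mixup(4, 8, 1, 0, lambda = 0.25)  # x 7, y 0.25
mixup <- function(x_i, x_j, y_i, y_j, lambda) {
  if (!identical(dim(x_i), dim(x_j)) || length(x_i) != length(x_j) ||
      length(y_i) != length(y_j)) {
    abort("mixup shape mismatch")
  }
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  list(x = lambda * x_i + (1 - lambda) * x_j,
       y = lambda * y_i + (1 - lambda) * y_j)
}

#' Draw a mixup mixing weight
#'
#' `lambda ~ Beta(alpha, alpha)`; with `alpha = 1` this is Uniform(0,1).
#'
#' @param cfg A [mixup_config()].
#' @return Scalar in \[0, 1\].
#' @export
sample_lambda <- function(cfg = mixup_config()) {
  rbeta(1, cfg$alpha, cfg$alpha)
}

#' Initialize an untrained estimator
#'
#' One encoder LSTM (shared across the seven motions), a linear
#' projection to the latent width, a predictor LSTM over the motion
#' sequence, and a linear output head.
#'
#' @param cfg A [model_config()].
#' @param n_motions Motions along the tensor's first axis (default 7;
#'   reduced-motion ablations use fewer).
#' @param seed Integer seed for the parameter initialization.
#' @return List of class `fmaue_estimator` (untrained: empty history).
#' @export
init_estimator <- function(cfg = model_config(), n_motions = 7, seed = 1) {
  par <- with_seed(seed, {
    enc <- lstm_init(cfg$input_size, cfg$encoder_hidden)
    proj <- linear_init(cfg$encoder_hidden, cfg$latent)
    pred <- lstm_init(cfg$latent, cfg$predictor_hidden)
    head <- linear_init(cfg$predictor_hidden, cfg$output_size)
    list(enc.Wx = enc$Wx, enc.Wh = enc$Wh, enc.b = enc$b,
         proj.W = proj$W, proj.b = proj$b,
         pred.Wx = pred$Wx, pred.Wh = pred$Wh, pred.b = pred$b,
         head.W = head$W, head.b = head$b)
  })
  structure(list(params = par, cfg = cfg, mixcfg = NULL,
                 n_motions = n_motions,
                 history = tibble::tibble(epoch = integer(),
                                          mse = numeric())),
            class = "fmaue_estimator")
}

#' @export
print.fmaue_estimator <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<fmaue_estimator>", x$n_motions, "motions |",
      format(np, big.mark = ","), "parameters\n")
  cat("  encoder", x$cfg$input_size, "->", x$cfg$encoder_hidden,
      "-> pool ->", x$cfg$latent, "| predictor", x$cfg$predictor_hidden,
      "->", x$cfg$output_size, "\n")
  if (nrow(x$history)) {
    cat("  trained", max(x$history$epoch), "epochs, final MSE",
        signif(tail(x$history$mse, 1), 4), "\n")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

# full forward pass. X: [B, M, WL, F]; mask: [B, M, WL] logical.
# Returns output [B, 4] plus all intermediates needed for backprop.
estimator_forward <- function(par, X, mask, cfg, dropout_mask = NULL) {
  d <- dim(X)
  B <- d[1]; M <- d[2]; WL <- d[3]; Fd <- d[4]
  BM <- B * M
  # [B,M,WL,F] flattens so row (t-1)*BM + (m-1)*B + b carries sample
  # (b, m) at window t -- exactly the stacked-step layout lstm_forward
  # expects with batch BM
  Xall <- matrix(X, BM * WL, Fd)
  w <- matrix(as.numeric(mask), BM, WL)
  w <- w / pmax(rowSums(w), 1)
  enc <- lstm_forward(Xall, WL, list(Wx = par$enc.Wx, Wh = par$enc.Wh,
                                     b = par$enc.b))
  pooled <- matrix(0, BM, cfg$encoder_hidden)
  for (t in seq_len(WL)) pooled <- pooled + enc$H[[t]] * w[, t]
  # rows of the latent matrix are ordered (m-1)*B + b, which doubles as
  # the stacked-step layout of the predictor LSTM (batch B, M steps)
  latent_bm <- sweep(pooled %*% par$proj.W, 2, par$proj.b, `+`)
  pred <- lstm_forward(latent_bm, M, list(Wx = par$pred.Wx,
                                          Wh = par$pred.Wh,
                                          b = par$pred.b))
  hT <- pred$H[[M]]
  hdrop <- if (is.null(dropout_mask)) hT else hT * dropout_mask
  out <- sweep(hdrop %*% par$head.W, 2, par$head.b, `+`)
  list(out = out, Xall = Xall, w = w, enc = enc, pooled = pooled,
       latent_bm = latent_bm, pred = pred, hT = hT,
       hdrop = hdrop, dropout_mask = dropout_mask,
       dims = c(B = B, M = M, WL = WL, Fd = Fd))
}

estimator_backward <- function(par, fw, dOut, cfg) {
  B <- fw$dims["B"]; M <- fw$dims["M"]; WL <- fw$dims["WL"]
  g <- list()
  g$head.W <- crossprod(fw$hdrop, dOut)
  g$head.b <- colSums(dOut)
  dhdrop <- dOut %*% t(par$head.W)
  dhT <- if (is.null(fw$dropout_mask)) dhdrop else dhdrop * fw$dropout_mask
  dHpred <- lapply(seq_len(M), function(m) matrix(0, B, cfg$predictor_hidden))
  dHpred[[M]] <- dhT
  bp <- lstm_backward(dHpred, fw$latent_bm, M,
                      list(Wx = par$pred.Wx, Wh = par$pred.Wh,
                           b = par$pred.b),
                      fw$pred$cache, want_dx = TRUE)
  g$pred.Wx <- bp$dWx; g$pred.Wh <- bp$dWh; g$pred.b <- bp$db
  dlatent_bm <- bp$dXall
  g$proj.W <- crossprod(fw$pooled, dlatent_bm)
  g$proj.b <- colSums(dlatent_bm)
  dpooled <- tcrossprod(dlatent_bm, par$proj.W)
  dHenc <- lapply(seq_len(WL), function(t) dpooled * fw$w[, t])
  be <- lstm_backward(dHenc, fw$Xall, WL,
                      list(Wx = par$enc.Wx, Wh = par$enc.Wh, b = par$enc.b),
                      fw$enc$cache, want_dx = FALSE)
  g$enc.Wx <- be$dWx; g$enc.Wh <- be$dWh; g$enc.b <- be$db
  g
}

# mean-squared-error loss and parameter gradients for one (possibly
# mixed) batch; the numerical-gradient tests exercise this directly
estimator_loss_grads <- function(par, X, mask, y, cfg, dropout_mask = NULL) {
  fw <- estimator_forward(par, X, mask, cfg, dropout_mask)
  err <- fw$out - y
  loss <- mean(err^2)
  dOut <- 2 * err / length(err)
  grads <- estimator_backward(par, fw, dOut, cfg)
  list(loss = loss, grads = grads, out = fw$out)
}

#' Encode a feature tensor into per-motion latents
#'
#' Each motion's window sequence is passed through the shared encoder
#' LSTM, the hidden states are mean-pooled over the real (non-padded)
#' windows, and a linear layer projects the pooled 256-vector down to the
#' 128-dimensional latent, giving a `[n_motions, 128]` matrix.
#'
#' @param model An `fmaue_estimator`.
#' @param tensor A normalized `fmaue_tensor` (`[n_motions, WL, 1530]`).
#' @return `n_motions x latent` matrix.
#' @export
encode <- function(model, tensor) {
  d <- dim(tensor)
  if (length(d) != 3 || d[1] != model$n_motions ||
      d[3] != model$cfg$input_size) {
    abort("tensor shape does not match the model configuration")
  }
  X <- array(0, c(1, d[1], d[2], d[3]))
  X[1, , , ] <- tensor
  mask <- attr(tensor, "mask")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  m <- array(mask, c(1, d[1], d[2]))
  m[1, , ] <- mask
  fw <- estimator_forward(model$params, X, m, model$cfg)
  matrix(fw$latent_bm, d[1], model$cfg$latent)
}

#' Predict normalized sub-scores from a latent matrix
#'
#' The predictor LSTM consumes the latent rows as a sequence in the fixed
#' motion order; the final-step hidden state passes through the
#' (inference-inactive) dropout and the linear head to give a `[1, 4]`
#' output of normalized sub-scores.
#'
#' @param model An `fmaue_estimator`.
#' @param latent `n_motions x latent` matrix from [encode()].
#' @return `1 x 4` matrix of normalized scores.
#' @export
predict_from_latent <- function(model, latent) {
  if (!is.matrix(latent) || nrow(latent) != model$n_motions ||
      ncol(latent) != model$cfg$latent) {
    abort("latent shape does not match the model configuration")
  }
  par <- model$params
  pred <- lstm_forward(latent, nrow(latent),
                       list(Wx = par$pred.Wx, Wh = par$pred.Wh,
                            b = par$pred.b))
  hT <- pred$H[[nrow(latent)]]
  sweep(hT %*% par$head.W, 2, par$head.b, `+`)
}

#' Predict normalized sub-scores for a feature tensor
#'
#' @param object An `fmaue_estimator`.
#' @param tensor A normalized `fmaue_tensor`.
#' @param ... Unused.
#' @return `1 x 4` matrix of normalized scores (deterministic: dropout is
#'   inactive at inference).
#' @export
predict.fmaue_estimator <- function(object, tensor, ...) {
  predict_from_latent(object, encode(object, tensor))
}

#' Save or load a self-describing estimator checkpoint
#'
#' A checkpoint is a single-file archive holding the parameters, model
#' and mixup configurations, training history, the feature-registry
#' version, and (when attached) the normalization statistics, so a saved
#' model can be reloaded and applied without the training session.
#'
#' @param model A trained `fmaue_estimator`.
#' @param path File path for the checkpoint.
#' @param norm Optional `fmaue_norm` to embed.
#' @return `save_estimator` invisibly returns `path`; `load_estimator`
#'   returns the `fmaue_estimator` (with a `norm` element when one was
#'   embedded).
#' @export
save_estimator <- function(model, path, norm = NULL) {
  payload <- list(params = model$params, cfg = model$cfg,
                  mixcfg = model$mixcfg, n_motions = model$n_motions,
                  history = model$history, norm = norm,
                  registry_version = REGISTRY_VERSION)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  p <- readRDS(path)
  if (!identical(p$registry_version, REGISTRY_VERSION)) {
    warn(paste0("checkpoint was built against feature registry ",
                p$registry_version, "; current is ", REGISTRY_VERSION))
  }
  structure(list(params = p$params, cfg = p$cfg, mixcfg = p$mixcfg,
                 n_motions = p$n_motions, history = p$history,
                 norm = p$norm),
            class = "fmaue_estimator")
}

#' Train the estimator
#'
#' Minimizes the MSE between predictions and (mixed-up) normalized
#' targets with Adam. Each batch is mixed with probability
#' `mixcfg$apply_prob`: a single `lambda ~ Beta(alpha, alpha)` is drawn
#' and the batch is convexly combined with a random within-batch
#' permutation of itself (targets likewise). With `apply_prob = 0` the
#' loop is plain MSE regression. Fully reproducible given `seed`.
#'
#' @param tensors List of normalized `fmaue_tensor` (training samples).
#' @param scores `n x 4` matrix of normalized true scores.
#' @param cfg A [model_config()].
#' @param mixcfg A [mixup_config()].
#' @param seed Integer seed (initialization, shuffling, mixup, dropout).
#' @return A trained `fmaue_estimator` with per-epoch MSE history.
#' @export
train_estimator <- function(tensors, scores, cfg = model_config(),
                            mixcfg = mixup_config(), seed = 1) {
  n <- length(tensors)
  if (n < 1) abort("need at least one training sample")
  scores <- matrix(scores, n, cfg$output_size)
  d <- dim(tensors[[1]])
  M <- d[1]; WL <- d[2]; Fd <- d[3]
  # flat layouts (one row per sample) make batch gather and mixup cheap
  X <- array(0, c(n, M, WL, Fd))
  maskarr <- array(TRUE, c(n, M, WL))
  for (i in seq_len(n)) {
    X[i, , , ] <- tensors[[i]]
    mk <- attr(tensors[[i]], "mask")
    if (!is.null(mk)) maskarr[i, , ] <- mk
  }
  Xmat <- matrix(X, n, M * WL * Fd)
  maskmat <- matrix(maskarr, n, M * WL)
  rm(X, maskarr)
  model <- init_estimator(cfg, n_motions = M, seed = seed)
  # deep-copy the parameter buffers: the Adam kernel updates them in place
  par <- lapply(model$params, function(x) x + 0)
  st <- adam_init(par)
  step <- 0
  hist <- numeric(cfg$epochs)
  with_seed(derive_seed(seed, 77), {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1, n)]
        B <- length(idx)
        Xb <- Xmat[idx, , drop = FALSE]
        yb <- scores[idx, , drop = FALSE]
        mb <- maskmat[idx, , drop = FALSE]
        if (B > 1 && runif(1) < mixcfg$apply_prob) {
          lam <- rbeta(1, mixcfg$alpha, mixcfg$alpha)
          p2 <- sample(B)
          Xb <- lam * Xb + (1 - lam) * Xb[p2, , drop = FALSE]
          yb <- lam * yb + (1 - lam) * yb[p2, , drop = FALSE]
          mb <- mb | mb[p2, , drop = FALSE]
        }
        dim(Xb) <- c(B, M, WL, Fd)
        dim(mb) <- c(B, M, WL)
        dm <- NULL
        if (cfg$dropout > 0) {
          dm <- (matrix(runif(B * cfg$predictor_hidden), B,
                        cfg$predictor_hidden) > cfg$dropout) /
            (1 - cfg$dropout)
        }
        lg <- estimator_loss_grads(par, Xb, mb, yb, cfg, dm)
        if (!is.finite(lg$loss)) {
          abort(paste0("NaN loss at epoch ", ep, "; aborting training"))
        }
        step <- step + 1
        upd <- adam_step(par, lg$grads, st, cfg$lr, step)
        par <- upd$params
        st <- upd$state
        losses <- c(losses, lg$loss)
      }
      hist[ep] <- mean(losses)
    }
  })
  model$params <- par
  model$mixcfg <- mixcfg
  model$history <- tibble::tibble(epoch = seq_len(cfg$epochs), mse = hist)
  model
}
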