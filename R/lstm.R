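# Dense LSTM layer with full backpropagation through time, implemented as
# batched BLAS matrix algebra. Gate order in the concatenated weight
# matrices is (input i, forget f, cell g, output o). Parameters follow the
# conventional uniform(-k, k) initialization with k = 1/sqrt(hidden).
#
# For speed the input projection of all time steps is computed as a single
# matrix product (it does not depend on the recurrence), and the weight
# gradients are likewise accumulated with one product over the stacked
# per-step gate gradients.

sigmoid <- function(x) 1 / (1 + exp(-x))

rand_unif <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)

lstm_init <- function(input, hidden) {
  k <- 1 / sqrt(hidden)
  list(Wx = rand_unif(input, 4 * hidden, k),
       Wh = rand_unif(hidden, 4 * hidden, k),
       b = runif(4 * hidden, -k, k))
}

linear_init <- function(input, output) {
  k <- 1 / sqrt(input)
  list(W = rand_unif(input, output, k), b = runif(output, -k, k))
}

# Xall: [(Tn * B) x D] inputs, rows (t-1)*B + b. Returns hidden states per
# step and the cache needed for BPTT.
lstm_forward <- function(Xall, Tn, p) {
  B <- nrow(Xall) / Tn
  Hd <- ncol(p$Wh) / 4
  Zx <- Xall %*% p$Wx
  h <- matrix(0, B, Hd)
  cc <- matrix(0, B, Hd)
  ii <- function(g) ((g - 1) * Hd + 1):(g * Hd)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1) * B + 1):(t * B)
    z <- Zx[rows, , drop = FALSE] + h %*% p$Wh
    z <- sweep(z, 2, p$b, `+`)
    i <- sigmoid(z[, ii(1), drop = FALSE])
    f <- sigmoid(z[, ii(2), drop = FALSE])
    g <- tanh(z[, ii(3), drop = FALSE])
    o <- sigmoid(z[, ii(4), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    H[[t]] <- h
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                       tc = tc, h_prev = h_prev)
  }
  list(H = H, cache = cache)
}

# dH: list over T of [B x H] gradients w.r.t. the hidden states.
# Returns parameter gradients and, when want_dx, the input gradients
# (stacked like Xall).
lstm_backward <- function(dH, Xall, Tn, p, cache, want_dx = FALSE) {
  B <- nrow(Xall) / Tn
  Hd <- ncol(p$Wh) / 4
  dZall <- matrix(0, nrow(Xall), 4 * Hd)
  Hprev <- matrix(0, nrow(Xall), Hd)
  dh_next <- matrix(0, B, Hd)
  dc_next <- matrix(0, B, Hd)
  for (t in rev(seq_len(Tn))) {
    cs <- cache[[t]]
    dh <- dH[[t]] + dh_next
    do <- dh * cs$tc
    dc <- dh * cs$o * (1 - cs$tc^2) + dc_next
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc_next <- dc * cs$f
    dz <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do * cs$o * (1 - cs$o))
    rows <- ((t - 1) * B + 1):(t * B)
    dZall[rows, ] <- dz
    Hprev[rows, ] <- cs$h_prev
    dh_next <- tcrossprod(dz, p$Wh)
  }
  out <- list(dWx = crossprod(Xall, dZall),
              dWh = crossprod(Hprev, dZall),
              db = colSums(dZall))
  if (want_dx) out$dXall <- tcrossprod(dZall, p$Wx)
  out
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# In-place Adam update (C++ kernel): params, moment estimates and the
# update are mutated without allocation; the caller owns all buffers.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    adam_update_cpp(params[[nm]], state[[nm]]$m, state[[nm]]$v,
                    grads[[nm]], lr, beta1, beta2, eps,
                    1 - beta1^t, 1 - beta2^t)
  }
  list(params = params, state = state)
}
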