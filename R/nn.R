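# Minimal neural-network primitives in base R matrix code: explicit forward
# and backward passes for the layers the encoder and classifier need, plus
# AdamW with decoupled weight decay and a cosine-annealing learning rate.
# Arrays with a sequence axis are stored as (n*T) x C matrices whose rows are
# ordered sample-fastest (column-major reshape of an (n, T, C) array), so the
# same reshape convention must be used on both passes.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# ---- conv1d (valid padding, stride 1) ---------------------------------------

# x: (n*T_in) x C_in matrix; returns im2col matrix (n*T_out) x (k*C_in)
im2col <- function(x, n, t_in, k) {
  c_in <- ncol(x)
  t_out <- t_in - k + 1L
  arr <- array(x, c(n, t_in, c_in))
  cols <- matrix(0, n * t_out, k * c_in)
  for (j in seq_len(k)) {
    sub <- arr[, j:(j + t_out - 1L), , drop = FALSE]
    dim(sub) <- c(n * t_out, c_in)
    cols[, ((j - 1L) * c_in + 1L):(j * c_in)] <- sub
  }
  cols
}

col2im <- function(dcols, n, t_in, k, c_in) {
  t_out <- t_in - k + 1L
  darr <- array(0, c(n, t_in, c_in))
  for (j in seq_len(k)) {
    piece <- dcols[, ((j - 1L) * c_in + 1L):(j * c_in), drop = FALSE]
    dim(piece) <- c(n, t_out, c_in)
    darr[, j:(j + t_out - 1L), ] <- darr[, j:(j + t_out - 1L), , drop = FALSE] + piece
  }
  dim(darr) <- c(n * t_in, c_in)
  darr
}

conv1d_forward <- function(x, w, b, n, t_in, k) {
  cols <- im2col(x, n, t_in, k)
  out <- sweep(cols %*% w, 2, b, "+")
  list(out = out, cols = cols)
}

conv1d_backward <- function(dout, cache_cols, w, n, t_in, k, c_in) {
  dw <- crossprod(cache_cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(w)
  dx <- col2im(dcols, n, t_in, k, c_in)
  list(dx = dx, dw = dw, db = db)
}

# ---- batch norm (per channel over all rows) ---------------------------------

bn_forward <- function(x, gamma, beta, running, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, invstd = invstd, running = running)
}

bn_backward <- function(dout, cache, gamma) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * cache$xhat)
  dx <- sweep(
    sweep(dxhat, 2, mean_dxhat) - sweep(cache$xhat, 2, mean_dxhat_xhat, "*"),
    2, cache$invstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- simple layers ----------------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, mask) dout * mask

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - p
  mask <- matrix(stats::runif(length(x)) < keep, nrow(x), ncol(x)) / keep
  list(out = x * mask, mask = mask)
}
dropout_backward <- function(dout, mask) if (is.null(mask)) dout else dout * mask

dense_forward <- function(x, w, b) list(out = sweep(x %*% w, 2, b, "+"), x = x)
dense_backward <- function(dout, x, w) {
  list(dx = dout %*% t(w), dw = crossprod(x, dout), db = colSums(dout))
}

# global max pool over the sequence axis: x is (n*T) x C, returns n x C
maxpool_forward <- function(x, n, t) {
  c_ <- ncol(x)
  arr <- array(x, c(n, t, c_))
  idx <- apply(arr, c(1, 3), which.max)   # n x C positions
  out <- matrix(0, n, c_)
  for (ch in seq_len(c_)) out[, ch] <- arr[cbind(seq_len(n), idx[, ch], ch)]
  list(out = out, idx = idx)
}
maxpool_backward <- function(dout, idx, n, t) {
  c_ <- ncol(dout)
  darr <- array(0, c(n, t, c_))
  for (ch in seq_len(c_)) {
    darr[cbind(seq_len(n), idx[, ch], ch)] <- dout[, ch]
  }
  dim(darr) <- c(n * t, c_)
  darr
}

# ---- optimizer / schedule ---------------------------------------------------

adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

# Decoupled weight decay: p <- p - lr * (mhat/(sqrt(vhat)+eps) + wd * p)
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-6,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Cosine-annealed learning rate
#'
#' @param epoch current epoch (1-based).
#' @param total total number of epochs in the schedule.
#' @param lr0 initial learning rate.
#' @param lr_min floor of the schedule.
#' @return the learning rate for `epoch`.
#' @keywords internal
cosine_lr <- function(epoch, total, lr0, lr_min = 0) {
  if (total <= 1L) return(lr0)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / (total - 1)))
}
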