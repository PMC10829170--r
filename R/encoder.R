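# The contrastive molecular encoder: token embedding + 1D-convolutional
# feature extractor e(.) producing the representation h, a two-layer
# projection head g(.) producing z, and InfoNCE pre-training over
# canonical/randomized SMILES view pairs.

#' Encoder configuration
#'
#' Architecture and training-geometry constants of the contrastive encoder.
#' The embedding width (116), vocabulary size (148) and representation width
#' (262) are the framework's fixed constants; the convolution stack, dropout,
#' projection head and temperature are tunable.
#'
#' @param vocab_size vocabulary size (148).
#' @param embed_dim token embedding width (116).
#' @param conv_channels output channels of each conv block.
#' @param kernel_sizes kernel length of each conv block (same length as
#'   `conv_channels`).
#' @param dropout dropout probability between conv blocks, in \[0, 1).
#' @param repr_dim width of the transferred representation h (262).
#' @param proj_dims widths of the two projection-head layers.
#' @param temperature InfoNCE temperature tau (> 0; default 0.1, chosen on
#'   representation-quality diagnostics, see the package vignette).
#' @param max_len fixed token-sequence length fed to the encoder.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(vocab_size = 148L, embed_dim = 116L,
                           conv_channels = c(128L, 192L, 256L),
                           kernel_sizes = c(5L, 5L, 3L),
                           dropout = 0.1, repr_dim = 262L,
                           proj_dims = c(256L, 128L),
                           temperature = 0.1, max_len = 250L) {
  if (length(conv_channels) != length(kernel_sizes) || length(conv_channels) < 1L)
    config_error("conv_channels and kernel_sizes must have equal length >= 1")
  if (dropout < 0 || dropout >= 1) config_error("dropout must be in [0, 1)")
  if (temperature <= 0) config_error("temperature must be > 0")
  if (length(proj_dims) != 2L) config_error("proj_dims must have length 2")
  if (max_len <= sum(kernel_sizes - 1L))
    config_error("max_len too short for the convolution stack")
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim),
                 conv_channels = as.integer(conv_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 dropout = dropout, repr_dim = as.integer(repr_dim),
                 proj_dims = as.integer(proj_dims),
                 temperature = temperature, max_len = as.integer(max_len)),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(paste0("<encoder_config: vocab %d, embed %d, conv [%s] k=[%s], ",
                     "repr %d, proj [%s], tau %.3g, max_len %d>\n"),
              x$vocab_size, x$embed_dim,
              paste(x$conv_channels, collapse = ","),
              paste(x$kernel_sizes, collapse = ","),
              x$repr_dim, paste(x$proj_dims, collapse = ","),
              x$temperature, x$max_len))
  invisible(x)
}

#' Initialize an untrained encoder
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for the parameter initialization.
#' @return list of class `encoder_net` with `params`, `bn` running statistics
#'   and the config.
#' @export
init_encoder <- function(config = encoder_config(), seed = 0L) {
  with_seed(seed, {
    p <- list()
    p$emb <- matrix(stats::rnorm(config$vocab_size * config$embed_dim, sd = 0.1),
                    config$vocab_size, config$embed_dim)
    bn <- list()
    c_in <- config$embed_dim
    for (b in seq_along(config$conv_channels)) {
      k <- config$kernel_sizes[b]; c_out <- config$conv_channels[b]
      p[[paste0("conv", b, "_w")]] <- he_init(k * c_in, c_out, k * c_in)
      p[[paste0("conv", b, "_b")]] <- numeric(c_out)
      p[[paste0("bn", b, "_gamma")]] <- rep(1, c_out)
      p[[paste0("bn", b, "_beta")]] <- numeric(c_out)
      bn[[b]] <- list(mean = numeric(c_out), var = rep(1, c_out))
      c_in <- c_out
    }
    p$repr_w <- he_init(c_in, config$repr_dim, c_in)
    p$repr_b <- numeric(config$repr_dim)
    p$proj1_w <- he_init(config$repr_dim, config$proj_dims[1], config$repr_dim)
    p$proj1_b <- numeric(config$proj_dims[1])
    p$proj2_w <- he_init(config$proj_dims[1], config$proj_dims[2],
                         config$proj_dims[1])
    p$proj2_b <- numeric(config$proj_dims[2])
    structure(list(params = p, bn = bn, config = config), class = "encoder_net")
  })
}

# Forward pass. ids: n x max_len matrix of 0-based token ids. Returns the
# output (h or z), the cache needed for the backward pass, and the net (whose
# batch-norm running statistics are updated when training = TRUE).
encoder_forward <- function(net, ids, mode = "projection", training = FALSE) {
  cfg <- net$config
  if (!is.matrix(ids)) shape_error("ids must be a matrix")
  if (ncol(ids) != cfg$max_len)
    shape_error(sprintf("token length %d != config max_len %d",
                        ncol(ids), cfg$max_len))
  if (any(ids < 0L) || any(ids >= cfg$vocab_size))
    shape_error("token id outside vocabulary")
  n <- nrow(ids)
  flat <- as.vector(ids) + 1L
  x <- net$params$emb[flat, , drop = FALSE]   # (n*L) x D, sample-fastest
  t_cur <- cfg$max_len
  blocks <- list()
  for (b in seq_along(cfg$conv_channels)) {
    k <- cfg$kernel_sizes[b]
    c_in <- ncol(x)
    cv <- conv1d_forward(x, net$params[[paste0("conv", b, "_w")]],
                         net$params[[paste0("conv", b, "_b")]], n, t_cur, k)
    bnr <- bn_forward(cv$out, net$params[[paste0("bn", b, "_gamma")]],
                      net$params[[paste0("bn", b, "_beta")]],
                      net$bn[[b]], training)
    net$bn[[b]] <- bnr$running
    rl <- relu_forward(bnr$out)
    dr <- dropout_forward(rl$out, cfg$dropout, training)
    blocks[[b]] <- list(cols = cv$cols, bn = bnr, relu_mask = rl$mask,
                        drop_mask = dr$mask, t_in = t_cur, c_in = c_in, k = k)
    x <- dr$out
    t_cur <- t_cur - k + 1L
  }
  mp <- maxpool_forward(x, n, t_cur)
  hr <- dense_forward(mp$out, net$params$repr_w, net$params$repr_b)
  cache <- list(flat = flat, n = n, blocks = blocks, mp = mp, hr = hr,
                t_pool = t_cur)
  if (mode == "representation") {
    return(list(out = hr$out, cache = cache, net = net))
  }
  p1 <- dense_forward(hr$out, net$params$proj1_w, net$params$proj1_b)
  r1 <- relu_forward(p1$out)
  p2 <- dense_forward(r1$out, net$params$proj2_w, net$params$proj2_b)
  cache$p1 <- p1; cache$r1 <- r1; cache$p2 <- p2
  list(out = p2$out, cache = cache, net = net)
}

# Backward pass; dout has the shape of the forward output (z gradients for
# mode = "projection"). Returns a named list of parameter gradients.
encoder_backward <- function(net, cache, dout, mode = "projection") {
  cfg <- net$config
  g <- list()
  if (mode == "projection") {
    d2 <- dense_backward(dout, cache$p2$x, net$params$proj2_w)
    g$proj2_w <- d2$dw; g$proj2_b <- d2$db
    dr1 <- relu_backward(d2$dx, cache$r1$mask)
    d1 <- dense_backward(dr1, cache$p1$x, net$params$proj1_w)
    g$proj1_w <- d1$dw; g$proj1_b <- d1$db
    dh <- d1$dx
  } else {
    dh <- dout
  }
  dr <- dense_backward(dh, cache$hr$x, net$params$repr_w)
  g$repr_w <- dr$dw; g$repr_b <- dr$db
  dx <- maxpool_backward(dr$dx, cache$mp$idx, cache$n, cache$t_pool)
  for (b in rev(seq_along(cfg$conv_channels))) {
    blk <- cache$blocks[[b]]
    dx <- dropout_backward(dx, blk$drop_mask)
    dx <- relu_backward(dx, blk$relu_mask)
    bnb <- bn_backward(dx, blk$bn, net$params[[paste0("bn", b, "_gamma")]])
    g[[paste0("bn", b, "_gamma")]] <- bnb$dgamma
    g[[paste0("bn", b, "_beta")]] <- bnb$dbeta
    cvb <- conv1d_backward(bnb$dx, blk$cols,
                           net$params[[paste0("conv", b, "_w")]],
                           cache$n, blk$t_in, blk$k, blk$c_in)
    g[[paste0("conv", b, "_w")]] <- cvb$dw
    g[[paste0("conv", b, "_b")]] <- cvb$db
    dx <- cvb$dx
  }
  # scatter-add embedding gradient
  demb <- rowsum(dx, group = cache$flat)
  g$emb <- matrix(0, cfg$vocab_size, cfg$embed_dim)
  g$emb[as.integer(rownames(demb)), ] <- demb
  g
}

#' Embed token sequences or SMILES with a (pre-)trained encoder
#'
#' Runs the encoder in evaluation mode (dropout off, batch statistics
#' frozen), returning either the transferred representation h or the
#' projection z.
#'
#' @param model an `encoder_net` or a [pretrain()] state (its best
#'   checkpoint is used).
#' @param x an n x max_len matrix of 0-based token ids, a list of
#'   [encode()] results, or a character vector of SMILES (encoded
#'   internally).
#' @param mode `"representation"` (width `repr_dim`) or `"projection"`.
#' @param vocab vocabulary used when `x` contains SMILES strings.
#' @return numeric matrix with one row per input.
#' @export
embed <- function(model, x, mode = c("representation", "projection"),
                  vocab = build_vocabulary()) {
  mode <- match.arg(mode)
  net <- if (inherits(model, "pretrain_state")) model$net else model
  if (!inherits(net, "encoder_net")) config_error("model is not an encoder")
  if (is.character(x)) {
    x <- encode_batch(x, vocab, net$config$max_len)
  } else if (is.list(x) && !is.matrix(x)) {
    x <- do.call(rbind, lapply(x, function(s) s$ids))
  }
  encoder_forward(net, x, mode = mode, training = FALSE)$out
}

# ---- contrastive objective --------------------------------------------------

#' Cosine similarity of two vectors
#'
#' `(a . b) / (||a|| ||b||)`, clamped to \[-1, 1\] against floating-point
#' rounding. The maximum attainable value is 1 (parallel vectors), the
#' minimum -1 (anti-parallel).
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return a real in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) shape_error("vector lengths differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) degenerate_vector_error()
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Construct a contrastive batch
#'
#' @param z numeric matrix of 2m projected views.
#' @param pair_index 0-based integer vector mapping each row to its positive
#'   partner; must be an involution with no fixed points.
#' @return list of class `contrastive_batch`.
#' @export
contrastive_batch <- function(z, pair_index) {
  z <- as.matrix(z)
  pair_index <- as.integer(pair_index)
  n <- nrow(z)
  if (length(pair_index) != n) shape_error("pair_index length != rows of z")
  if (any(pair_index < 0L) || any(pair_index >= n))
    value_error("pair_index out of range")
  p1 <- pair_index + 1L
  if (any(p1[p1] != seq_len(n)) || any(p1 == seq_len(n)))
    value_error("pair_index must be a fixed-point-free involution")
  structure(list(z = z, pair_index = pair_index), class = "contrastive_batch")
}

# loss + gradient in one pass; pair is 1-based partner index
info_nce_core <- function(z, pair, tau, want_grad = FALSE) {
  n <- nrow(z)
  norms <- sqrt(rowSums(z^2))
  if (any(norms == 0)) degenerate_vector_error("projection row with zero norm")
  u <- z / norms
  s <- tcrossprod(u)
  logits <- s / tau
  diag(logits) <- -Inf
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  denom <- rowSums(ex)
  p <- ex / denom
  loss_i <- -(logits[cbind(seq_len(n), pair)] - mx - log(denom))
  loss <- mean(loss_i)
  if (!want_grad) return(list(loss = loss))
  onehot <- matrix(0, n, n)
  onehot[cbind(seq_len(n), pair)] <- 1
  dlogits <- (p - onehot) / n
  ds <- dlogits / tau
  du <- (ds + t(ds)) %*% u
  dz <- (du - u * rowSums(du * u)) / norms
  list(loss = loss, dz = dz)
}

#' InfoNCE contrastive loss
#'
#' For each ordered positive pair (i, j) the per-pair loss is
#' `-log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`
#' with `sim` the cosine similarity; the returned value is the mean over all
#' 2m ordered pairs, computed with the max-subtraction log-sum-exp trick.
#'
#' @param batch a [contrastive_batch()].
#' @param temperature positive temperature tau.
#' @return non-negative scalar loss.
#' @export
info_nce_loss <- function(batch, temperature) {
  if (!inherits(batch, "contrastive_batch"))
    value_error("batch must be a contrastive_batch")
  if (temperature <= 0) value_error("temperature must be > 0")
  info_nce_core(batch$z, batch$pair_index + 1L, temperature)$loss
}

#' Top-1 view-retrieval accuracy
#'
#' Fraction of anchors whose own positive partner (row i of `z_candidates`)
#' attains the strict maximum cosine similarity among all candidates; ties
#' count as failures.
#'
#' @param z_anchor,z_candidates matrices with m rows each; row i of
#'   `z_candidates` is the positive partner of row i of `z_anchor`.
#' @return a real in \[0, 1\].
#' @export
top1_accuracy <- function(z_anchor, z_candidates) {
  z_anchor <- as.matrix(z_anchor); z_candidates <- as.matrix(z_candidates)
  if (ncol(z_anchor) != ncol(z_candidates)) shape_error("widths differ")
  if (nrow(z_anchor) != nrow(z_candidates)) shape_error("row counts differ")
  m <- nrow(z_anchor)
  if (m < 2L) value_error("need at least 2 anchors")
  ua <- z_anchor / sqrt(rowSums(z_anchor^2))
  uc <- z_candidates / sqrt(rowSums(z_candidates^2))
  s <- tcrossprod(ua, uc)
  hits <- vapply(seq_len(m), function(i) {
    s[i, i] > max(s[i, -i])
  }, logical(1))
  mean(hits)
}

# ---- pre-training -----------------------------------------------------------

#' Contrastive pre-training on enumerated SMILES views
#'
#' Each epoch every training molecule contributes its canonical SMILES plus
#' one randomized view drawn (with a per-epoch seed) from its pre-enumerated
#' view pool (at most 50 views per molecule). Batches of 2m views are scored
#' with the InfoNCE loss and optimized with AdamW (decoupled weight decay)
#' under a cosine-annealed learning rate. Molecules are split 80:20 into
#' train/validation with the MaxMin diversity picker; the best checkpoint by
#' validation loss is retained.
#'
#' @param molecules a data.frame from [molecule_table()] (column
#'   `smiles_canonical`) or a character vector of SMILES.
#' @param config an [encoder_config()].
#' @param epochs number of epochs (0 returns the initialized model).
#' @param batch_size molecules per batch (>= 2; each contributes 2 views).
#' @param seed master seed; pooling, shuffling, dropout and initialization
#'   all derive from it, so runs are exactly reproducible.
#' @param val_fraction fraction of molecules held out as the diverse
#'   validation set (default 0.2).
#' @param lr initial learning rate (default 1e-3).
#' @param weight_decay AdamW decoupled weight decay (default 1e-6).
#' @param pool_size views enumerated per molecule (capped at 50).
#' @param verbose print one line per epoch.
#' @return list of class `pretrain_state`: `net` (best checkpoint),
#'   `final_net`, `best_val_loss`, `history` (per-epoch train_loss, val_loss,
#'   acc_top1), `config`, and the train/validation indices.
#' @export
pretrain <- function(molecules, config = encoder_config(), epochs,
                     batch_size, seed = 0L, val_fraction = 0.2,
                     lr = 1e-3, weight_decay = 1e-6, pool_size = 50L,
                     verbose = FALSE) {
  smiles <- if (is.data.frame(molecules)) molecules$smiles_canonical
            else canonicalize(molecules)
  if (length(smiles) < 2L) config_error("need at least 2 molecules")
  if (batch_size < 2L)
    config_error("batch_size must be >= 2: the contrastive loss is undefined")
  vocab <- build_vocabulary()
  if (config$vocab_size != length(vocab$tokens))
    config_error("config vocab_size does not match the vocabulary")

  n_mol <- length(smiles)
  # diverse validation side via MaxMin on ECFP fingerprints
  fps <- lapply(smiles, circular_fingerprint)
  mm <- maxmin_split(fps, select_fraction = val_fraction,
                     seed = derive_seed(seed, "maxmin"))
  val_idx <- mm$selected; train_idx <- mm$remainder

  # view pools (<= 50 views each), enumerated once
  pools <- lapply(seq_len(n_mol), function(i) {
    enumerate_randomized(smiles[i], pool_size,
                         seed = derive_seed(seed, "pool", i))
  })
  can_ids <- encode_batch(smiles, vocab, config$max_len)
  pool_ids <- lapply(pools, function(v) encode_batch(v, vocab, config$max_len))

  net <- init_encoder(config, seed = derive_seed(seed, "init"))
  opt <- adamw_init(net$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), acc_top1 = numeric())
  best <- list(net = net, val_loss = Inf)
  if (epochs == 0L) {
    return(structure(list(net = net, final_net = net, best_val_loss = NA_real_,
                          history = history, config = config,
                          train_indices = train_idx, val_indices = val_idx),
                     class = "pretrain_state"))
  }

  eval_split <- function(idx) {
    # canonical vs first pool view, evaluation mode
    anchors <- can_ids[idx, , drop = FALSE]
    views <- do.call(rbind, lapply(pool_ids[idx], function(m) m[1, ]))
    za <- encoder_forward(net, anchors, "projection", FALSE)$out
    zv <- encoder_forward(net, views, "projection", FALSE)$out
    z <- rbind(za, zv)
    m <- length(idx)
    pair <- c(m + seq_len(m), seq_len(m))
    list(loss = info_nce_core(z, pair, config$temperature)$loss,
         acc = if (m >= 2L) top1_accuracy(za, zv) else NA_real_)
  }

  for (e in seq_len(epochs)) {
    lr_e <- cosine_lr(e, epochs, lr)
    train_loss <- with_seed(derive_seed(seed, "epoch", e), {
      order_idx <- sample(train_idx)
      losses <- numeric()
      start <- 1L
      while (start <= length(order_idx)) {
        idx <- order_idx[start:min(start + batch_size - 1L, length(order_idx))]
        start <- start + batch_size
        if (length(idx) < 2L) break
        m <- length(idx)
        views <- do.call(rbind, lapply(idx, function(i) {
          pm <- pool_ids[[i]]
          pm[sample.int(nrow(pm), 1L), ]
        }))
        ids <- rbind(can_ids[idx, , drop = FALSE], views)
        fw <- encoder_forward(net, ids, "projection", training = TRUE)
        net <- fw$net
        pair <- c(m + seq_len(m), seq_len(m))
        res <- info_nce_core(fw$out, pair, config$temperature, want_grad = TRUE)
        grads <- encoder_backward(net, fw$cache, res$dz, "projection")
        upd <- adamw_step(net$params, grads, opt, lr_e, weight_decay)
        net$params <- upd$params
        opt <- upd$state
        losses <- c(losses, res$loss)
      }
      mean(losses)
    })
    ev <- with_seed(derive_seed(seed, "eval", e), eval_split(val_idx))
    history <- rbind(history, data.frame(epoch = e, train_loss = train_loss,
                                         val_loss = ev$loss, acc_top1 = ev$acc))
    if (ev$loss < best$val_loss) best <- list(net = net, val_loss = ev$loss)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  acc_top1 %.3f",
                      e, lr_e, train_loss, ev$loss, ev$acc))
  }
  structure(list(net = best$net, final_net = net,
                 best_val_loss = best$val_loss, history = history,
                 config = config, train_indices = train_idx,
                 val_indices = val_idx),
            class = "pretrain_state")
}

#' @export
print.pretrain_state <- function(x, ...) {
  cat(sprintf("<pretrain_state: %d epochs, best val loss %.4f>\n",
              nrow(x$history), x$best_val_loss))
  invisible(x)
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint bundles the model parameters, the configuration and a hash
#' of the vocabulary so stale encodings are detected at load time.
#'
#' @param state a `pretrain_state` or `encoder_net`.
#' @param path file path.
#' @return `save_checkpoint` returns `path`; `load_checkpoint` the restored
#'   object.
#' @export
save_checkpoint <- function(state, path) {
  vocab <- build_vocabulary()
  obj <- list(state = state,
              vocab_hash = sum(utf8ToInt(paste(vocab$tokens, collapse = ""))))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  vocab <- build_vocabulary()
  h <- sum(utf8ToInt(paste(vocab$tokens, collapse = "")))
  if (!identical(obj$vocab_hash, h))
    config_error("checkpoint was built against a different vocabulary")
  obj$state
}

#' Export embeddings to CSV
#'
#' @param model encoder or pretrain state.
#' @param molecules molecule table (columns `id`, `smiles_canonical`).
#' @param path output CSV path.
#' @param mode representation or projection.
#' @return the path, invisibly.
#' @export
export_embeddings <- function(model, molecules, path,
                              mode = "representation") {
  h <- embed(model, molecules$smiles_canonical, mode = mode)
  df <- data.frame(id = molecules$id, h)
  names(df) <- c("id", sprintf("dim_%d", seq_len(ncol(h))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
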