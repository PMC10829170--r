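# Transfer stage: frozen-encoder drug representations are concatenated per
# pair and fed to a feed-forward multiclass side-effect classifier trained
# with the negative log-likelihood objective under one of three
# imbalance-handling sampling strategies.

#' Classifier configuration
#'
#' @param hidden_dims widths of the hidden layers (default 1024, 512).
#' @param dropout dropout probability between hidden layers.
#' @param n_classes number of side-effect classes C (>= 2).
#' @param batch_size minibatch size (default 256).
#' @param epochs training epochs (default 200; the best epoch by validation
#'   weighted F1 is kept).
#' @param sampler one of `"balanced_batch"`, `"class_weight"`,
#'   `"weighted_random"`.
#' @param symmetrize_pairs if TRUE the training set additionally contains
#'   the swapped order of every pair.
#' @param standardize if TRUE pair features are z-scored on the training
#'   partition before the classifier sees them. Off by default: the
#'   transfer procedure feeds the concatenated representations to the
#'   classifier as-is, and the conditioning of the learned representation is
#'   part of what the pre-training ablation measures.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(hidden_dims = c(1024L, 512L), dropout = 0.2,
                              n_classes, batch_size = 256L, epochs = 200L,
                              sampler = c("balanced_batch", "class_weight",
                                          "weighted_random"),
                              symmetrize_pairs = FALSE, standardize = FALSE) {
  sampler <- match.arg(sampler)
  if (n_classes < 2L) config_error("n_classes must be >= 2")
  if (dropout < 0 || dropout >= 1) config_error("dropout must be in [0, 1)")
  structure(list(hidden_dims = as.integer(hidden_dims), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), sampler = sampler,
                 symmetrize_pairs = isTRUE(symmetrize_pairs),
                 standardize = isTRUE(standardize)),
            class = "classifier_config")
}

#' Concatenate a drug-pair representation
#'
#' `[h1 || h2]` — order-sensitive by construction; use
#' `symmetrize_pairs` in the classifier config to train on both orders.
#'
#' @param h1,h2 representation vectors of equal width.
#' @return numeric vector of width `2 * length(h1)`.
#' @export
featurize_pair <- function(h1, h2) {
  if (length(h1) != length(h2)) shape_error("representation widths differ")
  c(h1, h2)
}

#' Negative log-likelihood loss
#'
#' `-(1/n) sum_i log P(Y = y_i | x_i)` from a matrix of per-class
#' log-probabilities.
#'
#' @param log_prob n x C matrix of log-probabilities (each row must
#'   exponentiate-and-sum to 1 within 1e-6).
#' @param labels integer vector of true classes (0-based).
#' @return non-negative scalar.
#' @export
nll_loss <- function(log_prob, labels) {
  log_prob <- as.matrix(log_prob)
  n <- nrow(log_prob); C <- ncol(log_prob)
  if (length(labels) != n) shape_error("labels length != rows")
  if (any(labels < 0L | labels >= C)) value_error("label outside 0..C-1")
  if (any(abs(rowSums(exp(log_prob)) - 1) > 1e-6))
    value_error("rows must be log-probabilities summing (in exp) to 1")
  -mean(log_prob[cbind(seq_len(n), labels + 1L)])
}

#' Minibatch sampler for imbalanced classes
#'
#' Returns a deterministic batch iterator implementing one of the three
#' imbalance-handling strategies: `balanced_batch` emits batches whose
#' per-class counts differ by at most one (minority classes resampled with
#' replacement; if C exceeds the batch size, each batch covers a rotating
#' subset of classes, one example each); `class_weight` weights every
#' example by the inverse of its class frequency and draws a class by its
#' total weight — every class carries weight n_c * (1/n_c) = 1, so classes
#' are drawn uniformly — then an example uniformly within the class;
#' `weighted_random` draws examples with replacement with probability
#' proportional to 1/(class frequency).
#'
#' @param labels integer class vector (every class present at least once).
#' @param strategy sampling strategy.
#' @param batch_size examples per batch.
#' @param seed integer seed; the batch stream is reproducible under it.
#' @return list with `draw()` (returns the next index vector) and `reset()`.
#' @export
make_sampler <- function(labels, strategy = c("balanced_batch", "class_weight",
                                              "weighted_random"),
                         batch_size, seed = 0L) {
  strategy <- match.arg(strategy)
  classes <- sort(unique(labels))
  C <- length(classes)
  if (length(labels) == 0L || C == 0L) value_error("empty class")
  idx_by_class <- lapply(classes, function(c) which(labels == c))
  freq <- vapply(idx_by_class, length, integer(1))
  if (strategy == "balanced_batch" && C > batch_size)
    message("more classes than batch_size: batches rotate over class subsets")
  counter <- new.env(parent = emptyenv())
  counter$t <- 0L
  draw <- function() {
    counter$t <- counter$t + 1L
    with_seed(derive_seed(seed, "batch", counter$t), {
      if (strategy == "balanced_batch") {
        if (C > batch_size) {
          start <- ((counter$t - 1L) * batch_size) %% C
          cls_sel <- ((start + seq_len(batch_size) - 1L) %% C) + 1L
          out <- vapply(cls_sel, function(ci) {
            ids <- idx_by_class[[ci]]
            ids[sample.int(length(ids), 1L)]
          }, integer(1))
        } else {
          base <- batch_size %/% C
          rem <- batch_size %% C
          extra_cls <- if (rem > 0L)
            (((counter$t - 1L) * rem + seq_len(rem) - 1L) %% C) + 1L
          else integer()
          out <- unlist(lapply(seq_len(C), function(ci) {
            k <- base + sum(extra_cls == ci)
            ids <- idx_by_class[[ci]]
            ids[sample.int(length(ids), k, replace = TRUE)]
          }))
          out <- sample(out)   # shuffle within the batch
        }
      } else if (strategy == "class_weight") {
        # inverse-frequency example weights aggregated per class: each class
        # carries total weight n_c * (1/n_c) = 1, so classes are drawn
        # uniformly, then an example uniformly within the class
        cls_sel <- sample.int(C, batch_size, replace = TRUE)
        out <- vapply(cls_sel, function(ci) {
          ids <- idx_by_class[[ci]]
          ids[sample.int(length(ids), 1L)]
        }, integer(1))
      } else {
        w <- 1 / freq[match(labels, classes)]
        out <- sample.int(length(labels), batch_size, replace = TRUE, prob = w)
      }
      out
    })
  }
  list(draw = draw, reset = function() counter$t <- 0L,
       strategy = strategy, n_classes = C)
}

# ---- MLP internals ----------------------------------------------------------

init_mlp <- function(in_dim, hidden, n_classes, seed) {
  with_seed(seed, {
    p <- list()
    dims <- c(in_dim, hidden, n_classes)
    for (l in seq_len(length(dims) - 1L)) {
      p[[paste0("w", l)]] <- he_init(dims[l], dims[l + 1L], dims[l])
      p[[paste0("b", l)]] <- numeric(dims[l + 1L])
    }
    p
  })
}

mlp_forward <- function(p, x, dropout, training) {
  n_layer <- length(p) / 2L
  cache <- list()
  for (l in seq_len(n_layer)) {
    d <- dense_forward(x, p[[paste0("w", l)]], p[[paste0("b", l)]])
    cache[[l]] <- list(dense = d)
    x <- d$out
    if (l < n_layer) {
      r <- relu_forward(x)
      dr <- dropout_forward(r$out, dropout, training)
      cache[[l]]$relu_mask <- r$mask
      cache[[l]]$drop_mask <- dr$mask
      x <- dr$out
    }
  }
  list(logits = x, cache = cache)
}

mlp_backward <- function(p, cache, dlogits) {
  n_layer <- length(p) / 2L
  g <- list()
  dx <- dlogits
  for (l in rev(seq_len(n_layer))) {
    if (l < n_layer) {
      dx <- dropout_backward(dx, cache[[l]]$drop_mask)
      dx <- relu_backward(dx, cache[[l]]$relu_mask)
    }
    d <- dense_backward(dx, cache[[l]]$dense$x, p[[paste0("w", l)]])
    g[[paste0("w", l)]] <- d$dw
    g[[paste0("b", l)]] <- d$db
    dx <- d$dx
  }
  g
}

log_softmax <- function(logits) {
  mx <- apply(logits, 1, max)
  s <- logits - mx
  s - log(rowSums(exp(s)))
}

# ---- training ---------------------------------------------------------------

pair_features <- function(pairs, drug_repr) {
  h1 <- drug_repr[pairs$drug1_smiles, , drop = FALSE]
  h2 <- drug_repr[pairs$drug2_smiles, , drop = FALSE]
  cbind(h1, h2)
}

#' Train and evaluate the DDI side-effect classifier
#'
#' The encoder is used as a frozen feature extractor: every distinct drug is
#' embedded once (representation h), pair features are the concatenation
#' `[h1 || h2]`, and only the newly added feed-forward layers are trained
#' (AdamW, cosine-annealed learning rate, NLL objective, the configured
#' imbalance sampler). The epoch with the best validation weighted F1 is
#' kept for inference.
#'
#' @param train,val,test data.frames of pairs (`drug1_smiles`,
#'   `drug2_smiles`, `label`); labels must share one 0..C-1 space.
#' @param encoder a [pretrain()] state or `encoder_net` (frozen), or an
#'   [encoder_config()] — in which case a randomly initialized frozen
#'   encoder of that shape is used (the un-pretrained ablation arm). `NULL`
#'   means the default config's random encoder.
#' @param config a [classifier_config()].
#' @param seed integer seed (initialization, samplers, dropout).
#' @param lr initial learning rate.
#' @param weight_decay AdamW weight decay.
#' @param verbose print one line per epoch.
#' @return list of class `ddi_model`: fitted parameters, the frozen drug
#'   representations, per-partition `metric_report`s in `$reports`, and the
#'   training history.
#' @export
train_and_evaluate <- function(train, val, test, encoder = NULL, config,
                               seed = 0L, lr = 1e-3, weight_decay = 1e-6,
                               verbose = FALSE) {
  if (nrow(train) == 0L || nrow(val) == 0L || nrow(test) == 0L)
    config_error("all partitions must be non-empty")
  C <- config$n_classes
  for (part in list(train, val, test)) {
    if (any(part$label < 0L | part$label >= C))
      config_error("label outside the configured class space")
  }
  if (is.null(encoder)) encoder <- encoder_config()
  if (inherits(encoder, "encoder_config")) {
    encoder <- init_encoder(encoder, seed = derive_seed(seed, "randenc"))
  }
  net <- if (inherits(encoder, "pretrain_state")) encoder$net else encoder

  drugs <- unique(c(train$drug1_smiles, train$drug2_smiles,
                    val$drug1_smiles, val$drug2_smiles,
                    test$drug1_smiles, test$drug2_smiles))
  h <- embed(net, drugs, mode = "representation")
  rownames(h) <- drugs

  train_fit <- train
  if (config$symmetrize_pairs) {
    swapped <- data.frame(drug1_smiles = train$drug2_smiles,
                          drug2_smiles = train$drug1_smiles,
                          label = train$label, stringsAsFactors = FALSE)
    train_fit <- rbind(train, swapped)
  }
  x_train <- pair_features(train_fit, h)
  if (isTRUE(config$standardize)) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- numeric(ncol(x_train))
    sdv <- rep(1, ncol(x_train))
  }
  scale_x <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  x_train <- scale_x(x_train)
  x_val <- scale_x(pair_features(val, h))
  x_test <- scale_x(pair_features(test, h))

  p <- init_mlp(ncol(x_train), config$hidden_dims, C,
                derive_seed(seed, "mlp"))
  opt <- adamw_init(p)
  sampler <- make_sampler(train_fit$label, config$sampler,
                          config$batch_size, derive_seed(seed, "sampler"))
  steps_per_epoch <- max(1L, ceiling(nrow(x_train) / config$batch_size))

  predict_prob <- function(x) {
    lp <- log_softmax(mlp_forward(p, x, config$dropout, FALSE)$logits)
    exp(lp)
  }
  best <- list(p = p, f1 = -Inf, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_f1 = numeric())
  for (e in seq_len(config$epochs)) {
    lr_e <- cosine_lr(e, config$epochs, lr)
    losses <- with_seed(derive_seed(seed, "cls_epoch", e), {
      ls <- numeric(steps_per_epoch)
      for (s in seq_len(steps_per_epoch)) {
        idx <- sampler$draw()
        xb <- x_train[idx, , drop = FALSE]
        yb <- train_fit$label[idx]
        fw <- mlp_forward(p, xb, config$dropout, TRUE)
        lp <- log_softmax(fw$logits)
        ls[s] <- nll_loss(lp, yb)
        nb <- length(idx)
        dlogits <- exp(lp)
        dlogits[cbind(seq_len(nb), yb + 1L)] <-
          dlogits[cbind(seq_len(nb), yb + 1L)] - 1
        dlogits <- dlogits / nb
        g <- mlp_backward(p, fw$cache, dlogits)
        upd <- adamw_step(p, g, opt, lr_e, weight_decay)
        p <- upd$params
        opt <- upd$state
      }
      ls
    })
    val_rep <- classification_report(val$label, predict_prob(x_val))
    history <- rbind(history, data.frame(epoch = e, train_loss = mean(losses),
                                         val_f1 = val_rep$f1_weighted))
    if (val_rep$f1_weighted > best$f1)
      best <- list(p = p, f1 = val_rep$f1_weighted, epoch = e)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val F1w %.4f", e, mean(losses),
                      val_rep$f1_weighted))
  }
  p <- best$p
  reports <- list(train = classification_report(train$label,
                                                predict_prob(scale_x(pair_features(train, h)))),
                  val = classification_report(val$label, predict_prob(x_val)),
                  test = classification_report(test$label, predict_prob(x_test)))
  structure(list(params = p, config = config, drug_repr = h,
                 scaler = list(mean = mu, sd = sdv), reports = reports,
                 best_epoch = best$epoch, history = history,
                 encoder = net),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model: best epoch %d, test F1w %.3f>\n",
              x$best_epoch, x$reports$test$f1_weighted))
  invisible(x)
}

#' Predict side-effect class probabilities for drug pairs
#'
#' @param model a fitted `ddi_model`.
#' @param pairs data.frame with `drug1_smiles`, `drug2_smiles`.
#' @return n x C matrix of class probabilities (rows sum to 1).
#' @export
predict_ddi <- function(model, pairs) {
  drugs <- unique(c(pairs$drug1_smiles, pairs$drug2_smiles))
  new <- setdiff(drugs, rownames(model$drug_repr))
  h <- model$drug_repr
  if (length(new) > 0L) {
    hn <- embed(model$encoder, new, mode = "representation")
    rownames(hn) <- new
    h <- rbind(h, hn)
  }
  x <- pair_features(pairs, h)
  x <- sweep(sweep(x, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  lp <- log_softmax(mlp_forward(model$params, x, model$config$dropout,
                                FALSE)$logits)
  exp(lp)
}
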