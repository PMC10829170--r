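test_that("cosine similarity attains its stated bounds and exact values", {
  expect_identical(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_identical(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-6)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)),
               class = "degenerate_vector_error")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), class = "shape_error")
})

test_that("InfoNCE matches its closed-form special cases", {
  # all four projections identical: every similarity equal, denominator has
  # 2m - 1 = 3 equal terms -> log 3, independent of temperature
  z <- matrix(rep(c(0.3, 0.4), each = 4), 4, 2)
  b <- contrastive_batch(z, c(1L, 0L, 3L, 2L))
  for (tau in c(0.1, 0.5, 2)) {
    expect_equal(info_nce_loss(b, tau), log(3), tolerance = 1e-9)
  }
  # m = 1: the denominator holds only the positive term -> loss 0
  z2 <- matrix(c(1, 0, 0.2, 0.9), 2, 2, byrow = TRUE)
  expect_equal(info_nce_loss(contrastive_batch(z2, c(1L, 0L)), 0.3), 0,
               tolerance = 1e-9)
  # m = 2 with two orthogonal duplicated pairs at tau = 1:
  # per-pair loss -log(e / (e + 2))
  z3 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  got <- info_nce_loss(contrastive_batch(z3, c(1L, 0L, 3L, 2L)), 1)
  expect_equal(got, -log(exp(1) / (exp(1) + 2)), tolerance = 1e-6)
  expect_equal(got, 0.55144, tolerance = 1e-4)
})

test_that("InfoNCE equals a brute-force double-loop oracle on random batches", {
  set.seed(20)
  for (rep in 1:50) {
    m <- sample(2:8, 1)
    d <- sample(c(4L, 16L), 1)
    z <- matrix(rnorm(2 * m * d), 2 * m, d)
    perm0 <- c(m + seq_len(m), seq_len(m)) - 1L
    tau <- runif(1, 0.2, 2)
    expect_equal(info_nce_loss(contrastive_batch(z, perm0), tau),
                 nce_bruteforce(z, perm0, tau), tolerance = 1e-6)
  }
})

test_that("lower temperature decreases the loss for well-separated positives", {
  z <- rbind(c(1, 0.02), c(1, -0.02), c(-0.02, 1), c(0.02, 1))
  b <- contrastive_batch(z, c(1L, 0L, 3L, 2L))
  taus <- c(1, 0.5, 0.2, 0.1)
  losses <- vapply(taus, function(t) info_nce_loss(b, t), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("contrastive batches reject invalid pairings", {
  z <- matrix(rnorm(8), 4, 2)
  expect_error(contrastive_batch(z, c(0L, 1L, 2L, 3L)), class = "value_error")
  expect_error(contrastive_batch(z, c(1L, 0L, 3L)), class = "shape_error")
})

test_that("embedding widths follow the configuration and the default is 262", {
  cfg <- tiny_encoder_config()
  net <- init_encoder(cfg, seed = 1)
  v <- build_vocabulary()
  ids <- contrastDDI:::encode_batch(c("CCO", "c1ccccc1"), v, cfg$max_len)
  h <- embed(net, ids, mode = "representation")
  expect_identical(dim(h), c(2L, 12L))
  z <- embed(net, ids, mode = "projection")
  expect_identical(ncol(z), cfg$proj_dims[2])
  # framework constants under the default configuration
  dflt <- encoder_config()
  expect_identical(dflt$vocab_size, 148L)
  expect_identical(dflt$embed_dim, 116L)
  expect_identical(dflt$repr_dim, 262L)
  net_d <- init_encoder(dflt, seed = 1)
  hd <- embed(net_d, c("CCO", "c1ccccc1"))
  expect_identical(ncol(hd), 262L)
})

test_that("evaluation-mode embedding is deterministic for identical inputs", {
  cfg <- tiny_encoder_config(dropout = 0.3)
  net <- init_encoder(cfg, seed = 2)
  h <- embed(net, c("CCO", "CCO", "c1ccccc1"))
  expect_identical(h[1, ], h[2, ])
  h2 <- embed(net, c("CCO", "CCO", "c1ccccc1"))
  expect_identical(h, h2)
})

test_that("encoder gradients match finite differences", {
  cfg <- encoder_config(embed_dim = 5L, conv_channels = c(4L, 3L),
                        kernel_sizes = c(3L, 3L), dropout = 0,
                        repr_dim = 6L, proj_dims = c(5L, 4L), max_len = 10L)
  net <- init_encoder(cfg, seed = 4)
  set.seed(9)
  ids <- matrix(sample(0:147, 4 * 10, replace = TRUE), 4, 10)
  pair <- c(3L, 4L, 1L, 2L)
  fw <- contrastDDI:::encoder_forward(net, ids, "projection", TRUE)
  res <- contrastDDI:::info_nce_core(fw$out, pair, 0.6, want_grad = TRUE)
  grads <- contrastDDI:::encoder_backward(fw$net, fw$cache, res$dz)
  eps <- 1e-5
  for (nm in c("conv1_w", "bn2_gamma", "repr_w", "proj1_w")) {
    idx <- sample(length(net$params[[nm]]), 3)
    for (i in idx) {
      up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      lu <- contrastDDI:::info_nce_core(
        contrastDDI:::encoder_forward(up, ids, "projection", TRUE)$out,
        pair, 0.6)$loss
      ld <- contrastDDI:::info_nce_core(
        contrastDDI:::encoder_forward(dn, ids, "projection", TRUE)$out,
        pair, 0.6)$loss
      expect_equal(grads[[nm]][i], (lu - ld) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("top-1 retrieval accuracy handles identity, shifts and chance level", {
  z <- diag(6)
  expect_identical(top1_accuracy(z, z), 1)
  expect_identical(top1_accuracy(z, z[c(2:6, 1), ]), 0)
  expect_error(top1_accuracy(z, diag(5)), class = "shape_error")
  # random rankings give 1/m on average (Monte-Carlo oracle)
  set.seed(33)
  m <- 100L
  accs <- replicate(200, {
    top1_accuracy(matrix(rnorm(m * 64), m, 64), matrix(rnorm(m * 64), m, 64))
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / m), 3 * se + 1e-12)
})

test_that("pretraining is reproducible, records history, and epochs = 0 is inert", {
  lib <- small_library()[1:16, ]
  cfg <- tiny_encoder_config()
  st0 <- pretrain(lib, cfg, epochs = 0L, batch_size = 4, seed = 5,
                  pool_size = 4)
  expect_identical(nrow(st0$history), 0L)
  expect_s3_class(st0$net, "encoder_net")
  st1 <- pretrain(lib, cfg, epochs = 2L, batch_size = 4, seed = 5,
                  pool_size = 4)
  st2 <- pretrain(lib, cfg, epochs = 2L, batch_size = 4, seed = 5,
                  pool_size = 4)
  expect_identical(st1$history, st2$history)
  expect_identical(st1$net$params, st2$net$params)
  expect_identical(nrow(st1$history), 2L)
  expect_equal(st1$best_val_loss, min(st1$history$val_loss))
  expect_error(pretrain(lib, cfg, epochs = 1L, batch_size = 1, seed = 1),
               class = "config_error")
})

test_that("checkpoints round-trip through disk with a vocabulary guard", {
  lib <- small_library()[1:8, ]
  st <- pretrain(lib, tiny_encoder_config(), epochs = 1L, batch_size = 4,
                 seed = 6, pool_size = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path)
  expect_identical(back$net$params, st$net$params)
})
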