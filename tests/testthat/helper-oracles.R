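# Independent oracles used to cross-check the package implementations, and
# memoized small fixtures shared across test files. Oracles are deliberately
# naive (brute force / closed form) and share no code with the functions
# they validate.

.fixture_cache <- new.env(parent = emptyenv())

small_library <- function() {
  if (is.null(.fixture_cache$lib)) {
    .fixture_cache$lib <- generate_molecule_library(
      fixture_config(n_scaffold_families = 4L, per_family = 10L, seed = 42L))
  }
  .fixture_cache$lib
}

small_ddi <- function(label_noise = 0, n_pairs = 600L, n_classes = 4L,
                      seed = 7L) {
  key <- sprintf("ddi_%g_%d_%d_%d", label_noise, n_pairs, n_classes, seed)
  if (is.null(.fixture_cache[[key]])) {
    fc <- fixture_config(n_scaffold_families = 4L, per_family = 10L,
                         n_classes = n_classes, label_noise = label_noise,
                         n_pairs = n_pairs, seed = seed)
    .fixture_cache[[key]] <- generate_ddi_dataset(small_library(), fc)
  }
  .fixture_cache[[key]]
}

tiny_encoder_config <- function(dropout = 0, ...) {
  encoder_config(embed_dim = 8L, conv_channels = c(8L, 8L),
                 kernel_sizes = c(3L, 3L), dropout = dropout, repr_dim = 12L,
                 proj_dims = c(10L, 8L), max_len = 32L, ...)
}

# brute-force InfoNCE: explicit double loop over ordered pairs and
# normalizing sums, built on cosine_similarity directly
nce_bruteforce <- function(z, pair_index0, tau) {
  n <- nrow(z)
  total <- 0
  for (i in seq_len(n)) {
    j <- pair_index0[i] + 1L
    num <- exp(cosine_similarity(z[i, ], z[j, ]) / tau)
    den <- 0
    for (k in seq_len(n)) {
      if (k != i) den <- den + exp(cosine_similarity(z[i, ], z[k, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / n
}

# brute-force Apriori: enumerate every non-empty subset of the item universe
# and count containing transactions
apriori_bruteforce <- function(transactions, min_support) {
  transactions <- lapply(transactions, unique)
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  out <- list()
  for (mask in seq_len(2L^length(items) - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2L^(seq_along(items) - 1L)))
    set <- items[sel]
    cnt <- sum(vapply(transactions, function(t) all(set %in% t), logical(1)))
    if (cnt / n >= min_support - 1e-12) {
      out[[length(out) + 1L]] <- list(itemset = set, support = cnt / n)
    }
  }
  out
}

# canonical string key per itemset (order-preserving across the collection)
itemset_key_each <- function(sets) {
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}
# sorted key set for whole-collection comparison
itemset_key <- function(sets) sort(itemset_key_each(sets))

# confusion-matrix metric oracle: per-class one-vs-rest arithmetic,
# Mann-Whitney AUROC, step-sum average precision
report_oracle <- function(y_true, prob) {
  C <- ncol(prob)
  y_pred <- apply(prob, 1, which.max) - 1L
  support <- prec <- rec <- f1 <- auroc <- auprc <- numeric(C)
  for (c in 0:(C - 1L)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    support[c + 1] <- sum(y_true == c)
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else NA
    f1[c + 1] <- if (!is.na(rec[c + 1]) && prec[c + 1] + rec[c + 1] > 0)
      2 * prec[c + 1] * rec[c + 1] / (prec[c + 1] + rec[c + 1]) else 0
    pos <- prob[y_true == c, c + 1]; neg <- prob[y_true != c, c + 1]
    if (length(pos) > 0 && length(neg) > 0) {
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      auroc[c + 1] <- mean(cmp)
    } else auroc[c + 1] <- NA
    if (length(pos) > 0) {
      ord <- order(prob[, c + 1], decreasing = TRUE)
      yy <- as.integer(y_true[ord] == c)
      auprc[c + 1] <- sum((cumsum(yy) / seq_along(yy))[yy == 1]) / sum(yy)
    } else auprc[c + 1] <- NA
  }
  present <- support > 0
  w <- support[present] / sum(support[present])
  list(acc = mean(y_pred == y_true),
       f1_weighted = sum(w * f1[present]),
       precision_weighted = sum(w * prec[present]),
       recall_weighted = sum(w * rec[present]),
       auroc_macro = mean(auroc[present], na.rm = TRUE),
       auprc_macro = mean(auprc[present], na.rm = TRUE))
}

# random probability matrix with rows summing to 1
random_prob <- function(n, C) {
  m <- matrix(stats::rexp(n * C), n, C)
  m / rowSums(m)
}
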