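toy_transactions <- list(c("A", "B"), c("A", "B"), c("A", "C"), c("B"))

test_that("FP-Growth reproduces the worked toy supports", {
  got <- fp_growth(toy_transactions, 0.5)
  key <- sapply(got$itemset, paste, collapse = ",")
  supp <- setNames(got$support, key)
  expect_equal(unname(supp["A"]), 0.75)
  expect_equal(unname(supp["B"]), 0.75)
  expect_equal(unname(supp["A,B"]), 0.5)
  expect_identical(nrow(got), 3L)          # C (0.25) is below threshold
  # min_support = 1 keeps only items in every transaction
  expect_identical(nrow(fp_growth(toy_transactions, 1)), 0L)
  expect_identical(nrow(fp_growth(list(c("A"), c("A")), 1)), 1L)
  expect_error(fp_growth(toy_transactions, 0), class = "value_error")
  expect_error(fp_growth(list(), 0.5), class = "value_error")
})

test_that("FP-Growth equals brute-force Apriori on random transaction sets", {
  set.seed(17)
  for (i in 1:40) {
    n_items <- sample(3:10, 1)
    n_trans <- sample(5:60, 1)
    items <- LETTERS[seq_len(n_items)]
    trans <- lapply(seq_len(n_trans), function(j) {
      sample(items, sample.int(min(n_items, 6L), 1))
    })
    ms <- sample(c(0.05, 0.1, 0.25, 0.5), 1)
    got <- fp_growth(trans, ms)
    want <- apriori_bruteforce(trans, ms)
    expect_identical(itemset_key(got$itemset),
                     itemset_key(lapply(want, `[[`, "itemset")))
    want_supp <- setNames(vapply(want, `[[`, numeric(1), "support"),
                          itemset_key_each(lapply(want, `[[`, "itemset")))
    got_supp <- setNames(got$support, itemset_key_each(got$itemset))
    expect_equal(got_supp[names(want_supp)], want_supp, tolerance = 1e-12)
  }
})

test_that("association rules carry the hand-computed support/confidence/lift", {
  freq <- fp_growth(toy_transactions, 0.2)
  rules <- association_rules(freq, min_confidence = 0)
  key <- sprintf("%s=>%s",
                 sapply(rules$antecedent, paste, collapse = ","),
                 sapply(rules$consequent, paste, collapse = ","))
  ab <- which(key == "A=>B")
  expect_equal(rules$support[ab], 0.5)
  expect_equal(rules$confidence[ab], 0.5 / 0.75, tolerance = 1e-12)
  expect_equal(rules$lift[ab], (0.5 / 0.75) / 0.75, tolerance = 1e-12)
  # a consequent always co-occurring with its antecedent: C => A
  ca <- which(key == "C=>A")
  expect_equal(rules$confidence[ca], 1)
  # constructed independence: P(X, Y) = P(X) P(Y) gives lift 1
  ind <- list(c("X", "Y"), c("X"), c("Y"), character(0))
  ind[[4]] <- c("Z")
  rules_ind <- association_rules(fp_growth(ind, 0.2), min_confidence = 0)
  k2 <- sprintf("%s=>%s",
                sapply(rules_ind$antecedent, paste, collapse = ","),
                sapply(rules_ind$consequent, paste, collapse = ","))
  expect_equal(rules_ind$lift[k2 == "X=>Y"], 1, tolerance = 1e-12)
  expect_error(association_rules(freq, 2), class = "value_error")
})

test_that("profile matrices binarize pair occurrences", {
  pairs <- data.frame(
    drug1_smiles = c("OCCc1ccccc1", "Cc1ccccc1", "CC1CCNCC1", "CCO"),
    drug2_smiles = c("CC1CCNCC1", "CC1CCNCC1", "Cc1ccncc1", "Cc1ccccc1"),
    label = c("L0", "L0", "L1", "L2"),
    stringsAsFactors = FALSE)
  pm <- build_profile_matrix(pairs, "interaction")
  benz <- canonicalize("c1ccccc1"); pip <- canonicalize("C1CCNCC1")
  # two pairs share the benzene x piperidine combination -> still 1
  expect_identical(pm$values[match(benz, pm$row_names),
                             match(pip, pm$col_names)], 1L)
  expect_true(all(pm$values %in% c(0L, 1L)))
  # brute-force scan: every observed combination set, nothing else
  sc <- function(s) { x <- murcko_scaffold(s); if (nzchar(x)) x else "(acyclic)" }
  for (i in seq_len(nrow(pm$values))) {
    for (j in seq_len(ncol(pm$values))) {
      seen <- any(vapply(seq_len(nrow(pairs)), function(k) {
        sc(pairs$drug1_smiles[k]) == pm$row_names[i] &&
          sc(pairs$drug2_smiles[k]) == pm$col_names[j]
      }, logical(1)))
      expect_identical(pm$values[i, j] == 1L, seen)
    }
  }
  # duplicated input pairs leave the matrix unchanged
  pm_dup <- build_profile_matrix(rbind(pairs, pairs), "interaction")
  expect_identical(pm_dup$values, pm$values)
  # side-effect mode: acyclic drugs form their own row
  pm_se <- build_profile_matrix(pairs, "side_effect")
  expect_true("(acyclic)" %in% pm_se$row_names)
  expect_identical(pm_se$col_names, c("L0", "L1", "L2"))
  expect_identical(pm_se$values[match("(acyclic)", pm_se$row_names), ],
                   c(0L, 0L, 1L))
  # empty input -> 0 x 0
  empty <- build_profile_matrix(pairs[0, ], "interaction")
  expect_identical(dim(empty$values), c(0L, 0L))
})

test_that("the similarity suite reproduces the popcount worked example", {
  # N = 16, a = 4, b = 6, c = 3
  a <- c(rep(1, 4), rep(0, 12))
  b <- c(0, 1, 1, 1, rep(0, 4), 1, 1, 1, rep(0, 5))
  expect_equal(bit_similarity(a, b, "tanimoto"), 3 / 7, tolerance = 1e-12)
  expect_equal(bit_similarity(a, b, "dice"), 0.6, tolerance = 1e-12)
  expect_equal(bit_similarity(a, b, "kulczynski"), 0.625, tolerance = 1e-12)
  expect_equal(bit_similarity(a, b, "asymmetric"), 0.75, tolerance = 1e-12)
  # reference cheminformatics toolkit (RDKit RogotGoldbergSimilarity) on the
  # same bitvectors: 0.7090909090909091
  expect_equal(bit_similarity(a, b, "rogot_goldberg"), 0.70909090909,
               tolerance = 1e-9)
})

test_that("similarity metrics are symmetric, bounded and tanimoto <= dice", {
  set.seed(19)
  metrics <- c("tanimoto", "dice", "kulczynski", "asymmetric",
               "rogot_goldberg")
  for (i in 1:25) {
    a <- rbinom(24, 1, 0.4); b <- rbinom(24, 1, 0.4)
    if (sum(a) == 0 || sum(b) == 0) next
    for (m in metrics) {
      expect_equal(bit_similarity(a, b, m), bit_similarity(b, a, m),
                   tolerance = 1e-12, label = m)
    }
    expect_lte(bit_similarity(a, b, "tanimoto"),
               bit_similarity(a, b, "dice") + 1e-12)
  }
  v <- rbinom(24, 1, 0.5); v[1] <- 1
  for (m in c("tanimoto", "dice", "kulczynski", "asymmetric")) {
    expect_equal(bit_similarity(v, v, m), 1, label = m)
  }
  z <- rep(0, 8)
  expect_equal(bit_similarity(c(1, 1, rep(0, 6)), c(0, 0, 1, 1, rep(0, 4)),
                              "tanimoto"), 0)
  expect_error(bit_similarity(z, z, "tanimoto"),
               class = "degenerate_vector_error")
})

test_that("Jaccard profile clustering matches the reference hierarchical cut", {
  # 5-row toy: two tight profile groups and one outlier. The reference
  # single-linkage + depth-2 inconsistency cut (SciPy fclusterdata with the
  # Jaccard metric, t = 1.0) yields labels (1, 1, 2, 2, 3).
  m <- rbind(c(1, 1, 1, 0, 0, 0, 0, 0),
             c(1, 1, 0, 0, 0, 0, 0, 0),
             c(0, 0, 0, 1, 1, 1, 0, 0),
             c(0, 0, 0, 1, 1, 0, 0, 0),
             c(0, 0, 0, 0, 0, 0, 1, 1))
  labels <- cluster_binary_profiles(m, threshold = 1.0)
  expect_identical(length(unique(labels)), 3L)
  expect_identical(labels[1], labels[2])
  expect_identical(labels[3], labels[4])
  expect_false(labels[1] == labels[3])
  expect_false(labels[5] %in% labels[1:4])
})

test_that("identical profiles co-cluster and orthogonal ones stay singletons", {
  m <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 1, 0, 0), c(1, 0, 1, 0))
  labels <- cluster_binary_profiles(m, threshold = 1.0)
  expect_identical(labels[1], labels[2])
  expect_identical(labels[1], labels[4])
  orth <- diag(4L)
  labels2 <- cluster_binary_profiles(orth, threshold = -1)
  expect_identical(length(unique(labels2)), 4L)
  expect_warning(l3 <- cluster_binary_profiles(rbind(c(1, 1), c(0, 0)), 1.0),
                 "all-zero")
  expect_identical(length(unique(l3)), 2L)
})

test_that("intra/inter cluster summaries behave on constructed families", {
  fp <- function(bits) structure(list(bits = as.integer(bits),
                                      n_bits = length(bits), radius = 2L),
                                 class = "fingerprint")
  same <- lapply(1:3, function(i) fp(c(1, 1, 1, 1, 0, 0, 0, 0)))
  s <- cluster_similarity_summary(rep(1L, 3), same)
  expect_equal(s$intra, 1)
  # two block-structured families: intra similarity exceeds inter
  famA <- lapply(1:3, function(i) { b <- rep(0, 12); b[1:4] <- 1; b[4 + i] <- 1; fp(b) })
  famB <- lapply(1:3, function(i) { b <- rep(0, 12); b[9:12] <- 1; b[4 + i] <- 1; fp(b) })
  s2 <- cluster_similarity_summary(c(1L, 1L, 1L, 2L, 2L, 2L), c(famA, famB))
  expect_gt(s2$intra, s2$inter)
  expect_identical(sum(s2$per_cluster$n_pairs),
                   sum(choose(table(c(1, 1, 1, 2, 2, 2)), 2)))
  expect_error(cluster_similarity_summary(1:3, same), class = "value_error")
})

test_that("pair transactions encode scaffolds with optional labels", {
  pairs <- data.frame(drug1_smiles = c("OCCc1ccccc1", "CCO"),
                      drug2_smiles = c("CC1CCNCC1", "Cc1ccccc1"),
                      label = c("L0", "L1"), stringsAsFactors = FALSE)
  tr <- pair_transactions(pairs)
  expect_identical(length(tr), 2L)
  expect_true("(acyclic)" %in% tr[[2]])
  tr2 <- pair_transactions(pairs, include_label = TRUE)
  expect_true("label:L0" %in% tr2[[1]])
  expect_identical(anyDuplicated(tr2[[1]]), 0L)
})
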