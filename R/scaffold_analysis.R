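# Scaffold-level dataset mining: FP-Growth frequent-itemset mining over
# scaffold(/side-effect) transactions, association rules, binary
# interaction and side-effect profile matrices, single-linkage Jaccard
# clustering with an inconsistency-criterion cut, and a five-metric binary
# similarity suite with intra/inter-cluster summaries.

ACYCLIC_LABEL <- "(acyclic)"

scaffold_or_acyclic <- function(s) ifelse(nzchar(s), s, ACYCLIC_LABEL)

#' Build scaffold transactions from a DDI pair table
#'
#' One transaction per pair containing the two drugs' scaffold families
#' (acyclic drugs contribute the shared `"(acyclic)"` item) and, optionally,
#' the side-effect label as an additional item. Items within a transaction
#' are unique.
#'
#' @param pairs data.frame with `drug1_smiles`, `drug2_smiles`, `label`.
#' @param include_label add the side-effect label as an item.
#' @param scaffold_fn function mapping SMILES to scaffold (default
#'   [murcko_scaffold()]); results are cached per distinct SMILES.
#' @return list of character vectors (class `transaction_set`).
#' @export
pair_transactions <- function(pairs, include_label = FALSE,
                              scaffold_fn = murcko_scaffold) {
  drugs <- unique(c(pairs$drug1_smiles, pairs$drug2_smiles))
  sc <- vapply(drugs, scaffold_fn, character(1))
  sc <- scaffold_or_acyclic(sc)
  names(sc) <- drugs
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    items <- c(sc[[pairs$drug1_smiles[i]]], sc[[pairs$drug2_smiles[i]]])
    if (include_label) items <- c(items, paste0("label:", pairs$label[i]))
    unique(items)
  })
  structure(out, class = "transaction_set")
}

# ---- FP-Growth --------------------------------------------------------------

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item; e$count <- 0; e$children <- list(); e$parent <- parent
  e
}

fp_insert <- function(root, items, w, header) {
  node <- root
  for (it in items) {
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- fp_node(it, node)
      node$children[[it]] <- child
      header[[it]] <- c(header[[it]], child)
    }
    child$count <- child$count + w
    node <- child
  }
  header
}

fp_mine <- function(transactions, weights, min_count, suffix, N, acc) {
  # frequent items in this (conditional) database
  items <- unlist(transactions)
  w_rep <- rep(weights, lengths(transactions))
  counts <- tapply(w_rep, items, sum)
  freq_items <- names(counts)[counts >= min_count]
  if (length(freq_items) == 0L) return(acc)
  # deterministic order: decreasing count, then lexical
  ord <- order(-counts[freq_items], freq_items)
  freq_items <- freq_items[ord]
  # build tree with items ordered by global-in-db frequency
  root <- fp_node(NULL, NULL)
  header <- stats::setNames(vector("list", length(freq_items)), freq_items)
  rank <- stats::setNames(seq_along(freq_items), freq_items)
  for (i in seq_along(transactions)) {
    its <- transactions[[i]]
    its <- its[its %in% freq_items]
    if (length(its) == 0L) next
    its <- its[order(rank[its])]
    header <- fp_insert(root, its, weights[i], header)
  }
  # mine items in increasing frequency order
  for (it in rev(freq_items)) {
    supp <- sum(vapply(header[[it]], function(nd) nd$count, numeric(1)))
    itemset <- sort(c(it, suffix))
    acc[[paste(itemset, collapse = "\r")]] <- supp / N
    # conditional pattern base
    ctrans <- list(); cw <- numeric()
    for (nd in header[[it]]) {
      path <- character()
      p <- nd$parent
      while (!is.null(p$item)) {
        path <- c(p$item, path)
        p <- p$parent
      }
      if (length(path) > 0L) {
        ctrans[[length(ctrans) + 1L]] <- path
        cw <- c(cw, nd$count)
      }
    }
    if (length(ctrans) > 0L)
      acc <- fp_mine(ctrans, cw, min_count, c(it, suffix), N, acc)
  }
  acc
}

#' FP-Growth frequent itemset mining
#'
#' Exhaustively enumerates all itemsets whose support (fraction of
#' transactions containing the itemset) reaches `min_support`, using the
#' FP-tree recursive mining algorithm.
#'
#' @param transactions list of character vectors (items per transaction;
#'   duplicates within a transaction are collapsed).
#' @param min_support minimum support in (0, 1].
#' @return data.frame with list-column `itemset` (sorted character vectors)
#'   and `support`, ordered by decreasing support then lexically.
#' @export
fp_growth <- function(transactions, min_support) {
  if (min_support <= 0 || min_support > 1)
    value_error("min_support must be in (0, 1]")
  if (length(transactions) == 0L) value_error("need at least one transaction")
  transactions <- lapply(transactions, function(t) unique(as.character(t)))
  N <- length(transactions)
  min_count <- min_support * N - 1e-9
  acc <- fp_mine(transactions, rep(1, N), min_count, character(), N, list())
  if (length(acc) == 0L)
    return(data.frame(itemset = I(list()), support = numeric()))
  itemsets <- lapply(names(acc), function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  support <- unlist(acc, use.names = FALSE)
  key <- vapply(itemsets, paste, character(1), collapse = " ")
  ord <- order(-support, key)
  out <- data.frame(support = support[ord])
  out$itemset <- I(itemsets[ord])
  out[, c("itemset", "support")]
}

#' Association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every non-trivial bipartition
#' into antecedent A and consequent B: support = supp(A u B), confidence =
#' supp(A u B)/supp(A), lift = confidence/supp(B). Rules below
#' `min_confidence` are dropped.
#'
#' @param frequent output of [fp_growth()] (computed from `transactions`).
#' @param min_confidence confidence threshold in \[0, 1\].
#' @return data.frame with list-columns `antecedent`, `consequent` and
#'   numeric `support`, `confidence`, `lift`.
#' @export
association_rules <- function(frequent, min_confidence = 0) {
  if (min_confidence < 0 || min_confidence > 1)
    value_error("min_confidence must be in [0, 1]")
  supp_of <- stats::setNames(frequent$support,
                             vapply(frequent$itemset, paste, character(1),
                                    collapse = "\r"))
  look <- function(items) {
    s <- supp_of[paste(sort(items), collapse = "\r")]
    if (is.na(s)) value_error(sprintf(
      "support of {%s} unknown; frequent set is not downward-closed",
      paste(items, collapse = ", ")))
    unname(s)
  }
  rows <- list()
  for (r in seq_len(nrow(frequent))) {
    items <- frequent$itemset[[r]]
    k <- length(items)
    if (k < 2L) next
    s_ab <- frequent$support[r]
    for (mask in seq_len(2L^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      a <- items[sel]; b <- items[!sel]
      conf <- s_ab / look(a)
      if (conf < min_confidence) next
      rows[[length(rows) + 1L]] <-
        list(antecedent = a, consequent = b, support = s_ab,
             confidence = conf, lift = conf / look(b))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(antecedent = I(list()), consequent = I(list()),
                      support = numeric(), confidence = numeric(),
                      lift = numeric()))
  out <- data.frame(
    support = vapply(rows, `[[`, numeric(1), "support"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    lift = vapply(rows, `[[`, numeric(1), "lift"))
  out$antecedent <- I(lapply(rows, `[[`, "antecedent"))
  out$consequent <- I(lapply(rows, `[[`, "consequent"))
  out[, c("antecedent", "consequent", "support", "confidence", "lift")]
}

# ---- profile matrices -------------------------------------------------------

#' Binary scaffold profile matrix
#'
#' `mode = "interaction"`: rows are scaffolds observed at pair position 1,
#' columns scaffolds at position 2; cell (i, j) is 1 iff any pair with that
#' scaffold combination exists (presence, deliberately not a count).
#' `mode = "side_effect"`: rows are scaffolds from either position, columns
#' side-effect labels; cell is 1 iff the scaffold occurs in any pair with
#' that label.
#'
#' @param pairs data.frame with `drug1_smiles`, `drug2_smiles`, `label`.
#' @param mode `"interaction"` or `"side_effect"`.
#' @param scaffold_fn scaffold function (cached per distinct SMILES).
#' @param symmetrize for interaction mode, also set cell (j, i) for every
#'   observed (i, j) over the union of scaffolds on both axes.
#' @return list of class `profile_matrix`: binary `values`, `row_names`,
#'   `col_names`, `mode`.
#' @export
build_profile_matrix <- function(pairs, mode = c("interaction", "side_effect"),
                                 scaffold_fn = murcko_scaffold,
                                 symmetrize = FALSE) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) {
    return(structure(list(values = matrix(0L, 0, 0), row_names = character(),
                          col_names = character(), mode = mode),
                     class = "profile_matrix"))
  }
  drugs <- unique(c(pairs$drug1_smiles, pairs$drug2_smiles))
  sc <- scaffold_or_acyclic(vapply(drugs, scaffold_fn, character(1)))
  names(sc) <- drugs
  s1 <- unname(sc[pairs$drug1_smiles])
  s2 <- unname(sc[pairs$drug2_smiles])
  if (mode == "interaction") {
    rn <- sort(unique(s1)); cn <- sort(unique(s2))
    if (symmetrize) rn <- cn <- sort(unique(c(s1, s2)))
    values <- matrix(0L, length(rn), length(cn))
    values[cbind(match(s1, rn), match(s2, cn))] <- 1L
    if (symmetrize) values[cbind(match(s2, rn), match(s1, cn))] <- 1L
  } else {
    rn <- sort(unique(c(s1, s2)))
    cn <- sort(unique(as.character(pairs$label)))
    values <- matrix(0L, length(rn), length(cn))
    lab <- as.character(pairs$label)
    values[cbind(match(s1, rn), match(lab, cn))] <- 1L
    values[cbind(match(s2, rn), match(lab, cn))] <- 1L
  }
  structure(list(values = values, row_names = rn, col_names = cn, mode = mode),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix %s: %d x %d, %d cells set>\n", x$mode,
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Write a profile matrix as CSV with named rows/columns
#' @param pm a `profile_matrix`.
#' @param path output path.
#' @export
write_profile_matrix <- function(pm, path) {
  m <- pm$values
  dimnames(m) <- list(pm$row_names, pm$col_names)
  utils::write.csv(m, path)
  invisible(path)
}

# ---- binary similarity suite ------------------------------------------------

#' Binary-vector similarity metrics
#'
#' With popcounts `a = |A|`, `b = |B|`, intersection `c = |A & B|`, length
#' `N` and `d = N - a - b + c`:
#' tanimoto `c/(a+b-c)`; dice `2c/(a+b)`; kulczynski `c(a+b)/(2ab)`;
#' asymmetric `c/min(a,b)`; rogot_goldberg `c/(a+b) + d/(2N-a-b)`.
#' Jaccard similarity on binary profiles equals tanimoto.
#'
#' @param a,b 0/1 vectors (or `fingerprint` objects) of equal length.
#' @param metric one of `"tanimoto"`, `"dice"`, `"kulczynski"`,
#'   `"asymmetric"`, `"rogot_goldberg"`.
#' @return similarity value.
#' @export
bit_similarity <- function(a, b, metric = c("tanimoto", "dice", "kulczynski",
                                            "asymmetric", "rogot_goldberg")) {
  metric <- match.arg(metric)
  va <- if (inherits(a, "fingerprint")) a$bits else as.integer(a)
  vb <- if (inherits(b, "fingerprint")) b$bits else as.integer(b)
  if (length(va) != length(vb)) shape_error("vector lengths differ")
  N <- length(va)
  pa <- sum(va); pb <- sum(vb); pc <- sum(va & vb)
  pd <- N - pa - pb + pc
  switch(metric,
    tanimoto = {
      if (pa + pb - pc == 0) degenerate_vector_error("both vectors empty")
      pc / (pa + pb - pc)
    },
    dice = {
      if (pa + pb == 0) degenerate_vector_error("both vectors empty")
      2 * pc / (pa + pb)
    },
    kulczynski = {
      if (pa == 0 || pb == 0) degenerate_vector_error("empty vector")
      pc * (pa + pb) / (2 * pa * pb)
    },
    asymmetric = {
      if (min(pa, pb) == 0) degenerate_vector_error("empty vector")
      pc / min(pa, pb)
    },
    rogot_goldberg = {
      if (pa + pb == 0 || 2 * N - pa - pb == 0)
        degenerate_vector_error("degenerate vectors for rogot_goldberg")
      pc / (pa + pb) + pd / (2 * N - pa - pb)
    })
}

# ---- clustering -------------------------------------------------------------

# Inconsistency coefficient of each merge in an hclust tree, depth 2: the
# link's height standardized against the heights of itself and its direct
# children links (sd with n-1 denominator; 0 when the sd is 0).
inconsistency <- function(merge, height) {
  n_link <- nrow(merge)
  vapply(seq_len(n_link), function(i) {
    hs <- height[i]
    for (child in merge[i, ]) if (child > 0) hs <- c(hs, height[child])
    s <- stats::sd(hs)
    if (length(hs) < 2L || s == 0 || is.na(s)) 0 else (height[i] - mean(hs)) / s
  }, numeric(1))
}

#' Cluster binary profiles by Jaccard similarity
#'
#' Agglomerative single-linkage clustering on Jaccard distance
#' (1 - tanimoto of the binary rows), cut with the inconsistency criterion:
#' a subtree becomes one cluster when every link in it (depth-2
#' inconsistency coefficient) is at most `threshold`. Rows with identical
#' profiles always co-cluster; all-zero rows (undefined Jaccard) are made
#' singletons with a warning.
#'
#' @param pm a `profile_matrix` (or plain binary matrix).
#' @param threshold inconsistency cut threshold (default 1.0).
#' @return integer cluster labels, one per row, in input row order.
#' @export
cluster_binary_profiles <- function(pm, threshold = 1.0) {
  values <- if (inherits(pm, "profile_matrix")) pm$values else as.matrix(pm)
  n <- nrow(values)
  if (n < 1L) value_error("need at least one row")
  labels <- integer(n)
  zero <- rowSums(values) == 0
  if (any(zero))
    warning(sprintf("%d all-zero profile row(s) assigned singleton clusters",
                    sum(zero)))
  nz <- which(!zero)
  next_label <- 0L
  if (length(nz) == 1L) {
    labels[nz] <- next_label <- 1L
  } else if (length(nz) > 1L) {
    m <- values[nz, , drop = FALSE]
    inter <- tcrossprod(m)
    pop <- rowSums(m)
    uni <- outer(pop, pop, "+") - inter
    d <- stats::as.dist(1 - inter / uni)
    hc <- stats::hclust(d, method = "single")
    coef <- inconsistency(hc$merge, hc$height)
    # a link is consistent if its coefficient and all its descendants' are <= t
    ok <- logical(nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      ok[i] <- coef[i] <= threshold &&
        all(vapply(hc$merge[i, ], function(ch) ch < 0 || ok[ch], logical(1)))
    }
    cl <- integer(length(nz))
    assign_cluster <- function(node, lab) {
      if (node < 0) { cl[-node] <<- lab; return(invisible()) }
      assign_cluster(hc$merge[node, 1], lab)
      assign_cluster(hc$merge[node, 2], lab)
    }
    roots_done <- logical(nrow(hc$merge))
    walk <- function(node) {
      if (node < 0) {
        next_label <<- next_label + 1L
        cl[-node] <<- next_label
      } else if (ok[node]) {
        next_label <<- next_label + 1L
        assign_cluster(node, next_label)
      } else {
        walk(hc$merge[node, 1])
        walk(hc$merge[node, 2])
      }
    }
    walk(nrow(hc$merge))  # the final merge is the tree root
    labels[nz] <- cl
  }
  for (i in which(zero)) {
    next_label <- next_label + 1L
    labels[i] <- next_label
  }
  labels
}

#' Intra/inter-cluster structural similarity summary
#'
#' Intracluster similarity is the average pairwise `bit_similarity` among
#' members of the same cluster (clusters of size >= 2); intercluster
#' similarity the average over pairs from distinct clusters.
#'
#' @param clusters integer cluster labels.
#' @param fingerprints list of fingerprints aligned with `clusters`.
#' @param metric similarity metric name (see [bit_similarity()]).
#' @return list with `intra`, `inter` and a `per_cluster` data.frame
#'   (cluster, size, n_pairs, mean_similarity).
#' @export
cluster_similarity_summary <- function(clusters, fingerprints,
                                       metric = "tanimoto") {
  if (length(clusters) != length(fingerprints))
    shape_error("clusters and fingerprints lengths differ")
  sizes <- table(clusters)
  if (!any(sizes >= 2L))
    value_error("no cluster of size >= 2: intracluster similarity undefined")
  n <- length(clusters)
  sim <- function(i, j) bit_similarity(fingerprints[[i]], fingerprints[[j]],
                                       metric)
  intra_vals <- numeric(); inter_vals <- numeric()
  per <- list()
  for (cl in names(sizes)) {
    members <- which(clusters == as.integer(cl))
    k <- length(members)
    vals <- numeric()
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
        vals <- c(vals, sim(members[i], members[j]))
      intra_vals <- c(intra_vals, vals)
    }
    per[[cl]] <- data.frame(cluster = as.integer(cl), size = k,
                            n_pairs = k * (k - 1L) / 2L,
                            mean_similarity = if (length(vals)) mean(vals)
                                              else NA_real_)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (clusters[i] != clusters[j]) inter_vals <- c(inter_vals, sim(i, j))
  }
  list(intra = mean(intra_vals),
       inter = if (length(inter_vals)) mean(inter_vals) else NA_real_,
       per_cluster = do.call(rbind, per))
}
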