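# Dataset partitioning: MaxMin diversity selection for pre-training and the
# three DDI evaluation schemes (random stratified, one-unseen, both-unseen).

#' Greedy MaxMin diversity split
#'
#' Selects a maximally diverse subset on Tanimoto distance (1 - Tanimoto):
#' the first compound is picked uniformly at random under `seed`; each
#' subsequent pick maximizes the minimum distance to the already-selected
#' set. Used to carve a validation set as diverse as the pool it came from.
#'
#' @param fingerprints list of [circular_fingerprint()] objects.
#' @param select_fraction fraction of compounds to select, in (0, 1);
#'   `ceiling(fraction * N)` compounds are returned.
#' @param seed integer seed (determines the first pick only).
#' @return list with integer index vectors `selected` and `remainder`.
#' @export
maxmin_split <- function(fingerprints, select_fraction, seed = 0L) {
  n <- length(fingerprints)
  if (n < 2L) value_error("need at least 2 fingerprints")
  if (select_fraction <= 0 || select_fraction >= 1)
    value_error("select_fraction must be in (0, 1)")
  n_sel <- as.integer(ceiling(select_fraction * n))
  bits <- do.call(rbind, lapply(fingerprints, function(f) {
    if (inherits(f, "fingerprint")) f$bits else as.integer(f)
  }))
  pop <- rowSums(bits)
  inter <- tcrossprod(bits)                       # pairwise intersections
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)         # empty-vs-empty: identical
  dist <- 1 - sim
  first <- with_seed(seed, sample.int(n, 1L))
  selected <- first
  min_dist <- dist[, first]
  while (length(selected) < n_sel) {
    min_dist[selected] <- -Inf
    pick <- which.max(min_dist)                   # ties: lowest index
    selected <- c(selected, pick)
    min_dist <- pmin(min_dist, dist[, pick])
  }
  list(selected = selected, remainder = setdiff(seq_len(n), selected))
}

split_spec <- function(scheme, train_ids, val_ids, test_ids,
                       holdout_drugs = character(), seed = NA_integer_) {
  structure(list(scheme = scheme, train_ids = as.integer(train_ids),
                 val_ids = as.integer(val_ids),
                 test_ids = as.integer(test_ids),
                 holdout_drugs = holdout_drugs, seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec %s: %d train / %d val / %d test, %d holdout drugs>\n",
              x$scheme, length(x$train_ids), length(x$val_ids),
              length(x$test_ids), length(x$holdout_drugs)))
  invisible(x)
}

# allocate class counts to partitions matching ratios within +-1 per class
allocate_stratified <- function(idx_by_class, ratios, seed) {
  train <- integer(); val <- integer(); test <- integer()
  with_seed(seed, {
    for (cls in names(idx_by_class)) {
      idx <- sample(idx_by_class[[cls]])
      k <- length(idx)
      n_tr <- round(ratios[1] * k)
      n_va <- round(ratios[2] * k)
      if (n_tr + n_va > k) n_va <- k - n_tr
      train <- c(train, idx[seq_len(n_tr)])
      if (n_va > 0L) val <- c(val, idx[n_tr + seq_len(n_va)])
      if (k - n_tr - n_va > 0L) test <- c(test, idx[(n_tr + n_va + 1L):k])
    }
  })
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Stratified random split of DDI examples (Task 1)
#'
#' Partitions drug-pair examples into train/validation/test so that each
#' class keeps the global proportions within one example, using a seeded
#' shuffle per class. Classes with fewer than 3 examples are pooled
#' best-effort with a warning.
#'
#' @param examples data.frame with a `label` column (integer classes).
#' @param ratios numeric triple summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed integer seed.
#' @return a `split_spec` with scheme `"random"`; ids are row indices into
#'   `examples`.
#' @export
stratified_random_split <- function(examples, ratios = c(0.8, 0.1, 0.1),
                                    seed = 0L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    value_error("ratios must be a triple summing to 1")
  labels <- examples$label
  counts <- table(labels)
  small <- names(counts)[counts < 3L]
  if (length(small) > 0L)
    warning(sprintf("%d class(es) have fewer than 3 examples; split is best-effort",
                    length(small)))
  idx_by_class <- split(seq_along(labels), labels)
  parts <- allocate_stratified(idx_by_class, ratios, seed)
  split_spec("random", parts$train, parts$val, parts$test, seed = seed)
}

#' Cold-start splits with unseen drugs (Tasks 2 and 3)
#'
#' Holds out a fraction of drugs as "new". Training pairs are those whose
#' drugs are both known; the one-unseen test set contains pairs with exactly
#' one held-out drug, the both-unseen test set pairs with two. The two
#' returned specs share the identical training set; validation is carved
#' from the known-drug pairs by stratified sampling. Every input pair is
#' assigned to exactly one bucket.
#'
#' @param examples data.frame with columns `drug1_smiles`, `drug2_smiles`,
#'   `label`.
#' @param holdout_fraction fraction of distinct drugs held out (default 0.1).
#' @param val_fraction fraction of known-drug pairs used for validation.
#' @param seed integer seed.
#' @return list with `split_spec`s `one_unseen` and `both_unseen`.
#' @export
unseen_drug_splits <- function(examples, holdout_fraction = 0.1,
                               val_fraction = 0.1, seed = 0L) {
  drugs <- unique(c(examples$drug1_smiles, examples$drug2_smiles))
  n_hold <- max(1L, round(holdout_fraction * length(drugs)))
  if (n_hold >= length(drugs))
    degenerate_split_error("holdout would swallow every drug")
  holdout <- with_seed(derive_seed(seed, "holdout"),
                       sample(drugs, n_hold))
  in_hold1 <- examples$drug1_smiles %in% holdout
  in_hold2 <- examples$drug2_smiles %in% holdout
  n_unseen <- in_hold1 + in_hold2
  known_idx <- which(n_unseen == 0L)
  test2 <- which(n_unseen == 1L)
  test3 <- which(n_unseen == 2L)
  if (length(known_idx) == 0L || length(test2) == 0L || length(test3) == 0L)
    degenerate_split_error("a split bucket is empty; adjust holdout_fraction")
  # carve validation from the known-drug pairs, stratified by class
  idx_by_class <- split(known_idx, examples$label[known_idx])
  parts <- allocate_stratified(idx_by_class,
                               c(1 - val_fraction, val_fraction, 0),
                               derive_seed(seed, "val"))
  train <- parts$train; val <- parts$val
  list(one_unseen = split_spec("one_unseen", train, val, sort(test2),
                               holdout, seed),
       both_unseen = split_spec("both_unseen", train, val, sort(test3),
                                holdout, seed))
}

#' Verify the internal invariants of a split
#'
#' Checks disjointness, coverage (scheme `"random"`), and the unseen-drug
#' bucket properties. Used by the property tests; errors on violation.
#'
#' @param spec a `split_spec`.
#' @param examples the data.frame it indexes.
#' @return `TRUE`, invisibly.
#' @export
validate_split <- function(spec, examples) {
  all_ids <- c(spec$train_ids, spec$val_ids, spec$test_ids)
  if (anyDuplicated(all_ids) > 0L) value_error("partitions overlap")
  if (spec$scheme == "random" && length(all_ids) != nrow(examples))
    value_error("random split does not cover the input")
  if (spec$scheme %in% c("one_unseen", "both_unseen")) {
    h <- spec$holdout_drugs
    n_unseen <- (examples$drug1_smiles %in% h) + (examples$drug2_smiles %in% h)
    want <- if (spec$scheme == "one_unseen") 1L else 2L
    if (!all(n_unseen[spec$test_ids] == want))
      value_error("test pair with wrong number of unseen drugs")
    if (any(n_unseen[c(spec$train_ids, spec$val_ids)] > 0L))
      value_error("holdout drug leaked into train/val")
  }
  invisible(TRUE)
}

#' Serialize / restore a split as JSON
#'
#' @param spec a `split_spec` (or for `read_split`, a path).
#' @param path output file.
#' @return `write_split` the path; `read_split` the restored spec.
#' @export
write_split <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_spec(x$scheme, x$train_ids, x$val_ids, x$test_ids,
             x$holdout_drugs %||% character(), x$seed)
}
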