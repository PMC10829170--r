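# Evaluation metrics: support-weighted accuracy/precision/recall/F1, macro
# one-vs-rest AUROC (via pROC) and AUPRC (average precision), plus the
# dataset-diversity metrics SNN and Scaff.

average_precision <- function(y, score) {
  # step-sum average precision: sum over recall increments of precision
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Multiclass classification report
#'
#' Computes accuracy and per-class one-vs-rest precision/recall/F1 (averaged
#' with class-support weights) together with macro-averaged AUROC and AUPRC
#' from the class-probability matrix. Classes absent from `y_true` are kept
#' in the per-class table but excluded from the averages with a note; for
#' AUROC a class additionally needs at least one negative.
#'
#' @param y_true integer vector of true classes (0-based, < C).
#' @param prob n x C matrix of class probabilities (rows sum to 1 within
#'   1e-6).
#' @return list of class `metric_report`: `acc`, `f1_weighted`,
#'   `precision_weighted`, `recall_weighted`, `auroc_macro`, `auprc_macro`,
#'   and a `per_class` data.frame.
#' @export
classification_report <- function(y_true, prob) {
  prob <- as.matrix(prob)
  n <- length(y_true)
  if (nrow(prob) != n) shape_error("y_true and prob row counts differ")
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    value_error("probability rows must sum to 1")
  C <- ncol(prob)
  if (any(y_true < 0L | y_true >= C)) value_error("label outside 0..C-1")
  y_pred <- max.col(prob, ties.method = "first") - 1L
  acc <- mean(y_pred == y_true)
  per <- data.frame(class = 0:(C - 1L), support = 0L, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, auroc = NA_real_,
                    auprc = NA_real_)
  for (c in 0:(C - 1L)) {
    pos <- y_true == c
    per$support[c + 1L] <- sum(pos)
    tp <- sum(pos & y_pred == c)
    fp <- sum(!pos & y_pred == c)
    fn <- sum(pos & y_pred != c)
    prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    per$precision[c + 1L] <- prec
    per$recall[c + 1L] <- rec
    per$f1[c + 1L] <- if (!is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else if (!is.na(rec)) 0 else NA_real_
    if (sum(pos) > 0L && sum(!pos) > 0L) {
      per$auroc[c + 1L] <- as.numeric(pROC::auc(pROC::roc(
        response = as.integer(pos), predictor = prob[, c + 1L],
        levels = c(0, 1), direction = "<", quiet = TRUE)))
    }
    if (sum(pos) > 0L) {
      per$auprc[c + 1L] <- average_precision(as.integer(pos), prob[, c + 1L])
    }
  }
  present <- per$support > 0L
  if (!all(present))
    message(sprintf("%d class(es) absent from y_true excluded from averages",
                    sum(!present)))
  w <- per$support[present] / sum(per$support[present])
  structure(list(
    acc = acc,
    f1_weighted = sum(w * per$f1[present]),
    precision_weighted = sum(w * per$precision[present]),
    recall_weighted = sum(w * per$recall[present]),
    auroc_macro = mean(per$auroc[present], na.rm = TRUE),
    auprc_macro = mean(per$auprc[present], na.rm = TRUE),
    per_class = per), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report: acc %.3f, F1w %.3f, Pw %.3f, Rw %.3f, ",
                     "AUROC %.3f, AUPRC %.3f>\n"),
              x$acc, x$f1_weighted, x$precision_weighted, x$recall_weighted,
              x$auroc_macro, x$auprc_macro))
  invisible(x)
}

#' Serialize a metric report
#'
#' Headline metrics go to JSON; the per-class table to CSV when
#' `per_class_path` is given.
#'
#' @param report a `metric_report`.
#' @param path JSON output path.
#' @param per_class_path optional CSV path for the per-class table.
#' @export
write_metric_report <- function(report, path, per_class_path = NULL) {
  head <- report[c("acc", "f1_weighted", "precision_weighted",
                   "recall_weighted", "auroc_macro", "auprc_macro")]
  jsonlite::write_json(head, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(per_class_path))
    utils::write.csv(report$per_class, per_class_path, row.names = FALSE)
  invisible(path)
}

#' Similarity to the nearest neighbor (SNN)
#'
#' Mean over query fingerprints of the maximum Tanimoto similarity to any
#' reference fingerprint. High values indicate low structural novelty of the
#' query set relative to the reference set.
#'
#' @param query_fps,reference_fps non-empty lists of fingerprints with equal
#'   `n_bits`.
#' @return a real in \[0, 1\].
#' @export
snn <- function(query_fps, reference_fps) {
  if (length(query_fps) == 0L || length(reference_fps) == 0L)
    value_error("empty fingerprint list")
  mean(vapply(query_fps, function(q) {
    max(vapply(reference_fps, function(r) {
      tryCatch(tanimoto(q, r), degenerate_vector_error = function(e) 1)
    }, numeric(1)))
  }, numeric(1)))
}

#' Scaffold-composition similarity (Scaff)
#'
#' Cosine similarity between the scaffold-frequency count vectors of two
#' molecule sets over the union of observed scaffolds. Acyclic molecules
#' (empty scaffold) count as one shared "no-scaffold" bucket.
#'
#' @param set_a,set_b molecule tables with a `scaffold` column.
#' @return a real in \[0, 1\].
#' @export
scaffold_similarity <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) value_error("empty molecule set")
  all_sc <- union(set_a$scaffold, set_b$scaffold)
  ca <- as.numeric(table(factor(set_a$scaffold, levels = all_sc)))
  cb <- as.numeric(table(factor(set_b$scaffold, levels = all_sc)))
  sum(ca * cb) / (sqrt(sum(ca^2)) * sqrt(sum(cb^2)))
}
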