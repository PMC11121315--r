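#' Average precision of a ranked prediction list
#'
#' The precision-recall curve is swept over descending score thresholds
#' (tied scores grouped at one threshold) and summarized as
#' sum_n (R_n - R_(n-1)) P_n — the recall-increment-weighted average of the
#' precision at each threshold. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 true contact labels.
#' @return AP in \[0, 1\]; `NA` with a warning when there is no positive
#'   label (the sequence is then excluded from aggregate averages).
#' @export
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- sum(labels)
  if (npos == 0) {
    warning("average_precision: no positive labels; undefined")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(diff(s) != 0)            # last index of each tied group
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  npred <- grp_end
  prec <- tp / npred
  rec <- tp / npos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Average precision of a binary contact annotation
#'
#' When predictions are a 0/1 contact map (e.g. read directly off a predicted
#' structure) rather than ranked scores, the threshold sweep collapses to a
#' single threshold and the average precision reduces to P x R, the product
#' of the observed precision and recall. With zero predicted positives the
#' precision is taken as 0 (pessimistic) with a warning.
#'
#' @param labels logical or 0/1 true labels.
#' @param annotations logical or 0/1 predicted labels.
#' @return P x R in \[0, 1\].
#' @export
binary_average_precision <- function(labels, annotations) {
  y <- as.numeric(labels); a <- as.numeric(annotations)
  stopifnot(length(y) == length(a), all(a %in% c(0, 1)))
  npos <- sum(y)
  if (npos == 0) {
    warning("binary_average_precision: no positive labels; undefined")
    return(NA_real_)
  }
  tp <- sum(y == 1 & a == 1)
  if (sum(a) == 0) {
    warning("binary_average_precision: no predicted positives; precision taken as 0")
    return(0)
  }
  (tp / sum(a)) * (tp / npos)
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' True-positive rate against false-positive rate over the grouped descending
#' score sweep, integrated with trapezoids.
#'
#' @inheritParams average_precision
#' @return AUC in \[0, 1\]; `NA` with a warning for single-class labels.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- sum(labels); nneg <- length(labels) - npos
  if (npos == 0 || nneg == 0) {
    warning("auc_roc: single-class labels; undefined")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(y)[grp_end] / npos)
  fpr <- c(0, (grp_end - cumsum(y)[grp_end]) / nneg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Top-k precision and recall at L-based cutoffs
#'
#' For each fraction f of L (the combined TM helix length), the k =
#' max(1, floor(L f)) highest-scoring pairs (clamped to the number of pairs)
#' are called positive; ties are broken lexicographically by (i, j) for
#' determinism. Precision is TP/k, recall TP/#contacts.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels.
#' @param L combined TM helix length of the sequence.
#' @param pairs optional data.frame with `i`, `j` used for tie-breaking.
#' @param fractions fractions of L at which to cut.
#' @return data.frame with `fraction`, `k`, `precision`, `recall`.
#' @export
topk_precision_recall <- function(scores, labels, L,
                                  pairs = NULL,
                                  fractions = c(1, 1/2, 1/5, 1/10)) {
  stopifnot(L >= 1)
  y <- as.numeric(labels)
  n <- length(scores)
  ord <- if (is.null(pairs)) order(-scores)
         else order(-scores, pairs$i, pairs$j)
  ys <- y[ord]
  npos <- sum(y)
  if (npos == 0) warning("topk_precision_recall: no contacts; recall undefined")
  res <- lapply(fractions, function(f) {
    k <- max(1L, floor(L * f))
    k <- min(k, n)
    tp <- sum(ys[seq_len(k)])
    data.frame(fraction = f, k = k, precision = tp / k,
               recall = if (npos > 0) tp / npos else NA_real_)
  })
  do.call(rbind, res)
}

#' Pooled feature statistics
#'
#' A single mean and standard deviation pooled over every entry of a feature
#' matrix — the summary used to compare the stability of scaled features
#' between structure sources (experimental vs predicted/noisy).
#'
#' @param X numeric feature matrix.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
feature_statistics <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0L) stop("feature_statistics: empty matrix")
  v <- as.numeric(X)
  c(mean = mean(v), sd = stats::sd(v))
}

#' Per-sequence evaluation report
#'
#' Computes per-chain average precision, AUC-ROC and top-L/L2/L5/L10
#' precision/recall from scored candidate pairs, then the aggregate mean and
#' SD across sequences. Chains whose labels are degenerate for a metric (no
#' positive for AP, single class for AUC) carry `NA` there and are excluded
#' from that metric's aggregate, with a note in the report.
#'
#' @param fs a `pair_feature_set` carrying labels (see [build_dataset()]).
#' @param scores numeric score per row of `fs` (or 0/1 annotations with
#'   `binary = TRUE`).
#' @param annotations named list of [helix_annotation()] (for L).
#' @param binary if `TRUE`, scores are a binary contact annotation and AP is
#'   computed as P x R; AUC and top-k are still computed from the 0/1 values.
#' @return An `eval_report`: `per_sequence` data.frame and `aggregate`
#'   (mean/sd per metric).
#' @export
eval_report <- function(fs, scores, annotations, binary = FALSE) {
  stopifnot(length(scores) == nrow(fs$X), !is.null(fs$labels))
  ids <- unique(fs$meta$chain_id)
  rows <- lapply(ids, function(id) {
    sel <- fs$meta$chain_id == id
    y <- fs$labels[sel]; s <- scores[sel]
    p <- fs$meta[sel, c("i", "j")]
    L <- tm_length(annotations[[id]])
    ap <- if (binary) suppressWarnings(binary_average_precision(y, s))
          else suppressWarnings(average_precision(s, y))
    auc <- suppressWarnings(auc_roc(s, y))
    tk <- suppressWarnings(topk_precision_recall(s, y, L, pairs = p))
    data.frame(chain_id = id, AP = ap, AUC = auc,
               P_L = tk$precision[1], R_L = tk$recall[1],
               P_L2 = tk$precision[2], R_L2 = tk$recall[2],
               P_L5 = tk$precision[3], R_L5 = tk$recall[3],
               P_L10 = tk$precision[4], R_L10 = tk$recall[4],
               L = L, n_pairs = sum(sel), n_contacts = sum(y),
               stringsAsFactors = FALSE)
  })
  per_seq <- do.call(rbind, rows)
  met <- setdiff(names(per_seq), c("chain_id", "L", "n_pairs", "n_contacts"))
  aggregate <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(per_seq[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(met, function(m) stats::sd(per_seq[[m]], na.rm = TRUE), numeric(1)),
    n_excluded = vapply(met, function(m) sum(is.na(per_seq[[m]])), numeric(1)),
    row.names = NULL)
  structure(list(per_sequence = per_seq, aggregate = aggregate,
                 binary = binary),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d sequences%s\n", nrow(x$per_sequence),
              if (x$binary) " (binary-annotation mode, AP = P x R)" else ""))
  agg <- x$aggregate
  for (k in seq_len(nrow(agg)))
    cat(sprintf("  %-6s %.4f +- %.4f%s\n", agg$metric[k], agg$mean[k], agg$sd[k],
                if (agg$n_excluded[k] > 0)
                  sprintf("  (%d excluded)", agg$n_excluded[k]) else ""))
  invisible(x)
}

#' Sequence-level k-fold cross-validation
#'
#' Chains (never individual pairs) are partitioned into k folds, `repeats`
#' times with per-repeat seeds. In each fold the scaler and classifier are
#' fitted on the training chains only and evaluated on the held-out chains.
#' When `test_chains` is given, features of each validation chain are taken
#' from its entry there (e.g. a noisy/predicted twin) while labels always
#' come from the clean `chains` — the train-on-experimental /
#' test-on-predicted protocol.
#'
#' @param chains named list of clean [chain_structure()].
#' @param annotations named list of [helix_annotation()].
#' @param feature_kind `"SDF"` or `"CF"`.
#' @param config a [contact_net_config()]; its seed is combined with the
#'   fold/repeat seeds.
#' @param k number of folds.
#' @param repeats number of repeats.
#' @param fold_seeds one seed per repeat (default `0:(repeats-1)`).
#' @param test_chains optional named list of twin chains to evaluate on.
#' @param threshold,min_sep contact definition parameters.
#' @return A `crossval_report`: `per_sequence` rows (one per chain x repeat),
#'   `aggregate`, `folds` (assignments), `seeds`.
#' @export
crossvalidate <- function(chains, annotations, feature_kind = c("SDF", "CF"),
                          config = contact_net_config(), k = 5L, repeats = 5L,
                          fold_seeds = NULL, test_chains = NULL,
                          threshold = 5.5, min_sep = 5L) {
  feature_kind <- match.arg(feature_kind)
  ids <- sort(names(chains))
  if (length(ids) < k) stop("crossvalidate: fewer chains (", length(ids),
                            ") than folds (", k, ")")
  if (is.null(fold_seeds)) fold_seeds <- seq_len(repeats) - 1L
  stopifnot(length(fold_seeds) == repeats)

  ds_clean <- build_dataset(chains, annotations, feature_kind,
                            threshold = threshold, min_sep = min_sep)
  ds_test <- if (is.null(test_chains)) ds_clean
             else build_dataset(test_chains, annotations, feature_kind,
                                label_chains = chains,
                                threshold = threshold, min_sep = min_sep)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  all_rows <- list(); fold_log <- list()
  for (r in seq_len(repeats)) {
    set.seed(fold_seeds[r])
    fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
    fold_log[[r]] <- fold_of
    for (f in seq_len(k)) {
      val_ids <- ids[fold_of == f]
      train_ids <- setdiff(ids, val_ids)
      tr <- subset_chains(ds_clean, train_ids)
      cfg <- config
      cfg$seed <- config$seed + 1000L * (r - 1L) + f
      model <- contact_net(tr$X, tr$labels, config = cfg)
      va <- subset_chains(ds_test, val_ids)
      if (nrow(va$X) == 0L) next
      sc <- predict(model, va$X)
      rep_eval <- eval_report(va, sc, annotations)
      rows <- rep_eval$per_sequence
      rows$repeat_id <- r; rows$fold <- f
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  per_seq <- do.call(rbind, all_rows)
  met <- setdiff(names(per_seq),
                 c("chain_id", "L", "n_pairs", "n_contacts", "repeat_id", "fold"))
  aggregate <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(per_seq[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(met, function(m) stats::sd(per_seq[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(list(per_sequence = per_seq, aggregate = aggregate,
                 folds = fold_log, seeds = fold_seeds, k = k,
                 repeats = repeats, feature_kind = feature_kind),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %s, %d-fold x %d repeats (seeds %s)\n",
              x$feature_kind, x$k, x$repeats, paste(x$seeds, collapse = ",")))
  agg <- x$aggregate
  for (kk in seq_len(nrow(agg)))
    cat(sprintf("  %-6s %.4f +- %.4f\n", agg$metric[kk], agg$mean[kk], agg$sd[kk]))
  invisible(x)
}
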