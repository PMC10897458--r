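# Ground-truth scoring of clustering output.  Matching is by shared rows:
# every ground-truth assembly is matched to the predicted cluster sharing
# most of its points (greedy one-to-one by descending overlap), TP are the
# assembly's points in its matched cluster, FN its points predicted noise,
# FP its points assigned to any other predicted cluster.  Correctly
# predicted noise contributes to no metric (there is no TN on an
# aggregate basis).

#' Match predicted clusters to ground-truth assemblies
#'
#' @param pred_labels,true_labels Equal-length integer vectors; `-1` =
#'   noise in both.
#' @return data.frame with one row per ground-truth assembly: `assembly_id`,
#'   `matched` (predicted cluster id or `NA`), `tp`, `fp`, `fn`, `n`.
#' @export
match_clusters <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("label vectors differ in length")
  gt_ids <- sort(unique(true_labels[true_labels != -1L]))
  ov <- table(true = true_labels, pred = pred_labels)
  pred_ids <- suppressWarnings(as.integer(colnames(ov)))
  cand <- data.frame()
  for (g in gt_ids) {
    row <- ov[as.character(g), , drop = TRUE]
    for (j in which(pred_ids != -1L & row > 0))
      cand <- rbind(cand, data.frame(gt = g, pred = pred_ids[j],
                                     n = as.integer(row[j])))
  }
  matched <- stats::setNames(rep(NA_integer_, length(gt_ids)),
                             as.character(gt_ids))
  if (nrow(cand)) {
    cand <- cand[order(-cand$n, cand$pred, cand$gt), ]
    used_pred <- integer(0)
    for (i in seq_len(nrow(cand))) {
      g <- as.character(cand$gt[i])
      if (!is.na(matched[g]) || cand$pred[i] %in% used_pred) next
      matched[g] <- cand$pred[i]
      used_pred <- c(used_pred, cand$pred[i])
    }
  }
  out <- data.frame(assembly_id = gt_ids, matched = unname(matched),
                    tp = 0L, fp = 0L, fn = 0L, n = 0L)
  for (i in seq_along(gt_ids)) {
    mine <- true_labels == gt_ids[i]
    out$n[i] <- sum(mine)
    out$fn[i] <- sum(mine & pred_labels == -1L)
    if (!is.na(out$matched[i])) {
      out$tp[i] <- sum(mine & pred_labels == out$matched[i])
      out$fp[i] <- sum(mine & pred_labels != -1L &
                         pred_labels != out$matched[i])
    } else {
      out$fp[i] <- sum(mine & pred_labels != -1L)
    }
  }
  out
}

#' Per-aggregate segmentation accuracy
#'
#' `TP / (TP + FP + FN)` per assembly, disregarding relative cluster size.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return Accuracy in `[0, 1]` per element.
#' @export
aggregate_accuracy <- function(tp, fp, fn) {
  tot <- tp + fp + fn
  if (any(tot == 0)) stop("accuracy undefined: TP + FP + FN = 0")
  tp / tot
}

#' Precision, recall and F1 with micro/macro/weighted aggregation
#'
#' Micro pools all counts before computing the metrics; macro averages the
#' per-class metrics; weighted averages them with TP weights.  Undefined
#' ratios (zero denominator) are reported as 0 and flagged.
#'
#' @param tp,fp,fn Per-class count vectors.
#' @param aggregation `"macro"` (default), `"micro"` or `"weighted"`.
#' @return List: `precision`, `recall`, `f1`, `per_class` (data.frame),
#'   `flagged` (`TRUE` when any zero-denominator convention was applied).
#' @export
precision_recall_f1 <- function(tp, fp, fn,
                                aggregation = c("macro", "micro",
                                                "weighted")) {
  aggregation <- match.arg(aggregation)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  flagged <- any(tp + fp == 0) || any(tp + fn == 0) ||
    any(prec + rec == 0)
  per_class <- data.frame(tp = tp, fp = fp, fn = fn, precision = prec,
                          recall = rec, f1 = f1)
  if (aggregation == "micro") {
    P <- safe_div(sum(tp), sum(tp) + sum(fp))
    R <- safe_div(sum(tp), sum(tp) + sum(fn))
    F1 <- safe_div(2 * P * R, P + R)
  } else if (aggregation == "macro") {
    P <- mean(prec); R <- mean(rec); F1 <- mean(f1)
  } else {
    w <- if (sum(tp) > 0) tp / sum(tp) else rep(1 / length(tp), length(tp))
    P <- sum(w * prec); R <- sum(w * rec); F1 <- sum(w * f1)
  }
  list(precision = P, recall = R, f1 = F1, per_class = per_class,
       flagged = flagged)
}

#' Growth-onset offsets of matched clusters
#'
#' For every ground-truth assembly with a matched predicted cluster,
#' `|earliest frame of the predicted cluster - true onset frame|`.
#' Unmatched assemblies are excluded and counted.
#'
#' @param pred_labels Predicted labels per localization.
#' @param t Frame index per localization.
#' @param matching Output of [match_clusters()].
#' @param true_onsets Named (by `assembly_id`) or ordered vector of true
#'   onset frames, one per row of `matching`.
#' @return List: `offsets` (frames, one per matched assembly), `mean`,
#'   `median`, `n_unmatched`.
#' @export
onset_offsets <- function(pred_labels, t, matching, true_onsets) {
  if (is.null(names(true_onsets)))
    names(true_onsets) <- as.character(matching$assembly_id)
  ok <- !is.na(matching$matched)
  offs <- vapply(which(ok), function(i) {
    pred_t <- min(t[pred_labels == matching$matched[i]])
    abs(pred_t - true_onsets[[as.character(matching$assembly_id[i])]])
  }, 0)
  list(offsets = offs,
       mean = if (length(offs)) mean(offs) else NA_real_,
       median = if (length(offs)) stats::median(offs) else NA_real_,
       n_unmatched = sum(!ok))
}

#' Score a clustering against ground truth
#'
#' Full metrics report: cluster matching, per-aggregate accuracy (mean and
#' median), precision/recall/F1 at micro, macro and weighted aggregation,
#' and (when time and onsets are available) growth-onset offsets.
#'
#' @param pred_labels,true_labels Per-row labels (`-1` = noise).
#' @param t Optional frame indices (for onset offsets).
#' @param true_onsets Optional true onset frames (named by assembly id).
#' @return Object of class `metrics_report`.
#' @export
evaluate_clustering <- function(pred_labels, true_labels, t = NULL,
                                true_onsets = NULL) {
  m <- match_clusters(pred_labels, true_labels)
  acc <- aggregate_accuracy(m$tp, m$fp, m$fn)
  rep <- list(
    per_assembly = cbind(m, accuracy = acc),
    accuracy_mean = mean(acc), accuracy_median = stats::median(acc),
    macro = precision_recall_f1(m$tp, m$fp, m$fn, "macro"),
    micro = precision_recall_f1(m$tp, m$fp, m$fn, "micro"),
    weighted = precision_recall_f1(m$tp, m$fp, m$fn, "weighted"))
  if (!is.null(t) && !is.null(true_onsets))
    rep$onsets <- onset_offsets(pred_labels, t, m, true_onsets)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report: %d assemblies | accuracy mean %.3f ",
                     "median %.3f | macro P %.3f R %.3f F1 %.3f>\n"),
              nrow(x$per_assembly), x$accuracy_mean, x$accuracy_median,
              x$macro$precision, x$macro$recall, x$macro$f1))
  if (!is.null(x$onsets))
    cat(sprintf("  onset offset mean %.1f frames (%d unmatched)\n",
                x$onsets$mean, x$onsets$n_unmatched))
  invisible(x)
}
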