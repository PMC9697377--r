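#' Match detections to ground truth by greedy IoU assignment
#'
#' Detections are visited in descending confidence order (ties broken by
#' input order). Each detection is matched to the unconsumed ground-truth box
#' with which it has the highest IoU; if that IoU exceeds `iou_thresh` the
#' detection is a true positive and the ground-truth box is consumed,
#' otherwise it is a false positive. The threshold test is strict
#' (`IoU > 0.5` by default); set `strict = FALSE` for the `>=` convention
#' used by some toolkits.
#'
#' @param dets boxes data.frame with scores (one class)
#' @param gts boxes data.frame of ground truth (same class)
#' @param iou_thresh IoU threshold, default 0.5
#' @param strict if `TRUE` (default) a detection must exceed the threshold;
#'   if `FALSE`, meeting it suffices
#' @return object of class `match_flags`: list with `tp` (logical vector in
#'   descending-score order), `n_gt`, and `order` (permutation applied to
#'   `dets`)
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5, strict = TRUE) {
  validate_boxes(dets)
  validate_boxes(gts)
  if (nrow(dets) > 0 && anyNA(dets$score)) {
    stop("every detection must carry a confidence score")
  }
  ord <- order(dets$score, decreasing = TRUE, method = "radix")
  tp <- logical(nrow(dets))
  used <- logical(nrow(gts))
  if (nrow(dets) > 0 && nrow(gts) > 0) {
    m <- iou_matrix(dets[ord, , drop = FALSE], gts)
    for (i in seq_along(ord)) {
      free <- which(!used)
      if (length(free) == 0) break
      j <- free[which.max(m[i, free])]
      best <- m[i, j]
      hit <- if (strict) best > iou_thresh else best >= iou_thresh
      if (hit) {
        tp[i] <- TRUE
        used[j] <- TRUE
      }
    }
  }
  structure(list(tp = tp, n_gt = nrow(gts), order = ord),
            class = "match_flags")
}

#' Cumulative precision/recall curve from match flags
#'
#' Point `k` of the curve is `precision = cumTP(k) / k` and
#' `recall = cumTP(k) / n_gt`, sweeping the confidence threshold down
#' through the ranked detections.
#'
#' @param flags a `match_flags` object
#' @return object of class `pr_curve`: list with equal-length `precision`
#'   and `recall` vectors (one point per detection)
#' @export
precision_recall <- function(flags) {
  stopifnot(inherits(flags, "match_flags"))
  n <- length(flags$tp)
  if (flags$n_gt == 0 && n > 0) {
    stop("recall is undefined: no ground-truth boxes but detections present")
  }
  ct <- cumsum(flags$tp)
  structure(list(precision = if (n) ct / seq_len(n) else numeric(),
                 recall = if (n) ct / flags$n_gt else numeric()),
            class = "pr_curve")
}

#' Average precision: area under the precision/recall curve
#'
#' With `method = "all_point"` (default) the raw curve is replaced by its
#' monotone precision envelope and the exact area under the resulting step
#' function is returned; `"eleven_point"` instead averages the interpolated
#' precision at recalls 0, 0.1, ..., 1.
#'
#' @param pr a `pr_curve` object
#' @param method `"all_point"` or `"eleven_point"`
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(pr, method = c("all_point", "eleven_point")) {
  stopifnot(inherits(pr, "pr_curve"))
  method <- match.arg(method)
  if (length(pr$recall) == 0) {
    warning("empty precision/recall curve; AP = 0")
    return(0)
  }
  mrec <- c(0, pr$recall)
  mpre <- c(0, pr$precision)
  # monotone envelope from the right
  for (i in seq(length(mpre) - 1, 1)) mpre[i] <- max(mpre[i], mpre[i + 1])
  if (method == "all_point") {
    sum(diff(mrec) * mpre[-1])
  } else {
    sum(vapply(seq(0, 1, 0.1), function(r) {
      ok <- mrec >= r
      if (any(ok)) max(mpre[ok]) else 0
    }, 0)) / 11
  }
}

#' Mean average precision over classes
#'
#' Arithmetic mean of the per-class AP values: `mAP = (1/c) * sum_j AP_j`.
#'
#' @param per_class_ap named numeric vector of per-class AP values (any
#'   consistent scale; percentages in, percentages out)
#' @return the mean
#' @examples
#' mean_ap(c(a = 100, b = 50)) # 75
#' @export
mean_ap <- function(per_class_ap) {
  if (length(per_class_ap) == 0) stop("need at least one class AP")
  mean(per_class_ap)
}

#' Evaluate detections against ground truth, per class
#'
#' Runs the full accuracy stack for each class independently: detections of
#' that class are ranked by confidence across all images, matched greedily
#' against same-image ground truth (`IoU > iou_thresh`), swept into a
#' precision/recall curve and integrated into AP. The reported per-class
#' recall is the final point of the sweep (confidence threshold down to 0).
#' Values are percentages; `mean_ap` is the arithmetic mean over classes.
#'
#' @param dets boxes data.frame with an `image` column and scores
#' @param gts boxes data.frame with an `image` column
#' @param classes character vector of class labels to evaluate; defaults to
#'   the classes present in `gts`
#' @param iou_thresh IoU threshold (default 0.5, strict)
#' @param strict strict (`>`) vs inclusive (`>=`) threshold test
#' @param method AP integration method, see [average_precision()]
#' @return object of class `eval_report`
#' @export
evaluate <- function(dets, gts, classes = NULL, iou_thresh = 0.5,
                     strict = TRUE, method = "all_point") {
  if (is.null(classes)) classes <- sort(unique(as.character(gts$label)))
  bad <- setdiff(unique(as.character(dets$label)), as.character(classes))
  if (length(bad) > 0) {
    stop("detections carry unknown class label(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(dets$image)) dets$image <- "img"
  if (is.null(gts$image)) gts$image <- "img"
  per <- lapply(classes, function(cl) {
    d <- dets[dets$label == cl, , drop = FALSE]
    g <- gts[gts$label == cl, , drop = FALSE]
    n_gt <- nrow(g)
    if (n_gt == 0) {
      warning("class ", cl, " has no ground truth; recall/AP reported as 0")
      return(c(recall = 0, ap = 0))
    }
    # rank class detections across the whole dataset, match within image
    ord <- order(d$score, decreasing = TRUE, method = "radix")
    d <- d[ord, , drop = FALSE]
    consumed <- logical(n_gt)
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      gi <- which(g$image == d$image[i] & !consumed)
      if (length(gi) == 0) next
      ious <- iou_matrix(d[i, , drop = FALSE], g[gi, , drop = FALSE])[1, ]
      j <- which.max(ious)
      hit <- if (strict) ious[j] > iou_thresh else ious[j] >= iou_thresh
      if (hit) {
        tp[i] <- TRUE
        consumed[gi[j]] <- TRUE
      }
    }
    fl <- structure(list(tp = tp, n_gt = n_gt, order = seq_len(nrow(d))),
                    class = "match_flags")
    pr <- precision_recall(fl)
    ap <- if (nrow(d) == 0) 0 else
      suppressWarnings(average_precision(pr, method = method))
    rec <- if (nrow(d) == 0) 0 else pr$recall[length(pr$recall)]
    c(recall = 100 * rec, ap = 100 * ap)
  })
  tab <- do.call(rbind, per)
  rep <- list(per_class = data.frame(class = as.character(classes),
                                     recall = tab[, "recall"],
                                     ap = tab[, "ap"],
                                     stringsAsFactors = FALSE,
                                     row.names = NULL),
              mean_recall = mean(tab[, "recall"]),
              mean_ap = mean_ap(tab[, "ap"]))
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, digits = 1, ...) {
  df <- x$per_class
  wcl <- max(nchar(c("Class", df$class, "Mean")))
  fmt <- function(v) formatC(v, format = "f", digits = digits, width = 7)
  cat(formatC("Class", width = wcl, flag = "-"), formatC("Recall", width = 8),
      formatC("AP", width = 8), "\n", sep = "")
  for (i in seq_len(nrow(df))) {
    cat(formatC(df$class[i], width = wcl, flag = "-"), " ",
        fmt(df$recall[i]), " ", fmt(df$ap[i]), "\n", sep = "")
  }
  cat(formatC("Mean", width = wcl, flag = "-"), " ", fmt(x$mean_recall),
      " ", fmt(x$mean_ap), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  rbind(x$per_class,
        data.frame(class = "Mean", recall = x$mean_recall, ap = x$mean_ap,
                   stringsAsFactors = FALSE))
}

#' Write an evaluation report as CSV
#'
#' Columns `class, recall, ap` (percent), with a final `Mean` row.
#'
#' @param report an `eval_report`
#' @param path output file
#' @export
write_eval_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
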