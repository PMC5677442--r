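# Detection-vs-truth matching, TP/FN/FP accuracy and survey-style reporting.

#' TP/FN/FP tallies for one ROI
#'
#' @param samples Number of true mounds present.
#' @param tp,fn,fp True positive / false negative / false positive counts;
#'   `tp + fn` must equal `samples`.
#' @return An `eval_counts` list with the accuracy `tp / (tp + fn + fp)`
#'   attached (`NA` when all counts are zero).
#' @export
eval_counts <- function(samples, tp, fn, fp) {
  stopifnot(is_count(samples), is_count(tp), is_count(fn), is_count(fp))
  if (tp + fn != samples) {
    abort_ms("tp + fn must equal the number of true mounds (samples)", "data_error")
  }
  acc <- if (tp + fn + fp > 0) tp / (tp + fn + fp) else NA_real_
  structure(list(samples = as.integer(samples), tp = as.integer(tp),
                 fn = as.integer(fn), fp = as.integer(fp), accuracy = acc),
            class = "eval_counts")
}

#' Detection accuracy from TP/FN/FP counts
#'
#' The survey's single detection-quality score:
#' `accuracy = TP / (TP + FN + FP)`. Unlike recall it also charges false
#' positives; unlike precision it also charges misses.
#'
#' @param tp,fn,fp Non-negative counts, not all zero.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' detection_accuracy(87, 32, 9)   # 0.6797: the pooled survey-level score
#' detection_accuracy(11, 2, 3)    # 0.6875
#' @export
detection_accuracy <- function(tp, fn, fp) {
  stopifnot(is_count(tp), is_count(fn), is_count(fp))
  if (tp + fn + fp == 0) {
    abort_ms("accuracy undefined when TP, FN and FP are all zero", "data_error")
  }
  tp / (tp + fn + fp)
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching by ascending centroid distance: the closest
#' (detection, truth) pair within `max_centroid_dist_px` is matched first,
#' both are removed, and so on. Matched detections are TP, leftover truths
#' FN, leftover detections FP.
#'
#' @param detections List of `detection`s from [detect_mounds()].
#' @param truth A `ground_truth_set` from [generate_scene()].
#' @param max_centroid_dist_px Match radius; defaults to 1.5 times the truth
#'   mounds' largest core semi-axis (visual co-location without overlap
#'   computation).
#' @return An [eval_counts()].
#' @export
match_detections <- function(detections, truth, max_centroid_dist_px = NULL) {
  stopifnot(inherits(truth, "ground_truth_set"))
  n_truth <- length(truth$mounds)
  if (is.null(max_centroid_dist_px)) {
    max_centroid_dist_px <- if (n_truth == 0) 0 else
      1.5 * max(vapply(truth$mounds, function(m) max(m$core_axes_px), 0))
  }
  n_det <- length(detections)
  if (n_det == 0 || n_truth == 0) {
    return(eval_counts(n_truth, 0L, n_truth, n_det))
  }
  # detection centroids are 0-based pixel coordinates; truth is 1-based
  det_rc <- t(vapply(detections, function(d)
    c(d$centroid[["y"]] + 1, d$centroid[["x"]] + 1), numeric(2)))
  tru_rc <- t(vapply(truth$mounds, function(m)
    c(m$centroid[["row"]], m$centroid[["col"]]), numeric(2)))
  dmat <- outer(det_rc[, 1], tru_rc[, 1], `-`)^2 + outer(det_rc[, 2], tru_rc[, 2], `-`)^2
  dmat <- sqrt(dmat)
  tp <- 0L
  repeat {
    i <- which.min(dmat)
    if (!length(i) || !is.finite(dmat[i]) || dmat[i] > max_centroid_dist_px) break
    tp <- tp + 1L
    ri <- (i - 1) %% nrow(dmat) + 1; ci <- (i - 1) %/% nrow(dmat) + 1
    dmat[ri, ] <- Inf; dmat[, ci] <- Inf
  }
  eval_counts(n_truth, tp, n_truth - tp, n_det - tp)
}

#' Aggregate per-ROI tallies into a survey report
#'
#' Emits one row per ROI plus a `Total` row (column sums, with accuracy
#' recomputed on the pooled counts — not the mean of the per-ROI
#' accuracies) and a `Proportion` row expressing TP, FN and FP as
#' percentages of the total mound count. Percentages are reported to one
#' decimal place.
#'
#' @param per_roi Named (or unnamed) list of [eval_counts()], one per ROI.
#' @return A data frame with columns `roi`, `samples`, `tp`, `fn`, `fp`,
#'   `accuracy_pct`.
#' @export
aggregate_report <- function(per_roi) {
  stopifnot(length(per_roi) >= 1)
  ids <- names(per_roi)
  if (is.null(ids)) ids <- as.character(seq_along(per_roi))
  rows <- do.call(rbind, lapply(seq_along(per_roi), function(i) {
    ec <- per_roi[[i]]
    data.frame(roi = ids[i], samples = ec$samples, tp = ec$tp, fn = ec$fn,
               fp = ec$fp,
               accuracy_pct = if (is.na(ec$accuracy)) NA_real_ else
                 round(100 * ec$accuracy, 1))
  }))
  tot <- c(samples = sum(rows$samples), tp = sum(rows$tp),
           fn = sum(rows$fn), fp = sum(rows$fp))
  total_row <- data.frame(roi = "Total", samples = tot[["samples"]],
                          tp = tot[["tp"]], fn = tot[["fn"]], fp = tot[["fp"]],
                          accuracy_pct = round(100 * detection_accuracy(tot[["tp"]],
                                                                tot[["fn"]],
                                                                tot[["fp"]]), 1))
  prop_row <- data.frame(roi = "Proportion", samples = 100,
                         tp = round(100 * tot[["tp"]] / tot[["samples"]], 1),
                         fn = round(100 * tot[["fn"]] / tot[["samples"]], 1),
                         fp = round(100 * tot[["fp"]] / tot[["samples"]], 1),
                         accuracy_pct = NA_real_)
  out <- rbind(rows, total_row, prop_row)
  rownames(out) <- NULL
  out
}

#' Read per-ROI tallies from CSV
#'
#' Column layout mirrors the survey report: `roi, samples, tp, fn, fp`
#' (`Total`/`Proportion` rows, if present, are dropped and recomputed).
#' The package ships an example register of 25 surveyed ROIs at
#' `system.file("extdata", "roi_counts.csv", package = "moundscan")`.
#'
#' @param path CSV path.
#' @return Named list of [eval_counts()].
#' @export
read_roi_counts <- function(path) {
  df <- utils::read.csv(path, colClasses = c(roi = "character"))
  need <- c("roi", "samples", "tp", "fn", "fp")
  if (!all(need %in% names(df))) {
    abort_ms(sprintf("ROI counts CSV needs columns %s", paste(need, collapse = ",")),
             "format_error")
  }
  df <- df[!df$roi %in% c("Total", "Proportion"), ]
  out <- lapply(seq_len(nrow(df)), function(i)
    eval_counts(df$samples[i], df$tp[i], df$fn[i], df$fp[i]))
  stats::setNames(out, df$roi)
}

#' @rdname aggregate_report
#' @param report Data frame from `aggregate_report`.
#' @param path Output CSV path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, na = "")
  invisible(path)
}
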