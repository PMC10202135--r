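# Detection matching and counting metrics, with per-development-stage
# reporting.
#
# Conventions: a detection is a true positive when greedily matched one-to-one
# to a ground-truth box with IoU above the threshold (0.5); unmatched
# detections are false positives, unmatched ground truths false negatives.
# Counting metrics (MAE, RMSE, R2) compare per-image tip counts in their
# standard forms.

box4 <- function(b) {
  if (is.data.frame(b)) as.numeric(c(b$box_x[1], b$box_y[1], b$box_w[1], b$box_h[1]))
  else as.numeric(b)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x, y, w, h)` (top-left corner, width, height) or one-row data
#' frames with `box_x`, `box_y`, `box_w`, `box_h`.
#'
#' @param boxA,boxB Boxes.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @examples
#' iou(c(0, 0, 12, 12), c(6, 0, 12, 12)) # 1/3
#' @export
iou <- function(boxA, boxB) {
  a <- box4(boxA); b <- box4(boxB)
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    abort("Boxes must have positive area.", class = "wheattips_invalid_box")
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Pairwise IoU matrix between detection and ground-truth box tables.
iou_matrix <- function(dets, gts) {
  nd <- nrow(dets); ng <- nrow(gts)
  M <- matrix(0, nd, ng)
  if (nd == 0 || ng == 0) return(M)
  dx0 <- dets$box_x; dy0 <- dets$box_y
  dx1 <- dets$box_x + dets$box_w; dy1 <- dets$box_y + dets$box_h
  gx0 <- gts$box_x; gy0 <- gts$box_y
  gx1 <- gts$box_x + gts$box_w; gy1 <- gts$box_y + gts$box_h
  for (j in seq_len(ng)) {
    ix <- pmax(0, pmin(dx1, gx1[j]) - pmax(dx0, gx0[j]))
    iy <- pmax(0, pmin(dy1, gy1[j]) - pmax(dy0, gy0[j]))
    inter <- ix * iy
    M[, j] <- inter /
      (dets$box_w * dets$box_h + gts$box_w[j] * gts$box_h[j] - inter)
  }
  M
}

#' Match detections to ground truth
#'
#' Greedy matching in decreasing IoU order: each ground truth matches at most
#' one detection; matched pairs with IoU strictly above the threshold are
#' true positives, unmatched detections false positives, unmatched ground
#' truths false negatives. The counts are invariant to the order of the
#' input rows.
#'
#' @param dets,gts Tibbles with `box_x`, `box_y`, `box_w`, `box_h` (empty
#'   tables are valid).
#' @param iou_threshold Matching threshold (pairs must exceed it).
#' @return A list: `counts` (tibble `tp`, `fp`, `fn`) and `matches` (tibble
#'   `det`, `gt`, `iou` of matched row indices).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  M <- iou_matrix(dets, gts)
  cand <- which(M > iou_threshold, arr.ind = TRUE)
  matches <- tibble(det = integer(), gt = integer(), iou = double())
  if (length(cand) > 0) {
    ord <- order(M[cand], decreasing = TRUE,
                 cand[, 1], cand[, 2])  # deterministic tie-break
    det_used <- logical(nd); gt_used <- logical(ng)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (det_used[i] || gt_used[j]) next
      det_used[i] <- TRUE; gt_used[j] <- TRUE
      matches <- bind_rows(matches,
                           tibble(det = i, gt = j, iou = M[i, j]))
    }
  }
  tp <- nrow(matches)
  list(counts = tibble(tp = tp, fp = nd - tp, fn = ng - tp),
       matches = matches)
}

#' Precision and recall from match counts
#'
#' p = tp / (tp + fp), r = tp / (tp + fn). A zero denominator yields `NA`
#' (undefined-metric marker), never a division error.
#'
#' @param counts Tibble or list with `tp`, `fp`, `fn`.
#' @return A tibble with `precision` and `recall`.
#' @examples
#' precision_recall(list(tp = 6, fp = 2, fn = 4)) # p = 0.75, r = 0.6
#' @export
precision_recall <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tibble(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Counting accuracy metrics
#'
#' MAE = mean |y - yhat|, RMSE = sqrt(mean (y - yhat)^2), and the standard
#' coefficient of determination R2 = 1 - SS_res / SS_tot. R2 is `NA` when
#' fewer than two observations are given or the true counts have zero
#' variance.
#'
#' @param y True (manual) per-image counts.
#' @param y_hat Predicted per-image counts.
#' @return A tibble with `mae`, `rmse`, `r2`.
#' @examples
#' count_metrics(c(10, 20, 30), c(12, 18, 30))
#' @export
count_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    abort("`y` and `y_hat` must have equal length.",
          class = "wheattips_invalid_parameter")
  if (length(y) == 0)
    return(tibble(mae = NA_real_, rmse = NA_real_, r2 = NA_real_))
  res <- y - y_hat
  sst <- sum((y - mean(y))^2)
  tibble(mae = mean(abs(res)),
         rmse = sqrt(mean(res^2)),
         r2 = if (length(y) >= 2 && sst > 0) 1 - sum(res^2) / sst else NA_real_)
}

#' Per-image evaluation table
#'
#' Matches detections to annotations image by image.
#'
#' @param gts List of ground-truth annotation tibbles (one per image).
#' @param dets List of detection tibbles (same length/order).
#' @param stages Numeric Haun stage per image (optional).
#' @param iou_threshold Matching threshold.
#' @return A tibble with one row per image: `image`, `stage`, `y`, `y_hat`,
#'   `tp`, `fp`, `fn`.
#' @export
eval_image_table <- function(gts, dets, stages = NULL, iou_threshold = 0.5) {
  stopifnot(length(gts) == length(dets))
  if (is.null(stages)) stages <- rep(NA_real_, length(gts))
  rows <- map(seq_along(gts), function(i) {
    cnt <- match_detections(dets[[i]], gts[[i]], iou_threshold)$counts
    tibble(image = i, stage = stages[i],
           y = nrow(gts[[i]]), y_hat = nrow(dets[[i]]),
           tp = cnt$tp, fp = cnt$fp, fn = cnt$fn)
  })
  bind_rows(rows)
}

stage_bin <- function(stage) {
  pmin(pmax(floor(stage), 1), 4)
}

#' Detection and counting report, overall and per development stage
#'
#' Bins images by the floor of their Haun stage, clamped to 1..4, and
#' computes precision/recall from pooled match counts plus MAE/RMSE/R2 from
#' per-image counts, per bin and overall. Empty bins are omitted.
#'
#' @param per_image A tibble as from [eval_image_table()].
#' @return A `tip_eval` object; see [tidy.tip_eval()] / [glance.tip_eval()].
#' @export
per_stage_report <- function(per_image) {
  summarise_bin <- function(df, label) {
    pr <- precision_recall(list(tp = sum(df$tp), fp = sum(df$fp),
                                fn = sum(df$fn)))
    cm <- count_metrics(df$y, df$y_hat)
    tibble(stage = label, n_images = nrow(df),
           tp = sum(df$tp), fp = sum(df$fp), fn = sum(df$fn),
           precision = pr$precision, recall = pr$recall,
           mae = cm$mae, rmse = cm$rmse, r2 = cm$r2)
  }
  overall <- summarise_bin(per_image, "overall")
  staged <- per_image[!is.na(per_image$stage), , drop = FALSE]
  per_stage <- NULL
  if (nrow(staged) > 0) {
    bins <- stage_bin(staged$stage)
    per_stage <- bind_rows(lapply(sort(unique(bins)), function(b)
      summarise_bin(staged[bins == b, , drop = FALSE], as.character(b))))
  }
  structure(list(overall = overall,
                 per_stage = per_stage %||% overall[0, ],
                 per_image = per_image),
            class = "tip_eval")
}

#' @export
print.tip_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<tip_eval> %d images | precision %.3f recall %.3f | ",
                     "MAE %.2f RMSE %.2f R2 %s\n"),
              o$n_images, o$precision, o$recall, o$mae, o$rmse,
              ifelse(is.na(o$r2), "NA", sprintf("%.3f", o$r2))))
  invisible(x)
}

#' Tidy a tip-detection evaluation
#'
#' `tidy()` returns one row per development-stage bin; `glance()` the overall
#' one-row summary.
#'
#' @param x A `tip_eval` from [per_stage_report()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tip_eval <- function(x, ...) x$per_stage

#' @rdname tidy.tip_eval
#' @export
glance.tip_eval <- function(x, ...) x$overall

#' Write an evaluation report as CSV and JSON
#'
#' @param report A `tip_eval`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  tab <- bind_rows(report$overall, report$per_stage)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(overall = report$overall,
                              per_stage = report$per_stage),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}
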