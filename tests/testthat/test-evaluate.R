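test_that("IoU follows its closed form", {
  expect_equal(iou(c(0, 0, 12, 12), c(0, 0, 12, 12)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(50, 50, 10, 10)), 0)
  expect_equal(iou(c(0, 0, 12, 12), c(6, 0, 12, 12)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 12), c(0, 0, 12, 12)),
               class = "wheattips_invalid_box")
})

test_that("greedy matching resolves duplicates one-to-one", {
  gt <- tibble::tibble(box_x = 0, box_y = 0, box_w = 12, box_h = 12)
  det1 <- gt
  m <- match_detections(det1, gt)
  expect_equal(as.numeric(m$counts), c(1, 0, 0))

  det2 <- dplyr::bind_rows(gt, gt)  # two identical detections on one truth
  m2 <- match_detections(det2, gt)
  expect_equal(as.numeric(m2$counts), c(1, 1, 0))

  m0 <- match_detections(det1[0, ], gt)
  expect_equal(as.numeric(m0$counts), c(0, 0, 1))
})

test_that("matching counts agree with an optimal-assignment oracle", {
  mk <- function(u, v) tibble::tibble(box_x = u - 6, box_y = v - 6,
                                      box_w = 12, box_h = 12)
  # all pairwise IoUs above threshold: every detection 1 px off its truth
  set.seed(9)
  gu <- runif(20, 20, 400); gv <- runif(20, 20, 400)
  gt <- mk(gu, gv)
  det <- mk(gu + 1, gv)
  adj <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20)
    adj[i, j] <- iou(as.numeric(det[i, ]), as.numeric(gt[j, ])) > 0.5
  got <- match_detections(det, gt)$counts$tp
  expect_equal(got, oracle_max_matching(adj))

  # all pairs below threshold
  det_far <- mk(gu + 300, gv + 300)
  adj2 <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20)
    adj2[i, j] <- iou(as.numeric(det_far[i, ]), as.numeric(gt[j, ])) > 0.5
  expect_equal(match_detections(det_far, gt)$counts$tp,
               oracle_max_matching(adj2))
  expect_equal(match_detections(det_far, gt)$counts$tp, 0)
})

test_that("precision and recall follow their definitions with NA guards", {
  pr <- precision_recall(list(tp = 6, fp = 2, fn = 4))
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.6)
  pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 5))
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)
  prn <- precision_recall(list(tp = 7, fp = 0, fn = 0))
  expect_equal(prn$precision, 1)
  expect_equal(prn$recall, 1)
})

test_that("counting metrics reproduce hand arithmetic", {
  m <- count_metrics(c(10, 20, 30), c(12, 18, 30))
  expect_equal(m$mae, 4 / 3)
  expect_equal(m$rmse, sqrt(8 / 3))
  expect_equal(m$r2, 1 - 8 / 200)

  perfect <- count_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(as.numeric(perfect), c(0, 0, 1))

  const <- count_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(const$mae, 2 / 3)
  expect_equal(const$rmse, sqrt(2 / 3))
  expect_equal(const$r2, 0)  # the constant mean predictor scores exactly 0

  flat <- count_metrics(c(5, 5, 5), c(4, 6, 5))
  expect_true(is.na(flat$r2))  # zero variance in the truth
})

test_that("rmse dominates mae over random count series", {
  set.seed(123)
  for (k in 1:200) {
    n <- sample(2:30, 1)
    y <- rpois(n, 20); yh <- rpois(n, 20)
    m <- count_metrics(y, yh)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
})

test_that("matching counts are invariant to detection order", {
  set.seed(77)
  mk <- function(u, v) tibble::tibble(box_x = u - 6, box_y = v - 6,
                                      box_w = 12, box_h = 12)
  gt <- mk(runif(15, 10, 200), runif(15, 10, 200))
  det <- mk(runif(15, 10, 200), runif(15, 10, 200))
  a <- match_detections(det, gt)$counts
  perm <- sample(15)
  b <- match_detections(det[perm, ], gt)$counts
  expect_equal(a, b)
})

test_that("per-stage reports bin, clamp and add up", {
  per_image <- tibble::tibble(
    image = 1:6, stage = c(2.3, 2.3, 0.5, 1.2, 3.7, 3.9),
    y = c(5, 6, 2, 3, 9, 11), y_hat = c(5, 5, 2, 4, 7, 10),
    tp = c(5, 5, 2, 3, 7, 9), fp = c(0, 0, 0, 1, 0, 1),
    fn = c(0, 1, 0, 0, 2, 2))
  rep_all <- per_stage_report(per_image)
  expect_s3_class(rep_all, "tip_eval")
  expect_setequal(tidy(rep_all)$stage, c("1", "2", "3"))  # 0.5 clamps into 1
  expect_equal(sum(tidy(rep_all)$tp), glance(rep_all)$tp)
  expect_gte(glance(rep_all)$rmse, glance(rep_all)$mae)

  one_bin <- per_stage_report(per_image[1:2, ])
  expect_equal(tidy(one_bin)$precision, glance(one_bin)$precision)
  expect_equal(tidy(one_bin)$mae, glance(one_bin)$mae)

  tab <- eval_image_table(
    gts = list(tibble::tibble(box_x = 0, box_y = 0, box_w = 12, box_h = 12)),
    dets = list(tibble::tibble(box_x = 1, box_y = 0, box_w = 12, box_h = 12)),
    stages = 2.1)
  expect_equal(tab$tp, 1)
  expect_equal(tab$y, 1)
})

test_that("evaluation reports serialize to CSV and JSON", {
  per_image <- tibble::tibble(image = 1:3, stage = c(1.5, 2.5, 2.6),
                              y = c(3, 4, 5), y_hat = c(3, 3, 5),
                              tp = c(3, 3, 4), fp = c(0, 0, 1),
                              fn = c(0, 1, 1))
  rep <- per_stage_report(per_image)
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, pc, pj)
  expect_equal(nrow(utils::read.csv(pc)), 1 + nrow(tidy(rep)))
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(j$overall$tp, glance(rep)$tp)
})
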