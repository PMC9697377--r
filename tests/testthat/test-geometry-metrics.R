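test_that("IoU follows rectangle-area arithmetic and is symmetric", {
  a <- boxes_from_corners(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  b <- boxes_from_corners(5, 0, 15, 10)
  expect_equal(box_iou(a, b), 50 / 150)
  expect_equal(box_iou(b, a), box_iou(a, b))
  far <- boxes_from_corners(100, 100, 110, 120)
  expect_equal(box_iou(a, far), 0)
  # symmetry + range over random pairs
  set.seed(7)
  for (i in 1:50) {
    p <- boxes(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 30),
               runif(1, 1, 30))
    q <- boxes(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 30),
               runif(1, 1, 30))
    v <- box_iou(p, q)
    expect_equal(v, box_iou(q, p))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_error(boxes(0, 0, -1, 5), "positive")
})

test_that("greedy matching consumes each ground truth once, by score", {
  gt <- boxes_from_corners(0, 0, 10, 10, label = "a")
  d_hit <- boxes_from_corners(0, 0, 10, 16.6, label = "a", score = 0.9)
  expect_gt(box_iou(d_hit, gt), 0.5)
  fl <- match_detections(d_hit, gt)
  expect_identical(fl$tp, TRUE)
  d_miss <- boxes_from_corners(0, 0, 10, 26, label = "a", score = 0.9)
  expect_lt(box_iou(d_miss, gt), 0.5)
  expect_identical(match_detections(d_miss, gt)$tp, FALSE)
  # two detections over one GT: higher score wins, the other is FP
  two <- boxes_from_corners(c(0, 0), c(0, 0), c(10, 10), c(11, 12),
                            label = "a", score = c(0.9, 0.8))
  expect_identical(match_detections(two, gt)$tp, c(TRUE, FALSE))
  # ... regardless of input order (sorted by score first)
  two_rev <- two[2:1, ]
  expect_identical(match_detections(two_rev, gt)$tp, c(TRUE, FALSE))
  # strictness: IoU exactly at threshold is FP by default, TP with >=
  d_at <- boxes_from_corners(0, 0, 10, 5, label = "a", score = 0.5)
  expect_equal(box_iou(d_at, gt), 0.5)
  expect_identical(match_detections(d_at, gt)$tp, FALSE)
  expect_identical(match_detections(d_at, gt, strict = FALSE)$tp, TRUE)
  expect_error(match_detections(boxes_from_corners(0, 0, 1, 1, label = "a"),
                                gt), "score")
})

test_that("precision/recall points follow the cumulative definitions", {
  fl <- structure(list(tp = c(TRUE, TRUE, FALSE), n_gt = 4,
                       order = 1:3), class = "match_flags")
  pr <- precision_recall(fl)
  expect_equal(pr$precision, c(1, 1, 2 / 3))
  expect_equal(pr$recall, c(0.25, 0.5, 0.5))
  # all TP with n_gt = #dets ends at precision 1, recall 1
  fl2 <- structure(list(tp = rep(TRUE, 5), n_gt = 5, order = 1:5),
                   class = "match_flags")
  pr2 <- precision_recall(fl2)
  expect_equal(tail(pr2$precision, 1), 1)
  expect_equal(tail(pr2$recall, 1), 1)
  expect_error(precision_recall(structure(list(tp = TRUE, n_gt = 0,
                                               order = 1L),
                                          class = "match_flags")),
               "undefined")
  # random flag sequences match the loop oracle
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    tp <- runif(n) < 0.5
    n_gt <- sum(tp) + sample(0:5, 1)
    if (n_gt == 0) next
    fl <- structure(list(tp = tp, n_gt = n_gt, order = seq_len(n)),
                    class = "match_flags")
    pr <- precision_recall(fl)
    or <- oracle_pr(tp, n_gt)
    expect_equal(pr$precision, or$precision)
    expect_equal(pr$recall, or$recall)
    expect_true(all(diff(pr$recall) >= 0))
  }
})

test_that("average precision equals fine-grid integration of the envelope", {
  # frozen case: flags TP, FP, TP with n_gt = 2
  fl <- structure(list(tp = c(TRUE, FALSE, TRUE), n_gt = 2, order = 1:3),
                  class = "match_flags")
  pr <- precision_recall(fl)
  expect_equal(average_precision(pr), 5 / 6)
  expect_equal(average_precision(pr),
               oracle_ap_grid(pr$precision, pr$recall, n_grid = 1e5),
               tolerance = 1e-4)
  # perfect detector and all-FP extremes
  perf <- precision_recall(structure(list(tp = rep(TRUE, 4), n_gt = 4,
                                          order = 1:4),
                                     class = "match_flags"))
  expect_equal(average_precision(perf), 1)
  allfp <- precision_recall(structure(list(tp = rep(FALSE, 4), n_gt = 2,
                                           order = 1:4),
                                      class = "match_flags"))
  expect_equal(average_precision(allfp), 0)
  expect_warning(ap0 <- average_precision(
    structure(list(precision = numeric(), recall = numeric()),
              class = "pr_curve")), "empty")
  expect_equal(ap0, 0)
  # AP never exceeds 1; eleven-point stays within [0, 1] too
  set.seed(23)
  for (i in 1:50) {
    n <- sample(1:25, 1)
    tp <- runif(n) < runif(1)
    n_gt <- max(1, sum(tp) + sample(0:4, 1))
    pr <- precision_recall(structure(list(tp = tp, n_gt = n_gt,
                                          order = seq_len(n)),
                                     class = "match_flags"))
    for (m in c("all_point", "eleven_point")) {
      ap <- average_precision(pr, method = m)
      expect_gte(ap, 0)
      expect_lte(ap, 1)
    }
  }
})

test_that("mean AP aggregates per-class APs arithmetically", {
  expect_equal(mean_ap(rep(100, 10)), 100)
  expect_equal(mean_ap(c(a = 62, b = 62, c = 62)), 62)
  pub <- read.csv(system.file("extdata", "published_results.csv",
                              package = "pestdetectr"))
  ours <- pub[pub$detector == "AMFFP", ]
  expect_equal(round(mean_ap(ours$ap), 1), 70.1)
  expect_equal(round(mean_ap(ours$recall), 1), 74.3)
  fpn <- pub[pub$detector == "FPN", ]
  expect_equal(round(mean_ap(fpn$ap), 1), 65.2)
  expect_equal(round(mean_ap(ours$ap), 1) - round(mean_ap(fpn$ap), 1), 4.9)
  expect_error(mean_ap(numeric()), "at least one")
})

test_that("evaluate decomposes per class and is exact on self-detections", {
  set.seed(31)
  mk <- function(n, labels, img) {
    boxes(cx = runif(n, 10, 90), cy = runif(n, 10, 90),
          w = runif(n, 4, 20), h = runif(n, 4, 20),
          label = sample(labels, n, replace = TRUE))
  }
  gts <- do.call(rbind, lapply(1:6, function(i) {
    g <- mk(4, c("a", "b", "c"), i)
    g$image <- paste0("im", i)
    g
  }))
  # detections identical to ground truth with score 1 -> everything 100
  dets <- gts
  dets$score <- 1
  rep <- evaluate(dets, gts, classes = c("a", "b", "c"))
  expect_equal(rep$mean_ap, 100)
  expect_equal(rep$mean_recall, 100)
  expect_true(all(rep$per_class$ap == 100))
  # no detections at all
  empty <- cbind(boxes(), image = character(0))
  rep0 <- evaluate(empty, gts, classes = c("a", "b", "c"))
  expect_equal(rep0$mean_ap, 0)
  expect_equal(rep0$mean_recall, 0)
  # unknown labels are rejected with the offending label named
  bad <- dets
  bad$label[1] <- "zzz"
  expect_error(evaluate(bad, gts, classes = c("a", "b", "c")), "zzz")
  # multi-class evaluation equals running each class alone
  noisy <- do.call(rbind, lapply(split(gts, seq_len(nrow(gts))),
                                 function(g) {
    d <- g
    d$cx <- d$cx + rnorm(1, 0, 3)
    d$w <- d$w * runif(1, 0.8, 1.25)
    d$score <- runif(1)
    d
  }))
  extra <- mk(10, c("a", "b", "c"), 0)
  extra$score <- runif(10)
  extra$image <- sample(paste0("im", 1:6), 10, replace = TRUE)
  noisy <- rbind(noisy, extra)
  full <- evaluate(noisy, gts, classes = c("a", "b", "c"))
  for (cl in c("a", "b", "c")) {
    single <- evaluate(noisy[noisy$label == cl, ],
                       gts[gts$label == cl, ], classes = cl)
    expect_equal(full$per_class$ap[full$per_class$class == cl],
                 single$per_class$ap)
    expect_equal(full$per_class$recall[full$per_class$class == cl],
                 single$per_class$recall)
  }
})

test_that("evaluation reports render and serialize with a Mean row", {
  gt <- boxes_from_corners(c(0, 20), c(0, 0), c(10, 30), c(10, 10),
                           label = c("a", "b"))
  gt$image <- "im1"
  d <- gt
  d$score <- 0.9
  rep <- evaluate(d, gt, classes = c("a", "b"))
  txt <- capture.output(print(rep))
  expect_true(any(grepl("^Mean", txt)))
  expect_true(any(grepl("Recall", txt)))
  csv <- file.path(tempdir(), "rep.csv")
  write_eval_csv(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$class, c("a", "b", "Mean"))
  expect_equal(back$ap[3], mean(back$ap[1:2]))
})
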