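# IoU matching and the F1avg metric.

# strip instances: 1 x n horizontal runs of pixels with exact, hand-chosen
# IoUs against each other
strip_instance <- function(row, col0, len, dim = c(40L, 60L), score = 1) {
  pix <- cbind(x = col0:(col0 + len - 1L), y = rep(row, len))
  storage.mode(pix) <- "integer"
  structure(list(center = c(col0 + len / 2, row), efd = NULL, score = score,
                 pixels = pix, dim = dim, mean_fl = NA_real_,
                 suspicious = NA),
            class = "cell_instance")
}

test_that("mask_iou handles the textbook cases", {
  a <- strip_instance(2, 0, 10)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, strip_instance(5, 0, 10)), 0)
  # 3x3 squares overlapping in 6 pixels: 6 / 12
  m1 <- matrix(FALSE, 10, 10); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[3:5, 2:4] <- TRUE
  expect_equal(mask_iou(m1, m2), 6 / 12)
  expect_error(mask_iou(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
               "undefined")
})

test_that("match_at_tau is a maximum (not greedy) matching", {
  # pred1 overlaps gt1 (0.75) and gt2 (0.55); pred2 overlaps only gt1
  # (0.6). Greedy by IoU would take (p1, g1) and strand p2; the maximum
  # matching pairs (p1, g2), (p2, g1) at tau = 0.5.
  iou <- matrix(c(0.75, 0.6, 0.55, 0), 2, 2)
  m <- match_at_tau(list(1, 2), list(1, 2), 0.5, iou = iou)
  expect_equal(m, list(TP = 2L, FP = 0L, FN = 0L))
  # at 0.6 the (p1, g2) edge disappears and both predictions compete for g1
  m6 <- match_at_tau(list(1, 2), list(1, 2), 0.6, iou = iou)
  expect_equal(m6$TP, 1L)
  m7 <- match_at_tau(list(1, 2), list(1, 2), 0.7, iou = iou)
  expect_equal(m7, list(TP = 1L, FP = 1L, FN = 1L))
})

test_that("the worked two-cell case scores f1avg = 0.4", {
  # strips engineered to exact IoUs 0.75 = 6/8 and 0.55 = 22/40
  gt <- list(strip_instance(2, 0, 7), strip_instance(6, 0, 31))
  pred <- list(strip_instance(2, 1, 7),   # shift 1: IoU 6/8
               strip_instance(6, 9, 31))  # shift 9: IoU 22/40
  expect_equal(mask_iou(pred[[1]], gt[[1]]), 0.75)
  expect_equal(mask_iou(pred[[2]], gt[[2]]), 0.55)
  rep <- f1avg_report(pred, gt)
  expect_equal(rep$per_tau$F1, c(1, 0.5, 0.5, 0, 0))
  expect_equal(rep$f1avg, 0.4)
})

test_that("degenerate prediction/ground-truth sets follow the conventions", {
  gt <- list(strip_instance(2, 0, 7))
  perfect <- f1avg_report(gt, gt)
  expect_equal(perfect$f1avg, 1)
  none <- f1avg_report(list(), gt)
  expect_equal(none$f1avg, 0)
  expect_equal(none$per_tau$FN, rep(1L, 5))
  vacuous <- f1avg_report(list(), list())
  expect_equal(vacuous$f1avg, 1)
})

test_that("f1avg matches exhaustive-assignment enumeration on random cases", {
  set.seed(42)
  for (case in 1:60) {
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    pred <- random_instances(np)
    gt <- random_instances(ng, jitter = 1)
    iou <- efdcell:::iou_matrix(pred, gt)
    got <- f1avg_report(pred, gt)$f1avg
    expect_equal(got, oracle_f1avg(iou), tolerance = 1e-12)
  }
})

test_that("f1avg is invariant to the ordering of instances", {
  set.seed(11)
  pred <- random_instances(5)
  gt <- random_instances(5, jitter = 2)
  base <- f1avg_report(pred, gt)$f1avg
  for (i in 1:5) {
    expect_equal(f1avg_report(sample(pred), sample(gt))$f1avg, base)
  }
})

test_that("TP + FN equals the ground-truth count at every threshold", {
  set.seed(13)
  pred <- random_instances(6)
  gt <- random_instances(4, jitter = 1.5)
  rep <- f1avg_report(pred, gt)
  expect_true(all(rep$per_tau$TP + rep$per_tau$FN == length(gt)))
  expect_true(all(rep$per_tau$TP + rep$per_tau$FP == length(pred)))
  expect_true(all(diff(rep$per_tau$F1) <= 1e-12)) # non-increasing in tau
})

test_that("eroding predicted masks never improves the score", {
  erode1 <- function(inst) {
    m <- efdcell:::pixels_to_mask(inst$pixels, inst$dim)
    H <- nrow(m); W <- ncol(m)
    keep <- m
    keep[1, ] <- FALSE; keep[H, ] <- FALSE; keep[, 1] <- FALSE; keep[, W] <- FALSE
    inner <- m[c(2:H, H), ] & m[c(1, 1:(H - 1)), ] &
             m[, c(2:W, W)] & m[, c(1, 1:(W - 1))] & m
    idx <- which(inner, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    inst$pixels <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
    inst
  }
  set.seed(31)
  for (rep_i in 1:5) {
    gt <- random_instances(6)
    pred <- gt
    base <- f1avg_report(pred, gt)$f1avg
    eroded <- Filter(Negate(is.null), lapply(pred, erode1))
    expect_lte(f1avg_report(eroded, gt)$f1avg, base + 1e-12)
  }
})

test_that("macro and micro dataset aggregation both work", {
  set.seed(4)
  pairs <- lapply(1:3, function(i) {
    gt <- random_instances(4)
    list(pred = gt, gt = gt)
  })
  expect_equal(f1avg_dataset(pairs, mode = "macro")$f1avg, 1)
  expect_equal(f1avg_dataset(pairs, mode = "micro")$f1avg, 1)
  # one bad image drags macro down by exactly 1/3
  pairs[[2]]$pred <- list()
  expect_equal(f1avg_dataset(pairs, mode = "macro")$f1avg, 2 / 3)
  mic <- f1avg_dataset(pairs, mode = "micro")
  expect_true(mic$f1avg > 2 / 3 && mic$f1avg < 1) # pooled counts differ
})
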