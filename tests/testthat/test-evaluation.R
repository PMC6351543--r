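test_that("mIoU matches hand-counted confusion examples", {
  # 2x2 image, GT = left column tumor, prediction = all tumor
  gt <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred <- matrix(1L, 2, 2)
  cc <- confusion_counts(pred, gt)
  expect_equal(tumor_iou(cc), 0.5)
  expect_equal(miou(cc), 0.25)
  # perfect prediction
  expect_equal(miou(confusion_counts(gt, gt)), 1.0)
  # complement (both classes present) -> 0
  expect_equal(miou(confusion_counts(1L - gt, gt)), 0)
  # class absent from prediction and truth scores 1: all-normal slide, all-normal prediction
  z <- matrix(0L, 3, 3)
  expect_equal(miou(confusion_counts(z, z)), 1.0)
  expect_equal(tumor_iou(confusion_counts(z, z)), 1.0)
})

test_that("mIoU equals the naive per-pixel counting oracle on random masks", {
  for (i in 1:30) {
    pred <- random_mask(12, 9, p = runif(1), seed = 2 * i)
    gt <- random_mask(12, 9, p = runif(1), seed = 2 * i + 1)
    expect_equal(miou(confusion_counts(pred, gt)), brute_miou(pred, gt),
                 tolerance = 1e-15)
  }
})

test_that("slide AUC equals Mann-Whitney with midranks", {
  expect_equal(slide_auc(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(slide_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # swapping labels complements the AUC
  set.seed(21)
  s <- runif(20); l <- as.integer(runif(20) < 0.5)
  if (sum(l) %in% c(0, 20)) l[1:2] <- c(0L, 1L)
  expect_equal(slide_auc(s, l), 1 - slide_auc(s, 1 - l), tolerance = 1e-12)
  # tie-free data: AUC = U / (n1 * n0) by explicit pair counting
  u <- 0
  for (i in which(l == 1)) for (j in which(l == 0)) u <- u + (s[i] > s[j])
  expect_equal(slide_auc(s, l), u / (sum(l) * sum(1 - l)), tolerance = 1e-12)
  expect_error(slide_auc(s, rep(1, 20)), "both tumor and normal")
})

test_that("heatmap detections are one per connected component at its maximum", {
  d <- matrix(0, 8, 8)
  d[2:3, 2:3] <- c(0.7, 0.8, 0.6, 0.9)
  d[6, 6] <- 0.75
  hm <- prob_heatmap(d, 8)
  det <- heatmap_to_detections(hm)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$prob), c(0.75, 0.9))
  best <- det[which.max(det$prob), ]
  expect_equal(c(best$x, best$y), c(2, 2))  # 0-based coords of d[3,3]
  expect_equal(nrow(heatmap_to_detections(prob_heatmap(matrix(0.1, 4, 4), 8))), 0)
  # two blobs can merge at a lower threshold: count is threshold-dependent
  d2 <- matrix(0, 5, 5); d2[2, 2] <- 0.9; d2[2, 4] <- 0.9; d2[2, 3] <- 0.45
  expect_equal(nrow(heatmap_to_detections(prob_heatmap(d2, 8), 0.5)), 2)
  expect_equal(nrow(heatmap_to_detections(prob_heatmap(d2, 8), 0.4)), 1)
})

test_that("FROC matches closed cases and the brute-force threshold sweep", {
  # all lesions hit with probability 1, zero FPs -> 1.0
  gt1 <- matrix(0L, 10, 10); gt1[2:3, 2:3] <- 1L; gt1[7:8, 7:8] <- 1L
  det1 <- data.frame(x = c(1, 6), y = c(1, 6), prob = c(1, 1))
  expect_equal(froc(list(list(gt = gt1, detections = det1)))$score, 1.0)
  # no detections -> 0
  nodet <- data.frame(x = integer(0), y = integer(0), prob = numeric(0))
  expect_equal(froc(list(list(gt = gt1, detections = nodet)))$score, 0)
  expect_error(froc(list(list(gt = matrix(0L, 4, 4), detections = nodet))), "no lesions")

  # constructed 2-slide case vs brute-force sweep
  gt2 <- matrix(0L, 10, 10); gt2[5:6, 5:6] <- 1L
  det2 <- data.frame(x = c(4, 0, 9, 3), y = c(4, 0, 9, 9),
                     prob = c(0.7, 0.6, 0.4, 0.3))
  per <- list(list(gt = gt1, detections = det1), list(gt = gt2, detections = det2))
  got <- froc(per)
  want <- brute_froc(per)
  expect_equal(got$score, want$score, tolerance = 1e-12)
  expect_equal(got$curve$sensitivity, want$curve$sensitivity, tolerance = 1e-12)
  expect_equal(got$curve$fp_per_slide, want$curve$fp_per_slide, tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded, degenerate for constant metrics, and shrink with n", {
  data10 <- as.list(rnorm(10, mean = 5))
  const <- bootstrap_ci(function(d) 3.25, data10, B = 100, seed = 1)
  expect_equal(unname(const), c(3.25, 3.25), ignore_attr = TRUE)
  ci_a <- bootstrap_ci(function(d) mean(unlist(d)), data10, B = 500, seed = 7)
  ci_b <- bootstrap_ci(function(d) mean(unlist(d)), data10, B = 500, seed = 7)
  expect_identical(ci_a, ci_b)
  set.seed(9)
  data100 <- as.list(rnorm(100, mean = 5))
  ci_big <- bootstrap_ci(function(d) mean(unlist(d)), data100, B = 500, seed = 7)
  expect_lt(diff(unname(ci_big)), diff(unname(ci_a)))
})

test_that("cohort evaluation aggregates per-slide metrics as stated", {
  mk <- function(hm, gt, label) list(heatmap = prob_heatmap(hm, 8), gt = gt, label = label)
  gt_t <- matrix(0L, 6, 6); gt_t[2:3, 2:3] <- 1L
  hm_t <- matrix(0.1, 6, 6); hm_t[2:3, 2:3] <- 0.9
  gt_n <- matrix(0L, 6, 6)
  hm_n <- matrix(0.1, 6, 6)
  ev <- evaluate_cohort(list(mk(hm_t, gt_t, 1), mk(hm_n, gt_n, 0)))
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$froc, 1.0)
  expect_equal(ev$tumor_miou, 1.0)
  expect_equal(ev$miou, 1.0)
  expect_equal(nrow(ev$per_slide), 2)
})
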