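# small synthetic slide shared across cascade tests
local_gen <- generate_slide(synth_spec(width0 = 1024, height0 = 1024,
                                       tissue_fraction = 0.3, n_tumor_blobs = 2,
                                       blob_radius = c(60, 120), seed = 7))

test_that("rough_pass with the zero-noise oracle marks exactly the windows touching tumor", {
  g <- local_gen
  tissue <- compute_tissue_mask(g$slide)
  rough <- rough_pass(g$slide, tissue, oracle_classifier(g$gt))
  # every predicted cell is 1 iff its window contains a tumor pixel
  plan <- plan_rough_tiles(tissue, c(1024, 1024))
  labs <- label_patches(plan, g$gt)
  for (i in seq_len(nrow(plan))) {
    cell <- c(plan$y[i] %/% 128, plan$x[i] %/% 128) + 1L
    if (rough$counts[cell[1], cell[2]] == 1L)  # single-contribution cells are unambiguous
      expect_equal(rough$data[cell[1], cell[2]], as.numeric(labs$label[i]))
  }
  # deterministic
  rough2 <- rough_pass(g$slide, tissue, oracle_classifier(g$gt))
  expect_identical(rough$data, rough2$data)
})

test_that("an empty tissue mask yields an all-zero rough heatmap", {
  empty <- mask_raster(matrix(0L, 32, 32), 32)
  expect_warning(
    rough <- rough_pass(local_gen$slide, empty, oracle_classifier(local_gen$gt)),
    "empty")
  expect_true(all(rough$data == 0))
})

test_that("candidate selection is a strict threshold", {
  hm <- prob_heatmap(matrix(0.4, 4, 4), 128)
  expect_true(all(select_candidates(hm)$data == 0L))
  expect_true(all(select_candidates(prob_heatmap(matrix(0.6, 4, 4), 128))$data == 1L))
  expect_true(all(select_candidates(prob_heatmap(matrix(0.5, 4, 4), 128))$data == 0L))
  expect_error(select_candidates(hm, thr = 1.1), "\\[0, 1\\]")
})

test_that("dense tile planning covers candidates with the aligned half-overlap grid", {
  # single candidate cell at scale-128 (10,10) -> 4 covering 2560-tiles
  cand <- matrix(0L, 41, 41); cand[11, 11] <- 1L
  plan <- plan_dense_tiles(mask_raster(cand, 128), c(5248, 5248))
  expect_equal(nrow(plan), 4)
  expect_setequal(paste(plan$x, plan$y),
                  c("0 0", "0 1280", "1280 0", "1280 1280"))

  # empty candidates -> empty plan
  p0 <- plan_dense_tiles(mask_raster(matrix(0L, 40, 40), 128), c(5120, 5120))
  expect_equal(nrow(p0), 0)

  # candidates everywhere on a 5120^2 slide -> 3x3 grid
  pall <- plan_dense_tiles(mask_raster(matrix(1L, 40, 40), 128), c(5120, 5120))
  expect_equal(nrow(pall), 9)
  expect_true(all(pall$x %% 1280 == 0 & pall$y %% 1280 == 0))

  # every candidate cell is covered by >= 1 window (brute force)
  set.seed(8)
  cand2 <- mask_raster(random_mask(32, 32, p = 0.05, seed = 88), 128)
  plan2 <- plan_dense_tiles(cand2, c(4096, 4096))
  cells <- which(cand2$data == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(cells))) {
    cx <- (cells[i, 2] - 1L) * 128; cy <- (cells[i, 1] - 1L) * 128
    covered <- any(plan2$x <= cx + 127 & plan2$x + 2560 > cx &
                   plan2$y <= cy + 127 & plan2$y + 2560 > cy)
    expect_true(covered)
  }
})

test_that("lowering the candidate threshold never shrinks the dense tile set", {
  g <- local_gen
  tissue <- compute_tissue_mask(g$slide)
  rough <- rough_pass(g$slide, tissue, oracle_classifier(g$gt, noise_sd = 0.2, seed = 2))
  n_tiles <- vapply(c(0.8, 0.5, 0.2, 0.05), function(thr) {
    nrow(plan_dense_tiles(select_candidates(rough, thr), c(1024, 1024),
                          size = 256, stride = 128))
  }, numeric(1))
  expect_true(all(diff(n_tiles) >= 0))
})

test_that("cascade equals full-slide segmentation on the covered area, pixel-exact", {
  g <- local_gen
  seg <- oracle_segmenter(g$gt, flip_rate = 0.2, seed = 3)  # noisy, to make equality non-trivial
  all_cand <- mask_raster(matrix(1L, 8, 8), 128)
  plan_all <- plan_dense_tiles(all_cand, c(1024, 1024), size = 256, stride = 128)
  # full-slide tiling constructed independently of the candidate mechanism
  ful <- expand.grid(x = seq(0, 768, 128), y = seq(0, 768, 128))
  plan_manual <- tile_plan(ful, 256, 128, "dense")
  hm_cand <- dense_pass(g$slide, plan_all, seg)
  hm_manual <- dense_pass(g$slide, plan_manual, seg)
  expect_identical(hm_cand$data, hm_manual$data)
})

test_that("end-to-end cascade with zero-noise oracles recovers the lattice ground truth", {
  g <- local_gen
  res <- cascade_segment(g$slide, oracle_classifier(g$gt), oracle_segmenter(g$gt),
                         tile = 512, stride = 256)
  gt8 <- lattice_mask(g$gt, 8)
  # within the covered region the binarized heatmap equals the lattice ground truth
  cov <- res$dense$counts > 0
  expect_true(all(((res$dense$data > 0.5) * 1L)[cov] == gt8$data[cov]))
  # and all tumor lattice pixels are covered
  expect_true(all(cov[gt8$data == 1L]))
  expect_equal(tumor_iou(confusion_counts(res$dense$data > 0.5, gt8$data)), 1.0)
})

test_that("multi-model dense passes average per tile", {
  g <- local_gen
  seg_lo <- oracle_segmenter(g$gt, prob_pos = 0.8, prob_neg = 0.0)
  seg_hi <- oracle_segmenter(g$gt, prob_pos = 1.0, prob_neg = 0.2)
  plan <- plan_dense_tiles(mask_raster(matrix(1L, 8, 8), 128), c(1024, 1024),
                           size = 256, stride = 256)
  hm <- dense_pass(g$slide, plan, list(seg_lo, seg_hi))
  gt8 <- lattice_mask(g$gt, 8)
  expect_true(all(abs(hm$data[gt8$data == 1L] - 0.9) < 1e-12))
  expect_true(all(abs(hm$data[gt8$data == 0L] - 0.1) < 1e-12))
})
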