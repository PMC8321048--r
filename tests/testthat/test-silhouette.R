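test_that("background model converges on constant input and flags motion", {
  cfg <- fall_config()
  nr <- 40; nc <- 60
  model <- background_model(nr, nc, cfg)
  const <- matrix(0.5, nr, nc)
  # cold start: first frame of a fresh model is all background
  st <- update_background(model, const)
  expect_equal(sum(st$mask), 0)
  for (i in 1:199) st <- update_background(st$model, const)
  expect_lt(mean(st$mask), 0.01)
  expect_error(update_background(st$model, matrix(0.5, nr + 1, nc)),
               "shape")
})

test_that("a translating bright rectangle is recovered by the raw mask", {
  nr <- 60; nc <- 100
  model <- background_model(nr, nc, fall_config())
  truth <- NULL
  st <- list(model = model)
  for (i in 1:70) {
    frame <- matrix(0.2, nr, nc)
    c0 <- 5 + i                                # steady horizontal drift
    truth <- rect_mask(nr, nc, 10, 49, c0, c0 + 19)
    frame[truth == 1L] <- 0.9
    st <- update_background(st$model, frame)
  }
  expect_gte(iou(st$mask, truth), 0.8)
})

test_that("graph-cut refinement removes pepper noise and lowers the energy", {
  set.seed(19)
  nr <- 50; nc <- 70
  truth <- rect_mask(nr, nc, 10, 39, 20, 49)
  frame <- matrix(0.1, nr, nc)
  frame[truth == 1L] <- 0.9
  frame <- frame + matrix(rnorm(nr * nc, 0, 0.02), nr, nc)
  noisy <- truth
  flip <- sample(length(noisy), round(0.03 * length(noisy)))
  noisy[flip] <- 1L - noisy[flip]
  refined <- refine_mask(frame, noisy)
  expect_gt(iou(refined, truth), iou(noisy, truth))
  expect_lte(graphcut_energy(frame, refined, seeds = noisy),
             graphcut_energy(frame, noisy, seeds = noisy))
})

test_that("zero pairwise weight reduces the cut to the unary decision", {
  set.seed(20)
  nr <- 30; nc <- 30
  truth <- rect_mask(nr, nc, 5, 24, 8, 21)
  frame <- matrix(0.15, nr, nc)
  frame[truth == 1L] <- 0.85
  frame <- frame + matrix(rnorm(nr * nc, 0, 0.05), nr, nc)
  cfg0 <- fall_config(gc_lambda = 0)
  refined <- refine_mask(frame, truth, cfg0)
  en <- fallhmm:::build_energy(frame, truth, cfg0)
  unary_opt <- matrix(as.integer(en$d_fg < en$d_bg), nr, nc)
  expect_identical(unname(refined), unname(unary_opt))
})

test_that("degenerate seeds pass through with a warning", {
  frame <- matrix(0.5, 10, 10)
  empty <- matrix(0L, 10, 10)
  expect_identical(refine_mask(frame, empty), empty)
  full <- matrix(1L, 10, 10)
  expect_warning(out <- refine_mask(frame, full), "degenerate")
  expect_identical(out, full)
})

test_that("largest component keeps one 8-connected blob deterministically", {
  m <- matrix(0L, 30, 30)
  m[2:11, 2:6] <- 1L                           # 50 px blob
  m[20:24, 20:21] <- 1L                        # 10 px blob
  keep <- largest_component(m)
  expect_equal(sum(keep), 50)
  expect_equal(sum(keep[2:11, 2:6]), 50)
  single <- rect_mask(20, 20, 3, 9, 4, 11)
  expect_equal(largest_component(single), single)
  expect_equal(sum(largest_component(matrix(0L, 5, 5))), 0)
  # diagonal chain is a single 8-connected component
  diagm <- matrix(0L, 10, 10); diag(diagm) <- 1L
  expect_equal(sum(largest_component(diagm)), 10)
  # size tie: the component whose first raster-order pixel is smaller wins
  tie <- matrix(0L, 10, 10)
  tie[5, 8] <- 1L                              # raster rank 48
  tie[6, 2] <- 1L                              # raster rank 52
  keep <- largest_component(tie)
  expect_equal(sum(keep), 1)
  expect_equal(keep[5, 8], 1L)
})

test_that("morphological opening and closing behave on pepper/holes", {
  m <- rect_mask(20, 20, 5, 14, 5, 14)
  speck <- m; speck[2, 2] <- 1L
  expect_equal(open_mask(speck), open_mask(m))
  hole <- m; hole[10, 10] <- 0L
  expect_equal(close_mask(hole), close_mask(m))
  expect_identical(open_mask(m, 0), m)
})

test_that("full segmentation recovers the synthetic silhouette", {
  script <- action_script("walk", 4.8)
  base <- small_cfg(51, noise_sigma = 0)
  sc0 <- generate_scene(script, base, render = "gray")
  masks0 <- segment_sequence(sc0$frames)
  n <- sc0$n_frames
  expect_gte(iou(masks0[[n]], sc0$masks[[n]]), 0.95)
  expect_true(all(vapply(masks0, function(m)
    all(m %in% c(0L, 1L)), logical(1))))
  sc10 <- generate_scene(script, small_cfg(52, noise_sigma = 10),
                         render = "gray")
  masks10 <- segment_sequence(sc10$frames)
  expect_gte(iou(masks10[[n]], sc10$masks[[n]]), 0.8)
})
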