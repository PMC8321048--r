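test_that("moving average matches its definition and the naive oracle", {
  expect_equal(moving_average(rep(7, 25), 6), rep(7, 25))
  expect_equal(moving_average(1:5, 1)[3], 3)
  expect_equal(moving_average(1:5, 0), as.numeric(1:5))
  # interior of a linear ramp is reproduced exactly
  x <- 0.5 * (0:40)
  expect_equal(moving_average(x, 4)[5:37], x[5:37])
  set.seed(11)
  for (N in c(1, 3, 10)) {
    x <- rnorm(60)
    expect_equal(moving_average(x, N), naive_ma(x, N))
  }
  expect_error(moving_average(numeric(0), 2), "empty")
})

test_that("moving average is linear in its input", {
  set.seed(12)
  x <- rnorm(80); y <- rnorm(80)
  expect_equal(moving_average(2.5 * x - 1.3 * y, 7),
               2.5 * moving_average(x, 7) - 1.3 * moving_average(y, 7))
})

test_that("modified difference matches closed forms and the naive oracle", {
  expect_equal(modified_difference(rep(3.2, 30), 2, 3), rep(0, 30))
  md <- modified_difference(as.numeric(1:40), 0, 1)
  expect_equal(md[3:38], rep(2, 36))           # unit ramp, N0=0, N1=1
  # unit step of height c: max MD equals c, attained near the step
  c0 <- 4.7; t0 <- 60
  x <- c(rep(0, t0), rep(c0, 80))
  md <- modified_difference(x, 0, 10)
  expect_equal(max(md), max(naive_md(x, 0, 10)))
  # one pre-step sample always dilutes the smaller window: 2N1/(2N1+1) of c
  expect_gte(max(md), c0 * 20 / 21 - 1e-12)
  expect_lte(max(md), c0 + 1e-12)
  expect_lte(abs(which.max(md) - t0), 1)
  set.seed(13)
  x <- rnorm(90)
  expect_equal(modified_difference(x, 2, 5), naive_md(x, 2, 5))
  expect_error(modified_difference(rnorm(10), 0, 5), "too short")
})

test_that("modified difference is antisymmetric under time reversal", {
  set.seed(14)
  x <- cumsum(rnorm(120))
  N0 <- 1; N1 <- 6
  md <- modified_difference(x, N0, N1)
  mdr <- modified_difference(rev(x), N0, N1)
  interior <- (2 * (N0 + N1) + 1):(120 - 2 * (N0 + N1))
  expect_equal(mdr[interior], -rev(md)[interior])
})

test_that("extremum search returns the global extremum with earliest-frame ties", {
  md <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  ev <- find_extremum(md, "max")
  expect_equal(ev$t_star, 5)
  expect_equal(ev$value, 5)
  expect_null(find_extremum(rep(0, 20), "max"))
  two <- c(0, 3, 0, 0, 3, 0)
  expect_equal(find_extremum(two, "max")$t_star, 1)
  expect_equal(find_extremum(-two, "min")$value, -3)
})

test_that("half-width interpolates the half-level crossings", {
  md <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  ev <- half_width(md, find_extremum(md, "max"))
  expect_equal(c(ev$f1, ev$f2, ev$v_hw), c(2.5, 7.5, 5))
  expect_equal(ev$t_star - ev$f1, ev$f2 - ev$t_star)  # symmetric curve
  # rectangular pulse of width W: v_hw within one frame of W
  for (W in c(5, 12)) {
    md <- c(rep(0, 20), rep(2, W), rep(0, 20))
    ev <- half_width(md, find_extremum(md, "max"))
    expect_lte(abs(ev$v_hw - W), 1)
  }
  # invariant under positive scaling of MD
  md <- dnorm(seq(-4, 4, length.out = 101), 0, 1)
  v1 <- half_width(md, find_extremum(md, "max"))$v_hw
  v2 <- half_width(37.5 * md, find_extremum(37.5 * md, "max"))$v_hw
  expect_equal(v1, v2)
  # monotone series: no crossing on one side, clamped with a warning
  ramp <- as.numeric(0:10)
  expect_warning(ev <- half_width(ramp, find_extremum(ramp, "max")),
                 "clamping")
  expect_equal(ev$f2, 10)
})

test_that("period thresholds follow the min/max/midpoint rule", {
  w <- data.frame(class = c("fall", "fall", "normal", "normal"),
                  d = c(30, 35, 18, 20),
                  a = c(30, 35, 18, 20),
                  r = c(30, 35, 18, 20))
  thr <- learn_period_thresholds(w)
  expect_equal(unname(thr$alpha1), rep(30, 3))
  expect_equal(unname(thr$alpha2), rep(20, 3))
  expect_equal(unname(thr$pd), rep(25, 3))
  expect_equal(predict(thr, c(d = 26, a = 26, r = 26))$video_class, "l1")
  expect_equal(predict(thr, c(d = 24, a = 24, r = 24))$video_class, "l2")
  expect_error(learn_period_thresholds(w[w$class == "fall", ]),
               "at least one")
})

test_that("strictly separated width distributions classify perfectly leave-one-out", {
  set.seed(15)
  n <- 12
  widths <- data.frame(
    class = rep(c("fall", "normal"), each = n),
    d = c(runif(n, 90, 120), runif(n, 5, 40)),
    a = c(runif(n, 80, 110), runif(n, 5, 45)),
    r = c(runif(n, 95, 125), runif(n, 10, 60)))
  hits <- vapply(seq_len(2 * n), function(i) {
    thr <- learn_period_thresholds(widths[-i, ])
    cls <- predict(thr, unlist(widths[i, c("d", "a", "r")]))$video_class
    cls == ifelse(widths$class[i] == "fall", "l1", "l2")
  }, logical(1))
  expect_true(all(hits))
})

test_that("video analysis finds feature-specific extrema inside the fall window", {
  run <- function(fall_action, seed) {
    sc <- generate_scene(
      action_script(c("walk", fall_action, "lie"), c(5, 0.8, 6.2)),
      scene_config(width = 120, height = 90, person_height = 36,
                   seed = seed))
    list(an = analyze_video(extract_feature_series(sc$masks)),
         fall = sc$fall_intervals)
  }
  side <- run("fall_sideways", 21)
  expect_equal(side$an$features$d$event$polarity, "min")
  expect_equal(side$an$features$r$event$polarity, "max")
  for (f in c("d", "r")) {
    t_star <- side$an$features[[f]]$event$t_star
    expect_gte(t_star, side$fall$start - 30)
    expect_lte(t_star, side$fall$end + 30)
  }
  expect_equal(side$an$features$a$event$polarity, "min")  # area shrinks
  fwd <- run("fall_forward", 22)
  expect_equal(fwd$an$features$a$event$polarity, "max")   # area spreads
})

test_that("all-walking scenes stay below fall-trained thresholds", {
  mk <- function(kind, seed, total) {
    sc <- generate_scene(scene_script(kind, seed = seed, total = total),
                         scene_config(width = 120, height = 90,
                                      person_height = 36, seed = seed))
    video_widths(analyze_video(extract_feature_series(sc$masks)))
  }
  wf1 <- mk("fall", 31, 35); wf2 <- mk("fall", 32, 35)
  wn1 <- mk("normal", 33, 20); wn2 <- mk("normal", 34, 20)
  thr <- learn_period_thresholds(data.frame(
    class = c("fall", "fall", "normal", "normal"),
    d = c(wf1["d"], wf2["d"], wn1["d"], wn2["d"]),
    a = c(wf1["a"], wf2["a"], wn1["a"], wn2["a"]),
    r = c(wf1["r"], wf2["r"], wn1["r"], wn2["r"])))
  held_out <- mk("normal", 35, 20)
  expect_equal(predict(thr, held_out)$video_class, "l2")
})
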