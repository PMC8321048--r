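flat_thresholds <- function(pd = 6) {
  learn_period_thresholds(data.frame(class = c("fall", "normal"),
                                     d = c(2 * pd - 2, 2),
                                     a = c(2 * pd - 2, 2),
                                     r = c(2 * pd - 2, 2)))
}

test_that("symbol encoding maps flag triples to the eight tree leaves", {
  thr <- flat_thresholds(6)      # pd = 6 for every feature
  # no intervals at all: every frame is o8
  s <- symbolize(NULL, thr, 10)
  expect_equal(as.integer(s), rep(8L, 10))
  # all three features detected over the same window: o1 inside
  iv <- data.frame(feature = c("d", "a", "r"), f1 = 2, f2 = 5, v_hw = 10)
  s <- symbolize(iv, thr, 8)
  expect_equal(as.integer(s), c(8, 8, 1, 1, 1, 1, 8, 8))
  # d and r only (a below threshold): o3 inside
  iv$v_hw <- c(10, 3, 10)
  s <- symbolize(iv, thr, 8)
  expect_equal(as.integer(s)[4], 3L)
  # d only: o4; r only: o7; a only: o6
  one <- function(f) {
    iv <- data.frame(feature = f, f1 = 0, f2 = 7, v_hw = 10)
    as.integer(symbolize(iv, thr, 8))[1]
  }
  expect_equal(one("d"), 4L)
  expect_equal(one("a"), 6L)
  expect_equal(one("r"), 7L)
  # fractional interval bounds widen to whole frames
  iv <- data.frame(feature = "d", f1 = 2.6, f2 = 4.2, v_hw = 10)
  expect_equal(which(as.integer(symbolize(iv, thr, 8)) == 4L), 3:6)
  expect_error(symbolize(NULL, thr, 0), "positive")
})

test_that("co-occurrence counting enumerates consecutive state pairs", {
  M <- count_cooccurrences(c("S1", "S1", "S2"))
  expect_equal(as.vector(M), c(1L, 0L, 1L, 0L))   # C11, C21, C12, C22
  M <- count_cooccurrences(c("S1", "S2", "S1", "S2", "S1"))
  expect_equal(M["S1", "S2"], 2L)
  expect_equal(M["S2", "S1"], 2L)
  expect_equal(M["S1", "S1"] + M["S2", "S2"], 0L)
  M <- count_cooccurrences(rep("S2", 9))
  expect_equal(M["S2", "S2"], 8L)
  expect_equal(sum(M), 8L)
  expect_error(count_cooccurrences("S1"), "at least 2")
})

test_that("transition matrix reproduces the worked example and edge cases", {
  A <- transition_matrix(PRINTED_M)
  expect_equal(round(as.vector(t(A)), 5),
               c(0.07229, 0.92771, 0.07229, 0.92771))
  expect_equal(transition_matrix(matrix(c(5, 0, 0, 7), 2)),
               matrix(c(1, 0, 0, 1), 2, dimnames = list(c("S1", "S2"),
                                                        c("S1", "S2"))))
  expect_equal(as.vector(transition_matrix(matrix(1, 2, 2))), rep(0.5, 4))
  expect_warning(A0 <- transition_matrix(matrix(c(0, 0, 3, 5), 2,
                                                byrow = TRUE)),
                 "never observed")
  expect_equal(as.vector(A0[1, ]), c(0.5, 0.5))
})

test_that("emission matrix matches the worked abnormal row and stays stochastic", {
  B <- suppressWarnings(emission_matrix(rep("S1", 4), c(1L, 1L, 3L, 1L)))
  expect_equal(as.vector(B[1, ]), c(0.75, 0, 0.25, 0, 0, 0, 0, 0))
  B <- suppressWarnings(emission_matrix(rep("S2", 6), rep(8L, 6)))
  expect_equal(B["S2", "o8"], 1)
  # uniform symbols at large n approach 1/8 per symbol
  set.seed(16)
  sym <- sample(1:8, 8000, replace = TRUE)
  B <- suppressWarnings(emission_matrix(rep("S1", 8000), sym))
  expect_true(all(abs(B[1, ] - 1 / 8) < 0.02))
  # rows sum to one for any pseudocount
  for (pc in c(0, 0.5, 3)) {
    B <- emission_matrix(c("S1", "S2", "S1"), c(1L, 8L, 2L), pc)
    expect_equal(rowSums(B), c(S1 = 1, S2 = 1))
  }
  expect_error(emission_matrix("S1", c(1L, 2L)), "equal length")
})

test_that("viterbi handles forced paths and zero-probability symbols", {
  ident <- list(A = diag(2), B = diag(8)[1:2, ], pi = c(0.5, 0.5))
  expect_equal(viterbi(rep(1L, 6), ident), rep("S1", 6))
  expect_equal(viterbi(rep(2L, 6), ident), rep("S2", 6))
  # printed model: b1(8) = 0 forces all-o8 sequences into the normal state
  printed <- list(A = PRINTED_A, B = printed_B(), pi = c(0.8, 0.2))
  expect_equal(viterbi(rep(8L, 40), printed), rep("S2", 40))
  expect_error(viterbi(c(1L, 4L), printed), "frame 1")
  expect_error(viterbi(integer(0), printed), "empty")
})

test_that("viterbi equals exhaustive path enumeration on random models", {
  set.seed(17)
  for (rep in 1:30) {
    m <- rand_model()
    T <- sample(1:9, 1)
    sym <- sample(1:8, T, replace = TRUE)
    expect_identical(viterbi(sym, m), brute_viterbi(sym, m))
  }
})

test_that("frame-level evaluation computes the confusion metrics", {
  pred <- rep(c("S1", "S2", "S2", "S1"), c(9, 1, 90, 0))
  truth <- rep(c("S1", "S2"), c(10, 90))
  ev <- evaluate_states(pred, truth)
  expect_equal(unname(ev$counts), c(9, 1, 90, 0))
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 90)
  expect_equal(ev$accuracy, 99)
  expect_equal(ev$specificity, 100)
  expect_equal(ev$npv, 90 / 91 * 100)
  perfect <- evaluate_states(truth, truth)
  expect_true(all(c(perfect$precision, perfect$recall, perfect$accuracy,
                    perfect$specificity, perfect$npv) == 100))
  w <- capture_warnings(deg <- evaluate_states(rep("S2", 10), rep("S2", 10)))
  expect_true(any(grepl("recall", w)))
  expect_true(is.nan(deg$recall))
  expect_equal(deg$specificity, 100)
  expect_error(evaluate_states(character(0), character(0)), "empty")
  expect_error(evaluate_states("S1", c("S1", "S2")), "equal length")
})

test_that("the guard window excludes borderline false alarms next to true falls", {
  truth <- rep(c("S2", "S1", "S2"), c(10, 5, 10))
  pred <- rep(c("S2", "S1", "S2"), c(8, 9, 8))   # spills 2 frames both sides
  plain <- evaluate_states(pred, truth)
  guarded <- evaluate_states(pred, truth, guard = 3)
  expect_equal(unname(plain$counts["Ns2"]), 4)
  expect_equal(unname(guarded$counts["Ns2"]), 0)
  expect_equal(guarded$specificity, 100)
  expect_lt(plain$specificity, 100)
})
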