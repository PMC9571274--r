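worked <- matrix(c(1, 2, 5, 3, 1, 2, 4, 3, 1), nrow = 3)  # [[1,3,4],[2,1,3],[5,2,1]]

test_that("worked dynamic-programming instance agrees with the enumeration oracle", {
  oracle <- dtw_brute_force(worked)
  expect_equal(oracle$dtw_value, 3)
  dp <- dtw_accumulate(worked)
  expect_equal(dp$dtw_value, oracle$dtw_value)
  expect_equal(dp$acc[1, 1], worked[1, 1])
  path <- optimal_path(dp, worked)
  expect_equal(path$steps, cbind(i = 1:3, j = 1:3))
  expect_equal(path$length_l, 3L)
  expect_equal(path$path_cost, dp$dtw_value)
})

test_that("accumulation matches brute force on random small matrices", {
  set.seed(99)
  for (k in 1:120) {  # the full 500-matrix sweep runs in test-acceptance.R
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    cost <- matrix(stats::runif(n * m, 0, 180), n, m)
    dp <- dtw_accumulate(cost)
    expect_equal(dp$dtw_value, dtw_brute_force(cost)$dtw_value,
                 tolerance = 1e-10)
    # accumulated entries dominate their cell costs; path-cost identity
    expect_true(all(dp$acc >= cost - 1e-12))
    p <- optimal_path(dp, cost)
    expect_equal(p$path_cost, dp$dtw_value, tolerance = 1e-10)
    expect_gte(p$length_l, max(n, m))
    expect_lte(p$length_l, n + m - 1)
    # symmetric step pattern: transposing the cost transposes the problem
    expect_equal(dtw_accumulate(t(cost))$dtw_value, dp$dtw_value,
                 tolerance = 1e-10)
  }
  expect_error(dtw_brute_force(matrix(0, 8, 8)), "guard")
  expect_error(dtw_accumulate(matrix(numeric(0), 0, 0)), "empty")
})

test_that("degenerate shapes: forced paths and tie-breaking", {
  row <- matrix(c(2, 3, 4), 1, 3)
  expect_equal(dtw_accumulate(row)$dtw_value, 9)  # only one path: the row sum
  p <- optimal_path(dtw_accumulate(row), row)
  expect_equal(p$steps[, "j"], 1:3, ignore_attr = TRUE)
  one <- matrix(7, 1, 1)
  expect_equal(dtw_accumulate(one)$dtw_value, 7)
  expect_equal(optimal_path(dtw_accumulate(one), one)$length_l, 1L)
  # all-zero square: ties resolve to the diagonal, l = n
  z <- matrix(0, 4, 4)
  pz <- optimal_path(dtw_accumulate(z), z)
  expect_equal(pz$steps, cbind(i = 1:4, j = 1:4))
})

test_that("similarity_score substitutions and bounds", {
  expect_equal(similarity_score(0, V = 3, l = 10, agg = "max"), 1)
  expect_equal(similarity_score(0, V = 3, l = 10, agg = "max",
                                mode = "paper_literal"), 1)
  expect_equal(similarity_score(180 * 5 * 20, V = 5, l = 20, agg = "sum"), 0)
  expect_equal(similarity_score(180 * 5 * 20, V = 5, l = 20, agg = "sum",
                                mode = "paper_literal"), 0)
  expect_equal(similarity_score(3, V = 3, l = 3, agg = "max"), 1 - 3 / 540)
  expect_equal(similarity_score(3, V = 3, l = 3, agg = "max",
                                mode = "paper_literal"), 1 - 3 / 1620)
  set.seed(2)
  for (k in 1:50) {
    V <- sample(1:12, 1); l <- sample(1:600, 1)
    agg <- sample(angle_aggregations(), 1)
    dtw <- stats::runif(1, 0, 180 * V * l)
    for (mode in c("bounded", "paper_literal")) {
      s <- similarity_score(dtw, V, l, agg, mode)
      expect_gte(s, 0); expect_lte(s, 1)
    }
  }
  expect_error(similarity_score(1, V = 0, l = 3, agg = "max"), "V")
  expect_error(similarity_score(-1, V = 1, l = 3, agg = "max"), "dtw_value")
})

test_that("build_cost_matrix cells equal independent per-pair recomputation", {
  std <- generate_action("punch", noise_mm = 0, frames = 2)
  test <- generate_action("punch", noise_mm = 15, frames = 3, seed = 21)
  vset <- vector_set_for("local_pelvis", "punch")
  for (agg in angle_aggregations()) {
    cm <- build_cost_matrix(std, test, vset, agg)
    expect_equal(dim(cm), c(2L, 3L))
    for (i in 1:2) for (j in 1:3) {
      ref <- aggregate_angles(
        frame_angle_set(skeleton_frame(std, i), skeleton_frame(test, j), vset),
        agg)
      expect_equal(cm[i, j], ref, tolerance = 1e-9)
    }
  }
  # identical sequences: zero diagonal
  cm <- build_cost_matrix(std, std, vset, "max")
  expect_equal(diag(cm), rep(0, 2), tolerance = 1e-9)
})

test_that("added joint noise does not decrease the DTW cost on average", {
  std <- generate_action("one_armed_call_for_help", noise_mm = 0, frames = 30)
  vset <- vector_set_for("local_pelvis", "one_armed_call_for_help")
  base <- dtw_accumulate(build_cost_matrix(std, std, vset, "max"))$dtw_value
  deltas <- vapply(1:8, function(seed) {
    noisy <- generate_action("one_armed_call_for_help", noise_mm = 15,
                             frames = 30, seed = seed)
    dtw_accumulate(build_cost_matrix(std, noisy, vset, "max"))$dtw_value - base
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
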