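published_sets <- list(
  overall_adjacent = list(all = c("AB", "BC", "DE", "EF", "GI", "IK", "HJ", "JL")),
  overall_pelvis = list(all = c("OA", "OB", "OC", "OD", "OE", "OF",
                                "OG", "OH", "OI", "OJ", "OK", "OL")),
  local_adjacent = list(
    punch = c("AB", "BC"), one_armed_call_for_help = c("AB", "BC"),
    arms_for_help = c("AB", "BC", "DE", "EF"),
    trip_forward = c("PA", "QD", "OG", "OH"),
    trip_backwards = c("PA", "QD", "OG", "OH")),
  local_pelvis = list(
    punch = c("OA", "OB", "OC"), one_armed_call_for_help = c("OA", "OB", "OC"),
    arms_for_help = c("OA", "OB", "OC", "OD", "OE", "OF"),
    trip_forward = c("OA", "OP", "OQ", "OD", "OG", "OH"),
    trip_backwards = c("OA", "OP", "OQ", "OD", "OG", "OH"))
)

test_that("vector_set_for reproduces every published (scheme, action) row", {
  for (scheme in c("overall_adjacent", "overall_pelvis")) {
    for (action in all_actions()) {
      vs <- vector_set_for(scheme, action)
      expect_identical(vs$codes, published_sets[[scheme]]$all)
      expect_equal(vs$V, length(published_sets[[scheme]]$all))
    }
  }
  for (scheme in c("local_adjacent", "local_pelvis")) {
    for (action in unsafe_actions()) {
      vs <- vector_set_for(scheme, action)
      expect_identical(vs$codes, published_sets[[scheme]][[action]])
      expect_equal(vs$V, length(published_sets[[scheme]][[action]]))
      expect_true(all(vs$start != vs$end))
      expect_equal(anyDuplicated(vs$codes), 0L)
      if (scheme == "local_pelvis") {
        expect_true(all(vs$start == "PELVIS"))
      }
    }
    for (action in safe_actions()) {
      expect_error(vector_set_for(scheme, action), "no local vector set")
    }
  }
  expect_error(vector_set_for("diagonal_method", "punch"))
})

test_that("bone_vectors subtracts joint positions and is translation-invariant", {
  s <- toy_sequence(3)
  fr <- skeleton_frame(s, 1)
  vset <- vector_set_for("local_pelvis", "punch")
  bv <- bone_vectors(fr, vset)
  expect_equal(dim(bv), c(3L, 3L))
  expect_equal(bv["OA", ],
               fr$positions["SHOULDER_RIGHT", ] - fr$positions["PELVIS", ],
               ignore_attr = TRUE)
  shifted <- fr
  shifted$positions <- sweep(fr$positions, 2, c(50, 50, 50), `+`)
  expect_equal(bone_vectors(shifted, vset), bv)
  # missing joint is named in the error
  fr$valid["ELBOW_RIGHT"] <- FALSE
  expect_error(bone_vectors(fr, vset), "ELBOW_RIGHT")
})

test_that("angle_between matches closed forms and its invariances", {
  expect_equal(angle_between(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle_between(c(1, 0, 0), c(1, 1, 0)), 45)
  set.seed(11)
  for (k in 1:25) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    a <- angle_between(u, v)
    expect_gte(a, 0); expect_lte(a, 180)
    expect_equal(angle_between(v, u), a)                     # symmetry
    expect_equal(angle_between(3.7 * u, 0.2 * v), a,         # scale invariance
                 tolerance = 1e-9)
  }
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0), degenerate = "strict"),
               "degenerate")
  expect_warning(z <- angle_between(c(0, 0, 0), c(1, 0, 0)), "zero-length")
  expect_equal(z, 0)
})

test_that("frame_angle_set: identity, scale invariance, rotation sensitivity", {
  s <- generate_action("punch", noise_mm = 0, frames = 6)
  vset <- vector_set_for("local_pelvis", "punch")
  f1 <- skeleton_frame(s, 2)
  expect_equal(frame_angle_set(f1, f1, vset), rep(0, 3), tolerance = 1e-7)
  # uniform scaling about any fixed point leaves all angles unchanged
  f2 <- f1
  f2$positions <- 2 * (f1$positions - 100) + 100
  expect_equal(frame_angle_set(f1, f2, vset), rep(0, 3), tolerance = 1e-7)
  # a 90-degree rotation about the vertical axis turns every
  # horizontal-plane vector by exactly 90 degrees
  fr <- f1
  fr$positions[] <- 0
  fr$positions["PELVIS", ] <- c(0, 0, 0)
  fr$positions["SHOULDER_RIGHT", ] <- c(100, 0, 0)
  fr$positions["ELBOW_RIGHT", ] <- c(0, 0, 200)
  fr$positions["WRIST_RIGHT", ] <- c(70, 0, 70)
  rot <- fr
  rot$positions <- rotate_y_90(fr$positions)
  expect_equal(frame_angle_set(fr, rot, vset), rep(90, 3), tolerance = 1e-7)
})

test_that("aggregate_angles arithmetic and ordering properties", {
  expect_equal(aggregate_angles(c(10, 20, 30), "sum"), 60)
  expect_equal(aggregate_angles(c(10, 20, 30), "mean"), 20)
  expect_equal(aggregate_angles(c(10, 20, 30), "max"), 30)
  for (theta in c(0, 37.5, 180)) {
    for (agg in angle_aggregations()) {
      expect_equal(aggregate_angles(theta, agg), theta)  # singleton collapse
    }
  }
  set.seed(5)
  for (k in 1:20) {
    n <- sample(1:12, 1)
    a <- stats::runif(n, 0, 180)
    expect_gte(aggregate_angles(a, "max"), aggregate_angles(a, "mean"))
    expect_equal(aggregate_angles(a, "sum"),
                 n * aggregate_angles(a, "mean"), tolerance = 1e-9)
    expect_lte(aggregate_angles(a, "sum"), 180 * n)
    expect_gte(aggregate_angles(a, "sum"), aggregate_angles(a, "max"))
  }
  expect_error(aggregate_angles(numeric(0), "max"), "empty")
})
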