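# FK oracle for the first three joints: product of DH rows 1-3
shoulder_fk <- function(q123, geom) {
  dh <- arm_dh_table(geom$l_u, geom$l_f)
  A1 <- dh_transform(dh[1, ], q123[1])
  A2 <- dh_transform(dh[2, ], q123[2])
  A3 <- dh_transform(dh[3, ], q123[3])
  A1$R %*% A2$R %*% A3$R
}

wrist_fk <- function(q567, geom) {
  dh <- arm_dh_table(geom$l_u, geom$l_f)
  A5 <- dh_transform(dh[5, ], q567[1])
  A6 <- dh_transform(dh[6, ], q567[2])
  A7 <- dh_transform(dh[7, ], q567[3])
  A5$R %*% A6$R %*% A7$R
}

test_that("both shoulder branches reproduce the source rotation", {
  geom <- test_geom()
  R <- shoulder_fk(c(0.3, -0.4, 0.2), geom)
  cands <- shoulder_joint_candidates(R)
  expect_equal(cands[[1]]$q, c(0.3, -0.4, 0.2), tolerance = 1e-9)
  set.seed(51)
  for (i in 1:300) {
    q <- runif(3, -1.4, 1.4)
    R <- shoulder_fk(q, geom)
    for (cand in shoulder_joint_candidates(R))
      expect_lt(max(abs(shoulder_fk(cand$q, geom) - R)), 1e-9)
  }
  # identity-like reference
  cands <- shoulder_joint_candidates(shoulder_fk(c(0, 0, 0), geom))
  expect_equal(cands[[1]]$q, c(0, 0, 0), tolerance = 1e-12)
})

test_that("elbow flexion follows from the wrist-shoulder distance", {
  geom <- test_geom()
  l_u <- geom$l_u; l_f <- geom$l_f
  S <- c(0, 0, 0)
  expect_equal(
    elbow_flexion_from_distance(S, c(sqrt(l_u^2 + l_f^2), 0, 0), l_u, l_f), 0)
  expect_equal(
    elbow_flexion_from_distance(S, c(l_u + l_f, 0, 0), l_u, l_f), -pi / 2)
  expect_equal(
    elbow_flexion_from_distance(S, c(l_u - l_f, 0, 0), l_u, l_f), pi / 2)
  expect_error(
    elbow_flexion_from_distance(S, c(l_u + l_f + 0.01, 0, 0), l_u, l_f),
    "inconsistent")
  # roundtrip against the forward kinematics
  set.seed(52)
  for (i in 1:100) {
    q <- random_q(1)[1, ]
    pts <- joint_points(q, geom)
    expect_equal(elbow_flexion_from_distance(pts$S, pts$W, l_u, l_f), q[4],
                 tolerance = 1e-9)
  }
})

test_that("both wrist branches reproduce the source rotation and the
           half-turn branch leaves the anatomical range", {
  geom <- test_geom()
  R <- wrist_fk(c(0.2, 0.1, -0.3), geom)
  cands <- wrist_joint_candidates(R)
  expect_equal(cands[[1]]$q, c(0.2, 0.1, -0.3), tolerance = 1e-9)
  set.seed(53)
  n_outside <- 0L
  for (i in 1:300) {
    q <- runif(3, -1.4, 1.4)
    R <- wrist_fk(q, geom)
    cands <- wrist_joint_candidates(R)
    for (cand in cands)
      expect_lt(max(abs(wrist_fk(cand$q, geom) - R)), 1e-9)
    if (any(abs(cands[[2]]$q) > pi / 2 + 1e-9)) n_outside <- n_outside + 1L
  }
  expect_equal(n_outside, 300L)
})

test_that("exactly one branch combination is anatomical and it is exact", {
  geom <- test_geom()
  set.seed(54)
  for (i in 1:300) {
    q <- runif(7, -pi / 2 + 0.05, pi / 2 - 0.05)
    fk <- forward_kinematics(q, geom)
    q0 <- initial_pose(attr(fk, "base"), fk[[3]], fk[[7]], geom)
    expect_lt(max(abs(q0 - q)), 1e-6)
  }
})

test_that("initial pose from a recording matches the simulated truth", {
  geom <- test_geom()
  traj <- generate_joint_trajectory(1, 0.01, seed = 7)
  rec <- simulate_recording(traj, geom)
  q0 <- initial_pose_from_recording(rec, geom)
  expect_lt(max(abs(q0 - traj$q[1, ])), 1e-6)
})

test_that("gimbal configurations are flagged, with the free angle zeroed", {
  geom <- test_geom()
  R <- shoulder_fk(c(0.4, pi / 2, -0.3), geom)
  cands <- shoulder_joint_candidates(R)
  expect_true(cands[[1]]$degenerate)
  expect_equal(cands[[1]]$q[1], 0)
  expect_equal(abs(cands[[1]]$q[2]), pi / 2, tolerance = 1e-9)
})

test_that("an impossible candidate set reports all four branches", {
  sc <- list(list(q = c(2, 2, 2), branch = "i", degenerate = FALSE),
             list(q = c(-2, 2, -2), branch = "ii", degenerate = FALSE))
  wc <- list(list(q = c(2, 0, 2), branch = "iii", degenerate = FALSE),
             list(q = c(-2, 0, 2), branch = "iv", degenerate = FALSE))
  expect_error(select_anatomical(sc, 0.2, wc), "no anatomical solution")
})
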