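test_that("geometric Jacobian matches finite differences of the hand pose", {
  geom <- test_geom()
  set.seed(31)
  qs <- random_q(25)
  for (k in seq_len(nrow(qs))) {
    J <- geometric_jacobian(qs[k, ], geom)
    expect_lt(max(abs(J - fd_hand_jacobian(qs[k, ], geom))), 1e-6)
  }
  # full rank away from singularities
  expect_equal(sum(svd(geometric_jacobian(
    c(0.3, -0.2, 0.4, 0.5, -0.3, 0.2, 0.1), geom))$d > 1e-6), 6L)
})

test_that("wrist-centred columns have no linear part", {
  geom <- test_geom()
  # joints 5-7 rotate about axes through the wrist point itself
  J <- geometric_jacobian(c(0.3, -0.2, 0.4, 0.5, -0.3, 0.2, 0.1), geom)
  expect_lt(max(abs(J[1:3, 5:7])), 1e-12)
})

test_that("swivel angle satisfies its defining properties", {
  geom <- test_geom()
  ref <- swivel_reference_axis(geom)
  S <- c(0, 0, 0); W <- c(0.1, -0.35, 0.2)
  n <- (W - S) / sqrt(sum((W - S)^2))
  r <- ref - sum(ref * n) * n
  E0 <- S + 0.5 * (W - S) + 0.2 * r / sqrt(sum(r^2))  # in the reference plane
  expect_equal(swivel_angle(S, E0, W, ref), 0, tolerance = 1e-12)
  set.seed(32)
  for (delta in runif(10, -2.5, 2.5)) {
    E1 <- S + as.numeric(axis_angle_rotation(n, delta) %*% (E0 - S))
    expect_equal(swivel_angle(S, E1, W, ref), wrap_angle(delta),
                 tolerance = 1e-10)
  }
  expect_error(swivel_angle(S, E0, S, ref), "coincide")
  expect_error(swivel_angle(S, S + 0.4 * n, W, ref), "collinear")
  expect_error(swivel_angle(S, E0, S + 0.4 * ref, ref), "parallel")
})

test_that("swivel Jacobian has zero distal entries and predicts the rate", {
  geom <- test_geom()
  set.seed(33)
  qs <- random_q(20, lim = 1.0)
  for (k in seq_len(nrow(qs))) {
    J <- swivel_jacobian(qs[k, ], geom)
    expect_equal(dim(J), c(1L, 7L))
    expect_equal(as.numeric(J[5:7]), c(0, 0, 0))
  }
  # alpha-dot predicted by J_alpha q-dot matches the discrete slope of the
  # swivel angle along a slow synthetic joint path (independent oracle)
  ref <- swivel_reference_axis(geom)
  q0 <- c(0.3, -0.2, 0.4, 0.3, 0, 0, 0)
  qd <- c(0.2, -0.1, 0.15, 0.25, 0, 0, 0)
  dt <- 1e-3
  al <- vapply(0:2, function(k) {
    pts <- joint_points(q0 + k * dt * qd, geom)
    swivel_angle(pts$S, pts$E, pts$W, ref)
  }, numeric(1))
  discrete <- wrap_angle(al[3] - al[1]) / (2 * dt)
  predicted <- as.numeric(swivel_jacobian(q0 + dt * qd, geom, ref) %*% qd)
  expect_lt(abs(discrete - predicted), 1e-3)
})

test_that("augmented Jacobian stacks the geometric and swivel rows", {
  geom <- test_geom()
  q <- c(0.3, -0.2, 0.4, 0.5, -0.3, 0.2, 0.1)
  JA <- augmented_jacobian(q, geom)
  expect_equal(dim(JA), c(7L, 7L))
  expect_equal(JA[1:6, ], geometric_jacobian(q, geom))
  expect_gt(abs(det(JA)), 1e-12)
})

test_that("damped pseudoinverse obeys its closed forms and bounds", {
  expect_equal(damped_pseudoinverse(diag(7), 0.5), diag(7) / 1.5,
               tolerance = 1e-12)
  set.seed(34)
  J <- matrix(rnorm(49), 7, 7) + 3 * diag(7)
  expect_lt(max(abs(damped_pseudoinverse(J, 0) - solve(J))), 1e-10)
  # convergence to the exact inverse as damping vanishes
  expect_lt(max(abs(damped_pseudoinverse(J, 1e-12) - solve(J))), 1e-8)
  # singular matrix: finite, and gain bounded by 1/(2 sqrt(k2))
  Js <- J; Js[, 7] <- Js[, 6]
  Jstar <- damped_pseudoinverse(Js, 0.5)
  expect_true(all(is.finite(Jstar)))
  expect_lt(max(svd(Jstar)$d), 1 / (2 * sqrt(0.5)) + 1e-12)
  expect_error(damped_pseudoinverse(Js %*% t(Js) * 0, 0))
})

test_that("task-space error composes position, axis-angle and swivel parts", {
  a <- rigid_transform(rot_z(0.3), c(0.1, 0.2, 0.3))
  expect_equal(pose_error(a, a, 0.4, 0.4), rep(0, 7))
  b <- rigid_transform(rot_z(0.3), c(0.11, 0.2, 0.3))
  expect_equal(pose_error(a, b, 0, 0), c(0.01, 0, 0, 0, 0, 0, 0))
  delta <- 1e-3
  d <- rigid_transform(rot_z(0.3 + delta), c(0.1, 0.2, 0.3))
  expect_equal(pose_error(a, d, 0, 0)[4:6], c(0, 0, delta),
               tolerance = delta^3)
  # swivel error wraps across the branch cut
  expect_equal(pose_error(a, a, -3, 3)[7], wrap_angle(6), tolerance = 1e-12)
})

test_that("closed-loop step is a fixed point at the target and contracts", {
  geom <- test_geom()
  cfg <- ik_config(k2 = 1e-8)
  ref <- swivel_reference_axis(geom)
  q <- c(0.3, -0.2, 0.4, 0.5, -0.3, 0.2, 0.1)
  fk <- forward_kinematics(q, geom)
  pts <- joint_points(q, geom)
  al <- swivel_angle(pts$S, pts$E, pts$W, ref)
  q1 <- ik_step(q, fk[[7]], al, numeric(6), 0, cfg, geom)
  expect_equal(as.numeric(q1), q, tolerance = 1e-9)

  target <- rigid_transform(fk[[7]]$R, fk[[7]]$p + c(0.005, 0, 0))
  e0 <- sqrt(sum(pose_error(fk[[7]], target, al, al)^2))
  q2 <- as.numeric(ik_step(q, target, al, numeric(6), 0, cfg, geom))
  fk2 <- forward_kinematics(q2, geom)
  pts2 <- joint_points(q2, geom)
  al2 <- swivel_angle(pts2$S, pts2$E, pts2$W, ref)
  e1 <- sqrt(sum(pose_error(fk2[[7]], target, al2, al)^2))
  expect_lt(e1, e0)

  expect_error(ik_step(q * NA, target, al, numeric(6), 0, cfg, geom),
               "non-finite")
})

test_that("a static recording yields a static joint estimate", {
  geom <- test_geom()
  traj <- generate_joint_trajectory(1, 0.01, seed = 1, amplitude_scale = 0)
  rec <- simulate_recording(traj, geom)
  recon <- reconstruct_trajectory(rec, geom)
  expect_lt(max(abs(sweep(recon$q, 2, recon$q[1, ]))), 1e-9)
})

test_that("noiseless tracking recovers the joints to a fraction of a degree", {
  geom <- test_geom()
  traj <- generate_joint_trajectory(10, 0.01, seed = 5)
  rec <- simulate_recording(traj, geom)
  recon <- reconstruct_trajectory(rec, geom)
  err <- abs(wrap_angle(recon$q - traj$q)) * 180 / pi
  expect_lt(max(err), 0.5)
  # steady-state task error on the static tail of the loop stays tiny
  expect_lt(stats::median(recon$diagnostics$err_norm, na.rm = TRUE), 1e-3)
})
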