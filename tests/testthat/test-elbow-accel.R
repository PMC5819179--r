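test_that("gravity rotation satisfies the measurement contract", {
  g0 <- c(0, 1, 0)
  # reference reading: identity
  expect_equal(gravity_rotation(c(0, 1, 0))$R, diag(3))
  # quarter turn: axis (0,1,0) x (1,0,0) = (0,0,-1), angle pi/2
  rot <- gravity_rotation(c(1, 0, 0))
  expect_equal(rot$theta, pi / 2, tolerance = 1e-12)
  expect_equal(rot$V, c(0, 0, -1), tolerance = 1e-12)
  expect_lt(max(abs(rot$R %*% c(1, 0, 0) - g0)), 1e-12)
  # antiparallel branch
  rot <- gravity_rotation(c(0, -1, 0))
  expect_lt(max(abs(rot$R %*% c(0, -1, 0) - g0)), 1e-12)
  expect_true(is_rotation(rot$R, 1e-12))
  # property: contract residual over random unit vectors
  set.seed(41)
  for (i in 1:500) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    rot <- gravity_rotation(v)
    expect_lt(max(abs(rot$R %*% v - g0)), 1e-12)
    expect_true(is_rotation(rot$R, 1e-10))
  }
  # quasi-static band
  expect_error(gravity_rotation(c(0, 0.5, 0)), "quasi-static")
})

test_that("gamma roots satisfy the plane constraint", {
  geom <- test_geom()
  set.seed(42)
  qs <- random_q(300)
  for (k in seq_len(nrow(qs))) {
    q <- qs[k, ]
    pts <- joint_points(q, geom)
    rot <- gravity_rotation(true_accel(q, geom))
    gam <- solve_gamma(rot, pts$S, pts$W, geom)
    cands <- elbow_candidates(gam, rot, pts$S, geom)
    sw <- pts$W - pts$S
    for (i in 1:2) {
      # sensor XY plane through S contains W: Z axis orthogonal to W - S
      expect_lt(abs(sum(cands$poses[[i]]$R[, 3] * sw)),
                1e-9 * sqrt(sum(sw^2)))
      expect_equal(sqrt(sum((cands$elbows[i, ] - pts$S)^2)), geom$l_u,
                   tolerance = 1e-12)
    }
  }
})

test_that("pre-satisfied constraint admits gamma = 0 and the c = 0 case is a
           half-turn pair with antiparallel normals", {
  geom <- test_geom()
  q <- c(0.3, -0.2, 0.4, 0.5, 0, 0, 0)
  pts <- joint_points(q, geom)
  rot <- gravity_rotation(true_accel(q, geom))
  # manufacture a wrist for which rot's own XY plane already contains W - S:
  # move W along a direction orthogonal to rot's Z axis
  dirs <- geom$mount_ref_rotation %*% rot$R[, c(1, 2)]
  W0 <- pts$S + 0.4 * as.numeric(dirs[, 1] + 0.3 * dirs[, 2]) /
    sqrt(sum((dirs[, 1] + 0.3 * dirs[, 2])^2))
  gam <- solve_gamma(rot, pts$S, W0, geom)
  expect_lt(min(abs(wrap_angle(gam))), 1e-9)

  # c = 0 arises when the sensor Z axis is orthogonal to gravity (zero
  # z-component reading): the homogeneous harmonic equation gives roots a
  # half-turn apart and -- only in this case -- antiparallel candidate
  # normals
  rot0 <- gravity_rotation(c(0.6, 0.8, 0))
  Wc <- pts$S + c(0.12, -0.3, 0.2)
  gam <- solve_gamma(rot0, pts$S, Wc, geom)
  expect_equal(abs(wrap_angle(gam[1] - gam[2])), pi, tolerance = 1e-9)
  cands <- elbow_candidates(gam, rot0, pts$S, geom)
  expect_lt(max(abs(cands$poses[[1]]$R[, 3] + cands$poses[[2]]$R[, 3])), 1e-9)
})

test_that("candidate selection recovers the true elbow on random postures", {
  geom <- test_geom()
  set.seed(43)
  qs <- random_q(300)
  for (k in seq_len(nrow(qs))) {
    q <- qs[k, ]
    pts <- joint_points(q, geom)
    est <- estimate_elbow(true_accel(q, geom), pts$S, pts$W, geom)
    expect_lt(sqrt(sum((est$pose$p - pts$E)^2)), 1e-9)
  }
})

test_that("the spurious candidate fails the orientation or length check", {
  geom <- test_geom()
  set.seed(44)
  qs <- random_q(100, lim = 1.0)
  for (k in seq_len(nrow(qs))) {
    q <- qs[k, ]
    pts <- joint_points(q, geom)
    rot <- gravity_rotation(true_accel(q, geom))
    gam <- solve_gamma(rot, pts$S, pts$W, geom)
    cands <- elbow_candidates(gam, rot, pts$S, geom)
    sel <- select_elbow(cands, pts$S, pts$W, geom)
    other <- 3L - sel
    d_other <- sum(cands$poses[[other]]$R[, 3] *
                     cross3(pts$W - cands$elbows[other, ],
                            pts$S - cands$elbows[other, ]))
    lf_dev <- abs(sqrt(sum((pts$W - cands$elbows[other, ])^2)) - geom$l_f)
    expect_true(d_other < 0 || lf_dev > 1e-6)
    expect_lt(sqrt(sum((cands$elbows[sel, ] - pts$E)^2)), 1e-9)
  }
})

test_that("collinear arm raises the degenerate selection error", {
  geom <- test_geom()
  q <- c(0.3, -0.2, 0.4, -pi / 2, 0, 0, 0)  # full extension
  pts <- joint_points(q, geom)
  rot <- gravity_rotation(true_accel(q, geom))
  gam <- solve_gamma(rot, pts$S, pts$W, geom)
  cands <- elbow_candidates(gam, rot, pts$S, geom)
  expect_error(select_elbow(cands, pts$S, pts$W, geom), "collinear")
  # with a previous estimate, the wrapper falls back instead of failing
  prev <- estimate_elbow(true_accel(q + c(0, 0, 0, 0.4, 0, 0, 0), geom),
                         pts$S,
                         joint_points(q + c(0, 0, 0, 0.4, 0, 0, 0), geom)$W,
                         geom)
  est <- estimate_elbow(true_accel(q, geom), pts$S, pts$W, geom, prev = prev)
  expect_true(est$index %in% c(1L, 2L))
})

test_that("elbow pose composes the mounting rotations", {
  geom <- test_geom()
  # reference posture: acc0_R_acc = I, so rR_e = rR_acc0 . acc0R_e
  q <- rep(0, 7)
  pts <- joint_points(q, geom)
  est <- estimate_elbow(true_accel(q, geom), pts$S, pts$W, geom)
  expect_lt(max(abs(est$pose$R -
                      geom$mount_ref_rotation %*% geom$elbow_in_accel_ref)),
            1e-9)
  # random postures: orientation equals the FK elbow frame, det +1
  set.seed(45)
  for (k in 1:100) {
    q <- random_q(1)[1, ]
    pts <- joint_points(q, geom)
    est <- estimate_elbow(true_accel(q, geom), pts$S, pts$W, geom)
    expect_lt(abs(det(est$pose$R) - 1), 1e-10)
    R3 <- forward_kinematics(q, geom)[[3]]$R
    expect_lt(max(abs(est$pose$R - R3)), 1e-9)
  }
})

test_that("quasi-static gating holds the previous orientation", {
  geom <- test_geom()
  q <- c(0.3, -0.2, 0.4, 0.5, 0, 0, 0)
  pts <- joint_points(q, geom)
  good <- estimate_elbow(true_accel(q, geom), pts$S, pts$W, geom)
  shaken <- true_accel(q, geom) * 1.5  # dynamic acceleration burst
  est <- estimate_elbow(shaken, pts$S, pts$W, geom, prev = good)
  expect_true(est$gated)
  expect_lt(sqrt(sum((est$pose$p - pts$E)^2)), 1e-9)
  expect_error(estimate_elbow(shaken, pts$S, pts$W, geom), "gate")
})
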