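# shared fixtures: default geometry and random-configuration draws

test_geom <- function() arm_geometry(0.31, 0.25)

# n random joint configurations, uniform in [-lim, lim]^7
random_q <- function(n, lim = 1.3) {
  matrix(stats::runif(7 * n, -lim, lim), n, 7L)
}

random_rotation <- function() {
  v <- stats::rnorm(3)
  axis_angle_rotation(v, stats::runif(1, 0, pi))
}

# independent finite-difference Jacobian of the hand pose
fd_hand_jacobian <- function(q, geom, h = 1e-6) {
  J <- matrix(0, 6L, 7L)
  for (i in 1:7) {
    qp <- q; qp[i] <- q[i] + h
    qm <- q; qm[i] <- q[i] - h
    fp <- forward_kinematics(qp, geom)[[7]]
    fm <- forward_kinematics(qm, geom)[[7]]
    J[1:3, i] <- (fp$p - fm$p) / (2 * h)
    J[4:6, i] <- rotation_log(fp$R %*% t(fm$R)) / (2 * h)
  }
  J
}

# noiseless accelerometer reading implied by a configuration
true_accel <- function(q, geom) {
  as.numeric(t(accel_orientation(q, geom)) %*% reference_gravity(geom))
}
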