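# arm7ik — upper-limb joint reconstruction from an end-effector robot and one accelerometer

End-effector rehabilitation robots attach to the patient only at the hand:
they log the hand pose precisely but are blind to the seven joint angles of
the arm behind it, and it is the per-joint range of motion (ROM) that
therapists combine with clinical scales to assess recovery. `arm7ik`
reconstructs those joint angles — shoulder abduction-adduction (q1),
flexion-extension (q2), internal-external rotation (q3), elbow
flexion-extension (q4), pronation-supination (q5), ulnar-radial deviation
(q6) and wrist flexion-extension (q7) — from the robot end-effector pose,
the shoulder position, and a single accelerometer strapped to the upper
arm. It is written for biomechanics and rehabilitation-engineering groups
that run end-effector therapy and want joint-level kinematics without an
optoelectronic lab.

## Method in brief

The arm is a 7-DoF Denavit-Hartenberg chain with links `l_u` (upper arm)
and `l_f` (forearm). Redundancy with respect to the 6-DoF hand pose is
resolved through the swivel angle α (rotation of the elbow about the
shoulder-wrist axis against a fixed reference plane). Joint velocities
come from closed-loop inverse kinematics on the augmented Jacobian with a
damped least-squares inverse,

    q̇ = J_A† { [v̇_d; α̇_d] + K·err },    J_A† = J_Aᵀ (J_A J_Aᵀ + k² I)⁻¹,
    q(t_k) = q(t_{k-1}) + q̇ Δt,

where `J_A` stacks the 6×7 geometric Jacobian with the 1×7 swivel-angle
row. The target swivel angle comes from the elbow location, estimated each
sample from the accelerometer: under the quasi-static assumption the
sensor reads the gravity direction, which pins its orientation up to a
rotation γ about the gravity axis; requiring the sensor XY plane to
contain the shoulder-wrist segment reduces γ to two roots, and the
anatomically consistent candidate is selected by the elbow flexion-axis
orientation plus forearm-length consistency. A closed-form solver supplies
the initial configuration from the first sample (two shoulder branches,
unique elbow angle via `q4 = arcsin[(l_u² + l_f² − ‖W−S‖²)/(2 l_u l_f)]`,
two wrist branches; exactly one combination is anatomical).

Because no public recordings of this sensor setup exist, the package
includes a first-class synthetic-motion module (`generate_joint_trajectory`,
`simulate_recording`, `inject_shoulder_steps`) that emulates quasi-static
reaching therapy and the three sensor streams, so the whole pipeline is
validated by parameter recovery. The methods vignette
(`vignettes/arm-kinematic-reconstruction.Rmd`) documents the model,
parameter choices, and known limitations.

## Worked example

Simulate a 20 s therapy-scale session at 100 Hz with realistic sensor
noise (0.01 g accelerometer noise, 1 cm recorded trunk drift), then
reconstruct it and score against the simulated ground truth:

```r
library(arm7ik)
geom <- arm_geometry(0.31, 0.25)   # upper-arm and forearm lengths, m
traj <- generate_joint_trajectory(duration_s = 20, dt_s = 0.01, seed = 42)
rec  <- simulate_recording(traj, geom,
                           noise_spec(accel_sigma = 0.01,
                                      shoulder_drift_amplitude = 0.01,
                                      seed = 43))

q0 <- initial_pose_from_recording(rec, geom)
round(as.numeric(q0) * 180 / pi, 2)
#> [1] 13.00  7.58  9.47 15.11 -0.73  4.19 -9.34

recon <- reconstruct_trajectory(rec, geom, q0 = q0)
m <- joint_metrics(recon, rec, geom)
print(m$joints, digits = 3)
#>   joint rmse_deg sd_deg     r
#> 1    q1    0.451  0.446 0.989
#> 2    q2    0.257  0.175 0.998
#> 3    q3    0.514  0.511 0.994
#> 4    q4    0.558  0.557 0.997
#> 5    q5    0.444  0.443 0.988
#> 6    q6    0.607  0.607 0.957
#> 7    q7    0.638  0.601 0.914
round(m$elbow_rmse_cm, 2)
#> [1] 0.4
```

The initial pose lands on the true starting configuration (the closed form
is exact to rounding); under this noise model every joint tracks within a
degree RMSE with correlations above 0.9, and the accelerometer-based elbow
localization stays within half a centimeter. `m$rom_deg` compares per-joint
ROM — the clinically reported quantity — between the estimate and the
truth. Diagnostics (task error norm, Jacobian condition number, gating and
branch flags) ride along in `recon$diagnostics`.

A thin command-line wrapper covers the same pipeline for file-based
sessions (CSV streams + JSON geometry):

```sh
inst/cli/arm7ik simulate --duration 60 --seed 1 --out-prefix session
inst/cli/arm7ik reconstruct --geometry geom.json --poses session_poses.csv \
    --accel session_accel.csv --shoulder session_shoulder.csv \
    --joints session_joints.csv --out-dir out
```

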