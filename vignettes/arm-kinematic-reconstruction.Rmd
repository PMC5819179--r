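---
title: "Reconstructing upper-limb joint kinematics from an end-effector robot and one accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing upper-limb joint kinematics from an end-effector robot and one accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arm7ik)
```

## The problem

End-effector rehabilitation robots hold the patient only at the hand. They
log the hand pose and interaction forces with high fidelity, but they know
nothing about the configuration of the arm behind the hand — and it is the
per-joint range of motion (ROM), not the hand path, that therapists combine
with clinical scales to assess recovery. `arm7ik` reconstructs the seven
joint angles of the human arm during such a therapy from three streams that
a clinical setup can actually provide:

* the robot end-effector (wrist/hand) pose,
* the shoulder position (measured once, or tracked during the session),
* one accelerometer strapped to the upper arm.

## Arm model

The arm is modelled as a 7-DoF serial chain with two links, the upper arm
`l_u` and the forearm `l_f`: a spherical shoulder (abduction-adduction
`q1`, flexion-extension `q2`, internal-external rotation `q3`), elbow
flexion-extension (`q4`), forearm pronation-supination (`q5`), and a 2-DoF
wrist (`q6` ulnar-radial deviation, `q7` flexion-extension). Frames follow
the classical (distal) Denavit-Hartenberg convention; `arm_dh_table()`
prints the parameters. Two consequences of this convention worth noting,
both verified by roundtrip tests rather than taken on trust:

* the shoulder-wrist distance satisfies
  `||W - S||^2 = l_u^2 + l_f^2 - 2 l_u l_f sin(q4)`, so the elbow angle is
  recovered by an *arcsine* (not the arccosine a textbook law-of-cosines
  would suggest), and full elbow extension sits at `q4 = -pi/2`;
* all joints are nominally confined to `[-pi/2, pi/2]`, which is what makes
  the closed-form initial pose unambiguous (below).

Joint limits are advisory during reconstruction (a warning, never a clamp):
patients may slightly exceed nominal ranges, and clamping would inject
discontinuities into the closed loop.

## Closed-loop inverse kinematics on the augmented Jacobian

A 7-DoF arm is redundant for a 6-DoF hand pose. The redundancy is
parameterized by the swivel angle: the rotation of the elbow about the
shoulder-wrist axis, measured against a reference plane. Stacking the 6x7
geometric Jacobian with the 1x7 swivel-angle gradient gives a square
augmented Jacobian `J_A`, and joint velocities follow from the damped
least-squares inverse with a feedback term that cancels integration drift:

```
qdot = J_A^T (J_A J_A^T + k2 I)^-1 { [vdot_d; alphadot_d] + K err }
q(t_k) = q(t_{k-1}) + qdot * dt
```

The target swivel angle comes from the accelerometer-based elbow estimate;
the feedforward twist from backward finite differences of consecutive
recorded hand poses (robot logs provide poses, not velocities). The error
vector stacks the position difference, the axis-angle vector of the
relative rotation, and the wrapped swivel difference — the wrapping to
`(-pi, pi]` matters, or a swivel crossing the branch cut would drag the arm
through a full turn.

### Numerical choices and parameters

* **Gain `K = 1.5`** on all seven error rows (heterogeneous units, meters
  and radians alike, as in the original clinical tuning). At 100 Hz this
  gives a drift-correction time constant of about 0.7 s.
* **Damping `k2`.** The default is `5e-7` (squared meters). The clinical
  tuning of this algorithm is usually quoted as `k2 = 0.5` — but against a
  Jacobian whose position rows are in *millimeters*. On the SI meter scale
  used here the augmented Jacobian's singular values are of order 0.1-2, so
  taking 0.5 literally would damp the whole task and bias quasi-static
  tracking by tens of degrees, which is incompatible with the few-degree
  accuracies this class of algorithm achieves. `0.5 mm^2 = 5e-7 m^2`
  preserves the original *relative* damping.
* **Variable damping near singularities.** A constant tiny damping leaves
  the loop exposed where the chain loses rank (e.g. wrist gimbal
  passages): noisy targets then demand infeasible velocities and can kick
  the state onto a mirrored solution branch. `ik_step()` therefore raises
  the damping smoothly (numerical filtering) once the smallest singular
  value of `J_A` falls below `sing_sigma = 0.1` — below the 0.15-0.22
  range measured across the nominal workspace — up to an extra
  `sing_k2 = 0.0025` at the singularity itself. Well-conditioned postures
  are untouched, which is what keeps noiseless recovery exact.
* **Swivel reference axis.** Any fixed axis is admissible as long as
  targets and Jacobian share it, but the reference plane degenerates when
  the shoulder-wrist axis aligns with the chosen axis. With the default
  mounting the reference posture hangs the upper arm *along gravity*, and
  simulated sessions bring the shoulder-wrist axis within 0.007 of the
  gravity direction — a gravity-aligned reference axis is the worst
  possible choice for this workspace. The default
  (`swivel_reference_axis()`) is therefore a fixed horizontal axis (robot
  X projected orthogonal to gravity), whose worst-case margin over the
  same sessions is 0.37. It is configurable via
  `ik_config(swivel_ref_axis = )`.
* **Joint-velocity saturation** (`qdot_max = 5` rad/s): the commanded
  velocity vector is rescaled (direction preserved) when any component
  exceeds the cap. True joint speeds in this regime stay below 0.5 rad/s,
  so the 10x cap never engages in normal operation; it exists to stop a
  single inconsistent sample — an unrecorded trunk shift, a sensor glitch
  — from throwing the integrated state across the workspace onto a
  mirrored solution branch. It also guarantees per-sample output
  continuity (`|dq| <= qdot_max * dt`).
* **Swivel Jacobian by central finite differences** (step `1e-6` rad,
  wrapped differences): there is no closed form in circulation for this
  parameterization, and the finite-difference row is verified against an
  independent discrete-rate oracle in the tests. Its distal entries
  (q5-q7) are exactly zero since the three arm points depend only on
  q1-q4.
* **Condition monitoring**: each step records the condition number of
  `J_A`; crossing `1e6` emits a warning, never an abort.

## Elbow localization from one accelerometer

Assuming slow (quasi-static) movement, the accelerometer reads the gravity
direction in its own frame; at the reference posture that reading is
`(0, 1, 0)` by construction of the mounting. A single sample constrains the
sensor orientation up to a rotation `gamma` about the gravity axis:
`gravity_rotation()` builds one consistent rotation via the cross-product
(Rodrigues) form — with explicit branches for the near-zero and
antiparallel singularities — and `solve_gamma()` imposes the physical
constraint that the sensor XY plane contain the shoulder-to-wrist segment.
That constraint is linear in `cos(gamma)`, `sin(gamma)` and yields two
candidate orientations, hence two candidate elbows at `l_u` along the
sensor Y axis from the shoulder.

One matrix-orientation subtlety: the printed Rodrigues construction maps
the reference reading onto the sample, while the measurement model needs
the inverse relation; the implementation uses the transpose and pins the
choice with a machine-precision contract test (`R %*% sample = (0,1,0)`).

**Candidate disambiguation.** The true candidate's Z axis (the elbow
flexion axis) points along `(W-E) x (S-E)`. A subtlety discovered during
validation: the two candidates' Z axes are *not* antiparallel in general —
they are the two intersections of the gravity cone with the plane
orthogonal to the shoulder-wrist axis, and are antiparallel only when the
sensor Z is orthogonal to gravity. For part of the workspace both
candidates therefore pass the orientation sign test. The selector
(`select_elbow()`) resolves this with forearm-length consistency — the
spurious candidate misplaces the elbow by decimeters relative to
`||W - E|| = l_f` — and keeps the sign test as the validity check. Near
full extension the flexion axis is unobservable (the cross product
vanishes); the selector raises an error and the session loop holds the
previously selected branch.

Samples whose norm leaves `[0.8, 1.2]` g fail the quasi-static gate and
hold the previous orientation, implementing the slow-movement assumption
rather than trusting a sample contaminated by dynamic acceleration.

**Grazing-intersection sensitivity.** A second weakness surfaced during
noisy validation: where the gravity cone *grazes* the constraint plane
(the discriminant of the `gamma` equation approaches zero) the candidate
elbows become square-root-sensitive to accelerometer noise, and a 0.01 g
error can displace both candidates by centimeters to decimeters for
seconds at a time, with the selection itself still correct. The session
loop therefore applies an elbow *continuity gate*
(`reconstruct_trajectory(elbow_speed_max = 1)`, m/s): the true elbow
moves below ~0.2 m/s in this regime while the grazing artifact jumps at
5-20 m/s between samples, so a 1 m/s threshold separates them cleanly.
The gate compares each raw estimate against the previous *raw* estimate,
so a genuine level shift (e.g. after an abrupt trunk movement) passes
after a single gated sample rather than latching stale.

## Closed-form initial pose

The integration needs a starting configuration. With the shoulder pose,
the accelerometer-estimated elbow pose and the robot wrist pose all known
at the first sample, the joint angles follow in closed form: two branches
for the shoulder triple from the shoulder-to-elbow rotation, the elbow
angle uniquely from the shoulder-wrist distance (the arcsine form above),
and two branches for the wrist triple from the residual rotation. Exactly
one of the four branch combinations lands inside the anatomical box
`[-pi/2, pi/2]^7` for interior configurations; boundary ties are broken by
the smallest total excursion. One printed-formula defect surfaced during
verification: the commonly quoted second shoulder branch repeats the
first branch's `q1`, which fails the FK roundtrip; the correct second
branch shifts `q1` and `q3` by a half-turn, and that is what
`shoulder_joint_candidates()` implements (roundtrip residual ~1e-16).
Gimbal configurations (`|q2|` or `|q6|` at `pi/2`) are flagged and the
underdetermined angle set to zero by convention.

## The synthetic-data generator

With no public recordings of this setup, validation is by parameter
recovery on synthetic sessions. `generate_joint_trajectory()` emulates
slow point-to-point reaching therapy: sums of 0.05-0.2 Hz sinusoids around
a working posture within ±0.35 rad of the reference, per-joint ROM targets
of 0.15-0.7 rad (about 9-40 degrees, the scale reported for end-effector
therapy sessions), hard confinement to `(-pi/2 + 0.1, pi/2 - 0.1)` and a
0.5 rad/s speed cap (the quasi-static regime). `simulate_recording()`
derives the three sensor streams through the forward kinematics; the
accelerometer model is purely gravitational, with dynamic acceleration
represented only by the noise term and the gating test.

Disturbances are deliberately split in two:

* **Recorded trunk drift** (`noise_spec(shoulder_drift_amplitude = )`):
  the arm base really moves, the poses follow, and the shoulder stream
  records it. This tests the algorithm's central robustness claim — that
  *measured* shoulder motion is compensated.
* **Unrecorded steps** (`inject_shoulder_steps()`): the shoulder stream is
  shifted while the poses are left untouched, emulating abrupt trunk
  compensation that the measurement misses. Here the inputs are mutually
  inconsistent and only stability (finite, continuous output) is expected,
  not accuracy.

What the simulator does *not* emulate: dynamic acceleration beyond white
noise, sensor bias and drift, mounting misalignment, soft-tissue artifact,
or scapular/clavicular motion. Passing the recovery suite therefore
demonstrates the correctness and stability of the reconstruction
machinery, not field accuracy on patients.

## Validation bands

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, at the study scale of 60 s sessions at
100 Hz:

1. noiseless end-to-end recovery: per-joint RMSE below 0.5 degrees and
   elbow/wrist position RMSE below 1e-3 cm (measured: ~0.03-0.07 degrees
   and ~1e-15 cm);
2. a realism band with 0.01 g accelerometer noise plus 1 cm recorded trunk
   drift over five seeded sessions: per-joint mean RMSE below 5 degrees
   and per-joint mean Pearson R above 0.9 (individual small-ROM joints can
   dip lower in a single session, as they do in optoelectronic validations
   of this algorithm class);
3. exactness and uniqueness of the closed-form initial pose on 1000 random
   interior configurations (max error ~1e-14 rad);
4. machine-precision contracts of the elbow estimator (gravity-rotation
   residual, gamma plane residual, 100% candidate selection on
   non-degenerate poses);
5. Jacobian oracles against independent finite differences and the exact
   damping limit `k2 -> 0`;
6. bounded, finite output under 5 cm unrecorded shoulder steps.

## Known limitations

* **Gimbal branch flips.** Near `|q2| = pi/2` the mirrored shoulder branch
  is task-identical; under heavy noise a closed loop that wanders across
  the gimbal can settle on it. The therapy-scale trajectories this tool
  targets stay well clear; excursions approaching the gimbal would need an
  explicit branch monitor.
* **Swivel reference degeneracy.** A fixed reference axis always has two
  degenerate shoulder-wrist directions. The default axis pushes them to
  the edge of the reachable workspace but cannot remove them.
* **Quasi-static sensor model.** Fast or jerky movement violates the
  gravity-only accelerometer assumption; the gate only rejects the worst
  samples.
* **Fixed segment lengths.** Errors in the manually measured `l_u`, `l_f`
  propagate directly into the elbow estimate and `q4`.
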