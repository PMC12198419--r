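test_that("skeleton stature equals height times scale factor", {
  expect_equal(skeleton_stature(fx_skeleton(1.80, 75, 1.0)), 1.80,
               tolerance = 1e-9)
  expect_equal(skeleton_stature(fx_skeleton(1.80, 75, 1.10)), 1.98,
               tolerance = 1e-9)
  expect_error(subject_meta("x", -1.7, 70), "positive")
  expect_error(subject_meta("x", 1.7, 0), "positive")
  expect_error(subject_meta("x", 1.7, 70, 1.2), "scale_factor")
})

test_that("default layout has the published marker and keypoint counts", {
  mt <- fx_skeleton()$markers
  expect_equal(sum(mt$type == "keypoint"), 20)
  expect_equal(sum(mt$type == "anatomical"), 43)
  expect_equal(sum(mt$in_body & mt$type == "keypoint"), 15)
  expect_equal(sum(mt$in_arm & mt$type == "keypoint"), 7)
  expect_equal(sum(mt$in_body & mt$type == "anatomical"), 35)
  expect_equal(sum(mt$in_arm & mt$type == "anatomical"), 8)
  for (sd in c("r", "l"))
    expect_equal(sum(mt$is_foot & mt$segment == paste0("foot_", sd)), 3)
  # single 6-DOF root
  co <- fx_skeleton()$coordinates
  expect_equal(sum(co$segment == "pelvis"), 6)
  expect_length(analysis_dofs(), 21)
})

test_that("uniform scaling is homogeneous and composes", {
  sk <- fx_skeleton()
  s1 <- scale_skeleton(sk, 1.0)
  expect_equal(s1, sk)
  s2 <- scale_skeleton(scale_skeleton(sk, 2), 2)
  s4 <- scale_skeleton(sk, 4)
  expect_equal(s2$markers, s4$markers)
  expect_equal(s2$segments, s4$segments)
  expect_error(scale_skeleton(sk, -1), "> 0")
  # zero-pose marker positions scale about the root
  q0 <- stats::setNames(rep(0, nrow(sk$coordinates)), sk$coordinates$name)
  p1 <- markerlift:::fk_markers(sk, markerlift:::fk_frame(sk, q0))
  s09 <- scale_skeleton(sk, 0.9)
  p09 <- markerlift:::fk_markers(s09, markerlift:::fk_frame(s09, q0))
  expect_max_abs(p09 - 0.9 * p1, 1e-9)
})

test_that("forward kinematics is rigid and equivariant", {
  sk <- fx_skeleton()
  traj <- generate_motion("freestyle", 1.5, 60, sk, seed = 3)
  seqn <- forward_kinematics(sk, traj)
  mt <- sk$markers
  for (sg in c("pelvis", "torso", "thigh_r", "foot_l")) {
    ms <- mt$name[mt$segment == sg]
    if (length(ms) < 2) next
    d0 <- dist(seqn$positions[1, ms, ])
    for (f in c(30, 89))
      expect_max_abs(dist(seqn$positions[f, ms, ]) - d0, 1e-9)
  }
  # pure root translation shifts every marker
  q <- traj$values[1:2, , drop = FALSE] * 0
  qt <- q; qt[, c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <-
    rep(c(0.5, 0, 0), each = 2)
  s0 <- forward_kinematics(sk, joint_trajectory(60, traj$coordinates, q))
  st <- forward_kinematics(sk, joint_trajectory(60, traj$coordinates, qt))
  expect_max_abs(st$positions[, , 1] - s0$positions[, , 1] - 0.5, 1e-12)
  expect_max_abs(st$positions[, , 2:3] - s0$positions[, , 2:3], 1e-12)
  # 90 degree yaw: pairwise distances unchanged (brute-force comparison)
  qy <- q; qy[, "pelvis_yaw"] <- pi / 2
  sy <- forward_kinematics(sk, joint_trajectory(60, traj$coordinates, qy))
  expect_max_abs(dist(sy$positions[1, , ]) - dist(s0$positions[1, , ]), 1e-9)
  # coordinate mismatch -> schema error
  bad <- joint_trajectory(60, traj$coordinates[-1], traj$values[, -1])
  expect_error(forward_kinematics(sk, bad), "match")
})

test_that("motion generation is deterministic, in-bounds and class-shaped", {
  sk <- fx_skeleton()
  expect_error(generate_motion("moonwalk", 2, 60, sk), "unknown")
  co <- sk$coordinates
  for (kind in c("gait", "squat", "sit_to_stand", "jump", "rolling",
                 "freestyle", "static")) {
    a <- generate_motion(kind, 2, 60, sk, seed = 5)
    b <- generate_motion(kind, 2, 60, sk, seed = 5)
    expect_identical(a, b)
    for (i in seq_len(nrow(co))) {
      expect_gte(min(a$values[, i]), co$lower[i])
      expect_lte(max(a$values[, i]), co$upper[i])
    }
  }
  expect_max_abs(diff(generate_motion("static", 1, 60, sk)$values), 0 + 1e-15)
  # squat: pelvis height has at least two local minima over 4 s
  sq <- generate_motion("squat", 4, 60, sk, seed = 1)
  py <- sq$values[, "pelvis_ty"]
  expect_gte(sum(diff(sign(diff(py))) > 0), 2)
  # rolling sweeps the root through prone and supine
  ro <- generate_motion("rolling", 4, 60, sk, seed = 1)
  expect_gte(max(ro$values[, "pelvis_pitch"]) -
             min(ro$values[, "pelvis_pitch"]), 1.5 * pi)
})

test_that("corpus synthesis quintuples subjects and is reproducible", {
  corp <- fx_corpus()
  pv <- corpus_provenance(corp)
  expect_equal(nrow(pv), 4 * 5)  # 4 base subjects x 5 scales x 1 trial
  expect_setequal(unique(pv$scale), c(0.90, 0.95, 1.00, 1.05, 1.10))
  corp2 <- synthesize_corpus(
    corpus_config(4, c(gait = 0.5, squat = 0.5), trials_per_subject = 1,
                  duration = 2), seed = 7)
  expect_identical(corp, corp2)
  expect_error(corpus_config(3, numeric(0)), "non-empty")
})
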