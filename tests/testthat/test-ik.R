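test_that("noiseless dense markers are inverted to the true kinematics", {
  sk <- fx_skeleton()
  traj <- generate_motion("gait", 1.0, 60, sk, seed = 2)
  seqn <- forward_kinematics(sk, traj)
  anat <- markerlift:::scope_targets("body")
  dense <- markerlift:::.subset_sequence(seqn, anat)
  ik <- solve_ik(sk, dense)
  dofs <- analysis_dofs()
  rot <- dofs[!grepl("_t[xyz]$", dofs)]
  err <- ik$traj$values[, dofs] - traj$values[, dofs]
  expect_lt(max(abs(err[, rot])) * 180 / pi, 0.06)
  expect_lt(max(abs(err[, c("pelvis_tx", "pelvis_ty", "pelvis_tz")])), 1e-4)
  expect_true(all(ik$residual >= 0))
  expect_lt(mean(ik$residual), 1e-5)
})

test_that("a rigid translation is absorbed by the pelvis translations", {
  sk <- fx_skeleton()
  traj <- generate_motion("squat", 1.0, 60, sk, seed = 4)
  seqn <- forward_kinematics(sk, traj)
  dense <- markerlift:::.subset_sequence(seqn,
                                         markerlift:::scope_targets("body"))
  ik0 <- solve_ik(sk, dense)
  shifted <- dense
  tvec <- c(0.4, 0.2, -0.3)
  for (k in 1:3) shifted$positions[, , k] <- shifted$positions[, , k] + tvec[k]
  ik1 <- solve_ik(sk, shifted)
  d <- ik1$traj$values - ik0$traj$values
  expect_max_abs(d[, "pelvis_tx"] - tvec[1], 1e-5)
  expect_max_abs(d[, "pelvis_ty"] - tvec[2], 1e-5)
  expect_max_abs(d[, "pelvis_tz"] - tvec[3], 1e-5)
  others <- setdiff(colnames(d), c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  expect_max_abs(d[, others], 1e-5)
})

test_that("repeated frames give identical solutions (no warm-start drift)", {
  sk <- fx_skeleton()
  traj <- generate_motion("gait", 0.2, 60, sk, seed = 1)
  seqn <- forward_kinematics(sk, traj)
  dense <- markerlift:::.subset_sequence(seqn,
                                         markerlift:::scope_targets("body"))
  dup <- dense
  dup$positions <- dense$positions[c(1, 1, 1, 2, 2), , , drop = FALSE]
  ik <- solve_ik(sk, dup)
  expect_max_abs(ik$traj$values[2, ] - ik$traj$values[1, ], 2e-5)
  expect_max_abs(ik$traj$values[3, ] - ik$traj$values[1, ], 2e-5)
  expect_max_abs(ik$traj$values[5, ] - ik$traj$values[4, ], 2e-5)
})

test_that("static scaling recovers the generating scale factor", {
  sk <- fx_skeleton()
  sk110 <- fx_skeleton(scale = 1.10)
  static110 <- markerlift:::.static_sequence(sk110)
  frame <- markerlift:::.subset_sequence(static110,
                                         markerlift:::scope_targets("body"))
  scaled <- scale_to_static(sk, frame)
  expect_lt(abs(attr(scaled, "scale_factor") - 1.10), 1e-3)
  # self-consistency: a frame from the same skeleton recovers scale 1
  own <- markerlift:::.subset_sequence(markerlift:::.static_sequence(sk),
                                       markerlift:::scope_targets("body"))
  self <- scale_to_static(sk, own)
  expect_lt(abs(attr(self, "scale_factor") - 1.0), 1e-4)
  # scaling never fits the static frame worse than the unscaled skeleton
  q0 <- stats::setNames(rep(0, nrow(sk$coordinates)), sk$coordinates$name)
  obs <- matrix(frame$positions[1, , ], ncol = 3,
                dimnames = list(dimnames(frame$positions)[[2]], NULL))
  mk_idx <- match(rownames(obs), sk$markers$name)
  unscaled <- markerlift:::.ik_frame(sk, obs, mk_idx,
                                     rep(1, nrow(obs)), q0,
                                     markerlift:::.active_coords(sk, rownames(obs)))
  expect_lte(attr(scaled, "residual"), unscaled$residual + 1e-12)
  # underdetermined error
  few <- obs[1:3, , drop = FALSE]
  expect_error(scale_to_static(sk, few), "underdetermined")
})

test_that("sparse noisy keypoints recover kinematics worse than dense markers", {
  sk <- fx_skeleton()
  traj <- generate_motion("gait", 1.0, 60, sk, seed = 6)
  seqn <- forward_kinematics(sk, traj)
  dofs <- analysis_dofs()
  rot <- dofs[!grepl("_t[xyz]$", dofs)]
  dense <- markerlift:::.subset_sequence(seqn,
                                         markerlift:::scope_targets("body"))
  kp <- markerlift:::.subset_sequence(seqn, marker_names(sk, "keypoint"))
  kp$positions <- add_keypoint_noise(kp$positions, 0.018, seed = 3)
  ik_dense <- solve_ik(sk, dense)
  ik_kp <- solve_ik(sk, kp)
  err_dense <- mean(abs(ik_dense$traj$values[, rot] - traj$values[, rot]))
  err_kp <- mean(abs(ik_kp$traj$values[, rot] - traj$values[, rot]))
  expect_gt(err_kp, err_dense)
})

test_that("degenerate marker sets are rejected", {
  sk <- fx_skeleton()
  seqn <- fx_sequence(5)
  few <- markerlift:::.subset_sequence(seqn, c("c7", "t10", "clav"))
  expect_error(solve_ik(sk, few), "at least 4")
  bad <- seqn
  dimnames(bad$positions)[[2]][1] <- "nonexistent"
  expect_error(solve_ik(sk, bad), "not on skeleton")
})
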