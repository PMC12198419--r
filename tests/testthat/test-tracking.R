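planar_ref <- function(vals, rate = 60) {
  joint_trajectory(rate, markerlift:::PLANAR_COORDS, vals)
}

test_that("the zero-phase low-pass filter passes DC and kills high frequencies", {
  n <- 241
  t <- (seq_len(n) - 1) / 60
  vals <- matrix(0, n, 10, dimnames = list(NULL, markerlift:::PLANAR_COORDS))
  vals[, "hip_r"] <- 0.3
  vals[, "knee_r"] <- sin(2 * pi * 20 * t)
  vals[, "ankle_r"] <- sin(2 * pi * 1 * t)
  f <- lowpass_filter(planar_ref(vals), 4)
  expect_max_abs(f$values[, "hip_r"] - 0.3, 1e-6)
  mid <- 60:180
  expect_lt(max(abs(f$values[mid, "knee_r"])), 0.05)     # > 95% attenuation
  expect_gt(max(abs(f$values[mid, "ankle_r"])), 0.9)     # passband intact
  # filtering twice adds no phase shift: peaks stay aligned
  f2 <- lowpass_filter(f, 4)
  expect_equal(which.max(f2$values[mid, "ankle_r"]),
               which.max(f$values[mid, "ankle_r"]))
  expect_error(lowpass_filter(planar_ref(vals), 30), "Nyquist")
})

test_that("tracking problems encode buffers, periodicity and weights", {
  expect_error(tracking_weights(w1 = -1), "non-negative")
  expect_error(tracking_weights(t0 = 1, tf = 1), "exceed")
  model <- planar_model(1.70, 68)
  vals <- matrix(0, 121, 10, dimnames = list(NULL, markerlift:::PLANAR_COORDS))
  vals[, "pelvis_ty"] <- standing_pelvis_height(model)
  ref <- planar_ref(vals)
  w <- tracking_weights(t0 = 0.5, tf = 1.5)
  p0 <- build_tracking_problem(ref, w, options = list(mesh_intervals = 10),
                               model = model)
  expect_equal(range(p0$times), c(0.5, 1.5))
  expect_true(all(p0$report_mask))
  pb <- build_tracking_problem(ref, w, options = list(mesh_intervals = 30,
                                                      time_buffer = 0.25),
                               model = model)
  expect_equal(range(pb$times), c(0.25, 1.75))
  expect_true(any(!pb$report_mask))
  expect_equal(range(pb$times[pb$report_mask]), c(0.5, 1.5))
  expect_error(build_tracking_problem(ref, tracking_weights(t0 = 0, tf = 3),
                                      model = model), "span")
  expect_error(build_tracking_problem(ref, w,
                                      options = list(mesh_intervals = 5),
                                      model = model), "at least 10")
  pp <- build_tracking_problem(ref, w, options = list(mesh_intervals = 10,
                                                      periodic_pelvis = TRUE),
                               model = model)
  lay <- markerlift:::.row_layout(pp)
  expect_length(lay$per_rows, 6)
})

test_that("contact spheres above the ground produce no force", {
  model <- planar_model()
  q <- stats::setNames(numeric(10), markerlift:::PLANAR_COORDS)
  q["pelvis_ty"] <- standing_pelvis_height(model) + 0.3   # airborne
  cf <- markerlift:::contact_forces(model, q)
  for (ct in cf) expect_max_abs(ct$f, 1e-6)
  # penetrating feet produce upward force
  q["pelvis_ty"] <- standing_pelvis_height(model)
  cf2 <- markerlift:::contact_forces(model, q)
  expect_gt(sum(vapply(cf2, function(x) x$f[, 2], numeric(1))), 100)
})

test_that("static standing tracks to equilibrium with weight support", {
  model <- planar_model(1.75, 75)
  n <- 61
  vals <- matrix(0, n, 10, dimnames = list(NULL, markerlift:::PLANAR_COORDS))
  vals[, "pelvis_ty"] <- standing_pelvis_height(model)
  ref <- planar_ref(vals)
  w <- tracking_weights(w1 = 0.1, w2 = 0.01, w3 = 100, w4 = 1, w5 = 1e-4,
                        t0 = 0.3, tf = 0.7)
  prob <- build_tracking_problem(ref, w,
                                 options = list(mesh_intervals = 14,
                                                time_buffer = 0.3),
                                 model = model)
  res <- solve_tracking(prob)
  expect_true(res$converged)
  expect_lt(res$max_defect, 1e-6)
  grf <- grf_from_contacts(res)
  total <- tapply(grf$fy_bw, grf$time, sum)
  expect_lt(abs(mean(total) - 100), 1)
  # tracked posture stays at the reference
  keep <- prob$report_mask
  expect_lt(max(abs(res$q[keep, 3:10] - prob$qref[keep, 3:10])) * 180 / pi,
            0.5)
  # non-converged results are refused by reporters
  fake <- res; fake$converged <- FALSE
  expect_error(grf_from_contacts(fake), "converge")
})

test_that("periodic squat tracking satisfies defects and periodicity", {
  model <- planar_model(1.72, 70)
  pc <- markerlift:::PLANAR_COORDS
  t <- (0:120) / 60
  d <- 0.5 * (1 - cos(2 * pi * t / 2))
  sq <- matrix(0, 121, 10, dimnames = list(NULL, pc))
  sq[, "hip_r"] <- 1.0 * d; sq[, "hip_l"] <- 1.0 * d
  sq[, "knee_r"] <- -1.4 * d; sq[, "knee_l"] <- -1.4 * d
  sq[, "ankle_r"] <- 0.35 * d; sq[, "ankle_l"] <- 0.35 * d
  sq[, "lumbar"] <- -0.2 * d
  sq[, "pelvis_ty"] <- consistent_pelvis_height(model, sq)
  ref <- lowpass_filter(planar_ref(sq), 4)
  w <- tracking_weights(w1 = 0.1, w2 = 0.01, w3 = 100, w4 = 1, w5 = 1e-4,
                        t0 = 0, tf = 2)
  prob <- build_tracking_problem(ref, w,
                                 options = list(mesh_intervals = 16,
                                                periodic_pelvis = TRUE),
                                 model = model)
  res <- solve_tracking(prob)
  expect_true(res$converged)
  expect_lt(res$max_defect, 1e-6)
  nlast <- nrow(res$q)
  expect_max_abs(res$q[1, 1:3] - res$q[nlast, 1:3], 1e-6)
  expect_max_abs(res$qd[1, 1:3] - res$qd[nlast, 1:3], 1e-6)
  # impulse balance over the periodic cycle: the time-averaged total
  # vertical force equals body weight, up to trapezoid discretization error
  grf <- grf_from_contacts(res)
  total <- tapply(grf$fy_bw, grf$time, sum)
  trap_mean <- (sum(total) - (total[1] + total[length(total)]) / 2) /
    (length(total) - 1)
  expect_lt(abs(trap_mean - 100), 5)
})

test_that("dynamics RMSE matches constant-offset closed forms", {
  g <- tibble::tibble(time = rep(1:5 / 60, 2),
                      foot = rep(c("r", "l"), each = 5),
                      fy_bw = 50, fx_bw = 0)
  g2 <- g; g2$fy_bw <- g2$fy_bw + 5
  out <- dynamics_rmse(g2, g)
  expect_equal(out$rmse[out$component == "grf_vertical_r"], 5)
  expect_equal(out$rmse[out$component == "grf_anterior_posterior_r"], 0)
  m <- tibble::tibble(time = rep(1:5 / 60, 2),
                      joint = rep(c("hip_r", "knee_r"), each = 5),
                      moment_bwht = 1)
  m2 <- m; m2$moment_bwht[m2$joint == "knee_r"] <- 1.5
  out2 <- dynamics_rmse(g, g, m2, m)
  expect_equal(out2$rmse[out2$component == "moment_knee_r"], 0.5)
  expect_equal(out2$rmse[out2$component == "moment_hip_r"], 0)
  bad <- g; bad$foot <- rev(bad$foot)
  expect_error(dynamics_rmse(bad, g), "aligned")
})
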