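# Optimal-control tracking simulation: effort + kinematic tracking cost,
# trapezoidal direct collocation with implicit dynamics defects, movement
# options (time buffers, periodic pelvis, heel-lift penalty), solved by an
# augmented Lagrangian over a sparse damped Gauss-Newton inner solver.
# Reports ground reaction forces in %BW and joint moments in %BW*ht.

#' Zero-phase Butterworth low-pass filter for joint trajectories
#'
#' Forward-backward 4th-order Butterworth with reflection padding at the
#' endpoints (no phase shift).
#'
#' @param traj a [joint_trajectory()].
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @return the filtered [joint_trajectory()].
#' @export
lowpass_filter <- function(traj, cutoff) {
  if (cutoff >= traj$rate / 2) stopf("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (traj$rate / 2), type = "low")
  vals <- traj$values
  n <- nrow(vals)
  p <- min(n - 1L, 90L)
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- signal::filter(bf, xp)
    y <- rev(signal::filter(bf, rev(y)))
    vals[, j] <- y[(p + 1):(p + n)]
  }
  joint_trajectory(traj$rate, traj$coordinates, vals)
}

#' Tracking-cost weights
#'
#' Effort weights on squared activations (`w1`) and torque-motor excitations
#' (`w2`), and tracking weights on squared deviations of joint positions
#' (`w3`), velocities (`w4`) and accelerations (`w5`) from the (filtered)
#' experimental reference, integrated over the window `[t0, tf]`.
#'
#' @param w1,w2,w3,w4,w5 non-negative weights.
#' @param t0,tf window bounds in seconds (`tf > t0`).
#' @return a `tracking_weights` list.
#' @export
tracking_weights <- function(w1 = 0.1, w2 = 0.01, w3 = 100, w4 = 1,
                             w5 = 1e-4, t0 = 0, tf = 1) {
  w <- c(w1, w2, w3, w4, w5)
  if (any(w < 0)) stopf("weights must be non-negative")
  if (tf <= t0) stopf("tf must exceed t0")
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5,
                 t0 = t0, tf = tf), class = "tracking_weights")
}

#' Build a tracking-simulation problem
#'
#' Transcribes the tracking cost over reference kinematics into a direct
#' collocation problem on a uniform mesh with implicit dynamics defects.
#' Reference velocities and accelerations are obtained by spline
#' differentiation of the (filtered) reference positions. Time buffers extend
#' the horizon on both sides and are excluded from reported metrics; the
#' periodic-pelvis option adds equality constraints on pelvis position and
#' speed at the horizon bounds; the heel-lift penalty adds a smooth cost on
#' heel-sphere clearance.
#'
#' @param ref a [joint_trajectory()] with the planar coordinates, filtered
#'   and at 60 Hz.
#' @param weights a [tracking_weights()].
#' @param options list: `time_buffer` (s), `periodic_pelvis` (flag),
#'   `heel_lift_penalty` (weight), `mesh_intervals` (>= 10; default 100 per
#'   second of horizon).
#' @param model a [planar_model()].
#' @return a `tracksim_problem`.
#' @export
build_tracking_problem <- function(ref, weights, options = list(),
                                   model = planar_model()) {
  opts <- utils::modifyList(list(time_buffer = 0, periodic_pelvis = FALSE,
                                 heel_lift_penalty = 0,
                                 mesh_intervals = NULL), options)
  if (!all(PLANAR_COORDS %in% ref$coordinates))
    stopf("reference must contain the planar coordinates")
  span <- c(0, (nrow(ref$values) - 1) / ref$rate)
  t0 <- weights$t0 - opts$time_buffer
  tf <- weights$tf + opts$time_buffer
  if (t0 < span[1] - 1e-9 || tf > span[2] + 1e-9)
    stopf("horizon [%g, %g] not inside reference span [%g, %g]",
          t0, tf, span[1], span[2])
  N <- as.integer(opts$mesh_intervals %||% max(10, ceiling(100 * (tf - t0))))
  if (N < 10) stopf("mesh_intervals must be at least 10")
  times <- seq(t0, tf, length.out = N + 1L)
  tref <- seq(span[1], span[2], by = 1 / ref$rate)
  qref <- matrix(0, N + 1L, length(PLANAR_COORDS),
                 dimnames = list(NULL, PLANAR_COORDS))
  qdref <- qref; qddref <- qref
  for (cn in PLANAR_COORDS) {
    sf <- stats::splinefun(tref, ref$values[, cn], method = "natural")
    qref[, cn] <- sf(times)
    qdref[, cn] <- sf(times, deriv = 1)
    qddref[, cn] <- sf(times, deriv = 2)
  }
  report <- times >= weights$t0 - 1e-9 & times <= weights$tf + 1e-9
  structure(list(model = model, weights = weights, options = opts,
                 times = times, N = N, h = diff(times)[1],
                 qref = qref, qdref = qdref, qddref = qddref,
                 report_mask = report),
            class = "tracksim_problem")
}

# ---- transcription ----------------------------------------------------------
# Per node: q(10) qd(10) qdd(10) aP(7) aM(7) eP(7) eM(7) = 58 variables,
# node-major packing. Objective rows per node: 14 activation + 14 excitation
# + 30 tracking + 2 heel = 60; constraint rows: 34 defects per interval
# (q, qd, a), 10 scaled dynamics per node, 6 optional periodicity rows.
.NV_Q <- 10L; .NV_A <- 7L
.NODE_VARS <- 58L
.N_OBJ_ROWS <- 60L
.N_DEF_ROWS <- 34L

.unpack_z <- function(z, n) {
  zm <- matrix(z, .NODE_VARS, n)
  list(Q = t(zm[1:10, , drop = FALSE]),
       Qd = t(zm[11:20, , drop = FALSE]),
       Qdd = t(zm[21:30, , drop = FALSE]),
       A = t(zm[31:44, , drop = FALSE]),
       E = t(zm[45:58, , drop = FALSE]))
}

.var_bounds <- function(problem) {
  lb_q <- c(-10, -10, -2 * pi, -0.6, -0.6, -0.6, -2.3, -2.3, -0.9, -0.9)
  ub_q <- c(10, 10, 2 * pi, 0.8, 2.2, 2.2, 0.1, 0.1, 0.9, 0.9)
  lo <- c(lb_q, rep(-20, 10), rep(-500, 10), rep(0, 28))
  hi <- c(ub_q, rep(20, 10), rep(500, 10), rep(1, 28))
  list(lo = rep(lo, problem$N + 1L), hi = rep(hi, problem$N + 1L))
}

.tracking_residuals <- function(problem, z) {
  N <- problem$N; n <- N + 1L; h <- problem$h
  model <- problem$model
  w <- problem$weights
  st <- .unpack_z(z, n)
  dynr <- planar_dynamics_residual_vec(model, st$Q, st$Qd, st$Qdd, st$A)
  # objective rows, node-major (60 x n matrix flattened)
  sqk <- sqrt(h * ifelse(seq_len(n) %in% c(1L, n), 0.5, 1))
  heel <- if (problem$options$heel_lift_penalty > 0)
    sqrt(problem$options$heel_lift_penalty) *
      smooth_pos(dynr$heel_clearance, 1e-3) else matrix(0, n, 2)
  ob <- rbind(sqrt(w$w1) * t(st$A),
              sqrt(w$w2) * t(st$E),
              sqrt(w$w3) * t(st$Q - problem$qref),
              sqrt(w$w4) * t(st$Qd - problem$qdref),
              sqrt(w$w5) * t(st$Qdd - problem$qddref),
              t(heel))
  ob <- ob * rep(sqk, each = .N_OBJ_ROWS)
  # defects per interval (34 x N), then dynamics per node (10 x n)
  i1 <- seq_len(N); i2 <- i1 + 1L
  Adot <- (st$E - st$A) / model$act_tau
  D <- rbind(
    t(st$Q[i2, ] - st$Q[i1, ] - h / 2 * (st$Qd[i1, ] + st$Qd[i2, ])),
    t(st$Qd[i2, ] - st$Qd[i1, ] - h / 2 * (st$Qdd[i1, ] + st$Qdd[i2, ])),
    t(st$A[i2, ] - st$A[i1, ] - h / 2 * (Adot[i1, ] + Adot[i2, ])))
  per <- numeric(0)
  if (isTRUE(problem$options$periodic_pelvis))
    per <- c(st$Q[1, 1:3] - st$Q[n, 1:3], st$Qd[1, 1:3] - st$Qd[n, 1:3])
  list(obj = as.vector(ob), con = c(as.vector(D), as.vector(t(dynr$resid)),
                                    per))
}

.row_layout <- function(problem) {
  N <- problem$N
  n_obj <- (N + 1L) * .N_OBJ_ROWS
  per <- isTRUE(problem$options$periodic_pelvis)
  list(
    n_obj = n_obj,
    n_con = N * .N_DEF_ROWS + (N + 1L) * 10L + if (per) 6L else 0L,
    obj_rows = function(k) ((k - 1L) * .N_OBJ_ROWS + 1L):(k * .N_OBJ_ROWS),
    def_rows = function(k) n_obj + ((k - 1L) * .N_DEF_ROWS + 1L):(k * .N_DEF_ROWS),
    dyn_rows = function(k) n_obj + N * .N_DEF_ROWS +
      ((k - 1L) * 10L + 1L):(k * 10L),
    per_rows = if (per) n_obj + N * .N_DEF_ROWS + (N + 1L) * 10L + 1:6
               else integer(0))
}

# The transcription is linear in every row except the dynamics defects and
# the heel-clearance penalty, which are node-local. The Jacobian is therefore
# assembled as a constant sparse part (objective, integration defects,
# periodicity; built once) plus a node-local part obtained by finite
# differences of the dynamics alone (one evaluation per node variable,
# perturbed at every node simultaneously).
.jac_constant <- function(problem) {
  N <- problem$N; n <- N + 1L; h <- problem$h
  lay <- .row_layout(problem)
  w <- problem$weights
  tau <- problem$model$act_tau
  sqk <- sqrt(h * ifelse(seq_len(n) %in% c(1L, n), 0.5, 1))
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  for (k in seq_len(n)) {
    orow <- (k - 1L) * .N_OBJ_ROWS
    col0 <- (k - 1L) * .NODE_VARS
    add(orow + 1:14, col0 + 31:44, rep(sqk[k] * sqrt(w$w1), 14))
    add(orow + 15:28, col0 + 45:58, rep(sqk[k] * sqrt(w$w2), 14))
    add(orow + 29:38, col0 + 1:10, rep(sqk[k] * sqrt(w$w3), 10))
    add(orow + 39:48, col0 + 11:20, rep(sqk[k] * sqrt(w$w4), 10))
    add(orow + 49:58, col0 + 21:30, rep(sqk[k] * sqrt(w$w5), 10))
  }
  for (k in seq_len(N)) {
    drow <- (k - 1L) * .N_DEF_ROWS + lay$n_obj
    ca <- (k - 1L) * .NODE_VARS; cb <- k * .NODE_VARS
    add(drow + 1:10, cb + 1:10, rep(1, 10))
    add(drow + 1:10, ca + 1:10, rep(-1, 10))
    add(drow + 1:10, ca + 11:20, rep(-h / 2, 10))
    add(drow + 1:10, cb + 11:20, rep(-h / 2, 10))
    add(drow + 11:20, cb + 11:20, rep(1, 10))
    add(drow + 11:20, ca + 11:20, rep(-1, 10))
    add(drow + 11:20, ca + 21:30, rep(-h / 2, 10))
    add(drow + 11:20, cb + 21:30, rep(-h / 2, 10))
    add(drow + 21:34, cb + 31:44, rep(1 + h / (2 * tau), 14))
    add(drow + 21:34, ca + 31:44, rep(-1 + h / (2 * tau), 14))
    add(drow + 21:34, ca + 45:58, rep(-h / (2 * tau), 14))
    add(drow + 21:34, cb + 45:58, rep(-h / (2 * tau), 14))
  }
  if (length(lay$per_rows)) {
    add(lay$per_rows, c(1:3, 11:13), rep(1, 6))
    add(lay$per_rows, N * .NODE_VARS + c(1:3, 11:13), rep(-1, 6))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(lay$n_obj + lay$n_con, n * .NODE_VARS))
}

.jac_dynamic <- function(problem, z, fd = 1e-6) {
  N <- problem$N; n <- N + 1L
  model <- problem$model
  lay <- .row_layout(problem)
  st <- .unpack_z(z, n)
  base <- planar_dynamics_residual_vec(model, st$Q, st$Qd, st$Qdd, st$A)
  sqk <- sqrt(problem$h * ifelse(seq_len(n) %in% c(1L, n), 0.5, 1))
  wh <- problem$options$heel_lift_penalty
  heel0 <- if (wh > 0) sqrt(wh) * smooth_pos(base$heel_clearance, 1e-3)
  dyn_row0 <- lay$n_obj + N * .N_DEF_ROWS
  ii <- list(); jj <- list(); xx <- list(); idx <- 0L
  for (v in seq_len(44L)) {
    mats <- st
    if (v <= 10) mats$Q[, v] <- mats$Q[, v] + fd
    else if (v <= 20) mats$Qd[, v - 10] <- mats$Qd[, v - 10] + fd
    else if (v <= 30) mats$Qdd[, v - 20] <- mats$Qdd[, v - 20] + fd
    else mats$A[, v - 30] <- mats$A[, v - 30] + fd
    pert <- planar_dynamics_residual_vec(model, mats$Q, mats$Qd, mats$Qdd,
                                         mats$A)
    dres <- (pert$resid - base$resid) / fd
    cols <- (seq_len(n) - 1L) * .NODE_VARS + v
    for (k in which(rowSums(dres != 0) > 0)) {
      nzj <- which(dres[k, ] != 0)
      idx <- idx + 1L
      ii[[idx]] <- dyn_row0 + (k - 1L) * 10L + nzj
      jj[[idx]] <- rep(cols[k], length(nzj))
      xx[[idx]] <- dres[k, nzj]
    }
    if (wh > 0 && v <= 10) {
      dh <- (sqrt(wh) * smooth_pos(pert$heel_clearance, 1e-3) - heel0) /
        fd * sqk
      for (k in which(rowSums(dh != 0) > 0)) {
        nzj <- which(dh[k, ] != 0)
        idx <- idx + 1L
        ii[[idx]] <- (k - 1L) * .N_OBJ_ROWS + 58L + nzj
        jj[[idx]] <- rep(cols[k], length(nzj))
        xx[[idx]] <- dh[k, nzj]
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(lay$n_obj + lay$n_con, n * .NODE_VARS))
}

.tracking_jacobian <- function(problem, z, jconst, fd = 1e-6) {
  jconst + .jac_dynamic(problem, z, fd)
}

#' Solve a tracking-simulation problem
#'
#' Augmented-Lagrangian treatment of the collocation defects around a sparse
#' damped Gauss-Newton inner solver; variables are clamped to their bounds.
#' Returns converged trajectories or a non-convergence flag (never a silent
#' failure); non-converged results are excluded from aggregate metrics by
#' [grf_from_contacts()] and [joint_moments()], which refuse them.
#'
#' @param problem a `tracksim_problem` from [build_tracking_problem()].
#' @param control list: `max_outer`, `max_inner`, `mu0`, `tol_con`
#'   (constraint tolerance, default 1e-6), `verbose`.
#' @return an object of class `tracksim_result`.
#' @export
solve_tracking <- function(problem, control = list()) {
  ctl <- utils::modifyList(list(max_outer = 20L, max_inner = 40L, mu0 = 1e4,
                                tol_con = 1e-6, verbose = FALSE), control)
  N <- problem$N; n <- N + 1L
  nz <- n * .NODE_VARS
  bounds <- .var_bounds(problem)
  clamp <- function(zv) pmin(pmax(zv, bounds$lo), bounds$hi)
  # initial guess: reference kinematics with activations from inverse
  # dynamics along the reference (leaves only the unactuated pelvis rows and
  # contact imbalance infeasible)
  id0 <- planar_id_vec(problem$model, problem$qref, problem$qdref,
                       problem$qddref)
  tauj <- id0$tau[, problem$model$joints, drop = FALSE]
  aP <- pmin(pmax(sweep(tauj, 2, problem$model$tau_max, "/"), 0), 1)
  aM <- pmin(pmax(sweep(-tauj, 2, problem$model$tau_max, "/"), 0), 1)
  z <- as.vector(t(cbind(problem$qref, problem$qdref, problem$qddref,
                         aP, aM, aP, aM)))
  z <- clamp(z)
  r <- .tracking_residuals(problem, z)
  lam <- numeric(length(r$con))
  mu <- ctl$mu0
  lay <- .row_layout(problem)
  jconst <- .jac_constant(problem)
  best_con <- Inf
  status <- "max_iterations"
  for (outer in seq_len(ctl$max_outer)) {
    al_resid <- function(rr) c(rr$obj, sqrt(mu) * (rr$con + lam / (2 * mu)))
    cost <- function(rr) sum(al_resid(rr)^2)
    cur <- cost(r)
    lambda_lm <- 1e-4
    for (inner in seq_len(ctl$max_inner)) {
      J <- .tracking_jacobian(problem, z, jconst)
      sc <- c(rep(1, lay$n_obj), rep(sqrt(mu), lay$n_con))
      Js <- Matrix::Diagonal(x = sc) %*% J
      rs <- al_resid(r)
      g <- as.vector(Matrix::crossprod(Js, rs))
      H <- Matrix::crossprod(Js)
      accepted <- FALSE
      rel <- Inf
      for (try_ in 1:10) {
        Hd <- H + Matrix::Diagonal(nz, lambda_lm * (Matrix::diag(H) + 1e-8))
        step <- tryCatch(as.vector(Matrix::solve(Hd, -g)),
                         error = function(e) NULL)
        if (is.null(step)) { lambda_lm <- lambda_lm * 10; next }
        # bound-constrained step: fix variables that the unconstrained step
        # pushes past their bounds, re-solve for the free ones so the linear
        # defect rows stay satisfied on the active set
        zn <- z + step
        fixed <- integer(0)
        for (pass in 1:4) {
          viol <- which(zn < bounds$lo - 1e-12 | zn > bounds$hi + 1e-12)
          viol <- setdiff(viol, fixed)
          if (!length(viol)) break
          fixed <- sort(c(fixed, viol))
          zfix <- pmin(pmax(z[fixed] + step[fixed], bounds$lo[fixed]),
                       bounds$hi[fixed])
          free <- setdiff(seq_len(nz), fixed)
          rhs <- -g[free] -
            as.vector(Hd[free, fixed, drop = FALSE] %*% (zfix - z[fixed]))
          step_free <- tryCatch(
            as.vector(Matrix::solve(Hd[free, free, drop = FALSE], rhs)),
            error = function(e) NULL)
          if (is.null(step_free)) break
          zn <- z
          zn[fixed] <- zfix
          zn[free] <- z[free] + step_free
        }
        zn <- clamp(zn)
        rn <- .tracking_residuals(problem, zn)
        cn <- cost(rn)
        if (cn <= cur) {
          rel <- (cur - cn) / max(cur, 1e-300)
          z <- zn; r <- rn; cur <- cn
          lambda_lm <- max(lambda_lm / 5, 1e-10)
          accepted <- TRUE
          break
        }
        lambda_lm <- lambda_lm * 10
      }
      if (!accepted || rel < 1e-10) break
    }
    con_norm <- if (length(r$con)) max(abs(r$con)) else 0
    if (ctl$verbose)
      message(sprintf("outer %d: cost %.6g, max|c| %.3g, mu %g",
                      outer, cur, con_norm, mu))
    if (con_norm < ctl$tol_con) { status <- "converged"; break }
    lam <- lam + 2 * mu * r$con
    if (con_norm > 0.25 * best_con) mu <- min(mu * 4, 1e12)
    best_con <- min(best_con, con_norm)
  }
  st <- .unpack_z(z, n)
  colnames(st$Q) <- colnames(st$Qd) <- colnames(st$Qdd) <- PLANAR_COORDS
  structure(list(status = status, converged = status == "converged",
                 times = problem$times, q = st$Q, qd = st$Qd, qdd = st$Qdd,
                 a = st$A, e = st$E,
                 objective = sum(r$obj^2),
                 max_defect = if (length(r$con)) max(abs(r$con)) else 0,
                 problem = problem),
            class = "tracksim_result")
}

#' @exportS3Method base::print
print.tracksim_result <- function(x, ...) {
  cat(sprintf("<tracksim_result> %s, %d nodes, objective %.4g, max defect %.2g\n",
              x$status, length(x$times), x$objective, x$max_defect))
  invisible(x)
}

#' Ground reaction forces from the contact model
#'
#' Recomputes the smooth sphere contact forces along the solution and sums
#' them per foot; reported in percent bodyweight. Buffer nodes are excluded
#' by default.
#'
#' @param result a converged `tracksim_result`.
#' @param trim_buffers drop mesh nodes outside the reporting window.
#' @return tibble: time, foot, vertical (`fy_bw`) and anterior-posterior
#'   (`fx_bw`) force in %BW.
#' @export
grf_from_contacts <- function(result, trim_buffers = TRUE) {
  if (!result$converged) stopf("tracking solution did not converge")
  problem <- result$problem
  model <- problem$model
  bw <- model$mass * GRAVITY
  keep <- if (trim_buffers) which(problem$report_mask)
          else seq_along(result$times)
  ks <- planar_kin_vec(model, result$q, result$qd)
  cf <- contact_forces_vec(model, ks)
  out <- list()
  for (ft in c("foot_r", "foot_l")) {
    fsum <- Reduce(`+`, lapply(cf[vapply(cf, function(x)
      identical(x$segment, ft), logical(1))], `[[`, "f"))
    out[[ft]] <- tibble::tibble(time = result$times[keep],
                                foot = sub("foot_", "", ft),
                                fy_bw = 100 * fsum[keep, 2] / bw,
                                fx_bw = 100 * fsum[keep, 1] / bw)
  }
  do.call(rbind, out)
}

#' Joint moments of a tracking solution
#'
#' Actuator torques (torque limit times net activation) in percent bodyweight
#' times stature.
#'
#' @param result a converged `tracksim_result`.
#' @param trim_buffers drop mesh nodes outside the reporting window.
#' @return tibble: time, joint, moment (%BW*ht).
#' @export
joint_moments <- function(result, trim_buffers = TRUE) {
  if (!result$converged) stopf("tracking solution did not converge")
  problem <- result$problem
  model <- problem$model
  denom <- model$mass * GRAVITY * model$height
  keep <- if (trim_buffers) which(problem$report_mask)
          else seq_along(result$times)
  np <- length(model$joints)
  tau <- (result$a[, seq_len(np), drop = FALSE] -
          result$a[, np + seq_len(np), drop = FALSE]) *
    rep(model$tau_max, each = nrow(result$a))
  do.call(rbind, lapply(seq_len(np), function(j)
    tibble::tibble(time = result$times[keep], joint = model$joints[j],
                   moment_bwht = 100 * tau[keep, j] / denom)))
}

#' RMSE of simulated dynamics against reference series
#'
#' Per-component RMSE of ground reaction forces (%BW) and joint moments
#' (%BW*ht) on aligned, buffer-trimmed series.
#'
#' @param sim_grf,ref_grf tibbles as from [grf_from_contacts()], aligned.
#' @param sim_moments,ref_moments tibbles as from [joint_moments()], aligned
#'   (optional).
#' @return tibble: component, rmse, unit.
#' @export
dynamics_rmse <- function(sim_grf, ref_grf, sim_moments = NULL,
                          ref_moments = NULL) {
  if (nrow(sim_grf) != nrow(ref_grf) || !all(sim_grf$foot == ref_grf$foot))
    stopf("ground-reaction series are not aligned")
  out <- list()
  for (ft in unique(sim_grf$foot)) {
    s <- sim_grf[sim_grf$foot == ft, ]; r <- ref_grf[ref_grf$foot == ft, ]
    out[[length(out) + 1L]] <- tibble::tibble(
      component = paste0("grf_vertical_", ft),
      rmse = rmse(s$fy_bw, r$fy_bw), unit = "%BW")
    out[[length(out) + 1L]] <- tibble::tibble(
      component = paste0("grf_anterior_posterior_", ft),
      rmse = rmse(s$fx_bw, r$fx_bw), unit = "%BW")
  }
  if (!is.null(sim_moments) && !is.null(ref_moments)) {
    if (nrow(sim_moments) != nrow(ref_moments) ||
        !all(sim_moments$joint == ref_moments$joint))
      stopf("joint-moment series are not aligned")
    for (j in unique(sim_moments$joint)) {
      s <- sim_moments[sim_moments$joint == j, ]
      r <- ref_moments[ref_moments$joint == j, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        component = paste0("moment_", j),
        rmse = rmse(s$moment_bwht, r$moment_bwht), unit = "%BW*ht")
    }
  }
  do.call(rbind, out)
}
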