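# Torque-actuated planar (sagittal) multi-body model with smooth foot-ground
# contact, used by the tracking simulations. Pelvis translations + pitch,
# lumbar, and hip/knee/ankle per side (10 coordinates); each non-root joint
# is driven by an antagonistic pair of torque actuators with first-order
# activation dynamics. Inverse dynamics via a planar recursive Newton-Euler
# pass, vectorized over mesh nodes; contact via three Hunt-Crossley-like
# spheres per foot with smoothed Coulomb friction.

PLANAR_COORDS <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt", "lumbar",
                   "hip_r", "hip_l", "knee_r", "knee_l", "ankle_r", "ankle_l")
PLANAR_JOINTS <- c("lumbar", "hip_r", "hip_l", "knee_r", "knee_l",
                   "ankle_r", "ankle_l")
GRAVITY <- 9.80665

#' Planar tracking-simulation model
#'
#' Segment masses and inertias follow standard anthropometric fractions of
#' body mass and stature; torque limits scale with body mass. The torso
#' segment lumps trunk, head and arms.
#'
#' @param height subject stature (m).
#' @param mass subject mass (kg).
#' @return a `planar_model` list (segments, actuators, contact spheres).
#' @export
planar_model <- function(height = 1.75, mass = 75) {
  H <- height; M <- mass
  seg <- function(name, parent, joint_coord, r_joint, com, m, rg) {
    list(name = name, parent = parent, joint_coord = joint_coord,
         r_joint = r_joint, com = com, m = m, I = m * rg^2)
  }
  thigh_len <- 0.245 * H; shank_len <- 0.245 * H; foot_len <- 0.152 * H
  segments <- list(
    pelvis = seg("pelvis", NA, NA, c(0, 0), c(0, 0), 0.142 * M, 0.10 * H),
    torso = seg("torso", "pelvis", "lumbar", c(0, 0.10 * H),
                c(0, 0.20 * H), 0.536 * M, 0.25 * H),
    thigh_r = seg("thigh_r", "pelvis", "hip_r", c(0, 0),
                  c(0, -0.433 * thigh_len), 0.100 * M, 0.323 * thigh_len),
    thigh_l = seg("thigh_l", "pelvis", "hip_l", c(0, 0),
                  c(0, -0.433 * thigh_len), 0.100 * M, 0.323 * thigh_len),
    shank_r = seg("shank_r", "thigh_r", "knee_r", c(0, -thigh_len),
                  c(0, -0.433 * shank_len), 0.0465 * M, 0.302 * shank_len),
    shank_l = seg("shank_l", "thigh_l", "knee_l", c(0, -thigh_len),
                  c(0, -0.433 * shank_len), 0.0465 * M, 0.302 * shank_len),
    foot_r = seg("foot_r", "shank_r", "ankle_r", c(0, -shank_len),
                 c(0.05 * H, -0.025 * H), 0.0145 * M, 0.475 * foot_len),
    foot_l = seg("foot_l", "shank_l", "ankle_l", c(0, -shank_len),
                 c(0.05 * H, -0.025 * H), 0.0145 * M, 0.475 * foot_len))
  tau_max <- c(lumbar = 2.0, hip_r = 2.0, hip_l = 2.0, knee_r = 2.0,
               knee_l = 2.0, ankle_r = 1.6, ankle_l = 1.6) * M
  spheres <- list()
  for (sd in c("r", "l")) {
    locs <- list(c(-0.040 * H, -0.025 * H), c(0.050 * H, -0.025 * H),
                 c(0.115 * H, -0.025 * H))
    for (i in seq_len(3))
      spheres[[paste0("foot_", sd, "_s", i)]] <-
        list(segment = paste0("foot_", sd), pos = locs[[i]], radius = 0.02,
             heel = i == 1L)
  }
  structure(list(height = H, mass = M, segments = segments,
                 coords = PLANAR_COORDS, joints = PLANAR_JOINTS,
                 tau_max = tau_max, spheres = spheres,
                 contact = list(k = 1e6, c_damp = 2.0, mu = 0.8,
                                v_smooth = 0.05, eps = 1e-4),
                 act_tau = 0.05),
            class = "planar_model")
}

# smooth positive part: 0.5*(x + sqrt(x^2 + eps^2))
smooth_pos <- function(x, eps = 1e-4) 0.5 * (x + sqrt(x^2 + eps^2))

# Vectorized planar forward pass over n poses. Q/Qd/Qdd are n x 10 matrices
# in PLANAR_COORDS order. Returns per-segment lists of length-n vectors and
# n x 2 matrices.
planar_kin_vec <- function(model, Q, Qd = NULL, Qdd = NULL) {
  n <- nrow(Q)
  if (is.null(Qd)) Qd <- Q * 0
  if (is.null(Qdd)) Qdd <- Q * 0
  ks <- list()
  for (s in model$segments) {
    if (is.na(s$parent)) {
      th <- Q[, 3]; om <- Qd[, 3]; al <- Qdd[, 3]
      p <- Q[, 1:2, drop = FALSE]
      v <- Qd[, 1:2, drop = FALSE]
      a <- Qdd[, 1:2, drop = FALSE]
    } else {
      pk <- ks[[s$parent]]
      ji <- match(s$joint_coord, model$coords)
      d1 <- pk$cth * s$r_joint[1] - pk$sth * s$r_joint[2]
      d2 <- pk$sth * s$r_joint[1] + pk$cth * s$r_joint[2]
      p <- cbind(pk$p[, 1] + d1, pk$p[, 2] + d2)
      v <- cbind(pk$v[, 1] - pk$om * d2, pk$v[, 2] + pk$om * d1)
      a <- cbind(pk$a[, 1] - pk$al * d2 - pk$om^2 * d1,
                 pk$a[, 2] + pk$al * d1 - pk$om^2 * d2)
      th <- pk$th + Q[, ji]; om <- pk$om + Qd[, ji]; al <- pk$al + Qdd[, ji]
    }
    cth <- cos(th); sth <- sin(th)
    c1 <- cth * s$com[1] - sth * s$com[2]
    c2 <- sth * s$com[1] + cth * s$com[2]
    ks[[s$name]] <- list(th = th, om = om, al = al, p = p, v = v, a = a,
                         cth = cth, sth = sth,
                         com = cbind(p[, 1] + c1, p[, 2] + c2),
                         acom = cbind(a[, 1] - al * c2 - om^2 * c1,
                                      a[, 2] + al * c1 - om^2 * c2))
  }
  ks
}

# Vectorized contact forces: per sphere, world force (n x 2), application
# point (n x 2) and clearance (n) above ground.
contact_forces_vec <- function(model, ks) {
  cc <- model$contact
  out <- list()
  for (nm in names(model$spheres)) {
    sp <- model$spheres[[nm]]
    k_ <- ks[[sp$segment]]
    c1 <- k_$cth * sp$pos[1] - k_$sth * sp$pos[2]
    c2 <- k_$sth * sp$pos[1] + k_$cth * sp$pos[2]
    ps <- cbind(k_$p[, 1] + c1, k_$p[, 2] + c2)
    vs <- cbind(k_$v[, 1] - k_$om * c2, k_$v[, 2] + k_$om * c1)
    depth <- sp$radius - ps[, 2]
    ds <- smooth_pos(depth, cc$eps)
    vfac <- smooth_pos(1 - cc$c_damp * vs[, 2], 0.1)
    fn <- cc$k * ds^1.5 * vfac
    ft <- -cc$mu * fn * tanh(vs[, 1] / cc$v_smooth)
    out[[nm]] <- list(f = cbind(ft, fn), p = ps, segment = sp$segment,
                      heel = sp$heel, clearance = ps[, 2] - sp$radius)
  }
  out
}

# Vectorized generalized inverse dynamics including gravity and contact:
# the generalized force (n x 10) that actuators + pelvis residuals would
# need to supply, plus heel-sphere clearances (n x 2).
planar_id_vec <- function(model, Q, Qd, Qdd) {
  n <- nrow(Q)
  ks <- planar_kin_vec(model, Q, Qd, Qdd)
  contacts <- contact_forces_vec(model, ks)
  zero2 <- matrix(0, n, 2)
  fext <- lapply(model$segments, function(s) list(f = zero2, n = numeric(n)))
  for (ct in contacts) {
    s <- ct$segment
    fext[[s]]$f <- fext[[s]]$f + ct$f
    r1 <- ct$p[, 1] - ks[[s]]$com[, 1]
    r2 <- ct$p[, 2] - ks[[s]]$com[, 2]
    fext[[s]]$n <- fext[[s]]$n + r1 * ct$f[, 2] - r2 * ct$f[, 1]
  }
  Fb <- list(); Nb <- list()
  for (s in model$segments) {
    nm <- s$name
    Fb[[nm]] <- cbind(s$m * ks[[nm]]$acom[, 1] - fext[[nm]]$f[, 1],
                      s$m * ks[[nm]]$acom[, 2] + s$m * GRAVITY -
                        fext[[nm]]$f[, 2])
    Nb[[nm]] <- s$I * ks[[nm]]$al - fext[[nm]]$n
  }
  children <- split(names(model$segments)[-1],
                    vapply(model$segments[-1], function(s) s$parent,
                           character(1)))
  fj <- list(); nj <- list()
  for (nm in rev(names(model$segments))) {
    f <- Fb[[nm]]
    r1 <- ks[[nm]]$com[, 1] - ks[[nm]]$p[, 1]
    r2 <- ks[[nm]]$com[, 2] - ks[[nm]]$p[, 2]
    nn <- Nb[[nm]] + r1 * Fb[[nm]][, 2] - r2 * Fb[[nm]][, 1]
    for (ch in children[[nm]] %||% character(0)) {
      d1 <- ks[[ch]]$p[, 1] - ks[[nm]]$p[, 1]
      d2 <- ks[[ch]]$p[, 2] - ks[[nm]]$p[, 2]
      nn <- nn + nj[[ch]] + d1 * fj[[ch]][, 2] - d2 * fj[[ch]][, 1]
      f <- f + fj[[ch]]
    }
    fj[[nm]] <- f
    nj[[nm]] <- nn
  }
  tau <- matrix(0, n, length(model$coords),
                dimnames = list(NULL, model$coords))
  tau[, "pelvis_tx"] <- fj$pelvis[, 1]
  tau[, "pelvis_ty"] <- fj$pelvis[, 2]
  tau[, "pelvis_tilt"] <- nj$pelvis
  joint_seg <- vapply(model$joints, function(j)
    names(which(vapply(model$segments, function(s)
      identical(s$joint_coord, j), logical(1)))), character(1))
  for (j in model$joints) tau[, j] <- nj[[joint_seg[[j]]]]
  heel <- do.call(cbind, lapply(contacts[vapply(contacts, `[[`, logical(1),
                                                "heel")], `[[`, "clearance"))
  list(tau = tau, heel_clearance = heel, contacts = contacts)
}

# Scaled dynamics defect (n x 10): ID(q,qd,qdd) - tau_actuators, forces
# scaled by body weight and torques by body weight x half stature.
planar_dynamics_residual_vec <- function(model, Q, Qd, Qdd, A) {
  id <- planar_id_vec(model, Q, Qd, Qdd)
  np <- length(model$joints)
  tau_app <- (A[, seq_len(np), drop = FALSE] -
              A[, np + seq_len(np), drop = FALSE]) *
    rep(model$tau_max, each = nrow(A))
  r <- id$tau
  r[, model$joints] <- r[, model$joints] - tau_app
  wt <- model$mass * GRAVITY
  scale <- ifelse(grepl("_t[xy]$", model$coords), wt, wt * 0.5 * model$height)
  list(resid = r / rep(scale, each = nrow(r)),
       heel_clearance = id$heel_clearance)
}

# Scalar conveniences used by tests and reporting.
planar_inverse_dynamics <- function(model, q, qd, qdd) {
  id <- planar_id_vec(model, matrix(q, 1), matrix(qd, 1), matrix(qdd, 1))
  stats::setNames(id$tau[1, ], model$coords)
}

contact_forces <- function(model, q, qd = NULL) {
  if (is.null(qd)) qd <- q * 0
  ks <- planar_kin_vec(model, matrix(q, 1), matrix(qd, 1))
  contact_forces_vec(model, ks)
}

#' Pelvis height consistent with ground contact for given joint angles
#'
#' For each frame of a planar pose matrix (pelvis translations ignored),
#' returns the pelvis height that places the lowest contact sphere at its
#' static equilibrium penetration. Used to build dynamically sensible
#' reference motions where the feet stay on the ground.
#'
#' @param model a [planar_model()].
#' @param Q n x 10 matrix of planar coordinates (PLANAR_COORDS order).
#' @return numeric vector of pelvis_ty values (m).
#' @export
consistent_pelvis_height <- function(model, Q) {
  Q0 <- Q
  Q0[, 1:2] <- 0
  ks <- planar_kin_vec(model, Q0)
  lows <- do.call(pmin, lapply(names(model$spheres), function(nm) {
    sp <- model$spheres[[nm]]
    k_ <- ks[[sp$segment]]
    k_$p[, 2] + k_$sth * sp$pos[1] + k_$cth * sp$pos[2]
  }))
  delta <- (model$mass * GRAVITY / (6 * model$contact$k))^(2 / 3)
  model$spheres[[1]]$radius - delta - lows
}

#' Standing pelvis height at static contact equilibrium
#'
#' Pelvis height at which the six contact spheres support body weight in the
#' zero pose (used to build standing references).
#'
#' @param model a [planar_model()].
#' @return pelvis_ty in metres.
#' @export
standing_pelvis_height <- function(model) {
  H <- model$height
  rel <- -(0.245 + 0.245 + 0.025) * H  # sphere center below pelvis origin
  delta <- (model$mass * GRAVITY / (6 * model$contact$k))^(2 / 3)
  model$spheres[[1]]$radius - delta - rel
}
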