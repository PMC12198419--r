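# Model scaling and inverse kinematics: fit a global skeleton scale to a
# static frame, then per-frame joint angles to marker trajectories by
# damped Gauss-Newton weighted nonlinear least squares with analytic
# kinematic Jacobians and warm starts from the previous frame.

# Coordinates that influence at least one of the given markers.
.active_coords <- function(skeleton, markers) {
  co <- skeleton$coordinates
  mt <- skeleton$markers[skeleton$markers$name %in% markers, ]
  # ancestors of each marker's segment
  parent_of <- vapply(skeleton$segments, function(s)
    if (is.na(s$parent)) NA_character_ else s$parent, character(1))
  seg_chain <- function(seg) {
    chain <- character(0)
    while (!is.na(seg)) {
      chain <- c(chain, seg)
      seg <- parent_of[[seg]]
    }
    chain
  }
  segs <- unique(unlist(lapply(unique(mt$segment), seg_chain)))
  which(co$segment %in% segs)
}

# Chain-membership matrix: does active coordinate j influence marker i?
.chain_matrix <- function(skeleton, mt, active) {
  co <- skeleton$coordinates
  ancestors <- function(seg) {
    chain <- character(0)
    while (!is.na(seg)) {
      chain <- c(chain, seg)
      seg <- skeleton$segments[[seg]]$parent
    }
    chain
  }
  anc <- lapply(stats::setNames(nm = unique(mt$segment)), ancestors)
  out <- matrix(FALSE, nrow(mt), length(active))
  for (i in seq_len(nrow(mt)))
    out[i, ] <- co$segment[active] %in% anc[[mt$segment[i]]]
  out
}

# One-frame weighted Gauss-Newton/Levenberg solve.
.ik_frame <- function(skeleton, obs, mk_idx, weights, q, active, reg = 1e-6,
                      q_prev = NULL, max_iter = 60, tol = 1e-12,
                      chain = NULL) {
  co <- skeleton$coordinates
  mt <- skeleton$markers[mk_idx, , drop = FALSE]
  nq <- length(active)
  if (is.null(chain)) chain <- .chain_matrix(skeleton, mt, active)
  if (is.null(q_prev)) q_prev <- q
  sw <- sqrt(rep(weights, each = 3))
  lambda <- 1e-8
  cost_of <- function(qv) {
    fr <- fk_frame(skeleton, qv)
    model <- fk_markers(skeleton, fr, mt$name)
    r <- as.vector(t(obs - model)) * sw
    list(r = r, fr = fr, model = model,
         cost = sum(r^2) + reg * sum((qv[active] - q_prev[active])^2))
  }
  cur <- cost_of(q)
  ran_out <- FALSE
  last_rel <- Inf
  for (iter in seq_len(max_iter)) {
    # analytic Jacobian of stacked (xyz per marker) residuals wrt active coords
    J <- matrix(0, 3 * nrow(mt), nq)
    for (mi in seq_len(nrow(mt))) {
      xw <- cur$model[mi, ]
      rows <- (3 * mi - 2):(3 * mi)
      for (ai in which(chain[mi, ])) {
        ci <- active[ai]
        if (co$kind[ci] == "t") {
          J[rows, ai] <- cur$fr$dof_axis[ci, ]
        } else {
          a <- cur$fr$dof_axis[ci, ]
          p0 <- cur$fr$dof_point[ci, ]
          J[rows, ai] <- c(a[2] * (xw[3] - p0[3]) - a[3] * (xw[2] - p0[2]),
                           a[3] * (xw[1] - p0[1]) - a[1] * (xw[3] - p0[3]),
                           a[1] * (xw[2] - p0[2]) - a[2] * (xw[1] - p0[1]))
        }
      }
    }
    # residual r = sw*(obs - model); d r / d q = -sw * J
    Jw <- -J * sw
    g <- crossprod(Jw, cur$r) + reg * (q[active] - q_prev[active])
    Hk <- crossprod(Jw) + diag(reg, nq)
    improved <- FALSE
    for (k in 1:8) {
      step <- tryCatch(solve(Hk + diag(lambda, nq), -g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      qn <- q
      qn[active] <- pmin(pmax(q[active] + as.vector(step), co$lower[active]),
                         co$upper[active])
      cand <- cost_of(qn)
      if (cand$cost < cur$cost - 1e-16) {
        last_rel <- (cur$cost - cand$cost) / max(cur$cost, 1e-300)
        q <- qn; cur <- cand
        lambda <- max(lambda / 4, 1e-10)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || sum(g^2) < tol) break
    ran_out <- iter == max_iter
  }
  # a stalled line search or a vanishing cost decrease marks a stationary
  # point; only running out of iterations while still descending counts as
  # an optimizer failure
  list(q = q, residual = sqrt(mean(rowSums((obs - cur$model)^2))),
       converged = !(ran_out && last_rel > 1e-8))
}

#' Solve inverse kinematics for a marker sequence
#'
#' Per-frame minimization of the weighted squared distances between observed
#' and model marker positions over the coordinates that influence the
#' observed markers, warm-started from the previous frame, with a tiny
#' regularization pull toward the previous frame to resolve redundancy.
#'
#' @param skeleton a `skeleton_model` (typically from [scale_to_static()]).
#' @param markers a [motion_sequence()] whose marker names are a subset of the
#'   skeleton's.
#' @param weights optional named per-marker weights (default 1).
#' @param coords optional coordinate subset to solve for; defaults to all
#'   coordinates that influence the observed markers.
#' @param q0 optional named initial coordinates for the first frame.
#' @param max_iter Gauss-Newton iteration cap per frame.
#' @return an object of class `ik_result` with the recovered
#'   [joint_trajectory()], per-frame residuals (m) and the weights used.
#' @export
solve_ik <- function(skeleton, markers, weights = NULL, coords = NULL,
                     q0 = NULL, max_iter = 60) {
  co <- skeleton$coordinates
  mn <- dimnames(markers$positions)[[2]]
  mk_idx <- match(mn, skeleton$markers$name)
  if (anyNA(mk_idx))
    stopf("markers not on skeleton: %s",
          paste(mn[is.na(mk_idx)], collapse = ", "))
  if (length(mn) < 4) stopf("need at least 4 markers for inverse kinematics")
  active <- if (is.null(coords)) .active_coords(skeleton, mn)
            else match(coords, co$name)
  if (anyNA(active)) stopf("unknown coordinate in 'coords'")
  w <- rep(1, length(mn))
  names(w) <- mn
  if (!is.null(weights)) w[names(weights)] <- weights
  n <- dim(markers$positions)[1]
  qmat <- matrix(0, n, nrow(co), dimnames = list(NULL, co$name))
  residual <- numeric(n)
  flagged <- logical(n)
  q <- stats::setNames(rep(0, nrow(co)), co$name)
  if (!is.null(q0)) q[names(q0)] <- q0
  q_prev <- NULL
  chain <- .chain_matrix(skeleton, skeleton$markers[mk_idx, , drop = FALSE],
                         active)
  for (f in seq_len(n)) {
    obs <- matrix(markers$positions[f, , ], ncol = 3)
    sol <- .ik_frame(skeleton, obs, mk_idx, w, q, active, q_prev = q_prev,
                     max_iter = max_iter, chain = chain)
    if (!sol$converged) flagged[f] <- TRUE
    q <- sol$q
    qmat[f, ] <- q
    residual[f] <- sol$residual
    q_prev <- q
  }
  if (any(flagged)) {
    warning(sprintf("inverse kinematics flagged %d non-converged frame(s); interpolated",
                    sum(flagged)))
    ok <- which(!flagged)
    for (j in seq_len(ncol(qmat)))
      qmat[flagged, j] <- stats::approx(ok, qmat[ok, j], xout = which(flagged),
                                        rule = 2)$y
  }
  structure(list(traj = joint_trajectory(markers$rate, co$name, qmat),
                 residual = residual, weights = w, flagged = flagged,
                 active = co$name[active]),
            class = "ik_result")
}

#' @exportS3Method base::print
print.ik_result <- function(x, ...) {
  cat(sprintf("<ik_result> %d frames, %d active coordinates, mean residual %.2f mm\n",
              nrow(x$traj$values), length(x$active), mean(x$residual) * 1000))
  invisible(x)
}

#' Scale a skeleton to a static frame
#'
#' Finds the single global scale factor (with an optimized static pose) that
#' minimizes the squared marker distances to a static calibration frame, in
#' the manner of marker-based model scaling. The returned skeleton never fits
#' the static frame worse than the unscaled skeleton.
#'
#' @param skeleton a `skeleton_model`.
#' @param static_frame named markers x 3 matrix (metres), or a
#'   [motion_sequence()] whose first frame is used.
#' @param interval search interval for the scale factor.
#' @return the scaled `skeleton_model`, with attributes `scale_factor` and
#'   `residual` (m).
#' @export
scale_to_static <- function(skeleton, static_frame, interval = c(0.7, 1.4)) {
  if (inherits(static_frame, "motion_sequence")) {
    sf <- matrix(static_frame$positions[1, , ], ncol = 3)
    rownames(sf) <- dimnames(static_frame$positions)[[2]]
    static_frame <- sf
  }
  mn <- rownames(static_frame)
  if (length(mn) < 4) stopf("static frame is underdetermined (< 4 markers)")
  mk_idx <- match(mn, skeleton$markers$name)
  if (anyNA(mk_idx)) stopf("static frame contains unknown markers")
  active <- .active_coords(skeleton, mn)
  fit_resid <- function(s) {
    sk <- scale_skeleton(skeleton, s)
    q <- stats::setNames(rep(0, nrow(sk$coordinates)), sk$coordinates$name)
    sol <- .ik_frame(sk, static_frame, mk_idx, rep(1, length(mn)), q, active,
                     max_iter = 80)
    sol$residual
  }
  opt <- stats::optimize(fit_resid, interval = interval, tol = 1e-6)
  base <- fit_resid(1.0)
  s_star <- if (opt$objective <= base) opt$minimum else 1.0
  out <- scale_skeleton(skeleton, s_star)
  attr(out, "scale_factor") <- s_star
  attr(out, "residual") <- min(opt$objective, base)
  out
}
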