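# Kinematic accuracy metrics and the generalizability evaluation protocol:
# joint-angle RMSE of keypoint-direct and enhancer-based pipelines against
# reference kinematics from dense anatomical markers, aggregated per
# condition, trial and activity.

#' Per-marker position RMSE between two sequences
#'
#' Root-mean-square of the 3-D error distance over frames for each marker,
#' in millimetres, on non-normalized positions.
#'
#' @param pred,ref [motion_sequence()] objects with aligned frames and
#'   matching marker names.
#' @return list with `per_marker` (tibble: marker, rmse_mm) and `mean_mm`.
#' @export
marker_rmse <- function(pred, ref) {
  mp <- dimnames(pred$positions)[[2]]
  mr <- dimnames(ref$positions)[[2]]
  if (!setequal(mp, mr) || dim(pred$positions)[1] != dim(ref$positions)[1])
    stopf("sequences are not aligned (marker names or frame counts differ)")
  vals <- vapply(mp, function(m)
    sqrt(mean(rowSums((pred$positions[, m, ] - ref$positions[, m, ])^2))) *
      1000,
    numeric(1))
  list(per_marker = tibble::tibble(marker = mp, rmse_mm = unname(vals)),
       mean_mm = mean(vals))
}

#' Per-coordinate kinematics RMSE
#'
#' RMSE per degree of freedom between two joint trajectories; rotations are
#' reported in degrees, pelvis translations in millimetres. Rotation and
#' translation channels are never mixed in one aggregate.
#'
#' @param pred,ref [joint_trajectory()] objects with the same coordinate
#'   ordering and rate.
#' @param dof_set coordinate names to report (default: the 21 analysis
#'   degrees of freedom).
#' @return a `kinematics_report` tibble with columns `dof`, `rmse`, `unit`,
#'   `channel`.
#' @export
kinematics_rmse <- function(pred, ref, dof_set = analysis_dofs()) {
  if (abs(pred$rate - ref$rate) > 1e-9) stopf("sampling rates differ")
  if (nrow(pred$values) != nrow(ref$values)) stopf("frame counts differ")
  missing <- setdiff(dof_set, intersect(pred$coordinates, ref$coordinates))
  if (length(missing)) stopf("coordinates not present: %s",
                             paste(missing, collapse = ", "))
  rows <- lapply(dof_set, function(d) {
    trans <- grepl("_t[xyz]$", d)
    e <- pred$values[, d] - ref$values[, d]
    if (trans)
      tibble::tibble(dof = d, rmse = sqrt(mean(e^2)) * 1000, unit = "mm",
                     channel = "translation")
    else {
      # angular differences are compared on the circle
      e <- (e + pi) %% (2 * pi) - pi
      tibble::tibble(dof = d, rmse = rad2deg(sqrt(mean(e^2))), unit = "deg",
                     channel = "rotation")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kinematics_report", class(out))
  out
}

#' Aggregate kinematics reports over trials and activities
#'
#' Within each activity, per-DOF errors are averaged over trials and then
#' over degrees of freedom; the reported value is the mean over activities
#' (with sd and range across DOFs of the trial-averaged errors). Rotations
#' and translations are aggregated separately.
#'
#' @param reports list of `kinematics_report` tibbles.
#' @param activities character vector, one activity label per report.
#' @return a tibble with one row per channel: mean, sd, min, max and the
#'   per-activity means.
#' @export
summarize_kinematics <- function(reports, activities = NULL) {
  if (is.null(activities)) activities <- rep("all", length(reports))
  stack <- do.call(rbind, Map(function(r, a, i)
    tibble::tibble(activity = a, trial = i, dof = r$dof, rmse = r$rmse,
                   unit = r$unit, channel = r$channel),
    reports, activities, seq_along(reports)))
  out <- list()
  for (ch in unique(stack$channel)) {
    sc <- stack[stack$channel == ch, ]
    per_act <- vapply(split(sc, sc$activity), function(a) {
      # average over trials per DOF, then over DOFs
      per_dof <- tapply(a$rmse, a$dof, mean)
      mean(per_dof)
    }, numeric(1))
    per_dof_all <- tapply(sc$rmse, sc$dof, mean)
    out[[ch]] <- tibble::tibble(
      channel = ch, mean = mean(per_act), sd = stats::sd(per_dof_all),
      min = min(per_dof_all), max = max(per_dof_all),
      unit = sc$unit[1], n_dofs = length(per_dof_all))
  }
  do.call(rbind, out)
}

#' Kinematics-report comparison plot
#'
#' @param object a tibble with columns `condition`, `dof`, `rmse`, `channel`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_condition_rmse <- function(object, ...) {
  df <- object[object$channel == "rotation", ]
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = rmse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "joint-angle RMSE (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# Build a static calibration sequence (zero pose) for a subject variant.
.static_sequence <- function(skeleton, frames = 5) {
  co <- skeleton$coordinates
  traj <- joint_trajectory(60, co$name,
                           matrix(0, frames, nrow(co),
                                  dimnames = list(NULL, co$name)))
  forward_kinematics(skeleton, traj, movement_class = "static")
}

.subset_sequence <- function(seq, markers) {
  motion_sequence(rate = seq$rate,
                  positions = seq$positions[, markers, , drop = FALSE],
                  meta = seq$meta, movement_class = seq$movement_class)
}

#' Run the generalizability evaluation protocol
#'
#' For every sequence of a held-out corpus: compute reference kinematics by
#' inverse kinematics on the noiseless dense anatomical markers, then compare
#' joint kinematics recovered from (a) noiseless keypoints, (b) keypoints
#' with Gaussian noise, and (c) anatomical markers predicted by each supplied
#' enhancer pair from the noisy keypoints. Each condition is preceded by
#' static scaling on a synthetic calibration pose observed under the same
#' condition. Errors if the corpus shares base subjects with an enhancer's
#' training set.
#'
#' @param corpus a held-out `mocap_corpus`.
#' @param enhancers named list of `list(body =, arm =)` trained enhancer
#'   pairs.
#' @param noise_sd keypoint noise sd in metres.
#' @param seed integer seed.
#' @param dof_set coordinates to evaluate (default the 21 analysis DOFs).
#' @param template_height stature of the generic template skeleton that is
#'   scaled per condition.
#' @return a tibble (condition x sequence x DOF RMSE) with a summary
#'   attribute (`attr(x, "summary")`).
#' @export
run_generalizability_protocol <- function(corpus, enhancers = list(),
                                          noise_sd = 0.018, seed = 1,
                                          dof_set = analysis_dofs(),
                                          template_height = 1.70) {
  for (nm in names(enhancers)) {
    tr <- enhancers[[nm]]$body$train_subjects
    overlap <- intersect(tr, corpus$subjects$subject_id)
    if (length(overlap))
      stopf("evaluation corpus overlaps training subjects of '%s': %s", nm,
            paste(overlap, collapse = ", "))
  }
  kp_all <- unique(c(scope_keypoints("body"), scope_keypoints("arm"),
                     "kp_hip_r", "kp_hip_l", "kp_midhip"))
  anat_body <- scope_targets("body")
  rows <- list()
  i <- 0L
  for (id in names(corpus$sequences)) {
    s <- corpus$sequences[[id]]
    i <- i + 1L
    skel_true <- build_default_skeleton(s$meta)
    static_seq <- .static_sequence(skel_true)
    template <- build_default_skeleton(
      subject_meta("template", template_height, 70, 1.0))

    run_condition <- function(markers_seq, static_markers) {
      skel <- scale_to_static(template, static_markers)
      solve_ik(skel, markers_seq)
    }

    # reference: noiseless dense anatomical markers
    ref_ik <- run_condition(.subset_sequence(s, anat_body),
                            .subset_sequence(static_seq, anat_body))

    kp_seq <- .subset_sequence(s, kp_all)
    kp_static <- .subset_sequence(static_seq, kp_all)
    conds <- list()
    conds[["keypoints_no_noise"]] <- run_condition(kp_seq, kp_static)

    kp_noisy <- kp_seq
    kp_noisy$positions <- add_keypoint_noise(kp_seq$positions, noise_sd,
                                             seed = seed * 131L + i)
    kp_static_noisy <- kp_static
    kp_static_noisy$positions <- add_keypoint_noise(kp_static$positions,
                                                    noise_sd,
                                                    seed = seed * 137L + i)
    conds[["keypoints_noise"]] <- run_condition(kp_noisy, kp_static_noisy)

    for (nm in names(enhancers)) {
      en <- enhancers[[nm]]
      pred <- enhance(en$body, en$arm, kp_noisy, s$meta)
      pred_body <- .subset_sequence(pred, anat_body)
      static_pred <- enhance(en$body, en$arm,
                             .pad_static(kp_static_noisy), s$meta)
      conds[[nm]] <- run_condition(pred_body,
                                   .subset_sequence(.first_frames(static_pred, 5),
                                                    anat_body))
    }

    for (cn in names(conds)) {
      rep_ <- kinematics_rmse(conds[[cn]]$traj, ref_ik$traj, dof_set)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(condition = cn, sequence = id,
                       movement_class = s$movement_class,
                       dof = rep_$dof, rmse = rep_$rmse, unit = rep_$unit,
                       channel = rep_$channel)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$condition), function(d) {
    rot <- d[d$channel == "rotation", ]
    tr <- d[d$channel == "translation", ]
    tibble::tibble(condition = d$condition[1],
                   rot_mean_deg = mean(tapply(rot$rmse, rot$dof, mean)),
                   trans_mean_mm = mean(tapply(tr$rmse, tr$dof, mean)))
  }))
  attr(out, "summary") <- summ
  out
}

# The static calibration pose is shorter than one model window; tile it.
.pad_static <- function(seq, frames = WINDOW_FRAMES) {
  n <- dim(seq$positions)[1]
  idx <- rep(seq_len(n), length.out = max(frames, n))
  motion_sequence(rate = seq$rate,
                  positions = seq$positions[idx, , , drop = FALSE],
                  meta = seq$meta, movement_class = seq$movement_class)
}

.first_frames <- function(seq, k) {
  motion_sequence(rate = seq$rate,
                  positions = seq$positions[seq_len(k), , , drop = FALSE],
                  meta = seq$meta, movement_class = seq$movement_class)
}
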