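# Data preparation for enhancer training: resampling to 60 Hz, 1-s windows
# with 50% overlap, root-centering at the hip-keypoint midpoint, height
# normalization, Gaussian keypoint noise, 8-fold rotation augmentation,
# feature standardization, per-subject splits and source balancing.

WINDOW_FRAMES <- 60L
WINDOW_HOP <- 30L

#' Resample a motion sequence to a target rate
#'
#' Linear interpolation of every marker coordinate onto a uniform grid
#' spanning the original duration.
#'
#' @param seq a [motion_sequence()].
#' @param target_rate target sampling rate in Hz.
#' @return the resampled [motion_sequence()].
#' @export
resample_sequence <- function(seq, target_rate = 60) {
  if (target_rate <= 0) stopf("target rate must be positive")
  n <- dim(seq$positions)[1]
  if (n < 2) stopf("sequence too short to resample (needs >= 2 frames)")
  t_old <- (seq_len(n) - 1) / seq$rate
  dur <- t_old[n]
  t_new <- seq(0, dur, by = 1 / target_rate)
  m <- dim(seq$positions)[2]
  out <- array(0, dim = c(length(t_new), m, 3),
               dimnames = list(NULL, dimnames(seq$positions)[[2]],
                               c("x", "y", "z")))
  for (j in seq_len(m)) for (k in 1:3)
    out[, j, k] <- stats::approx(t_old, seq$positions[, j, k],
                                 xout = t_new)$y
  motion_sequence(rate = target_rate, positions = out, meta = seq$meta,
                  movement_class = seq$movement_class)
}

#' Cut a sequence into overlapping fixed-length windows
#'
#' Windows of 1 s (60 frames at 60 Hz) with 50% overlap (hop 30); a trailing
#' remainder shorter than a window is discarded. A sequence shorter than one
#' window yields an empty list.
#'
#' @param seq a [motion_sequence()] at 60 Hz.
#' @param length window length in seconds.
#' @param overlap overlap fraction.
#' @return list of raw windows: each has `positions` (frames x markers x 3)
#'   and `start` (frame index).
#' @export
make_windows <- function(seq, length = 1, overlap = 0.5) {
  wlen <- as.integer(round(length * seq$rate))
  hop <- as.integer(round(wlen * (1 - overlap)))
  n <- dim(seq$positions)[1]
  if (n < wlen) return(list())
  starts <- seq(1L, n - wlen + 1L, by = hop)
  lapply(starts, function(s0)
    list(positions = seq$positions[s0:(s0 + wlen - 1L), , , drop = FALSE],
         start = s0))
}

#' Root-center marker positions at the hip-keypoint midpoint
#'
#' Per frame, the root (midpoint of the two hip keypoints) is subtracted from
#' every marker; the root track is returned so the transform can be inverted.
#'
#' @param positions frames x markers x 3 array with marker dimnames.
#' @param hip_left,hip_right hip keypoint names.
#' @return list with `positions` (centered) and `root_track` (frames x 3).
#' @export
root_center <- function(positions, hip_left = "kp_hip_l",
                        hip_right = "kp_hip_r") {
  mn <- dimnames(positions)[[2]]
  if (!all(c(hip_left, hip_right) %in% mn))
    stopf("hip keypoints '%s'/'%s' missing from positions", hip_left, hip_right)
  root <- (positions[, hip_left, ] + positions[, hip_right, ]) / 2
  root <- matrix(root, ncol = 3)
  centered <- positions
  for (k in 1:3) centered[, , k] <- positions[, , k] - root[, k]
  list(positions = centered, root_track = root)
}

#' Normalize positions by subject height
#'
#' @param positions numeric array or matrix of positions (metres).
#' @param height subject stature in metres.
#' @param invert multiply instead of divide (exact inverse).
#' @return positions scaled by `1/height` (or `height`).
#' @export
height_normalize <- function(positions, height, invert = FALSE) {
  if (height <= 0) stopf("height must be positive")
  if (invert) positions * height else positions / height
}

#' Add Gaussian observation noise to keypoint positions
#'
#' Independent zero-mean Gaussian noise per frame, marker and axis, emulating
#' pose-estimation and triangulation error. Deterministic per seed; never
#' applied to target (anatomical) markers.
#'
#' @param positions frames x markers x 3 array (metres).
#' @param sd noise standard deviation in metres (default 0.018 = 18 mm).
#' @param seed integer seed.
#' @return the perturbed array.
#' @export
add_keypoint_noise <- function(positions, sd = 0.018, seed = 1) {
  if (sd < 0) stopf("noise sd must be >= 0")
  if (sd == 0) return(positions)
  with_seed(seed, positions + stats::rnorm(length(positions), 0, sd))
}

# Rotate xyz triplet columns of a frames x (3K) matrix by rotation matrix R.
rotate_triplets <- function(mat, R) {
  K <- ncol(mat) / 3
  out <- mat
  for (k in seq_len(K)) {
    idx <- (3 * k - 2):(3 * k)
    out[, idx] <- mat[, idx] %*% t(R)
  }
  out
}

#' Eight-fold rotation augmentation of a training window
#'
#' Six copies rotated about the vertical (y) axis by 0, 60, ..., 300 degrees
#' and two copies by seeded uniformly random Euler (Z-Y-X) rotations. The same
#' rotation is applied to inputs and targets; height/weight channels are
#' untouched. Inputs must be root-centered.
#'
#' @param window a training window (list with `kp` and `target` matrices of
#'   xyz triplet columns).
#' @param seed integer seed for the two random rotations.
#' @return list of 8 windows, each tagged with its rotation.
#' @export
rotate_augment <- function(window, seed = 1) {
  rots <- lapply(seq(0, 300, by = 60), function(a) rot_y(deg2rad(a)))
  tags <- sprintf("yaw%03d", seq(0, 300, by = 60))
  rnd <- with_seed(seed, list(random_euler_rotation(),
                              random_euler_rotation()))
  rots <- c(rots, rnd)
  tags <- c(tags, "euler1", "euler2")
  lapply(seq_along(rots), function(i) {
    w <- window
    w$kp <- rotate_triplets(window$kp, rots[[i]])
    w$target <- rotate_triplets(window$target, rots[[i]])
    w$rotation <- tags[i]
    w
  })
}

#' Fit feature standardization statistics
#'
#' Per-feature mean and standard deviation of the input (keypoint coordinates
#' plus height and weight channels) and target features, computed over all
#' frames of the supplied (training) windows. Zero-variance features are
#' flagged and given sd 1.
#'
#' @param windows list of training windows (normalized units).
#' @param noise_sd the keypoint noise sd recorded with the statistics.
#' @return an object of class `norm_stats`.
#' @export
fit_norm_stats <- function(windows, noise_sd = 0.018) {
  if (!length(windows)) stopf("no windows supplied")
  xin <- do.call(rbind, lapply(windows, function(w)
    cbind(w$kp, w$height, w$weight)))
  xout <- do.call(rbind, lapply(windows, function(w) w$target))
  sd0 <- function(m) apply(m, 2, stats::sd)
  in_sd <- sd0(xin); out_sd <- sd0(xout)
  flagged <- c(which(in_sd == 0), ncol(xin) + which(out_sd == 0))
  in_sd[in_sd == 0] <- 1; out_sd[out_sd == 0] <- 1
  structure(list(input_mean = colMeans(xin), input_sd = in_sd,
                 target_mean = colMeans(xout), target_sd = out_sd,
                 flagged = flagged, noise_sd = noise_sd),
            class = "norm_stats")
}

#' Standardize (or de-standardize) a training window
#'
#' Affine per-feature transform using training-split statistics. The input
#' matrix gains the height/weight channels; `invert` restores the original
#' window.
#'
#' @param window a training window.
#' @param stats a [fit_norm_stats()] object.
#' @param invert undo the standardization.
#' @return the transformed window; standardized windows carry an `input`
#'   matrix (keypoints + height/weight channels).
#' @export
standardize <- function(window, stats, invert = FALSE) {
  if (!invert) {
    xin <- cbind(window$kp, window$height, window$weight)
    window$input <- sweep(sweep(xin, 2, stats$input_mean), 2,
                          stats$input_sd, "/")
    window$target_raw <- window$target
    window$target <- sweep(sweep(window$target, 2, stats$target_mean), 2,
                           stats$target_sd, "/")
    window$standardized <- TRUE
  } else {
    xin <- sweep(sweep(window$input, 2, stats$input_sd, "*"), 2,
                 stats$input_mean, "+")
    window$kp <- xin[, seq_len(ncol(xin) - 2), drop = FALSE]
    window$target <- sweep(sweep(window$target, 2, stats$target_sd, "*"), 2,
                           stats$target_mean, "+")
    window$standardized <- FALSE
  }
  window
}

#' Split a corpus by base subject
#'
#' All sequences of a base subject (including its five scale variants) land in
#' exactly one split. Subject counts follow the largest-remainder rule with a
#' minimum of one subject per split; assignment is a seeded permutation.
#'
#' @param corpus a `mocap_corpus`.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @return named list of three `mocap_corpus` objects (train, val, test).
#' @export
split_by_subject <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  subj <- corpus$subjects$subject_id
  S <- length(subj)
  if (S < 3) stopf("need at least 3 base subjects to split")
  base <- floor(fractions * S)
  rem <- fractions * S - base
  left <- S - sum(base)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  # minimum one subject per split, taken from the largest split
  while (any(base == 0)) {
    base[which.max(base)] <- max(base) - 1
    base[which(base == 0)[1]] <- 1
  }
  perm <- with_seed(seed, sample(subj))
  groups <- split(perm, rep(c("train", "val", "test"), times = base))
  subset_corpus <- function(ids) {
    keep <- vapply(corpus$sequences, function(s)
      attr(s, "provenance")$base_subject %in% ids, logical(1))
    structure(list(sequences = corpus$sequences[keep],
                   subjects = corpus$subjects[subj %in% ids, , drop = FALSE]),
              class = "mocap_corpus")
  }
  lapply(groups[c("train", "val", "test")], subset_corpus)
}

#' Balance window counts across sources
#'
#' Seeded uniform subsampling of over-represented sources down to their quota;
#' sources under quota are untouched. Quotas >= 1 are absolute window counts;
#' quotas in (0, 1) are proportions of the total input count.
#'
#' @param windows list of training windows (each with a `source` field).
#' @param quotas named numeric vector of per-source quotas.
#' @param seed integer seed.
#' @return the retained windows (a sub-multiset of the input).
#' @export
balance_sources <- function(windows, quotas, seed = 1) {
  if (any(quotas < 0)) stopf("quotas must be non-negative")
  src <- vapply(windows, function(w) w$source %||% "unknown", character(1))
  keep <- rep(TRUE, length(windows))
  total <- length(windows)
  for (s in names(quotas)) {
    idx <- which(src == s)
    cap <- if (quotas[[s]] < 1) floor(quotas[[s]] * total) else quotas[[s]]
    if (length(idx) > cap) {
      drop <- with_seed(seed + utf8ToInt(substr(s, 1, 1)),
                        sample(idx, length(idx) - cap))
      keep[drop] <- FALSE
    }
  }
  windows[keep]
}

# Keypoint orderings per model scope (fixed feature layout).
scope_keypoints <- function(scope) {
  switch(scope,
    body = c("kp_neck", "kp_shoulder_r", "kp_shoulder_l", "kp_hip_r",
             "kp_hip_l", "kp_knee_r", "kp_knee_l", "kp_ankle_r", "kp_ankle_l",
             "kp_heel_r", "kp_heel_l", "kp_bigtoe_r", "kp_bigtoe_l",
             "kp_smalltoe_r", "kp_smalltoe_l"),
    arm = c("kp_neck", "kp_shoulder_r", "kp_shoulder_l", "kp_elbow_r",
            "kp_elbow_l", "kp_wrist_r", "kp_wrist_l"),
    stopf("unknown scope '%s'", scope))
}

scope_targets <- function(scope, marker_table = .default_marker_table()) {
  mt <- marker_table[marker_table$type == "anatomical", ]
  if (scope == "body") mt$name[mt$in_body] else mt$name[mt$in_arm]
}

# Flatten frames x markers x 3 to frames x (3K) for a marker subset.
flatten_markers <- function(positions, markers) {
  n <- dim(positions)[1]
  sub <- positions[, markers, , drop = FALSE]
  matrix(aperm(sub, c(1, 3, 2)), nrow = n,
         dimnames = list(NULL, paste0(rep(markers, each = 3),
                                      c("_x", "_y", "_z"))))
}

#' Build training windows from a corpus
#'
#' Full preparation pipeline for one model scope: resample to 60 Hz,
#' root-center at the hip midpoint, add Gaussian keypoint noise (metric
#' units, inputs only), window (1 s, 50% overlap), rotation-augment 8-fold,
#' and height-normalize. Standardization statistics are fitted separately
#' with [fit_norm_stats()] on the training split only.
#'
#' @param corpus a `mocap_corpus` (or a split from [split_by_subject()]).
#' @param scope `"body"` or `"arm"`.
#' @param noise_sd keypoint noise sd in metres.
#' @param augment apply 8-fold rotation augmentation.
#' @param seed integer seed (noise and random rotations).
#' @return list of training windows (normalized, not yet standardized).
#' @export
make_training_windows <- function(corpus, scope = "body", noise_sd = 0.018,
                                  augment = TRUE, seed = 1) {
  kp_names <- scope_keypoints(scope)
  tg_names <- scope_targets(scope)
  out <- list()
  i <- 0L
  for (id in names(corpus$sequences)) {
    s <- corpus$sequences[[id]]
    if (abs(s$rate - 60) > 1e-9) s <- resample_sequence(s, 60)
    pv <- attr(s, "provenance") %||% list(base_subject = s$meta$subject_id,
                                          source = s$movement_class)
    h <- effective_stature(s$meta)
    rc <- root_center(s$positions)
    kp_all <- rc$positions[, unique(c(kp_names, "kp_hip_r", "kp_hip_l")), ,
                           drop = FALSE]
    i <- i + 1L
    kp_noisy <- add_keypoint_noise(kp_all, sd = noise_sd,
                                   seed = seed * 7919L + i)
    for (w in make_windows(s)) {
      fr <- w$start:(w$start + WINDOW_FRAMES - 1L)
      win <- list(
        kp = flatten_markers(kp_noisy[fr, , , drop = FALSE], kp_names),
        target = flatten_markers(rc$positions[fr, , , drop = FALSE], tg_names),
        root = rc$root_track[fr, , drop = FALSE],
        height = h, weight = s$meta$mass, scope = scope,
        subject = pv$id %||% id, base_subject = pv$base_subject,
        movement_class = s$movement_class, source = pv$source %||%
          s$movement_class, rotation = "none")
      wins <- if (augment) rotate_augment(win, seed = seed * 104729L + i)
              else list(win)
      wins <- lapply(wins, function(ww) {
        ww$kp <- height_normalize(ww$kp, h)
        ww$target <- height_normalize(ww$target, h)
        ww
      })
      out <- c(out, wins)
    }
  }
  out
}

#' Collate standardized windows into training arrays
#'
#' @param windows list of windows from [make_training_windows()].
#' @param stats a [fit_norm_stats()] object.
#' @return list with `x` (N x 60 x F_in), `y` (N x 60 x F_out), `heights`,
#'   `weights`, `subjects` and `stats`.
#' @export
collate_windows <- function(windows, stats) {
  n <- length(windows)
  if (!n) stopf("no windows to collate")
  w1 <- standardize(windows[[1]], stats)
  x <- array(0, dim = c(n, nrow(w1$input), ncol(w1$input)))
  y <- array(0, dim = c(n, nrow(w1$target), ncol(w1$target)))
  heights <- numeric(n); weights <- numeric(n); subjects <- character(n)
  for (i in seq_len(n)) {
    w <- standardize(windows[[i]], stats)
    x[i, , ] <- w$input
    y[i, , ] <- w$target
    heights[i] <- w$height; weights[i] <- w$weight
    subjects[i] <- w$base_subject %||% NA_character_
  }
  list(x = x, y = y, heights = heights, weights = weights,
       subjects = subjects, stats = stats)
}
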