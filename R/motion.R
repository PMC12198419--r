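# Synthetic movement generation: deterministic, seeded coordinate patterns per
# movement class, used to emulate a diverse motion-capture corpus (gait- and
# squat-like periodic patterns, orientation-changing rolling, band-limited
# freestyle motion).

.movement_classes <- c("gait", "squat", "sit_to_stand", "jump", "rolling",
                       "freestyle", "static")

#' Generate a synthetic joint trajectory
#'
#' Produces a deterministic (per seed) joint-coordinate time series for one of
#' the supported movement classes. Gait and squat are periodic patterns,
#' rolling sweeps the root orientation continuously through prone and supine,
#' freestyle is band-limited random motion within the coordinate bounds, and
#' static holds the zero pose. All frames respect the skeleton's coordinate
#' bounds.
#'
#' @param kind movement class (see [motion_sequence()]).
#' @param duration trial duration in seconds.
#' @param rate sampling rate in Hz.
#' @param skeleton a `skeleton_model` (bounds and coordinate set).
#' @param seed integer seed.
#' @return a [joint_trajectory()].
#' @export
generate_motion <- function(kind, duration, rate, skeleton, seed = 1) {
  if (!kind %in% .movement_classes) stopf("unknown movement class '%s'", kind)
  if (duration <= 0 || rate <= 0) stopf("duration and rate must be positive")
  co <- skeleton$coordinates
  n <- max(2L, floor(duration * rate))
  t <- (seq_len(n) - 1) / rate
  q <- matrix(0, n, nrow(co), dimnames = list(NULL, co$name))

  set_ <- function(name, values) q[, name] <<- values
  with_seed(seed, {
    amp_jit <- function(base, rel = 0.15) base * (1 + stats::runif(1, -rel, rel))
    phase <- stats::runif(1, 0, 2 * pi)
    switch(kind,
      static = NULL,
      gait = {
        f <- amp_jit(0.9)          # stride frequency, Hz
        w <- 2 * pi * f
        hf <- amp_jit(0.55)
        set_("hip_flex_r", hf * sin(w * t + phase))
        set_("hip_flex_l", hf * sin(w * t + phase + pi))
        kf <- amp_jit(0.75)
        set_("knee_r", -kf * 0.5 * (1 - cos(w * t + phase + 0.5)))
        set_("knee_l", -kf * 0.5 * (1 - cos(w * t + phase + pi + 0.5)))
        set_("ankle_r", 0.18 * sin(w * t + phase + 1.2))
        set_("ankle_l", 0.18 * sin(w * t + phase + pi + 1.2))
        set_("lumbar_ext", 0.05 * sin(2 * w * t))
        set_("lumbar_rot", 0.10 * sin(w * t + phase))
        set_("shoulder_flex_r", 0.35 * sin(w * t + phase + pi))
        set_("shoulder_flex_l", 0.35 * sin(w * t + phase))
        set_("elbow_r", 0.4 + 0.15 * sin(w * t + phase + pi))
        set_("elbow_l", 0.4 + 0.15 * sin(w * t + phase))
        set_("pelvis_tx", amp_jit(1.2) * t)
        set_("pelvis_ty", 0.02 * sin(2 * w * t + phase))
      },
      squat = {
        period <- 2.0              # one repetition every 2 s
        d <- 0.5 * (1 - cos(2 * pi * t / period))
        set_("hip_flex_r", 1.4 * d); set_("hip_flex_l", 1.4 * d)
        set_("knee_r", -1.9 * d);    set_("knee_l", -1.9 * d)
        set_("ankle_r", 0.35 * d);   set_("ankle_l", 0.35 * d)
        set_("lumbar_ext", -0.25 * d)
        set_("shoulder_flex_r", 0.9 * d); set_("shoulder_flex_l", 0.9 * d)
        set_("pelvis_ty", -0.35 * d)
        set_("pelvis_tx", -0.08 * d)
      },
      sit_to_stand = {
        # seated at t=0, rise over first half, stand for second half
        r <- pmin(1, pmax(0, 2 * t / duration))
        d <- 1 - 0.5 * (1 - cos(pi * pmin(1, r)))
        set_("hip_flex_r", 1.5 * d); set_("hip_flex_l", 1.5 * d)
        set_("knee_r", -1.7 * d);    set_("knee_l", -1.7 * d)
        set_("ankle_r", 0.25 * d);   set_("ankle_l", 0.25 * d)
        set_("lumbar_ext", -0.35 * d)
        set_("pelvis_ty", -0.30 * d)
      },
      jump = {
        # crouch, extend, flight; a kinematic drop-jump-like pattern
        f <- 1 / duration
        d <- pmax(0, sin(2 * pi * f * t))^2
        fl <- pmax(0, sin(2 * pi * f * t - pi))^2
        set_("hip_flex_r", 1.2 * d); set_("hip_flex_l", 1.2 * d)
        set_("knee_r", -1.6 * d);    set_("knee_l", -1.6 * d)
        set_("ankle_r", 0.3 * d - 0.4 * fl)
        set_("ankle_l", 0.3 * d - 0.4 * fl)
        set_("shoulder_flex_r", 1.2 * d); set_("shoulder_flex_l", 1.2 * d)
        set_("pelvis_ty", -0.3 * d + 0.35 * fl)
      },
      rolling = {
        # continuous root rotation sweeping upright -> prone -> supine
        set_("pelvis_pitch", 2 * pi * t / duration + phase * 0)
        set_("pelvis_ty", -0.2)
        set_("hip_flex_r", 0.3 + 0.2 * sin(2 * pi * t / duration))
        set_("hip_flex_l", 0.3 + 0.2 * cos(2 * pi * t / duration))
        set_("knee_r", -0.4 - 0.2 * sin(2 * pi * t / duration))
        set_("knee_l", -0.4 - 0.2 * cos(2 * pi * t / duration))
        set_("shoulder_flex_r", 0.8 + 0.4 * sin(2 * pi * t / duration))
        set_("shoulder_flex_l", 0.8 + 0.4 * cos(2 * pi * t / duration))
        set_("elbow_r", 0.6); set_("elbow_l", 0.6)
      },
      freestyle = {
        for (i in seq_len(nrow(co))) {
          nm <- co$name[i]
          mid <- (co$lower[i] + co$upper[i]) / 2
          half <- (co$upper[i] - co$lower[i]) / 2
          if (co$kind[i] == "t") { mid <- 0; half <- 0.5 }
          # freestyle emulates upright, roughly forward-facing recordings;
          # large orientation changes belong to the rolling class
          if (nm == "pelvis_yaw") half <- 0.5
          if (nm %in% c("pelvis_pitch", "pelvis_roll")) half <- 0.25
          sig <- rep(0, n)
          for (k in 1:4) {
            fk <- stats::runif(1, 0.15, 1.4)
            ak <- stats::runif(1, 0, 1) / k
            ph <- stats::runif(1, 0, 2 * pi)
            sig <- sig + ak * sin(2 * pi * fk * t + ph)
          }
          set_(nm, mid + 0.9 * half * tanh(sig))
        }
      })
  })
  # safety clamp to bounds
  for (i in seq_len(nrow(co)))
    q[, i] <- pmin(pmax(q[, i], co$lower[i]), co$upper[i])
  joint_trajectory(rate, co$name, q)
}

#' Corpus synthesis configuration
#'
#' @param n_subjects number of base subjects.
#' @param movement_mix named numeric vector of class proportions used to draw
#'   trial movement classes.
#' @param trials_per_subject trials per base subject.
#' @param duration trial duration in seconds.
#' @param rate sampling rate in Hz.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(n_subjects, movement_mix, trials_per_subject = 2,
                          duration = 4, rate = 60) {
  if (length(movement_mix) == 0 || sum(movement_mix) <= 0)
    stopf("movement mix must be a non-empty set of positive proportions")
  if (is.null(names(movement_mix)) ||
      !all(names(movement_mix) %in% .movement_classes))
    stopf("movement mix names must be movement classes")
  structure(list(n_subjects = n_subjects,
                 movement_mix = movement_mix / sum(movement_mix),
                 trials_per_subject = trials_per_subject,
                 duration = duration, rate = rate), class = "corpus_config")
}

.scale_grid <- c(0.90, 0.95, 1.00, 1.05, 1.10)

#' Synthesize a motion corpus
#'
#' For each base subject, draws movement trials (classes sampled from the
#' configured mix) and emits the five uniformly scaled subject variants (90,
#' 95, 100, 105, 110 percent), quintupling the corpus. All scale variants of
#' a subject share the same joint trajectories; only the skeleton geometry is
#' scaled. Deterministic per seed.
#'
#' @param config a [corpus_config()].
#' @param seed integer seed.
#' @return an object of class `mocap_corpus`: a list with `sequences` (each a
#'   [motion_sequence()] with provenance attributes) and `subjects`.
#' @export
synthesize_corpus <- function(config, seed = 1) {
  if (!inherits(config, "corpus_config")) config <- do.call(corpus_config, config)
  subjects <- with_seed(seed, {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(config$n_subjects)),
      height = round(stats::runif(config$n_subjects, 1.50, 1.95), 3),
      bmi = round(stats::runif(config$n_subjects, 19, 29), 2)
    )
  })
  subjects$mass <- round(subjects$bmi * subjects$height^2, 1)

  sequences <- list()
  for (si in seq_len(config$n_subjects)) {
    sid <- subjects$subject_id[si]
    classes <- with_seed(seed + 1000L + si, {
      sample(names(config$movement_mix), config$trials_per_subject,
             replace = TRUE, prob = config$movement_mix)
    })
    base_meta <- subject_meta(sid, subjects$height[si], subjects$mass[si], 1.0)
    base_skel <- build_default_skeleton(base_meta)
    for (ti in seq_along(classes)) {
      traj <- generate_motion(classes[ti], config$duration, config$rate,
                              base_skel, seed = seed * 13L + si * 101L + ti)
      for (sc in .scale_grid) {
        meta <- subject_meta(sid, subjects$height[si],
                             round(subjects$mass[si] * sc^3, 1), sc)
        skel <- build_default_skeleton(meta)
        seqn <- forward_kinematics(skel, traj, movement_class = classes[ti])
        id <- sprintf("%s_x%03d_t%02d_%s", sid, round(sc * 100), ti, classes[ti])
        attr(seqn, "provenance") <- list(id = id, base_subject = sid,
                                         scale = sc, trial = ti,
                                         movement_class = classes[ti],
                                         source = classes[ti])
        sequences[[id]] <- seqn
      }
    }
  }
  structure(list(sequences = sequences, subjects = subjects, config = config,
                 seed = seed), class = "mocap_corpus")
}

#' @exportS3Method base::print
print.mocap_corpus <- function(x, ...) {
  cat(sprintf("<mocap_corpus> %d sequences, %d base subjects x %d scales\n",
              length(x$sequences), nrow(x$subjects), length(.scale_grid)))
  invisible(x)
}

#' Provenance table of a corpus
#'
#' @param corpus a `mocap_corpus`.
#' @return a tibble with one row per sequence.
#' @export
corpus_provenance <- function(corpus) {
  rows <- lapply(corpus$sequences, function(s) {
    pv <- attr(s, "provenance")
    tibble::tibble(id = pv$id, base_subject = pv$base_subject,
                   scale = pv$scale, trial = pv$trial,
                   movement_class = pv$movement_class,
                   frames = dim(s$positions)[1])
  })
  do.call(rbind, rows)
}
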