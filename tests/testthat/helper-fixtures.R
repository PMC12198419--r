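# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_skeleton <- function(height = 1.75, mass = 70, scale = 1.0) {
  build_default_skeleton(subject_meta("T1", height, mass, scale))
}

# Small corpus reused across preprocessing/evaluation tests.
fx_corpus <- function() {
  if (is.null(.fx$corpus))
    .fx$corpus <- synthesize_corpus(
      corpus_config(4, c(gait = 0.5, squat = 0.5), trials_per_subject = 1,
                    duration = 2), seed = 7)
  .fx$corpus
}

# A motion sequence with a given frame count (markers carried over from the
# default skeleton, zero-pose constant positions).
fx_sequence <- function(frames, rate = 60) {
  sk <- fx_skeleton()
  q <- matrix(0, frames, nrow(sk$coordinates),
              dimnames = list(NULL, sk$coordinates$name))
  forward_kinematics(sk, joint_trajectory(rate, sk$coordinates$name, q),
                     movement_class = "static")
}

# Minimal trained-enhancer wrapper around an untrained model with identity
# standardization, sufficient for exercising the inference pipeline.
fx_identity_enhancer <- function(cfg, seed = 1) {
  m <- build_enhancer(cfg, seed = seed)
  stats <- structure(list(input_mean = rep(0, cfg$input_width),
                          input_sd = rep(1, cfg$input_width),
                          target_mean = rep(0, cfg$output_width),
                          target_sd = rep(1, cfg$output_width),
                          flagged = integer(0), noise_sd = 0.018),
                     class = "norm_stats")
  structure(list(model = m, config = cfg, stats = stats, val_rmse = NA_real_,
                 seed = seed, train_subjects = character(0)),
            class = "trained_enhancer")
}

expect_max_abs <- function(x, tol) testthat::expect_lt(max(abs(x)), tol)
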