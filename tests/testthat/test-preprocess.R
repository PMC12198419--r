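test_that("resampling preserves duration and is exact on linear signals", {
  s <- fx_sequence(240, rate = 120)
  # linear ramp on one marker
  s$positions[, 1, 1] <- seq(0, 1, length.out = 240)
  r <- resample_sequence(s, 60)
  expect_equal(dim(r$positions)[1], 120)
  expect_equal(r$rate, 60)
  t_new <- (seq_len(120) - 1) / 60
  expect_max_abs(r$positions[, 1, 1] - t_new / (239 / 120), 1e-12)
  s60 <- fx_sequence(60)
  expect_max_abs(resample_sequence(s60, 60)$positions - s60$positions, 1e-12)
  short <- fx_sequence(2)
  short$positions <- short$positions[1, , , drop = FALSE]
  expect_error(resample_sequence(short, 60), "short")
})

test_that("windowing uses hop 30 and discards the remainder", {
  expect_length(make_windows(fx_sequence(60)), 1)
  expect_length(make_windows(fx_sequence(300)), 9)
  expect_length(make_windows(fx_sequence(59)), 0)
  for (n in c(61, 90, 121, 250)) {
    expect_length(make_windows(fx_sequence(n)),
                  max(0, floor((n - 60) / 30) + 1))
  }
  w <- make_windows(fx_sequence(120))
  expect_equal(vapply(w, `[[`, numeric(1), "start"), c(1, 31, 61))
})

test_that("root centering subtracts the hip midpoint and inverts exactly", {
  s <- fx_corpus()$sequences[[2]]
  rc <- root_center(s$positions)
  mid <- (rc$positions[, "kp_hip_l", ] + rc$positions[, "kp_hip_r", ]) / 2
  expect_max_abs(mid, 1e-12)
  # translation invariance
  s2 <- s
  for (k in 1:3) s2$positions[, , k] <- s2$positions[, , k] + c(1, -2, 3)[k]
  rc2 <- root_center(s2$positions)
  expect_max_abs(rc2$positions - rc$positions, 1e-12)
  # inversion round trip
  back <- rc$positions
  for (k in 1:3) back[, , k] <- back[, , k] + rc$root_track[, k]
  expect_max_abs(back - s$positions, 1e-12)
  bad <- s$positions[, 4:10, , drop = FALSE]
  expect_error(root_center(bad), "missing")
})

test_that("height normalization is an exact inverse pair", {
  x <- array(rnorm(300), dim = c(10, 10, 3))
  expect_max_abs(height_normalize(height_normalize(x, 1.83), 1.83,
                                  invert = TRUE) - x, 1e-12)
  expect_identical(height_normalize(x, 1), x)
  expect_error(height_normalize(x, 0), "positive")
})

test_that("keypoint noise has the configured scale and is seeded", {
  x <- array(0, dim = c(40, 20, 3),
             dimnames = list(NULL, paste0("m", 1:20), NULL))
  expect_identical(add_keypoint_noise(x, sd = 0), x)
  a <- add_keypoint_noise(x, 0.018, seed = 5)
  b <- add_keypoint_noise(x, 0.018, seed = 5)
  expect_identical(a, b)
  big <- array(0, dim = c(1200, 30, 3))
  n <- add_keypoint_noise(big, 0.018, seed = 11)
  expect_lt(abs(sd(n) - 0.018) / 0.018, 0.01)  # 1% at >= 1e5 draws
})

test_that("rotation augmentation yields 8 isometric copies", {
  set.seed(4)
  win <- list(kp = matrix(rnorm(60 * 9), 60, 9),
              target = matrix(rnorm(60 * 12), 60, 12),
              height = 1.7, weight = 70)
  aug <- rotate_augment(win, seed = 2)
  expect_length(aug, 8)
  expect_identical(rotate_augment(win, seed = 2)[[8]]$kp, aug[[8]]$kp)
  d0 <- dist(matrix(win$kp[7, ], ncol = 3, byrow = TRUE))
  for (a in aug) {
    expect_max_abs(dist(matrix(a$kp[7, ], ncol = 3, byrow = TRUE)) - d0, 1e-9)
    expect_equal(a$height, win$height)
  }
  # vertical-axis copies leave the y coordinate unchanged
  ycols <- seq(2, 9, by = 3)
  for (i in 1:6) expect_max_abs(aug[[i]]$kp[, ycols] - win$kp[, ycols], 1e-12)
  # the two random rotations generally change it
  expect_gt(max(abs(aug[[7]]$kp[, ycols] - win$kp[, ycols])), 1e-4)
})

test_that("rotation commutes with root centering", {
  s <- fx_corpus()$sequences[[1]]
  R <- markerlift:::rot_y(1.1)
  rot_seq <- s
  n <- dim(s$positions)[1]
  for (f in seq_len(n)) rot_seq$positions[f, , ] <- s$positions[f, , ] %*% t(R)
  a <- root_center(rot_seq$positions)$positions          # rotate then center
  b <- root_center(s$positions)$positions
  for (f in seq_len(n)) b[f, , ] <- b[f, , ] %*% t(R)    # center then rotate
  expect_max_abs(a - b, 1e-12)
})

test_that("standardization uses train statistics and inverts", {
  wins <- make_training_windows(fx_corpus(), "body", noise_sd = 0.01,
                                augment = FALSE, seed = 3)
  stats <- fit_norm_stats(wins)
  std <- lapply(wins, standardize, stats = stats)
  xin <- do.call(rbind, lapply(std, `[[`, "input"))
  pos_cols <- seq_len(ncol(xin) - 2)
  expect_max_abs(colMeans(xin)[pos_cols], 1e-8)
  expect_max_abs(apply(xin[, pos_cols], 2, sd) - 1, 1e-6)
  rt <- standardize(std[[1]], stats, invert = TRUE)
  expect_max_abs(rt$kp - wins[[1]]$kp, 1e-10)
  expect_max_abs(rt$target - wins[[1]]$target, 1e-10)
  # zero-variance feature flagged with sd 1
  degen <- list(list(kp = cbind(rep(0.5, 60), matrix(rnorm(120), 60, 2)),
                     target = matrix(rnorm(180), 60, 3),
                     height = 1.7, weight = 70))
  st1 <- fit_norm_stats(degen)
  expect_true(1 %in% st1$flagged)
  expect_true(all(st1$input_sd > 0))
})

test_that("full normalization round trip reproduces raw positions", {
  s <- fx_corpus()$sequences[[3]]
  h <- effective_stature(s$meta)
  rc <- root_center(s$positions)
  kp <- markerlift:::flatten_markers(rc$positions,
                                     markerlift:::scope_keypoints("body"))
  win <- list(kp = height_normalize(kp[1:60, ], h), target =
                height_normalize(kp[1:60, ], h), height = h, weight = 70)
  stats <- fit_norm_stats(list(win))
  back <- standardize(standardize(win, stats), stats, invert = TRUE)
  raw <- height_normalize(back$kp, h, invert = TRUE)
  expect_max_abs(raw - kp[1:60, ], 1e-9)
})

test_that("per-subject splits keep scale variants together", {
  corp <- synthesize_corpus(
    corpus_config(10, c(gait = 1), trials_per_subject = 1, duration = 1.2),
    seed = 3)
  sp <- split_by_subject(corp, c(0.8, 0.1, 0.1), seed = 1)
  subj <- lapply(sp, function(x) unique(corpus_provenance(x)$base_subject))
  expect_length(subj$train, 8)
  expect_length(subj$val, 1)
  expect_length(subj$test, 1)
  expect_length(intersect(subj$train, subj$val), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$val, subj$test), 0)
  # every variant of a test subject stays in test
  pv <- corpus_provenance(sp$test)
  expect_equal(nrow(pv), 5)
  expect_error(split_by_subject(corp, c(0.8, 0.3, 0.1)), "sum to 1")
})

test_that("source balancing caps over-represented sources only", {
  wins <- lapply(1:30, function(i)
    list(source = if (i <= 25) "gait" else "squat", id = i))
  out <- balance_sources(wins, c(gait = 10), seed = 1)
  src <- vapply(out, `[[`, character(1), "source")
  expect_equal(sum(src == "gait"), 10)
  expect_equal(sum(src == "squat"), 5)
  expect_true(all(vapply(out, `[[`, numeric(1), "id") %in% 1:30))
  expect_length(balance_sources(wins, c(gait = 100), seed = 1), 30)
  expect_error(balance_sources(wins, c(gait = -1)), "non-negative")
})
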