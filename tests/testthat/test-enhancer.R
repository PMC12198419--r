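test_that("enhancer configuration validates widths and hyperparameters", {
  expect_error(enhancer_config("transformer", "body", tf_heads = 3),
               "heads x key size")
  expect_error(enhancer_config("lstm", "body", batch_size = 0), "positive")
  cfg <- enhancer_config("lstm", "arm")
  expect_equal(cfg$input_width, 23L)
  expect_equal(cfg$output_width, 24L)
  expect_equal(cfg$lstm_layers, 5L)
})

test_that("the linear enhancer is a per-frame affine map", {
  cfg <- enhancer_config("linear", "body", input_width = 5, output_width = 4)
  m <- build_enhancer(cfg, seed = 2)
  x <- array(rnorm(3 * 7 * 5), dim = c(3, 7, 5))
  out <- markerlift:::nn_forward(m, x)$out
  for (b in 1:3) for (t in c(1, 7))
    expect_max_abs(out[b, t, ] -
                   (x[b, t, ] %*% m$params$W + m$params$b), 1e-12)
})

test_that("an LSTM with zeroed weights outputs its readout bias", {
  cfg <- enhancer_config("lstm", "body", lstm_layers = 2, lstm_units = 8,
                         input_width = 5, output_width = 3)
  m <- build_enhancer(cfg, seed = 1)
  m$params <- markerlift:::tree_map(function(p) p * 0, m$params)
  m$params$readout$b <- c(1, -2, 3)
  out <- markerlift:::nn_forward(m, array(rnorm(60), dim = c(2, 2, 5)))$out
  for (b in 1:2) for (t in 1:2)
    expect_equal(unname(out[b, t, ]), c(1, -2, 3))
})

test_that("the transformer is frame-permutation sensitive", {
  cfg <- enhancer_config("transformer", "body", tf_embed = 16, tf_ff = 32,
                         tf_layers = 1, tf_heads = 2, tf_key_size = 8,
                         input_width = 5, output_width = 3)
  m <- build_enhancer(cfg, seed = 3)
  set.seed(1)
  x <- array(rnorm(1 * 6 * 5), dim = c(1, 6, 5))
  xp <- x[, c(3, 1, 2, 6, 4, 5), , drop = FALSE]
  out <- markerlift:::nn_forward(m, x)$out
  outp <- markerlift:::nn_forward(m, xp)$out
  # identical frame content, different order: the positional encoding makes
  # the outputs differ even on matching frames
  expect_gt(max(abs(out[1, 1, ] - outp[1, 2, ])), 1e-6)
})

test_that("weighted MSE matches hand computations and bounds plain MSE", {
  p <- array(rnorm(2 * 4 * 6), dim = c(2, 4, 6))
  expect_equal(weighted_mse(p, p), 0)
  q <- p + rnorm(length(p))
  expect_equal(weighted_mse(p, q), mean((p - q)^2))
  w <- c(1, 1, 1, 2, 1, 1)
  expect_gte(weighted_mse(p, q, w), weighted_mse(p, q))
  # error on exactly one doubled coordinate in a 1-frame window
  p1 <- array(0, dim = c(1, 1, 6)); q1 <- p1
  q1[1, 1, 4] <- 0.3
  expect_equal(weighted_mse(p1, q1, w), 2 * 0.3^2 / 6)
  expect_equal(weighted_mse(p1, q1, w), 2 * weighted_mse(p1, q1))
  expect_error(weighted_mse(p, q, w[1:3]), "length")
})

test_that("body loss weights double the 18 foot-marker features", {
  w <- loss_weights(enhancer_config("lstm", "body"))
  expect_length(w, 105)
  expect_equal(sum(w == 2), 18)
  tg <- markerlift:::scope_targets("body")
  foot_idx <- which(tg %in% c("cal_r", "mt1_r", "mt5_r",
                              "cal_l", "mt1_l", "mt5_l"))
  expect_true(all(w[as.vector(sapply(foot_idx, function(i)
    (3 * i - 2):(3 * i)))] == 2))
  expect_true(all(loss_weights(enhancer_config("lstm", "arm")) == 1))
})

test_that("backpropagated gradients match central finite differences", {
  configs <- list(
    enhancer_config("linear", "body", input_width = 4, output_width = 3),
    enhancer_config("lstm", "body", lstm_layers = 2, lstm_units = 6,
                    input_width = 4, output_width = 3),
    enhancer_config("transformer", "body", tf_embed = 8, tf_ff = 16,
                    tf_layers = 2, tf_heads = 2, tf_key_size = 4,
                    input_width = 4, output_width = 3))
  for (cfg in configs) {
    m <- build_enhancer(cfg, seed = 4)
    set.seed(9)
    x <- array(rnorm(2 * 5 * 4), dim = c(2, 5, 4))
    y <- array(rnorm(2 * 5 * 3), dim = c(2, 5, 3))
    w <- c(1, 2, 1)
    ga <- unlist(markerlift:::.loss_and_grad(m, x, y, w)$grads,
                 use.names = FALSE)
    pv <- unlist(m$params, use.names = FALSE)
    loss_at <- function(v) {
      m2 <- m
      m2$params <- utils::relist(v, m$params)
      out <- markerlift:::nn_forward(m2, x)$out
      weighted_mse(out, y, w)
    }
    idx <- sort(sample(length(pv), min(50, length(pv))))
    h <- 1e-6
    gn <- vapply(idx, function(j) {
      up <- pv; up[j] <- up[j] + h
      dn <- pv; dn[j] <- dn[j] - h
      (loss_at(up) - loss_at(dn)) / (2 * h)
    }, numeric(1))
    rel <- max(abs(ga[idx] - gn) / pmax(1e-6, abs(gn) + abs(ga[idx])))
    expect_lt(rel, 1e-3)
  }
})

test_that("training stops early and restores the best validation weights", {
  set.seed(2)
  Fin <- 4; Fout <- 3
  W <- matrix(rnorm(Fin * Fout), Fin, Fout)
  x <- array(rnorm(80 * 10 * Fin), dim = c(80, 10, Fin))
  xm <- x; dim(xm) <- c(800, Fin)
  y <- array(xm %*% W, dim = c(80, 10, Fout))
  stats <- structure(list(input_mean = rep(0, Fin), input_sd = rep(1, Fin),
                          target_mean = rep(0, Fout), target_sd = rep(1, Fout),
                          flagged = integer(0), noise_sd = 0),
                     class = "norm_stats")
  mk <- function(i) list(x = x[i, , , drop = FALSE], y = y[i, , , drop = FALSE],
                         heights = rep(1, length(i)), weights = rep(70, length(i)),
                         subjects = rep("s", length(i)), stats = stats)
  cfg <- enhancer_config("linear", "body", input_width = Fin,
                         output_width = Fout, learning_rate = 1e-2,
                         max_epochs = 40, batch_size = 16)
  run <- train_enhancer(build_enhancer(cfg, seed = 1), mk(1:60), mk(61:80),
                        seed = 5)
  h <- run$history
  # best-restoration: the restored epoch has the minimum validation loss
  expect_equal(run$best_epoch, which.min(h$val_loss))
  # early stopping: no more than patience epochs after the best one
  expect_lte(nrow(h), run$best_epoch + cfg$patience)
  expect_error(train_enhancer(build_enhancer(cfg), mk(integer(0)), mk(1:5)),
               "empty")
})

test_that("best-of-two selection uses validation RMSE with seed tie-break", {
  a <- structure(list(val_rmse = 10.1, seed = 1), class = "trained_enhancer")
  b <- structure(list(val_rmse = 9.8, seed = 2), class = "trained_enhancer")
  expect_identical(select_best_of_two(a, b), b)
  b$val_rmse <- 10.1
  expect_identical(select_best_of_two(a, b), a)
  expect_identical(select_best_of_two(b, a), a)
})

test_that("enhance emits 43 markers and is translation-equivariant", {
  body <- fx_identity_enhancer(enhancer_config("lstm", "body",
                                               lstm_layers = 1,
                                               lstm_units = 8), seed = 1)
  arm <- fx_identity_enhancer(enhancer_config("lstm", "arm",
                                              lstm_layers = 1,
                                              lstm_units = 8), seed = 1)
  s <- fx_corpus()$sequences[[1]]
  kp <- motion_sequence(60, s$positions[, marker_names(fx_skeleton(),
                                                       "keypoint"), ,
                                        drop = FALSE],
                        s$meta, s$movement_class)
  out1 <- enhance(body, arm, kp)
  expect_equal(dim(out1$positions)[2], 43)
  expect_equal(dim(out1$positions)[1], dim(kp$positions)[1])
  # determinism
  expect_identical(enhance(body, arm, kp)$positions, out1$positions)
  # exact translation equivariance through root centering
  kp2 <- kp
  for (k in 1:3) kp2$positions[, , k] <- kp2$positions[, , k] + c(2, 1, -3)[k]
  out2 <- enhance(body, arm, kp2)
  for (k in 1:3)
    expect_max_abs(out2$positions[, , k] - out1$positions[, , k] -
                   c(2, 1, -3)[k], 1e-9)
  # errors
  short <- motion_sequence(60, kp$positions[1:30, , , drop = FALSE], s$meta)
  expect_error(enhance(body, arm, short), "short")
  missing <- motion_sequence(60, kp$positions[, 1:10, , drop = FALSE], s$meta)
  expect_error(enhance(body, arm, missing), "missing")
})
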