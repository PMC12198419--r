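# Marker enhancer models: configuration, construction, weighted loss,
# training protocol (Adam, batch 64, early stopping on validation loss,
# best-weight restoration, train-twice-select-best) and full inference from
# raw keypoint sequences to de-normalized anatomical marker trajectories.

#' Enhancer model configuration
#'
#' Defaults reproduce the published architectures: per-frame linear maps,
#' stacked LSTMs (4 body / 5 arm layers of 128 units, single bias vector per
#' gate set), and a 2-block, 4-head transformer encoder (embedding 256,
#' feed-forward 1024, key size 64, fixed sinusoidal positional encoding).
#' Input widths are 47 (body: 15 keypoints x 3 + height + weight) and 23
#' (arm: 7 keypoints x 3 + height + weight); output widths 105 (35 markers)
#' and 24 (8 markers).
#'
#' @param architecture one of `"linear"`, `"lstm"`, `"transformer"`.
#' @param scope `"body"` or `"arm"`.
#' @param lstm_layers,lstm_units LSTM depth and width.
#' @param tf_embed,tf_ff,tf_layers,tf_heads,tf_key_size transformer shape.
#' @param learning_rate Adam learning rate (the transformer uses a warm-up /
#'   inverse-square-root schedule instead).
#' @param batch_size minibatch size.
#' @param patience,min_delta early-stopping settings on validation loss.
#' @param foot_weight loss weight for the three markers on each foot.
#' @param max_epochs safety cap on training epochs.
#' @param input_width,output_width feature widths; derived from `scope` when
#'   omitted.
#' @return an object of class `enhancer_config`.
#' @export
enhancer_config <- function(architecture = c("lstm", "linear", "transformer"),
                            scope = c("body", "arm"),
                            lstm_layers = NULL, lstm_units = 128,
                            tf_embed = 256, tf_ff = 1024, tf_layers = 2,
                            tf_heads = 4, tf_key_size = 64,
                            learning_rate = 6e-5, batch_size = 64,
                            patience = 3, min_delta = 0, foot_weight = 2,
                            max_epochs = 200,
                            input_width = NULL, output_width = NULL) {
  architecture <- match.arg(architecture)
  scope <- match.arg(scope)
  if (is.null(lstm_layers)) lstm_layers <- if (scope == "body") 4L else 5L
  if (is.null(input_width))
    input_width <- if (scope == "body") 47L else 23L
  if (is.null(output_width))
    output_width <- if (scope == "body") 105L else 24L
  cfg <- list(architecture = architecture, scope = scope,
              input_width = as.integer(input_width),
              output_width = as.integer(output_width),
              lstm_layers = as.integer(lstm_layers),
              lstm_units = as.integer(lstm_units),
              tf_embed = as.integer(tf_embed), tf_ff = as.integer(tf_ff),
              tf_layers = as.integer(tf_layers),
              tf_heads = as.integer(tf_heads),
              tf_key_size = as.integer(tf_key_size),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              patience = as.integer(patience), min_delta = min_delta,
              foot_weight = foot_weight, max_epochs = as.integer(max_epochs))
  if (cfg$tf_embed != cfg$tf_heads * cfg$tf_key_size)
    stopf("embedding dimension must equal heads x key size")
  hyper <- unlist(cfg[c("input_width", "output_width", "lstm_layers",
                        "lstm_units", "tf_embed", "tf_ff", "tf_layers",
                        "tf_heads", "tf_key_size", "batch_size", "patience",
                        "foot_weight", "max_epochs")])
  if (any(hyper <= 0)) stopf("hyperparameters must be positive")
  structure(cfg, class = "enhancer_config")
}

#' Build an untrained enhancer model
#'
#' Weight matrices use uniform fan-in initialization under the supplied seed;
#' biases start at zero (layer-norm gains at one).
#'
#' @param config an [enhancer_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `enhancer_model`.
#' @export
build_enhancer <- function(config, seed = 1) {
  params <- with_seed(seed, switch(config$architecture,
    linear = init_linear(config$input_width, config$output_width),
    lstm = init_lstm(config$input_width, config$output_width,
                     config$lstm_layers, config$lstm_units),
    transformer = init_transformer(config$input_width, config$output_width,
                                   config$tf_embed, config$tf_ff,
                                   config$tf_layers, config$tf_heads)))
  structure(list(config = config, params = params, seed = seed),
            class = "enhancer_model")
}

#' Count trainable parameters of an enhancer model
#'
#' Counts every trainable scalar: weight matrices, all biases, and layer-norm
#' gains/offsets. The fixed sinusoidal positional encoding carries no
#' parameters and is excluded by construction.
#'
#' @param model an `enhancer_model` or `trained_enhancer`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "trained_enhancer")) model <- model$model
  as.integer(tree_sum(model$params))
}

#' Per-output-feature loss weights
#'
#' Weight `foot_weight` (default 2) on the nine coordinates of the three
#' markers on each foot, 1 elsewhere. The arm model has no foot markers, so
#' its weights are all 1.
#'
#' @param config an [enhancer_config()].
#' @return numeric vector of length `output_width`.
#' @export
loss_weights <- function(config) {
  w <- rep(1, config$output_width)
  tg <- scope_targets(config$scope)
  if (config$output_width == 3L * length(tg)) {
    mt <- .default_marker_table()
    foot <- mt$name[mt$is_foot]
    for (i in which(tg %in% foot)) w[(3 * i - 2):(3 * i)] <- config$foot_weight
  }
  w
}

#' Weighted mean squared error
#'
#' Mean over all batch elements, frames and output features of
#' `weight * (pred - target)^2`.
#'
#' @param pred,target arrays of matching shape (batch x frames x features or
#'   frames x features).
#' @param weights per-feature weight vector (last dimension).
#' @return scalar loss.
#' @export
weighted_mse <- function(pred, target, weights = NULL) {
  if (!identical(dim(pred), dim(target)) &&
      !identical(length(pred), length(target)))
    stopf("prediction/target shape mismatch")
  err2 <- (pred - target)^2
  nf <- if (is.null(dim(err2))) length(err2) else dim(err2)[length(dim(err2))]
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf) stopf("weights length does not match features")
  if (is.null(dim(err2))) return(mean(err2 * weights))
  d <- dim(err2)
  wfull <- array(rep(weights, each = prod(d[-length(d)])), dim = d)
  mean(err2 * wfull)
}

# Loss and gradient for a standardized batch.
.loss_and_grad <- function(model, xb, yb, w) {
  fw <- nn_forward(model, xb, cache = TRUE)
  err <- fw$out - yb
  d <- dim(err)
  wfull <- array(rep(w, each = d[1] * d[2]), dim = d)
  loss <- mean(err^2 * wfull)
  dout <- 2 * err * wfull / prod(d)
  bw <- nn_backward(model, fw$cache, dout)
  list(loss = loss, grads = bw$grads)
}

.val_loss <- function(model, data, w, batch = 256L) {
  n <- dim(data$x)[1]
  tot <- 0
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    out <- nn_forward(model, data$x[idx, , , drop = FALSE])$out
    err <- out - data$y[idx, , , drop = FALSE]
    d <- dim(err)
    wfull <- array(rep(w, each = d[1] * d[2]), dim = d)
    tot <- tot + sum(err^2 * wfull)
  }
  tot / (n * dim(data$x)[2] * length(w))
}

# RMSE of de-normalized predictions in millimetres.
.val_rmse_mm <- function(model, data, batch = 256L) {
  st <- data$stats
  n <- dim(data$x)[1]
  sse <- 0; cnt <- 0
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    out <- nn_forward(model, data$x[idx, , , drop = FALSE])$out
    tgt <- data$y[idx, , , drop = FALSE]
    d <- dim(out)
    sdf <- array(rep(st$target_sd, each = d[1] * d[2]), dim = d)
    diff <- (out - tgt) * sdf   # means cancel in the difference
    hts <- array(rep(data$heights[idx], d[2] * d[3]), dim = d)
    diff <- diff * hts * 1000
    sse <- sse + sum(diff^2)
    cnt <- cnt + length(diff)
  }
  sqrt(sse / cnt)
}

#' Train an enhancer model
#'
#' Minibatch Adam (batch 64 by default; the transformer uses the warm-up /
#' inverse-square-root learning-rate schedule) with early stopping when the
#' validation loss fails to improve by more than `min_delta` for `patience`
#' consecutive epochs; the best-validation weights are restored. Deterministic
#' per seed.
#'
#' @param model an `enhancer_model` from [build_enhancer()].
#' @param train,val collated datasets from [collate_windows()] sharing the
#'   same [fit_norm_stats()] statistics.
#' @param config optional config override (defaults to the model's).
#' @param seed integer seed (epoch shuffling).
#' @return an object of class `trained_enhancer` with fields `model`,
#'   `stats`, `history`, `val_rmse` (mm) and `seed`.
#' @export
train_enhancer <- function(model, train, val, config = NULL, seed = 1) {
  config <- config %||% model$config
  n <- dim(train$x)[1]
  if (!n) stopf("empty training set")
  w <- loss_weights(config)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  bad <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(seed * 1000L + epoch, sample.int(n))
    tr_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(n, s + config$batch_size - 1L)]
      xb <- train$x[idx, , , drop = FALSE]
      yb <- train$y[idx, , , drop = FALSE]
      lg <- .loss_and_grad(model, xb, yb, w)
      lr <- if (config$architecture == "transformer")
        transformer_lr(state$t + 1L, config$tf_embed) else config$learning_rate
      upd <- adam_step(model$params, lg$grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + lg$loss; nb <- nb + 1L
    }
    vl <- .val_loss(model, val, w)
    history[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / nb,
                          val_loss = vl)
    if (vl < best$loss - config$min_delta) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model$params <- best$params
  hist <- tibble::as_tibble(do.call(rbind, history))
  vr <- .val_rmse_mm(model, val)
  structure(list(model = model, config = config, stats = train$stats,
                 history = hist, val_rmse = vr, best_epoch = best$epoch,
                 seed = seed, train_subjects = unique(train$subjects)),
            class = "trained_enhancer")
}

#' @exportS3Method base::print
print.trained_enhancer <- function(x, ...) {
  cat(sprintf("<trained_enhancer> %s/%s, %d params, val RMSE %.2f mm (epoch %d)\n",
              x$config$architecture, x$config$scope, count_parameters(x),
              x$val_rmse, x$best_epoch))
  invisible(x)
}

#' Select the better of two training runs
#'
#' Returns the run with the lower validation RMSE; ties break to the lower
#' seed. Test data is never consulted.
#'
#' @param run_a,run_b `trained_enhancer` objects sharing data and config.
#' @return the selected `trained_enhancer`.
#' @export
select_best_of_two <- function(run_a, run_b) {
  if (run_b$val_rmse < run_a$val_rmse) return(run_b)
  if (run_a$val_rmse < run_b$val_rmse) return(run_a)
  if (run_a$seed <= run_b$seed) run_a else run_b
}

#' Glance at a trained enhancer
#'
#' One-row tibble summary in the broom style.
#'
#' @param x a `trained_enhancer`.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.trained_enhancer <- function(x, ...) {
  tibble::tibble(architecture = x$config$architecture, scope = x$config$scope,
                 parameters = count_parameters(x), epochs = nrow(x$history),
                 best_epoch = x$best_epoch, val_rmse_mm = x$val_rmse)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Training-history plot
#'
#' @param object a `trained_enhancer`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.trained_enhancer <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss, set = "train"),
              data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss, colour = set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted MSE (standardized units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# Inference windows covering every frame: 50% overlap plus a tail window
# aligned to the last frame when needed.
.inference_starts <- function(n) {
  if (n < WINDOW_FRAMES) stopf("sequence too short: need >= %d frames", WINDOW_FRAMES)
  starts <- seq(1L, n - WINDOW_FRAMES + 1L, by = WINDOW_HOP)
  if (utils::tail(starts, 1) + WINDOW_FRAMES - 1L < n)
    starts <- c(starts, n - WINDOW_FRAMES + 1L)
  starts
}

# Predict de-normalized (root-centered, metric) marker positions for one
# scope from a root-centered keypoint array.
.predict_scope <- function(trained, kp_centered, height, weight) {
  cfg <- trained$config
  st <- trained$stats
  kp_names <- scope_keypoints(cfg$scope)
  n <- dim(kp_centered)[1]
  feats <- flatten_markers(kp_centered, kp_names)
  feats <- height_normalize(feats, height)
  starts <- .inference_starts(n)
  B <- length(starts)
  x <- array(0, dim = c(B, WINDOW_FRAMES, cfg$input_width))
  for (i in seq_len(B)) {
    fr <- starts[i]:(starts[i] + WINDOW_FRAMES - 1L)
    xin <- cbind(feats[fr, , drop = FALSE], height, weight)
    x[i, , ] <- sweep(sweep(xin, 2, st$input_mean), 2, st$input_sd, "/")
  }
  out <- nn_forward(trained$model, x)$out
  acc <- matrix(0, n, cfg$output_width)
  cnt <- numeric(n)
  for (i in seq_len(B)) {
    fr <- starts[i]:(starts[i] + WINDOW_FRAMES - 1L)
    pred <- sweep(sweep(out[i, , ], 2, st$target_sd, "*"), 2,
                  st$target_mean, "+")
    acc[fr, ] <- acc[fr, ] + pred
    cnt[fr] <- cnt[fr] + 1
  }
  height_normalize(acc / cnt, height, invert = TRUE)
}

#' Lift a keypoint sequence to anatomical markers
#'
#' Full inference pipeline: root-center at the hip-keypoint midpoint,
#' height-normalize, standardize, window (1 s, 50% overlap, tail-aligned
#' final window), predict per window with the body and arm models, average
#' overlapping predictions, de-standardize, de-normalize and restore the
#' root track. Output is the 43-marker anatomical set (35 body + 8 arm) at
#' 60 Hz in metres.
#'
#' @param body_model,arm_model `trained_enhancer` objects for the two scopes.
#' @param keypoints a [motion_sequence()] containing the 20 keypoints at 60 Hz.
#' @param meta optional [subject_meta()] (defaults to the sequence's).
#' @return a [motion_sequence()] with 43 anatomical markers.
#' @export
enhance <- function(body_model, arm_model, keypoints, meta = NULL) {
  meta <- meta %||% keypoints$meta
  need <- unique(c(scope_keypoints("body"), scope_keypoints("arm"),
                   "kp_hip_r", "kp_hip_l"))
  if (!all(need %in% dimnames(keypoints$positions)[[2]]))
    stopf("keypoint sequence is missing required keypoints: %s",
          paste(setdiff(need, dimnames(keypoints$positions)[[2]]),
                collapse = ", "))
  n <- dim(keypoints$positions)[1]
  if (n < WINDOW_FRAMES) stopf("sequence too short: need >= %d frames", WINDOW_FRAMES)
  h <- effective_stature(meta)
  rc <- root_center(keypoints$positions)
  body <- .predict_scope(body_model, rc$positions, h, meta$mass)
  arm <- .predict_scope(arm_model, rc$positions, h, meta$mass)
  tg <- c(scope_targets("body"), scope_targets("arm"))
  flat <- cbind(body, arm)
  pos <- aperm(array(flat, dim = c(n, 3, length(tg))), c(1, 3, 2))
  for (k in 1:3) pos[, , k] <- pos[, , k] + rc$root_track[, k]
  dimnames(pos) <- list(NULL, tg, c("x", "y", "z"))
  motion_sequence(rate = keypoints$rate, positions = pos, meta = meta,
                  movement_class = keypoints$movement_class)
}
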