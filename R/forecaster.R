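# Performance-prediction models: uni-/bi-directional LSTM forecasters
# (one-step and autoregressive full-step prediction) plus a linear baseline,
# trained on observed learning-curve prefixes.

FORECASTER_VARIANTS <- c("uni_one_step", "uni_full_step",
                         "bi_one_step", "bi_full_step", "linear_baseline")

#' Specify a learning-curve forecaster
#'
#' Four recurrent variants share one architecture (an LSTM over sliding
#' windows of curve points, each point carrying data ratio, log10 parameter
#' count and Dice) and differ in direction (uni/bi) and prediction mode:
#' one-step predicts the next Dice from actual observed history only, while
#' full-step rolls the model out autoregressively, feeding its own
#' predictions back as inputs. `linear_baseline` ignores the recurrent
#' settings and fits ordinary least squares dsc ~ data_ratio per curve
#' prefix.
#'
#' @param variant One of `r paste(FORECASTER_VARIANTS, collapse = ", ")`.
#' @param window Lookback length (>= 1).
#' @param hidden_size LSTM hidden units (>= 1).
#' @param layers Recurrent layers (only 1 supported).
#' @param lr Adam learning rate.
#' @param epochs Full-batch training epochs.
#' @param input_smoothing Width of the trailing (causal) moving average
#'   applied to the Dice input features (targets are never smoothed); 1
#'   disables smoothing.
#' @param seed Integer seed.
#' @return Object of class `forecaster_spec`.
#' @export
forecaster_spec <- function(variant = "uni_full_step", window = 5L,
                            hidden_size = 64L, layers = 1L, lr = 1e-2,
                            epochs = 500L, input_smoothing = 3L, seed = 0L) {
  variant <- match.arg(variant, FORECASTER_VARIANTS)
  if (window < 1) stop_config("forecaster_spec: window must be >= 1")
  if (hidden_size < 1) stop_config("forecaster_spec: hidden_size must be >= 1")
  if (layers != 1L) stop_config("forecaster_spec: only 1 recurrent layer is supported")
  structure(list(variant = variant, window = as.integer(window),
                 hidden_size = as.integer(hidden_size), layers = 1L,
                 lr = lr, epochs = as.integer(epochs),
                 input_smoothing = as.integer(input_smoothing),
                 seed = as.integer(seed)),
            class = "forecaster_spec")
}

split_curves <- function(curves) {
  key <- interaction(curves$task_id, curves$depth, drop = TRUE)
  lapply(split(seq_len(nrow(curves)), key), function(i) {
    cv <- curves[i, , drop = FALSE]
    cv[order(cv$data_ratio), , drop = FALSE]
  })
}

prefix_length <- function(n, observed_fraction) max(1L, as.integer(round(n * observed_fraction)))

# trailing (causal) moving average: input features are smoothed so that
# teacher-forced training windows look like the smooth windows an
# autoregressive rollout generates; targets are never smoothed
trailing_ma <- function(v, w) {
  if (w <= 1) return(v)
  vapply(seq_along(v), function(i) mean(v[max(1, i - w + 1):i]), numeric(1))
}

# normalized feature row: (ratio, plog in [0,1], dsc)
curve_features <- function(ratio, plog, dsc, norm) {
  p <- if (norm$plog_max > norm$plog_min)
    (plog - norm$plog_min) / (norm$plog_max - norm$plog_min) else 0.5
  cbind(ratio, p, dsc)
}

# ---- LSTM core --------------------------------------------------------------

lstm_init <- function(input_dim, H, seed, bi) {
  with_seed(seed, {
    mk <- function(nr, nc) {
      s <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -s, s), nr, nc)
    }
    cell <- function() {
      b <- rep(0, 4 * H)
      b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      list(Wx = mk(4 * H, input_dim), Wh = mk(4 * H, H), b = b)
    }
    w <- list(fwd = cell())
    if (bi) w$bwd <- cell()
    hd <- if (bi) 2 * H else H
    w$Wy <- mk(1, hd)
    w$by <- -3  # softplus(-3) ~ 0.05: increments start at curve scale
    w
  })
}

# forward over a window batch; X: (W, B, F). Returns final hidden state and
# caches for BPTT.
lstm_fw <- function(cell, X, H) {
  W <- dim(X)[1]; B <- dim(X)[2]
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  cache <- vector("list", W)
  for (t in seq_len(W)) {
    xt <- matrix(X[t, , ], B)
    z <- xt %*% t(cell$Wx) + h %*% t(cell$Wh) + rep(cell$b, each = B)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cst + i * g
    cache[[t]] <- list(x = xt, hprev = h, cprev = cst, i = i, f = f, g = g,
                       o = o, c = c_new)
    cst <- c_new
    h <- o * tanh(c_new)
  }
  list(h = h, cache = cache)
}

lstm_bw <- function(cell, cache, dh_final, H) {
  W <- length(cache); B <- nrow(dh_final)
  dWx <- cell$Wx * 0; dWh <- cell$Wh * 0; db <- cell$b * 0
  dh <- dh_final; dc <- matrix(0, B, H)
  for (t in seq(W, 1)) {
    cb <- cache[[t]]
    tc <- tanh(cb$c)
    do <- dh * tc
    dc <- dc + dh * cb$o * (1 - tc^2)
    di <- dc * cb$g; df <- dc * cb$cprev; dg <- dc * cb$i
    dz <- cbind(di * cb$i * (1 - cb$i), df * cb$f * (1 - cb$f),
                dg * (1 - cb$g^2), do * cb$o * (1 - cb$o))
    dWx <- dWx + t(dz) %*% cb$x
    dWh <- dWh + t(dz) %*% cb$hprev
    db <- db + colSums(dz)
    dh <- dz %*% cell$Wh
    dc <- dc * cb$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Residual monotone head: the forecast is the window's last Dice plus a
# softplus-constrained (nonnegative) learned increment. Learning curves are
# non-decreasing in expectation, so a saturated curve defaults to
# persistence and an autoregressive rollout cannot drift downward when
# extrapolating beyond the observed ratio range.
fc_head <- function(w, hf, hb = NULL, last_dsc) {
  h <- if (is.null(hb)) hf else cbind(hf, hb)
  z <- as.numeric(h %*% t(w$Wy) + w$by)
  list(pred = last_dsc + softplus(z), z = z)
}

# one gradient step on the MSE of all windows; returns weights + loss
lstm_epoch <- function(w, X, Xrev, y, H, bi, state, lr) {
  B <- length(y)
  W <- dim(X)[1]
  last_dsc <- X[W, , 3]
  ff <- lstm_fw(w$fwd, X, H)
  fb <- if (bi) lstm_fw(w$bwd, Xrev, H) else NULL
  hd <- fc_head(w, ff$h, if (bi) fb$h else NULL, last_dsc)
  err <- hd$pred - y
  loss <- mean(err^2)
  dz <- matrix(2 * err / B * sigmoid(hd$z), ncol = 1)  # d softplus = sigmoid
  hcat <- if (bi) cbind(ff$h, fb$h) else ff$h
  gWy <- t(dz) %*% hcat
  gby <- sum(dz)
  dh <- dz %*% w$Wy
  gf <- lstm_bw(w$fwd, ff$cache, dh[, 1:H, drop = FALSE], H)
  grads <- list(Wy = gWy, by = gby, fwd.Wx = gf$Wx, fwd.Wh = gf$Wh, fwd.b = gf$b)
  if (bi) {
    gb <- lstm_bw(w$bwd, fb$cache, dh[, (H + 1):(2 * H), drop = FALSE], H)
    grads$bwd.Wx <- gb$Wx; grads$bwd.Wh <- gb$Wh; grads$bwd.b <- gb$b
  }
  flat <- list(Wy = w$Wy, by = w$by, fwd.Wx = w$fwd$Wx, fwd.Wh = w$fwd$Wh,
               fwd.b = w$fwd$b)
  if (bi) { flat$bwd.Wx <- w$bwd$Wx; flat$bwd.Wh <- w$bwd$Wh; flat$bwd.b <- w$bwd$b }
  upd <- adam_step(flat, grads, state, lr)
  w$Wy <- upd$params$Wy; w$by <- upd$params$by
  w$fwd$Wx <- upd$params$fwd.Wx; w$fwd$Wh <- upd$params$fwd.Wh; w$fwd$b <- upd$params$fwd.b
  if (bi) {
    w$bwd$Wx <- upd$params$bwd.Wx; w$bwd$Wh <- upd$params$bwd.Wh; w$bwd$b <- upd$params$bwd.b
  }
  list(w = w, state = upd$state, loss = loss)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a forecaster to the observed prefixes of a curve family
#'
#' Sliding windows of length `spec$window` are drawn jointly from the first
#' `observed_fraction` of every curve; each window of (data ratio, log10
#' parameter count, Dice) feature triples is trained to predict the next
#' Dice value (teacher forcing, full-batch Adam, MSE loss). Bi-directional
#' variants run a second LSTM over the reversed window; no variant ever
#' reads curve values at or beyond the point it is asked to predict.
#'
#' @param curves A `learning_curves` data.frame (multiple depths allowed;
#'   they are trained jointly, with parameter count as a covariate).
#' @param spec A [forecaster_spec()].
#' @param observed_fraction Fraction of each curve treated as observed.
#' @return Object of class `dicecast_forecaster`.
#' @export
fit_forecaster <- function(curves, spec = forecaster_spec(),
                           observed_fraction = 0.5) {
  stopifnot(inherits(spec, "forecaster_spec"))
  cs <- split_curves(curves)
  plog <- log10(pmax(curves$param_count, 1))
  norm <- list(plog_min = min(plog), plog_max = max(plog))
  fc <- structure(list(spec = spec, norm = norm,
                       observed_fraction = observed_fraction),
                  class = "dicecast_forecaster")
  if (spec$variant == "linear_baseline") {
    fc$lines <- lapply(cs, function(cv) {
      P <- prefix_length(nrow(cv), observed_fraction)
      pre <- cv[seq_len(P), ]
      coef(lm(dsc ~ data_ratio, data = pre))
    })
    return(fc)
  }
  W <- spec$window
  xs <- list(); ys <- numeric(0)
  for (nm in names(cs)) {
    cv <- cs[[nm]]
    P <- prefix_length(nrow(cv), observed_fraction)
    if (P < W + 1)
      stop_config("fit_forecaster: curve %s has observed prefix %d < window+1 = %d",
                  nm, P, W + 1)
    dsc_in <- trailing_ma(cv$dsc, spec$input_smoothing)
    feats <- curve_features(cv$data_ratio, log10(pmax(cv$param_count, 1)), dsc_in, norm)
    for (i in seq(W, P - 1)) {
      xs[[length(xs) + 1]] <- feats[(i - W + 1):i, , drop = FALSE]
      ys <- c(ys, cv$dsc[i + 1])
    }
  }
  B <- length(ys)
  X <- array(0, c(W, B, 3))
  for (b in seq_len(B)) X[, b, ] <- xs[[b]]
  Xrev <- X[W:1, , , drop = FALSE]
  bi <- startsWith(spec$variant, "bi")
  H <- spec$hidden_size
  w <- lstm_init(3L, H, spec$seed, bi)
  state <- adam_init(list(Wy = w$Wy, by = w$by, fwd.Wx = w$fwd$Wx,
                          fwd.Wh = w$fwd$Wh, fwd.b = w$fwd$b,
                          bwd.Wx = if (bi) w$bwd$Wx else NULL,
                          bwd.Wh = if (bi) w$bwd$Wh else NULL,
                          bwd.b = if (bi) w$bwd$b else NULL))
  state$m <- state$m[!vapply(state$m, is.null, logical(1))]
  state$v <- state$v[!vapply(state$v, is.null, logical(1))]
  loss <- NA_real_
  for (ep in seq_len(spec$epochs)) {
    r <- lstm_epoch(w, X, Xrev, ys, H, bi, state, spec$lr)
    w <- r$w; state <- r$state; loss <- r$loss
  }
  fc$weights <- w
  fc$train_loss <- loss
  fc
}

# predict the next dsc from a feature window (rows = window steps)
forecaster_step <- function(fc, window_feats) {
  sp <- fc$spec; H <- sp$hidden_size
  bi <- startsWith(sp$variant, "bi")
  X <- array(window_feats, c(nrow(window_feats), 1, 3))
  ff <- lstm_fw(fc$weights$fwd, X, H)
  fb <- if (bi) lstm_fw(fc$weights$bwd, X[nrow(window_feats):1, , , drop = FALSE], H)
  hd <- fc_head(fc$weights, ff$h, if (bi) fb$h else NULL,
                window_feats[nrow(window_feats), 3])
  min(max(hd$pred, 0), 1)
}

#' One-step-ahead Dice prediction
#'
#' Predicts the Dice at position `t` of a curve from the actual observed
#' values at positions `1 .. t-1` only (the last `window` of them).
#'
#' @param fc A fitted [fit_forecaster()] handle.
#' @param curve Single-curve `learning_curves` data.frame, ratio-ascending.
#' @param t Position to predict (needs `t - 1 >= window`).
#' @return Predicted Dice, clamped to \[0, 1\].
#' @export
predict_one_step <- function(fc, curve, t) {
  W <- fc$spec$window
  if (t - 1 < W)
    stop_config("predict_one_step: position %d needs at least %d observed points", t, W)
  if (fc$spec$variant == "linear_baseline")
    return(linear_predict(fc, curve, curve$data_ratio[t]))
  dsc_in <- trailing_ma(curve$dsc[seq_len(t - 1)], fc$spec$input_smoothing)
  feats <- curve_features(curve$data_ratio[seq_len(t - 1)],
                          log10(pmax(curve$param_count[1], 1)), dsc_in, fc$norm)
  forecaster_step(fc, feats[(t - W):(t - 1), , drop = FALSE])
}

#' Autoregressive full-step rollout
#'
#' Starting from an observed prefix, forecasts `horizon` further Dice
#' values; each step's Dice input is the previous prediction while the data
#' ratio (and parameter count) inputs advance along the ladder.
#'
#' @inheritParams predict_one_step
#' @param curve_prefix Observed prefix (>= `window` rows).
#' @param horizon Number of steps to forecast (> 0).
#' @param future_ratios Data ratios of the forecast steps; defaults to
#'   continuing the prefix's arithmetic spacing.
#' @return Numeric vector of length `horizon`, clamped to \[0, 1\].
#' @export
predict_full_step <- function(fc, curve_prefix, horizon, future_ratios = NULL) {
  if (horizon <= 0) stop_config("predict_full_step: horizon must be > 0")
  W <- fc$spec$window
  n <- nrow(curve_prefix)
  if (n < W) stop_config("predict_full_step: prefix length %d < window %d", n, W)
  if (is.null(future_ratios)) {
    step <- if (n >= 2) curve_prefix$data_ratio[n] - curve_prefix$data_ratio[n - 1] else 0.02
    future_ratios <- curve_prefix$data_ratio[n] + step * seq_len(horizon)
  }
  if (fc$spec$variant == "linear_baseline")
    return(vapply(future_ratios, function(r) linear_predict(fc, curve_prefix, r),
                  numeric(1)))
  plog <- log10(pmax(curve_prefix$param_count[1], 1))
  ratios <- c(curve_prefix$data_ratio, future_ratios)
  dscs <- curve_prefix$dsc
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    t <- n + h
    dsc_in <- trailing_ma(dscs, fc$spec$input_smoothing)
    feats <- curve_features(ratios[(t - W):(t - 1)], plog,
                            dsc_in[(t - W):(t - 1)], fc$norm)
    out[h] <- forecaster_step(fc, feats)
    dscs <- c(dscs, out[h])
  }
  out
}

linear_predict <- function(fc, curve, ratio) {
  key <- paste(curve$task_id[1], curve$depth[1], sep = ".")
  ln <- fc$lines[[key]]
  if (is.null(ln)) ln <- coef(lm(dsc ~ data_ratio,
                                 data = curve[seq_len(prefix_length(nrow(curve),
                                   fc$observed_fraction)), ]))
  min(max(ln[1] + ln[2] * ratio, 0), 1)
}

#' Evaluate forecaster variants against held-out curve tails
#'
#' Fits each variant on the observed prefixes, forecasts every point after
#' the prefix (one-step variants with teacher forcing on actual history,
#' full-step variants by autoregressive rollout), and tabulates the mean
#' absolute error (population mean +/- std) per depth plus the cross-depth
#' average over all predicted points.
#'
#' @param curves A `learning_curves` data.frame with >= 1 curve per depth.
#' @param specs List of [forecaster_spec()]s (default: all four recurrent
#'   variants plus the linear baseline).
#' @param observed_fraction Fraction of each curve treated as observed.
#' @return List of per-variant evaluations; each has `variant`, `per_depth`
#'   (data.frame depth, mae_mean, mae_std, n) and `overall`.
#' @export
evaluate_forecasters <- function(curves, specs = NULL, observed_fraction = 0.5) {
  if (is.null(specs))
    specs <- lapply(FORECASTER_VARIANTS, function(v) forecaster_spec(variant = v))
  cs <- split_curves(curves)
  lapply(specs, function(sp) {
    fc <- fit_forecaster(curves, sp, observed_fraction)
    errs <- list()
    for (nm in names(cs)) {
      cv <- cs[[nm]]
      P <- prefix_length(nrow(cv), observed_fraction)
      if (P >= nrow(cv)) next
      idx <- (P + 1):nrow(cv)
      pred <- if (grepl("one_step", sp$variant) || sp$variant == "linear_baseline") {
        vapply(idx, function(t) predict_one_step(fc, cv, t), numeric(1))
      } else {
        predict_full_step(fc, cv[seq_len(P), ], horizon = length(idx),
                          future_ratios = cv$data_ratio[idx])
      }
      errs[[nm]] <- data.frame(depth = cv$depth[1],
                               err = abs(pred - cv$dsc[idx]))
    }
    all <- do.call(rbind, errs)
    per <- do.call(rbind, lapply(split(all, all$depth), function(d)
      data.frame(depth = d$depth[1], mae_mean = mean(d$err),
                 mae_std = sqrt(mean((d$err - mean(d$err))^2)), n = nrow(d))))
    rownames(per) <- NULL
    list(variant = sp$variant, per_depth = per,
         overall = c(mae_mean = mean(all$err),
                     mae_std = sqrt(mean((all$err - mean(all$err))^2)),
                     n = nrow(all)))
  })
}

#' Format forecaster evaluations as a variants-by-depth table
#'
#' Mirrors the usual reporting layout: one row per prediction method, one
#' column per segmentation-model depth plus a cross-depth Average column,
#' entries "mean +/- std" of the absolute error. The spread is the
#' population standard deviation.
#'
#' @param evals Output of [evaluate_forecasters()].
#' @param digits Decimal places.
#' @return A character data.frame.
#' @export
forecast_evaluation_table <- function(evals, digits = 4) {
  depths <- sort(unique(unlist(lapply(evals, function(e) e$per_depth$depth))))
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
  rows <- lapply(evals, function(e) {
    vals <- vapply(depths, function(d) {
      i <- match(d, e$per_depth$depth)
      if (is.na(i)) "-" else fmt(e$per_depth$mae_mean[i], e$per_depth$mae_std[i])
    }, character(1))
    c(setNames(vals, as.character(depths)),
      Average = fmt(e$overall[["mae_mean"]], e$overall[["mae_std"]]))
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- vapply(evals, `[[`, character(1), "variant")
  out
}
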