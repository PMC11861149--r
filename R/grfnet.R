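# The main model: CNN front end + recurrent stack + dense head, trained
# with Adam on mean-squared error. glmnet-style matrix interface.

ARCHITECTURES <- c("xlstm", "slstm", "mlstm", "lstm")

#' Default architecture and training configuration
#'
#' Returns the per-architecture defaults used throughout: the three
#' extended-LSTM variants train with batch size 128, hidden size 64, 25
#' epochs and one stacked layer (the xLSTM stacking an mLSTM block followed
#' by an sLSTM block); the vanilla LSTM uses batch size 256, hidden size
#' 128, 55 epochs and 2 stacked layers. The CNN front end is fixed at
#' kernel size 3 and pool size 2 with 32 filters; the optimizer is Adam at
#' learning rate 1e-3 on MSE loss. All of these can be overridden through
#' [grfnet()] arguments.
#'
#' @param architecture one of `"xlstm"`, `"slstm"`, `"mlstm"`, `"lstm"`.
#' @return named list of defaults.
#' @export
grf_config <- function(architecture = ARCHITECTURES) {
  architecture <- match.arg(architecture)
  base <- list(architecture = architecture, n_filters = 32, kernel_size = 3,
               pool_size = 2, lr = 1e-3, loss = "mse",
               module_order = c("m", "s"))
  if (architecture == "lstm") {
    c(base, list(batch_size = 256, hidden_size = 128, epochs = 55,
                 stacked_layers = 2))
  } else {
    c(base, list(batch_size = 128, hidden_size = 64, epochs = 25,
                 stacked_layers = 1))
  }
}

rec_stack_types <- function(architecture, stacked_layers, module_order) {
  if (architecture == "xlstm") {
    if (!all(module_order %in% c("m", "s"))) {
      stop("module_order must be a sequence over 'm' and 's'", call. = FALSE)
    }
    rep(ifelse(module_order == "m", "mlstm", "slstm"), times = stacked_layers)
  } else {
    rep(architecture, times = stacked_layers)
  }
}

init_grfnet_params <- function(channels, n_points, config) {
  types <- rec_stack_types(config$architecture, config$stacked_layers,
                           config$module_order)
  conv_fan <- config$kernel_size * channels
  params <- list(conv = list(
    W = runif_mat(conv_fan, config$n_filters, 1 / sqrt(conv_fan)),
    b = numeric(config$n_filters)
  ))
  insz <- config$n_filters
  rec <- vector("list", length(types))
  for (l in seq_along(types)) {
    rec[[l]] <- init_rec_layer(types[l], insz, config$hidden_size)
    insz <- config$hidden_size
  }
  params$rec <- rec
  t_pool <- n_points %/% config$pool_size
  dense_fan <- t_pool * config$hidden_size
  params$dense <- list(
    W = runif_mat(dense_fan, n_points, 1 / sqrt(dense_fan)),
    b = numeric(n_points)
  )
  params
}

# X rows are channel-major flattened curves; reshape to (B, channels, T).
x_to_array <- function(x, channels, n_points) {
  B <- nrow(x)
  a <- array(t(x), c(n_points, channels, B))
  aperm(a, c(3, 2, 1))
}

net_forward <- function(params, Xarr, config, want_cache = TRUE) {
  conv <- conv_forward(Xarr, params$conv$W, params$conv$b,
                       activation = "relu", pool_size = config$pool_size,
                       want_cache = want_cache)
  seqs <- list(conv$out)
  fws <- vector("list", length(params$rec))
  for (l in seq_along(params$rec)) {
    fws[[l]] <- rec_layer_forward(params$rec[[l]], seqs[[l]],
                                  want_cache = want_cache)
    seqs[[l + 1]] <- fws[[l]]$h
  }
  top <- seqs[[length(seqs)]]
  B <- dim(top)[1]
  Hmat <- matrix(aperm(top, c(1, 3, 2)), B,
                 dim(top)[2] * dim(top)[3])      # (B, Tp*H), time-major
  pred <- dense_forward(Hmat, params$dense$W, params$dense$b)
  list(pred = pred, conv = conv, fws = fws, seqs = seqs, Hmat = Hmat)
}

net_backward <- function(params, Xarr, fwd, dPred, config) {
  dn <- dense_backward(dPred, fwd$Hmat, params$dense$W)
  top <- fwd$seqs[[length(fwd$seqs)]]
  B <- dim(top)[1]; H <- dim(top)[2]; Tp <- dim(top)[3]
  dTop <- aperm(array(dn$dH, c(B, Tp, H)), c(1, 3, 2))
  grads <- list()
  dH <- dTop
  rec_grads <- vector("list", length(params$rec))
  for (l in rev(seq_along(params$rec))) {
    bw <- rec_layer_backward(params$rec[[l]], fwd$seqs[[l]], fwd$fws[[l]], dH)
    rec_grads[[l]] <- c(list(type = params$rec[[l]]$type), bw$grads)
    dH <- bw$dX
  }
  cb <- conv_backward(dH, fwd$conv$cache, params$conv$W)
  list(conv = list(W = cb$dW, b = cb$db),
       rec = rec_grads,
       dense = list(W = dn$dW, b = dn$db))
}

mse_loss <- function(pred, y) mean((pred - y)^2)

#' Fit a CNN-recurrent network predicting vGRF curves from joint angles
#'
#' Trains one of the four architectures -- `"xlstm"` (mLSTM block followed
#' by an sLSTM block), `"slstm"`, `"mlstm"`, or the vanilla `"lstm"` -- to
#' map time-normalized joint-angle curves to the 101-point stance-phase
#' vGRF curve. The input matrix holds one trial per row, channel-major
#' flattened (each channel's `n_points` values contiguous), as produced by
#' [assemble_designs()]; inputs and targets are expected min-max scaled
#' (see [minmax_fit_transform()] and [cv_grfnet()], which handles the
#' per-fold scaling). Optimization is Adam on MSE with seeded shuffling and
#' initialization, so results are reproducible from `seed`.
#'
#' @param x numeric matrix `n x (channels * n_points)`.
#' @param y numeric matrix `n x n_points` of target curves.
#' @param architecture model family; defaults per [grf_config()].
#' @param epochs,batch_size,hidden_size,stacked_layers,module_order,n_filters,lr
#'   overrides of the architecture defaults.
#' @param validation optional list with `x` and `y`; when given, the test
#'   loss is recorded each epoch alongside the training loss.
#' @param seed integer seed for initialization and shuffling.
#' @param verbose print the loss each epoch.
#' @return an object of class `grfnet` with methods [print()],
#'   [summary()], [coef()], [predict()], [residuals()] and [plot()].
#' @export
grfnet <- function(x, y,
                   architecture = c("xlstm", "slstm", "mlstm", "lstm"),
                   epochs = NULL, batch_size = NULL, hidden_size = NULL,
                   stacked_layers = NULL, module_order = NULL,
                   n_filters = NULL, lr = NULL,
                   validation = NULL, seed = 1, verbose = FALSE) {
  architecture <- match.arg(architecture)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows",
                               call. = FALSE)
  config <- grf_config(architecture)
  for (nm in c("epochs", "batch_size", "hidden_size", "stacked_layers",
               "module_order", "n_filters", "lr")) {
    val <- get(nm)
    if (!is.null(val)) config[[nm]] <- val
  }
  n_points <- ncol(y)
  if (ncol(x) %% n_points != 0) {
    stop("ncol(x) = ", ncol(x), " is not a multiple of the curve length ",
         n_points, call. = FALSE)
  }
  channels <- ncol(x) / n_points
  config$channels <- channels
  config$n_points <- n_points
  config$seed <- seed

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  params <- init_grfnet_params(channels, n_points, config)
  opt <- adam_init(params)
  n <- nrow(x)
  Xval <- if (!is.null(validation))
    x_to_array(as.matrix(validation$x), channels, n_points)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        test_loss = numeric())
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- idx[s:min(s + config$batch_size - 1, n)]
        Xb <- x_to_array(x[rows, , drop = FALSE], channels, n_points)
        yb <- y[rows, , drop = FALSE]
        fwd <- net_forward(params, Xb, config, want_cache = TRUE)
        loss <- mse_loss(fwd$pred, yb)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               "; try a lower learning rate", call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(rows)
        dPred <- 2 * (fwd$pred - yb) / length(yb)
        grads <- net_backward(params, Xb, fwd, dPred, config)
        st <- adam_step(params, grads, opt, lr = config$lr)
        params <- st$params
        opt <- st$state
      }
      test_loss <- NA_real_
      if (!is.null(validation)) {
        pv <- net_forward(params, Xval, config, want_cache = FALSE)$pred
        test_loss <- mse_loss(pv, as.matrix(validation$y))
      }
      history[ep, ] <- list(ep, ep_loss / n, test_loss)
      if (verbose) {
        cat(sprintf("epoch %3d  train %.5f%s\n", ep, ep_loss / n,
                    if (is.na(test_loss)) "" else sprintf("  test %.5f",
                                                          test_loss)))
      }
    }
  }
  fitted_vals <- net_forward(params, x_to_array(x, channels, n_points),
                             config, want_cache = FALSE)$pred
  structure(list(
    params = params, config = config, history = history,
    fitted.values = fitted_vals, y = y,
    call = match.call()
  ), class = "grfnet")
}

#' @export
print.grfnet <- function(x, ...) {
  cfg <- x$config
  types <- vapply(x$params$rec, `[[`, "", "type")
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 0)) else
    if (is.numeric(p)) length(p) else 0
  np <- count(x$params)
  cat(sprintf("CNN-%s vGRF model: %d input channels x %d points -> %d-point curve\n",
              toupper(cfg$architecture), cfg$channels, cfg$n_points,
              cfg$n_points))
  cat(sprintf("  conv(k=%d, %d filters) + pool(%d) -> %s -> dense head; %s parameters\n",
              cfg$kernel_size, cfg$n_filters, cfg$pool_size,
              paste(types, collapse = " -> "), format(np, big.mark = ",")))
  if (nrow(x$history) > 0) {
    cat(sprintf("  trained %d epochs (batch %d, Adam lr %g); final train MSE %.5g\n",
                nrow(x$history), cfg$batch_size, cfg$lr,
                x$history$train_loss[nrow(x$history)]))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.grfnet <- function(object, ...) {
  res <- object$y - object$fitted.values
  out <- list(
    config = object$config,
    history = object$history,
    train_mse = mean(res^2),
    train_r2 = r_squared(object$y, object$fitted.values)
  )
  class(out) <- "summary.grfnet"
  out
}

#' @export
print.summary.grfnet <- function(x, ...) {
  cat(sprintf("CNN-%s fit: train MSE %.5g, per-curve R^2 %.4f over %d epochs\n",
              toupper(x$config$architecture), x$train_mse, x$train_r2,
              nrow(x$history)))
  invisible(x)
}

#' @export
coef.grfnet <- function(object, ...) object$params

#' Predict vGRF curves for new joint-angle inputs
#'
#' @param object a fitted [grfnet()] model.
#' @param newx matrix with the same feature layout as the training `x`.
#' @param ... unused.
#' @return matrix `nrow(newx) x n_points` of predicted curves.
#' @export
predict.grfnet <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  cfg <- object$config
  if (ncol(newx) != cfg$channels * cfg$n_points) {
    stop("newx has ", ncol(newx), " columns; the model was trained with ",
         cfg$channels * cfg$n_points, call. = FALSE)
  }
  net_forward(object$params, x_to_array(newx, cfg$channels, cfg$n_points),
              cfg, want_cache = FALSE)$pred
}

#' @export
residuals.grfnet <- function(object, ...) object$y - object$fitted.values

#' Plot a fitted grfnet model
#'
#' `type = "loss"` draws the per-epoch training (and, when recorded, test)
#' loss; `type = "fit"` overlays the mean observed and mean fitted vGRF
#' curves over stance percent.
#'
#' @param x a fitted [grfnet()] model.
#' @param type `"loss"` or `"fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grfnet <- function(x, type = c("loss", "fit"), ...) {
  type <- match.arg(type)
  if (type == "loss") {
    h <- x$history
    if (nrow(h) == 0) stop("no training history to plot", call. = FALSE)
    graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                   ylab = "MSE loss", ...)
    if (any(is.finite(h$test_loss))) {
      graphics::lines(h$epoch, h$test_loss, lty = 2)
      graphics::legend("topright", legend = c("train", "test"),
                       lty = c(1, 2), bty = "n")
    }
  } else {
    pct <- seq(0, 100, length.out = x$config$n_points)
    graphics::plot(pct, colMeans(x$y), type = "l", xlab = "stance (%)",
                   ylab = "vGRF (scaled)", ...)
    graphics::lines(pct, colMeans(x$fitted.values), lty = 2)
    graphics::legend("topright", legend = c("observed mean", "fitted mean"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
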