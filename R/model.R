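#' @title Feedforward tree-cover regressor
#' @description The 12-400-200-100-50-25-1 ReLU network that maps the twelve
#'   phase-by-band features to percent tree cover, with seeded He
#'   initialization, Adam/MSE training with early stopping, prediction with
#'   clipping to 0-100%, and the annual-maximum-NDVI postprocessing mask.
#' @name model
NULL

#' Network architecture specification
#'
#' @param hidden integer vector of hidden-layer widths; default
#'   `c(400, 200, 100, 50, 25)`.
#' @param input input width (12 features).
#' @param output output width (1, percent tree cover).
#' @return An object of class `ftc_netspec`.
#' @export
network_spec <- function(hidden = c(400L, 200L, 100L, 50L, 25L),
                         input = 12L, output = 1L) {
  widths <- as.integer(c(input, hidden, output))
  if (any(widths < 1)) stop("all layer widths must be >= 1")
  structure(list(input = as.integer(input), hidden = as.integer(hidden),
                 output = as.integer(output), widths = widths,
                 activation = "relu"),
            class = "ftc_netspec")
}

#' Build an untrained network
#'
#' He-normal weight initialization (`sd = sqrt(2 / fan_in)`), zero biases,
#' ReLU between hidden layers, linear output; fully determined by the seed.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the initialization draws.
#' @return An object of class `ftc_network` with weight matrices `W` and
#'   bias vectors `b`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "ftc_netspec"))
  set.seed(as.integer(seed))
  nl <- length(spec$widths) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fin <- spec$widths[l]; fout <- spec$widths[l + 1L]
    W[[l]] <- matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout)
    b[[l]] <- rep(0, fout)
  }
  structure(list(spec = spec, W = W, b = b, seed = as.integer(seed)),
            class = "ftc_network")
}

# forward pass; returns activations per layer when keep_hidden (for backprop)
net_forward <- function(net, X, keep_hidden = FALSE) {
  nl <- length(net$W)
  A <- X
  acts <- if (keep_hidden) vector("list", nl + 1L) else NULL
  if (keep_hidden) acts[[1]] <- A
  for (l in seq_len(nl)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], `+`)
    A <- if (l < nl) pmax(Z, 0) else Z
    if (keep_hidden) acts[[l + 1L]] <- A
  }
  if (keep_hidden) acts else A
}

#' Train the tree-cover network
#'
#' Mean-squared-error loss, Adam optimizer, mini-batches, per-feature z-score
#' standardization (learned from the training rows), targets scaled to
#' `[0, 1]` internally, early stopping on a held-out validation split. All
#' randomness (validation split, batch order) derives from `seed`.
#'
#' @param net an [build_network()] result (its seed is superseded by `seed`
#'   via a fresh initialization when `reinit = TRUE`, the default).
#' @param X numeric matrix `n x 12` of features (or an `ftc_training` whose
#'   data carries the canonical feature columns).
#' @param y numeric vector of targets in percent (ignored when `X` is an
#'   `ftc_training`).
#' @param lr initial Adam learning rate (default 1e-3); halved whenever the
#'   validation loss fails to improve for 3 consecutive epochs (plateau
#'   decay).
#' @param batch_size mini-batch size (default 1024).
#' @param epochs maximum epochs (default 100).
#' @param patience early-stopping patience in epochs (default 5).
#' @param val_frac validation fraction (default 0.1).
#' @param seed integer seed.
#' @param reinit reinitialize weights from `seed` before training.
#' @param verbose print per-epoch losses.
#' @return An object of class `ftc_model`: trained `net`, standardization
#'   `mu`/`sdev`, target scale, `history` (per-epoch train/validation loss),
#'   `seed`.
#' @export
train_network <- function(net, X, y = NULL, lr = 1e-3, batch_size = 1024L,
                          epochs = 100L, patience = 5L, val_frac = 0.1,
                          seed = 1L, reinit = TRUE, verbose = FALSE) {
  if (inherits(X, "ftc_training")) {
    df <- X$data
    y <- df$target
    X <- as.matrix(df[, feature_names(), drop = FALSE])
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 100)
    stop("need at least 100 training rows; generate more (e.g. with ",
         "simulate_scene) before training")
  if (length(y) != n) stop("X and y disagree in length")
  if (ncol(X) != net$spec$input) stop("feature width does not match the network")
  set.seed(as.integer(seed))
  if (reinit) {
    net <- build_network(net$spec, seed = seed)
    set.seed(as.integer(seed))  # split/batch stream independent of init draws
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  y_scale <- 100
  ys <- y / y_scale
  nval <- max(1L, as.integer(floor(val_frac * n)))
  perm <- sample.int(n)
  val_idx <- perm[seq_len(nval)]
  tr_idx <- perm[-seq_len(nval)]
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
  Xval <- Xs[val_idx, , drop = FALSE]; yval <- ys[val_idx]
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr_now <- lr
  best_val <- Inf; best <- net; stall <- 0L
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double())
  ntr <- length(tr_idx)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    tl <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      acts <- net_forward(net, Xb, keep_hidden = TRUE)
      pred <- acts[[nl + 1L]][, 1]
      err <- pred - yb
      tl <- tl + mean(err^2); nb <- nb + 1L
      delta <- matrix(2 * err / length(err), ncol = 1)
      step <- step + 1L
      for (l in nl:1) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        net$W[[l]] <- net$W[[l]] -
          lr_now * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        net$b[[l]] <- net$b[[l]] -
          lr_now * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    val_pred <- net_forward(net, Xval)[, 1]
    vl <- mean((val_pred - yval)^2)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = tl / nb, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d train %.5f val %.5f", ep, tl / nb, vl))
    if (vl < best_val - 1e-9) {
      best_val <- vl; best <- net; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall %% 3L == 0L) lr_now <- lr_now / 2  # plateau decay
      if (stall >= patience) break
    }
  }
  structure(list(net = best, mu = mu, sdev = sdev, y_scale = y_scale,
                 history = history, seed = as.integer(seed),
                 spec = net$spec),
            class = "ftc_model")
}

#' Predict percent tree cover
#'
#' Applies the stored standardization, runs the forward pass, rescales and
#' clips the raw output to `[0, 100]`. Rows with any non-finite feature give
#' NA (fill).
#'
#' @param object an `ftc_model`.
#' @param newdata numeric matrix `n x 12` or a single feature vector.
#' @param ... unused.
#' @return Numeric vector of tree cover percentages.
#' @export
predict.ftc_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$spec$input) stop("feature width does not match the model")
  out <- rep(NA_real_, nrow(X))
  ok <- apply(is.finite(X), 1, all)
  if (any(ok)) {
    Xs <- sweep(sweep(X[ok, , drop = FALSE], 2, object$mu), 2, object$sdev, `/`)
    raw <- net_forward(object$net, Xs)[, 1] * object$y_scale
    out[ok] <- pmin(100, pmax(0, raw))
  }
  out
}

#' Postprocess a predicted cover grid
#'
#' Pixels whose annual maximum NDVI is below `ndvi_threshold` are marked
#' non-tree (0% cover, strict `<` so the boundary keeps its prediction);
#' water and permanent snow/ice pixels become NA (nodata).
#'
#' @param cover matrix of predicted tree cover (%).
#' @param max_ndvi matrix of annual maximum NDVI.
#' @param landcover optional character matrix; `"water"` and `"snow_ice"`
#'   become nodata.
#' @param ndvi_threshold default 0.35.
#' @return The postprocessed cover matrix.
#' @export
postprocess <- function(cover, max_ndvi, landcover = NULL,
                        ndvi_threshold = 0.35) {
  cover <- as.matrix(cover); max_ndvi <- as.matrix(max_ndvi)
  if (!all(dim(cover) == dim(max_ndvi))) stop("grids are not conformable")
  cover[is.finite(max_ndvi) & max_ndvi < ndvi_threshold] <- 0
  if (!is.null(landcover))
    cover[landcover %in% c("water", "snow_ice")] <- NA_real_
  cover
}

#' Save / load a trained model
#'
#' The model file is a self-describing R serialization of the architecture,
#' standardization parameters, weights and training history; a round trip
#' reproduces predictions bit-exactly.
#'
#' @param model an `ftc_model`.
#' @param path file path.
#' @return `load_ftc_model` returns the `ftc_model`.
#' @export
save_ftc_model <- function(model, path) {
  stopifnot(inherits(model, "ftc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ftc_model
#' @export
load_ftc_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ftc_model"))
  model
}
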