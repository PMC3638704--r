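#' Build balanced training and verification voxel sets
#'
#' Samples half of the lesion-marked voxels (within the body and texture
#' validity masks) uniformly at random, an equal number of non-lesion
#' body-tissue voxels, and splits the pool stratified by class into a
#' training set and a verification set. The two sets are disjoint,
#' class-balanced to within one voxel, differ in total size by at most
#' one voxel, and are fully reproducible from the seed.
#'
#' @param lesion_mask 3D logical array of lesion-marked voxels (the
#'   positive class), non-empty.
#' @param body_mask,validity_mask 3D logical arrays restricting the
#'   sampling universe.
#' @param tex A `texture_maps` object supplying the per-voxel features.
#' @param seed Integer RNG seed.
#' @return List with elements `training` and `verification`, each a
#'   `voxel_set`: linear `coords`, `features` matrix, binary `labels`
#'   (1 = lesion), and the `seed`.
#' @export
build_training_and_verification_sets <- function(lesion_mask, body_mask,
                                                 validity_mask, tex,
                                                 seed = 1L) {
  stop_if_not_mask(lesion_mask, "lesion_mask")
  stop_if_not_mask(body_mask, "body_mask")
  stop_if_not_mask(validity_mask, "validity_mask")
  eligible <- body_mask & validity_mask
  les <- which(lesion_mask & eligible)
  if (!length(les)) stop("lesion mask is empty within the evaluable region")
  tis <- which(eligible & !lesion_mask)
  n_les <- ceiling(length(les) / 2)
  if (length(tis) < n_les)
    stop("not enough non-lesion body voxels to balance the sample")
  with_seed(seed, {
    pick_les <- sample(les, n_les)
    pick_tis <- sample(tis, n_les)
    # stratified split with swapped rounding so both sets stay balanced
    # to within one voxel and equal in size
    n_ver_les <- n_les %/% 2L
    ver <- c(pick_les[seq_len(n_ver_les)],
             pick_tis[seq_len(n_les - n_ver_les) + n_ver_les])
    trn <- setdiff(c(pick_les, pick_tis), ver)
  })
  mk <- function(coords) {
    structure(list(coords = coords,
                   features = texture_feature_matrix(tex, coords),
                   labels = as.integer(lesion_mask[coords]),
                   seed = seed),
              class = "voxel_set")
  }
  list(training = mk(trn), verification = mk(ver))
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d voxels (%d lesion / %d tissue), %d features\n",
              length(x$coords), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$features)))
  invisible(x)
}

#' Neural-network training configuration
#'
#' @param hidden Hidden-layer width (default 15 units, tanh activation;
#'   the output unit is linear).
#' @param max_epochs Upper bound on full-batch epochs.
#' @param patience Early stopping: epochs without verification-MSE
#'   improvement before training halts (best weights are restored).
#' @param learning_rate,momentum Full-batch gradient descent settings;
#'   the learning rate is halved whenever an epoch increases the
#'   training MSE (deterministic bold-driver safeguard).
#' @param seed Seed for the weight initialization.
#' @return An `nn_config` list.
#' @export
nn_config <- function(hidden = 15L, max_epochs = 2000L, patience = 100L,
                      learning_rate = 0.05, momentum = 0.9, seed = 1L) {
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "nn_config")
}

.nn_forward <- function(W1, b1, w2, b2, X) {
  H <- tanh(sweep(X %*% W1, 2L, b1, "+"))
  list(H = H, out = as.vector(H %*% w2) + b2)
}

#' Train the voxel classifier network
#'
#' Fits a one-hidden-layer feedforward network (default 15 tanh units,
#' one linear output) to the 0/1 voxel labels by minimizing the mean
#' squared error with full-batch gradient descent plus momentum.
#' Features are standardized with training-set statistics
#' (zero-variance features are dropped and recorded); training stops
#' early when the verification-set MSE has not improved for `patience`
#' epochs, restoring the best-verification weights. Deterministic given
#' the data and the seed in `config`.
#'
#' @param train,verify `voxel_set`s from
#'   [build_training_and_verification_sets()].
#' @param config An [nn_config()].
#' @return A `dce_nn` model: weights, the feature scaler, the indices of
#'   retained features, and the per-epoch MSE history.
#' @export
train_nn <- function(train, verify, config = nn_config()) {
  stopifnot(inherits(train, "voxel_set"), inherits(verify, "voxel_set"))
  X <- train$features
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite feature values in training set, first offender: ",
         colnames(X)[bad[1L, 2L]])
  if (any(!is.finite(verify$features)))
    stop("non-finite feature values in verification set")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- unname(which(sdv > 0))
  if (!length(keep)) stop("all features have zero variance")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], "/")
  Vs <- sweep(sweep(verify$features[, keep, drop = FALSE], 2L, mu[keep]),
              2L, sdv[keep], "/")
  y <- as.numeric(train$labels)
  yv <- as.numeric(verify$labels)
  p <- length(keep); h <- config$hidden; n <- nrow(Xs)
  with_seed(config$seed, {
    a1 <- sqrt(6 / (p + h)); a2 <- sqrt(6 / (h + 1))
    W1 <- matrix(stats::runif(p * h, -a1, a1), p, h)
    b1 <- numeric(h)
    w2 <- matrix(stats::runif(h, -a2, a2), h, 1L)
    b2 <- 0
  })
  vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0
  lr <- config$learning_rate; lr_max <- 20 * lr
  mom <- config$momentum
  hist_tr <- hist_ve <- numeric(0)
  best <- list(mse = Inf)
  wait <- 0L
  mse_at <- function(W1, b1, w2, b2)
    mean((.nn_forward(W1, b1, w2, b2, Xs)$out - y)^2)
  fw <- .nn_forward(W1, b1, w2, b2, Xs)
  mse_tr <- mean((fw$out - y)^2)
  for (ep in seq_len(config$max_epochs)) {
    err <- fw$out - y
    dout <- matrix(2 * err / n, ncol = 1L)
    gw2 <- t(fw$H) %*% dout
    gb2 <- sum(dout)
    dH <- (dout %*% t(w2)) * (1 - fw$H^2)
    gW1 <- t(Xs) %*% dH
    gb1 <- colSums(dH)
    # momentum step with rollback: if the epoch would raise the training
    # MSE, halve the rate and drop the momentum until it does not
    repeat {
      nW1 <- mom * vW1 - lr * gW1; nb1 <- mom * vb1 - lr * gb1
      nw2 <- mom * vw2 - lr * gw2; nb2 <- mom * vb2 - lr * gb2
      mse_new <- mse_at(W1 + nW1, b1 + nb1, w2 + nw2, b2 + nb2)
      if ((is.finite(mse_new) && mse_new <= mse_tr) || lr < 1e-10) break
      lr <- lr / 2
      vW1 <- vW1 * 0; vb1 <- vb1 * 0; vw2 <- vw2 * 0; vb2 <- 0
    }
    vW1 <- nW1; vb1 <- nb1; vw2 <- nw2; vb2 <- nb2
    W1 <- W1 + vW1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2
    lr <- min(lr * 1.05, lr_max)
    mse_tr <- mse_new
    fw <- .nn_forward(W1, b1, w2, b2, Xs)
    mse_ve <- mean((.nn_forward(W1, b1, w2, b2, Vs)$out - yv)^2)
    hist_tr <- c(hist_tr, mse_tr); hist_ve <- c(hist_ve, mse_ve)
    if (mse_ve < best$mse - 1e-9) {
      best <- list(mse = mse_ve, W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (is.null(best$W1))
    best <- list(mse = hist_ve[1L], W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 epoch = length(hist_tr))
  structure(list(W1 = best$W1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
                 feature_names = colnames(X), kept = keep,
                 scaler = list(mean = mu[keep], sd = sdv[keep]),
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_mse = hist_tr,
                                      verification_mse = hist_ve),
                 best_epoch = best$epoch, config = config),
            class = "dce_nn")
}

#' @export
print.dce_nn <- function(x, ...) {
  cat(sprintf("<dce_nn> %d -> %d (tanh) -> 1 (linear); best epoch %d, verification MSE %.4g\n",
              length(x$kept), ncol(x$W1), x$best_epoch,
              min(x$history$verification_mse)))
  invisible(x)
}

#' @export
summary.dce_nn <- function(object, ...) {
  h <- object$history
  cat("Feedforward voxel classifier\n")
  cat(sprintf("  inputs: %d of %d features retained (zero-variance dropped)\n",
              length(object$kept), length(object$feature_names)))
  cat(sprintf("  hidden units: %d (tanh), output: 1 (linear, clipped to [0,1])\n",
              ncol(object$W1)))
  cat(sprintf("  epochs run: %d, best verification MSE %.4g at epoch %d\n",
              nrow(h), min(h$verification_mse), object$best_epoch))
  invisible(object)
}

#' Predict malignancy scores
#'
#' Forward pass of the trained network on standardized features; the
#' linear output is clipped to [0, 1].
#'
#' @param object A `dce_nn` model.
#' @param newdata Feature matrix with the columns the model was trained
#'   on (a `voxel_set` is also accepted).
#' @param ... Unused.
#' @return Numeric vector of scores in [0, 1].
#' @export
predict.dce_nn <- function(object, newdata, ...) {
  if (inherits(newdata, "voxel_set")) newdata <- newdata$features
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$feature_names))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 length(object$feature_names), ncol(newdata)))
  Xs <- sweep(sweep(newdata[, object$kept, drop = FALSE], 2L,
                    object$scaler$mean), 2L, object$scaler$sd, "/")
  clamp01(.nn_forward(object$W1, object$b1, object$w2, object$b2, Xs)$out)
}

#' Voxelwise malignancy score volume
#'
#' Applies the classifier to every voxel inside both the body and
#' texture validity masks; all other voxels score 0.
#'
#' @param model A `dce_nn`.
#' @param tex A `texture_maps` object (the model's feature source).
#' @param body_mask 3D logical array.
#' @return 3D numeric array of scores in [0, 1].
#' @export
predict_scores <- function(model, tex, body_mask) {
  stop_if_not_mask(body_mask, "body_mask")
  scores <- array(0, dim(body_mask))
  vox <- which(body_mask & tex$validity_mask)
  if (length(vox))
    scores[vox] <- predict(model, texture_feature_matrix(tex, vox))
  scores
}

#' Threshold a score volume into a malignancy mask
#'
#' @param scores Numeric array of scores in [0, 1].
#' @param threshold Scalar in (0, 1); voxels with `scores >= threshold`
#'   are classified malignant.
#' @return Logical array.
#' @export
threshold_scores <- function(scores, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  scores >= threshold
}

#' Default classifier decision thresholds
#'
#' The seven operating points swept when reporting voxelwise TPF/FPF:
#' 39%, 49%, 59%, 69%, 78%, 88% and 98% of the network output range.
#'
#' @return Numeric vector of thresholds in (0, 1).
#' @export
default_thresholds <- function() c(0.39, 0.49, 0.59, 0.69, 0.78, 0.88, 0.98)

#' Save or load a trained classifier as portable JSON
#'
#' Serializes the network weights, the feature scaler, the retained
#' feature names and the training configuration to a single JSON file.
#'
#' @param model A `dce_nn`.
#' @param path Destination (for `save_nn_model`) or source (for
#'   `load_nn_model`) file path.
#' @return `save_nn_model()` the path invisibly; `load_nn_model()` the
#'   restored `dce_nn` (training history is not round-tripped).
#' @export
save_nn_model <- function(model, path) {
  stopifnot(inherits(model, "dce_nn"))
  payload <- list(
    W1 = model$W1, b1 = model$b1, w2 = as.vector(model$w2), b2 = model$b2,
    feature_names = model$feature_names, kept = model$kept,
    scaler = model$scaler, best_epoch = model$best_epoch,
    config = unclass(model$config),
    fingerprint = fingerprint(jsonlite::toJSON(unclass(model$config),
                                               auto_unbox = TRUE)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_nn_model
#' @export
load_nn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- length(p$b1)
  structure(list(W1 = matrix(as.numeric(p$W1), ncol = h), b1 = as.numeric(p$b1),
                 w2 = matrix(as.numeric(p$w2), ncol = 1L),
                 b2 = as.numeric(p$b2),
                 feature_names = p$feature_names,
                 kept = as.integer(p$kept),
                 scaler = list(mean = as.numeric(p$scaler$mean),
                               sd = as.numeric(p$scaler$sd)),
                 history = NULL, best_epoch = p$best_epoch,
                 config = do.call(nn_config, as.list(p$config))),
            class = "dce_nn")
}
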