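#' Standardize an intensity volume
#'
#' Subtracts the mean intensity and divides by the standard deviation
#' (population sd over all voxels), the same normalization applied before
#' network training and inference. A constant volume cannot be scaled: it is
#' returned zero-centered (all zeros) with a warning.
#'
#' @param volume numeric 2D/3D array.
#' @return standardized array of the same shape.
#' @export
standardize <- function(volume) {
  volume <- as_vol3d(volume)
  m <- mean(volume)
  s <- sqrt(mean((volume - m)^2))
  if (s < 1e-12) {
    warning("constant volume: standard deviation is zero, returning zeros")
    return(volume - m)
  }
  (volume - m) / s
}

#' Loss configuration
#'
#' The training loss is \code{alpha * BCE + beta_loss * Dice}, where BCE is
#' the mean binary cross-entropy over voxels and the Dice loss is
#' \code{1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)} with
#' smoothing \code{eps = 1e-6}. \code{kind} presets the weights:
#' \code{"bce"} = (1, 0), \code{"dice"} = (0, 1), \code{"bce_dice"} = (1, 1).
#'
#' @param kind one of \code{"bce_dice"}, \code{"bce"}, \code{"dice"}.
#' @param alpha,beta_loss non-negative mixing weights (override the preset).
#' @return an object of class \code{loss_config}.
#' @export
loss_config <- function(kind = c("bce_dice", "bce", "dice"),
                        alpha = NULL, beta_loss = NULL) {
  kind <- match.arg(kind)
  preset <- switch(kind, bce = c(1, 0), dice = c(0, 1), bce_dice = c(1, 1))
  alpha <- if (is.null(alpha)) preset[1] else alpha
  beta_loss <- if (is.null(beta_loss)) preset[2] else beta_loss
  if (alpha < 0 || beta_loss < 0) stop("loss weights must be >= 0")
  if (alpha == 0 && beta_loss == 0) stop("alpha and beta_loss cannot both be 0")
  structure(list(kind = kind, alpha = alpha, beta_loss = beta_loss,
                 eps = 1e-6), class = "loss_config")
}

#' Combined BCE + Dice loss
#'
#' Evaluates \code{alpha * BCE + beta_loss * Dice} between a predicted
#' probability map and a target map of the same shape (see [loss_config()]
#' for the exact form). Probabilities are clamped away from 0/1 before the
#' logarithm.
#'
#' @param pred probability map in (0, 1).
#' @param target target map (binary or soft), same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss value.
#' @export
bce_dice_loss <- function(pred, target, cfg = loss_config("bce_dice")) {
  assert_same_shape(pred, target, "pred/target")
  p <- .clamp(as.numeric(pred), 1e-7, 1 - 1e-7)
  t <- as.numeric(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- 1 - (2 * sum(p * t) + cfg$eps) / (sum(p) + sum(t) + cfg$eps)
  cfg$alpha * bce + cfg$beta_loss * dice
}

# Loss and d(loss)/d(logits) over a batch, computed from logits for numeric
# stability; the Dice term pools over the whole batch.
loss_and_grad <- function(logits, probs, targets, cfg) {
  nvox <- sum(vapply(targets, length, numeric(1)))
  sp <- sum(vapply(probs, sum, numeric(1)))
  st <- sum(vapply(targets, sum, numeric(1)))
  spt <- sum(mapply(function(p, t) sum(p * t), probs, targets))
  num <- 2 * spt + cfg$eps
  den <- sp + st + cfg$eps
  bce <- 0
  for (i in seq_along(logits)) {
    z <- logits[[i]]; t <- targets[[i]]
    # softplus(z) - t*z, stable for large |z|
    bce <- bce + sum(pmax(z, 0) - t * z + log1p(exp(-abs(z))))
  }
  bce <- bce / nvox
  dice <- 1 - num / den
  loss <- cfg$alpha * bce + cfg$beta_loss * dice
  dlogits <- vector("list", length(logits))
  for (i in seq_along(logits)) {
    p <- probs[[i]]; t <- targets[[i]]
    dbce <- (p - t) / nvox
    ddice_dp <- -(2 * t * den - num) / den^2
    dl <- cfg$alpha * dbce + cfg$beta_loss * ddice_dp * p * (1 - p)
    dim(dl) <- dim(p)
    dlogits[[i]] <- dl
  }
  list(loss = loss, bce = bce, dice = dice, dlogits = dlogits)
}

#' Training configuration
#'
#' Optimization follows Adam with \code{beta1 = 0.9}, \code{beta2 = 0.999},
#' L2 weight decay \code{1e-5} and initial learning rate \code{2e-4}; the
#' learning rate is halved (\code{lr_reduction_factor}) whenever the
#' validation score fails to improve for \code{patience} consecutive
#' validations. The validation score is the adjusted Rand error of the
#' segmentation obtained by thresholding the predicted map at
#' \code{validation_delta} and running 6-connected components on the
#' complement; the checkpoint with the lowest validation ARand is returned.
#'
#' @param patch_shape training patch shape (z, y, x).
#' @param patches_per_iteration patches per optimization step.
#' @param max_iterations total optimization steps.
#' @param learning_rate,beta1,beta2,weight_decay Adam settings.
#' @param lr_reduction_factor divisor applied to the learning rate on a
#'   validation plateau.
#' @param patience validations without improvement before the reduction.
#' @param validate_every iterations between validations.
#' @param validation_delta probability threshold for the validation metric.
#' @param loss a [loss_config()].
#' @param augment list of switches: \code{flips}, \code{rot_xy},
#'   \code{elastic}, \code{elastic_alpha}, \code{elastic_grid},
#'   \code{gaussian_sd}, \code{poisson_scale}.
#' @param rng_seed seed controlling sampling and augmentation; training is
#'   deterministic given the seed (single-threaded).
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(patch_shape = c(16L, 16L, 16L),
                         patches_per_iteration = 4L,
                         max_iterations = 300L,
                         learning_rate = 2e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-5,
                         lr_reduction_factor = 2, patience = 3L,
                         validate_every = 50L, validation_delta = 0.4,
                         loss = loss_config("bce_dice"),
                         augment = list(flips = TRUE, rot_xy = TRUE,
                                        elastic = FALSE, elastic_alpha = 2,
                                        elastic_grid = 8L,
                                        gaussian_sd = 0, poisson_scale = 0),
                         rng_seed = 7L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(patch_shape = as.integer(patch_shape),
                 patches_per_iteration = as.integer(patches_per_iteration),
                 max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 lr_reduction_factor = lr_reduction_factor,
                 patience = as.integer(patience),
                 validate_every = as.integer(validate_every),
                 validation_delta = validation_delta,
                 loss = loss, augment = augment,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Apply training augmentations to a patch/target pair
#'
#' Geometric transforms (random y/x flips, random 90-degree rotations in the
#' XY plane, optional grid-based elastic deformation) are applied identically
#' to the patch and its target; intensity noise (additive Gaussian, shot
#' noise) is applied to the patch only. Draws from the current R RNG stream,
#' so results are deterministic under a fixed seed.
#'
#' @param patch intensity patch, dim (z, y, x).
#' @param target matching target patch.
#' @param augment switch list, see [train_config()].
#' @return list with elements \code{patch} and \code{target}.
#' @export
apply_augmentations <- function(patch, target,
                                augment = list(flips = TRUE, rot_xy = TRUE)) {
  assert_same_shape(patch, target, "patch/target")
  a <- function(nm, def = FALSE) if (is.null(augment[[nm]])) def else augment[[nm]]
  d <- dim(patch)
  if (isTRUE(a("flips"))) {
    if (runif(1) < 0.5) { patch <- patch[, rev(seq_len(d[2])), , drop = FALSE]
                          target <- target[, rev(seq_len(d[2])), , drop = FALSE] }
    if (runif(1) < 0.5) { patch <- patch[, , rev(seq_len(d[3])), drop = FALSE]
                          target <- target[, , rev(seq_len(d[3])), drop = FALSE] }
  }
  if (isTRUE(a("rot_xy"))) {
    k <- sample(0:3, 1)
    if (d[2] != d[3]) k <- if (k %% 2 == 1) (k + 1) %% 4 else k
    if (k > 0) {
      patch <- rot90_xy(patch, k)
      target <- rot90_xy(target, k)
    }
  }
  if (isTRUE(a("elastic"))) {
    w <- elastic_field(d, alpha = a("elastic_alpha", 2),
                       grid = a("elastic_grid", 8L))
    patch <- warp_xy(patch, w, order = 1L)
    target <- warp_xy(target, w, order = 0L)
  }
  gsd <- a("gaussian_sd", 0)
  if (gsd > 0) patch <- patch + array(rnorm(length(patch), sd = gsd), d)
  psc <- a("poisson_scale", 0)
  if (psc > 0) {
    lam <- pmax(patch, 0) / psc
    patch <- patch + array(rpois(length(patch), lam) * psc - pmax(patch, 0), d)
  }
  list(patch = patch, target = target)
}

# 90-degree rotation(s) in the (y, x) plane of a (z, y, x) array.
rot90_xy <- function(x, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    x <- aperm(x, c(1L, 3L, 2L))
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  }
  x
}

# Random in-plane displacement field from a coarse Gaussian grid, bilinearly
# upsampled; the same field is used on every z-slice.
elastic_field <- function(d, alpha, grid) {
  gy <- max(2L, ceiling(d[2] / grid) + 1L)
  gx <- max(2L, ceiling(d[3] / grid) + 1L)
  up <- function(g) {
    yy <- seq(1, gy, length.out = d[2])
    xx <- seq(1, gx, length.out = d[3])
    y0 <- pmin(floor(yy), gy - 1L); x0 <- pmin(floor(xx), gx - 1L)
    wy <- yy - y0; wx <- xx - x0
    m00 <- g[cbind(rep(y0, d[3]), rep(x0, each = d[2]))]
    m10 <- g[cbind(rep(y0 + 1, d[3]), rep(x0, each = d[2]))]
    m01 <- g[cbind(rep(y0, d[3]), rep(x0 + 1, each = d[2]))]
    m11 <- g[cbind(rep(y0 + 1, d[3]), rep(x0 + 1, each = d[2]))]
    wy_f <- rep(wy, d[3]); wx_f <- rep(wx, each = d[2])
    matrix(m00 * (1 - wy_f) * (1 - wx_f) + m10 * wy_f * (1 - wx_f) +
           m01 * (1 - wy_f) * wx_f + m11 * wy_f * wx_f, d[2], d[3])
  }
  dy <- up(matrix(rnorm(gy * gx, sd = alpha), gy, gx))
  dx <- up(matrix(rnorm(gy * gx, sd = alpha), gy, gx))
  list(dy = dy, dx = dx)
}

# Warp every z-slice by the in-plane displacement field; order 1 = bilinear,
# order 0 = nearest (labels/targets). Coordinates clamp at the borders.
warp_xy <- function(x, field, order = 1L) {
  d <- dim(x)
  ys <- rep(seq_len(d[2]), d[3]) + as.vector(field$dy)
  xs <- rep(seq_len(d[3]), each = d[2]) + as.vector(field$dx)
  ys <- .clamp(ys, 1, d[2]); xs <- .clamp(xs, 1, d[3])
  out <- x
  if (order == 0L) {
    iy <- round(ys); ix <- round(xs)
    for (z in seq_len(d[1])) {
      sl <- matrix(x[z, , ], d[2], d[3])
      out[z, , ] <- sl[cbind(iy, ix)]
    }
  } else {
    y0 <- pmin(floor(ys), d[2] - 1L); x0 <- pmin(floor(xs), d[3] - 1L)
    wy <- ys - y0; wx <- xs - x0
    for (z in seq_len(d[1])) {
      sl <- matrix(x[z, , ], d[2], d[3])
      v <- sl[cbind(y0, x0)] * (1 - wy) * (1 - wx) +
           sl[cbind(y0 + 1, x0)] * wy * (1 - wx) +
           sl[cbind(y0, x0 + 1)] * (1 - wy) * wx +
           sl[cbind(y0 + 1, x0 + 1)] * wy * wx
      out[z, , ] <- v
    }
  }
  out
}

adam_step <- function(params, grads, opt, lr, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + cfg$weight_decay * params[[nm]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(params = params, opt = opt)
}

# Validation: ARand of thresholded prediction + 6-connected components of the
# non-boundary complement, against the ground-truth labeling.
validation_arand <- function(model, val_set, cfg) {
  icfg <- inference_config(patch_shape = cfg$patch_shape)
  scores <- vapply(val_set, function(v) {
    pred <- predict_tiled(model, standardize(v$raw), icfg)
    mask <- array(as.integer(pred <= cfg$validation_delta), dim(pred))
    cells <- cpp_label6(mask)
    arand_error(cells, v$labels)
  }, numeric(1))
  mean(scores)
}

#' Train a boundary-prediction network
#'
#' Runs Adam on randomly sampled (and augmented) patches from the training
#' volumes, validating periodically with the adjusted Rand error of the
#' thresholded-and-connected-components segmentation. Returns the checkpoint
#' with the lowest validation ARand, together with the full training history.
#' Raw volumes are standardized internally; targets must be probability maps
#' (typically binary boundary targets from [labels_to_boundary_target()]).
#'
#' @param model a [build_network()] model.
#' @param train_set list of \code{list(raw =, target =)} volumes.
#' @param val_set list of \code{list(raw =, labels =)} volumes (ground-truth
#'   labelings are needed for the validation metric).
#' @param cfg a [train_config()].
#' @return list with elements \code{model} (best checkpoint) and
#'   \code{history} (data frames \code{loss} and \code{validation}).
#' @export
train_boundary_cnn <- function(model, train_set, val_set, cfg = train_config()) {
  if (length(train_set) < 1 || length(val_set) < 1) {
    stop("need at least one training and one validation volume")
  }
  p <- cfg$patch_shape
  train_set <- lapply(train_set, function(v) {
    v$raw <- standardize(as_vol3d(v$raw))
    v$target <- as_vol3d(v$target)
    if (any(dim(v$raw)[1:3] < p)) stop("patch larger than a training volume")
    v
  })
  val_set <- lapply(val_set, function(v) {
    v$raw <- as_vol3d(v$raw)
    v$labels <- assert_label_volume(v$labels)
    v
  })
  losses <- numeric(cfg$max_iterations)
  val_iters <- integer(0); val_scores <- numeric(0)
  best <- list(score = Inf, params = model$params, state = model$state)
  opt <- list(t = 0L, m = list(), v = list())
  lr <- cfg$learning_rate
  no_improve <- 0L
  with_seed(cfg$rng_seed, {
    for (it in seq_len(cfg$max_iterations)) {
      xs <- vector("list", cfg$patches_per_iteration)
      ts <- vector("list", cfg$patches_per_iteration)
      for (b in seq_len(cfg$patches_per_iteration)) {
        vi <- sample.int(length(train_set), 1)
        v <- train_set[[vi]]
        d <- dim(v$raw)
        c0 <- vapply(1:3, function(a) sample.int(d[a] - p[a] + 1L, 1), integer(1))
        sl <- lapply(1:3, function(a) c0[a]:(c0[a] + p[a] - 1L))
        patch <- v$raw[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
        target <- v$target[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
        aug <- apply_augmentations(patch, target, cfg$augment)
        x <- aug$patch; dim(x) <- c(p, 1L)
        t <- aug$target; dim(t) <- c(p, 1L)
        xs[[b]] <- x; ts[[b]] <- t
      }
      fw <- unet_forward(model, xs, training = TRUE)
      model <- fw$model
      lg <- loss_and_grad(fw$logits, fw$probs, ts, cfg$loss)
      if (!is.finite(lg$loss)) {
        stop("training aborted: non-finite loss at iteration ", it)
      }
      losses[it] <- lg$loss
      grads <- unet_backward(model, fw, lg$dlogits)
      st <- adam_step(model$params, grads, opt, lr, cfg)
      model$params <- st$params
      opt <- st$opt
      if (it %% cfg$validate_every == 0 || it == cfg$max_iterations) {
        score <- validation_arand(model, val_set, cfg)
        val_iters <- c(val_iters, it)
        val_scores <- c(val_scores, score)
        if (score < best$score - 1e-12) {
          best <- list(score = score, params = model$params, state = model$state)
          no_improve <- 0L
        } else {
          no_improve <- no_improve + 1L
          if (no_improve >= cfg$patience) {
            lr <- lr / cfg$lr_reduction_factor
            no_improve <- 0L
          }
        }
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  list(model = model,
       history = list(
         loss = data.frame(iteration = seq_len(cfg$max_iterations),
                           loss = losses),
         validation = data.frame(iteration = val_iters, arand = val_scores,
                                 best = val_scores <= cummin(val_scores))))
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the network configuration together with all weights and
#' normalization statistics.
#'
#' @param model a \code{boundary_cnn}.
#' @param path file path (.rds).
#' @return \code{load_model} returns the model; \code{save_model} its path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "boundary_cnn")) stop("not a boundary_cnn checkpoint")
  model
}
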