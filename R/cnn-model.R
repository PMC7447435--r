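#' Configuration of the boundary-prediction network
#'
#' Describes a plain or residual U-Net operating on single-channel volumes.
#' Each convolution unit applies normalization, then a "same" convolution,
#' then ReLU (in that order); the very first unit of the network skips
#' normalization. The residual variant adds a projected (1x1x1 convolution)
#' shortcut around each two-convolution block, so it has strictly more
#' parameters than the plain variant at equal depth. In 2D mode kernels and
#' pooling act on the (y, x) axes only and volumes are single z-slices.
#'
#' @param architecture \code{"unet"} or \code{"residual_unet"}.
#' @param dims 2 or 3.
#' @param feature_maps strictly increasing positive integers, one per level
#'   (at least 2 levels).
#' @param normalization \code{"group"} or \code{"batch"}.
#' @param group_count groups for group normalization (effective count is
#'   capped at the channel count and must divide it).
#' @param in_channels,out_channels input/output channel counts (default 1).
#' @return an object of class \code{network_config}.
#' @export
network_config <- function(architecture = c("unet", "residual_unet"),
                           dims = 3L,
                           feature_maps = c(16L, 32L),
                           normalization = c("group", "batch"),
                           group_count = 8L,
                           in_channels = 1L, out_channels = 1L) {
  architecture <- match.arg(architecture)
  normalization <- match.arg(normalization)
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  feature_maps <- as.integer(feature_maps)
  if (length(feature_maps) < 2L) stop("need at least 2 levels of feature maps")
  if (any(feature_maps < 1L) || any(diff(feature_maps) <= 0L)) {
    stop("feature_maps must be positive and strictly increasing")
  }
  if (group_count < 1L) stop("group_count must be positive")
  structure(list(architecture = architecture, dims = dims,
                 feature_maps = feature_maps,
                 normalization = normalization,
                 group_count = as.integer(group_count),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "network_config")
}

net_kernel <- function(cfg) if (cfg$dims == 3L) c(3L, 3L, 3L) else c(1L, 3L, 3L)
net_pool <- function(cfg) if (cfg$dims == 3L) c(2L, 2L, 2L) else c(1L, 2L, 2L)

# Block plan: every encoder/decoder block is two conv units; residual blocks
# add a 1x1 projection shortcut and defer the second ReLU until after the add.
plan_blocks <- function(cfg) {
  fm <- cfg$feature_maps
  L <- length(fm)
  k <- net_kernel(cfg)
  blocks <- list()
  cin <- cfg$in_channels
  first <- TRUE
  for (l in seq_len(L)) {
    blocks[[paste0("enc", l)]] <- list(cin = cin, cout = fm[l], kernel = k,
                                       first = first)
    first <- FALSE
    cin <- fm[l]
  }
  for (l in rev(seq_len(L - 1L))) {
    blocks[[paste0("dec", l)]] <- list(cin = fm[l + 1L] + fm[l], cout = fm[l],
                                       kernel = k, first = FALSE)
  }
  blocks
}

#' Build a boundary-prediction network
#'
#' Instantiates the U-Net described by a [network_config()] with He-initialized
#' convolution weights. The returned model maps an input patch to a
#' same-shaped single-channel sigmoid probability map.
#'
#' @param cfg a [network_config()].
#' @param rng_seed seed for weight initialization (deterministic build).
#' @return an object of class \code{boundary_cnn}.
#' @export
build_network <- function(cfg, rng_seed = 42L) {
  if (!inherits(cfg, "network_config")) stop("cfg must be a network_config")
  blocks <- plan_blocks(cfg)
  params <- list()
  state <- list()
  residual <- cfg$architecture == "residual_unet"
  with_seed(rng_seed, {
    he <- function(k, cin, cout) {
      array(rnorm(prod(k) * cin * cout, sd = sqrt(2 / (prod(k) * cin))),
            c(k, cin, cout))
    }
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      chans <- c(b$cin, b$cout)
      for (u in 1:2) {
        pre <- paste0(nm, ".u", u)
        has_norm <- !(b$first && u == 1L)
        if (has_norm) {
          params[[paste0(pre, ".g")]] <- rep(1, chans[u])
          params[[paste0(pre, ".bt")]] <- rep(0, chans[u])
          if (cfg$normalization == "batch") {
            state[[pre]] <- list(rm = rep(0, chans[u]), rv = rep(1, chans[u]))
          }
        }
        params[[paste0(pre, ".w")]] <- he(b$kernel, chans[u], b$cout)
        params[[paste0(pre, ".b")]] <- rep(0, b$cout)
      }
      if (residual) {
        params[[paste0(nm, ".proj.w")]] <- he(c(1L, 1L, 1L), b$cin, b$cout)
        params[[paste0(nm, ".proj.b")]] <- rep(0, b$cout)
      }
    }
    params[["out.w"]] <- he(c(1L, 1L, 1L), cfg$feature_maps[1L], cfg$out_channels)
    params[["out.b"]] <- rep(0, cfg$out_channels)
  })
  structure(list(cfg = cfg, blocks = blocks, params = params, state = state),
            class = "boundary_cnn")
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Number of trainable parameters of a model
#' @param model a \code{boundary_cnn}.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

norm_forward_any <- function(model, pre, xs, training) {
  p <- model$params
  if (model$cfg$normalization == "batch") {
    r <- batchnorm_forward(xs, p[[paste0(pre, ".g")]], p[[paste0(pre, ".bt")]],
                           model$state[[pre]], training)
    if (training) model$state[[pre]] <- r$state
    list(out = r$out, cache = c(r$cache, list(kind = "batch")), model = model)
  } else {
    r <- groupnorm_forward(xs, p[[paste0(pre, ".g")]], p[[paste0(pre, ".bt")]],
                           model$cfg$group_count)
    list(out = r$out, cache = c(r$cache, list(kind = "group")), model = model)
  }
}

norm_backward_any <- function(cache, dys) {
  if (cache$kind == "batch") batchnorm_backward(cache, dys)
  else groupnorm_backward(cache, dys)
}

unit_forward <- function(model, nm, u, xs, training, act = TRUE) {
  b <- model$blocks[[nm]]
  pre <- paste0(nm, ".u", u)
  has_norm <- !(b$first && u == 1L)
  cache <- list(pre = pre, has_norm = has_norm, act = act)
  if (has_norm) {
    r <- norm_forward_any(model, pre, xs, training)
    model <- r$model
    cache$norm <- r$cache
    xs <- r$out
  }
  cache$conv_in <- xs
  h <- conv_forward(xs, model$params[[paste0(pre, ".w")]],
                    model$params[[paste0(pre, ".b")]])
  if (act) {
    cache$pre_relu <- h
    h <- relu_forward(h)
  }
  list(out = h, cache = cache, model = model)
}

unit_backward <- function(model, cache, dys, grads) {
  pre <- cache$pre
  if (cache$act) dys <- relu_backward(cache$pre_relu, dys)
  g <- conv_backward(cache$conv_in, model$params[[paste0(pre, ".w")]], dys)
  grads[[paste0(pre, ".w")]] <- (grads[[paste0(pre, ".w")]] %||% 0) + g$dw
  grads[[paste0(pre, ".b")]] <- (grads[[paste0(pre, ".b")]] %||% 0) + g$db
  dys <- g$dx
  if (cache$has_norm) {
    gn <- norm_backward_any(cache$norm, dys)
    grads[[paste0(pre, ".g")]] <- (grads[[paste0(pre, ".g")]] %||% 0) + gn$dgamma
    grads[[paste0(pre, ".bt")]] <- (grads[[paste0(pre, ".bt")]] %||% 0) + gn$dbeta
    dys <- gn$dx
  }
  list(dx = dys, grads = grads)
}

block_forward <- function(model, nm, xs, training) {
  residual <- model$cfg$architecture == "residual_unet"
  cache <- list(nm = nm, residual = residual)
  if (residual) {
    r1 <- unit_forward(model, nm, 1L, xs, training, act = TRUE)
    model <- r1$model
    r2 <- unit_forward(model, nm, 2L, r1$out, training, act = FALSE)
    model <- r2$model
    pw <- model$params[[paste0(nm, ".proj.w")]]
    pb <- model$params[[paste0(nm, ".proj.b")]]
    sc <- conv_forward(xs, pw, pb)
    summ <- Map(`+`, r2$out, sc)
    cache$u1 <- r1$cache; cache$u2 <- r2$cache
    cache$proj_in <- xs
    cache$pre_relu <- summ
    out <- relu_forward(summ)
  } else {
    r1 <- unit_forward(model, nm, 1L, xs, training, act = TRUE)
    model <- r1$model
    r2 <- unit_forward(model, nm, 2L, r1$out, training, act = TRUE)
    model <- r2$model
    cache$u1 <- r1$cache; cache$u2 <- r2$cache
    out <- r2$out
  }
  list(out = out, cache = cache, model = model)
}

block_backward <- function(model, cache, dys, grads) {
  nm <- cache$nm
  if (cache$residual) {
    dys <- relu_backward(cache$pre_relu, dys)
    gp <- conv_backward(cache$proj_in, model$params[[paste0(nm, ".proj.w")]], dys)
    grads[[paste0(nm, ".proj.w")]] <- (grads[[paste0(nm, ".proj.w")]] %||% 0) + gp$dw
    grads[[paste0(nm, ".proj.b")]] <- (grads[[paste0(nm, ".proj.b")]] %||% 0) + gp$db
    r2 <- unit_backward(model, cache$u2, dys, grads)
    r1 <- unit_backward(model, cache$u1, r2$dx, r2$grads)
    dxs <- Map(`+`, r1$dx, gp$dx)
    list(dx = dxs, grads = r1$grads)
  } else {
    r2 <- unit_backward(model, cache$u2, dys, grads)
    r1 <- unit_backward(model, cache$u1, r2$dx, r2$grads)
    list(dx = r1$dx, grads = r1$grads)
  }
}

# Full forward pass over a batch (list of (d1,d2,d3,1) arrays). Spatial dims
# must be divisible by 2^(levels-1) along pooled axes; use net_forward_volume
# for arbitrary shapes.
unet_forward <- function(model, xs, training = FALSE) {
  cfg <- model$cfg
  L <- length(cfg$feature_maps)
  f <- net_pool(cfg)
  d <- dim(xs[[1]])[1:3]
  need <- f^(L - 1L)
  if (any(d %% need != 0)) {
    stop("input shape (", paste(d, collapse = "x"),
         ") must be divisible by ", paste(need, collapse = "x"),
         " for a ", L, "-level network; pad the input (see net_forward_volume)")
  }
  caches <- list()
  skips <- list()
  h <- xs
  for (l in seq_len(L)) {
    r <- block_forward(model, paste0("enc", l), h, training)
    model <- r$model
    caches[[paste0("enc", l)]] <- r$cache
    h <- r$out
    if (l < L) {
      skips[[l]] <- h
      pr <- maxpool_forward(h, f)
      caches[[paste0("pool", l)]] <- pr$cache
      h <- pr$out
    }
  }
  for (l in rev(seq_len(L - 1L))) {
    h <- upsample_forward(h, f)
    h <- concat_forward(h, skips[[l]])
    r <- block_forward(model, paste0("dec", l), h, training)
    model <- r$model
    caches[[paste0("dec", l)]] <- r$cache
    h <- r$out
  }
  logits <- conv_forward(h, model$params[["out.w"]], model$params[["out.b"]])
  caches[["out_in"]] <- h
  probs <- lapply(logits, function(z) 1 / (1 + exp(-z)))
  list(probs = probs, logits = logits, caches = caches, model = model)
}

# Backward pass from d(loss)/d(logits); returns named gradient list.
unet_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  L <- length(cfg$feature_maps)
  f <- net_pool(cfg)
  grads <- list()
  g <- conv_backward(fw$caches[["out_in"]], model$params[["out.w"]], dlogits)
  grads[["out.w"]] <- g$dw
  grads[["out.b"]] <- g$db
  dys <- g$dx
  dskips <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    r <- block_backward(model, fw$caches[[paste0("dec", l)]], dys, grads)
    grads <- r$grads
    cs <- concat_backward(r$dx, cfg$feature_maps[l + 1L])
    dskips[[l]] <- cs$db
    dys <- upsample_backward(cs$da, f)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dys <- maxpool_backward(fw$caches[[paste0("pool", l)]], dys)
      dys <- Map(`+`, dys, dskips[[l]])
    }
    r <- block_backward(model, fw$caches[[paste0("enc", l)]], dys, grads)
    grads <- r$grads
    dys <- r$dx
  }
  grads
}

# Run the network on one full volume of arbitrary shape: mirror-pads pooled
# axes up to the next multiple of 2^(levels-1), then crops the output back.
net_forward_volume <- function(model, volume) {
  volume <- as_vol3d(volume)
  d <- dim(volume)
  L <- length(model$cfg$feature_maps)
  need <- net_pool(model$cfg)^(L - 1L)
  pad <- (need - d %% need) %% need
  x <- mirror_pad(volume, c(0L, 0L, 0L), pad)
  dim(x) <- c(dim(x), 1L)
  fw <- unet_forward(model, list(x), training = FALSE)
  p <- fw$probs[[1]]
  p <- p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 1L, drop = FALSE]
  dim(p) <- d
  p
}
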