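# Building blocks of the compact CPU U-Net: 3D "same" convolution (C++
# im2col + GEMM), batch/group normalization, ReLU, 2x max pooling and nearest
# upsampling, all with explicit backward passes. A batch is a list of arrays
# with dim = (d1, d2, d3, channels); all patches in a batch share one shape.

NORM_EPS <- 1e-5

as_ch_mat <- function(x) {
  d <- dim(x)
  matrix(x, prod(d[1:3]), d[4])
}

conv_forward <- function(xs, w, b) {
  lapply(xs, function(x) cpp_conv3d_forward(x, w, b))
}

conv_backward <- function(xs, w, dys) {
  dw <- 0; db <- 0
  dxs <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    g <- cpp_conv3d_backward(xs[[i]], w, dys[[i]])
    dxs[[i]] <- g$dx
    dw <- dw + g$dw
    db <- db + g$db
  }
  dim(dw) <- dim(w)
  list(dx = dxs, dw = dw, db = db)
}

relu_forward <- function(xs) {
  lapply(xs, function(x) { x[x < 0] <- 0; x })
}

relu_backward <- function(pre, dys) {
  Map(function(p, dy) { dy[p <= 0] <- 0; dy }, pre, dys)
}

# Batch normalization: per-channel statistics over every sample and voxel of
# the batch (population variance). Running statistics (momentum 0.1) are used
# at inference time.
batchnorm_forward <- function(xs, gamma, beta, state, training) {
  d <- dim(xs[[1]])
  C <- d[4]
  if (training) {
    ms <- vapply(xs, function(x) colMeans(as_ch_mat(x)), numeric(C))
    mu <- rowMeans(matrix(ms, nrow = C))
    m2 <- vapply(xs, function(x) colMeans(as_ch_mat(x)^2), numeric(C))
    var <- rowMeans(matrix(m2, nrow = C)) - mu^2
    state$rm <- 0.9 * state$rm + 0.1 * mu
    state$rv <- 0.9 * state$rv + 0.1 * var
  } else {
    mu <- state$rm
    var <- state$rv
  }
  inv <- 1 / sqrt(var + NORM_EPS)
  xhat <- lapply(xs, function(x) {
    xm <- sweep(as_ch_mat(x), 2, mu, "-")
    xm <- sweep(xm, 2, inv, "*")
    dim(xm) <- d
    xm
  })
  out <- lapply(xhat, function(xh) {
    y <- sweep(as_ch_mat(xh), 2, gamma, "*")
    y <- sweep(y, 2, beta, "+")
    dim(y) <- d
    y
  })
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

batchnorm_backward <- function(cache, dys) {
  d <- cache$d; C <- d[4]
  m <- prod(d[1:3]) * length(dys)       # normalization count per channel
  sum_dy <- 0; sum_dyxh <- 0
  for (i in seq_along(dys)) {
    dym <- as_ch_mat(dys[[i]])
    xhm <- as_ch_mat(cache$xhat[[i]])
    sum_dy <- sum_dy + colSums(dym)
    sum_dyxh <- sum_dyxh + colSums(dym * xhm)
  }
  dgamma <- sum_dyxh
  dbeta <- sum_dy
  g_inv <- cache$gamma * cache$inv
  dxs <- vector("list", length(dys))
  for (i in seq_along(dys)) {
    dym <- as_ch_mat(dys[[i]])
    xhm <- as_ch_mat(cache$xhat[[i]])
    t1 <- sweep(dym, 2, sum_dy / m, "-")
    t2 <- sweep(xhm, 2, sum_dyxh / m, "*")
    dx <- sweep(t1 - t2, 2, g_inv, "*")
    dim(dx) <- d
    dxs[[i]] <- dx
  }
  list(dx = dxs, dgamma = dgamma, dbeta = dbeta)
}

# Group normalization: per-sample statistics over each group of channels and
# all voxels; per-channel affine. Effective group count is min(groups, C) and
# must divide C.
groupnorm_forward <- function(xs, gamma, beta, groups) {
  d <- dim(xs[[1]])
  C <- d[4]
  G <- min(groups, C)
  while (C %% G != 0) G <- G - 1L   # largest divisor of C not exceeding groups
  cg <- C %/% G
  nsp <- prod(d[1:3])
  xhat <- vector("list", length(xs))
  invs <- mus <- matrix(0, G, length(xs))
  for (i in seq_along(xs)) {
    xm <- matrix(xs[[i]], nsp * cg, G)
    mu <- colMeans(xm)
    var <- colMeans(xm^2) - mu^2
    inv <- 1 / sqrt(var + NORM_EPS)
    xh <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
    dim(xh) <- d
    xhat[[i]] <- xh
    invs[, i] <- inv; mus[, i] <- mu
  }
  out <- lapply(xhat, function(xh) {
    y <- sweep(as_ch_mat(xh), 2, gamma, "*")
    y <- sweep(y, 2, beta, "+")
    dim(y) <- d
    y
  })
  list(out = out,
       cache = list(xhat = xhat, invs = invs, gamma = gamma, d = d, G = G))
}

groupnorm_backward <- function(cache, dys) {
  d <- cache$d; C <- d[4]; G <- cache$G
  cg <- C %/% G
  nsp <- prod(d[1:3])
  m <- nsp * cg
  dgamma <- 0; dbeta <- 0
  dxs <- vector("list", length(dys))
  for (i in seq_along(dys)) {
    dym <- as_ch_mat(dys[[i]])
    xhm <- as_ch_mat(cache$xhat[[i]])
    dgamma <- dgamma + colSums(dym * xhm)
    dbeta <- dbeta + colSums(dym)
    dxh <- sweep(dym, 2, cache$gamma, "*")
    dxh_g <- matrix(dxh, m, G)
    xh_g <- matrix(xhm, m, G)
    s1 <- colMeans(dxh_g)
    s2 <- colMeans(dxh_g * xh_g)
    dx <- sweep(sweep(dxh_g, 2, s1, "-") - sweep(xh_g, 2, s2, "*"),
                2, cache$invs[, i], "*")
    dim(dx) <- d
    dxs[[i]] <- dx
  }
  list(dx = dxs, dgamma = dgamma, dbeta = dbeta)
}

# Max pooling with per-axis factors f (1 or 2); spatial dims must be
# divisible by f. Ties take the first element in column-major block order.
maxpool_forward <- function(xs, f) {
  d <- dim(xs[[1]])
  od <- c(d[1:3] %/% f, d[4])
  nf <- prod(f)
  res <- lapply(xs, function(x) {
    xr <- array(x, c(f[1], od[1], f[2], od[2], f[3], od[3], d[4]))
    mm <- matrix(aperm(xr, c(1, 3, 5, 2, 4, 6, 7)), nrow = nf)
    am <- max.col(t(mm), ties.method = "first")
    y <- mm[cbind(am, seq_len(ncol(mm)))]
    dim(y) <- od
    list(y = y, am = am)
  })
  list(out = lapply(res, `[[`, "y"),
       cache = list(am = lapply(res, `[[`, "am"), d = d, od = od, f = f))
}

maxpool_backward <- function(cache, dys) {
  d <- cache$d; od <- cache$od; f <- cache$f
  nf <- prod(f)
  Map(function(dy, am) {
    mm <- matrix(0, nf, prod(od))
    mm[cbind(am, seq_along(am))] <- as.numeric(dy)
    dim(mm) <- c(f[1], f[2], f[3], od[1], od[2], od[3], od[4])
    dx <- aperm(mm, c(1, 4, 2, 5, 3, 6, 7))
    dim(dx) <- d
    dx
  }, dys, cache$am)
}

upsample_forward <- function(xs, f) {
  d <- dim(xs[[1]])
  i1 <- rep(seq_len(d[1]), each = f[1])
  i2 <- rep(seq_len(d[2]), each = f[2])
  i3 <- rep(seq_len(d[3]), each = f[3])
  lapply(xs, function(x) x[i1, i2, i3, , drop = FALSE])
}

upsample_backward <- function(dys, f) {
  lapply(dys, function(dy) {
    d <- dim(dy)
    od <- c(d[1:3] %/% f, d[4])
    xr <- array(dy, c(f[1], od[1], f[2], od[2], f[3], od[3], d[4]))
    mm <- matrix(aperm(xr, c(1, 3, 5, 2, 4, 6, 7)), nrow = prod(f))
    dx <- colSums(mm)
    dim(dx) <- od
    dx
  })
}

concat_forward <- function(as, bs) {
  Map(function(a, b) {
    d <- dim(a)
    out <- c(a, b)
    dim(out) <- c(d[1:3], d[4] + dim(b)[4])
    out
  }, as, bs)
}

concat_backward <- function(dys, ca) {
  da <- lapply(dys, function(dy) {
    d <- dim(dy)
    out <- dy[, , , seq_len(ca), drop = FALSE]
    out
  })
  db <- lapply(dys, function(dy) {
    d <- dim(dy)
    dy[, , , (ca + 1):d[4], drop = FALSE]
  })
  list(da = da, db = db)
}
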