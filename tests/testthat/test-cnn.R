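# Boundary CNN: standardization, losses, network construction, gradients,
# augmentations, training behavior, tiled inference.

test_that("standardize centers and scales; degenerate input warns", {
  v <- array(rep(c(0, 2), each = 32), c(4, 4, 4))
  s <- standardize(v)
  expect_equal(sort(unique(as.vector(s))), c(-1, 1))
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_warning(z <- standardize(array(3, c(4, 4, 4))), "constant")
  expect_true(all(z == 0))
})

test_that("bce-dice loss has its closed-form values and limits", {
  t <- array(rep(c(0, 1), 32), c(4, 4, 4))
  eps <- 1e-7
  p_perfect <- array(ifelse(t == 1, 1 - eps, eps), dim(t))
  expect_lt(bce_dice_loss(p_perfect, t, loss_config("bce_dice")), 1e-5)
  # flat 0.5 prediction, pure BCE: exactly ln 2
  p_half <- array(0.5, dim(t))
  expect_equal(bce_dice_loss(p_half, t, loss_config("bce")), log(2),
               tolerance = 1e-12)
  # pure Dice of near-identical all-ones masks
  ones <- array(1, dim(t))
  expect_lt(bce_dice_loss(array(1 - eps, dim(t)), ones, loss_config("dice")),
            1e-5)
  expect_gte(bce_dice_loss(array(runif(64), dim(t)), t, loss_config("bce_dice")), 0)
  expect_error(bce_dice_loss(array(0.5, c(2, 2, 2)), t), "shape")
  expect_error(loss_config(alpha = 0, beta_loss = 0), "both")
})

test_that("network is shape-preserving; residual variant has more parameters", {
  for (nrm in c("group", "batch")) {
    m <- build_network(network_config("unet", feature_maps = c(4, 8),
                                      normalization = nrm, group_count = 2))
    x <- array(rnorm(16^3), c(16, 16, 16, 1))
    fw <- tissueseg:::unet_forward(m, list(x))
    expect_identical(dim(fw$probs[[1]]), c(16L, 16L, 16L, 1L))
    expect_true(all(fw$probs[[1]] > 0 & fw$probs[[1]] < 1))
  }
  plain <- build_network(network_config("unet", feature_maps = c(4, 8)))
  res <- build_network(network_config("residual_unet", feature_maps = c(4, 8)))
  expect_gt(count_parameters(res), count_parameters(plain))
  # non-divisible input is rejected at forward time with a clear message
  bad <- array(0, c(15, 16, 16, 1))
  expect_error(tissueseg:::unet_forward(plain, list(bad)), "divisible")
  # but net_forward_volume pads and crops transparently
  p <- tissueseg:::net_forward_volume(plain, array(rnorm(15 * 16 * 16),
                                                   c(15, 16, 16)))
  expect_identical(dim(p), c(15L, 16L, 16L))
  expect_error(network_config(feature_maps = c(8, 8)), "increasing")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(4)
  for (arch in c("unet", "residual_unet")) {
    cfg <- network_config(arch, feature_maps = c(3, 6),
                          normalization = if (arch == "unet") "batch" else "group",
                          group_count = 3)
    model <- build_network(cfg, rng_seed = 2)
    xs <- list(array(rnorm(6^3), c(6, 6, 6, 1)))
    ts <- list(array(rbinom(6^3, 1, 0.3), c(6, 6, 6, 1)))
    lcfg <- loss_config("bce_dice")
    lossfn <- function(m) {
      fw <- tissueseg:::unet_forward(m, xs, training = TRUE)
      tissueseg:::loss_and_grad(fw$logits, fw$probs, ts, lcfg)$loss
    }
    fw <- tissueseg:::unet_forward(model, xs, training = TRUE)
    lg <- tissueseg:::loss_and_grad(fw$logits, fw$probs, ts, lcfg)
    gr <- tissueseg:::unet_backward(fw$model, fw, lg$dlogits)
    for (nm in sample(names(gr), 4)) {
      i <- sample(length(model$params[[nm]]), 1)
      eps <- 1e-5
      m1 <- model; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("augmentations: identity when off, exact index correspondence", {
  set.seed(1)
  patch <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  target <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  off <- list(flips = FALSE, rot_xy = FALSE, elastic = FALSE)
  out <- apply_augmentations(patch, target, off)
  expect_identical(out$patch, patch)
  expect_identical(out$target, target)
  # 90-degree rotation keeps voxel-wise patch/target correspondence
  r1 <- tissueseg:::rot90_xy(patch, 1)
  rt <- tissueseg:::rot90_xy(target, 1)
  for (k in 1:20) {
    z <- sample(8, 1); y <- sample(8, 1); x <- sample(8, 1)
    # rot90: (z, y, x) -> (z, dim_x + 1 - x, y)
    expect_identical(r1[z, 8 + 1 - x, y], patch[z, y, x])
    expect_identical(rt[z, 8 + 1 - x, y], target[z, y, x])
  }
  expect_identical(tissueseg:::rot90_xy(patch, 4), patch)
  # flips are involutions
  f <- patch[, rev(seq_len(8)), , drop = FALSE]
  expect_identical(f[, rev(seq_len(8)), , drop = FALSE], patch)
  # geometric transforms commute with the boundary-target transform
  lab <- generate_voronoi_labels(tissue_sim_config(shape = c(8, 8, 8),
                                                   n_cells = 3, rng_seed = 2))
  expect_identical(labels_to_boundary_target(tissueseg:::rot90_xy(lab, 1), 1),
                   tissueseg:::rot90_xy(labels_to_boundary_target(lab, 1), 1))
  fl <- lab[, rev(seq_len(8)), , drop = FALSE]
  expect_identical(labels_to_boundary_target(fl, 1),
                   labels_to_boundary_target(lab, 1)[, rev(seq_len(8)), , drop = FALSE])
})

test_that("short training descends, is seed-deterministic, returns the argmin checkpoint", {
  mk <- function(seed) {
    cfg <- tissue_sim_config(shape = c(16, 16, 16), n_cells = 3, rng_seed = seed)
    lab <- generate_voronoi_labels(cfg)
    list(raw = simulate_membrane_image(lab, cfg),
         target = labels_to_boundary_target(lab, 1), labels = lab)
  }
  tr <- lapply(1:2, function(s) mk(s)[c("raw", "target")])
  va <- lapply(3, function(s) mk(s)[c("raw", "labels")])
  model <- build_network(network_config(feature_maps = c(4, 8),
                                        group_count = 2), rng_seed = 1)
  cfg <- train_config(patch_shape = c(8, 8, 8), patches_per_iteration = 2,
                      max_iterations = 40, validate_every = 20, rng_seed = 9)
  fit1 <- train_boundary_cnn(model, tr, va, cfg)
  fit2 <- train_boundary_cnn(model, tr, va, cfg)
  expect_identical(fit1$history$loss, fit2$history$loss)
  h <- fit1$history$loss$loss
  expect_lt(mean(tail(h, 5)), h[1])
  # returned checkpoint achieves the minimum recorded validation score
  best <- min(fit1$history$validation$arand)
  re <- tissueseg:::validation_arand(fit1$model, lapply(va, function(v) {
    v$raw <- tissueseg:::as_vol3d(v$raw); v }), cfg)
  expect_equal(re, best, tolerance = 1e-12)
  expect_error(train_boundary_cnn(model, list(), va, cfg), "at least one")
})

test_that("tiled inference: averaging identities and shape preservation", {
  model <- build_network(network_config(feature_maps = c(4, 8)), rng_seed = 3)
  # constant-output model: zero every weight, set the output bias
  for (nm in names(model$params)) model$params[[nm]][] <- 0
  model$params[["out.b"]][] <- log(0.7 / 0.3)   # sigmoid -> 0.7
  for (nm in names(model$params)) {
    if (grepl("\\.g$", nm)) model$params[[nm]][] <- 1
  }
  vol <- array(rnorm(20 * 24 * 28), c(20, 24, 28))
  pred <- predict_tiled(model, vol, inference_config(c(16, 16, 16)))
  expect_identical(dim(pred), dim(vol))
  expect_equal(max(abs(pred - 0.7)), 0, tolerance = 1e-12)
  # a volume smaller than one tile equals the single padded pass, cropped
  model2 <- build_network(network_config(feature_maps = c(4, 8)), rng_seed = 5)
  small <- array(rnorm(5 * 7 * 9), c(5, 7, 9))
  got <- predict_tiled(model2, small, inference_config(c(8, 8, 16)))
  padded <- tissueseg:::mirror_pad(small, c(0L, 0L, 0L), c(3L, 1L, 7L))
  ref <- tissueseg:::net_forward_volume(model2, padded)[1:5, 1:7, 1:9]
  expect_equal(got, array(ref, dim(small)), tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})
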