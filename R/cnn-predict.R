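#' Inference configuration
#'
#' Tiled inference parses a volume patch-by-patch with mirror padding and a
#' fixed fractional overlap between consecutive tiles, averaging the
#' per-tile probability maps; this suppresses checkerboard artifacts at tile
#' borders.
#'
#' @param patch_shape tile shape (z, y, x).
#' @param overlap_fraction fraction of overlap between consecutive tiles, in
#'   \[0, 1); default 0.5.
#' @return an object of class \code{inference_config}.
#' @export
inference_config <- function(patch_shape = c(32L, 32L, 32L),
                             overlap_fraction = 0.5) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  structure(list(patch_shape = as.integer(patch_shape),
                 overlap_fraction = overlap_fraction),
            class = "inference_config")
}

#' Predict a boundary map with overlapping tiles
#'
#' Every output voxel is the unweighted arithmetic mean of all tile
#' predictions covering it. Volumes smaller than a tile are mirror-padded up
#' to the tile size (and the result cropped back); inside the network,
#' inputs are additionally mirror-padded to the next multiple of
#' \code{2^(levels-1)}.
#'
#' @param model a trained \code{boundary_cnn}.
#' @param volume intensity volume (standardize beforehand if the model was
#'   trained on standardized data).
#' @param cfg an [inference_config()].
#' @return boundary probability map, same shape as \code{volume}.
#' @export
predict_tiled <- function(model, volume, cfg = inference_config()) {
  volume <- as_vol3d(volume)
  d0 <- dim(volume)
  p <- pmin(cfg$patch_shape, 2L * d0)   # mirror padding cannot exceed the axis
  pad <- pmax(p - d0, 0L)
  x <- mirror_pad(volume, c(0L, 0L, 0L), pad)
  d <- dim(x)
  stride <- pmax(1L, as.integer(floor(p * (1 - cfg$overlap_fraction))))
  starts <- lapply(1:3, function(a) {
    if (d[a] <= p[a]) return(1L)
    s <- seq.int(1L, d[a] - p[a] + 1L, by = stride[a])
    if (utils::tail(s, 1L) != d[a] - p[a] + 1L) s <- c(s, d[a] - p[a] + 1L)
    s
  })
  acc <- array(0, d)
  cnt <- array(0, d)
  for (s1 in starts[[1]]) for (s2 in starts[[2]]) for (s3 in starts[[3]]) {
    i1 <- s1:(s1 + p[1] - 1L); i2 <- s2:(s2 + p[2] - 1L); i3 <- s3:(s3 + p[3] - 1L)
    tile <- x[i1, i2, i3, drop = FALSE]
    pr <- net_forward_volume(model, tile)
    acc[i1, i2, i3] <- acc[i1, i2, i3] + pr
    cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1
  }
  out <- acc / cnt
  out <- out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(out) <- d0
  .clamp(out, 0, 1)
}
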