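# HDF5 / TIFF volume input-output. HDF5 dataset names follow the common
# ecosystem convention: `raw` (input intensities), `predictions` (float32
# boundary maps), `segmentation` (uint32 labels). Voxel size (micrometres,
# axis order z,y,x) travels as the dataset attribute `element_size_um`.
# TIFF files are multi-page (one page per z-slice); since TIFF pages store
# values in [0, 1], label pages are scaled by 2^-16 (exact in float32 for
# labels below 65536) and rescaled on read.

TIFF_LABEL_SCALE <- 65536

is_h5 <- function(path) grepl("\\.(h5|hdf5|hd5)$", path, ignore.case = TRUE)
is_tiff <- function(path) grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)

#' Read a volume from HDF5 or TIFF
#'
#' HDF5 volumes are read from \code{dataset} (an informative error lists the
#' available datasets if it is missing); multi-page TIFFs become z-stacks
#' and single 2D images single-slice volumes of shape (1, y, x). Float64
#' HDF5 data are accepted and treated as float32-precision maps with a
#' warning. Label volumes (\code{kind = "labels"}) are rounded to integers.
#'
#' @param path file path (.h5/.hdf5 or .tif/.tiff).
#' @param dataset HDF5 dataset name; defaults to \code{"raw"} (or the kind's
#'   conventional name).
#' @param kind \code{"intensity"}, \code{"boundary"} or \code{"labels"}.
#' @return array of dim (z, y, x), with a \code{voxel_size} attribute when
#'   the file records one.
#' @export
read_volume <- function(path, dataset = NULL,
                        kind = c("intensity", "boundary", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_h5(path)) {
    if (is.null(dataset)) {
      dataset <- switch(kind, intensity = "raw", boundary = "predictions",
                        labels = "segmentation")
    }
    ls <- rhdf5::h5ls(path)
    avail <- paste0(ls$group, "/", ls$name)
    avail <- sub("^//", "/", avail)
    want <- if (startsWith(dataset, "/")) dataset else paste0("/", dataset)
    if (!want %in% avail) {
      stop("dataset '", dataset, "' not found in ", path,
           "; available: ", paste(avail, collapse = ", "))
    }
    x <- rhdf5::h5read(path, dataset, read.attributes = TRUE)
    vs <- attr(x, "element_size_um")
    if (is.double(x) && kind != "labels") {
      # stored float64 is accepted; downstream treats maps as float32 precision
      if (!is.null(attr(x, "storage.mode64"))) warning("float64 input cast to float32")
    }
    attributes(x) <- list(dim = dim(x))
    x <- as_vol3d(x)
    if (!is.null(vs)) attr(x, "voxel_size") <- as.numeric(vs)
  } else if (is_tiff(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    x <- aperm(simplify2array(lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
      p
    })), c(3, 1, 2))
    if (kind == "labels") x <- x * TIFF_LABEL_SCALE
  } else {
    stop("unsupported file type: ", path, " (use .h5/.hdf5 or .tif/.tiff)")
  }
  if (kind == "labels") {
    x <- round(x)
    storage.mode(x) <- "integer"
  } else {
    storage.mode(x) <- "double"
  }
  x
}

#' Write a volume to HDF5 or TIFF
#'
#' HDF5 exports use uint32 storage for labels and float32 for maps; TIFF
#' exports write one 32-bit page per z-slice (labels scaled as described in
#' [read_volume()]). Existing HDF5 datasets of the same name are replaced.
#'
#' @param x volume array.
#' @param path output path (.h5/.hdf5 or .tif/.tiff).
#' @param dataset HDF5 dataset name (defaults by kind as in [read_volume()]).
#' @param kind \code{"intensity"}, \code{"boundary"} or \code{"labels"}.
#' @param voxel_size optional per-axis spacing (µm) stored as an attribute.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, dataset = NULL,
                         kind = c("intensity", "boundary", "labels"),
                         voxel_size = attr(x, "voxel_size")) {
  kind <- match.arg(kind)
  x <- as_vol3d(x)
  if (kind == "labels") {
    x <- assert_label_volume(x)
    if (max(x) >= TIFF_LABEL_SCALE && is_tiff(path)) {
      stop("TIFF label export supports labels below ", TIFF_LABEL_SCALE)
    }
  }
  if (is_h5(path)) {
    if (is.null(dataset)) {
      dataset <- switch(kind, intensity = "raw", boundary = "predictions",
                        labels = "segmentation")
    }
    if (!file.exists(path)) rhdf5::h5createFile(path)
    ls <- rhdf5::h5ls(path)
    if (dataset %in% ls$name) rhdf5::h5delete(path, dataset)
    h5type <- if (kind == "labels") "H5T_STD_U32LE" else "H5T_IEEE_F32LE"
    rhdf5::h5createDataset(path, dataset, dims = dim(x), H5type = h5type)
    rhdf5::h5write(if (kind == "labels") x else (x * 1.0), path, dataset)
    if (!is.null(voxel_size)) {
      fid <- rhdf5::H5Fopen(path)
      did <- rhdf5::H5Dopen(fid, dataset)
      rhdf5::h5writeAttribute(as.numeric(voxel_size), did, "element_size_um")
      rhdf5::H5Dclose(did)
      rhdf5::H5Fclose(fid)
    }
    rhdf5::h5closeAll()
  } else if (is_tiff(path)) {
    if (kind == "labels") {
      pages <- lapply(seq_len(dim(x)[1]),
                      function(z) matrix(x[z, , ] / TIFF_LABEL_SCALE,
                                         dim(x)[2], dim(x)[3]))
    } else {
      pages <- lapply(seq_len(dim(x)[1]),
                      function(z) matrix(.clamp(x[z, , ], 0, 1),
                                         dim(x)[2], dim(x)[3]))
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    stop("unsupported file type: ", path)
  }
  invisible(path)
}

#' Rescale a volume by per-axis factors
#'
#' Interpolates the volume onto a grid of shape \code{round(shape * factors)}
#' (center-aligned coordinates). \code{order = 1} is trilinear, \code{order
#' = 0} nearest-neighbor; label volumes must use order 0 so no fractional
#' labels are invented.
#'
#' @param volume input array.
#' @param factors positive per-axis scale factors (z, y, x).
#' @param order interpolation order, 0 or 1.
#' @return rescaled array.
#' @export
rescale_volume <- function(volume, factors, order = 1L) {
  volume <- as_vol3d(volume)
  is_lab <- is.integer(volume)
  if (is_lab && order != 0L) stop("label volumes must be rescaled with order 0")
  if (any(factors <= 0)) stop("factors must be positive")
  if (!order %in% c(0L, 1L)) stop("interpolation order must be 0 or 1")
  d <- dim(volume)
  od <- as.integer(round(d * factors))
  if (any(od < 1L)) stop("rescale factor produces an empty axis")
  resample_to(volume, od, order)
}

# Resample onto an explicit output grid (center-aligned coordinates).
resample_to <- function(volume, od, order = 1L) {
  volume <- as_vol3d(volume)
  is_lab <- is.integer(volume)
  d <- dim(volume)
  od <- as.integer(od)
  if (all(od == d)) return(volume)
  # center-aligned source coordinate of each output sample
  src <- lapply(1:3, function(a) {
    .clamp((seq_len(od[a]) - 0.5) * d[a] / od[a] + 0.5, 1, d[a])
  })
  if (order == 0L) {
    idx <- lapply(src, round)
    out <- volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - 1L))
    w <- lapply(1:3, function(a) src[[a]] - lo[[a]])
    if (d[1] == 1L) { lo[[1]] <- rep(1, od[1]); w[[1]] <- rep(0, od[1]) }
    if (d[2] == 1L) { lo[[2]] <- rep(1, od[2]); w[[2]] <- rep(0, od[2]) }
    if (d[3] == 1L) { lo[[3]] <- rep(1, od[3]); w[[3]] <- rep(0, od[3]) }
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
    out <- array(0, od)
    w1 <- array(w[[1]], od); w2 <- aperm(array(w[[2]], od[c(2, 1, 3)]), c(2, 1, 3))
    w3 <- aperm(array(w[[3]], od[c(3, 1, 2)]), c(2, 3, 1))
    g <- function(i1, i2, i3) volume[i1, i2, i3, drop = FALSE]
    out <- g(lo[[1]], lo[[2]], lo[[3]]) * (1 - w1) * (1 - w2) * (1 - w3) +
           g(hi[[1]], lo[[2]], lo[[3]]) * w1 * (1 - w2) * (1 - w3) +
           g(lo[[1]], hi[[2]], lo[[3]]) * (1 - w1) * w2 * (1 - w3) +
           g(hi[[1]], hi[[2]], lo[[3]]) * w1 * w2 * (1 - w3) +
           g(lo[[1]], lo[[2]], hi[[3]]) * (1 - w1) * (1 - w2) * w3 +
           g(hi[[1]], lo[[2]], hi[[3]]) * w1 * (1 - w2) * w3 +
           g(lo[[1]], hi[[2]], hi[[3]]) * (1 - w1) * w2 * w3 +
           g(hi[[1]], hi[[2]], hi[[3]]) * w1 * w2 * w3
    dim(out) <- od
  }
  if (is_lab) storage.mode(out) <- "integer"
  out
}
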