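#' Augmentation configuration
#'
#' Controls the training-time augmentation applied to low-grade (minority
#' class) slices. Each enabled transform is applied independently with
#' probability 0.5; the geometric chain (resize 448, center-crop 224,
#' random-crop 160) always runs.
#'
#' @param enable_flip,enable_cyclic_shift,enable_rotation,enable_salt_pepper,enable_duplication
#'   toggles mirroring the ablation rows.
#' @param rotation_range_deg symmetric rotation range, default c(-180, 180).
#' @param salt_pepper_fraction fraction of pixels corrupted, default 0.02.
#' @param shift_max_fraction cyclic-shift bound as a fraction of image
#'   size, default 0.5.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(enable_flip = TRUE, enable_cyclic_shift = TRUE,
                           enable_rotation = TRUE, enable_salt_pepper = TRUE,
                           enable_duplication = TRUE,
                           rotation_range_deg = c(-180, 180),
                           salt_pepper_fraction = 0.02,
                           shift_max_fraction = 0.5) {
  if (salt_pepper_fraction < 0 || salt_pepper_fraction > 1)
    stop2("salt_pepper_fraction must lie in [0,1]", class = "validation_error")
  if (shift_max_fraction <= 0 || shift_max_fraction > 1)
    stop2("shift_max_fraction must lie in (0,1]", class = "validation_error")
  rotation_range_deg <- check_range(rotation_range_deg, "rotation_range_deg")
  if (abs(rotation_range_deg[1] + rotation_range_deg[2]) > 1e-9)
    stop2("rotation_range_deg must be symmetric about 0",
          class = "validation_error")
  structure(list(enable_flip = enable_flip,
                 enable_cyclic_shift = enable_cyclic_shift,
                 enable_rotation = enable_rotation,
                 enable_salt_pepper = enable_salt_pepper,
                 enable_duplication = enable_duplication,
                 rotation_range_deg = rotation_range_deg,
                 salt_pepper_fraction = salt_pepper_fraction,
                 shift_max_fraction = shift_max_fraction),
            class = "augment_config")
}

as_chw <- function(image) {
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  image
}

#' Crop an image
#'
#' @param image H x W x C array (or matrix).
#' @param size target side length (square crop).
#' @param mode `"center"` (offset `floor((H-size)/2)`) or `"random"`
#'   (uniform over valid offsets).
#' @return size x size x C array.
#' @export
crop <- function(image, size, mode = c("center", "random")) {
  mode <- match.arg(mode)
  image <- as_chw(image)
  d <- dim(image)
  if (size > d[1] || size > d[2])
    stop2("crop size %d exceeds image extent %dx%d", size, d[1], d[2],
          class = "validation_error")
  off <- if (mode == "center") {
    c(floor((d[1] - size) / 2), floor((d[2] - size) / 2))
  } else {
    c(sample.int(d[1] - size + 1L, 1L) - 1L,
      sample.int(d[2] - size + 1L, 1L) - 1L)
  }
  image[off[1] + seq_len(size), off[2] + seq_len(size), , drop = FALSE]
}

.interp_cache <- new.env(parent = emptyenv())

# 1D bilinear interpolation matrix (n_dst x n_src), pixel-center aligned,
# cached: resizing is separable, so 2D resize is Rm %*% g %*% t(Cm)
interp_matrix <- function(n_src, n_dst) {
  key <- paste(n_src, n_dst)
  m <- .interp_cache[[key]]
  if (!is.null(m)) return(m)
  s <- pmin(pmax((seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5, 1), n_src)
  r0 <- pmin(floor(s), n_src - 1L)
  fr <- s - r0
  m <- matrix(0, n_dst, n_src)
  m[cbind(seq_len(n_dst), r0)] <- 1 - fr
  m[cbind(seq_len(n_dst), r0 + 1)] <- m[cbind(seq_len(n_dst), r0 + 1)] + fr
  .interp_cache[[key]] <- m
  m
}

#' Bilinear resize
#'
#' Per-channel bilinear interpolation with pixel-center alignment, so
#' resizing to the original size is the identity.
#'
#' @param image H x W x C array.
#' @param size target side length (square output).
#' @return size x size x C array.
#' @export
resize <- function(image, size) {
  if (size < 1) stop2("resize target must be positive", class = "validation_error")
  image <- as_chw(image)
  d <- dim(image)
  Rm <- interp_matrix(d[1], size)
  Cm <- interp_matrix(d[2], size)
  out <- array(0, c(size, size, d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- tcrossprod(Rm %*% image[, , ch], Cm)
  out
}

#' Mirror an image about an axis
#'
#' @param image H x W x C array.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (up-down).
#' @return flipped array.
#' @export
flip <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  image <- as_chw(image)
  if (axis == "horizontal") image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
}

#' Cyclic (wrap-around) translation
#'
#' The pixel at (r, c) moves to ((r + dy) mod H, (c + dx) mod W) in every
#' channel, so the multiset of pixel values is conserved exactly.
#'
#' @param image H x W x C array.
#' @param dx,dy integer shifts (columns, rows); taken modulo the size.
#' @return shifted array.
#' @export
cyclic_shift <- function(image, dx, dy) {
  image <- as_chw(image)
  d <- dim(image)
  ri <- ((seq_len(d[1]) - 1 - dy) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - dx) %% d[2]) + 1
  image[ri, ci, , drop = FALSE]
}

#' Rotate an image about its center
#'
#' Bilinear interpolation; out-of-bounds samples fill with 0 (the masked
#' tumor background). Exact multiples of 90 degrees reproduce the lattice
#' rotation to within floating-point error.
#'
#' @param image H x W x C array.
#' @param angle_deg rotation angle in degrees (counter-clockwise in
#'   row/column coordinates).
#' @return rotated array of the same size.
#' @export
rotate <- function(image, angle_deg) {
  if (!is.finite(angle_deg))
    stop2("angle must be finite", class = "validation_error")
  image <- as_chw(image)
  d <- dim(image)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ctr <- (d[1:2] + 1) / 2
  rr <- rep(seq_len(d[1]), times = d[2]) - ctr[1]
  cc <- rep(seq_len(d[2]), each = d[1]) - ctr[2]
  # inverse map: source = R(-theta) * dest
  sr <- ct * rr + st * cc + ctr[1]
  sc <- -st * rr + ct * cc + ctr[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inb <- function(r, c) r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
  samp <- function(g, r, c) {
    ok <- inb(r, c)
    v <- numeric(length(r))
    v[ok] <- g[cbind(r[ok], c[ok])]
    v
  }
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    g <- image[, , ch]
    v <- samp(g, r0, c0) * (1 - fr) * (1 - fc) +
      samp(g, r0 + 1, c0) * fr * (1 - fc) +
      samp(g, r0, c0 + 1) * (1 - fr) * fc +
      samp(g, r0 + 1, c0 + 1) * fr * fc
    out[, , ch] <- v
  }
  out
}

#' Salt-and-pepper noise
#'
#' A uniformly chosen fraction of pixel positions (the same positions in
#' all channels) is set to the channel maximum (salt) or 0 (pepper) with
#' equal odds.
#'
#' @param image H x W x C array.
#' @param fraction fraction of pixels corrupted, in [0,1].
#' @return corrupted array.
#' @export
salt_pepper <- function(image, fraction) {
  if (fraction < 0 || fraction > 1)
    stop2("fraction must lie in [0,1]", class = "validation_error")
  image <- as_chw(image)
  d <- dim(image)
  npix <- d[1] * d[2]
  ncorr <- round(fraction * npix)
  if (ncorr == 0) return(image)
  pos <- sample.int(npix, ncorr)
  salt <- runif(ncorr) < 0.5
  for (ch in seq_len(d[3])) {
    g <- image[, , ch]
    mx <- max(g)
    g[pos[salt]] <- mx
    g[pos[!salt]] <- 0
    image[, , ch] <- g
  }
  image
}

#' Training-time transform for minority (LGG) slices
#'
#' Geometric chain resize 448 -> center-crop 224 -> random-crop 160,
#' followed by each enabled stochastic transform (flip, cyclic shift,
#' rotation, salt and pepper) applied independently with probability 0.5.
#'
#' @param image raw slice, H x W x C.
#' @param config an [augment_config()].
#' @return 160 x 160 x C array.
#' @export
lgg_train_transform <- function(image, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  x <- resize(as_chw(image), 448L)
  x <- crop(x, 224L, "center")
  x <- crop(x, 160L, "random")
  if (config$enable_flip && runif(1) < 0.5)
    x <- flip(x, sample(c("horizontal", "vertical"), 1))
  if (config$enable_cyclic_shift && runif(1) < 0.5) {
    b <- floor(config$shift_max_fraction * 160)
    x <- cyclic_shift(x, sample(-b:b, 1), sample(-b:b, 1))
  }
  if (config$enable_rotation && runif(1) < 0.5)
    x <- rotate(x, runif(1, config$rotation_range_deg[1],
                         config$rotation_range_deg[2]))
  if (config$enable_salt_pepper && runif(1) < 0.5)
    x <- salt_pepper(x, config$salt_pepper_fraction)
  x
}

#' Deterministic evaluation-time transform
#'
#' Center crop to `size`; undersized slices are zero-padded first (the
#' surrounding ring stays zero).
#'
#' @param image raw slice, H x W x C.
#' @param size output side length (default 160).
#' @return size x size x C array.
#' @export
eval_transform <- function(image, size = 160L) {
  x <- as_chw(image)
  d <- dim(x)
  if (d[1] < size || d[2] < size) {
    nh <- max(d[1], size); nw <- max(d[2], size)
    pad <- array(0, c(nh, nw, d[3]))
    o <- c(floor((nh - d[1]) / 2), floor((nw - d[2]) / 2))
    pad[o[1] + seq_len(d[1]), o[2] + seq_len(d[2]), ] <- x
    x <- pad
  }
  crop(x, size, "center")
}
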