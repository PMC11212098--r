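#' Gradient-weighted class-activation heatmap for one slice
#'
#' Weighs the backbone's last spatial feature maps by the gradient of the
#' target-class logit with respect to each map (with a global-average-
#' pooling head this gradient is spatially uniform, so the weights come
#' in closed form from the projection and classifier matrices), rectifies
#' the weighted sum, bilinearly upsamples it to the input size and
#' min-max normalizes to [0,1]. A constant weighted sum yields an
#' all-zero map.
#'
#' @param model a fitted [fusion_fit()] model with a spatial backbone.
#' @param sample a `slice_sample` (needs `image` and `shape_features`).
#' @param target_class `"LGG"` or `"HGG"`.
#' @return matrix in [0,1] with the spatial size of the model input,
#'   class `heatmap`.
#' @export
activation_heatmap <- function(model, sample, target_class = "HGG") {
  stopifnot(inherits(model, "fusion_model"))
  if (model$features_only)
    stop2("model has no spatial feature maps to explain",
          class = "capability_error")
  cls <- match(target_class, model$class_order)
  if (is.na(cls)) stop2("unknown class '%s'", target_class, class = "validation_error")
  channel_idx <- match(model$channels, c("t1", "t2", "t1gd", "flair"))
  size <- model$backbone$input_size
  img <- eval_transform(sample$image, size)[, , channel_idx, drop = FALSE]
  x <- array(img / model$img_scale, c(size, size, length(channel_idx), 1))
  fwd <- backbone_forward(model$backbone, model$params$backbone, x)
  A <- fwd$spatial[, , , 1, drop = FALSE]      # h x w x F x 1
  hw <- dim(A)[1] * dim(A)[2]
  # d logit_cls / d feature_k, then spread uniformly over the map
  dlogit_dfeat <- model$params$proj$W %*% model$params$clf$W[1:14, cls]
  alpha <- as.numeric(dlogit_dfeat) / hw
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * A[, , k, 1]
  cam[cam < 0] <- 0
  cam <- resize(array(cam, c(dim(cam), 1L)), size)[, , 1]
  rng <- range(cam)
  cam <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
  structure(cam, class = c("heatmap", "matrix"))
}

#' Write a heatmap as grayscale plus red-overlay composite PNGs
#'
#' @param heatmap matrix in [0,1] from [activation_heatmap()].
#' @param image the matching slice image (H x W x C); channel 1 is used
#'   as the anatomical background for the overlay.
#' @param out_prefix path prefix; writes `<prefix>_map.png` and
#'   `<prefix>_overlay.png`.
#' @return character vector of the two file paths.
#' @export
write_heatmap_png <- function(heatmap, image, out_prefix) {
  gray <- pmin(pmax(unclass(heatmap), 0), 1)
  p1 <- paste0(out_prefix, "_map.png")
  png::writePNG(gray, p1)
  bg <- eval_transform(image, nrow(gray))[, , 1]
  rng <- range(bg)
  bg <- if (rng[2] > rng[1]) (bg - rng[1]) / (rng[2] - rng[1]) else bg * 0
  overlay <- array(0, c(dim(gray), 3))
  overlay[, , 1] <- pmin(1, bg * 0.6 + gray)   # red channel carries the map
  overlay[, , 2] <- bg * 0.6
  overlay[, , 3] <- bg * 0.6
  p2 <- paste0(out_prefix, "_overlay.png")
  png::writePNG(overlay, p2)
  c(p1, p2)
}
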