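#' Training configuration for the fusion classifier
#'
#' Defaults follow the study protocol: 20 epochs, batch size 16, Adam
#' with learning rate 0.001, L2 weight decay 5e-4, gradient decay 0.9 and
#' squared-gradient decay 0.99, cross-entropy loss.
#'
#' @param epochs,batch_size,learning_rate,weight_decay,gradient_decay,squared_gradient_decay
#'   optimizer settings.
#' @param seed integer seed for initialization, shuffling and
#'   augmentation draws.
#' @param channels modality subset used as input channels (default all
#'   four, order t1, t2, t1gd, flair).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L,
                         learning_rate = 0.001, weight_decay = 5e-4,
                         gradient_decay = 0.9, squared_gradient_decay = 0.99,
                         seed = 1L,
                         channels = c("t1", "t2", "t1gd", "flair")) {
  check_positive(c(epochs, batch_size, learning_rate), "epochs/batch_size/learning_rate")
  if (weight_decay < 0) stop2("weight_decay must be >= 0", class = "validation_error")
  for (d in c(gradient_decay, squared_gradient_decay))
    if (d <= 0 || d >= 1)
      stop2("decay rates must lie in (0,1)", class = "validation_error")
  channels <- match.arg(channels, c("t1", "t2", "t1gd", "flair"),
                        several.ok = TRUE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 gradient_decay = gradient_decay,
                 squared_gradient_decay = squared_gradient_decay,
                 seed = as.integer(seed), channels = channels),
            class = "train_config")
}

#' Fit a z-score scaler on a training feature matrix
#'
#' @param x numeric matrix (patients x 14), training patients only.
#' @return object of class `feature_scaler` with per-feature `mean` and
#'   `sd` (floored at 1e-8).
#' @export
feature_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(mean = colMeans(x),
                 sd = pmax(apply(x, 2, stats::sd), 1e-8),
                 n_fit = nrow(x)),
            class = "feature_scaler")
}

#' Standardize a feature matrix with a fitted scaler
#'
#' @param features numeric vector (one patient) or matrix.
#' @param scaler a fitted [feature_scaler()].
#' @return standardized matrix.
#' @export
standardize_features <- function(features, scaler) {
  if (!inherits(scaler, "feature_scaler"))
    stop2("scaler has not been fitted", class = "state_error")
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(x) != length(scaler$mean))
    stop2("feature length %d does not match scaler (%d)",
          ncol(x), length(scaler$mean), class = "shape_error")
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

# assemble an H x W x C x N batch from transformed slice images,
# restricted to the model's channel subset and scaled to unit-ish range
assemble_batch <- function(images, channel_idx, img_scale) {
  n <- length(images)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], length(channel_idx), n))
  for (i in seq_len(n))
    x[, , , i] <- images[[i]][, , channel_idx, drop = FALSE]
  x / img_scale
}

slice_grades <- function(samples) vapply(samples, `[[`, character(1), "grade")
slice_pids <- function(samples) vapply(samples, `[[`, character(1), "patient_id")

# model-internal forward: images batch + standardized feature matrix ->
# logits (N x 2) plus caches for backprop
fusion_forward_internal <- function(model, xbatch, zfeat) {
  if (is.null(model$backbone)) {
    logits <- cbind(zfeat, 0)[, 0, drop = FALSE]  # placeholder, not used
    stop2("internal: features-only model uses its own path", class = "state_error")
  }
  fwd <- backbone_forward(model$backbone, model$params$backbone, xbatch)
  proj <- fwd$features %*% model$params$proj$W +
    matrix(model$params$proj$b, nrow(fwd$features), 14, byrow = TRUE)
  fused <- cbind(proj, zfeat)
  logits <- fused %*% model$params$clf$W +
    matrix(model$params$clf$b, nrow(fused), 2, byrow = TRUE)
  list(logits = logits, fwd = fwd, proj = proj, fused = fused)
}

#' Fit the CNN + shape-feature fusion classifier
#'
#' The backbone's image feature vector is projected to 14 values by a
#' trainable affine map, concatenated with the patient's 14 standardized
#' shape features (the scaler is fitted here, on training patients only),
#' and the 28-vector is mapped by one affine layer to a 2-class softmax
#' (class order LGG, HGG). Optimized with Adam and cross-entropy at the
#' configured rates. Minority (LGG) slices pass through the stochastic
#' training transform each epoch; all other slices through the
#' deterministic center-crop path. When `config$channels` is a subset of
#' the four modalities only those channels feed the backbone.
#'
#' @param samples list of training `slice_sample`s, each carrying a
#'   `shape_features` vector (patient-level).
#' @param config a [train_config()].
#' @param backbone a [tiny_backbone()] (contract: any `cnn_backbone`).
#' @param augment an [augment_config()], applied to LGG slices;
#'   `NULL` disables augmentation (deterministic path for every slice).
#' @param features_only if `TRUE`, bypasses the backbone and projection
#'   entirely and trains a logistic-style classifier on the 14
#'   standardized shape features alone.
#' @param feature_weight multiplier applied to the standardized shape
#'   features entering the fused vector (0 zeroes the radiomics channel;
#'   used by ablations).
#' @return object of class `fusion_model` with the trained parameters,
#'   the persisted scaler, channel list, class order, config echo and a
#'   per-epoch `training_log`.
#' @export
fusion_fit <- function(samples, config = train_config(),
                       backbone = tiny_backbone(),
                       augment = augment_config(),
                       features_only = FALSE,
                       feature_weight = 1) {
  grades <- slice_grades(samples)
  if (length(unique(grades)) < 2)
    stop2("training set must contain both classes", class = "validation_error")
  class_order <- c("LGG", "HGG")
  y <- match(grades, class_order)
  channel_idx <- match(config$channels, c("t1", "t2", "t1gd", "flair"))

  # scaler fitted on unique training patients only
  pids <- slice_pids(samples)
  upat <- !duplicated(pids)
  featmat <- do.call(rbind, lapply(samples[upat], function(s) as.numeric(s$shape_features)))
  scaler <- feature_scaler(featmat)
  zfeat_all <- standardize_features(
    do.call(rbind, lapply(samples, function(s) as.numeric(s$shape_features))), scaler)

  img_scale <- max(1e-8, max(vapply(samples, function(s) max(abs(s$image)), 0)))

  model <- list(class_order = class_order, channels = config$channels,
                scaler = scaler, config = config, img_scale = img_scale,
                features_only = features_only, feature_weight = feature_weight,
                augment = augment)

  with_seed(config$seed, {
    if (features_only) {
      model$backbone <- NULL
      model$params <- list(clf = list(W = he_init(14, 2, 14), b = numeric(2)))
      dim(model$params$clf$W) <- c(14, 2)
    } else {
      backbone$in_channels <- length(channel_idx)
      model$backbone <- backbone
      fdim <- backbone$feature_dim
      model$params <- list(
        backbone = backbone_init_params(backbone),
        proj = list(W = he_init(fdim, 14, fdim), b = numeric(14)),
        clf = list(W = he_init(28, 2, 28), b = numeric(2))
      )
      dim(model$params$proj$W) <- c(fdim, 14)
      dim(model$params$clf$W) <- c(28, 2)
    }

    opt_tree <- if (features_only) model$params else
      c(model$params$backbone, list(proj = model$params$proj, clf = model$params$clf))
    state <- adam_init(opt_tree)
    log <- data.frame(epoch = integer(0), mean_loss = numeric(0))

    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(samples))
      losses <- c()
      for (start in seq(1, length(samples), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(samples))]
        zb <- zfeat_all[bi, , drop = FALSE] * feature_weight
        yb <- y[bi]
        if (features_only) {
          logits <- zb %*% model$params$clf$W +
            matrix(model$params$clf$b, length(bi), 2, byrow = TRUE)
          lg <- ce_loss_grad(logits, yb)
          grads <- list(clf = list(W = crossprod(zb, lg$dlogits),
                                   b = colSums(lg$dlogits)))
          st <- adam_step(model$params, grads, state, config$learning_rate,
                          config$weight_decay, config$gradient_decay,
                          config$squared_gradient_decay)
          model$params <- st$params; state <- st$state
        } else {
          imgs <- lapply(samples[bi], function(s) {
            if (!is.null(augment) && s$grade == "LGG")
              lgg_train_transform(s$image, augment)
            else eval_transform(s$image, backbone$input_size)
          })
          xb <- assemble_batch(imgs, channel_idx, img_scale)
          fw <- fusion_forward_internal(model, xb, zb)
          lg <- ce_loss_grad(fw$logits, yb)
          dfused <- tcrossprod(lg$dlogits, model$params$clf$W)
          gclf <- list(W = crossprod(fw$fused, lg$dlogits), b = colSums(lg$dlogits))
          dproj <- dfused[, 1:14, drop = FALSE]
          gproj <- list(W = crossprod(fw$fwd$features, dproj), b = colSums(dproj))
          dfeat <- tcrossprod(dproj, model$params$proj$W)
          gbb <- backbone_backward(model$backbone, model$params$backbone,
                                   fw$fwd, dfeat)
          grads <- c(gbb, list(proj = gproj, clf = gclf))
          flat <- c(model$params$backbone,
                    list(proj = model$params$proj, clf = model$params$clf))
          st <- adam_step(flat, grads, state, config$learning_rate,
                          config$weight_decay, config$gradient_decay,
                          config$squared_gradient_decay)
          state <- st$state
          model$params$backbone <- st$params[setdiff(names(st$params), c("proj", "clf"))]
          model$params$proj <- st$params$proj
          model$params$clf <- st$params$clf
        }
        losses <- c(losses, lg$loss)
      }
      log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(losses)))
    }
    model$training_log <- log
  })
  class(model) <- "fusion_model"
  model
}

#' Forward pass: class probabilities for one slice
#'
#' @param model a fitted [fusion_fit()] model.
#' @param image 160 x 160 x C slice (C = number of model channels), or
#'   `NULL` for a features-only model.
#' @param features the patient's raw 14-vector of shape features
#'   (standardized internally with the persisted scaler).
#' @return numeric probability pair (LGG, HGG) summing to 1.
#' @export
fusion_forward <- function(model, image, features) {
  stopifnot(inherits(model, "fusion_model"))
  z <- standardize_features(as.numeric(features), model$scaler) *
    model$feature_weight
  if (model$features_only) {
    logits <- z %*% model$params$clf$W +
      matrix(model$params$clf$b, 1, 2, byrow = TRUE)
  } else {
    d <- dim(image)
    nc <- length(model$channels)
    if (is.null(d) || length(d) != 3 || d[3] != nc)
      stop2("image must be HxWx%d for this model", nc, class = "shape_error")
    x <- array(image / model$img_scale, c(d, 1))
    fw <- fusion_forward_internal(model, x, z)
    logits <- fw$logits
  }
  p <- as.numeric(softmax_rows(logits))
  names(p) <- model$class_order
  p
}

#' Per-slice class probabilities for a set of samples
#'
#' Evaluation-time path: every slice goes through the deterministic
#' center-crop transform before the forward pass.
#'
#' @param model a fitted `fusion_model`.
#' @param samples list of `slice_sample`s.
#' @param batch_size forward batch size.
#' @return data.frame with patient_id, grade, p_lgg, p_hgg.
#' @export
predict_slices <- function(model, samples, batch_size = 32L) {
  stopifnot(inherits(model, "fusion_model"))
  zall <- standardize_features(
    do.call(rbind, lapply(samples, function(s) as.numeric(s$shape_features))),
    model$scaler) * model$feature_weight
  n <- length(samples)
  probs <- matrix(NA_real_, n, 2)
  if (model$features_only) {
    logits <- zall %*% model$params$clf$W +
      matrix(model$params$clf$b, n, 2, byrow = TRUE)
    probs <- softmax_rows(logits)
  } else {
    channel_idx <- match(model$channels, c("t1", "t2", "t1gd", "flair"))
    size <- model$backbone$input_size
    for (start in seq(1, n, by = batch_size)) {
      bi <- start:min(start + batch_size - 1, n)
      imgs <- lapply(samples[bi], function(s) eval_transform(s$image, size))
      xb <- assemble_batch(imgs, channel_idx, model$img_scale)
      fw <- fusion_forward_internal(model, xb, zall[bi, , drop = FALSE])
      probs[bi, ] <- softmax_rows(fw$logits)
    }
  }
  data.frame(patient_id = slice_pids(samples),
             grade = slice_grades(samples),
             p_lgg = probs[, 1], p_hgg = probs[, 2],
             stringsAsFactors = FALSE)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("Fusion grading model (LGG vs HGG)\n")
  if (x$features_only) {
    cat("  mode: shape features only (14 -> 2)\n")
  } else {
    cat(sprintf("  backbone: residual CNN, widths %s, feature dim %d\n",
                paste(x$backbone$widths, collapse = "/"),
                x$backbone$feature_dim))
    cat("  fused vector length: 28 (14 projected CNN + 14 shape)\n")
  }
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
              nrow(x$training_log), x$training_log$mean_loss[nrow(x$training_log)]))
  invisible(x)
}

#' @export
summary.fusion_model <- function(object, ...) {
  print(object)
  cat("\nTraining loss by epoch:\n")
  print(object$training_log, row.names = FALSE)
  invisible(object)
}

#' @export
coef.fusion_model <- function(object, ...) {
  list(classifier = object$params$clf,
       projection = if (!object$features_only) object$params$proj)
}

#' @export
predict.fusion_model <- function(object, samples, type = c("patient", "slice"), ...) {
  type <- match.arg(type)
  sp <- predict_slices(object, samples)
  if (type == "slice") sp else aggregate_by_patient(sp)
}
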