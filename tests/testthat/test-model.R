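test_that("conv and head gradients match finite differences", {
  set.seed(42)
  bb <- tiny_backbone(in_channels = 2, widths = c(3, 3), blocks = c(1, 1),
                      pool0 = 2, input_size = 8)
  params <- gliomafuse:::backbone_init_params(bb)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  proj <- list(W = matrix(rnorm(3 * 14, 0, 0.3), 3, 14), b = rnorm(14, 0, 0.1))
  clf <- list(W = matrix(rnorm(28 * 2, 0, 0.3), 28, 2), b = rnorm(2, 0, 0.1))
  z <- matrix(rnorm(3 * 14), 3, 14)
  y <- c(1L, 2L, 1L)
  loss_of <- function(params, proj, clf) {
    fwd <- gliomafuse:::backbone_forward(bb, params, x)
    pr <- fwd$features %*% proj$W + matrix(proj$b, 3, 14, byrow = TRUE)
    fu <- cbind(pr, z)
    lo <- fu %*% clf$W + matrix(clf$b, 3, 2, byrow = TRUE)
    gliomafuse:::ce_loss_grad(lo, y)$loss
  }
  # analytic gradients
  fwd <- gliomafuse:::backbone_forward(bb, params, x)
  pr <- fwd$features %*% proj$W + matrix(proj$b, 3, 14, byrow = TRUE)
  fu <- cbind(pr, z)
  lo <- fu %*% clf$W + matrix(clf$b, 3, 2, byrow = TRUE)
  lg <- gliomafuse:::ce_loss_grad(lo, y)
  dfu <- tcrossprod(lg$dlogits, clf$W)
  dpr <- dfu[, 1:14, drop = FALSE]
  dfeat <- tcrossprod(dpr, proj$W)
  gbb <- gliomafuse:::backbone_backward(bb, params, fwd, dfeat)
  gclf_W <- crossprod(fu, lg$dlogits)
  gproj_W <- crossprod(fwd$features, dpr)

  eps <- 1e-6
  num_grad <- function(get, set) {
    p0 <- get()
    (loss_of(set(p0 + eps)$params, set(p0 + eps)$proj, set(p0 + eps)$clf) -
       loss_of(set(p0 - eps)$params, set(p0 - eps)$proj, set(p0 - eps)$clf)) / (2 * eps)
  }
  # a handful of entries across parameter groups
  for (probe in list(c("stem", 1), c("stem", 5), c("s1b1c1", 3),
                     c("s2b1c2", 7))) {
    nm <- probe[1]; i <- as.integer(probe[2])
    g_num <- num_grad(
      function() params[[nm]]$W[i],
      function(v) { p <- params; p[[nm]]$W[i] <- v
        list(params = p, proj = proj, clf = clf) })
    expect_equal(gbb[[nm]]$W[i], g_num, tolerance = 1e-4)
  }
  g_num <- num_grad(function() clf$W[5],
                    function(v) { cl <- clf; cl$W[5] <- v
                      list(params = params, proj = proj, clf = cl) })
  expect_equal(gclf_W[5], g_num, tolerance = 1e-5)
  g_num <- num_grad(function() proj$W[2],
                    function(v) { pj <- proj; pj$W[2] <- v
                      list(params = params, proj = pj, clf = clf) })
  expect_equal(gproj_W[2], g_num, tolerance = 1e-5)
})

test_that("softmax outputs are a probability pair; zero classifier gives (0.5, 0.5)", {
  fx <- small_trained_fixture()
  model <- fx$model
  s <- fx$cohort$samples[[3]]
  p <- fusion_forward(model, eval_transform(s$image), s$shape_features)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(names(p), c("LGG", "HGG"))
  m0 <- model
  m0$params$clf$W[] <- 0; m0$params$clf$b[] <- 0
  p0 <- fusion_forward(m0, eval_transform(s$image), s$shape_features)
  expect_equal(unname(p0), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("wrong channel counts and feature lengths raise shape errors", {
  fx <- small_trained_fixture()
  s <- fx$cohort$samples[[1]]
  img3 <- eval_transform(s$image)[, , 1:3]
  expect_error(fusion_forward(fx$model, img3, s$shape_features),
               class = "shape_error")
  expect_error(fusion_forward(fx$model, eval_transform(s$image), rep(1, 13)),
               class = "shape_error")
})

test_that("the fused representation entering the classifier has length 28", {
  fx <- small_trained_fixture()
  expect_equal(dim(fx$model$params$clf$W), c(28, 2))
  expect_equal(dim(fx$model$params$proj$W),
               c(fx$model$backbone$feature_dim, 14))
  z <- standardize_features(as.numeric(fx$cohort$samples[[1]]$shape_features),
                            fx$model$scaler)
  x <- gliomafuse:::assemble_batch(list(eval_transform(fx$cohort$samples[[1]]$image)),
                      1:4, fx$model$img_scale)
  fw <- gliomafuse:::fusion_forward_internal(fx$model, x, z)
  expect_equal(ncol(fw$fused), 28)
})

test_that("feature scaler standardizes training data and guards state", {
  set.seed(1)
  x <- matrix(rnorm(40 * 14, 5, 3), 40, 14)
  sc <- feature_scaler(x)
  z <- standardize_features(x, sc)
  expect_equal(unname(colMeans(z)), rep(0, 14), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 14), tolerance = 1e-12)
  expect_equal(unname(standardize_features(sc$mean, sc)), matrix(0, 1, 14),
               tolerance = 1e-12)
  expect_error(standardize_features(x, list()), class = "state_error")
})

test_that("validation features are transformed with the training scaler unchanged", {
  fx <- small_trained_fixture()
  before <- fx$model$scaler
  val <- matrix(rnorm(5 * 14, 100, 10), 5, 14)
  invisible(standardize_features(val, fx$model$scaler))
  invisible(predict_slices(fx$model, fx$cohort$samples[1:5]))
  expect_identical(fx$model$scaler, before)
})

test_that("training decreases the loss and is seed-deterministic", {
  fx <- small_trained_fixture()
  log <- fx$model$training_log
  expect_lt(log$mean_loss[nrow(log)], log$mean_loss[1])
  spec <- phantom_spec(n_lgg = 2, n_hgg = 2, seed = 11,
                       grid_shape = c(32, 32, 24),
                       lgg_radius_mm = c(4, 6), hgg_radius_mm = c(8, 11))
  ch <- make_cohort_samples(spec, min_tumor_pixels = 20L)
  m1 <- fusion_fit(ch$samples, train_config(epochs = 1, seed = 3))
  m2 <- fusion_fit(ch$samples, train_config(epochs = 1, seed = 3))
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training sets are rejected", {
  fx <- small_trained_fixture()
  lgg_only <- Filter(function(s) s$grade == "LGG", fx$cohort$samples)
  expect_error(fusion_fit(lgg_only, train_config(epochs = 1)),
               class = "validation_error")
  expect_error(fusion_fit(list(), train_config(epochs = 1)))
})

test_that("slice predictions are complete, normalized and duplicate-consistent", {
  fx <- small_trained_fixture()
  sm <- fx$cohort$samples[1:6]
  sp <- predict_slices(fx$model, c(sm, sm[3]))
  expect_equal(nrow(sp), 7)
  expect_equal(sp$p_lgg + sp$p_hgg, rep(1, 7), tolerance = 1e-6)
  expect_equal(unlist(sp[7, c("p_lgg", "p_hgg")]),
               unlist(sp[3, c("p_lgg", "p_hgg")]), tolerance = 1e-12)
})

test_that("channel subsets drive the backbone input width", {
  spec <- phantom_spec(n_lgg = 2, n_hgg = 2, seed = 11,
                       grid_shape = c(32, 32, 24),
                       lgg_radius_mm = c(4, 6), hgg_radius_mm = c(8, 11))
  ch <- make_cohort_samples(spec, min_tumor_pixels = 20L)
  m <- fusion_fit(ch$samples,
                  train_config(epochs = 1, seed = 2, channels = "t2"))
  expect_equal(m$backbone$in_channels, 1L)
  sp <- predict_slices(m, ch$samples[1:3])
  expect_equal(sp$p_lgg + sp$p_hgg, rep(1, 3), tolerance = 1e-6)
})
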