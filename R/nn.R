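# Minimal CPU neural-network engine used by the fusion classifier.
#
# Convolution is im2col + BLAS matmul; batches are H x W x C x N arrays.
# Only what the grading model needs is implemented: 3x3 same-convolution
# with stride 1, ReLU, average pooling, residual blocks, global average
# pooling, linear layers, softmax cross-entropy and Adam.

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, k, pad) {
  key <- paste(H, W, C, k, pad)
  m <- .im2col_cache[[key]]
  if (!is.null(m)) return(m)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  outH <- H; outW <- W  # stride 1, same padding
  kr <- rep(seq_len(k), times = k * C)
  kc <- rep(rep(seq_len(k), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  oh <- rep(seq_len(outH), times = outW)
  ow <- rep(seq_len(outW), each = outH)
  # index[K, P] into padded (Hp, Wp, C) array
  r <- outer(kr - 1, oh, `+`)            # K x P, 1-based rows
  cc <- outer(kc - 1, ow, `+`)
  idx <- r + (cc - 1) * Hp + (ch - 1) * Hp * Wp
  gr <- as.vector(idx)
  m <- list(idx = idx, K = k * k * C, P = outH * outW,
            Hp = Hp, Wp = Wp, outH = outH, outW = outW,
            scatter_rows = sort(unique(gr)), scatter_group = gr)
  .im2col_cache[[key]] <- m
  m
}

pad_batch <- function(x, pad) {
  d <- dim(x)
  if (pad == 0) return(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# bias-free convolution (residual-network convention; keeps the zero
# background of tumor-masked slices exactly zero through the stack)
conv_fwd <- function(x, W, meta) {
  d <- dim(x); N <- d[4]
  xp <- pad_batch(x, 1L)
  xpm <- matrix(xp, ncol = N)
  M <- xpm[as.vector(meta$idx), , drop = FALSE]
  dim(M) <- c(meta$K, meta$P * N)
  out <- W %*% M
  Fn <- nrow(W)
  out <- aperm(array(out, c(Fn, meta$outH, meta$outW, N)), c(2, 3, 1, 4))
  list(out = out, M = M, dims = d)
}

conv_bwd <- function(cache, W, dy, meta) {
  d <- cache$dims; N <- d[4]; Fn <- nrow(W)
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(Fn, meta$P * N)
  dW <- tcrossprod(dym, cache$M)
  dM <- crossprod(W, dym)                      # K x (P*N)
  dim(dM) <- c(meta$K * meta$P, N)
  acc <- rowsum(dM, meta$scatter_group, reorder = TRUE)
  dxp <- matrix(0, meta$Hp * meta$Wp * d[3], N)
  dxp[meta$scatter_rows, ] <- acc
  dxp <- array(dxp, c(meta$Hp, meta$Wp, d[3], N))
  dx <- dxp[1 + seq_len(d[1]), 1 + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW)
}

avgpool_fwd <- function(x, p) {
  d <- dim(x)
  stopifnot(d[1] %% p == 0, d[2] %% p == 0)
  xr <- array(x, c(p, d[1] / p, p, d[2] / p, d[3], d[4]))
  xr <- aperm(xr, c(1, 3, 2, 4, 5, 6))
  dim(xr) <- c(p * p, d[1] / p * d[2] / p * d[3] * d[4])
  out <- array(colMeans(xr), c(d[1] / p, d[2] / p, d[3], d[4]))
  list(out = out, in_dim = d, p = p)
}

avgpool_bwd <- function(cache, dy) {
  d <- cache$in_dim; p <- cache$p
  g <- as.vector(dy) / (p * p)
  gr <- matrix(g, nrow = 1)[rep(1, p * p), , drop = FALSE]
  dim(gr) <- c(p, p, d[1] / p, d[2] / p, d[3], d[4])
  gr <- aperm(gr, c(1, 3, 2, 4, 5, 6))
  array(gr, d)
}

gap_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  feat <- matrix(colMeans(xm), d[3], d[4])
  list(out = t(feat), in_dim = d)           # N x C
}

gap_bwd <- function(cache, dy) {
  d <- cache$in_dim
  g <- t(dy) / (d[1] * d[2])                # C x N
  array(rep(as.vector(g), each = d[1] * d[2]), d)
}

he_init <- function(nout, nin, fan) matrix(rnorm(nout * nin, 0, sqrt(2 / fan)), nout, nin)

#' Backbone contract: a small residual CNN
#'
#' Builds a configurable residual convolutional backbone: an initial
#' average-pool by `pool0`, a 3x3 stem convolution to `widths[1]`, then
#' one stage per entry of `widths` (each stage `blocks[i]` identity
#' residual blocks of two 3x3 convolutions, followed by 2x2 average
#' pooling between stages), finished by global average pooling. The
#' feature dimension equals `widths[length(widths)]`. There are no
#' per-modality branches: the stem consumes all channels jointly.
#'
#' The default configuration is deliberately small so that training runs
#' on one CPU in minutes; deeper/wider configurations (more stages,
#' larger widths, more blocks) are built through the same constructor.
#'
#' @param in_channels number of input channels (modalities).
#' @param widths channel width per stage.
#' @param blocks number of residual blocks per stage.
#' @param pool0 initial average-pooling factor.
#' @param input_size spatial input side length (default 160).
#' @return object of class `cnn_backbone`.
#' @export
tiny_backbone <- function(in_channels = 4L, widths = c(8L, 8L),
                          blocks = c(1L, 1L), pool0 = 4L,
                          input_size = 160L) {
  stopifnot(length(widths) == length(blocks), length(widths) >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 widths = as.integer(widths), blocks = as.integer(blocks),
                 pool0 = as.integer(pool0), input_size = as.integer(input_size),
                 feature_dim = as.integer(widths[length(widths)])),
            class = "cnn_backbone")
}

backbone_init_params <- function(bb) {
  params <- list()
  cin <- bb$in_channels
  params$stem <- list(W = he_init(bb$widths[1], 9 * cin, 9 * cin))
  for (s in seq_along(bb$widths)) {
    w <- bb$widths[s]
    wprev <- if (s == 1) bb$widths[1] else bb$widths[s - 1]
    if (wprev != w)
      params[[paste0("proj", s)]] <- list(W = he_init(w, 9 * wprev, 9 * wprev))
    for (bl in seq_len(bb$blocks[s])) {
      id <- paste0("s", s, "b", bl)
      params[[paste0(id, "c1")]] <- list(W = he_init(w, 9 * w, 9 * w))
      params[[paste0(id, "c2")]] <- list(W = he_init(w, 9 * w, 9 * w))
    }
  }
  params
}

# Forward through the backbone. Returns the N x F feature matrix, the
# last spatial activation (for class-activation maps) and caches for
# backprop.
backbone_forward <- function(bb, params, x) {
  caches <- list()
  step <- 0L
  push <- function(entry) { step <<- step + 1L; caches[[step]] <<- entry }
  d <- dim(x)
  if (bb$pool0 > 1) {
    c0 <- avgpool_fwd(x, bb$pool0); push(list(op = "pool", cache = c0))
    x <- c0$out
  }
  meta_for <- function(x, cin) im2col_index(dim(x)[1], dim(x)[2], cin, 3L, 1L)
  m <- meta_for(x, bb$in_channels)
  cs <- conv_fwd(x, params$stem$W, m)
  push(list(op = "conv", id = "stem", cache = cs, meta = m))
  x <- cs$out
  mask <- x > 0; x <- x * mask
  push(list(op = "relu", mask = mask))
  for (s in seq_along(bb$widths)) {
    w <- bb$widths[s]
    wprev <- if (s == 1) bb$widths[1] else bb$widths[s - 1]
    if (s > 1) {
      cp <- avgpool_fwd(x, 2L); push(list(op = "pool", cache = cp)); x <- cp$out
    }
    if (wprev != w) {
      m <- meta_for(x, wprev)
      cc <- conv_fwd(x, params[[paste0("proj", s)]]$W, m)
      push(list(op = "conv", id = paste0("proj", s), cache = cc, meta = m))
      x <- cc$out
      mask <- x > 0; x <- x * mask
      push(list(op = "relu", mask = mask))
    }
    for (bl in seq_len(bb$blocks[s])) {
      id <- paste0("s", s, "b", bl)
      m <- meta_for(x, w)
      c1 <- conv_fwd(x, params[[paste0(id, "c1")]]$W, m)
      a1 <- c1$out; m1 <- a1 > 0; a1 <- a1 * m1
      c2 <- conv_fwd(a1, params[[paste0(id, "c2")]]$W, m)
      pre <- c2$out + x
      m2 <- pre > 0
      push(list(op = "resblock", id = id, c1 = c1, c2 = c2,
                m1 = m1, m2 = m2, meta = m))
      x <- pre * m2
    }
  }
  spatial <- x
  cg <- gap_fwd(x)
  push(list(op = "gap", cache = cg))
  list(features = cg$out, spatial = spatial, caches = caches[seq_len(step)])
}

# Backward pass; dfeat is N x F. Returns gradients for every backbone
# parameter (same tree shape as params).
backbone_backward <- function(bb, params, fwd, dfeat) {
  grads <- list()
  dy <- dfeat
  for (i in rev(seq_along(fwd$caches))) {
    e <- fwd$caches[[i]]
    if (e$op == "gap") {
      dy <- gap_bwd(e$cache, dy)
    } else if (e$op == "pool") {
      dy <- avgpool_bwd(e$cache, dy)
    } else if (e$op == "relu") {
      dy <- dy * e$mask
    } else if (e$op == "conv") {
      W <- params[[e$id]]$W
      bk <- conv_bwd(e$cache, W, dy, e$meta)
      grads[[e$id]] <- list(W = bk$dW)
      dy <- bk$dx
    } else if (e$op == "resblock") {
      dpre <- dy * e$m2
      W2 <- params[[paste0(e$id, "c2")]]$W
      b2 <- conv_bwd(e$c2, W2, dpre, e$meta)
      grads[[paste0(e$id, "c2")]] <- list(W = b2$dW)
      da1 <- b2$dx * e$m1
      W1 <- params[[paste0(e$id, "c1")]]$W
      b1 <- conv_bwd(e$c1, W1, da1, e$meta)
      grads[[paste0(e$id, "c1")]] <- list(W = b1$dW)
      dy <- b1$dx + dpre
    }
  }
  grads
}

# --- parameter-tree helpers and Adam ---------------------------------

ptree_map <- function(f, ...) {
  trees <- list(...)
  out <- trees[[1]]
  for (nm in names(out)) {
    for (p in names(out[[nm]])) {
      args <- lapply(trees, function(t) t[[nm]][[p]])
      out[[nm]][[p]] <- do.call(f, args)
    }
  }
  out
}

ptree_zero <- function(tree) ptree_map(function(x) x * 0, tree)

adam_init <- function(params) {
  list(m = ptree_zero(params), v = ptree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      g <- grads[[nm]][[p]] + wd * params[[nm]][[p]]
      state$m[[nm]][[p]] <- b1 * state$m[[nm]][[p]] + (1 - b1) * g
      state$v[[nm]][[p]] <- b2 * state$v[[nm]][[p]] + (1 - b2) * g * g
      mh <- state$m[[nm]][[p]] / (1 - b1^tt)
      vh <- state$v[[nm]][[p]] / (1 - b2^tt)
      params[[nm]][[p]] <- params[[nm]][[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and gradient; y is 1-based class index vector
ce_loss_grad <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl / n)
}
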