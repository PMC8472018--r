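# Internal CNN engine.
#
# All layers operate on matrices whose columns are samples, so every heavy
# step is one BLAS GEMM:
#   - a branch input is the (side*side*4) x N column-major flattening of the
#     (side, side, 4, N) encoded array;
#   - convolution is im2col (precomputed gather index with a zero row for
#     same-padding) followed by crossprod();
#   - the im2col scatter in the backward pass is a single rowsum().
# Feature planes inside a column are laid out (pixel fastest, then channel),
# matching dim() reinterpretation without copies wherever possible.

# ---- im2col convolution -----------------------------------------------------

# Gather index for k x k same-padding convolution over an H x W x C input.
# Row order of the column matrix: dr fastest, then dc, then channel; column
# order: output pixel, row-fastest. Out-of-bounds taps point at `zero_row`.
conv_spec <- function(H, W, C, k = 3L) {
  stopifnot(k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  plane <- H * W
  zero_row <- plane * C + 1L
  g <- expand.grid(dr = -half:half, dc = -half:half, ch = seq_len(C),
                   r = seq_len(H), cc = seq_len(W))
  rr <- g$r + g$dr
  cc <- g$cc + g$dc
  inside <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  idx <- ifelse(inside, rr + H * (cc - 1L) + plane * (g$ch - 1L), zero_row)
  list(H = H, W = W, C = C, k = k, k2C = k * k * C, plane = plane,
       zero_row = zero_row, idx = as.integer(idx))
}

# X: (H*W*C) x N. Returns post-ReLU activations as (H*W*F) x N plus caches.
conv_forward <- function(X, Wt, b, spec, cache = FALSE) {
  n <- ncol(X)
  X0 <- rbind(X, 0)
  Xi <- X0[spec$idx, , drop = FALSE]
  dim(Xi) <- c(spec$k2C, spec$plane * n)
  Z <- crossprod(Xi, Wt)                       # (plane*N) x F
  Z <- sweep(Z, 2L, b, "+")
  A <- Z
  A[A < 0] <- 0
  nf <- ncol(Wt)
  Am <- aperm(array(A, c(spec$plane, n, nf)), c(1L, 3L, 2L))
  dim(Am) <- c(spec$plane * nf, n)
  out <- list(A = Am)
  if (cache) {
    out$Xi <- Xi
    out$relu_mask <- Z > 0
  }
  out
}

# dA: (plane*F) x N gradient wrt post-ReLU output. Returns dX, dW, db.
conv_backward <- function(dA, Wt, spec, cache, n, need_dx = TRUE) {
  nf <- ncol(Wt)
  dAm <- aperm(array(dA, c(spec$plane, nf, n)), c(1L, 3L, 2L))
  dim(dAm) <- c(spec$plane * n, nf)
  dZ <- dAm * cache$relu_mask
  dW <- cache$Xi %*% dZ
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dcols <- Wt %*% t(dZ)                      # k2C x (plane*N)
    dim(dcols) <- c(spec$k2C * spec$plane, n)
    acc <- rowsum(dcols, group = spec$idx)     # sorted groups 1..(HWC), zero row last
    dX <- acc[-nrow(acc), , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- 2x2 max pooling --------------------------------------------------------

pool_spec <- function(H, W, C) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  g <- expand.grid(dr = 0:1, dc = 0:1, r = seq_len(Ho), cc = seq_len(Wo),
                   ch = seq_len(C))
  idx <- (2L * g$r - 1L + g$dr) + H * (2L * g$cc - 2L + g$dc) + H * W * (g$ch - 1L)
  m <- matrix(as.integer(idx), nrow = 4L)     # slot x (HoWo*C)
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo, idx = m)
}

pool_forward <- function(X, spec, cache = FALSE) {
  n <- ncol(X)
  a1 <- X[spec$idx[1L, ], , drop = FALSE]
  a2 <- X[spec$idx[2L, ], , drop = FALSE]
  a3 <- X[spec$idx[3L, ], , drop = FALSE]
  a4 <- X[spec$idx[4L, ], , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  out <- list(Y = m)
  if (cache) {
    w1 <- a1 == m
    w2 <- a2 == m & !w1
    w3 <- a3 == m & !(w1 | w2)
    w4 <- !(w1 | w2 | w3)
    out$mask <- list(w1, w2, w3, w4)
  }
  out
}

pool_backward <- function(dY, spec, cache) {
  dX <- matrix(0, spec$H * spec$W * spec$C, ncol(dY))
  for (k in 1:4) {
    dX[spec$idx[k, ], ] <- dY * cache$mask[[k]]
  }
  dX
}

# ---- branch = conv -> pool -> conv -> pool ----------------------------------

branch_specs <- function(side, f1, f2, k) {
  list(
    conv1 = conv_spec(side, side, 4L, k),
    pool1 = pool_spec(side, side, f1),
    conv2 = conv_spec(side %/% 2L, side %/% 2L, f1, k),
    pool2 = pool_spec(side %/% 2L, side %/% 2L, f2),
    out_dim = (side %/% 4L)^2 * f2
  )
}

branch_forward <- function(X, pw, specs, cache = FALSE) {
  c1 <- conv_forward(X, pw$conv1$W, pw$conv1$b, specs$conv1, cache)
  p1 <- pool_forward(c1$A, specs$pool1, cache)
  c2 <- conv_forward(p1$Y, pw$conv2$W, pw$conv2$b, specs$conv2, cache)
  p2 <- pool_forward(c2$A, specs$pool2, cache)
  list(out = p2$Y, c1 = c1, p1 = p1, c2 = c2, p2 = p2)
}

# Gradient wrt branch output back to conv weights; dX of conv1 never needed.
branch_backward <- function(dOut, fw, pw, specs, n) {
  dA2 <- pool_backward(dOut, specs$pool2, fw$p2)
  b2 <- conv_backward(dA2, pw$conv2$W, specs$conv2, fw$c2, n, need_dx = TRUE)
  dA1 <- pool_backward(b2$dX, specs$pool1, fw$p1)
  b1 <- conv_backward(dA1, pw$conv1$W, specs$conv1, fw$c1, n, need_dx = FALSE)
  list(conv1 = list(dW = b1$dW, db = b1$db),
       conv2 = list(dW = b2$dW, db = b2$db),
       dA2 = dA2)
}

# ---- full network -----------------------------------------------------------

# Forward pass through both branches and the merged dense head.
# drop_mask: NULL at inference; otherwise the inverted-dropout mask.
# cache levels: FALSE = inference only; "dense" = keep what the dense-head
# backward needs; TRUE = also keep the conv/pool caches for branch gradients.
net_forward <- function(params, Ex, Px, specs, drop_mask = NULL, cache = FALSE) {
  conv_cache <- isTRUE(cache)
  be <- branch_forward(Ex, params$enhancer, specs$enhancer, conv_cache)
  bp <- branch_forward(Px, params$promoter, specs$promoter, conv_cache)
  Xf <- rbind(be$out, bp$out)
  Z1 <- params$dense1$W %*% Xf + params$dense1$b[, 1L]
  H1 <- Z1
  H1[H1 < 0] <- 0
  H1d <- if (is.null(drop_mask)) H1 else H1 * drop_mask
  z <- params$out$W %*% H1d + params$out$b[1L, 1L]
  prob <- 1 / (1 + exp(-z))
  out <- list(prob = as.numeric(prob), logit = as.numeric(z))
  if (!isFALSE(cache)) {
    out$be <- be
    out$bp <- bp
    out$Xf <- Xf
    out$Z1 <- Z1
    out$H1d <- H1d
    out$drop_mask <- drop_mask
  }
  out
}

# Backward from a gradient on the logit; returns gradients for every tensor.
# skip_conv: omit the (expensive) branch gradients when every conv parameter
# group is frozen anyway.
net_backward <- function(params, fw, dlogit, specs, n, skip_conv = FALSE) {
  dz <- matrix(dlogit, nrow = 1L)
  gW2 <- dz %*% t(fw$H1d)
  gb2 <- matrix(sum(dz), 1L, 1L)
  dH1d <- t(params$out$W) %*% dz
  dH1 <- if (is.null(fw$drop_mask)) dH1d else dH1d * fw$drop_mask
  dZ1 <- dH1 * (fw$Z1 > 0)
  gW1 <- dZ1 %*% t(fw$Xf)
  gb1 <- matrix(rowSums(dZ1), ncol = 1L)
  ge <- gp <- NULL
  if (!skip_conv) {
    dXf <- t(params$dense1$W) %*% dZ1
    de <- nrow(fw$be$out)
    dFe <- dXf[seq_len(de), , drop = FALSE]
    dFp <- dXf[-seq_len(de), , drop = FALSE]
    ge <- branch_backward(dFe, fw$be, params$enhancer, specs$enhancer, n)
    gp <- branch_backward(dFp, fw$bp, params$promoter, specs$promoter, n)
  }
  list(enhancer = ge, promoter = gp,
       dense1 = list(dW = gW1, db = gb1),
       out = list(dW = gW2, db = gb2))
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- parameters & Adam ------------------------------------------------------

init_params <- function(config, specs) {
  k2 <- config$kernel_size^2
  f <- config$conv_filters
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  mk_branch <- function() list(
    conv1 = list(W = he(k2 * 4L, f[1]), b = rep(0, f[1])),
    conv2 = list(W = he(k2 * f[1], f[2]), b = rep(0, f[2]))
  )
  din <- specs$enhancer$out_dim + specs$promoter$out_dim
  list(
    enhancer = mk_branch(),
    promoter = mk_branch(),
    dense1 = list(W = t(he(din, config$dense_units)),
                  b = matrix(0, config$dense_units, 1L)),
    out = list(W = t(he(config$dense_units, 1L)), b = matrix(0, 1L, 1L))
  )
}

# Flat walk over the parameter tree; names identify freezable groups.
param_paths <- function() {
  list(
    e_conv1 = c("enhancer", "conv1"), e_conv2 = c("enhancer", "conv2"),
    p_conv1 = c("promoter", "conv1"), p_conv2 = c("promoter", "conv2"),
    dense1 = "dense1", out = "out"
  )
}

grad_at <- function(grads, path) {
  g <- grads[[path[1L]]]
  if (length(path) > 1L) g <- g[[path[2L]]]
  g
}

adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(param_paths())) {
    if (nm %in% frozen) next
    path <- param_paths()[[nm]]
    g <- grad_at(grads, path)
    for (tn in c("W", "b")) {
      gt <- if (tn == "W") g$dW else g$db
      p <- params
      # resolve references
      if (length(path) == 1L) {
        m <- opt$m[[path]][[tn]]
        v <- opt$v[[path]][[tn]]
        w <- params[[path]][[tn]]
      } else {
        m <- opt$m[[path[1]]][[path[2]]][[tn]]
        v <- opt$v[[path[1]]][[path[2]]][[tn]]
        w <- params[[path[1]]][[path[2]]][[tn]]
      }
      gt <- gt + 0 * w  # conform shape (db comes back as plain vector)
      dim(gt) <- dim(w)
      m <- beta1 * m + (1 - beta1) * gt
      v <- beta2 * v + (1 - beta2) * gt^2
      w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      if (length(path) == 1L) {
        opt$m[[path]][[tn]] <- m
        opt$v[[path]][[tn]] <- v
        params[[path]][[tn]] <- w
      } else {
        opt$m[[path[1]]][[path[2]]][[tn]] <- m
        opt$v[[path[1]]][[path[2]]][[tn]] <- v
        params[[path[1]]][[path[2]]][[tn]] <- w
      }
    }
  }
  list(params = params, opt = opt)
}
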