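# Minimal neural-network engine used by both cascade stages.
#
# Layers are environments (parameters and Adam state update in place);
# feature maps are stored (H, W, C, N) for 2D layers and (N, L, C) for 1D
# layers. Convolutions run as im2col gathers followed by BLAS matrix
# products; backward passes recompute the gathers instead of caching them
# to keep memory flat.

.im2col_cache <- new.env(parent = emptyenv())

# linear-index matrix (out pixels x k*k*C) into a padded (Hp, Wp, C) array
im2col_index <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  sy <- (seq_len(Ho) - 1L) * stride + 1L
  sx <- (seq_len(Wo) - 1L) * stride + 1L
  base <- rep(sy, times = Wo) + (rep(sx, each = Ho) - 1L) * Hp
  ki <- rep(seq_len(k) - 1L, times = k * C)
  kj <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  cc <- rep(seq_len(C) - 1L, each = k * k)
  off <- cc * Hp * Wp + kj * Hp + ki
  out <- list(idx = outer(base, off, `+`), Ho = Ho, Wo = Wo,
              sy = sy, sx = sx, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  cfg <- list(...)
  for (nm in names(cfg)) assign(nm, cfg[[nm]], envir = l)
  l$adam <- list()
  l
}

layer_dense <- function(n_in, n_out) {
  l <- new_layer("dense", n_in = n_in, n_out = n_out)
  l$W <- he_init(c(n_in, n_out), n_in)
  l$b <- numeric(n_out)
  l$pnames <- c("W", "b")
  l
}

layer_conv1d <- function(in_ch, out_ch, k) {
  l <- new_layer("conv1d", in_ch = in_ch, out_ch = out_ch, k = k)
  l$W <- he_init(c(k * in_ch, out_ch), k * in_ch)
  l$b <- numeric(out_ch)
  l$pnames <- c("W", "b")
  l
}

layer_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = FALSE) {
  l <- new_layer("conv2d", in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = as.integer(stride), pad = as.integer(pad),
                 bias = bias)
  l$W <- he_init(c(k * k * in_ch, out_ch), k * k * in_ch)
  l$pnames <- "W"
  if (bias) { l$b <- numeric(out_ch); l$pnames <- c("W", "b") }
  l
}

layer_bn <- function(n, dim2d = FALSE, eps = 1e-5, momentum = 0.1) {
  l <- new_layer(if (dim2d) "bn2d" else "bn1d", n = n, eps = eps,
                 momentum = momentum)
  l$gamma <- rep(1, n); l$beta <- numeric(n)
  l$run_mean <- numeric(n); l$run_var <- rep(1, n)
  l$pnames <- c("gamma", "beta")
  l
}

layer_relu <- function() { l <- new_layer("relu"); l$pnames <- character(); l }
layer_flatten <- function() { l <- new_layer("flatten"); l$pnames <- character(); l }
layer_dropout <- function(p) {
  l <- new_layer("dropout", p = p); l$pnames <- character(); l
}
layer_maxpool1d <- function(k, stride) {
  l <- new_layer("maxpool1d", k = k, stride = as.integer(stride))
  l$pnames <- character(); l
}
layer_maxpool2d <- function(k, stride, pad = 0L) {
  l <- new_layer("maxpool2d", k = k, stride = as.integer(stride),
                 pad = as.integer(pad))
  l$pnames <- character(); l
}
layer_gap2d <- function() { l <- new_layer("gap2d"); l$pnames <- character(); l }

layer_resblock <- function(in_ch, out_ch, stride = 1L, se = FALSE) {
  l <- new_layer("resblock", in_ch = in_ch, out_ch = out_ch,
                 stride = as.integer(stride), se = se)
  l$conv1 <- layer_conv2d(in_ch, out_ch, 3L, stride, 1L)
  l$bn1 <- layer_bn(out_ch, dim2d = TRUE)
  l$conv2 <- layer_conv2d(out_ch, out_ch, 3L, 1L, 1L)
  l$bn2 <- layer_bn(out_ch, dim2d = TRUE)
  l$project <- (stride != 1L || in_ch != out_ch)
  if (l$project) {
    l$convs <- layer_conv2d(in_ch, out_ch, 1L, stride, 0L)
    l$bns <- layer_bn(out_ch, dim2d = TRUE)
  }
  if (se) {
    r <- max(4L, out_ch %/% 4L)
    l$fc1 <- layer_dense(out_ch, r)
    l$fc2 <- layer_dense(r, out_ch)
  }
  l$pnames <- character()
  l
}

sublayers <- function(l) {
  out <- list(l$conv1, l$bn1, l$conv2, l$bn2)
  if (isTRUE(l$project)) out <- c(out, list(l$convs, l$bns))
  if (isTRUE(l$se)) out <- c(out, list(l$fc1, l$fc2))
  out
}

# ---- forward ----------------------------------------------------------------

layer_forward <- function(l, x, training) {
  switch(l$type,
    dense = {
      l$x <- x
      sweep(x %*% l$W, 2, l$b, `+`)
    },
    conv1d = {
      N <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
      k <- l$k; Lo <- L - k + 1L
      A <- array(0, c(N, Lo, k * C))
      for (c_ in seq_len(C)) for (j in seq_len(k)) {
        A[, , (c_ - 1L) * k + j] <- x[, j:(j + Lo - 1L), c_]
      }
      l$x <- x
      M <- matrix(A, N * Lo, k * C) %*% l$W
      M <- sweep(M, 2, l$b, `+`)
      array(M, c(N, Lo, l$out_ch))
    },
    conv2d = {
      d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
      ii <- im2col_index(H, W_, C, l$k, l$stride, l$pad)
      l$x <- x
      out <- array(0, c(ii$Ho, ii$Wo, l$out_ch, N))
      for (n in seq_len(N)) {
        xp <- pad_array(x[, , , n, drop = FALSE], l$pad)
        # index with the flattened vector: a matrix index whose column
        # count equals the array rank would be read as coordinates
        cols <- matrix(xp[as.vector(ii$idx)], nrow(ii$idx), ncol(ii$idx))
        M <- cols %*% l$W
        if (isTRUE(l$bias)) M <- sweep(M, 2, l$b, `+`)
        out[, , , n] <- array(M, c(ii$Ho, ii$Wo, l$out_ch))
      }
      out
    },
    bn1d = bn_forward(l, x, training, dim2d = FALSE),
    bn2d = bn_forward(l, x, training, dim2d = TRUE),
    relu = { l$mask <- x > 0; x * l$mask },
    flatten = {
      d <- dim(x)
      l$in_dim <- d
      matrix(x, d[1], prod(d[-1]))
    },
    dropout = {
      if (training && l$p > 0) {
        l$mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) >= l$p) / (1 - l$p)
        x * l$mask
      } else {
        l$mask <- NULL
        x
      }
    },
    maxpool1d = maxpool1d_forward(l, x),
    maxpool2d = maxpool2d_forward(l, x),
    gap2d = {
      d <- dim(x)
      l$in_dim <- d
      t(apply(x, c(3, 4), mean))
    },
    resblock = resblock_forward(l, x, training),
    stop("unknown layer type ", l$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_array <- function(x, pad) {
  # x is (H, W, C, 1); returns (H+2p, W+2p, C)
  d <- dim(x)
  if (pad == 0L) return(array(x, d[1:3]))
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x[, , , 1]
  out
}

bn_forward <- function(l, x, training, dim2d) {
  if (dim2d) {
    d <- dim(x)
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  } else {
    xm <- x
  }
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    mu <- l$run_mean; v <- l$run_var
  }
  istd <- 1 / sqrt(v + l$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
  l$xhat <- xhat; l$istd <- istd; l$training <- training
  if (dim2d) {
    d <- dim(x)
    l$in_dim <- d
    aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    out
  }
}

maxpool1d_forward <- function(l, x) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  k <- l$k; s <- l$stride
  Lp <- (L - k) %/% s + 1L
  sp <- (seq_len(Lp) - 1L) * s + 1L
  G <- array(0, c(N, Lp, C, k))
  for (j in seq_len(k)) G[, , , j] <- x[, sp + j - 1L, ]
  Gm <- matrix(G, N * Lp * C, k)
  arg <- max.col(Gm, ties.method = "first")
  out <- Gm[cbind(seq_len(nrow(Gm)), arg)]
  l$arg <- arg; l$in_dim <- d; l$sp <- sp
  array(out, c(N, Lp, C))
}

maxpool2d_forward <- function(l, x) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  k <- l$k; s <- l$stride; p <- l$pad
  Hp <- H + 2L * p; Wp <- W_ + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  xp <- array(-Inf, c(Hp, Wp, C, N))
  xp[p + seq_len(H), p + seq_len(W_), , ] <- x
  sy <- (seq_len(Ho) - 1L) * s + 1L
  sx <- (seq_len(Wo) - 1L) * s + 1L
  out <- array(-Inf, c(Ho, Wo, C, N))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    out <- pmax(out, xp[sy + ki - 1L, sx + kj - 1L, , , drop = FALSE])
  }
  l$xp <- xp; l$out <- out; l$in_dim <- d
  l$sy <- sy; l$sx <- sx
  out
}

resblock_forward <- function(l, x, training) {
  h <- layer_forward(l$conv1, x, training)
  h <- layer_forward(l$bn1, h, training)
  l$relu1 <- h > 0
  h <- h * l$relu1
  h <- layer_forward(l$conv2, h, training)
  h <- layer_forward(l$bn2, h, training)
  if (isTRUE(l$se)) {
    d <- dim(h)
    pooled <- t(apply(h, c(3, 4), mean))          # (N, C)
    z <- layer_forward(l$fc1, pooled, training)
    l$se_relu <- z > 0
    z <- z * l$se_relu
    z <- layer_forward(l$fc2, z, training)
    gate <- 1 / (1 + exp(-z))                     # (N, C)
    l$se_gate <- gate; l$se_pre <- h
    h <- h * aperm(array(t(gate), c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  }
  sc <- if (isTRUE(l$project)) {
    s1 <- layer_forward(l$convs, x, training)
    layer_forward(l$bns, s1, training)
  } else {
    x
  }
  pre <- h + sc
  l$relu_out <- pre > 0
  pre * l$relu_out
}

# ---- backward ---------------------------------------------------------------

layer_backward <- function(l, dout) {
  switch(l$type,
    dense = {
      l$dW <- crossprod(l$x, dout)
      l$db <- colSums(dout)
      dout %*% t(l$W)
    },
    conv1d = {
      x <- l$x
      N <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
      k <- l$k; Lo <- L - k + 1L
      A <- array(0, c(N, Lo, k * C))
      for (c_ in seq_len(C)) for (j in seq_len(k)) {
        A[, , (c_ - 1L) * k + j] <- x[, j:(j + Lo - 1L), c_]
      }
      dM <- matrix(dout, N * Lo, l$out_ch)
      cols <- matrix(A, N * Lo, k * C)
      l$dW <- crossprod(cols, dM)
      l$db <- colSums(dM)
      dcols <- array(dM %*% t(l$W), c(N, Lo, k * C))
      dx <- array(0, dim(x))
      for (c_ in seq_len(C)) for (j in seq_len(k)) {
        dx[, j:(j + Lo - 1L), c_] <- dx[, j:(j + Lo - 1L), c_] +
          dcols[, , (c_ - 1L) * k + j]
      }
      dx
    },
    conv2d = conv2d_backward(l, dout),
    bn1d = bn_backward(l, dout, dim2d = FALSE),
    bn2d = bn_backward(l, dout, dim2d = TRUE),
    relu = dout * l$mask,
    flatten = array(dout, l$in_dim),
    dropout = if (is.null(l$mask)) dout else dout * l$mask,
    maxpool1d = maxpool1d_backward(l, dout),
    maxpool2d = maxpool2d_backward(l, dout),
    gap2d = {
      d <- l$in_dim
      scale <- 1 / (d[1] * d[2])
      g <- aperm(array(t(dout) * scale, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
      g
    },
    resblock = resblock_backward(l, dout),
    stop("unknown layer type ", l$type)
  )
}

conv2d_backward <- function(l, dout) {
  x <- l$x
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  ii <- im2col_index(H, W_, C, l$k, l$stride, l$pad)
  k <- l$k; p <- l$pad
  dW <- matrix(0, nrow(l$W), ncol(l$W))
  db <- numeric(l$out_ch)
  dx <- array(0, d)
  R <- ii$Ho * ii$Wo
  for (n in seq_len(N)) {
    xp <- pad_array(x[, , , n, drop = FALSE], p)
    cols <- matrix(xp[as.vector(ii$idx)], R, ncol(ii$idx))
    dM <- matrix(dout[, , , n], R, l$out_ch)
    dW <- dW + crossprod(cols, dM)
    if (isTRUE(l$bias)) db <- db + colSums(dM)
    dcols <- dM %*% t(l$W)
    dxp <- array(0, dim(xp))
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      # all channels of one kernel offset at once (columns stride k*k)
      sel <- (seq_len(C) - 1L) * k * k + (kj - 1L) * k + ki
      dxp[ii$sy + ki - 1L, ii$sx + kj - 1L, ] <-
        dxp[ii$sy + ki - 1L, ii$sx + kj - 1L, , drop = FALSE] +
        array(dcols[, sel], c(ii$Ho, ii$Wo, C))
    }
    dx[, , , n] <- if (p > 0L) dxp[p + seq_len(H), p + seq_len(W_), , drop = FALSE] else dxp
  }
  l$dW <- dW
  if (isTRUE(l$bias)) l$db <- db
  dx
}

bn_backward <- function(l, dout, dim2d) {
  if (dim2d) {
    d <- l$in_dim
    dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  } else {
    dm <- dout
  }
  m <- nrow(dm)
  l$dgamma <- colSums(dm * l$xhat)
  l$dbeta <- colSums(dm)
  if (isTRUE(l$training)) {
    dxhat <- sweep(dm, 2, l$gamma, `*`)
    dxm <- sweep(
      dxhat - matrix(colMeans(dxhat), m, ncol(dm), byrow = TRUE) -
        l$xhat * matrix(colMeans(dxhat * l$xhat), m, ncol(dm), byrow = TRUE),
      2, l$istd, `*`)
  } else {
    dxm <- sweep(sweep(dm, 2, l$gamma, `*`), 2, l$istd, `*`)
  }
  if (dim2d) {
    d <- l$in_dim
    aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    dxm
  }
}

maxpool1d_backward <- function(l, dout) {
  d <- l$in_dim
  N <- d[1]; C <- d[3]
  Lp <- length(l$sp)
  dx <- array(0, d)
  dv <- as.vector(dout)
  # cell r of the flattened (N, Lp, C) grid took its max from offset arg[r]
  n_i <- ((seq_along(dv) - 1L) %% N) + 1L
  rest <- (seq_along(dv) - 1L) %/% N
  p_i <- (rest %% Lp) + 1L
  c_i <- (rest %/% Lp) + 1L
  src <- l$sp[p_i] + l$arg - 1L
  flat <- n_i + (src - 1L) * N + (c_i - 1L) * N * d[2]
  acc <- rowsum(dv, flat)
  dx[as.integer(rownames(acc))] <- acc[, 1]
  dx
}

maxpool2d_backward <- function(l, dout) {
  d <- l$in_dim
  k <- l$k; p <- l$pad
  dxp <- array(0, dim(l$xp))
  assigned <- array(FALSE, dim(l$out))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    g <- l$xp[l$sy + ki - 1L, l$sx + kj - 1L, , , drop = FALSE]
    hit <- (g == l$out) & !assigned
    if (any(hit)) {
      dxp[l$sy + ki - 1L, l$sx + kj - 1L, , ] <-
        dxp[l$sy + ki - 1L, l$sx + kj - 1L, , , drop = FALSE] + dout * hit
      assigned <- assigned | hit
    }
  }
  if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
}

resblock_backward <- function(l, dout) {
  dpre <- dout * l$relu_out
  dsc <- dpre
  dh <- dpre
  if (isTRUE(l$se)) {
    d <- dim(l$se_pre)
    gate4 <- aperm(array(t(l$se_gate), c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
    dh_pre <- dh * gate4
    dgate <- t(apply(dh * l$se_pre, c(3, 4), sum))   # (N, C)
    dz <- dgate * l$se_gate * (1 - l$se_gate)
    dz <- layer_backward(l$fc2, dz)
    dz <- dz * l$se_relu
    dpooled <- layer_backward(l$fc1, dz)
    scale <- 1 / (d[1] * d[2])
    dh <- dh_pre + aperm(array(t(dpooled) * scale, c(d[3], d[4], d[1], d[2])),
                         c(3, 4, 1, 2))
  }
  dh <- layer_backward(l$bn2, dh)
  dh <- layer_backward(l$conv2, dh)
  dh <- dh * l$relu1
  dh <- layer_backward(l$bn1, dh)
  dx <- layer_backward(l$conv1, dh)
  if (isTRUE(l$project)) {
    ds <- layer_backward(l$bns, dsc)
    dx <- dx + layer_backward(l$convs, ds)
  } else {
    dx <- dx + dsc
  }
  dx
}

# ---- network ----------------------------------------------------------------

nn_network <- function(layers) {
  structure(list(layers = layers), class = "nn_network")
}

nn_forward <- function(net, x, training = FALSE) {
  for (l in net$layers) x <- layer_forward(l, x, training)
  x
}

nn_backward <- function(net, dout) {
  for (l in rev(net$layers)) dout <- layer_backward(l, dout)
  dout
}

all_param_layers <- function(net) {
  out <- list()
  walk <- function(l) {
    if (l$type == "resblock") {
      for (s in sublayers(l)) walk(s)
    } else if (length(l$pnames)) {
      out[[length(out) + 1L]] <<- l
    }
  }
  for (l in net$layers) walk(l)
  out
}

n_params <- function(net) {
  sum(vapply(all_param_layers(net),
             function(l) sum(vapply(l$pnames, function(nm) length(l[[nm]]), 0)),
             0))
}

adam_step <- function(net, step, lr, betas = c(0.9, 0.999), eps = 1e-8,
                      weight_decay = 0) {
  b1 <- betas[1]; b2 <- betas[2]
  for (l in all_param_layers(net)) {
    for (nm in l$pnames) {
      g <- l[[paste0("d", nm)]]
      if (is.null(g)) next
      if (weight_decay > 0 && nm %in% c("W", "gamma")) {
        g <- g + weight_decay * l[[nm]]
      }
      st <- l$adam[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      l$adam[[nm]] <- st
      mhat <- st$m / (1 - b1^step)
      vhat <- st$v / (1 - b2^step)
      l[[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}

# numerically stable losses on logits; gradients are mean-reduced
loss_bce_logits <- function(z, y) {
  z <- as.vector(z); y <- as.numeric(y)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  list(loss = loss, grad = matrix((p - y) / length(y), ncol = 1))
}

loss_ce_logits <- function(Z, y) {
  # y: integer class index 1..K
  zmax <- apply(Z, 1, max)
  lse <- zmax + log(rowSums(exp(Z - zmax)))
  loss <- mean(lse - Z[cbind(seq_len(nrow(Z)), y)])
  P <- exp(Z - lse)
  P[cbind(seq_len(nrow(Z)), y)] <- P[cbind(seq_len(nrow(Z)), y)] - 1
  list(loss = loss, grad = P / nrow(Z))
}

# drop cached activations after training so models stay small
nn_clear_cache <- function(net) {
  walk <- function(l) {
    for (nm in c("x", "mask", "xhat", "istd", "arg", "xp", "out", "in_dim",
                 "relu1", "relu_out", "se_gate", "se_pre", "se_relu", "sp",
                 "sy", "sx"))
      if (!is.null(l[[nm]])) rm(list = nm, envir = l)
    if (l$type == "resblock") for (s in sublayers(l)) walk(s)
  }
  for (l in net$layers) walk(l)
  invisible(net)
}
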