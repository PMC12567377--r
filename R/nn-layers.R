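# Minimal neural-network layer framework.
#
# Activations are dense arrays:
#   feature maps  H x W x C x N   (N = batch)
#   token stacks  T x d x N
#   vectors       N x d matrices
# Every layer is an environment with fields
#   $type       layer name
#   $par, $gr   named lists of parameter / gradient arrays
#   $forward(x, train)   caching what backward needs
#   $backward(dy)        returns dx, fills $gr
#   $out_shape(s)        shape propagation (s excludes the batch axis)
#   $macs(s)             multiply-accumulate count per sample
# Composite blocks expose $layers so parameters can be walked recursively.
# All heavy lifting is k^2-offset array slicing plus BLAS matrix products.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$gr <- list()
  e$layers <- NULL
  e
}

# He-scaled Gaussian init.
w_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

unpad_hw <- function(x, p, h, w) {
  if (p == 0) return(x)
  x[(p + 1):(p + h), (p + 1):(p + w), , , drop = FALSE]
}

conv_out_len <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# ---------------------------------------------------------------------------
# Convolutions

nn_conv2d <- function(in_ch, out_ch, k, stride = 1, pad = 0, bias = TRUE) {
  e <- new_layer("conv2d")
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$k <- k
  e$stride <- stride; e$pad <- pad; e$bias <- bias
  e$par$W <- matrix(w_init(c(k * k * in_ch, out_ch), k * k * in_ch),
                    k * k * in_ch, out_ch)
  if (bias) e$par$b <- numeric(out_ch)
  # Per-offset accumulation: for each of the k^2 kernel offsets, a strided
  # slice is flattened to an (Hout*Wout*N) x C matrix and multiplied by the
  # matching weight block; avoids materializing the full im2col matrix.
  slice_mat <- function(xp, di, dj, Hout, Wout, C, N) {
    rows <- seq.int(di, by = stride, length.out = Hout)
    cols <- seq.int(dj, by = stride, length.out = Wout)
    sl <- xp[rows, cols, , , drop = FALSE]
    sp <- if (C == 1L) sl else aperm(sl, c(1, 2, 4, 3))
    dim(sp) <- c(Hout * Wout * N, C)
    sp
  }
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    abort_if(d[3] != in_ch, "conv2d: expected ", in_ch, " channels, got ", d[3])
    xp <- pad_hw(x, pad)
    Hout <- conv_out_len(d[1], k, stride, pad)
    Wout <- conv_out_len(d[2], k, stride, pad)
    N <- d[4]
    Y <- matrix(0, Hout * Wout * N, out_ch)
    blk <- 0L
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        sp <- slice_mat(xp, di, dj, Hout, Wout, in_ch, N)
        Y <- Y + sp %*% e$par$W[(blk * in_ch + 1L):((blk + 1L) * in_ch), ,
                                drop = FALSE]
        blk <- blk + 1L
      }
    }
    if (bias) Y <- Y + rep(e$par$b, each = nrow(Y))
    e$cache <- list(xp = xp, in_dim = d, Hout = Hout, Wout = Wout)
    dim(Y) <- c(Hout, Wout, N, out_ch)
    aperm(Y, c(1, 2, 4, 3))
  }
  e$backward <- function(dy) {
    cc <- e$cache
    Hout <- cc$Hout; Wout <- cc$Wout; N <- cc$in_dim[4]
    dym <- aperm(dy, c(1, 2, 4, 3))
    dim(dym) <- c(Hout * Wout * N, out_ch)
    gW <- matrix(0, k * k * in_ch, out_ch)
    dxp <- array(0, dim(cc$xp))
    blk <- 0L
    for (dj in seq_len(k)) {
      cols <- seq.int(dj, by = stride, length.out = Wout)
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = Hout)
        sp <- slice_mat(cc$xp, di, dj, Hout, Wout, in_ch, N)
        rng <- (blk * in_ch + 1L):((blk + 1L) * in_ch)
        gW[rng, ] <- crossprod(sp, dym)
        dsp <- tcrossprod(dym, e$par$W[rng, , drop = FALSE])
        if (in_ch == 1L) {
          dim(dsp) <- c(Hout, Wout, 1L, N)
        } else {
          dim(dsp) <- c(Hout, Wout, N, in_ch)
          dsp <- aperm(dsp, c(1, 2, 4, 3))
        }
        dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + dsp
        blk <- blk + 1L
      }
    }
    e$gr$W <- gW
    if (bias) e$gr$b <- colSums(dym)
    unpad_hw(dxp, pad, cc$in_dim[1], cc$in_dim[2])
  }
  e$out_shape <- function(s) c(conv_out_len(s[1], k, stride, pad),
                               conv_out_len(s[2], k, stride, pad), out_ch)
  e$macs <- function(s) {
    o <- e$out_shape(s)
    as.numeric(k) * k * in_ch * out_ch * o[1] * o[2]
  }
  e
}

nn_dwconv2d <- function(ch, k = 3, stride = 1, pad = 1, bias = TRUE) {
  e <- new_layer("dwconv2d")
  e$ch <- ch; e$k <- k; e$stride <- stride; e$pad <- pad; e$bias <- bias
  e$par$W <- w_init(c(k, k, ch), k * k)
  if (bias) e$par$b <- numeric(ch)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    abort_if(d[3] != ch, "dwconv2d: expected ", ch, " channels")
    xp <- pad_hw(x, pad)
    Hout <- conv_out_len(d[1], k, stride, pad)
    Wout <- conv_out_len(d[2], k, stride, pad)
    y <- array(0, c(Hout, Wout, ch, d[4]))
    hw <- Hout * Wout
    for (dj in seq_len(k)) {
      cols <- seq.int(dj, by = stride, length.out = Wout)
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = Hout)
        wv <- rep(e$par$W[di, dj, ], each = hw)
        y <- y + xp[rows, cols, , , drop = FALSE] * as.vector(wv)
      }
    }
    if (bias) y <- y + rep(rep(e$par$b, each = hw), times = d[4])
    e$cache <- list(xp = xp, in_dim = d, Hout = Hout, Wout = Wout)
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    Hout <- cc$Hout; Wout <- cc$Wout; hw <- Hout * Wout; N <- cc$in_dim[4]
    dW <- array(0, c(k, k, ch))
    dxp <- array(0, dim(cc$xp))
    for (dj in seq_len(k)) {
      cols <- seq.int(dj, by = stride, length.out = Wout)
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = Hout)
        sl <- cc$xp[rows, cols, , , drop = FALSE]
        prod_ <- sl * dy
        cs <- colSums(matrix(prod_, hw))            # (ch*N)
        dW[di, dj, ] <- rowSums(matrix(cs, ch, N))
        wv <- rep(e$par$W[di, dj, ], each = hw)
        dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
          dy * as.vector(wv)
      }
    }
    e$gr$W <- dW
    if (bias) e$gr$b <- rowSums(matrix(colSums(matrix(dy, hw)), ch, N))
    unpad_hw(dxp, pad, cc$in_dim[1], cc$in_dim[2])
  }
  e$out_shape <- function(s) c(conv_out_len(s[1], k, stride, pad),
                               conv_out_len(s[2], k, stride, pad), ch)
  e$macs <- function(s) {
    o <- e$out_shape(s)
    as.numeric(k) * k * ch * o[1] * o[2]
  }
  e
}

# ---------------------------------------------------------------------------
# Normalization and activations

nn_batchnorm2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- new_layer("batchnorm2d")
  e$ch <- ch; e$eps <- eps
  e$par$gamma <- rep(1, ch)
  e$par$beta <- numeric(ch)
  e$state <- list(mean = numeric(ch), var = rep(1, ch))
  # per-channel sums without transposing: fold (H*W, C*N), column-sum,
  # then row-sum the C x N matrix
  ch_sums <- function(z, d) {
    cs <- colSums(matrix(z, d[1] * d[2], ch * d[4]))
    rowSums(matrix(cs, ch, d[4]))
  }
  # broadcast a per-channel vector over (H, W, ., N)
  bc <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    n <- d[1] * d[2] * d[4]
    if (train) {
      mu <- ch_sums(x, d) / n
      v <- ch_sums(x^2, d) / n - mu^2
      e$state$mean <- (1 - momentum) * e$state$mean + momentum * mu
      e$state$var <- (1 - momentum) * e$state$var + momentum * v
    } else {
      mu <- e$state$mean; v <- e$state$var
    }
    ivar <- 1 / sqrt(v + eps)
    xhat <- (x - bc(mu, d)) * bc(ivar, d)
    dim(xhat) <- d
    y <- xhat * bc(e$par$gamma, d) + bc(e$par$beta, d)
    dim(y) <- d
    e$cache <- list(xhat = xhat, ivar = ivar, d = d, train = train, n = n)
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d; n <- cc$n
    e$gr$gamma <- ch_sums(dy * cc$xhat, d)
    e$gr$beta <- ch_sums(dy, d)
    g_ivar <- e$par$gamma * cc$ivar
    if (cc$train) {
      dx <- (dy - bc(e$gr$beta / n, d) -
               cc$xhat * bc(e$gr$gamma / n, d)) * bc(g_ivar, d)
    } else {
      dx <- dy * bc(g_ivar, d)
    }
    dim(dx) <- d
    dx
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) 0
  e
}

nn_act <- function(kind = c("relu", "gelu", "sigmoid")) {
  kind <- match.arg(kind)
  e <- new_layer(paste0("act_", kind))
  e$forward <- function(x, train = TRUE) {
    if (kind == "gelu") {
      p <- stats::pnorm(x)
      y <- x * p
      e$cache <- list(x = x, p = p)
    } else if (kind == "relu") {
      y <- pmax(x, 0)
      e$cache <- list(x = x)
    } else {
      y <- 1 / (1 + exp(-x))
      e$cache <- list(y = y)
    }
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    g <- switch(kind,
                relu = (cc$x > 0) * 1,
                gelu = cc$p + cc$x * stats::dnorm(cc$x),
                sigmoid = cc$y * (1 - cc$y))
    dx <- dy * g
    if (!is.null(dim(dy))) dim(dx) <- dim(dy)
    dx
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) 0
  e
}

nn_maxpool <- function(k, stride = k, pad = 0) {
  e <- new_layer("maxpool")
  e$k <- k; e$stride <- stride; e$pad <- pad
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    xp <- pad_hw(x, pad)
    if (pad > 0) { # -Inf padding so border maxima ignore the pad
      mask <- array(TRUE, dim(xp))
      mask[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , ] <- FALSE
      xp[mask] <- -Inf
    }
    Hout <- conv_out_len(d[1], k, stride, pad)
    Wout <- conv_out_len(d[2], k, stride, pad)
    best <- array(-Inf, c(Hout, Wout, d[3], d[4]))
    arg <- array(0L, dim(best))
    idx <- 1L
    for (dj in seq_len(k)) {
      cols <- seq.int(dj, by = stride, length.out = Wout)
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = Hout)
        sl <- xp[rows, cols, , , drop = FALSE]
        upd <- sl > best
        best[upd] <- sl[upd]
        arg[upd] <- idx
        idx <- idx + 1L
      }
    }
    e$cache <- list(arg = arg, in_dim = d, pdim = dim(xp),
                    Hout = Hout, Wout = Wout)
    best
  }
  e$backward <- function(dy) {
    cc <- e$cache
    dxp <- array(0, cc$pdim)
    idx <- 1L
    for (dj in seq_len(k)) {
      cols <- seq.int(dj, by = stride, length.out = cc$Wout)
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = cc$Hout)
        sel <- (cc$arg == idx) * dy
        dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + sel
        idx <- idx + 1L
      }
    }
    unpad_hw(dxp, pad, cc$in_dim[1], cc$in_dim[2])
  }
  e$out_shape <- function(s) c(conv_out_len(s[1], k, stride, pad),
                               conv_out_len(s[2], k, stride, pad), s[3])
  e$macs <- function(s) 0
  e
}

nn_gap <- function() {
  e <- new_layer("gap")
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    hw <- d[1] * d[2]
    m <- matrix(x, hw, d[3] * d[4])
    y <- matrix(colSums(m) / hw, d[3], d[4]) # C x N
    e$cache <- list(d = d)
    t(y)                                     # N x C
  }
  e$backward <- function(dy) {
    d <- e$cache$d
    hw <- d[1] * d[2]
    array(rep(as.vector(t(dy)) / hw, each = hw), d)
  }
  e$out_shape <- function(s) s[3]
  e$macs <- function(s) 0
  e
}

nn_linear <- function(in_d, out_d, bias = TRUE) {
  e <- new_layer("linear")
  e$in_d <- in_d; e$out_d <- out_d; e$bias <- bias
  e$par$W <- matrix(w_init(c(in_d, out_d), in_d), in_d, out_d)
  if (bias) e$par$b <- numeric(out_d)
  e$forward <- function(x, train = TRUE) {
    y <- x %*% e$par$W
    if (bias) y <- y + rep(e$par$b, each = nrow(y))
    e$cache <- list(x = x)
    y
  }
  e$backward <- function(dy) {
    e$gr$W <- crossprod(e$cache$x, dy)
    if (bias) e$gr$b <- colSums(dy)
    tcrossprod(dy, e$par$W)
  }
  e$out_shape <- function(s) out_d
  e$macs <- function(s) as.numeric(in_d) * out_d
  e
}

nn_flatten <- function() {
  e <- new_layer("flatten")
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    e$cache <- list(d = d)
    m <- matrix(x, prod(d[1:3]), d[4])
    t(m)
  }
  e$backward <- function(dy) array(t(dy), e$cache$d)
  e$out_shape <- function(s) prod(s)
  e$macs <- function(s) 0
  e
}

# (H, W, C, N) feature map -> (T = H*W, C, N) token stack.
nn_tokenize <- function() {
  e <- new_layer("tokenize")
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    e$cache <- list(d = d)
    array(x, c(d[1] * d[2], d[3], d[4]))
  }
  e$backward <- function(dy) array(dy, e$cache$d)
  e$out_shape <- function(s) c(s[1] * s[2], s[3])
  e$macs <- function(s) 0
  e
}

# Token-wise affine map on (T, in, N).
nn_tokenlinear <- function(in_d, out_d, bias = TRUE) {
  e <- new_layer("tokenlinear")
  e$in_d <- in_d; e$out_d <- out_d; e$bias <- bias
  e$par$W <- matrix(w_init(c(in_d, out_d), in_d), in_d, out_d)
  if (bias) e$par$b <- numeric(out_d)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    m <- aperm(x, c(1, 3, 2))
    dim(m) <- c(d[1] * d[3], in_d)
    y <- m %*% e$par$W
    if (bias) y <- y + rep(e$par$b, each = nrow(y))
    e$cache <- list(m = m, d = d)
    dim(y) <- c(d[1], d[3], out_d)
    aperm(y, c(1, 3, 2))
  }
  e$backward <- function(dy) {
    d <- e$cache$d
    dm <- aperm(dy, c(1, 3, 2))
    dim(dm) <- c(d[1] * d[3], out_d)
    e$gr$W <- crossprod(e$cache$m, dm)
    if (bias) e$gr$b <- colSums(dm)
    dx <- tcrossprod(dm, e$par$W)
    dim(dx) <- c(d[1], d[3], in_d)
    aperm(dx, c(1, 3, 2))
  }
  e$out_shape <- function(s) c(s[1], out_d)
  e$macs <- function(s) as.numeric(s[1]) * in_d * out_d
  e
}

# Layer normalization across the feature axis of (T, d, N).
nn_layernorm <- function(d_model, eps = 1e-5) {
  e <- new_layer("layernorm")
  e$d_model <- d_model; e$eps <- eps
  e$par$gamma <- rep(1, d_model)
  e$par$beta <- numeric(d_model)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    m <- aperm(x, c(1, 3, 2))
    dim(m) <- c(d[1] * d[3], d_model)
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc^2)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * ivar
    n <- nrow(m)
    y <- xhat * rep(e$par$gamma, each = n) + rep(e$par$beta, each = n)
    e$cache <- list(xhat = xhat, ivar = ivar, d = d)
    dim(y) <- c(d[1], d[3], d_model)
    aperm(y, c(1, 3, 2))
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d
    dm <- aperm(dy, c(1, 3, 2))
    dim(dm) <- c(d[1] * d[3], d_model)
    n <- nrow(dm)
    e$gr$gamma <- colSums(dm * cc$xhat)
    e$gr$beta <- colSums(dm)
    dxhat <- dm * rep(e$par$gamma, each = n)
    k <- d_model
    dx <- (dxhat - rowMeans(dxhat) -
             cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$ivar
    dim(dx) <- c(d[1], d[3], d_model)
    aperm(dx, c(1, 3, 2))
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) 0
  e
}

# ---------------------------------------------------------------------------
# Containers

nn_seq <- function(...) {
  e <- new_layer("seq")
  e$layers <- list(...)
  e$forward <- function(x, train = TRUE) {
    for (l in e$layers) x <- l$forward(x, train)
    x
  }
  e$backward <- function(dy) {
    for (l in rev(e$layers)) dy <- l$backward(dy)
    dy
  }
  e$out_shape <- function(s) {
    for (l in e$layers) s <- l$out_shape(s)
    s
  }
  e$macs <- function(s) {
    total <- 0
    for (l in e$layers) {
      total <- total + l$macs(s)
      s <- l$out_shape(s)
    }
    total
  }
  e
}

# Recursively collect every parameter-bearing layer environment.
walk_layers <- function(layer) {
  out <- list()
  if (length(layer$par) > 0) out <- list(layer)
  for (l in layer$layers %||% list()) out <- c(out, walk_layers(l))
  out
}

#' Count trainable parameters of a network
#' @param layer A network layer or composite.
#' @return Integer parameter count.
#' @keywords internal
n_params <- function(layer) {
  sum(vapply(walk_layers(layer),
             function(l) sum(vapply(l$par, length, 0L)), 0))
}
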