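# Composite network blocks: squeeze-excitation, MBConv, residual blocks,
# and the Transformer pieces (scaled-dot-product attention, multi-head
# attention, pre-LN encoder block).

# Squeeze-and-Excitation: global pooling -> bottleneck MLP -> sigmoid gate
# rescaling channels.
nn_se <- function(ch, ratio = 0.25) {
  e <- new_layer("se")
  mid <- max(1L, as.integer(round(ch * ratio)))
  e$ch <- ch; e$mid <- mid
  e$gap <- nn_gap()
  e$fc1 <- nn_linear(ch, mid)
  e$act <- nn_act("relu")
  e$fc2 <- nn_linear(mid, ch)
  e$sig <- nn_act("sigmoid")
  e$layers <- list(e$fc1, e$fc2)
  e$forward <- function(x, train = TRUE) {
    s <- e$sig$forward(e$fc2$forward(e$act$forward(
      e$fc1$forward(e$gap$forward(x, train), train), train), train), train)
    d <- dim(x)
    sb <- rep(as.vector(t(s)), each = d[1] * d[2]) # broadcast (N,C) over H,W
    e$cache <- list(x = x, s = s, d = d)
    x * sb
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d
    hw <- d[1] * d[2]
    sb <- rep(as.vector(t(cc$s)), each = hw)
    dx_direct <- dy * sb
    ds_flat <- colSums(matrix(dy * cc$x, hw))      # (C*N)
    ds <- t(matrix(ds_flat, d[3], d[4]))           # N x C
    dpool <- e$gap$backward(e$fc1$backward(e$act$backward(
      e$fc2$backward(e$sig$backward(ds)))))
    dx_direct + dpool
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) as.numeric(ch) * mid * 2
  e
}

# Inverted-bottleneck MBConv: 1x1 reduce, two depthwise-separable convs,
# SE reweighting, residual add when input/output shapes match.
nn_mbconv <- function(in_ch, out_ch, expansion = 4, se_ratio = 0.25) {
  e <- new_layer("mbconv")
  mid <- max(1L, out_ch %/% expansion)
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$mid <- mid
  e$body <- nn_seq(
    nn_conv2d(in_ch, mid, 1), nn_batchnorm2d(mid), nn_act("gelu"),
    nn_dwconv2d(mid, 3, 1, 1), nn_conv2d(mid, mid, 1),
    nn_batchnorm2d(mid), nn_act("gelu"),
    nn_dwconv2d(mid, 3, 1, 1), nn_conv2d(mid, out_ch, 1),
    nn_batchnorm2d(out_ch),
    nn_se(out_ch, se_ratio)
  )
  e$residual <- in_ch == out_ch
  e$layers <- list(e$body)
  e$forward <- function(x, train = TRUE) {
    y <- e$body$forward(x, train)
    if (e$residual) y + x else y
  }
  e$backward <- function(dy) {
    dx <- e$body$backward(dy)
    if (e$residual) dx + dy else dx
  }
  e$out_shape <- function(s) e$body$out_shape(s)
  e$macs <- function(s) e$body$macs(s)
  e
}

# Classic bottleneck residual block (1x1 down, 3x3, 1x1 up).
nn_bottleneck <- function(in_ch, width, out_ch, stride = 1) {
  e <- new_layer("bottleneck")
  e$body <- nn_seq(
    nn_conv2d(in_ch, width, 1, bias = FALSE), nn_batchnorm2d(width), nn_act("relu"),
    nn_conv2d(width, width, 3, stride, 1, bias = FALSE), nn_batchnorm2d(width),
    nn_act("relu"),
    nn_conv2d(width, out_ch, 1, bias = FALSE), nn_batchnorm2d(out_ch)
  )
  e$project <- stride != 1 || in_ch != out_ch
  if (e$project) {
    e$short <- nn_seq(nn_conv2d(in_ch, out_ch, 1, stride, bias = FALSE),
                      nn_batchnorm2d(out_ch))
  }
  e$relu <- nn_act("relu")
  e$layers <- if (e$project) list(e$body, e$short) else list(e$body)
  e$forward <- function(x, train = TRUE) {
    y <- e$body$forward(x, train)
    sc <- if (e$project) e$short$forward(x, train) else x
    e$relu$forward(y + sc, train)
  }
  e$backward <- function(dy) {
    dsum <- e$relu$backward(dy)
    dx <- e$body$backward(dsum)
    dsc <- if (e$project) e$short$backward(dsum) else dsum
    dx + dsc
  }
  e$out_shape <- function(s) e$body$out_shape(s)
  e$macs <- function(s) e$body$macs(s) + if (e$project) e$short$macs(s) else 0
  e
}

# Basic (two 3x3 convs) residual block, as in 18-layer residual networks.
nn_basicblock <- function(in_ch, out_ch, stride = 1) {
  e <- new_layer("basicblock")
  e$body <- nn_seq(
    nn_conv2d(in_ch, out_ch, 3, stride, 1, bias = FALSE), nn_batchnorm2d(out_ch),
    nn_act("relu"),
    nn_conv2d(out_ch, out_ch, 3, 1, 1, bias = FALSE), nn_batchnorm2d(out_ch)
  )
  e$project <- stride != 1 || in_ch != out_ch
  if (e$project) {
    e$short <- nn_seq(nn_conv2d(in_ch, out_ch, 1, stride, bias = FALSE),
                      nn_batchnorm2d(out_ch))
  }
  e$relu <- nn_act("relu")
  e$layers <- if (e$project) list(e$body, e$short) else list(e$body)
  e$forward <- function(x, train = TRUE) {
    y <- e$body$forward(x, train)
    sc <- if (e$project) e$short$forward(x, train) else x
    e$relu$forward(y + sc, train)
  }
  e$backward <- function(dy) {
    dsum <- e$relu$backward(dy)
    dx <- e$body$backward(dsum)
    dsc <- if (e$project) e$short$backward(dsum) else dsum
    dx + dsc
  }
  e$out_shape <- function(s) e$body$out_shape(s)
  e$macs <- function(s) e$body$macs(s) + if (e$project) e$short$macs(s) else 0
  e
}

# ---------------------------------------------------------------------------
# Attention

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`; each attention row is a probability
#' distribution over the keys.
#'
#' @param Q,K,V Matrices with `d_k` columns; `K` and `V` share a row count.
#' @param d_k Key width used in the scaling factor (default `ncol(Q)`).
#' @return List with `out` (weighted values) and `attn` (weight matrix,
#'   rows summing to 1).
#' @export
attention <- function(Q, K, V, d_k = ncol(Q)) {
  abort_if(is.null(d_k) || d_k <= 0, "d_k must be positive")
  abort_if(ncol(Q) != ncol(K) || nrow(K) != nrow(V),
           "incompatible Q/K/V shapes")
  S <- tcrossprod(Q, K) / sqrt(d_k)
  S <- S - apply(S, 1, max) # row-wise shift for softmax stability
  E <- exp(S)
  A <- E / rowSums(E)
  list(out = A %*% V, attn = A)
}

# Backward pass of attention given cached A, Q, K, V.
attention_backward <- function(dout, A, Q, K, V, d_k) {
  dA <- tcrossprod(dout, V)         # dout %*% t(V)
  dV <- crossprod(A, dout)
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% K / sqrt(d_k)
  dK <- crossprod(dS, Q) / sqrt(d_k)
  list(dQ = dQ, dK = dK, dV = dV)
}

#' Multi-head self-attention parameters
#'
#' @param d_model Token width; must be divisible by `h`.
#' @param h Head count.
#' @return A multi-head attention layer operating on (T, d_model, N).
#' @export
nn_mhsa <- function(d_model, h) {
  abort_if(d_model %% h != 0, "d_model (", d_model,
           ") not divisible by head count (", h, ")")
  e <- new_layer("mhsa")
  e$d_model <- d_model; e$h <- h; e$d_k <- d_model %/% h
  sd <- sqrt(1 / d_model)
  rnd <- function() matrix(stats::rnorm(d_model * d_model, 0, sd), d_model)
  e$par$Wq <- rnd(); e$par$Wk <- rnd(); e$par$Wv <- rnd(); e$par$Wo <- rnd()
  e$par$bq <- numeric(d_model); e$par$bk <- numeric(d_model)
  e$par$bv <- numeric(d_model); e$par$bo <- numeric(d_model)
  e$forward <- function(x, train = TRUE) {
    d <- dim(x) # T, d_model, N
    Tn <- d[1]; N <- d[3]
    dk <- e$d_k
    y <- array(0, d)
    attn <- array(0, c(Tn, Tn, h, N))
    cache <- vector("list", N)
    for (n in seq_len(N)) {
      Z <- x[, , n, drop = FALSE]; dim(Z) <- d[1:2]
      Q <- Z %*% e$par$Wq + rep(e$par$bq, each = Tn)
      K <- Z %*% e$par$Wk + rep(e$par$bk, each = Tn)
      V <- Z %*% e$par$Wv + rep(e$par$bv, each = Tn)
      Hc <- matrix(0, Tn, d_model)
      heads <- vector("list", h)
      for (hh in seq_len(h)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        at <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                        V[, cols, drop = FALSE], dk)
        Hc[, cols] <- at$out
        attn[, , hh, n] <- at$attn
        heads[[hh]] <- at$attn
      }
      y[, , n] <- Hc %*% e$par$Wo + rep(e$par$bo, each = Tn)
      cache[[n]] <- list(Z = Z, Q = Q, K = K, V = V, Hc = Hc, heads = heads)
    }
    e$last_attn <- attn
    e$cache <- list(percase = cache, d = d)
    y
  }
  e$backward <- function(dy) {
    d <- e$cache$d
    Tn <- d[1]; N <- d[3]; dk <- e$d_k
    gz <- lapply(e$par, function(p) array(0, dim(p) %||% length(p)))
    dx <- array(0, d)
    for (n in seq_len(N)) {
      cc <- e$cache$percase[[n]]
      dyn <- dy[, , n, drop = FALSE]; dim(dyn) <- d[1:2]
      gz$Wo <- gz$Wo + crossprod(cc$Hc, dyn)
      gz$bo <- gz$bo + colSums(dyn)
      dH <- tcrossprod(dyn, e$par$Wo)
      dQ <- matrix(0, Tn, d_model); dK <- dQ; dV <- dQ
      for (hh in seq_len(e$h)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        ab <- attention_backward(dH[, cols, drop = FALSE], cc$heads[[hh]],
                                 cc$Q[, cols, drop = FALSE],
                                 cc$K[, cols, drop = FALSE],
                                 cc$V[, cols, drop = FALSE], dk)
        dQ[, cols] <- ab$dQ; dK[, cols] <- ab$dK; dV[, cols] <- ab$dV
      }
      gz$Wq <- gz$Wq + crossprod(cc$Z, dQ); gz$bq <- gz$bq + colSums(dQ)
      gz$Wk <- gz$Wk + crossprod(cc$Z, dK); gz$bk <- gz$bk + colSums(dK)
      gz$Wv <- gz$Wv + crossprod(cc$Z, dV); gz$bv <- gz$bv + colSums(dV)
      dZ <- tcrossprod(dQ, e$par$Wq) + tcrossprod(dK, e$par$Wk) +
        tcrossprod(dV, e$par$Wv)
      dx[, , n] <- dZ
    }
    e$gr <- gz
    dx
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) {
    Tn <- s[1]
    4 * Tn * as.numeric(d_model)^2 + 2 * Tn^2 * d_model
  }
  e
}

#' Multi-head self-attention as a pure function
#'
#' Applies the projection/attention/concat/output-map pipeline of a
#' multi-head layer to one token matrix.
#'
#' @param Z Token matrix T x d_model.
#' @param params A layer from [nn_mhsa()] (its `$par` is used).
#' @return T x d_model output matrix.
#' @export
multi_head <- function(Z, params) {
  x <- array(Z, c(nrow(Z), ncol(Z), 1))
  out <- params$forward(x, train = FALSE)
  matrix(out, nrow(Z), ncol(Z))
}

#' Pre-LN Transformer encoder block
#'
#' `x1 = x + MHSA(LN1(x)); x2 = x1 + MLP(LN2(x1))` — residual connections
#' around both the attention and MLP branches, with layer normalization
#' applied before each.
#'
#' @param d_model Token width.
#' @param h Head count.
#' @param mlp_ratio MLP expansion ratio (default 4).
#' @return A block layer operating on (T, d_model, N) token stacks.
#' @export
nn_transformer_block <- function(d_model, h, mlp_ratio = 4) {
  e <- new_layer("transformer_block")
  e$ln1 <- nn_layernorm(d_model)
  e$msa <- nn_mhsa(d_model, h)
  e$ln2 <- nn_layernorm(d_model)
  e$mlp <- nn_seq(nn_tokenlinear(d_model, d_model * mlp_ratio), nn_act("gelu"),
                  nn_tokenlinear(d_model * mlp_ratio, d_model))
  e$layers <- list(e$ln1, e$msa, e$ln2, e$mlp)
  e$forward <- function(x, train = TRUE) {
    x1 <- x + e$msa$forward(e$ln1$forward(x, train), train)
    x1 + e$mlp$forward(e$ln2$forward(x1, train), train)
  }
  e$backward <- function(dy) {
    dx1 <- dy + e$ln2$backward(e$mlp$backward(dy))
    dx1 + e$ln1$backward(e$msa$backward(dx1))
  }
  e$out_shape <- function(s) s
  e$macs <- function(s) {
    e$msa$macs(s) + as.numeric(s[1]) * d_model * d_model * mlp_ratio * 2
  }
  e
}
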