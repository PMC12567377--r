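# Model architectures.
#
# EFEM  - EEG encoder: 3x3/s2 conv stem (BatchNorm + GELU), MBConv stages
#         with max-pool downsampling and squeeze-excitation, final feature
#         map flattened to tokens and projected to d_model.
# FEFEM - face encoder: 7x7/s2 conv stem, 3x3/s2 max-pool, bottleneck
#         residual stages (1x1 down, 3x3, 1x1 up; stride-2 at stage
#         starts), tokens as above.
# FFM   - fusion classifier: modality-type embeddings, class token, L_T
#         pre-LN Transformer blocks, linear head on the class token.
#
# In the fusion model the EFEM trunk is applied to each frequency band
# separately (shared weights, single-channel input), so every EEG token
# carries a band identity; attention attribution over bands reads the
# class-token attention mass of these per-band token groups.

#' Model configuration
#'
#' Reference configuration of the fusion network.  `efem`/`fefem` describe
#' the two encoders, `d_model`, `heads`, `depth` and `mlp_ratio` the
#' Transformer fusion module.  `proj_width` is the hidden width of the
#' token-projection head; its default is calibrated once so that the
#' reference model's trainable-parameter total matches the published
#' complexity budget of the architecture (15.2 M).
#'
#' @param d_model Token width (default 256; divisible by `heads`).
#' @param heads Attention head count (default 8).
#' @param depth Number of Transformer blocks L_T (default 2).
#' @param mlp_ratio MLP expansion ratio (default 4).
#' @param proj_width Token-projection hidden width (calibration knob).
#' @param efem List: `stem`, `widths`, `blocks`, `expansion`, `se_ratio`.
#' @param fefem List: `stem`, `widths`, `blocks`, `block_type`
#'   ("bottleneck" or "basic"), `bn_expansion` (bottleneck output
#'   multiplier, default 4).
#' @param eeg_size,face_size Input raster sizes.
#' @param n_classes Number of emotion classes (4).
#' @return A `model_config` list.
#' @export
model_config <- function(d_model = 256, heads = 8, depth = 2, mlp_ratio = 4,
                         proj_width = 430,
                         efem = list(stem = 32, widths = c(32, 64, 128, 256),
                                     blocks = c(2, 2, 2, 2), expansion = 4,
                                     se_ratio = 0.25),
                         fefem = list(stem = 60, widths = c(60, 120, 240, 480),
                                      blocks = c(2, 2, 2, 2),
                                      block_type = "bottleneck",
                                      bn_expansion = 4),
                         eeg_size = 224, face_size = 256, n_classes = 4) {
  abort_if(d_model %% heads != 0, "d_model must be divisible by heads")
  structure(list(d_model = d_model, heads = heads, depth = depth,
                 mlp_ratio = mlp_ratio, proj_width = proj_width,
                 efem = efem, fefem = fefem,
                 eeg_size = eeg_size, face_size = face_size,
                 n_classes = n_classes),
            class = "model_config")
}

#' Down-scaled model configuration for desk-scale experiments
#'
#' A small variant of the reference architecture used with 64 x 64 inputs.
#'
#' @return A `model_config`.
#' @export
desk_model_config <- function() {
  model_config(d_model = 48, heads = 4, depth = 2, mlp_ratio = 2,
               proj_width = 48,
               efem = list(stem = 6, widths = c(6, 12, 16, 24),
                           blocks = c(1, 1, 1, 1), expansion = 2,
                           se_ratio = 0.25),
               fefem = list(stem = 8, widths = c(6, 10, 14, 20),
                            blocks = c(1, 1, 1, 1), block_type = "bottleneck",
                            bn_expansion = 2),
               eeg_size = 64, face_size = 48)
}

# EFEM trunk: stem + MBConv stages.  in_ch = 5 for the unimodal stack
# encoder, 1 for the per-band fusion encoder.
build_efem_trunk <- function(cfg, in_ch = 5) {
  ef <- cfg$efem
  layers <- list(
    nn_conv2d(in_ch, ef$stem, 3, 2, 1), nn_batchnorm2d(ef$stem),
    nn_act("gelu"), nn_conv2d(ef$stem, ef$stem, 3, 2, 1)
  )
  prev <- ef$stem
  for (i in seq_along(ef$widths)) {
    layers <- c(layers, list(nn_maxpool(2, 2)))
    for (b in seq_len(ef$blocks[i])) {
      layers <- c(layers, list(nn_mbconv(prev, ef$widths[i], ef$expansion,
                                         ef$se_ratio)))
      prev <- ef$widths[i]
    }
  }
  do.call(nn_seq, layers)
}

# FEFEM trunk: 7x7 stem + residual stages.
build_fefem_trunk <- function(cfg) {
  ff <- cfg$fefem
  bottleneck <- identical(ff$block_type %||% "bottleneck", "bottleneck")
  exp_f <- if (bottleneck) ff$bn_expansion %||% 4 else 1
  layers <- list(
    nn_conv2d(3, ff$stem, 7, 2, 3, bias = FALSE), nn_batchnorm2d(ff$stem),
    nn_act("relu"), nn_maxpool(3, 2, 1)
  )
  prev <- ff$stem
  for (i in seq_along(ff$widths)) {
    for (b in seq_len(ff$blocks[i])) {
      stride <- if (b == 1 && i > 1) 2 else 1
      out_ch <- ff$widths[i] * exp_f
      blk <- if (bottleneck) {
        nn_bottleneck(prev, ff$widths[i], out_ch, stride)
      } else {
        nn_basicblock(prev, out_ch, stride)
      }
      layers <- c(layers, list(blk))
      prev <- out_ch
    }
  }
  do.call(nn_seq, layers)
}

# Token head: flatten the final map to tokens, project through the
# calibrated hidden width to d_model.
build_token_head <- function(c_final, cfg) {
  nn_seq(nn_tokenize(), nn_tokenlinear(c_final, cfg$proj_width),
         nn_act("gelu"), nn_tokenlinear(cfg$proj_width, cfg$d_model))
}

# Parameter-holding embedding "layer" for class token and modality-type
# embeddings (gradients accumulated by the fusion forward/backward).
nn_embeddings <- function(d_model) {
  e <- new_layer("embeddings")
  e$par$cls <- stats::rnorm(d_model, 0, 0.02)
  e$par$type_eeg <- stats::rnorm(d_model, 0, 0.02)
  e$par$type_face <- stats::rnorm(d_model, 0, 0.02)
  e$out_shape <- function(s) s
  e$macs <- function(s) 0
  e
}

#' Build an EEG encoder (EFEM) classifier or token encoder
#'
#' @param cfg A `model_config`.
#' @param in_ch Input channels (5 band maps).
#' @param seed RNG seed for initialization.
#' @return List with `trunk`, `head`, `classifier` layers; class
#'   `efem_encoder`.
#' @export
build_efem <- function(cfg = model_config(), in_ch = 5, seed = 1) {
  with_seed(seed, {
    trunk <- build_efem_trunk(cfg, in_ch)
    s <- trunk$out_shape(c(cfg$eeg_size, cfg$eeg_size, in_ch))
    head <- build_token_head(s[3], cfg)
    classifier <- nn_linear(cfg$d_model, cfg$n_classes)
    structure(list(trunk = trunk, head = head, classifier = classifier,
                   cfg = cfg, in_ch = in_ch, map_shape = s),
              class = "efem_encoder")
  })
}

#' Build a face encoder (FEFEM) classifier or token encoder
#'
#' @param cfg A `model_config`.
#' @param seed RNG seed for initialization.
#' @return List with `trunk`, `head`, `classifier`; class `fefem_encoder`.
#' @export
build_fefem <- function(cfg = model_config(), seed = 2) {
  with_seed(seed, {
    trunk <- build_fefem_trunk(cfg)
    s <- trunk$out_shape(c(cfg$face_size, cfg$face_size, 3))
    head <- build_token_head(s[3], cfg)
    classifier <- nn_linear(cfg$d_model, cfg$n_classes)
    structure(list(trunk = trunk, head = head, classifier = classifier,
                   cfg = cfg, map_shape = s),
              class = "fefem_encoder")
  })
}

#' EEG encoder forward pass to a token sequence
#'
#' @param enc An `efem_encoder`.
#' @param stack Array H x W x C x N of topographic band stacks.
#' @param train Training mode flag (BatchNorm batch statistics).
#' @return Tokens T_e x d_model x N.
#' @export
efem_forward <- function(enc, stack, train = FALSE) {
  d <- dim(stack)
  abort_if(d[3] != enc$in_ch, "expected ", enc$in_ch, "-channel input, got ",
           d[3], " channels")
  enc$head$forward(enc$trunk$forward(stack, train), train)
}

#' Face encoder forward pass to a token sequence
#'
#' @param enc A `fefem_encoder`.
#' @param frames Array H x W x 3 x N of normalized face frames.
#' @param train Training mode flag.
#' @return Tokens T_f x d_model x N.
#' @export
fefem_forward <- function(enc, frames, train = FALSE) {
  d <- dim(frames)
  abort_if(d[1] != enc$cfg$face_size || d[2] != enc$cfg$face_size,
           "expected ", enc$cfg$face_size, "x", enc$cfg$face_size, " frames")
  enc$head$forward(enc$trunk$forward(frames, train), train)
}

#' Build the full multimodal fusion model
#'
#' @param cfg A `model_config`.
#' @param seed RNG seed for initialization.
#' @return A `fusion_model`: per-band EEG encoder trunk (shared weights),
#'   face encoder, embeddings, Transformer blocks and classifier head.
#' @export
build_fusion_model <- function(cfg = model_config(), seed = 1) {
  with_seed(seed, {
    eeg_trunk <- build_efem_trunk(cfg, in_ch = 1)
    s_e <- eeg_trunk$out_shape(c(cfg$eeg_size, cfg$eeg_size, 1))
    eeg_head <- build_token_head(s_e[3], cfg)
    face_trunk <- build_fefem_trunk(cfg)
    s_f <- face_trunk$out_shape(c(cfg$face_size, cfg$face_size, 3))
    face_head <- build_token_head(s_f[3], cfg)
    emb <- nn_embeddings(cfg$d_model)
    blocks <- lapply(seq_len(cfg$depth),
                     function(i) nn_transformer_block(cfg$d_model, cfg$heads,
                                                      cfg$mlp_ratio))
    final_ln <- nn_layernorm(cfg$d_model)
    classifier <- nn_linear(cfg$d_model, cfg$n_classes)
    m <- structure(list(eeg_trunk = eeg_trunk, eeg_head = eeg_head,
                        face_trunk = face_trunk, face_head = face_head,
                        emb = emb, blocks = blocks, final_ln = final_ln,
                        classifier = classifier, cfg = cfg,
                        tokens_per_band = s_e[1] * s_e[2],
                        face_grid = s_f[1:2]),
                   class = "fusion_model")
    m
  })
}

# All parameter-bearing layers of a model (for the optimizer and counting).
model_layers <- function(model) {
  if (inherits(model, "fusion_model")) {
    c(walk_layers(model$eeg_trunk), walk_layers(model$eeg_head),
      walk_layers(model$face_trunk), walk_layers(model$face_head),
      list(model$emb),
      unlist(lapply(model$blocks, walk_layers), recursive = FALSE),
      walk_layers(model$final_ln), walk_layers(model$classifier))
  } else if (inherits(model, c("efem_encoder", "fefem_encoder"))) {
    c(walk_layers(model$trunk), walk_layers(model$head),
      walk_layers(model$classifier))
  } else if (inherits(model, "concat_model")) {
    c(model_layers(model$eeg), model_layers(model$face),
      walk_layers(model$head))
  } else {
    walk_layers(model)
  }
}

# Per-band application of the EEG trunk: (H, W, 5, N) is reinterpreted as a
# batch of 5N single-band maps; tokens are regrouped band-major so band b
# occupies token rows ((b-1)*T_s + 1):(b*T_s).
eeg_tokens_per_band <- function(model, stack, train = FALSE) {
  d <- dim(stack)
  xb <- stack
  dim(xb) <- c(d[1], d[2], 1, 5 * d[4])
  tok <- model$eeg_head$forward(model$eeg_trunk$forward(xb, train), train)
  td <- dim(tok) # T_s, d_model, 5N
  tok4 <- array(tok, c(td[1], td[2], 5, d[4]))
  tok4 <- aperm(tok4, c(1, 3, 2, 4))
  dim(tok4) <- c(td[1] * 5, td[2], d[4])
  tok4
}

eeg_tokens_per_band_backward <- function(model, dtok, d_stack) {
  Ts <- model$tokens_per_band
  dm <- dim(dtok)
  d4 <- array(dtok, c(Ts, 5, dm[2], dm[3]))
  d4 <- aperm(d4, c(1, 3, 2, 4))
  dim(d4) <- c(Ts, dm[2], 5 * dm[3])
  dmap <- model$eeg_head$backward(d4)
  dxb <- model$eeg_trunk$backward(dmap)
  dim(dxb) <- d_stack
  dxb
}

#' Fusion model forward pass
#'
#' Adds modality-type embeddings to the two token sequences, prepends the
#' class token, applies the pre-LN Transformer blocks and classifies from
#' the final class token.
#'
#' @param model A `fusion_model`.
#' @param eeg_tokens T_e x d_model x N tokens (band-major groups).
#' @param face_tokens T_f x d_model x N tokens.
#' @param train Training mode flag.
#' @return List: `logits` (N x 4), `attn` (list per block of
#'   T x T x heads x N attention weights).
#' @export
ffm_forward <- function(model, eeg_tokens, face_tokens, train = FALSE) {
  d_model <- model$cfg$d_model
  abort_if(dim(eeg_tokens)[2] != d_model || dim(face_tokens)[2] != d_model,
           "token width must equal d_model")
  Te <- dim(eeg_tokens)[1]; Tf <- dim(face_tokens)[1]
  N <- dim(eeg_tokens)[3]
  X <- array(0, c(1 + Te + Tf, d_model, N))
  X[1, , ] <- model$emb$par$cls
  X[1 + seq_len(Te), , ] <- eeg_tokens +
    rep(rep(model$emb$par$type_eeg, each = Te), times = N)
  X[1 + Te + seq_len(Tf), , ] <- face_tokens +
    rep(rep(model$emb$par$type_face, each = Tf), times = N)
  attn <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    X <- model$blocks[[i]]$forward(X, train)
    attn[[i]] <- model$blocks[[i]]$msa$last_attn
  }
  Xn <- model$final_ln$forward(X, train)
  cls <- t(matrix(Xn[1, , ], d_model, N))
  logits <- model$classifier$forward(cls, train)
  list(logits = logits, attn = attn, Te = Te, Tf = Tf)
}

# Backward through the fusion stage; returns gradients w.r.t. the two
# token stacks and accumulates embedding gradients.
ffm_backward <- function(model, dlogits, Te, Tf) {
  d_model <- model$cfg$d_model
  dcls <- model$classifier$backward(dlogits)
  N <- nrow(dcls)
  Ttot <- 1 + Te + Tf
  dXn <- array(0, c(Ttot, d_model, N))
  dXn[1, , ] <- t(dcls)
  dX <- model$final_ln$backward(dXn)
  for (blk in rev(model$blocks)) dX <- blk$backward(dX)
  dcls_tok <- dX[1, , , drop = FALSE]
  model$emb$gr$cls <- rowSums(matrix(dcls_tok, d_model, N))
  deeg <- dX[1 + seq_len(Te), , , drop = FALSE]
  dface <- dX[1 + Te + seq_len(Tf), , , drop = FALSE]
  model$emb$gr$type_eeg <- colSums(matrix(aperm(deeg, c(1, 3, 2)),
                                          Te * N, d_model))
  model$emb$gr$type_face <- colSums(matrix(aperm(dface, c(1, 3, 2)),
                                           Tf * N, d_model))
  list(deeg = deeg, dface = dface)
}

#' Concatenation-fusion baseline head
#'
#' Mean-pools each modality's tokens, concatenates the two embeddings and
#' applies a two-layer MLP.
#'
#' @param cfg A `model_config`.
#' @param seed RNG seed.
#' @return A `concat_model` with `eeg`, `face` encoders and `head`.
#' @export
build_concat_model <- function(cfg = model_config(), seed = 1) {
  eeg <- build_efem(cfg, in_ch = 5, seed = seed)
  face <- build_fefem(cfg, seed = seed + 1)
  head <- with_seed(seed + 2, nn_seq(nn_linear(2 * cfg$d_model, cfg$d_model),
                                     nn_act("gelu"),
                                     nn_linear(cfg$d_model, cfg$n_classes)))
  structure(list(eeg = eeg, face = face, head = head, cfg = cfg),
            class = "concat_model")
}

#' Concatenation-fusion forward pass
#'
#' @param model A `concat_model`.
#' @param eeg_tokens,face_tokens Token stacks (T x d_model x N).
#' @return N x 4 logits.
#' @export
fuse_concat <- function(model, eeg_tokens, face_tokens) {
  pe <- t(apply(eeg_tokens, 3, colMeans))  # N x d_model, mean over tokens
  pf <- t(apply(face_tokens, 3, colMeans))
  model$head$forward(cbind(pe, pf), train = TRUE)
}

#' Decision-level fusion of two class posteriors
#'
#' Equal-weight average of the two posterior matrices; rows that do not sum
#' to one are renormalized with a warning.
#'
#' @param p_eeg,p_face N x 4 class posterior matrices.
#' @return N x 4 fused posterior.
#' @export
fuse_decision <- function(p_eeg, p_face) {
  fix <- function(p, nm) {
    rs <- rowSums(p)
    if (any(abs(rs - 1) > 1e-6)) {
      warning("non-normalized ", nm, " posteriors; renormalizing")
      p <- p / rs
    }
    p
  }
  (fix(p_eeg, "EEG") + fix(p_face, "face")) / 2
}

# ---------------------------------------------------------------------------
# Counting utilities

#' Count trainable parameters and multiply-accumulates
#'
#' Parameter totals are exact sums over all trainable arrays; MAC counts
#' use layer-shape arithmetic (k^2 * Cin * Cout * Hout * Wout per
#' convolution, in*out per affine map, attention products in the fusion
#' blocks), with the 1 MAC = 1 FLOP convention of published model-budget
#' tables.
#'
#' @param model A built encoder, fusion model, or raw layer.
#' @param input_shape Input shape (H, W, C) for raw layers; built models
#'   know their own input sizes.
#' @return List with `params` and `macs`.
#' @export
count_params_flops <- function(model, input_shape = NULL) {
  if (inherits(model, "fusion_model")) {
    cfg <- model$cfg
    p <- sum(vapply(model_layers(model),
                    function(l) sum(vapply(l$par, length, 0L)), 0))
    s_e <- c(cfg$eeg_size, cfg$eeg_size, 1)
    macs_eeg <- 5 * (model$eeg_trunk$macs(s_e) +
                       model$eeg_head$macs(model$eeg_trunk$out_shape(s_e)))
    s_f <- c(cfg$face_size, cfg$face_size, 3)
    macs_face <- model$face_trunk$macs(s_f) +
      model$face_head$macs(model$face_trunk$out_shape(s_f))
    Te <- 5 * model$tokens_per_band
    Tf <- prod(model$face_grid)
    s_tok <- c(1 + Te + Tf, cfg$d_model)
    macs_fuse <- sum(vapply(model$blocks, function(b) b$macs(s_tok), 0)) +
      cfg$d_model * cfg$n_classes
    list(params = p, macs = macs_eeg + macs_face + macs_fuse)
  } else if (inherits(model, c("efem_encoder", "fefem_encoder"))) {
    cfg <- model$cfg
    s <- if (inherits(model, "efem_encoder")) {
      c(cfg$eeg_size, cfg$eeg_size, model$in_ch)
    } else {
      c(cfg$face_size, cfg$face_size, 3)
    }
    p <- sum(vapply(model_layers(model),
                    function(l) sum(vapply(l$par, length, 0L)), 0))
    m <- model$trunk$macs(s) + model$head$macs(model$trunk$out_shape(s)) +
      cfg$d_model * cfg$n_classes
    list(params = p, macs = m)
  } else {
    abort_if(is.null(input_shape), "input_shape required for raw layers")
    list(params = n_params(model), macs = model$macs(input_shape))
  }
}

#' Build a standard 18-layer residual image classifier
#'
#' The ubiquitous basic-block residual network (stem 7x7/s2 + max-pool,
#' four stages of two basic blocks at widths 64/128/256/512, global
#' pooling, 1000-way linear head), used as the complexity baseline in
#' model-budget comparisons.
#'
#' @param n_classes Output classes (default 1000).
#' @return A network layer (sequential container).
#' @export
build_resnet18 <- function(n_classes = 1000) {
  with_seed(0, {
    layers <- list(
      nn_conv2d(3, 64, 7, 2, 3, bias = FALSE), nn_batchnorm2d(64),
      nn_act("relu"), nn_maxpool(3, 2, 1)
    )
    prev <- 64
    widths <- c(64, 128, 256, 512)
    for (i in 1:4) {
      for (b in 1:2) {
        stride <- if (b == 1 && i > 1) 2 else 1
        layers <- c(layers, list(nn_basicblock(prev, widths[i], stride)))
        prev <- widths[i]
      }
    }
    layers <- c(layers, list(nn_gap(), nn_linear(512, n_classes)))
    do.call(nn_seq, layers)
  })
}
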