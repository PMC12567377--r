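test_that("attention matches its defining cases and the loop oracle", {
  set.seed(1)
  # single key/value: output equals V regardless of Q
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rnorm(4), 1, 4)
  V <- matrix(rnorm(4), 1, 4)
  at <- attention(Q, K, V, 4)
  expect_equal(at$out, rbind(V[1, ], V[1, ], V[1, ]), ignore_attr = TRUE)
  # equal logits (Q orthogonal to all keys): output is the mean of V rows
  K2 <- matrix(rnorm(20), 5, 4)
  V2 <- matrix(rnorm(20), 5, 4)
  at2 <- attention(matrix(0, 2, 4), K2, V2, 4)
  expect_equal(at2$out[1, ], colMeans(V2), tolerance = 1e-12)
  # rows of the attention matrix sum to one, non-negative
  Q3 <- matrix(rnorm(12), 3, 4); K3 <- matrix(rnorm(20), 5, 4)
  V3 <- matrix(rnorm(20), 5, 4)
  at3 <- attention(Q3, K3, V3, 4)
  expect_equal(rowSums(at3$attn), rep(1, 3))
  expect_true(all(at3$attn >= 0))
  # brute-force exp/normalize/accumulate oracle
  expect_equal(at3$out, oracle_attention(Q3, K3, V3, 4), tolerance = 1e-6)
  expect_error(attention(Q3, K3, V3, 0), "positive")
})

test_that("multi-head attention equals per-head manual computation", {
  set.seed(2)
  d_model <- 8
  expect_error(nn_mhsa(8, 3), "divisible")
  # h = 1 with identity output map equals plain attention on projections
  m1 <- nn_mhsa(d_model, 1)
  m1$par$Wo <- diag(d_model)
  m1$par$bo <- numeric(d_model)
  Z <- matrix(rnorm(5 * d_model), 5, d_model)
  got <- multi_head(Z, m1)
  Q <- Z %*% m1$par$Wq + rep(m1$par$bq, each = 5)
  K <- Z %*% m1$par$Wk + rep(m1$par$bk, each = 5)
  V <- Z %*% m1$par$Wv + rep(m1$par$bv, each = 5)
  expect_equal(got, attention(Q, K, V, d_model)$out, tolerance = 1e-10)
  # h = 2 vs a manual two-loop head computation
  m2 <- nn_mhsa(d_model, 2)
  got2 <- multi_head(Z, m2)
  Q <- Z %*% m2$par$Wq + rep(m2$par$bq, each = 5)
  K <- Z %*% m2$par$Wk + rep(m2$par$bk, each = 5)
  V <- Z %*% m2$par$Wv + rep(m2$par$bv, each = 5)
  H <- matrix(0, 5, d_model)
  for (h in 1:2) {
    cols <- ((h - 1) * 4 + 1):(h * 4)
    H[, cols] <- oracle_attention(Q[, cols], K[, cols], V[, cols], 4)
  }
  manual <- H %*% m2$par$Wo + rep(m2$par$bo, each = 5)
  expect_equal(got2, manual, tolerance = 1e-6)
  # output width is d_model for any divisor head count
  for (h in c(1, 2, 4, 8)) {
    expect_equal(ncol(multi_head(Z, nn_mhsa(d_model, h))), d_model)
  }
})

test_that("pre-LN blocks with zeroed residual branches are identities", {
  set.seed(3)
  blk <- nn_transformer_block(8, 2, 2)
  # zero every parameter feeding the two residual branches
  blk$msa$par$Wo <- matrix(0, 8, 8); blk$msa$par$bo <- numeric(8)
  blk$mlp$layers[[3]]$par$W <- matrix(0, 16, 8)
  blk$mlp$layers[[3]]$par$b <- numeric(8)
  x <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  expect_equal(blk$forward(x, train = FALSE), x, tolerance = 1e-12)
})

test_that("encoders honor their shape contracts and reject bad input", {
  cfg <- desk_model_config()
  ef <- build_efem(cfg, in_ch = 5, seed = 1)
  x <- array(rnorm(64 * 64 * 5 * 3), c(64, 64, 5, 3))
  tok <- efem_forward(ef, x)
  expect_equal(dim(tok)[2:3], c(cfg$d_model, 3))
  s <- ef$trunk$out_shape(c(64, 64, 5))
  expect_equal(dim(tok)[1], s[1] * s[2])
  expect_error(efem_forward(ef, array(0, c(64, 64, 3, 2))), "channel")
  # zero input stays finite
  tok0 <- efem_forward(ef, array(0, c(64, 64, 5, 2)))
  expect_true(all(is.finite(tok0)))
  ff <- build_fefem(cfg, seed = 1)
  xf <- array(rnorm(48 * 48 * 3 * 3), c(48, 48, 3, 3))
  tf_ <- fefem_forward(ff, xf)
  expect_equal(dim(tf_)[2:3], c(cfg$d_model, 3))
  expect_error(fefem_forward(ff, array(0, c(32, 32, 3, 2))), "48x48")
})

test_that("squeeze-excitation gates actually modulate the output", {
  set.seed(4)
  se <- mmhafnn:::nn_se(8, 0.25)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  y <- se$forward(x, train = FALSE)
  # bypass: force all gates to one by zeroing the gate map and saturating
  # its bias, then compare
  se$fc2$par$W <- matrix(0, nrow(se$fc2$par$W), ncol(se$fc2$par$W))
  se$fc2$par$b <- rep(30, 8) # sigmoid(30) ~ 1
  y_bypass <- se$forward(x, train = FALSE)
  expect_equal(y_bypass, x, tolerance = 1e-9) # gates 1 = identity
  expect_gt(max(abs(y - y_bypass)), 1e-3)     # active gates differ
})

test_that("residual blocks with zeroed bodies reduce to the skip path", {
  set.seed(5)
  bn <- mmhafnn:::nn_bottleneck(6, 4, 6, 1)
  # zero the last conv of the body: the residual branch contributes nothing
  body_convs <- Filter(function(l) l$type == "conv2d", bn$body$layers)
  last <- body_convs[[length(body_convs)]]
  last$par$W <- 0 * last$par$W
  x <- array(abs(rnorm(6 * 6 * 6 * 2)), c(6, 6, 6, 2)) # positive: ReLU-safe
  expect_equal(bn$forward(x, train = TRUE), x, tolerance = 1e-9)
})

test_that("fusion forward is permutation-invariant within a modality", {
  set.seed(6)
  cfg <- desk_model_config()
  net <- build_fusion_model(cfg, seed = 2)
  topo <- array(rnorm(64 * 64 * 5 * 2), c(64, 64, 5, 2))
  faces <- array(rnorm(48 * 48 * 3 * 2), c(48, 48, 3, 2))
  te <- mmhafnn:::eeg_tokens_per_band(net, topo)
  tf_ <- net$face_head$forward(net$face_trunk$forward(faces, FALSE), FALSE)
  out <- ffm_forward(net, te, tf_)
  # permute tokens inside each modality: class-token logits unchanged
  pe <- sample(dim(te)[1]); pf <- sample(dim(tf_)[1])
  out_p <- ffm_forward(net, te[pe, , , drop = FALSE], tf_[pf, , , drop = FALSE])
  expect_equal(out_p$logits, out$logits, tolerance = 1e-9)
  # attention records are row-stochastic at every layer
  for (A in out$attn) {
    sums <- apply(A, c(1, 3, 4), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("a depth-zero fusion stack ignores its inputs", {
  cfg <- desk_model_config()
  cfg$depth <- 0
  net <- build_fusion_model(cfg, seed = 3)
  te1 <- array(rnorm(5 * cfg$d_model * 2), c(5, cfg$d_model, 2))
  te2 <- array(rnorm(5 * cfg$d_model * 2), c(5, cfg$d_model, 2))
  tf1 <- array(rnorm(4 * cfg$d_model * 2), c(4, cfg$d_model, 2))
  o1 <- ffm_forward(net, te1, tf1)
  o2 <- ffm_forward(net, te2, tf1)
  expect_equal(o1$logits, o2$logits, tolerance = 1e-12)
})

test_that("concatenation fusion pools tokens and feeds both encoders", {
  set.seed(7)
  cfg <- desk_model_config()
  cm <- build_concat_model(cfg, seed = 4)
  te <- array(rnorm(5 * cfg$d_model * 2), c(5, cfg$d_model, 2))
  tf_ <- array(rnorm(4 * cfg$d_model * 2), c(4, cfg$d_model, 2))
  lg <- fuse_concat(cm, te, tf_)
  expect_equal(dim(lg), c(2, 4))
  # identical pooled embeddings give identical logits
  te2 <- te[c(2, 1, 3, 5, 4), , , drop = FALSE] # permutation: same mean
  expect_equal(fuse_concat(cm, te2, tf_), lg, tolerance = 1e-10)
  # gradient flows into both encoders (finite-difference on one weight each)
  topo <- array(rnorm(64 * 64 * 5 * 2), c(64, 64, 5, 2))
  faces <- array(rnorm(48 * 48 * 3 * 2), c(48, 48, 3, 2))
  y <- c(1, 3)
  loss_at <- function() {
    # train mode so the loss surface matches the batch-statistic gradients
    mmhafnn:::model_step(cm, "concat", topo, faces, y = y, train = TRUE)$loss
  }
  mmhafnn:::model_step(cm, "concat", topo, faces, y = y, train = TRUE)
  for (enc in list(cm$eeg$trunk$layers[[1]], cm$face$trunk$layers[[1]])) {
    g <- enc$gr$W[1]
    eps <- 1e-5
    w0 <- enc$par$W[1]
    enc$par$W[1] <- w0 + eps; lp <- loss_at()
    enc$par$W[1] <- w0 - eps; lm <- loss_at()
    enc$par$W[1] <- w0
    expect_equal(g, (lp - lm) / (2 * eps), tolerance = 1e-4)
    expect_gt(abs(g), 0)
  }
})

test_that("decision fusion averages posteriors and renormalizes", {
  p <- matrix(c(0.6, 0.4, 0, 0), 1)
  q <- matrix(c(0.2, 0.8, 0, 0), 1)
  expect_equal(as.vector(fuse_decision(p, q)), c(0.4, 0.6, 0, 0))
  expect_equal(fuse_decision(p, p), p)
  set.seed(8)
  a <- matrix(runif(8), 2); a <- a / rowSums(a)
  b <- matrix(runif(8), 2); b <- b / rowSums(b)
  expect_equal(rowSums(fuse_decision(a, b)), c(1, 1))
  expect_warning(fuse_decision(a * 2, b), "renormalizing")
})

test_that("parameter and MAC counting follows layer-shape arithmetic", {
  # single 1x1 convolution, 3 -> 8 channels, with bias
  cv <- mmhafnn:::nn_conv2d(3, 8, 1)
  expect_equal(count_params_flops(cv, c(10, 10, 3))$params, 3 * 8 + 8)
  # depthwise 3x3 on d channels: 9d weights + d biases, versus 9d^2 full
  d <- 16
  dw <- mmhafnn:::nn_dwconv2d(d, 3)
  expect_equal(count_params_flops(dw, c(8, 8, d))$params, 9 * d + d)
  full <- mmhafnn:::nn_conv2d(d, d, 3, pad = 1, bias = FALSE)
  expect_equal(count_params_flops(full, c(8, 8, d))$params, 9 * d^2)
  expect_equal(count_params_flops(dw, c(8, 8, d))$macs, 9 * d * 8 * 8)
  # a small face encoder against a hand-computed layer-by-layer sum
  cfg <- desk_model_config()
  cfg$fefem <- list(stem = 4, widths = c(4, 6), blocks = c(1, 1),
                    block_type = "bottleneck", bn_expansion = 2)
  cfg$face_size <- 32
  ff <- build_fefem(cfg, seed = 1)
  stem_p <- 7 * 7 * 3 * 4 + 2 * 4
  # block 1: 4 -> (1x1) 4 -> (3x3) 4 -> (1x1) 8, plus projection shortcut
  blk1 <- (4 * 4 + 2 * 4) + (9 * 4 * 4 + 2 * 4) + (4 * 8 + 2 * 8) +
    (4 * 8 + 2 * 8)
  # block 2: 8 -> 6 -> 6 -> 12 at stride 2, plus projection shortcut
  blk2 <- (8 * 6 + 2 * 6) + (9 * 6 * 6 + 2 * 6) + (6 * 12 + 2 * 12) +
    (8 * 12 + 2 * 12)
  c_final <- 12
  head_p <- (c_final * cfg$proj_width + cfg$proj_width) +
    (cfg$proj_width * cfg$d_model + cfg$d_model)
  clf_p <- cfg$d_model * 4 + 4
  expect_equal(count_params_flops(ff)$params,
               stem_p + blk1 + blk2 + head_p + clf_p)
})

test_that("the reference model's parameter total is architecture-determined", {
  p1 <- count_params_flops(build_fusion_model(model_config(), seed = 1))$params
  p2 <- count_params_flops(build_fusion_model(model_config(), seed = 99))$params
  expect_identical(p1, p2)
})
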