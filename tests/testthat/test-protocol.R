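toy_manifest <- function(n_subjects = 1, clips_per_emotion = 5, windows = 3) {
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    clips <- data.frame(subject = s,
                        clip = seq_len(4 * clips_per_emotion),
                        emotion = rep(EMOTIONS, each = clips_per_emotion))
    do.call(rbind, lapply(seq_len(nrow(clips)), function(i) {
      data.frame(clips[i, ], window = seq_len(windows), row.names = NULL)
    }))
  }))
}

test_that("clip-wise folds are stratified and leakage-free", {
  man <- toy_manifest(n_subjects = 3)
  split <- make_clip_folds(man, k = 5, seed = 1)
  a <- split$assignment
  # 20 clips -> 5 folds x 4 clips, one per emotion, per subject
  for (s in 1:3) {
    tab <- table(a$fold[a$subject == s], a$emotion[a$subject == s])
    expect_true(all(tab == 1))
  }
  expect_silent(check_fold_integrity(split, man))
  # leakage scan: no clip on both sides of any fold
  for (f in 1:5) {
    w <- fold_windows(split, man, f)
    expect_equal(length(intersect(w$train, w$val)), 0)
    expect_equal(sort(c(w$train, w$val)), seq_len(nrow(man)))
    tr_clips <- unique(paste(man$subject[w$train], man$clip[w$train]))
    va_clips <- unique(paste(man$subject[w$val], man$clip[w$val]))
    expect_equal(length(intersect(tr_clips, va_clips)), 0)
  }
  # different seeds give different (but both valid) assignments
  split2 <- make_clip_folds(man, k = 5, seed = 2)
  expect_false(identical(a$fold, split2$assignment$fold))
  expect_silent(check_fold_integrity(split2, man))
  # indivisible clip counts are rejected
  expect_error(make_clip_folds(toy_manifest(clips_per_emotion = 3), k = 5),
               "not divisible")
})

test_that("leave-one-subject-out splits exclude the held-out subject", {
  man <- toy_manifest(n_subjects = 4)
  splits <- make_loso_splits(man)
  expect_equal(length(splits), 4)
  for (sp in splits) {
    expect_equal(length(sp$train_subjects), 3)
    expect_false(sp$test_subject %in% sp$train_subjects)
  }
  expect_setequal(vapply(splits, `[[`, 1, "test_subject"), 1:4)
  expect_error(make_loso_splits(toy_manifest(n_subjects = 1)), "2 subjects")
})

test_that("cosine schedule hits its endpoints and midpoint exactly", {
  cfg <- list(eta_max = 1e-3, eta_min = 0, T_max = 100)
  expect_identical(cosine_lr(c(cfg, T_cur = 0)), 1e-3)
  expect_equal(cosine_lr(c(cfg, T_cur = 100)), 0)
  expect_equal(cosine_lr(c(cfg, T_cur = 50)), (1e-3 + 0) / 2)
  cfg2 <- list(eta_max = 1e-2, eta_min = 1e-4, T_max = 40)
  expect_equal(cosine_lr(c(cfg2, T_cur = 40)), 1e-4)
  expect_equal(cosine_lr(c(cfg2, T_cur = 20)), (1e-2 + 1e-4) / 2)
  # monotone non-increasing over a sweep
  lr <- vapply(0:40, function(t) cosine_lr(c(cfg2, T_cur = t)), 0)
  expect_true(all(diff(lr) <= 1e-15))
  expect_error(cosine_lr(list(eta_max = 1, eta_min = 0, T_max = 0, T_cur = 0)),
               "T_max")
  expect_error(cosine_lr(c(cfg, T_cur = 101)), "T_cur")
})

test_that("evaluation reports accuracy, confusion and per-subject detail", {
  y <- rep(1:4, each = 10)
  data <- list(y = y, subject = rep(1:2, 20))
  perfect <- factor(EMOTIONS[y], levels = EMOTIONS)
  ev <- evaluate(perfect, data)
  expect_equal(ev$accuracy, 100)
  expect_equal(unclass(ev$confusion), diag(4), ignore_attr = TRUE)
  expect_true(all(ev$per_subject == 100))
  # uniform-random predictions sit near chance (exact binomial band)
  set.seed(1)
  n <- 4000
  data2 <- list(y = sample(1:4, n, TRUE), subject = rep(1, n))
  rnd <- factor(EMOTIONS[sample(1:4, n, TRUE)], levels = EMOTIONS)
  ev2 <- evaluate(rnd, data2)
  ci <- stats::binom.test(round(n / 4), n, 0.25)$conf.int
  expect_gt(ev2$accuracy / 100, 0.25 - 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(ev2$accuracy / 100, 0.25 + 3 * sqrt(0.25 * 0.75 / n))
  expect_equal(unname(rowSums(ev2$confusion)), rep(1, 4), tolerance = 1e-12)
  expect_error(evaluate(perfect, list(y = integer(0))), "empty")
})

test_that("paired t-test matches the closed form and its symmetries", {
  a <- c(70, 75, 80, 85)
  expect_equal(paired_ttest(a, a), list(t = 0, p = 1, df = 3, mean_diff = 0))
  # differences (1, 2, 3): t = mean / (sd / sqrt(n)) = 2 / (1 / sqrt(3))
  b <- c(10, 20, 30)
  r <- paired_ttest(b + c(1, 2, 3), b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-2 * sqrt(3), 2), tolerance = 1e-9)
  # antisymmetry
  r2 <- paired_ttest(b, b + c(1, 2, 3))
  expect_equal(r2$t, -r$t, tolerance = 1e-9)
  expect_equal(r2$p, r$p, tolerance = 1e-9)
  # zero-variance non-zero differences are flagged
  expect_warning(r3 <- paired_ttest(c(2, 3, 4), c(1, 2, 3)), "undefined")
  expect_true(is.na(r3$t))
  expect_error(paired_ttest(1:3, 1:4), "match")
})

test_that("training is seeded, starts at chance loss and learns", {
  sm <- fix_small_data()
  split <- make_clip_folds(sm$data$manifest, k = 2, seed = 3)
  w <- fold_windows(split, sm$data$manifest, 1)
  tr <- mmhafnn:::subset_data(sm$data, w$train)
  cfg <- desk_model_config()
  # untrained 4-class model on balanced labels: loss ~ ln 4
  net <- build_efem(cfg, in_ch = 5, seed = 9)
  st <- mmhafnn:::model_step(net, "efem", tr$topo[, , , 1:16, drop = FALSE],
                             tr$faces[, , , 1:16, drop = FALSE],
                             y = tr$y[1:16], train = FALSE)
  expect_equal(st$loss, log(4), tolerance = 0.2)
  # identical seed and data give identical final weights
  f1 <- mmha_train(tr, method = "efem", cfg = cfg, epochs = 2, seed = 5)
  f2 <- mmha_train(tr, method = "efem", cfg = cfg, epochs = 2, seed = 5)
  expect_identical(coef(f1), coef(f2))
  # training loss decreases on separable synthetic data
  f3 <- mmha_train(tr, method = "efem", cfg = cfg, epochs = 6, seed = 5)
  sm3 <- stats::filter(f3$history$loss, rep(1 / 2, 2), sides = 1)
  expect_lt(f3$history$loss[6], f3$history$loss[1])
  expect_lt(min(sm3, na.rm = TRUE), sm3[2])
  expect_error(mmha_train(list(y = integer(0)), "efem"), "empty")
})

test_that("attribution renormalizes per group and respects token counts", {
  sm <- fix_small_data()
  cfg <- desk_model_config()
  idx <- seq(1, length(sm$data$y), by = 10)
  sub <- mmhafnn:::subset_data(sm$data, idx)
  fit <- mmha_train(sub, method = "mmha", cfg = cfg, epochs = 1, seed = 2)
  rep_ <- attention_attribution(fit, sub)
  expect_equal(sum(rep_$band_weights), 1, tolerance = 1e-9)
  expect_equal(sum(rep_$face_weights), 1, tolerance = 1e-9)
  expect_true(all(rep_$band_weights >= 0))
  # uniform attention (zeroed query map in the last block): group weights
  # exactly proportional to token counts
  net <- fit$network
  last <- net$blocks[[length(net$blocks)]]
  last$msa$par$Wq <- 0 * last$msa$par$Wq
  last$msa$par$bq <- 0 * last$msa$par$bq
  rep_u <- attention_attribution(fit, sub)
  Ts <- net$tokens_per_band
  expect_equal(unname(rep_u$band_weights), rep(Ts, 5) / (5 * Ts),
               tolerance = 1e-9)
  masks <- face_region_masks(net$face_grid[1], net$face_grid[2])
  counts <- as.vector(table(masks))
  expect_equal(unname(rep_u$face_weights), counts / sum(counts),
               tolerance = 1e-9)
  # masks must partition the grid
  bad <- masks
  bad[1] <- NA
  expect_error(attention_attribution(fit, sub, region_masks = bad),
               "partition")
  # grids of several sizes are partitioned
  for (g in list(c(2, 2), c(4, 4), c(8, 8), c(3, 5))) {
    m <- face_region_masks(g[1], g[2])
    expect_equal(length(m), g[1] * g[2])
    expect_false(anyNA(m))
  }
})

test_that("the attention record equals an explicit loop over heads", {
  set.seed(11)
  cfg <- desk_model_config()
  net <- build_fusion_model(cfg, seed = 4)
  te <- array(rnorm(5 * cfg$d_model * 2), c(5, cfg$d_model, 2))
  tf_ <- array(rnorm(4 * cfg$d_model * 2), c(4, cfg$d_model, 2))
  out <- ffm_forward(net, te, tf_)
  # rebuild the last block's input by replaying the stack, then compare the
  # recorded attention with a direct loop
  d_model <- cfg$d_model
  Te <- 5; Tf <- 4
  X <- array(0, c(1 + Te + Tf, d_model, 2))
  X[1, , ] <- net$emb$par$cls
  X[1 + seq_len(Te), , ] <- te + rep(rep(net$emb$par$type_eeg, each = Te), 2)
  X[1 + Te + seq_len(Tf), , ] <- tf_ +
    rep(rep(net$emb$par$type_face, each = Tf), 2)
  for (i in seq_len(length(net$blocks) - 1)) X <- net$blocks[[i]]$forward(X, FALSE)
  blk <- net$blocks[[length(net$blocks)]]
  Z_all <- blk$ln1$forward(X, FALSE)
  dk <- d_model / cfg$heads
  for (n in 1:2) {
    Z <- matrix(Z_all[, , n], 1 + Te + Tf, d_model)
    Q <- Z %*% blk$msa$par$Wq + rep(blk$msa$par$bq, each = nrow(Z))
    K <- Z %*% blk$msa$par$Wk + rep(blk$msa$par$bk, each = nrow(Z))
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- Q[, cols] %*% t(K[, cols]) / sqrt(dk)
      E <- exp(S - apply(S, 1, max))
      A_ref <- E / rowSums(E)
      expect_equal(out$attn[[length(out$attn)]][, , h, n], A_ref,
                   tolerance = 1e-8)
    }
  }
})

test_that("LOSO runs train without the held-out subject and report per subject", {
  sm <- fix_small_data()
  idx <- seq(1, length(sm$data$y), by = 2)
  sub <- mmhafnn:::subset_data(sm$data, idx)
  res <- run_loso(sub, cfg = desk_model_config(), method = "efem",
                  epochs = 1, seed = 4, subjects = 1)
  expect_equal(res$subject, 1)
  expect_equal(res$n, sum(sub$subject == 1))
  expect_true(res$accuracy >= 0 && res$accuracy <= 100)
  expect_true(is.finite(attr(res, "summary")["mean"]))
})
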