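# Shared fixtures (memoized so expensive objects are built once per run)
# and independent oracles used against the package implementation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fix_layout <- function() memo("layout", default_layout)

# Small dataset for unit-level checks: 2 subjects, 2 clips/emotion, 10 s.
fix_small_data <- function() {
  memo("small_data", function() {
    cfg <- synth_config(n_subjects = 2, clips_per_emotion = 2,
                        clip_duration = 10, seed = 11)
    ds <- synth_dataset(cfg, face_size = 48)
    list(cfg = cfg, ds = ds,
         data = prepare_model_data(ds, fix_layout(), map_size = 64))
  })
}

# Study-scale dataset: the generator defaults (4 subjects, 5 clips per
# emotion, 20 s clips -> 1600 windows), 64 x 64 maps, 48 x 48 frames.
fix_study_data <- function() {
  memo("study_data", function() {
    cfg <- synth_config(seed = 2024)
    ds <- synth_dataset(cfg, face_size = 48)
    prepare_model_data(ds, fix_layout(), map_size = 64)
  })
}

# Trained models of the study run (10 epochs, all methods), shared between
# the end-to-end recovery check and downstream attribution checks.
fix_study_models <- function() {
  memo("study_models", function() {
    data <- fix_study_data()
    split <- make_clip_folds(data$manifest, k = 5, seed = 2024)
    check_fold_integrity(split, data$manifest)
    w <- fold_windows(split, data$manifest, 1)
    tr <- mmhafnn:::subset_data(data, w$train)
    va <- mmhafnn:::subset_data(data, w$val)
    cfg <- desk_model_config()
    fits <- list()
    for (m in c("efem", "fefem", "concat", "mmha")) {
      fits[[m]] <- mmha_train(tr, method = m, cfg = cfg, epochs = 10,
                              batch_size = 32, seed = 2024)
    }
    list(fits = fits, train = tr, val = va, split = split)
  })
}

# --- Independent oracles ----------------------------------------------------

# Differential entropy of N(mu, sd^2) by numeric quadrature of -f ln f.
de_quadrature <- function(sd, mu = 0) {
  f <- function(x) {
    d <- stats::dnorm(x, mu, sd)
    ifelse(d > 0, -d * log(d), 0)
  }
  stats::integrate(f, mu - 12 * sd, mu + 12 * sd, rel.tol = 1e-10)$value
}

# Exhaustive quadrant-search rasterization oracle: plain loops, no shared
# code with the package stencil machinery.
oracle_rasterize <- function(values, layout, size) {
  half_box <- size * 100 / 224
  ex <- layout$coords[, 1]; ey <- layout$coords[, 2]
  out <- matrix(0, size, size)
  for (jj in seq_len(size)) {
    px <- ((jj - 0.5) - size / 2) / half_box
    for (ii in seq_len(size)) {
      py <- (size / 2 - (ii - 0.5)) / half_box
      dx <- ex - px; dy <- ey - py
      d2 <- dx^2 + dy^2
      if (min(d2) < 1e-12) {
        out[ii, jj] <- values[which.min(d2)]
        next
      }
      sel <- c(nw = NA, ne = NA, sw = NA, se = NA)
      masks <- list(nw = dx < 0 & dy > 0, ne = dx > 0 & dy > 0,
                    sw = dx < 0 & dy < 0, se = dx > 0 & dy < 0)
      ok <- TRUE
      for (q in 1:4) {
        cand <- which(masks[[q]])
        if (length(cand) == 0) { ok <- FALSE; break }
        sel[q] <- cand[which.min(d2[cand])]
      }
      if (!ok) next
      mirror_x <- c(2, 1, 4, 3); mirror_y <- c(3, 4, 1, 2)
      w <- numeric(4)
      for (q in 1:4) {
        w[q] <- abs(px - ex[sel[mirror_x[q]]]) * abs(py - ey[sel[mirror_y[q]]])
      }
      if (sum(w) <= 0) w <- rep(1, 4)
      w <- w / sum(w)
      out[ii, jj] <- sum(w * values[sel])
    }
  }
  out
}

# Scaled dot-product attention by explicit exp/normalize/accumulate loops.
oracle_attention <- function(Q, K, V, d_k) {
  nq <- nrow(Q); nk <- nrow(K)
  out <- matrix(0, nq, ncol(V))
  for (i in seq_len(nq)) {
    s <- numeric(nk)
    for (j in seq_len(nk)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    e <- exp(s - max(s))
    a <- e / sum(e)
    for (j in seq_len(nk)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

random_unit_disc_layout <- function(n) {
  r <- sqrt(stats::runif(n)) * 0.95
  a <- stats::runif(n, 0, 2 * pi)
  mmhafnn:::new_layout(paste0("e", seq_len(n)), cbind(r * cos(a), r * sin(a)))
}
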