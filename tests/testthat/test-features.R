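make_rec <- function(data, fs = 200) {
  eeg_recording(data, fs, paste0("ch", seq_len(nrow(data))))
}

test_that("band decomposition isolates and reconstructs power", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)[-1]
  sine10 <- sin(2 * pi * 10 * t)
  rec <- make_rec(matrix(sine10, 1))
  bands <- decompose_bands(rec)
  p_in <- mean(sine10^2)
  expect_gt(mean(bands$alpha$data^2), 0.95 * p_in)  # 10 Hz lives in alpha
  expect_lt(mean(bands$delta$data^2), 0.01 * p_in)
  # zero in, zero out
  z <- decompose_bands(make_rec(matrix(0, 1, 2000)))
  for (b in z) expect_true(all(b$data == 0))
  # band above Nyquist rejected
  expect_error(
    decompose_bands(make_rec(matrix(rnorm(2000), 1), fs = 80)),
    "Nyquist")
  # filter bank approximately reconstructs a 1-50 Hz band-limited input
  # (content inside the analysis range; at the outermost crossovers, 1 and
  # 50 Hz exactly, a two-sided bank necessarily halves the amplitude)
  set.seed(1)
  n <- 2000
  spec <- rep(0 + 0i, n)
  freqs <- (0:(n - 1)) * fs / n
  keep <- which(freqs > 1.25 & freqs < 48)
  spec[keep] <- complex(real = rnorm(length(keep)),
                        imaginary = rnorm(length(keep)))
  spec[n - keep + 2] <- Conj(spec[keep])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  xb <- decompose_bands(make_rec(matrix(x, 1)))
  recon <- Reduce(`+`, lapply(xb, function(b) b$data[1, ]))
  core <- 200:1800 # away from filter edge transients
  rel_l2 <- sqrt(sum((recon[core] - x[core])^2) / sum(x[core]^2))
  expect_lt(rel_l2, 0.1)
})

test_that("zero-phase filtering preserves a symmetric pulse's center", {
  fs <- 200
  n <- 2000
  center <- 1000.5
  pulse <- exp(-((seq_len(n) - center) / 40)^2)
  rec <- make_rec(matrix(pulse, 1))
  y <- decompose_bands(rec)$alpha$data[1, ]
  com <- sum(seq_len(n) * y^2) / sum(y^2)
  expect_equal(com, center, tolerance = 0.1)
})

test_that("windowing tiles the signal without gaps or overlap", {
  rec <- make_rec(matrix(seq_len(2 * 4000), 2, byrow = TRUE))
  w <- window_signal(rec, length = 1)
  expect_equal(dim(w), c(2, 200, 20))
  # 20.5 s -> trailing partial window dropped
  rec2 <- make_rec(matrix(rnorm(4100), 1))
  expect_equal(dim(window_signal(rec2, 1))[3], 20)
  # exact tiling: concatenated windows reproduce the first 4000 samples
  flat <- as.vector(w[1, , ])
  expect_identical(flat, as.numeric(rec$data[1, 1:4000]))
  # too-short recording -> zero windows, not an error
  expect_equal(dim(window_signal(make_rec(matrix(1:50, 1)), 1))[3], 0)
})

test_that("differential entropy matches its closed form and quadrature", {
  # forced zero of the closed form
  x <- c(-1, 1) * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x), 0, tolerance = 1e-12)
  # sigma^2 = 1 (variance computed with 1/n)
  x2 <- c(-1, 1)
  expect_equal(differential_entropy(x2), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(0.5 * log(2 * pi * exp(1)), 1.41894, tolerance = 1e-5)
  # closed form equals -integral(f ln f) for Gaussian densities
  for (s in c(0.5, 1, 2, 7)) {
    expect_equal(0.5 * log(2 * pi * exp(1) * s^2), de_quadrature(s),
                 tolerance = 1e-8)
  }
  # a large Gaussian sample's estimate approaches the sigma = 2 quadrature
  set.seed(4)
  xs <- rnorm(2e5, sd = 2)
  expect_equal(differential_entropy(xs), de_quadrature(2), tolerance = 5e-3)
  # degenerate cases
  expect_identical(differential_entropy(rep(3, 10)), -Inf)
  expect_error(differential_entropy(1), "2 samples")
  expect_error(differential_entropy(c(1, NA)), "finite")
})

test_that("amplitude scaling shifts every DE entry by exactly ln c", {
  set.seed(5)
  rec <- make_rec(matrix(rnorm(3 * 2000), 3))
  de1 <- extract_de_features(rec)
  rec2 <- rec
  rec2$data <- rec$data * 2
  de2 <- extract_de_features(rec2)
  expect_equal(as.vector(unclass(de2) - unclass(de1)),
               rep(log(2), length(de1)), tolerance = 1e-9)
  expect_equal(dim(de1), c(10, 3, 5))
})

test_that("face normalization implements per-subject min-max exactly", {
  mk <- function(v, s = 1, w = 1) {
    face_frame(array(v, c(2, 2, 3)), subject_id = s, clip_id = 1, window = w)
  }
  frames <- list(mk(2, w = 1), mk(4, w = 2), mk(6, w = 3))
  out <- normalize_faces(frames, subject_id = 1)
  expect_equal(unique(as.vector(out[[1]]$pixels)), 0)
  expect_equal(unique(as.vector(out[[2]]$pixels)), 0.5)
  expect_equal(unique(as.vector(out[[3]]$pixels)), 1)
  # constant features map to zero
  cst <- normalize_faces(list(mk(5, w = 1), mk(5, w = 2)))
  expect_true(all(cst[[1]]$pixels == 0))
  # bounds and idempotence on non-constant features
  set.seed(2)
  fr <- list(mk(runif(12), w = 1), mk(runif(12), w = 2), mk(runif(12), w = 3))
  o1 <- normalize_faces(fr)
  lo <- Reduce(pmin, lapply(o1, `[[`, "pixels"))
  hi <- Reduce(pmax, lapply(o1, `[[`, "pixels"))
  expect_true(all(lo == 0) && all(hi == 1))
  o2 <- normalize_faces(o1)
  expect_equal(o1[[2]]$pixels, o2[[2]]$pixels, tolerance = 1e-12)
  expect_error(normalize_faces(list()), "empty")
})

test_that("center crop and bilinear resize behave as specified", {
  # 512 -> 256 is a pure 2x2 average under bilinear resampling
  set.seed(3)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  out <- center_crop_resize(img, 256)
  expect_equal(dim(out), c(256, 256, 3))
  expect_equal(out[1, 1, 1], mean(img[1:2, 1:2, 1]), tolerance = 1e-12)
  expect_equal(out[100, 37, 2], mean(img[199:200, 73:74, 2]), tolerance = 1e-12)
  # 300 x 200 -> central 200 x 200 crop
  img2 <- array(0, c(300, 200, 3))
  img2[51:250, , ] <- 1
  out2 <- center_crop_resize(img2, 200)
  expect_true(all(out2 == 1))
  # constant image stays constant
  out3 <- center_crop_resize(array(0.4, c(97, 113, 3)), 256)
  expect_true(all(abs(out3 - 0.4) < 1e-12))
  expect_error(center_crop_resize(matrix(1, 4, 4)), "RGB")
})

test_that("signed rescaling maps normalized features onto [-1, 1]", {
  mk <- function(v, w) face_frame(array(v, c(2, 2, 3)), subject_id = 1,
                                  clip_id = 1, window = w)
  out <- normalize_faces(list(mk(2, 1), mk(4, 2), mk(6, 3)),
                         rescale_signed = TRUE)
  expect_equal(unique(as.vector(out[[1]]$pixels)), -1)
  expect_equal(unique(as.vector(out[[2]]$pixels)), 0)
  expect_equal(unique(as.vector(out[[3]]$pixels)), 1)
})
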