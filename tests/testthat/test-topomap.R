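test_that("default montage is a valid 62-electrode unit-disc layout", {
  L <- fix_layout()
  expect_equal(length(L$names), 62)
  expect_false(any(duplicated(L$names)))
  expect_true(all(sqrt(rowSums(L$coords^2)) <= 1 + 1e-9))
  # the projection keeps anatomy: frontal-pole in front, occipital behind
  expect_gt(L$coords[match("FPZ", L$names), 2], 0.7)
  expect_lt(L$coords[match("OZ", L$names), 2], -0.7)
  regions <- montage_regions(L)
  expect_true(all(c("frontal", "occipital", "parietal", "central") %in%
                    names(regions)))
  expect_setequal(unlist(regions, use.names = FALSE), L$names)
})

test_that("montage CSV round-trips exactly and rejects bad files", {
  L <- fix_layout()
  f <- tempfile(fileext = ".csv")
  write_layout(L, f)
  L2 <- load_layout(f)
  expect_identical(L2$names, L$names)
  expect_equal(L2$coords, L$coords, tolerance = 1e-12)
  # shipped montage matches the generated one
  shipped <- load_layout(system.file("extdata", "montage62.csv",
                                     package = "mmhafnn"))
  expect_equal(shipped$coords, L$coords, tolerance = 1e-9)
  # duplicate names rejected with the name listed
  bad <- data.frame(name = c("A", "A", "B"), x = c(0, .1, .2), y = c(0, 0, .1))
  fb <- tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE)
  expect_error(load_layout(fb), "duplicate electrode names: A")
})

test_that("stencils are exact at electrodes and symmetric on squares", {
  sq <- mmhafnn:::new_layout(c("a", "b", "c", "d"),
                             rbind(c(-.5, -.5), c(.5, -.5),
                                   c(-.5, .5), c(.5, .5)))
  s <- build_stencil(c(0, 0), sq)
  expect_equal(s$w, rep(0.25, 4))
  expect_equal(sum(c(1, 2, 3, 4)[s$idx] * s$w), 2.5)
  # coincident point returns that electrode with weight one
  s2 <- build_stencil(c(-.5, .5), sq)
  expect_equal(s2$idx, 3)
  expect_equal(s2$w, 1)
  # missing quadrant -> empty stencil
  expect_null(build_stencil(c(0.6, 0), sq))
})

test_that("constant vectors paint constant covered pixels, zero outside", {
  L <- fix_layout()
  m <- rasterize(rep(7, 62), L, 64)
  covered <- m != 0
  expect_gt(sum(covered), 1000)
  expect_true(all(abs(m[covered] - 7) < 1e-9))
  # convexity: values bounded by electrode extremes
  set.seed(1)
  v <- runif(62, -3, 5)
  m2 <- rasterize(v, L, 64)
  expect_true(all(m2[m2 != 0] >= min(v) - 1e-9))
  expect_true(all(m2[m2 != 0] <= max(v) + 1e-9))
  expect_error(rasterize(rep(1, 10), L, 32), "does not match")
})

test_that("rasterizer reduces to textbook bilinear interpolation on grids", {
  gx <- seq(-0.8, 0.8, length.out = 5)
  grid <- expand.grid(x = gx, y = gx)
  L <- mmhafnn:::new_layout(paste0("g", 1:25), as.matrix(grid))
  set.seed(2)
  v <- rnorm(25)
  size <- 64
  m <- rasterize(v, L, size)
  # textbook bilinear oracle on the rectangular grid
  half_box <- size * 100 / 224
  vm <- matrix(v, 5, 5) # [ix, iy]
  for (jj in seq(8, 56, by = 7)) {
    px <- ((jj - 0.5) - size / 2) / half_box
    for (ii in seq(8, 56, by = 7)) {
      py <- (size / 2 - (ii - 0.5)) / half_box
      if (px <= min(gx) || px >= max(gx) || py <= min(gx) || py >= max(gx)) next
      ix <- findInterval(px, gx); iy <- findInterval(py, gx)
      if (px == gx[ix] || py == gx[iy]) next
      fx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
      fy <- (py - gx[iy]) / (gx[iy + 1] - gx[iy])
      ref <- vm[ix, iy] * (1 - fx) * (1 - fy) + vm[ix + 1, iy] * fx * (1 - fy) +
        vm[ix, iy + 1] * (1 - fx) * fy + vm[ix + 1, iy + 1] * fx * fy
      expect_equal(m[ii, jj], ref, tolerance = 1e-10)
    }
  }
})

test_that("rasterizer equals the exhaustive quadrant-search oracle", {
  set.seed(7)
  for (rep_i in 1:5) {
    L <- random_unit_disc_layout(sample(10:62, 1))
    v <- rnorm(length(L$names))
    size <- 32
    expect_equal(rasterize(v, L, size), oracle_rasterize(v, L, size),
                 tolerance = 1e-10)
  }
})

test_that("band stacks have canonical order, clamping and zero behavior", {
  L <- fix_layout()
  set.seed(3)
  de <- matrix(rnorm(62 * 5), 62, 5)
  st <- stack_bands(de, L, size = 48)
  expect_equal(dim(st), c(48, 48, 5))
  for (b in 1:5) {
    expect_equal(unclass(st)[, , b], rasterize(de[, b], L, 48),
                 tolerance = 1e-12)
  }
  # permuting band columns permutes planes identically
  perm <- c(3, 1, 5, 2, 4)
  st2 <- stack_bands(de[, perm], L, size = 48)
  expect_equal(unclass(st2), unclass(st)[, , perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero vector -> all-zero stack; sentinel clamped to the floor
  expect_true(all(stack_bands(matrix(0, 62, 5), L, 32) == 0))
  de[5, 2] <- -Inf
  st3 <- stack_bands(de, L, size = 48, floor = -10)
  expect_true(all(is.finite(st3)))
})

test_that("the debug PNG writer scales covered pixels and keeps the border", {
  L <- fix_layout()
  m <- rasterize(rnorm(62, 5), L, 48)
  p <- tempfile(fileext = ".png")
  write_topomap_png(m, p)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(48, 48))
  expect_true(all(img[m == 0] == 0)) # border stays black
  expect_true(max(img) <= 1 && min(img) >= 0)
})
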