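# Topographic rasterization of per-band electrode values.
#
# A 62-value differential-entropy vector is painted onto a raster by a
# quadrant-wise bilinear scheme: for every pixel the nearest electrode in
# each of the four open quadrants (NW, NE, SW, SE) around the pixel is
# located, and the four values are combined with area-product weights
#   w_q = |px - x(q flipped E/W)| * |py - y(q flipped N/S)|,
# normalized to sum to one.  On a rectangular electrode grid this reduces
# exactly to textbook bilinear interpolation; pixels lacking an electrode
# in one of the four quadrants (the scalp border) are exactly zero.

# ---------------------------------------------------------------------------
# Electrode layouts

new_layout <- function(names, coords) {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(names = as.character(names), coords = coords),
            class = "electrode_layout")
}

validate_layout <- function(layout) {
  abort_if(!inherits(layout, "electrode_layout"), "not an electrode_layout")
  n <- length(layout$names)
  abort_if(nrow(layout$coords) != n, "names/coords length mismatch")
  dup <- layout$names[duplicated(layout$names)]
  abort_if(length(dup) > 0, "duplicate electrode names: ",
           paste(unique(dup), collapse = ", "))
  key <- paste(signif(layout$coords[, 1], 12), signif(layout$coords[, 2], 12))
  abort_if(anyDuplicated(key) > 0, "electrode coordinates are not distinct")
  r <- sqrt(rowSums(layout$coords^2))
  abort_if(any(r > 1 + 1e-9), "electrode coordinates outside the unit disc: ",
           paste(layout$names[r > 1 + 1e-9], collapse = ", "))
  invisible(layout)
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> ", length(x$names), " electrodes, unit-disc plane\n",
      sep = "")
  invisible(x)
}

# Spherical linear interpolation between two unit vectors.
slerp <- function(a, b, f) {
  w <- acos(max(-1, min(1, sum(a * b))))
  if (w < 1e-12) return(a)
  (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
}

# Unit-sphere point for inclination theta (radians from vertex) at disc
# angle alpha (0 = nose, positive angles toward the left hemisphere).
sph_point <- function(theta, alpha) {
  c(-sin(theta) * sin(alpha), sin(theta) * cos(alpha), cos(theta))
}

#' Default 62-channel electrode montage
#'
#' Coordinates for the extended 10-20 62-channel set used by 62-channel
#' emotion-recognition recordings (Neuroscan convention, CB1/CB2 included),
#' constructed by placing electrodes on great-circle arcs of a spherical
#' head model and applying an azimuthal-equidistant projection onto the
#' unit disc (nose up, left hemisphere at negative x).
#'
#' @return An `electrode_layout` with 62 named positions.
#' @export
default_layout <- function() {
  deg <- pi / 180
  pts <- list()
  add <- function(name, p) {
    theta <- acos(max(-1, min(1, p[3])))
    r <- theta / (pi / 2)
    pts[[name]] <<- r * c(p[1], p[2]) / max(sqrt(p[1]^2 + p[2]^2), 1e-12)
  }
  # Each row runs from a midline anchor to an outermost electrode on the
  # 72-degree circumferential ring; interior electrodes subdivide the
  # great-circle arc between the two.
  rows <- list(
    AF = list(mid = c(54, 0),   ring_angle = 36,  outer = c("AF7", "AF8"),
              inner = c("AF3"), keep_outer = FALSE),
    F  = list(mid = c(36, 0),   ring_angle = 54,  outer = c("F7", "F8"),
              inner = c("F1", "F3", "F5"), keep_outer = TRUE),
    FC = list(mid = c(18, 0),   ring_angle = 72,  outer = c("FT7", "FT8"),
              inner = c("FC1", "FC3", "FC5"), keep_outer = TRUE),
    C  = list(mid = c(0, 0),    ring_angle = 90,  outer = c("T7", "T8"),
              inner = c("C1", "C3", "C5"), keep_outer = TRUE),
    CP = list(mid = c(18, 180), ring_angle = 108, outer = c("TP7", "TP8"),
              inner = c("CP1", "CP3", "CP5"), keep_outer = TRUE),
    P  = list(mid = c(36, 180), ring_angle = 126, outer = c("P7", "P8"),
              inner = c("P1", "P3", "P5"), keep_outer = TRUE),
    PO = list(mid = c(54, 180), ring_angle = 144, outer = c("PO7", "PO8"),
              inner = c("PO3", "PO5"), keep_outer = TRUE)
  )
  midnames <- c(AF = "", F = "FZ", FC = "FCZ", C = "CZ",
                CP = "CPZ", P = "PZ", PO = "POZ")
  # frontal-pole and occipital electrodes sit on the ring itself
  add("FPZ", sph_point(72 * deg, 0))
  add("FP1", sph_point(72 * deg, 18 * deg))
  add("FP2", sph_point(72 * deg, -18 * deg))
  add("OZ", sph_point(72 * deg, pi))
  add("O1", sph_point(72 * deg, 162 * deg))
  add("O2", sph_point(72 * deg, -162 * deg))
  for (row in names(rows)) {
    rr <- rows[[row]]
    mid <- sph_point(rr$mid[1] * deg, if (rr$mid[2] == 0) 0 else pi)
    if (nzchar(midnames[[row]])) add(midnames[[row]], mid)
    n_arc <- length(rr$inner) + 1L
    for (side in 1:2) { # 1 = left, 2 = right
      sgn <- if (side == 1) 1 else -1
      ring <- sph_point(72 * deg, sgn * rr$ring_angle * deg)
      if (rr$keep_outer) add(rr$outer[side], ring)
      for (i in seq_along(rr$inner)) {
        lab <- rr$inner[i]
        nm <- if (side == 1) lab else {
          num <- as.integer(sub("^[A-Z]+", "", lab))
          paste0(sub("[0-9]+$", "", lab), num + 1L)
        }
        add(nm, slerp(mid, ring, i / n_arc))
      }
      if (!rr$keep_outer && row == "AF") next
    }
  }
  # Cerebellar electrodes below the occipital ring.
  add("CB1", sph_point(86 * deg, 160 * deg))
  add("CB2", sph_point(86 * deg, -160 * deg))
  ord <- c("FP1", "FPZ", "FP2", "AF3", "AF4",
           "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
           "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
           "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
           "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
           "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
           "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
           "CB1", "O1", "OZ", "O2", "CB2")
  coords <- do.call(rbind, pts[ord])
  validate_layout(new_layout(ord, coords))
}

#' Read an electrode layout from a montage CSV
#'
#' @param file CSV with columns `name,x,y`; coordinates in the unit disc.
#' @return An `electrode_layout`.
#' @export
load_layout <- function(file) {
  abort_if(!file.exists(file), "montage file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  abort_if(!all(c("name", "x", "y") %in% names(df)),
           "montage CSV must have columns name,x,y")
  validate_layout(new_layout(df$name, cbind(df$x, df$y)))
}

#' Write an electrode layout to a montage CSV
#'
#' @param layout An `electrode_layout`.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_layout <- function(layout, file) {
  validate_layout(layout)
  df <- data.frame(name = layout$names,
                   x = layout$coords[, 1], y = layout$coords[, 2])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Coarse anatomical groupings of a layout, by disc position.  Used by the
# synthetic generator to place per-emotion band signatures; not a claim of
# neurophysiological precision.
#' Channel regions of an electrode layout
#'
#' Partitions channels into frontal, central, parietal, occipital and
#' left/right temporal groups by their position on the projected disc.
#'
#' @param layout An `electrode_layout`.
#' @return Named list of character vectors of channel names.
#' @export
montage_regions <- function(layout) {
  x <- layout$coords[, 1]; y <- layout$coords[, 2]
  nm <- layout$names
  temporal <- abs(x) > 0.55
  region <- ifelse(temporal & x < 0, "left_temporal",
            ifelse(temporal, "right_temporal",
            ifelse(y > 0.30, "frontal",
            ifelse(y < -0.55, "occipital",
            ifelse(y < -0.15, "parietal", "central")))))
  split(nm, region)
}

# ---------------------------------------------------------------------------
# Stencils and rasterization

#' Four-quadrant interpolation stencil for one point
#'
#' Finds the nearest electrode in each open quadrant around `pixel` and the
#' bilinear area-product weights.  A point within `eps` of an electrode
#' receives that electrode with weight one; if any quadrant is unoccupied
#' the stencil is empty (`NULL`), and the rasterizer paints zero.
#'
#' @param pixel Numeric length-2 `(x, y)` in the layout plane.
#' @param layout An `electrode_layout`.
#' @param eps Coincidence tolerance.
#' @return `NULL`, or a list with `idx` (4 electrode indices, NW/NE/SW/SE,
#'   or a single index for a coincident point) and `w` (weights summing to 1).
#' @export
build_stencil <- function(pixel, layout, eps = 1e-6) {
  ex <- layout$coords[, 1]; ey <- layout$coords[, 2]
  dx <- ex - pixel[1]; dy <- ey - pixel[2]
  d2 <- dx * dx + dy * dy
  hit <- which(d2 < eps^2)
  if (length(hit) > 0) {
    i <- hit[which.min(d2[hit])]
    return(list(idx = i, w = 1))
  }
  quad <- list(nw = dx < 0 & dy > 0, ne = dx > 0 & dy > 0,
               sw = dx < 0 & dy < 0, se = dx > 0 & dy < 0)
  pick <- integer(4)
  for (q in 1:4) {
    cand <- which(quad[[q]])
    if (length(cand) == 0) return(NULL)
    pick[q] <- cand[which.min(d2[cand])]
  }
  # weight of each corner uses the x of its E/W mirror and the y of its
  # N/S mirror (classic bilinear on grids)
  mirror_x <- c(2, 1, 4, 3) # nw<->ne, sw<->se
  mirror_y <- c(3, 4, 1, 2) # nw<->sw, ne<->se
  w <- abs(pixel[1] - ex[pick[mirror_x]]) * abs(pixel[2] - ey[pick[mirror_y]])
  if (sum(w) <= 0) w <- rep(1, 4) # degenerate collinear case: plain average
  list(idx = pick, w = w / sum(w))
}

# Raster frame: the unit disc maps to the central (200/224)*size box of a
# size x size raster, pixel centers at half-integer raster coordinates,
# row 1 at the top (+y).
raster_pixel_coords <- function(size) {
  half_box <- size * 100 / 224
  j <- rep(seq_len(size), each = size)  # column
  i <- rep(seq_len(size), times = size) # row
  x <- ((j - 0.5) - size / 2) / half_box
  y <- (size / 2 - (i - 0.5)) / half_box
  cbind(x = x, y = y) # column-major pixel order: row fastest
}

.stencil_cache <- new.env(parent = emptyenv())

# Vectorized stencil field for a whole raster: 4 index columns and 4 weight
# columns per pixel (0 index = empty stencil).
stencil_field <- function(layout, size, eps = 1e-6) {
  key <- paste0(config_hash(list(c = round(layout$coords, 12), s = size)), "_", size)
  if (!is.null(.stencil_cache[[key]])) return(.stencil_cache[[key]])
  px <- raster_pixel_coords(size)
  np <- nrow(px); ne <- nrow(layout$coords)
  ex <- layout$coords[, 1]; ey <- layout$coords[, 2]
  dx <- outer(px[, 1], ex, function(p, e) e - p)
  dy <- outer(px[, 2], ey, function(p, e) e - p)
  d2 <- dx * dx + dy * dy
  idx <- matrix(0L, np, 4); colnames(idx) <- c("nw", "ne", "sw", "se")
  big <- Inf
  masked_argmin <- function(mask) {
    dm <- d2
    dm[!mask] <- big
    j <- max.col(-dm, ties.method = "first")
    j[dm[cbind(seq_len(np), j)] == big] <- 0L
    j
  }
  idx[, 1] <- masked_argmin(dx < 0 & dy > 0)
  idx[, 2] <- masked_argmin(dx > 0 & dy > 0)
  idx[, 3] <- masked_argmin(dx < 0 & dy < 0)
  idx[, 4] <- masked_argmin(dx > 0 & dy < 0)
  ok <- rowSums(idx == 0L) == 0L
  # coincident pixels
  mind <- max.col(-d2, ties.method = "first")
  hit <- d2[cbind(seq_len(np), mind)] < eps^2
  w <- matrix(0, np, 4)
  safe <- function(v, i) ifelse(i > 0, v[pmax(i, 1)], 0)
  mx <- c(2, 1, 4, 3); my <- c(3, 4, 1, 2)
  for (q in 1:4) {
    w[, q] <- abs(px[, 1] - safe(ex, idx[, mx[q]])) *
              abs(px[, 2] - safe(ey, idx[, my[q]]))
  }
  ws <- rowSums(w)
  degen <- ok & ws <= 0
  w[degen, ] <- 1
  ws[degen] <- 4
  w <- w / pmax(ws, .Machine$double.eps)
  w[!ok, ] <- 0
  # override with coincidence
  idx[hit, ] <- 0L
  idx[hit, 1] <- mind[hit]
  w[hit, ] <- 0
  w[hit, 1] <- 1
  ok[hit] <- TRUE
  field <- list(idx = idx, w = w, ok = ok, size = size)
  .stencil_cache[[key]] <- field
  field
}

#' Rasterize one band's electrode values to a topographic map
#'
#' @param values Numeric vector, one value per layout electrode.
#' @param layout An `electrode_layout`.
#' @param size Raster side length in pixels (default 224).
#' @return A `size` x `size` matrix (row 1 = top of the scalp disc); pixels
#'   without four-quadrant electrode coverage are exactly zero.
#' @export
rasterize <- function(values, layout, size = 224) {
  abort_if(length(values) != length(layout$names),
           "value vector length (", length(values),
           ") does not match layout size (", length(layout$names), ")")
  f <- stencil_field(layout, size)
  gather <- function(q) ifelse(f$idx[, q] > 0L, values[pmax(f$idx[, q], 1L)], 0)
  out <- f$w[, 1] * gather(1) + f$w[, 2] * gather(2) +
         f$w[, 3] * gather(3) + f$w[, 4] * gather(4)
  out[!f$ok] <- 0
  matrix(out, size, size)
}

#' Rasterize a 62 x 5 differential-entropy window into a band stack
#'
#' @param de_window Matrix channels x 5 bands (delta, theta, alpha, beta,
#'   gamma), in nats.
#' @param layout An `electrode_layout` matching the channel count.
#' @param size Raster side length (default 224).
#' @param floor Clamp floor in nats applied before rasterizing (sentinel
#'   handling for zero-variance windows); default -10.
#' @return Array `size x size x 5` (bands in canonical order), class
#'   `topographic_stack`.
#' @export
stack_bands <- function(de_window, layout, size = 224, floor = -10) {
  de_window <- as.matrix(de_window)
  abort_if(ncol(de_window) != 5, "expected 5 band columns")
  de_window <- pmax(de_window, floor)
  out <- array(0, c(size, size, 5))
  for (b in 1:5) out[, , b] <- rasterize(de_window[, b], layout, size)
  structure(out, class = "topographic_stack", floor = floor)
}

#' Write a topographic map as a debug grayscale PNG
#'
#' Min-max scales the covered pixels to `[0, 1]` (uncovered border pixels
#' stay black) and writes an 8-bit grayscale PNG for quick inspection.
#'
#' @param map A `size` x `size` matrix from [rasterize()], or one plane of
#'   a [stack_bands()] stack.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_topomap_png <- function(map, path) {
  m <- as.matrix(map)
  covered <- m != 0
  if (any(covered)) {
    rng <- range(m[covered])
    if (diff(rng) > 0) {
      m[covered] <- (m[covered] - rng[1]) / diff(rng)
    } else {
      m[covered] <- 1
    }
  }
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
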