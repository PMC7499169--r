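# Independent brute-force oracles and tiny fixture builders. Every oracle
# is a literal per-pixel / per-bin loop, deliberately kept separate from
# the vectorized implementation paths it checks.

mk_image <- function(r, g, b, timestamp = NULL) {
  px <- array(0L, dim = c(nrow(r), ncol(r), 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  uv_image(px, timestamp = timestamp)
}

rand_image <- function(h, w) {
  mk_image(matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w))
}

uniform_image <- function(h, w, r, g, b) {
  mk_image(matrix(r, h, w), matrix(g, h, w), matrix(b, h, w))
}

# per-pixel conditional loop implementing the classification rules verbatim
oracle_classify <- function(image, mask, delta, l) {
  codes <- plaque_classes()
  px <- image$pixels
  lab <- matrix(codes[["OUTSIDE"]], nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    g <- px[i, j, 2]; b <- px[i, j, 3]
    gb <- g - b
    if (gb > 0) {
      lab[i, j] <- codes[["VISIBLE"]]
    } else if (g > 0 && b > 0) {
      if (gb >= delta) lab[i, j] <- codes[["NV1"]]
      else if (gb >= l) lab[i, j] <- codes[["NV2"]]
      else lab[i, j] <- codes[["NONPLAQUE"]]
    } else {
      lab[i, j] <- codes[["NONPLAQUE"]]
    }
  }
  lab
}

# per-pixel 8-neighborhood loop
oracle_remove_isolated <- function(mask) {
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j]) next
    n <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) n <- n + 1L
    }
    if (n == 0L) out[i, j] <- FALSE
  }
  out
}

oracle_bright_artifacts <- function(mask, image, floor) {
  out <- mask
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (min(image$pixels[i, j, ]) >= floor) out[i, j] <- FALSE
  }
  out
}

# quantile threshold by explicit sort and rank
oracle_threshold <- function(image, fraction) {
  v <- sort(as.vector(image$pixels[, , 3] + image$pixels[, , 1]))
  v[ceiling(fraction * length(v))]
}

# solidity by an independent inclusion test: a point is inside a convex
# polygon iff the triangle areas it forms with the edges sum to the
# polygon area
oracle_solidity <- function(rows, cols) {
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3) return(1)
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  poly_area <- 0
  for (i in seq_len(nrow(hull))) {
    j <- if (i == nrow(hull)) 1 else i + 1
    poly_area <- poly_area + (hull[i, 1] * hull[j, 2] - hull[j, 1] * hull[i, 2])
  }
  poly_area <- abs(poly_area) / 2
  if (poly_area == 0) return(1)
  inside <- 0L
  for (r in min(rows):max(rows)) for (c in min(cols):max(cols)) {
    s <- 0
    for (i in seq_len(nrow(hull))) {
      j <- if (i == nrow(hull)) 1 else i + 1
      s <- s + tri_area(c(c, r), hull[i, ], hull[j, ])
    }
    if (abs(s - poly_area) < 1e-7 * max(1, poly_area)) inside <- inside + 1L
  }
  length(rows) / inside
}

# per-bin tally loop
oracle_histogram <- function(gb) {
  counts <- integer(511)
  v <- gb[!is.na(gb)]
  for (x in v) counts[x + 256L] <- counts[x + 256L] + 1L
  setNames(counts, -255:255)
}

# linear scan over v = -255..0
oracle_auto_l <- function(cur, ref, delta) {
  for (v in -255:0) {
    i <- v + 256L
    if (cur[i] > ref[i]) return(v)
  }
  delta
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

disc_in <- function(mask, center, radius) {
  r <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  c <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

ellipse_in <- function(mask, tooth) {
  r <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  c <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  ((r - tooth$center[1]) / tooth$radii[1])^2 +
    ((c - tooth$center[2]) / tooth$radii[2])^2 <= 1
}
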