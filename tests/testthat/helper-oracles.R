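# Independent brute-force oracles. These are deliberately written with
# different algorithms than the package internals (direct definitions,
# exhaustive loops, integer arithmetic) so agreement is meaningful.

# Exhaustive maximal-sphere local thickness (voxel units). For every
# foreground centre q: its radius from the direct minimum distance to any
# background voxel centre (voxels outside the volume count as background);
# then every sphere is painted. Membership: integer dist2(p, q) < edt2(q),
# thickness = 2*sqrt(edt2(q)) - 1.
oracle_local_thickness <- function(mask) {
  d <- dim(mask)  # (nz, ny, nx)
  co <- cbind(as.vector(slice.index(mask, 1)) - 1L,   # z
              as.vector(slice.index(mask, 2)) - 1L,   # y
              as.vector(slice.index(mask, 3)) - 1L)   # x
  v <- as.vector(mask)
  fg <- which(v)
  bgco <- co[!v, , drop = FALSE]
  fgco <- co[fg, , drop = FALSE]
  edt2 <- integer(length(fg))
  for (i in seq_along(fg)) {
    q <- fgco[i, ]
    b <- min(q[1] + 1L, d[1] - q[1], q[2] + 1L, d[2] - q[2], q[3] + 1L, d[3] - q[3])
    b2 <- b * b
    if (nrow(bgco))
      b2 <- min(b2, min((bgco[, 1] - q[1])^2 + (bgco[, 2] - q[2])^2 +
                          (bgco[, 3] - q[3])^2))
    edt2[i] <- b2
  }
  thick <- numeric(length(v))
  for (i in seq_along(fg)) {
    d2 <- (fgco[, 1] - fgco[i, 1])^2 + (fgco[, 2] - fgco[i, 2])^2 +
      (fgco[, 3] - fgco[i, 3])^2
    incl <- d2 < edt2[i]
    val <- 2 * sqrt(edt2[i]) - 1
    sel <- fg[incl]
    thick[sel] <- pmax(thick[sel], val)
  }
  array(thick, d)
}

# Per-voxel 3D median with edge replication, by direct neighbourhood
# gathering and sort().
oracle_median3d <- function(a, radius = 1L) {
  d <- dim(a)
  out <- a
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- pmin(pmax(z + (-radius:radius), 1L), d[1])
    yy <- pmin(pmax(y + (-radius:radius), 1L), d[2])
    xx <- pmin(pmax(x + (-radius:radius), 1L), d[3])
    nb <- a[zz, yy, xx]
    s <- sort(as.numeric(nb))
    out[z, y, x] <- s[(length(s) + 1L) %/% 2L]
  }
  out
}

# Direct (non-separable) 2D Gaussian convolution with edge replication,
# same kernel definition as the package (half-width ceil(4*sigma),
# normalized), but evaluated as an explicit 2D sum.
oracle_gauss2d <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  ny <- nrow(img); nx <- ncol(img)
  out <- img * 0
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- pmin(pmax(i + off, 1L), ny)
    jj <- pmin(pmax(j + off, 1L), nx)
    out[i, j] <- sum(k2 * img[ii, jj])
  }
  out
}

# Random blob mask: union of a few random balls, optionally salted with
# random voxels.
random_blob_mask <- function(dimzyx, n_balls = 3, salt = 0) {
  m <- array(FALSE, dimzyx)
  co <- cbind(as.vector(slice.index(m, 1)) - 1L,
              as.vector(slice.index(m, 2)) - 1L,
              as.vector(slice.index(m, 3)) - 1L)
  for (b in seq_len(n_balls)) {
    ctr <- c(runif(1, 0, dimzyx[1] - 1), runif(1, 0, dimzyx[2] - 1),
             runif(1, 0, dimzyx[3] - 1))
    r <- runif(1, 1, max(2, min(dimzyx) / 3))
    m <- m | array((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                     (co[, 3] - ctr[3])^2 <= r^2, dimzyx)
  }
  if (salt > 0) {
    idx <- sample(length(m), salt)
    m[idx] <- TRUE
  }
  m
}

# Luminance of an RGB array.
as_gray <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else img
}

# A small calibrated volume with banded structure, useful as a
# registration/rendering fixture.
banded_volume <- function(dims = c(40L, 64L, 64L), seed = 1L) {
  g <- expand.grid(z = 0:(dims[1] - 1), y = 0:(dims[2] - 1), x = 0:(dims[3] - 1))
  dat <- 30419 + 9870 * as.numeric((sin(g$x / 4) * cos(g$y / 5) + sin(g$z / 3)) > 0.3)
  volume(array(dat, dims), 8.48, calibration_state = "calibrated")
}
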