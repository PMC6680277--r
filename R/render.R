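# Rendering primitives: maximum intensity projections (axis-aligned and
# along arbitrary directions, including rotating sequences), orthogonal
# multiplanar views and oblique reslicing with bicubic interpolation.
#
# Geometry convention (shared with the registration module): continuous
# coordinates are zero-based (x, y, z) voxel units, voxel centres at
# integers; image u = columns (left to right), v = rows (top to bottom).

#' Oriented plane in volume coordinates
#'
#' @param origin 3D point `c(x, y, z)` in zero-based voxel units.
#' @param u_axis,v_axis Orthonormal in-plane directions; `u` maps to image
#'   columns, `v` to image rows.
#' @param extent `c(width_px, height_px)` of the resampled image.
#' @param sample_spacing Sample step along `u`/`v` in voxel units.
#' @return A `plane_spec` object.
#' @export
plane_spec <- function(origin, u_axis, v_axis, extent, sample_spacing = 1) {
  origin <- as.numeric(origin); u <- as.numeric(u_axis); v <- as.numeric(v_axis)
  stopifnot(length(origin) == 3L, length(u) == 3L, length(v) == 3L)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-8 || abs(sqrt(sum(v^2)) - 1) > 1e-8 ||
      abs(sum(u * v)) > 1e-8)
    stop("u_axis and v_axis must be orthonormal unit vectors")
  extent <- as.integer(extent)
  if (length(extent) != 2L || any(extent < 1L)) stop("extent must be positive (width, height)")
  if (sample_spacing <= 0) stop("sample_spacing must be > 0")
  structure(list(origin = origin, u_axis = u, v_axis = v, extent = extent,
                 sample_spacing = as.numeric(sample_spacing)),
            class = "plane_spec")
}

#' Display window for rendered images
#'
#' Clinical-style level/width windowing: grays in
#' `[level - width/2, level + width/2]` map linearly to `[0, 1]`, clamped
#' outside.
#'
#' @param window_level Centre gray value.
#' @param window_width Positive width.
#' @return A `render_settings` object.
#' @export
render_settings <- function(window_level, window_width) {
  if (!is.numeric(window_width) || window_width <= 0) stop("window_width must be > 0")
  structure(list(window_level = as.numeric(window_level),
                 window_width = as.numeric(window_width)),
            class = "render_settings")
}

#' @rdname render_settings
#' @param img Numeric matrix of gray values.
#' @param settings A `render_settings`.
#' @export
apply_window <- function(img, settings) {
  lo <- settings$window_level - settings$window_width / 2
  pmin(pmax((img - lo) / settings$window_width, 0), 1)
}

# ---- interpolation ---------------------------------------------------------

# Keys cubic convolution kernel, a = -0.5: interpolates exactly at lattice
# points and reproduces linear functions.
.cubic_w <- function(f) {
  # weights for taps at offsets -1, 0, 1, 2 given fractional position f in [0,1)
  a <- -0.5
  w0 <- a * (1 + f) ^ 3 - 5 * a * (1 + f) ^ 2 + 8 * a * (1 + f) - 4 * a
  w1 <- (a + 2) * f ^ 3 - (a + 3) * f ^ 2 + 1
  w2 <- (a + 2) * (1 - f) ^ 3 - (a + 3) * (1 - f) ^ 2 + 1
  w3 <- a * (2 - f) ^ 3 - 5 * a * (2 - f) ^ 2 + 8 * a * (2 - f) - 4 * a
  list(w0, w1, w2, w3)
}

# Sample a 3D array (dim nz,ny,nx) at continuous zero-based (x,y,z) points.
# pts: n x 3 matrix. Outside the volume domain -> pad. Support taps near the
# border are clamped (edge replication), which keeps lattice points exact.
.interp3 <- function(data, pts, method = c("bicubic", "trilinear"), pad = 0) {
  method <- match.arg(method)
  d <- dim(data); nz <- d[1]; ny <- d[2]; nx <- d[3]
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  eps <- 1e-9
  inside <- x >= -eps & x <= nx - 1 + eps &
            y >= -eps & y <= ny - 1 + eps &
            z >= -eps & z <= nz - 1 + eps
  out <- rep(as.numeric(pad), nrow(pts))
  if (!any(inside)) return(out)
  x <- pmin(pmax(x[inside], 0), nx - 1)
  y <- pmin(pmax(y[inside], 0), ny - 1)
  z <- pmin(pmax(z[inside], 0), nz - 1)
  if (method == "trilinear") {
    x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2); z0 <- pmin(floor(z), nz - 2)
    if (nx == 1) x0 <- rep(0, length(x)); if (ny == 1) y0 <- rep(0, length(y)); if (nz == 1) z0 <- rep(0, length(z))
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wx <- if (dx == 0) 1 - fx else fx
      wy <- if (dy == 0) 1 - fy else fy
      wz <- if (dz == 0) 1 - fz else fz
      xi <- pmin(x0 + dx, nx - 1); yi <- pmin(y0 + dy, ny - 1); zi <- pmin(z0 + dz, nz - 1)
      acc <- acc + wx * wy * wz * data[1 + zi + nz * (yi + ny * xi)]
    }
    out[inside] <- acc
  } else {
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    wx <- .cubic_w(fx); wy <- .cubic_w(fy); wz <- .cubic_w(fz)
    acc <- 0
    for (dx in -1:2) for (dy in -1:2) for (dz in -1:2) {
      xi <- pmin(pmax(x0 + dx, 0), nx - 1)
      yi <- pmin(pmax(y0 + dy, 0), ny - 1)
      zi <- pmin(pmax(z0 + dz, 0), nz - 1)
      w <- wx[[dx + 2]] * wy[[dy + 2]] * wz[[dz + 2]]
      acc <- acc + w * data[1 + zi + nz * (yi + ny * xi)]
    }
    out[inside] <- acc
  }
  out
}

# 2D analogue for images (matrix rows = y, cols = x), zero-based (x, y).
.interp2 <- function(img, pts, method = c("bicubic", "bilinear"), pad = 0) {
  method <- match.arg(method)
  ny <- nrow(img); nx <- ncol(img)
  x <- pts[, 1]; y <- pts[, 2]
  eps <- 1e-9
  inside <- x >= -eps & x <= nx - 1 + eps & y >= -eps & y <= ny - 1 + eps
  out <- rep(as.numeric(pad), nrow(pts))
  if (!any(inside)) return(out)
  x <- pmin(pmax(x[inside], 0), nx - 1)
  y <- pmin(pmax(y[inside], 0), ny - 1)
  if (method == "bilinear") {
    x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
    if (nx == 1) x0 <- rep(0, length(x)); if (ny == 1) y0 <- rep(0, length(y))
    fx <- x - x0; fy <- y - y0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) {
      w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      acc <- acc + w * img[1 + pmin(y0 + dy, ny - 1) + ny * pmin(x0 + dx, nx - 1)]
    }
    out[inside] <- acc
  } else {
    x0 <- floor(x); y0 <- floor(y)
    wx <- .cubic_w(x - x0); wy <- .cubic_w(y - y0)
    acc <- 0
    for (dx in -1:2) for (dy in -1:2) {
      xi <- pmin(pmax(x0 + dx, 0), nx - 1)
      yi <- pmin(pmax(y0 + dy, 0), ny - 1)
      acc <- acc + wx[[dx + 2]] * wy[[dy + 2]] * img[1 + yi + ny * xi]
    }
    out[inside] <- acc
  }
  out
}

# ---- MIP -------------------------------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Complete a projection direction into a (d, u, v) frame: v (image rows)
# follows +z where possible (+y when d is near +-z), u = d x v (columns).
.complete_basis <- function(d) {
  d <- d / sqrt(sum(d^2))
  h <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- h - sum(h * d) * d
  v <- v / sqrt(sum(v^2))
  list(d = d, u = .cross3(d, v), v = v)
}

.mip_oblique <- function(vol, d, u = NULL, v = NULL, settings = NULL) {
  dims <- vol$meta$shape  # nz, ny, nx
  if (is.null(u) || is.null(v)) {
    b <- .complete_basis(d); d <- b$d; u <- b$u; v <- b$v
  } else d <- d / sqrt(sum(d^2))
  ctr <- c(dims[3] - 1, dims[2] - 1, dims[1] - 1) / 2  # (x, y, z)
  L <- ceiling(sqrt(sum((dims - 1)^2)) / 2)
  off <- -L:L
  w <- length(off)
  grid_u <- rep(off, each = w)   # column offset for pixel (i, j): a = j - L - 1 (1-based)
  grid_v <- rep(off, times = w)  # row offset
  base <- cbind(ctr[1] + grid_u * u[1] + grid_v * v[1],
                ctr[2] + grid_u * u[2] + grid_v * v[2],
                ctr[3] + grid_u * u[3] + grid_v * v[3])
  acc <- rep(0, w * w)  # out-of-volume samples pad with 0 (calibrated air)
  for (t in off) {
    pts <- base + matrix(t * d, nrow(base), 3, byrow = TRUE)
    acc <- pmax(acc, .interp3(vol$data, pts, "trilinear", pad = 0))
  }
  img <- matrix(acc, w, w)  # rows = v, cols = u
  if (!is.null(settings)) img <- apply_window(img, settings)
  img
}

#' Maximum intensity projection
#'
#' Renders, for each ray path through the volume, only the brightest voxel.
#' Axis names (`"x"`, `"y"`, `"z"`) take the exact per-column maximum along
#' that axis; a numeric direction vector resamples the volume onto a rotated
#' grid (trilinear) and takes per-column maxima, padding with 0 outside the
#' volume.
#'
#' Output orientation: `"z"` gives rows = y, cols = x; `"y"` rows = z,
#' cols = x; `"x"` rows = z, cols = y.
#'
#' @param vol An `xrh_volume`.
#' @param direction Axis name or nonzero 3D vector `c(x, y, z)`.
#' @param settings Optional [render_settings()] applied to the output.
#' @return Numeric matrix.
#' @export
mip <- function(vol, direction = "z", settings = NULL) {
  .assert_volume(vol)
  if (is.character(direction)) {
    ax <- match.arg(direction, c("x", "y", "z"))
    img <- switch(ax,
      z = apply(vol$data, c(2, 3), max),
      y = apply(vol$data, c(1, 3), max),
      x = apply(vol$data, c(1, 2), max))
    if (!is.null(settings)) img <- apply_window(img, settings)
    return(img)
  }
  direction <- as.numeric(direction)
  if (length(direction) != 3L || sum(direction^2) == 0)
    stop("direction must be an axis name or a nonzero 3D vector")
  .mip_oblique(vol, direction, settings = settings)
}

#' Rotating maximum intensity projection
#'
#' A sequence of MIPs at `n_angles` uniformly spaced angular positions over
#' 360 degrees, rotating the projection direction about the given axis —
#' played as frames this restores the depth cue a single MIP lacks. Frame
#' `k` (zero-based) uses angle `k * 360 / n_angles`; frame 0 equals
#' `mip(vol, direction = <start direction>)` exactly (same resampling path
#' and image frame).
#'
#' Start directions: `+y` for `axis = "z"` and `axis = "x"` (image rows
#' follow z), `+z` for `axis = "y"` (rows follow y); the in-plane image
#' basis rotates continuously with the angle.
#'
#' @param vol An `xrh_volume`.
#' @param axis Rotation axis, `"x"`, `"y"` or `"z"`.
#' @param n_angles Integer >= 2.
#' @param settings Optional [render_settings()].
#' @return List of `n_angles` matrices (equal size).
#' @export
rotating_mip <- function(vol, axis = "z", n_angles = 8L, settings = NULL) {
  .assert_volume(vol)
  axis <- match.arg(axis, c("x", "y", "z"))
  n_angles <- as.integer(n_angles)
  if (is.na(n_angles) || n_angles < 2L) stop("n_angles must be an integer >= 2")
  lapply(seq_len(n_angles) - 1L, function(k) {
    th <- 2 * pi * k / n_angles
    # continuous in-angle bases agreeing with .complete_basis at theta = 0,
    # so frame 0 is bit-identical to mip(vol, <start direction>)
    bas <- switch(axis,
      z = list(d = c(sin(th), cos(th), 0), u = c(cos(th), -sin(th), 0), v = c(0, 0, 1)),
      y = list(d = c(sin(th), 0, cos(th)), u = c(-cos(th), 0, sin(th)), v = c(0, 1, 0)),
      x = list(d = c(0, cos(th), sin(th)), u = c(1, 0, 0), v = c(0, -sin(th), cos(th))))
    .mip_oblique(vol, bas$d, bas$u, bas$v, settings)
  })
}

#' Orthogonal multiplanar views through a point
#'
#' The three axis-aligned slices through a voxel, extracted exactly (no
#' interpolation): `xy` (rows y, cols x), `yz` (rows z, cols y) and `xz`
#' (rows z, cols x).
#'
#' @param vol An `xrh_volume`.
#' @param point Zero-based voxel coordinate `c(x, y, z)`.
#' @return List of three matrices `xy`, `yz`, `xz`.
#' @export
orthogonal_views <- function(vol, point) {
  .assert_volume(vol)
  p <- as.integer(round(point))
  sh <- vol$meta$shape
  if (length(p) != 3L || any(p < 0L) || p[1] >= sh[3] || p[2] >= sh[2] || p[3] >= sh[1])
    stop("point (x, y, z) out of volume bounds")
  list(xy = matrix(vol$data[p[3] + 1L, , ], sh[2]),
       yz = matrix(vol$data[, , p[1] + 1L], sh[1]),
       xz = matrix(vol$data[, p[2] + 1L, ], sh[1]))
}

#' Oblique reslice of a volume
#'
#' Resamples the volume on an arbitrary oriented plane:
#' `image[i, j] = volume(origin + i * spacing * v + j * spacing * u)` with
#' zero-based `i` (rows) and `j` (columns). Bicubic interpolation (cubic
#' convolution, exact at lattice points) is the default, matching the
#' protocol's landmark-plane resampling; trilinear is available and
#' reproduces linear gray ramps exactly. Samples falling outside the volume
#' are padded with 0, the calibrated gray value of air.
#'
#' @param vol An `xrh_volume`.
#' @param plane A [plane_spec()].
#' @param interpolation `"bicubic"` or `"trilinear"`.
#' @return Numeric matrix `height_px x width_px`.
#' @export
oblique_slice <- function(vol, plane, interpolation = c("bicubic", "trilinear")) {
  .assert_volume(vol)
  if (!inherits(plane, "plane_spec")) stop("plane must be a plane_spec")
  interpolation <- match.arg(interpolation)
  wpx <- plane$extent[1]; hpx <- plane$extent[2]
  jj <- rep(seq_len(wpx) - 1L, each = hpx)
  ii <- rep(seq_len(hpx) - 1L, times = wpx)
  s <- plane$sample_spacing
  pts <- cbind(plane$origin[1] + ii * s * plane$v_axis[1] + jj * s * plane$u_axis[1],
               plane$origin[2] + ii * s * plane$v_axis[2] + jj * s * plane$u_axis[2],
               plane$origin[3] + ii * s * plane$v_axis[3] + jj * s * plane$u_axis[3])
  matrix(.interp3(vol$data, pts, interpolation, pad = 0), hpx, wpx)
}
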