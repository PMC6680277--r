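# Coregistration of 2D histology slides with the 3D volume. Histology
# sections are cut from the very block that was scanned, so a physical
# counterpart of each slide exists inside the volume: >= 3 landmark features
# identified in both define a plane; the volume is resliced on that plane
# (bicubic); the slide is then elastically warped onto the virtual slice with
# a landmark-interpolating thin-plate spline to undo sectioning distortion.

#' Paired 2D/3D landmarks
#'
#' @param p2d `n x 2` matrix of `(x, y)` histology pixel coordinates
#'   (zero-based).
#' @param p3d `n x 3` matrix of `(x, y, z)` volume voxel coordinates
#'   (zero-based). At least 3 pairs; the 3D points must not be collinear.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(p2d, p3d) {
  p2d <- as.matrix(p2d); p3d <- as.matrix(p3d)
  if (ncol(p2d) != 2L || ncol(p3d) != 3L || nrow(p2d) != nrow(p3d))
    stop("landmarks must be paired n x 2 (2D) and n x 3 (3D) matrices")
  if (nrow(p3d) < 3L) stop("a minimum of three landmark pairs is required")
  ctr <- sweep(p3d, 2, colMeans(p3d))
  if (svd(ctr)$d[2] < 1e-8 * max(1, svd(ctr)$d[1]))
    stop("degenerate landmark configuration: 3D points are collinear")
  structure(list(p2d = unname(p2d), p3d = unname(p3d)), class = "landmark_set")
}

#' Read a landmark file
#'
#' Plain-text CSV with mandatory header `x2d,y2d,x3d,y3d,z3d`, one row per
#' pair, zero-based pixel/voxel coordinates.
#'
#' @param path CSV path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x2d", "y2d", "x3d", "y3d", "z3d")
  if (!all(need %in% names(df)))
    stop("landmark file must have header columns: ", paste(need, collapse = ","))
  landmark_set(as.matrix(df[, c("x2d", "y2d")]), as.matrix(df[, c("x3d", "y3d", "z3d")]))
}

#' @rdname read_landmarks
#' @param landmarks A [landmark_set()] to serialize.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(x2d = landmarks$p2d[, 1], y2d = landmarks$p2d[, 2],
                   x3d = landmarks$p3d[, 1], y3d = landmarks$p3d[, 2],
                   z3d = landmarks$p3d[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit a plane to 3D landmarks
#'
#' Total-least-squares plane: origin at the centroid, normal along the
#' smallest principal direction of the centered points; `u`/`v` are the two
#' leading principal directions (orthonormal, in-plane). Coplanar points are
#' fitted exactly.
#'
#' @param landmarks A [landmark_set()], or an `n x 3` matrix of 3D points.
#' @param extent Optional `c(width_px, height_px)`; default covers the
#'   projected landmark spread with a margin.
#' @param margin_px Margin added around the landmarks when `extent` is
#'   derived automatically.
#' @return A [plane_spec()]; the fit residuals are attached as
#'   `attr(, "residuals")`.
#' @export
fit_plane <- function(landmarks, extent = NULL, margin_px = 8) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$p3d else as.matrix(landmarks)
  if (nrow(pts) < 3L) stop("plane fitting needs at least three points")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen)
  if (sv$d[2] < 1e-8 * max(1, sv$d[1]))
    stop("degenerate landmark configuration: points are collinear")
  u <- sv$v[, 1]; v <- sv$v[, 2]; normal <- sv$v[, 3]
  # canonical axis signs (largest-magnitude component positive) so the
  # returned basis is reproducible across SVD implementations
  if (u[which.max(abs(u))] < 0) u <- -u
  if (v[which.max(abs(v))] < 0) v <- -v
  # in-plane coordinates of the landmarks
  pu <- cen %*% u; pv <- cen %*% v
  if (is.null(extent)) extent <- c(ceiling(diff(range(pu))) + 2 * margin_px,
                                   ceiling(diff(range(pv))) + 2 * margin_px)
  origin <- ctr + (min(pu) - margin_px) * u + (min(pv) - margin_px) * v
  ps <- plane_spec(origin, u, v, extent)
  attr(ps, "residuals") <- as.numeric(cen %*% normal)
  attr(ps, "normal") <- normal
  ps
}

#' Extract the virtual slice matching a histology slide
#'
#' Reslices the volume on the landmark-fitted plane and additionally at a
#' ladder of offsets along the plane normal, so the best-matching slice can
#' be chosen by eye (or ranked by normalized cross-correlation against a
#' reference image) — the choice is assisted, never silently automatic.
#'
#' @param vol An `xrh_volume`.
#' @param landmarks A [landmark_set()].
#' @param offsets Numeric vector of normal offsets in voxels for the
#'   candidate ladder (0 is always included).
#' @param interpolation Passed to [oblique_slice()].
#' @param reference Optional 2D grayscale image; when given, candidates are
#'   ranked by correlation with it (`$ncc`).
#' @return List: `image` (slice at offset 0), `plane`, `candidates` (list of
#'   matrices), `offsets`, and `ncc` (or `NULL`).
#' @export
match_slice <- function(vol, landmarks, offsets = seq(-4, 4, by = 1),
                        interpolation = "bicubic", reference = NULL) {
  .assert_volume(vol)
  plane <- fit_plane(landmarks)
  sh <- vol$meta$shape
  lim <- c(sh[3], sh[2], sh[1]) - 1
  ctr <- colMeans(landmarks$p3d)
  if (any(ctr < -0.5 - 1e-9) || any(ctr > lim + 0.5 + 1e-9))
    stop("fitted plane lies outside the volume")
  offsets <- sort(unique(c(0, as.numeric(offsets))))
  nrm <- attr(plane, "normal")
  candidates <- lapply(offsets, function(o) {
    p <- plane_spec(plane$origin + o * nrm, plane$u_axis, plane$v_axis,
                    plane$extent, plane$sample_spacing)
    oblique_slice(vol, p, interpolation)
  })
  ncc <- NULL
  if (!is.null(reference)) {
    ref <- as.numeric(reference)
    ncc <- vapply(candidates, function(cand) {
      v <- as.numeric(cand)
      if (stats::sd(v) == 0 || stats::sd(ref) == 0) return(NA_real_)
      stats::cor(v, ref)
    }, numeric(1))
  }
  list(image = candidates[[which(offsets == 0)]], plane = plane,
       candidates = candidates, offsets = offsets, ncc = ncc)
}

# ---- thin-plate spline -----------------------------------------------------

.tps_kernel <- function(r2) {
  # U(r) = r^2 log r, continuously extended by 0 at r = 0
  out <- r2 * 0
  pos <- r2 > 0
  out[pos] <- 0.5 * r2[pos] * log(r2[pos])
  out
}

.pdist2 <- function(a, b) {
  # squared distances between rows of a (n x 2) and b (m x 2)
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# Fit an interpolating (lambda = 0) or regularized TPS mapping src -> dst.
.tps_fit <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  K <- .tps_kernel(pmax(.pdist2(src, src), 0))
  P <- cbind(1, src)
  if (qr(P)$rank < 3L) return(NULL)  # collinear source points
  A <- rbind(cbind(K + lambda * diag(n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- solve(A, rhs)
  list(src = src, w = coef[seq_len(n), , drop = FALSE],
       a = coef[n + 1:3, , drop = FALSE], lambda = lambda)
}

.tps_eval <- function(fit, pts) {
  pts <- as.matrix(pts)
  U <- .tps_kernel(pmax(.pdist2(pts, fit$src), 0))
  cbind(1, pts) %*% fit$a + U %*% fit$w
}

.affine_fit <- function(src, dst) {
  # least-squares affine fallback (rank-deficient safe via SVD pseudoinverse)
  P <- cbind(1, src)
  sv <- svd(P)
  dpos <- sv$d > 1e-10 * sv$d[1]
  pinv <- sv$v[, dpos, drop = FALSE] %*%
    (t(sv$u[, dpos, drop = FALSE]) / sv$d[dpos])
  list(a = pinv %*% dst)
}

.affine_eval <- function(fit, pts) cbind(1, as.matrix(pts)) %*% fit$a

#' Elastic 2D registration by landmark-interpolating thin-plate spline
#'
#' Warps a histology image (moving) onto a CT slice (target) so that each
#' source landmark lands exactly on its paired target landmark
#' (`lambda = 0`, interpolating; `lambda > 0` trades exactness for
#' smoothness). The spline's affine part reproduces purely affine
#' deformations with vanishing radial coefficients. The warped image is
#' resampled with bicubic interpolation through the backward map (target to
#' moving); colour images are warped per channel. Collinear landmarks fall
#' back to an affine-only fit with a warning.
#'
#' @param moving 2D matrix (gray) or `h x w x 3` array (colour), the
#'   histology image.
#' @param target 2D matrix, the CT slice; defines the output extent.
#' @param src `n x 2` landmark coordinates in the moving image (zero-based
#'   x, y).
#' @param dst `n x 2` paired coordinates in the target image.
#' @param lambda Regularization weight (0 = interpolating).
#' @param pad Fill value outside the moving image.
#' @return List with `warp` (an `xrh_warp2d`) and `warped` (image with the
#'   target's extent).
#' @export
elastic_register <- function(moving, target, src, dst, lambda = 0, pad = 0) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || nrow(src) != nrow(dst))
    stop("at least three paired 2D landmarks are required")
  fwd <- .tps_fit(src, dst, lambda)
  bwd <- .tps_fit(dst, src, lambda)
  affine_only <- is.null(fwd) || is.null(bwd)
  if (affine_only) {
    warning("collinear landmarks: falling back to an affine-only fit")
    fwd <- .affine_fit(src, dst)
    bwd <- .affine_fit(dst, src)
  }
  tdim <- dim(target)[1:2]
  warp <- structure(list(fwd = fwd, bwd = bwd, affine_only = affine_only,
                         control_src = src, control_dst = dst,
                         domain = c(width = tdim[2], height = tdim[1])),
                    class = "xrh_warp2d")
  list(warp = warp, warped = warp_image(warp, moving, tdim, pad = pad))
}

#' Apply a 2D warp to an image
#'
#' Resamples `moving` on the warp's target grid using the backward map and
#' bicubic interpolation.
#'
#' @param warp An `xrh_warp2d`.
#' @param moving Gray matrix or colour array.
#' @param out_dim `c(rows, cols)` of the output (default: warp domain).
#' @param pad Fill value for samples outside `moving`.
#' @return Warped image with `out_dim` extent.
#' @export
warp_image <- function(warp, moving, out_dim = NULL, pad = 0) {
  if (is.null(out_dim)) out_dim <- c(warp$domain[["height"]], warp$domain[["width"]])
  h <- out_dim[1]; w <- out_dim[2]
  gx <- rep(seq_len(w) - 1L, each = h)
  gy <- rep(seq_len(h) - 1L, times = w)
  ev <- if (warp$affine_only) .affine_eval else .tps_eval
  srcpts <- ev(warp$bwd, cbind(gx, gy))
  if (length(dim(moving)) == 3L) {
    out <- array(0, c(h, w, dim(moving)[3]))
    for (ch in seq_len(dim(moving)[3]))
      out[, , ch] <- matrix(.interp2(moving[, , ch], srcpts, "bicubic", pad), h, w)
    out
  } else {
    matrix(.interp2(moving, srcpts, "bicubic", pad), h, w)
  }
}

#' Evaluate a warp's forward map
#'
#' @param warp An `xrh_warp2d`.
#' @param pts `n x 2` zero-based `(x, y)` points in the moving image.
#' @return `n x 2` mapped points in the target image.
#' @export
warp_forward <- function(warp, pts) {
  ev <- if (warp$affine_only) .affine_eval else .tps_eval
  ev(warp$fwd, pts)
}

#' Registration quality report
#'
#' Per-landmark residuals of the forward map (zero, to numerical tolerance,
#' for an interpolating spline) and the displacement-magnitude field
#' `|fwd(x) - x|` over the target domain — a map of how far the section had
#' to be unwarped to fit its undistorted state.
#'
#' @param warp An `xrh_warp2d`.
#' @param grid_step Sampling step (px) of the displacement map.
#' @return List: `landmark_residuals_px`, `mean_residual_px`,
#'   `max_residual_px`, `mean_displacement_px`, `max_displacement_px`,
#'   `displacement_map` (matrix).
#' @export
registration_report <- function(warp, grid_step = 1) {
  if (!inherits(warp, "xrh_warp2d")) stop("expected an xrh_warp2d")
  mapped <- warp_forward(warp, warp$control_src)
  res <- sqrt(rowSums((mapped - warp$control_dst)^2))
  w <- warp$domain[["width"]]; h <- warp$domain[["height"]]
  xs <- seq(0, w - 1, by = grid_step)
  ys <- seq(0, h - 1, by = grid_step)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  disp <- warp_forward(warp, cbind(gx, gy)) - cbind(gx, gy)
  mag <- matrix(sqrt(rowSums(disp^2)), length(ys), length(xs))
  list(landmark_residuals_px = res,
       mean_residual_px = mean(res), max_residual_px = max(res),
       mean_displacement_px = mean(mag), max_displacement_px = max(mag),
       displacement_map = mag)
}
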