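# Synthetic FFPE-like phantoms with ground truth. The generators emulate the
# gray-level structure the pipeline assumes — three populations with
# air < wax < tissue and additive Gaussian noise — plus geometric and
# foam-like tissue architectures whose thickness / volume fraction are known
# analytically or by direct counting, never by the code under test.

#' Phantom generation parameters
#'
#' Defaults sit on the calibrated 16-bit scale of the reference protocol:
#' air 0, paraffin wax 30419, tissue 40289, at 8.48 um voxels. For raw-scale
#' fixtures (preprocessing / calibration tests) pass arbitrary float means.
#'
#' @param shape Integer triple `(nz, ny, nx)`.
#' @param voxel_size_um Isotropic voxel size (um).
#' @param gray_air,gray_wax,gray_tissue Material means; must be strictly
#'   increasing.
#' @param noise_sigma Additive Gaussian noise SD (>= 0).
#' @param seed Integer seed; all generators are bit-reproducible under
#'   `(seed, parameters)`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), voxel_size_um = 8.48,
                         gray_air = 0, gray_wax = 30419, gray_tissue = 40289,
                         noise_sigma = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_size_um > 0,
            noise_sigma >= 0)
  if (!(gray_air < gray_wax && gray_wax < gray_tissue))
    stop("gray levels must satisfy gray_air < gray_wax < gray_tissue")
  list(shape = shape, voxel_size_um = voxel_size_um, gray_air = gray_air,
       gray_wax = gray_wax, gray_tissue = gray_tissue,
       noise_sigma = noise_sigma, seed = as.integer(seed))
}

# Run code under a local RNG state (restores the caller's .Random.seed).
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Zero-based coordinate grids for a (nz, ny, nx) array.
.coord_grids <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  list(z = array(rep(0:(nz - 1), times = ny * nx), shape),
       y = array(rep(rep(0:(ny - 1), each = nz), times = nx), shape),
       x = array(rep(0:(nx - 1), each = nz * ny), shape))
}

# Separable 3D Gaussian blur (edge replication), used by the foam generator.
.blur3d <- function(a, sigma) {
  taps <- .gauss_taps(sigma)
  d <- dim(a)
  # along z: (nz x ny*nx) matrix
  a <- array(.conv1d_mat(d[1], taps) %*% matrix(a, d[1]), d)
  # along y
  a <- aperm(array(.conv1d_mat(d[2], taps) %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  # along x
  a <- aperm(array(.conv1d_mat(d[3], taps) %*% matrix(aperm(a, c(3, 2, 1)), d[3]),
                   d[c(3, 2, 1)]), c(3, 2, 1))
  a
}

.add_noise <- function(data, sigma) {
  if (sigma > 0) data + array(rnorm(length(data), 0, sigma), dim(data)) else data
}

#' Calibration phantom: a wax cylinder in air
#'
#' A cylinder (axis along z) of paraffin-wax gray inside an air background,
#' with optional additive Gaussian noise — the synthetic stand-in for the
#' custom wax contrast phantom scanned alongside every sample batch.
#'
#' @param spec A [phantom_spec()].
#' @param radius_frac Cylinder radius as a fraction of the smaller XY
#'   half-extent.
#' @return An `xrh_volume` (float, `calibration_state = "preprocessed"`) with
#'   `attr(, "wax_mask")` / `attr(, "air_mask")` logical arrays.
#' @export
make_calibration_phantom <- function(spec = phantom_spec(), radius_frac = 0.38) {
  g <- .coord_grids(spec$shape)
  cx <- (spec$shape[3] - 1) / 2; cy <- (spec$shape[2] - 1) / 2
  r <- radius_frac * min(spec$shape[2:3] - 1)
  wax <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  data <- array(spec$gray_air, spec$shape)
  data[wax] <- spec$gray_wax
  data <- .with_seed(spec$seed, .add_noise(data, spec$noise_sigma))
  out <- volume(data, spec$voxel_size_um, "float32", "preprocessed")
  attr(out, "wax_mask") <- wax
  attr(out, "air_mask") <- !wax
  out
}

.paint_shape <- function(mask, g, shape) {
  dims_xyz <- c(max(g$x), max(g$y), max(g$z)) + 1L
  type <- shape$type
  if (type == "ball") {
    # digital ball of diameter d: voxel centres strictly inside radius d/2
    c3 <- shape$center  # (x, y, z), zero-based
    r <- shape$d / 2
    if (any(c3 - r < -1 + 1e-9) || any(c3 + r > dims_xyz - 1e-9))
      stop("ball extends outside the volume")
    mask | ((g$x - c3[1])^2 + (g$y - c3[2])^2 + (g$z - c3[3])^2 < r^2 - 1e-9)
  } else if (type == "slab") {
    ax <- match.arg(shape$axis, c("x", "y", "z"))
    at <- shape$at
    n_ax <- dims_xyz[match(ax, c("x", "y", "z"))]
    if (at < 0 || at + shape$t > n_ax) stop("slab extends outside the volume")
    idx <- g[[ax]]
    mask | (idx >= at & idx <= at + shape$t - 1)
  } else if (type == "rod") {
    ax <- match.arg(shape$axis, c("x", "y", "z"))
    r <- shape$d / 2
    perp <- setdiff(c("x", "y", "z"), ax)
    c2 <- shape$center  # 2 coords in the perpendicular plane, order perp[1], perp[2]
    nperp <- dims_xyz[match(perp, c("x", "y", "z"))]
    if (any(c2 - r < -1 + 1e-9) || any(c2 + r > nperp - 1e-9))
      stop("rod extends outside the volume")
    mask | ((g[[perp[1]]] - c2[1])^2 + (g[[perp[2]]] - c2[2])^2 < r^2 - 1e-9)
  } else stop("unknown shape type: ", type)
}

#' Geometric phantom with analytic thickness ground truth
#'
#' Paints digital balls, slabs and rods of tissue gray into a wax block
#' (optionally surrounded by an air margin). The true local thickness of each
#' primitive is its defining diameter/thickness, so the phantom doubles as an
#' analytic oracle for the morphometry module.
#'
#' Shapes are lists: `list(type = "ball", d = 15, center = c(x, y, z))`,
#' `list(type = "slab", t = 5, axis = "z", at = 10)`,
#' `list(type = "rod", d = 7, axis = "z", center = c(x, y))` (all voxel
#' units, zero-based; `d`/`t` in voxels).
#'
#' @param spec A [phantom_spec()].
#' @param shapes List of shape descriptors.
#' @param air_margin Air border width in voxels (0 = wax everywhere outside
#'   the tissue).
#' @return List `volume` (an `xrh_volume`, `calibrated`) and `ground_truth`
#'   (fields `tissue_mask`, `voi`, `true_volume_fraction`,
#'   `shape_thickness_um`).
#' @export
make_geometric_phantom <- function(spec = phantom_spec(), shapes, air_margin = 0L) {
  g <- .coord_grids(spec$shape)
  mask <- array(FALSE, spec$shape)
  for (s in shapes) mask <- .paint_shape(mask, g, s)
  if (!any(mask)) stop("shapes paint no voxels inside the volume")
  voi <- array(TRUE, spec$shape)
  if (air_margin > 0L) {
    m <- air_margin
    voi <- g$z >= m & g$z < spec$shape[1] - m &
           g$y >= m & g$y < spec$shape[2] - m &
           g$x >= m & g$x < spec$shape[3] - m
    mask <- mask & voi
  }
  data <- array(spec$gray_air, spec$shape)
  data[voi] <- spec$gray_wax
  data[mask] <- spec$gray_tissue
  data <- .with_seed(spec$seed, .add_noise(data, spec$noise_sigma))
  thick_um <- vapply(shapes, function(s)
    (if (s$type == "slab") s$t else s$d) * spec$voxel_size_um, numeric(1))
  list(volume = volume(data, spec$voxel_size_um, "float32", "calibrated"),
       ground_truth = list(tissue_mask = mask, voi = voi,
                           true_volume_fraction = sum(mask & voi) / sum(voi),
                           shape_thickness_um = thick_um))
}

#' Foam phantom: lung-parenchyma-like random tissue architecture
#'
#' Thresholded Gaussian random field: white noise is blurred with an
#' isotropic 3D Gaussian whose scale sets the feature size, then thresholded
#' at the exact order statistic giving the count ratio nearest `target_vf`.
#' The achieved volume fraction is therefore known by construction, and the
#' mean local thickness grows monotonically with `feature_scale_um`.
#'
#' @param spec A [phantom_spec()].
#' @param target_vf Target tissue volume fraction, strictly in (0, 1).
#' @param feature_scale_um Characteristic feature size (um); the blur SD is
#'   half this, in voxels.
#' @return List `volume` (an `xrh_volume`, `calibrated`) and `ground_truth`
#'   (fields `tissue_mask`, `voi`, `true_volume_fraction`).
#' @export
make_foam_phantom <- function(spec = phantom_spec(), target_vf = 0.33,
                              feature_scale_um = 4 * spec$voxel_size_um) {
  if (!(target_vf > 0 && target_vf < 1))
    stop("target_vf must lie strictly inside (0, 1)")
  n <- prod(spec$shape)
  field <- .with_seed(spec$seed, array(rnorm(n), spec$shape))
  sigma <- 0.5 * feature_scale_um / spec$voxel_size_um
  field <- .blur3d(field, sigma)
  k <- round((1 - target_vf) * n)
  k <- min(max(k, 1L), n - 1L)
  thr <- sort(as.numeric(field), partial = k)[k]
  mask <- field > thr
  data <- array(spec$gray_wax, spec$shape)
  data[mask] <- spec$gray_tissue
  data <- .with_seed(spec$seed + 1L, .add_noise(data, spec$noise_sigma))
  list(volume = volume(data, spec$voxel_size_um, "float32", "calibrated"),
       ground_truth = list(tissue_mask = mask, voi = array(TRUE, spec$shape),
                           true_volume_fraction = sum(mask) / n))
}

#' FFPE-like block phantom: air surround, wax block, foam tissue
#'
#' The complete synthetic specimen a real scan presents: an air field
#' surrounding a paraffin block (air margin in x/y), with foam-architecture
#' tissue (thresholded Gaussian random field, as in [make_foam_phantom()])
#' occupying a centred volume of interest. The central z-slice therefore
#' shows all three gray populations, as the calibration step expects.
#'
#' @param spec A [phantom_spec()]; its gray levels set the scale (raw float
#'   means or 16-bit values alike).
#' @param target_vf Tissue volume fraction inside the VOI, in (0, 1).
#' @param feature_scale_um Foam feature size (um).
#' @param air_margin Air border around the block in x/y (voxels).
#' @param voi_margin Margin from the volume faces to the VOI (x/y, voxels;
#'   must exceed `air_margin`); the VOI is also inset 4 voxels in z.
#' @param calibration_state State flag of the returned volume.
#' @return List `volume` (an `xrh_volume`) and `ground_truth` (fields
#'   `tissue_mask`, `voi`, `air_mask`, `wax_mask`, `true_volume_fraction`).
#' @export
make_block_phantom <- function(spec = phantom_spec(shape = c(40L, 96L, 96L)),
                               target_vf = 0.33,
                               feature_scale_um = 4 * spec$voxel_size_um,
                               air_margin = 16L, voi_margin = 32L,
                               calibration_state = "preprocessed") {
  if (voi_margin <= air_margin) stop("voi_margin must exceed air_margin")
  g <- .coord_grids(spec$shape)
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  block <- g$x >= air_margin & g$x < nx - air_margin &
           g$y >= air_margin & g$y < ny - air_margin
  voi <- g$x >= voi_margin & g$x < nx - voi_margin &
         g$y >= voi_margin & g$y < ny - voi_margin &
         g$z >= 4 & g$z < nz - 4
  if (!any(voi)) stop("empty VOI: margins too large for the volume shape")
  field <- .with_seed(spec$seed, array(rnorm(prod(spec$shape)), spec$shape))
  field <- .blur3d(field, 0.5 * feature_scale_um / spec$voxel_size_um)
  vv <- field[voi]
  k <- min(max(round((1 - target_vf) * length(vv)), 1L), length(vv) - 1L)
  thr <- sort(vv, partial = k)[k]
  mask <- voi & field > thr
  data <- array(spec$gray_air, spec$shape)
  data[block] <- spec$gray_wax
  data[mask] <- spec$gray_tissue
  data <- .with_seed(spec$seed + 10L, .add_noise(data, spec$noise_sigma))
  list(volume = volume(data, spec$voxel_size_um, "float32", calibration_state),
       ground_truth = list(tissue_mask = mask, voi = voi,
                           air_mask = !block, wax_mask = block & !mask,
                           true_volume_fraction = sum(mask) / sum(voi)))
}

# Smooth pseudo-random 2D displacement field: low-frequency sinusoids with
# seeded amplitudes/phases. Returns a function (n x 2 pts) -> (n x 2 u).
.smooth_field_2d <- function(extent_px, amplitude_px, seed) {
  pars <- .with_seed(seed, list(
    ax = runif(2, 0.4, 1), ay = runif(2, 0.4, 1),
    px = runif(4, 0, 2 * pi), py = runif(4, 0, 2 * pi)))
  # sectioning distortion is long-range (stretch/shear plus a gentle bend):
  # wavelengths are of the order of the section extent or longer
  Tx <- 1.8 * extent_px[1]; Ty <- 1.8 * extent_px[2]
  function(pts) {
    x <- pts[, 1]; y <- pts[, 2]
    ux <- amplitude_px * (pars$ax[1] * sin(2 * pi * x / Tx + pars$px[1]) *
                            cos(2 * pi * y / Ty + pars$px[2]) +
                          0.3 * pars$ax[2] * cos(2 * pi * y / (0.8 * Ty) + pars$px[3]) *
                            sin(2 * pi * x / (0.8 * Tx) + pars$px[4]))
    uy <- amplitude_px * (pars$ay[1] * sin(2 * pi * y / Ty + pars$py[1]) *
                            cos(2 * pi * x / Tx + pars$py[2]) +
                          0.3 * pars$ay[2] * cos(2 * pi * x / (0.8 * Tx) + pars$py[3]) *
                            sin(2 * pi * y / (0.8 * Ty) + pars$py[4]))
    cbind(ux, uy)
  }
}

#' Synthetic histology/CT pair with known plane and deformation
#'
#' Extracts the oblique slice `S` on `plane`, maps it to a stain-like colour
#' palette, and deforms it with a known smooth displacement field `u`:
#' the histology image is `H(x) = S(x + u(x))` (bicubic), emulating the
#' physical distortion of mechanical sectioning, plus optional noise.
#' Landmark pairs `(x, x + u(x))` at tissue-rich positions are returned with
#' the ground truth, so registration recovery can be scored against the
#' exact field without inverting it.
#'
#' @param vol An `xrh_volume`.
#' @param plane A [plane_spec()]; the true section plane.
#' @param amplitude_px Peak displacement amplitude (0 = undeformed copy).
#' @param n_landmarks Number of landmark pairs to generate.
#' @param noise_sd SD of additive image noise (intensity units of `[0, 1]`).
#' @param seed Integer seed.
#' @return List: `histology` (`h x w x 3` array in `[0, 1]`), `ct_slice`
#'   (gray matrix), `ground_truth` (fields `plane`, `displacement` (function),
#'   `landmarks_moving`, `landmarks_target`, `tissue_mask_2d`).
#' @export
make_histology_pair <- function(vol, plane, amplitude_px = 3, n_landmarks = 12L,
                                noise_sd = 0, seed = 1L) {
  .assert_volume(vol)
  s <- oblique_slice(vol, plane, "bicubic")
  rng <- range(s)
  sn <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s * 0
  tissue <- sn > 0.5  # upper gray population = tissue
  # eosin-like palette: background white, tissue pink-purple
  pal <- function(v) array(c(1 - 0.25 * v, 1 - 0.65 * v, 1 - 0.45 * v),
                           c(nrow(v), ncol(v), 3))
  u_fun <- .smooth_field_2d(c(ncol(s), nrow(s)), amplitude_px, seed)
  h <- nrow(s); w <- ncol(s)
  gx <- rep(seq_len(w) - 1L, each = h)
  gy <- rep(seq_len(h) - 1L, times = w)
  uu <- u_fun(cbind(gx, gy))
  src <- cbind(gx + uu[, 1], gy + uu[, 2])
  hist_gray <- matrix(.interp2(sn, src, "bicubic", pad = 0), h, w)
  hist_gray <- pmin(pmax(hist_gray, 0), 1)
  hist_img <- pal(hist_gray)
  if (noise_sd > 0)
    hist_img <- pmin(pmax(.with_seed(seed + 1L,
      hist_img + array(rnorm(length(hist_img), 0, noise_sd), dim(hist_img))), 0), 1)
  # landmarks on tissue, away from the border, spread over the section the
  # way an operator would pick them: stratified, one per grid cell
  margin <- 6
  ok <- tissue &
    row(sn) > margin & row(sn) <= h - margin &
    col(sn) > margin & col(sn) <= w - margin
  if (sum(ok) < n_landmarks)
    ok <- row(sn) > margin & row(sn) <= h - margin &
      col(sn) > margin & col(sn) <= w - margin
  ncol_cells <- ceiling(sqrt(n_landmarks))
  nrow_cells <- ceiling(n_landmarks / ncol_cells)
  cell <- (pmin(floor((col(sn) - 1) * ncol_cells / w), ncol_cells - 1)) * nrow_cells +
    pmin(floor((row(sn) - 1) * nrow_cells / h), nrow_cells - 1)
  pick <- .with_seed(seed + 2L, {
    chosen <- integer(0)
    for (cl in unique(sort(cell[ok]))) {
      incell <- which(ok & cell == cl)
      chosen <- c(chosen, if (length(incell) == 1L) incell else sample(incell, 1L))
    }
    extra <- setdiff(which(ok), chosen)
    if (length(chosen) < n_landmarks)
      chosen <- c(chosen, sample(extra, n_landmarks - length(chosen)))
    head(chosen, n_landmarks)
  })
  lx <- (pick - 1L) %/% h   # zero-based column = x
  ly <- (pick - 1L) %% h    # zero-based row = y
  lm_moving <- cbind(lx, ly)
  lm_target <- lm_moving + u_fun(lm_moving)
  list(histology = hist_img, ct_slice = s,
       ground_truth = list(plane = plane, displacement = u_fun,
                           landmarks_moving = lm_moving,
                           landmarks_target = lm_target,
                           tissue_mask_2d = tissue))
}
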