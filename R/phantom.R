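# Synthetic HU-calibrated head-and-neck-like CT phantoms with gold-standard
# and simulated second-observer label maps. Organs are analytic solids:
# brainstem and cervical cord as axial tubes, the mandible as a partial
# torus (arch), the parotids as laterally mirrored ellipsoids, all inside a
# soft-tissue body ellipsoid surrounded by air.

#' Phantom specification
#'
#' Defines the geometry and tissue model of a synthetic head-and-neck CT
#' phantom. The defaults emulate a cropped planning CT at 1x1x2.5 mm voxel
#' spacing: a soft-tissue body ellipsoid (~20 HU) in air (-1024 HU), a
#' bone-density mandible arch (~900 HU), soft-tissue brainstem and spinal
#' cord tubes and laterally symmetric parotid ellipsoids (30-60 HU), with
#' Gaussian noise and mild smoothing.
#'
#' @param shape Volume shape in voxels (default 64x64x16; up to 200x200x56).
#' @param spacing Voxel spacing in mm.
#' @param hu Named list of tissue mean HU values.
#' @param noise_sd Gaussian intensity noise, HU.
#' @param observer_mm Boundary perturbation magnitude for the simulated
#'   second observer, mm.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @return Object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(64, 64, 16), spacing = c(1, 1, 2.5),
                         hu = list(air = -1024, body = 20, brainstem = 45,
                                   mandible = 900, parotid = 60,
                                   spinal_cord = 35),
                         noise_sd = 12, observer_mm = 2, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd >= 0, observer_mm >= 0)
  structure(list(shape = shape, spacing = as.numeric(spacing), hu = hu,
                 noise_sd = noise_sd, observer_mm = observer_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate grids in voxel units (0-based), as nvox vectors
coord_grids <- function(shape) {
  x <- rep(seq_len(shape[1]) - 1L, times = shape[2] * shape[3])
  y <- rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), times = shape[3])
  z <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  list(x = x, y = y, z = z)
}

# analytic organ masks; all geometry is expressed in fractions of the volume
# so phantoms scale with shape, and placements are exactly mirror-symmetric
# about the mid-sagittal plane x = (nx-1)/2
phantom_masks <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  g <- coord_grids(d)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  mm_x <- (g$x - cx) * sp[1]; mm_y <- (g$y - cy) * sp[2]
  mm_z <- (g$z - cz) * sp[3]
  ext <- (d - 1) * sp / 2  # half-extents in mm
  ell <- function(x0, y0, z0, rx, ry, rz)
    ((mm_x - x0) / rx)^2 + ((mm_y - y0) / ry)^2 + ((mm_z - z0) / rz)^2 <= 1
  body <- ell(0, 0, 0, 0.92 * ext[1], 0.88 * ext[2], 1.25 * ext[3])
  # brainstem: axial tube, slightly posterior, upper half of the volume
  r_bs <- 0.13 * ext[1]
  brainstem <- (mm_x^2 + (mm_y - 0.10 * ext[2])^2 <= r_bs^2) &
               (mm_z >= 0.05 * ext[3])
  # spinal cord: thinner tube, more posterior, lower half
  r_sc <- 0.09 * ext[1]
  cord <- (mm_x^2 + (mm_y - 0.25 * ext[2])^2 <= r_sc^2) &
          (mm_z <= -0.05 * ext[3])
  # mandible: anterior partial torus (arch) with elliptical tube section
  R <- 0.52 * ext[1]; r_tube <- 0.10 * ext[1]; r_tube_z <- 0.35 * ext[3]
  rho <- sqrt(mm_x^2 + (mm_y + 0.12 * ext[2])^2)
  ang <- atan2(mm_x, -(mm_y + 0.12 * ext[2]))  # 0 = anterior
  mandible <- (((rho - R) / r_tube)^2 +
               ((mm_z + 0.25 * ext[3]) / r_tube_z)^2 <= 1) & (abs(ang) <= 1.9)
  # parotids: lateral ellipsoids, mirror pair about the mid-sagittal plane
  px <- 0.55 * ext[1]
  par_r <- ell(-px, 0.02 * ext[2], 0.1 * ext[3],
               0.16 * ext[1], 0.22 * ext[2], 0.5 * ext[3])
  par_l <- ell(px, 0.02 * ext[2], 0.1 * ext[3],
               0.16 * ext[1], 0.22 * ext[2], 0.5 * ext[3])
  msk <- function(v) array(v, d)
  list(body = msk(body), brainstem = msk(brainstem & body),
       mandible = msk(mandible & body),
       parotid_l = msk(par_l & body), parotid_r = msk(par_r & body),
       spinal_cord = msk(cord & body))
}

#' Generate a synthetic head-and-neck CT phantom
#'
#' Builds the CT volume, the gold-standard label map and a simulated
#' second-observer label map (a bounded smooth boundary perturbation of the
#' gold standard). Deterministic given \code{spec$seed}.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return Object of class \code{"phantom_case"}: list with \code{ct}
#'   (\code{ct_volume}), \code{gold}, \code{observer2} (\code{label_map}),
#'   \code{spec}.
#' @examples
#' case <- generate_phantom(phantom_spec(shape = c(32, 32, 8)))
#' sort(unique(as.vector(case$gold$labels)))
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  m <- phantom_masks(spec)
  codes <- oar_labels()
  lab <- array(0L, d)
  lab[m$brainstem] <- codes[["brainstem"]]
  lab[m$mandible] <- codes[["mandible"]]
  lab[m$parotid_l] <- codes[["parotid_l"]]
  lab[m$parotid_r] <- codes[["parotid_r"]]
  lab[m$spinal_cord] <- codes[["spinal_cord"]]
  hu <- spec$hu
  ct <- array(hu$air, d)
  ct[m$body] <- hu$body
  ct[m$brainstem] <- hu$brainstem
  ct[m$mandible] <- hu$mandible
  ct[m$parotid_l] <- hu$parotid
  ct[m$parotid_r] <- hu$parotid
  ct[m$spinal_cord] <- hu$spinal_cord
  if (spec$noise_sd > 0)
    ct <- ct + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  ct <- smooth3(ct)
  ct[ct < -1024] <- -1024
  gold <- label_map(lab, spec$spacing)
  obs2 <- perturb_observer(gold, spec$observer_mm, spec$spacing,
                           seed = spec$seed + 1L)
  structure(list(ct = ct_volume(ct, spec$spacing), gold = gold,
                 observer2 = obs2, spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("Synthetic head-and-neck CT phantom\n")
  print(x$ct)
  tb <- table(factor(x$gold$labels, levels = oar_labels(),
                     labels = names(oar_labels())))
  cat("Gold-standard voxels per structure:\n")
  print(tb)
  invisible(x)
}

# separable 1-2-1 smoothing along each axis (mild partial-volume blur)
smooth3 <- function(a) {
  k <- c(0.25, 0.5, 0.25)
  d <- dim(a)
  pad_conv <- function(m) {
    # m is a matrix whose rows are filtered (edge-replicated)
    m2 <- k[2] * m
    m2[-1, ] <- m2[-1, ] + k[1] * m[-nrow(m), ]
    m2[1, ] <- m2[1, ] + k[1] * m[1, ]
    m2[-nrow(m), ] <- m2[-nrow(m), ] + k[3] * m[-1, ]
    m2[nrow(m), ] <- m2[nrow(m), ] + k[3] * m[nrow(m), ]
    m2
  }
  a <- array(pad_conv(matrix(a, d[1])), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(pad_conv(matrix(a, d[2])), d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(pad_conv(matrix(a, d[3])), d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

#' Simulate a second observer by smooth boundary perturbation
#'
#' Applies, independently for every organ, a smooth random in-plane
#' displacement field (low-resolution Gaussian field, trilinearly
#' interpolated, rescaled so the maximum displacement over that organ's
#' voxels equals \code{magnitude_mm}) and resamples the organ's mask with
#' nearest-neighbour interpolation. Displacements are in-plane because
#' inter-observer contouring variability is dominantly slice-wise; the
#' per-organ scaling guarantees every organ's boundary actually moves
#' while the maximum displacement stays bounded by the magnitude.
#' Magnitude 0 returns the input unchanged; output codes are a subset of
#' the input codes (overlaps resolve in code order).
#'
#' @param gold A \code{\link{label_map}} (or integer array).
#' @param magnitude_mm Maximum boundary displacement in mm (>= 0).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @return A \code{label_map}.
#' @export
perturb_observer <- function(gold, magnitude_mm, spacing = c(1, 1, 2.5),
                             seed = 1L) {
  lab <- if (inherits(gold, "label_map")) gold$labels else gold
  if (inherits(gold, "label_map")) spacing <- gold$spacing
  stopifnot(magnitude_mm >= 0)
  if (magnitude_mm == 0) return(label_map(lab, spacing))
  d <- dim(lab)
  g <- coord_grids(d)
  codes <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- array(0L, d)
  cg <- pmax(c(4L, 4L, 2L), d %/% 16L)
  for (k in seq_along(codes)) {
    set.seed(seed + 1000L * (k - 1L))
    # smooth in-plane displacement field (mm), per organ
    disp <- lapply(1:2, function(i)
      upsample_to(array(stats::rnorm(prod(cg)), cg), d))
    organ <- lab == codes[k]
    mag <- sqrt(disp[[1]]^2 + disp[[2]]^2)
    scale <- magnitude_mm / max(mag[organ])
    # clamp so no voxel anywhere displaces farther than the magnitude
    f <- scale * pmin(1, magnitude_mm / pmax(mag * scale, 1e-12))
    sx <- g$x + as.vector(disp[[1]] * f) / spacing[1]
    sy <- g$y + as.vector(disp[[2]] * f) / spacing[2]
    warped <- nearest_sample(organ, sx, sy, g$z, fill = FALSE) > 0
    out[warped & out == 0L] <- codes[k]
  }
  label_map(out, spacing)
}

# trilinear upsampling of a coarse array onto an arbitrary target grid
upsample_to <- function(coarse, d) {
  cg <- dim(coarse)
  g <- coord_grids(d)
  # map target voxel centres onto the coarse grid's index space
  fx <- (g$x / max(d[1] - 1, 1)) * (cg[1] - 1)
  fy <- (g$y / max(d[2] - 1, 1)) * (cg[2] - 1)
  fz <- (g$z / max(d[3] - 1, 1)) * (cg[3] - 1)
  array(trilinear_sample(coarse, fx, fy, fz, fill = 0), d)
}

# trilinear interpolation at fractional 0-based coordinates
trilinear_sample <- function(a, fx, fy, fz, fill = 0) {
  d <- dim(a)
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  acc <- numeric(length(fx))
  get <- function(xi, yi, zi) {
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
    v <- rep(fill, length(xi))
    idx <- 1 + xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok])
    v[ok] <- a[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
         (if (dz) tz else 1 - tz)
    acc <- acc + w * get(x0 + dx, y0 + dy, z0 + dz)
  }
  acc
}

# nearest-neighbour sampling at fractional 0-based coordinates
nearest_sample <- function(a, fx, fy, fz, fill = 0L) {
  d <- dim(a)
  xi <- as.integer(round(fx)); yi <- as.integer(round(fy))
  zi <- as.integer(round(fz))
  ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
  v <- rep(fill, length(fx))
  idx <- 1 + xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok])
  v[ok] <- a[idx]
  v
}
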