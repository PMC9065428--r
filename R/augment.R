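# On-the-fly random 3D spatial augmentation of image/label pairs:
# lateral mirroring (with left/right label-code swap), integer-voxel
# shifts, small rotations about the left-right and cranio-caudal axes, and
# volumetric scaling. All elementary transforms are composed into a single
# resampling (tri-linear for intensities, nearest-neighbour for labels).

#' Augmentation policy
#'
#' Probabilities and magnitudes of the elementary transforms. Defaults
#' follow the training protocol: lateral mirroring with p = 0.5; shifts of
#' at most 4 voxels per axis with p = 1 (at 1x1x2.5 mm spacing: +-4 mm
#' in-plane, +-10 mm axially); rotations within +-10 degrees with p = 0.75
#' (about the left-right axis for cervical flexion/extension and the
#' cranio-caudal axis for axial rotation); volumetric scaling within
#' 90-110\% with p = 0.5.
#'
#' @param mirror_prob,shift_prob,rotate_prob,scale_prob Inclusion
#'   probabilities of each elementary transform.
#' @param shift_max Per-axis maximum shift in voxels (length 3).
#' @param rotate_max_deg Maximum rotation magnitude, degrees.
#' @param scale_range Scaling factor interval.
#' @param lr_label_pairs List of length-2 integer vectors: label-code pairs
#'   swapped on lateral mirroring (default: left/right parotid).
#' @return Object of class \code{"augmentation_policy"}.
#' @export
augmentation_policy <- function(mirror_prob = 0.5, shift_prob = 1,
                                shift_max = c(4, 4, 4),
                                rotate_prob = 0.75, rotate_max_deg = 10,
                                scale_prob = 0.5, scale_range = c(0.9, 1.1),
                                lr_label_pairs = list(c(3L, 4L))) {
  pr <- c(mirror_prob, shift_prob, rotate_prob, scale_prob)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (rotate_max_deg < 0) stop("rotate_max_deg must be >= 0")
  if (any(scale_range <= 0) || any(scale_range >= 2))
    stop("scale_range must lie within (0, 2)")
  structure(list(mirror_prob = mirror_prob, shift_prob = shift_prob,
                 shift_max = rep_len(as.numeric(shift_max), 3L),
                 rotate_prob = rotate_prob, rotate_max_deg = rotate_max_deg,
                 scale_prob = scale_prob, scale_range = as.numeric(scale_range),
                 lr_label_pairs = lr_label_pairs),
            class = "augmentation_policy")
}

#' Sample a random transform from a policy
#'
#' Each elementary transform is included independently with its policy
#' probability; parameters are drawn uniformly within the stated bounds.
#' The record fully determines the transform and is replayable: the same
#' seed yields an identical record.
#'
#' @param policy An \code{\link{augmentation_policy}}.
#' @param rng_seed Integer seed.
#' @return Object of class \code{"transform_record"}: list with elements
#'   \code{mirror} (logical), \code{shift} (voxels, or NULL),
#'   \code{rotate} (degrees about x and z axes, or NULL), \code{scale}
#'   (factor, or NULL), \code{seed}.
#' @export
sample_transform <- function(policy, rng_seed = 1L) {
  stopifnot(inherits(policy, "augmentation_policy"))
  set.seed(rng_seed)
  rec <- list(mirror = stats::runif(1) < policy$mirror_prob,
              shift = NULL, rotate = NULL, scale = NULL,
              seed = as.integer(rng_seed))
  if (stats::runif(1) < policy$shift_prob)
    rec$shift <- round(stats::runif(3, -policy$shift_max, policy$shift_max))
  if (stats::runif(1) < policy$rotate_prob)
    rec$rotate <- stats::runif(2, -policy$rotate_max_deg, policy$rotate_max_deg)
  if (stats::runif(1) < policy$scale_prob)
    rec$scale <- stats::runif(1, policy$scale_range[1], policy$scale_range[2])
  structure(rec, class = "transform_record")
}

#' @export
print.transform_record <- function(x, ...) {
  cat("Transform record (seed", x$seed, "):\n")
  cat("  mirror:", x$mirror, "\n")
  if (!is.null(x$shift)) cat("  shift (vox):", x$shift, "\n")
  if (!is.null(x$rotate))
    cat(sprintf("  rotate: %.2f deg (L-R axis), %.2f deg (C-C axis)\n",
                x$rotate[1], x$rotate[2]))
  if (!is.null(x$scale)) cat(sprintf("  scale: %.3f\n", x$scale))
  invisible(x)
}

is_identity_record <- function(rec) {
  !rec$mirror && is.null(rec$shift) && is.null(rec$rotate) && is.null(rec$scale)
}

#' Apply a sampled transform to an image/label pair
#'
#' Composes mirror, scale, rotation and shift into one affine map and
#' resamples in a single pass: tri-linear interpolation for intensities,
#' nearest-neighbour for labels (no label mixing). Out-of-field voxels are
#' filled with air (-1024 HU) / background. Lateral mirroring additionally
#' swaps the label codes in \code{policy$lr_label_pairs} so left/right
#' semantics survive. An identity record returns the inputs unchanged.
#'
#' @param volume A \code{\link{ct_volume}}.
#' @param labels A \code{\link{label_map}} with identical geometry.
#' @param record A \code{\link{sample_transform}} result.
#' @param lr_label_pairs Label pairs to swap on mirroring (default:
#'   left/right parotid codes 3 and 4).
#' @return List with transformed \code{volume} and \code{labels}.
#' @export
apply_transform <- function(volume, labels, record,
                            lr_label_pairs = list(c(3L, 4L))) {
  stopifnot(inherits(volume, "ct_volume"), inherits(labels, "label_map"),
            inherits(record, "transform_record"))
  check_same_geometry(dim(volume$intensities), dim(labels$labels),
                      volume$spacing, labels$spacing)
  if (is_identity_record(record))
    return(list(volume = volume, labels = labels))
  d <- dim(volume$intensities)
  sp <- volume$spacing
  ctr <- (d - 1) / 2
  # inverse mapping: for each output voxel centre, find the source position.
  # Forward composition is mirror -> scale -> rotate -> shift, so the
  # inverse applies -shift, rotate^-1, 1/scale, mirror in that order.
  g <- coord_grids(d)
  px <- g$x; py <- g$y; pz <- g$z
  if (!is.null(record$shift)) {
    px <- px - record$shift[1]; py <- py - record$shift[2]
    pz <- pz - record$shift[3]
  }
  # to mm about the centre
  mx <- (px - ctr[1]) * sp[1]; my <- (py - ctr[2]) * sp[2]
  mz <- (pz - ctr[3]) * sp[3]
  if (!is.null(record$rotate)) {
    ax <- -record$rotate[1] * pi / 180  # about x (left-right axis)
    az <- -record$rotate[2] * pi / 180  # about z (cranio-caudal axis)
    # inverse rotation: undo z-rotation then x-rotation
    c1 <- cos(az); s1 <- sin(az)
    tx <- c1 * mx - s1 * my; ty <- s1 * mx + c1 * my
    mx <- tx; my <- ty
    c2 <- cos(ax); s2 <- sin(ax)
    ty <- c2 * my - s2 * mz; tz <- s2 * my + c2 * mz
    my <- ty; mz <- tz
  }
  if (!is.null(record$scale)) {
    mx <- mx / record$scale; my <- my / record$scale; mz <- mz / record$scale
  }
  fx <- mx / sp[1] + ctr[1]; fy <- my / sp[2] + ctr[2]
  fz <- mz / sp[3] + ctr[3]
  if (record$mirror) fx <- (d[1] - 1) - fx
  ct_out <- trilinear_sample(volume$intensities, fx, fy, fz, fill = -1024)
  ct_out[ct_out < -1024] <- -1024  # interpolation round-off below the air floor
  lab_out <- nearest_sample(labels$labels, fx, fy, fz, fill = 0L)
  if (record$mirror) {
    for (pair in lr_label_pairs) {
      a <- lab_out == pair[1]; b <- lab_out == pair[2]
      lab_out[a] <- pair[2]; lab_out[b] <- pair[1]
    }
  }
  list(volume = ct_volume(array(ct_out, d), sp),
       labels = label_map(array(lab_out, d), sp))
}
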