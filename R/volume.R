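#' CT volume with calibrated Hounsfield intensities
#'
#' A 3D scalar field in Hounsfield units (HU) with anisotropic voxel spacing.
#' Axis convention (pinned repo-wide): first axis x = patient left-right,
#' second y = antero-posterior, third z = cranio-caudal; 0-based voxel
#' indices in all coordinate computations.
#'
#' @param intensities Numeric 3D array of HU values (finite).
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @return Object of class \code{"ct_volume"} with fields
#'   \code{intensities}, \code{spacing}.
#' @examples
#' ct_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2.5))
#' @export
ct_volume <- function(intensities, spacing = c(1, 1, 2.5)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("CT intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers (mm)")
  if (any(intensities < -1024)) {
    warning("volume contains intensities below -1024 HU (scanner padding?); ",
            "they window like any out-of-range value", call. = FALSE)
  }
  structure(list(intensities = intensities, spacing = spacing),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("CT volume: %dx%dx%d voxels @ %gx%gx%g mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Integer label map geometry-locked to a CT volume
#'
#' @param labels Integer-valued 3D array; 0 is background.
#' @param spacing Voxel spacing in mm.
#' @return Object of class \code{"label_map"}.
#' @export
label_map <- function(labels, spacing = c(1, 1, 2.5)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (anyNA(labels) || any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers (mm)")
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing = spacing),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  tb <- table(x$labels)
  cat(sprintf("Label map: %dx%dx%d voxels @ %gx%gx%g mm; codes: %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(names(tb), collapse = ", ")))
  invisible(x)
}

# internal: check two gridded objects share geometry
check_same_geometry <- function(a_dim, b_dim, a_sp = NULL, b_sp = NULL) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop("geometry mismatch: shapes differ (",
         paste(a_dim, collapse = "x"), " vs ", paste(b_dim, collapse = "x"), ")")
  if (!is.null(a_sp) && !is.null(b_sp) && !isTRUE(all.equal(a_sp, b_sp)))
    stop("geometry mismatch: voxel spacings differ")
  invisible(TRUE)
}
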