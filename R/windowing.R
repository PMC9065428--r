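#' CT window/level specification
#'
#' A window is the clinician-style intensity ramp used to map Hounsfield
#' units onto \code{[0, 1]}: brightness is set by the window level \code{L}
#' (the ramp centre) and contrast by the window width \code{W} (the HU span
#' between the 0 and 1 plateaus).
#'
#' @param level Window centre in HU.
#' @param width Window width in HU; must be strictly positive.
#' @param name Free-text tag (e.g. \code{"soft-tissue"}).
#' @return An object of class \code{"window_spec"} with fields
#'   \code{level}, \code{width}, \code{name}.
#' @examples
#' window_spec(488, 3024, "baseline")
#' @export
window_spec <- function(level, width, name = "") {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level))
    stop("window level must be a single finite number")
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("window width must be a single strictly positive number")
  structure(list(level = as.numeric(level), width = as.numeric(width),
                 name = as.character(name)[1L]),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("CT window '%s': L = %g HU, W = %g HU (edges %g .. %g HU)\n",
              x$name, x$level, x$width,
              x$level - x$width / 2, x$level + x$width / 2))
  invisible(x)
}

#' Named registry of window presets
#'
#' The \code{"baseline"} preset (L = 488, W = 3024) spans the full
#' conventional CT range \code{[-1024, 2512]} HU, standardising the entire
#' image onto \code{[0, 1]} in a single channel. The three contrast presets
#' are the standard radiological display windows for soft tissue, bony
#' anatomy and brain tissue; they form the default three-channel input.
#'
#' @param name Optional preset name; if missing, the whole registry (a named
#'   list of \code{\link{window_spec}}) is returned.
#' @return A \code{window_spec}, or a named list of them.
#' @examples
#' window_presets("baseline")
#' names(window_presets())
#' @export
window_presets <- function(name) {
  presets <- list(
    baseline      = window_spec(488, 3024, "baseline"),
    `soft-tissue` = window_spec(40, 400, "soft-tissue"),
    bone          = window_spec(400, 1800, "bone"),
    brain         = window_spec(40, 80, "brain")
  )
  if (missing(name)) return(presets)
  if (!name %in% names(presets))
    stop(sprintf("unknown window preset '%s' (available: %s)",
                 name, paste(names(presets), collapse = ", ")))
  presets[[name]]
}

#' The default multi-window channel set
#'
#' Soft-tissue, bone and brain windows, in this fixed channel order.
#' @return List of three \code{window_spec} objects.
#' @export
multi_window_set <- function() {
  window_presets()[c("soft-tissue", "bone", "brain")]
}

#' Apply a window ramp to a CT volume
#'
#' Maps intensities through the ramp
#' \code{clamp((I - (L - W/2)) / W, 0, 1)}: values at or below the lower
#' window edge map to 0, the level maps to 0.5, and values at or above the
#' upper edge map to 1.
#'
#' @param volume A \code{\link{ct_volume}} or a numeric 3D array of HU values.
#' @param spec A \code{\link{window_spec}}.
#' @return Numeric array of the same shape with values in \code{[0, 1]}.
#' @examples
#' v <- array(c(-1024, 488, 3000), dim = c(3, 1, 1))
#' apply_window(v, window_presets("baseline"))
#' @export
apply_window <- function(volume, spec) {
  if (!inherits(spec, "window_spec")) stop("'spec' must be a window_spec")
  x <- if (inherits(volume, "ct_volume")) volume$intensities else volume
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'volume' must be a 3D array or ct_volume")
  if (anyNA(x) || any(!is.finite(x)))
    stop("CT intensities must be finite")
  out <- (x - (spec$level - spec$width / 2)) / spec$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Stack several windows into a multi-channel network input
#'
#' Each window produces one channel; channels keep the order of \code{specs}.
#' A single full-range baseline window gives the 1-channel input; the three
#' contrast presets give the 3-channel input that feeds the network the same
#' volume under soft-tissue, bone and brain contrast simultaneously
#' (analogous to RGB channels in 2D natural images).
#'
#' @param volume A \code{\link{ct_volume}} or 3D HU array.
#' @param specs A \code{window_spec} or non-empty list of them.
#' @return Object of class \code{"windowed_input"}: a 4D array with
#'   dimensions \code{(nx, ny, nz, n_channels)} and attribute
#'   \code{"specs"}.
#' @examples
#' v <- array(0, dim = c(4, 4, 2))
#' dim(stack_windows(v, multi_window_set()))
#' @export
stack_windows <- function(volume, specs) {
  if (inherits(specs, "window_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L)
    stop("'specs' must be a non-empty list of window_spec objects")
  if (!all(vapply(specs, inherits, logical(1), "window_spec")))
    stop("'specs' must contain only window_spec objects")
  channels <- lapply(specs, function(s) apply_window(volume, s))
  d <- dim(channels[[1L]])
  out <- array(unlist(channels, use.names = FALSE), dim = c(d, length(specs)))
  structure(out, specs = specs, class = c("windowed_input", class(out)))
}

#' @export
print.windowed_input <- function(x, ...) {
  specs <- attr(x, "specs")
  cat(sprintf("Windowed CT input: %s voxels, %d channel(s)\n",
              paste(dim(x)[1:3], collapse = "x"), dim(x)[4L]))
  for (s in specs)
    cat(sprintf("  - %s (L=%g, W=%g)\n", s$name, s$level, s$width))
  invisible(x)
}
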