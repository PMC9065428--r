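# NIfTI I/O, the fixed-size crop with recorded offset, and the structured
# run configuration.

#' Read a CT volume or label map from NIfTI
#'
#' Reads a .nii/.nii.gz file, honouring its voxel spacing (pixdim). The
#' array is used in the file's native axis order, which the package treats
#' as (x = left-right, y = antero-posterior, z = cranio-caudal).
#'
#' @param path NIfTI file path.
#' @return A \code{\link{ct_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing metadata in ", path)
  suppressWarnings(ct_volume(array(as.numeric(img), dim(img)[1:3]),
                             spacing = sp))
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing metadata in ", path)
  label_map(array(as.integer(round(img)), dim(img)[1:3]), spacing = sp)
}

#' Write a CT volume or label map to NIfTI
#'
#' Volumes are stored as 32-bit float, label maps as 16-bit integers;
#' voxel spacing is written to pixdim so a round trip preserves geometry.
#'
#' @param x A \code{\link{ct_volume}} or \code{\link{label_map}}.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    img <- RNifti::asNifti(x$intensities)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (inherits(x, "label_map")) {
    img <- RNifti::asNifti(x$labels)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else stop("x must be a ct_volume or label_map")
  invisible(path)
}

#' Load a paired volume and label map
#'
#' @param vol_path,lab_path NIfTI paths.
#' @return List with \code{ct}, \code{gold}; errors if geometries differ.
#' @export
read_pair <- function(vol_path, lab_path) {
  ct <- read_volume(vol_path)
  lab <- read_labels(lab_path)
  check_same_geometry(dim(ct$intensities), dim(lab$labels),
                      ct$spacing, lab$spacing)
  list(ct = ct, gold = lab)
}

#' Crop (or pad) to a fixed sub-volume
#'
#' Extracts a sub-volume of exactly \code{target} voxels centred on
#' \code{centre} (default: the volume centre), padding with air
#' (-1024 HU) / background where the crop extends beyond the volume. The
#' crop offset is recorded so predictions can be mapped back with
#' \code{\link{uncrop_labels}}. This replaces anatomical-landmark cropping
#' with an explicit, configurable centre.
#'
#' @param volume A \code{\link{ct_volume}}.
#' @param labels Optional \code{\link{label_map}} cropped identically.
#' @param target Target shape in voxels (default 200x200x56).
#' @param centre Voxel coordinate (1-based, length 3) or NULL for the
#'   volume centre.
#' @return List with \code{volume}, \code{labels} (or NULL) and
#'   \code{offset} (0-based offset of the crop origin in the original
#'   volume, possibly negative when padding) plus \code{orig_dim}.
#' @export
crop_subvolume <- function(volume, labels = NULL, target = c(200, 200, 56),
                           centre = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$intensities)
  target <- as.integer(target)
  if (is.null(centre) || identical(centre, "volume-centre"))
    centre <- (d + 1) / 2
  start <- as.integer(ceiling(centre - target / 2))  # 1-based start
  take <- function(arr, fill) {
    out <- array(fill, target)
    src_lo <- pmax(start, 1L); src_hi <- pmin(start + target - 1L, d)
    if (all(src_lo <= src_hi)) {
      dst_lo <- src_lo - start + 1L
      dst_hi <- dst_lo + (src_hi - src_lo)
      out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
        arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    }
    out
  }
  res <- list(volume = ct_volume(take(volume$intensities, -1024),
                                 volume$spacing),
              labels = NULL, offset = start - 1L, orig_dim = d)
  if (!is.null(labels)) {
    check_same_geometry(d, dim(labels$labels))
    res$labels <- label_map(take(labels$labels, 0L), labels$spacing)
  }
  res
}

#' Map a cropped label map back onto the original grid
#'
#' Inverse of \code{\link{crop_subvolume}}: places the cropped prediction
#' at its recorded offset, with background outside the crop.
#'
#' @param labels A \code{\link{label_map}} on the cropped grid.
#' @param offset,orig_dim As returned by \code{\link{crop_subvolume}}.
#' @return A \code{\link{label_map}} on the original grid.
#' @export
uncrop_labels <- function(labels, offset, orig_dim) {
  stopifnot(inherits(labels, "label_map"))
  d <- dim(labels$labels)
  out <- array(0L, orig_dim)
  src_lo <- pmax(1L - offset, 1L)
  src_hi <- pmin(orig_dim - offset, d)
  dst_lo <- offset + src_lo; dst_hi <- offset + src_hi
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    labels$labels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                  src_lo[3]:src_hi[3]]
  label_map(out, labels$spacing)
}

# ---- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    windows = list(mode = "multi",
                   channels = list(
                     list(name = "soft-tissue", level = 40, width = 400),
                     list(name = "bone", level = 400, width = 1800),
                     list(name = "brain", level = 40, width = 80))),
    network = list(in_channels = 3L, num_classes = 6L,
                   decoder_mode = "transpose", deep_supervision = TRUE,
                   width_scale = 1),
    loss = list(kind = "explog", alpha = 0.5, xe_coefficient = 1,
                gamma = 0.3, epsilon = 1e-7),
    augmentation = list(mirror_prob = 0.5, shift_prob = 1,
                        shift_max = c(4, 4, 4), rotate_prob = 0.75,
                        rotate_max_deg = 10, scale_prob = 0.5,
                        scale_range = c(0.9, 1.1)),
    train = list(initial_lr = 1e-2, lr_decay_factor = 10,
                 plateau_patience_epochs = 100L, max_epochs = 1000L,
                 early_stop_patience_epochs = 250L, accumulation_steps = 4L),
    crop = list(target = c(200L, 200L, 56L), centre = "volume-centre")
  )
}

#' Read, validate and normalise a run configuration
#'
#' YAML configuration with sections \code{seed}, \code{windows},
#' \code{network}, \code{loss}, \code{augmentation}, \code{train},
#' \code{crop}; unknown top-level keys are rejected, missing keys take the
#' package defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Named list (class \code{"run_config"}).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Serialise a run configuration to YAML
#'
#' @param cfg A \code{run_config} (or plain list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# window specs from a run config
config_window_specs <- function(cfg) {
  if (identical(cfg$windows$mode, "baseline"))
    return(list(window_presets("baseline")))
  lapply(cfg$windows$channels, function(ch)
    window_spec(ch$level, ch$width, ch$name))
}

# network config from a run config
config_network <- function(cfg) {
  n <- cfg$network
  network_config(in_channels = if (identical(cfg$windows$mode, "baseline")) 1L
                               else as.integer(n$in_channels),
                 num_classes = as.integer(n$num_classes),
                 decoder_mode = n$decoder_mode,
                 deep_supervision = isTRUE(n$deep_supervision),
                 width_scale = n$width_scale)
}
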