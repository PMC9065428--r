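# The 3D residual U-Net with multi-level deep supervision and switchable
# transpose/resize decoder up-sampling.
#
# Reference channel scheme (reconstructed under the constraints imposed by
# the four reference trainable-parameter totals; see the methods vignette):
#   encoder blocks  in->16->32 | 32->32->64 | 64->64->128 | 128->128->256,
#   each with a 1x1x1 residual projection and 2x2x2 max pooling between
#   levels; channel-preserving decoder up-sampling (256, 128, 64); decoder
#   blocks 384->128->128 | 192->66->64 | 96->32->32; 3x3x3 main classifier;
#   1x1x1 auxiliary deep-supervision heads on the two upper decoder stages;
#   one learnable deep-supervision balance scalar. Block convolutions are
#   bias-free and followed by affine instance normalisation (batch size is
#   one, so batch statistics would be degenerate); projections, up-sampling
#   convolutions and classifier heads are bare linear maps.

#' Network architecture configuration
#'
#' Describes the segmentation network completely; the exact trainable
#' parameter count is derivable from a config without building the network.
#'
#' @param in_channels 1 (single full-range window) or 3 (multi-window input).
#' @param num_classes Classes including background (default 6 = background
#'   + 5 organs-at-risk).
#' @param decoder_mode \code{"transpose"} (2x2x2 stride-2 transpose
#'   convolutions) or \code{"resize"} (tri-linear up-sampling followed by a
#'   zero-padded 3x3x3 convolution).
#' @param deep_supervision Add auxiliary 1x1x1 classifier heads at the two
#'   upper decoder stages (training-time only).
#' @param width_scale Multiplies every feature-channel count (reduced
#'   networks for desk-scale experiments); 1 gives the reference scheme.
#' @return Object of class \code{"network_config"} with the per-layer
#'   channel scheme in \code{$scheme}.
#' @examples
#' cfg <- network_config(in_channels = 3, decoder_mode = "transpose")
#' cfg$scheme$enc_out
#' @export
network_config <- function(in_channels = 3L, num_classes = 6L,
                           decoder_mode = c("transpose", "resize"),
                           deep_supervision = TRUE, width_scale = 1) {
  decoder_mode <- match.arg(decoder_mode)
  if (!in_channels %in% c(1L, 3L))
    stop("in_channels must be 1 (baseline window) or 3 (multi-window)")
  if (num_classes < 2L) stop("need at least 2 classes")
  sw <- function(w) pmax(2L, as.integer(round(w * width_scale)))
  scheme <- list(
    stem     = sw(16L),
    enc_mid  = sw(c(16L, 32L, 64L, 128L)),
    enc_out  = sw(c(32L, 64L, 128L, 256L)),
    dec_out  = sw(c(128L, 64L, 32L)),
    dec_mid  = if (width_scale == 1) c(128L, 66L, 32L)
               else sw(c(128L, 64L, 32L)),
    head_kernel = 3L
  )
  scheme$enc_mid[1] <- scheme$stem
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 levels = 4L,
                 decoder_mode = decoder_mode,
                 deep_supervision = isTRUE(deep_supervision),
                 width_scale = width_scale,
                 norm_kind = "instance",
                 scheme = scheme),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  s <- x$scheme
  cat(sprintf(
    "3D Res-UNet config: %d input channel(s), %d classes, %s decoder,%s deep supervision\n",
    x$in_channels, x$num_classes, x$decoder_mode,
    if (x$deep_supervision) "" else " no"))
  cat(sprintf("  encoder: %s\n", paste(sprintf("%d->%d->%d",
      c(x$in_channels, s$enc_out[-4]), s$enc_mid, s$enc_out), collapse = " | ")))
  cat(sprintf("  decoder blocks: %s\n",
      paste(sprintf("->%d->%d", s$dec_mid, s$dec_out), collapse = " | ")))
  invisible(x)
}

he_init <- function(fan_in, nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build the segmentation network
#'
#' Constructs the 3D residual U-Net from its configuration, initialising
#' all weights (He initialisation for convolutions, unit gain / zero shift
#' for instance norms). Construction is deterministic given the seed.
#'
#' @param config A \code{\link{network_config}}.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class \code{"resunet3d"} holding \code{config} and the
#'   trainable parameter collection \code{params}.
#' @examples
#' net <- resunet3d(network_config(in_channels = 1), seed = 1)
#' count_trainable_parameters(net)
#' @export
resunet3d <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  s <- config$scheme
  enc_in <- c(config$in_channels, s$enc_out[-4])
  enc <- vector("list", 4L)
  for (l in 1:4) {
    I <- enc_in[l]; M <- s$enc_mid[l]; O <- s$enc_out[l]
    enc[[l]] <- list(
      w1 = he_init(27 * I, 27 * I, M), g1 = rep(1, M), b1 = rep(0, M),
      w2 = he_init(27 * M, 27 * M, O), g2 = rep(1, O), b2 = rep(0, O),
      proj = he_init(I, I, O))
  }
  up_ch <- c(s$enc_out[4], s$dec_out[1], s$dec_out[2])
  up <- vector("list", 3L)
  for (j in 1:3) {
    C <- up_ch[j]
    up[[j]] <- if (config$decoder_mode == "transpose")
      list(w = array(stats::rnorm(C * C * 8, 0, sqrt(2 / (8 * C))), c(C, C, 8)))
    else
      list(w = he_init(27 * C, 27 * C, C))
  }
  skips <- s$enc_out[3:1]
  dec <- vector("list", 3L)
  for (j in 1:3) {
    cin <- up_ch[j] + skips[j]; M <- s$dec_mid[j]; O <- s$dec_out[j]
    dec[[j]] <- list(
      w1 = he_init(27 * cin, 27 * cin, M), g1 = rep(1, M), b1 = rep(0, M),
      w2 = he_init(27 * M, 27 * M, O), g2 = rep(1, O), b2 = rep(0, O),
      proj = he_init(cin, cin, O))
  }
  head_w <- he_init(27 * s$dec_out[3], 27 * s$dec_out[3], config$num_classes)
  params <- list(enc = enc, up = up, dec = dec, head = head_w)
  if (config$deep_supervision) {
    params$aux1 <- he_init(s$dec_out[1], s$dec_out[1], config$num_classes)
    params$aux2 <- he_init(s$dec_out[2], s$dec_out[2], config$num_classes)
    params$ds_lambda <- 0
  }
  structure(list(config = config, params = params, mode = "inference"),
            class = "resunet3d")
}

#' Count trainable parameters
#'
#' Exact count of scalar trainable weights in a built network: convolution
#' kernels, instance-norm gains and shifts, residual projections, classifier
#' heads and the deep-supervision balance scalar.
#'
#' @param network A \code{\link{resunet3d}}.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(network) {
  stopifnot(inherits(network, "resunet3d"))
  n <- 0
  walk <- function(x) {
    if (is.list(x)) for (e in x) walk(e) else n <<- n + length(x)
  }
  walk(network$params)
  as.integer(n)
}

#' @export
print.resunet3d <- function(x, ...) {
  print(x$config)
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

block_forward <- function(p, x, dims) {
  a1 <- conv3_f(x, dims, p$w1)
  n1 <- inorm_f(a1, p$g1, p$b1)
  r1 <- n1$y * (n1$y > 0)
  a2 <- conv3_f(r1, dims, p$w2)
  n2 <- inorm_f(a2, p$g2, p$b2)
  sft <- x %*% p$proj
  s <- n2$y + sft
  y <- s * (s > 0)
  list(y = y, cache = list(x = x, dims = dims, n1 = n1, r1 = r1, n2 = n2,
                           m1 = n1$y > 0, my = s > 0))
}

block_backward <- function(p, cache, gy) {
  gs <- gy * cache$my
  gproj <- crossprod(cache$x, gs)
  gx <- gs %*% t(p$proj)
  ib2 <- inorm_b(cache$n2, p$g2, gs)
  cb2 <- conv3_b(cache$r1, cache$dims, p$w2, ib2$gx)
  gr1 <- cb2$gx * cache$m1
  ib1 <- inorm_b(cache$n1, p$g1, gr1)
  cb1 <- conv3_b(cache$x, cache$dims, p$w1, ib1$gx)
  gx <- gx + cb1$gx
  list(gx = gx,
       grads = list(w1 = cb1$gw, g1 = ib1$gg, b1 = ib1$gb,
                    w2 = cb2$gw, g2 = ib2$gg, b2 = ib2$gb, proj = gproj))
}

# pad a channel matrix's spatial grid so each dim is divisible by 2^(levels-1)
pad_to_multiple <- function(x, dims, mult = 8L) {
  tgt <- as.integer(ceiling(dims / mult) * mult)
  if (all(tgt == dims)) return(list(x = x, dims = dims, pad = NULL))
  lo <- (tgt - dims) %/% 2L
  arr <- array(0, c(tgt, ncol(x)))
  arr[lo[1] + 1:dims[1], lo[2] + 1:dims[2], lo[3] + 1:dims[3], ] <-
    array(x, c(dims, ncol(x)))
  list(x = matrix(arr, prod(tgt), ncol(x)), dims = tgt,
       pad = list(lo = lo, orig = dims))
}

unpad_matrix <- function(x, dims, pad) {
  if (is.null(pad)) return(x)
  arr <- array(x, c(dims, ncol(x)))
  sub <- arr[pad$lo[1] + 1:pad$orig[1], pad$lo[2] + 1:pad$orig[2],
             pad$lo[3] + 1:pad$orig[3], , drop = FALSE]
  matrix(sub, prod(pad$orig), ncol(x))
}

# core forward; input x: nvox x C matrix, dims divisible by 8
resunet_forward_core <- function(net, x, dims, training = FALSE) {
  p <- net$params; cfg <- net$config
  caches <- list(); skips <- list(); sdims <- list()
  cur <- x; cdims <- dims
  for (l in 1:4) {
    bl <- block_forward(p$enc[[l]], cur, cdims)
    if (training) caches[[paste0("enc", l)]] <- bl$cache
    if (l < 4) {
      skips[[l]] <- bl$y; sdims[[l]] <- cdims
      mp <- maxpool_f(bl$y, cdims)
      if (training) caches[[paste0("pool", l)]] <- mp
      cur <- mp$y; cdims <- cdims %/% 2L
    } else cur <- bl$y
  }
  dec_out <- list(); dec_dims <- list()
  for (j in 1:3) {
    if (cfg$decoder_mode == "transpose") {
      upy <- tconv_f(cur, cdims, p$up[[j]]$w)
      if (training) caches[[paste0("upin", j)]] <- list(x = cur, dims = cdims)
    } else {
      ux <- upsample2_f(cur, cdims)
      upy <- conv3_f(ux, 2L * cdims, p$up[[j]]$w)
      if (training) caches[[paste0("upin", j)]] <-
        list(x = cur, dims = cdims, ux = ux)
    }
    cdims <- 2L * cdims
    skip <- skips[[4 - j]]
    cat_in <- cbind(upy, skip)
    bl <- block_forward(p$dec[[j]], cat_in, cdims)
    if (training) {
      caches[[paste0("dec", j)]] <- bl$cache
      caches[[paste0("nup", j)]] <- ncol(upy)
    }
    cur <- bl$y
    dec_out[[j]] <- cur; dec_dims[[j]] <- cdims
  }
  logits <- conv3_f(cur, cdims, p$head)
  out <- list(logits = logits, dims = cdims)
  if (training && cfg$deep_supervision) {
    a1 <- dec_out[[1]] %*% p$aux1          # 1/4 resolution
    a2 <- dec_out[[2]] %*% p$aux2          # 1/2 resolution
    a1u <- upsample2_f(upsample2_f(a1, dec_dims[[1]]), 2L * dec_dims[[1]])
    a2u <- upsample2_f(a2, dec_dims[[2]])
    out$aux_logits <- list(a1u, a2u)
    caches$aux_in <- list(dec_out[[1]], dec_out[[2]])
    caches$aux_dims <- list(dec_dims[[1]], dec_dims[[2]])
  }
  if (training) {
    caches$head_in <- cur; caches$head_dims <- cdims
    out$caches <- caches
  }
  out
}

# core backward; g_main / g_aux are gradients w.r.t. logits
resunet_backward_core <- function(net, fw, g_main, g_aux = NULL) {
  p <- net$params; cfg <- net$config; ch <- fw$caches
  grads <- list(enc = vector("list", 4), up = vector("list", 3),
                dec = vector("list", 3))
  hb <- conv3_b(ch$head_in, ch$head_dims, p$head, g_main)
  grads$head <- hb$gw
  gcur <- hb$gx
  if (cfg$deep_supervision && !is.null(g_aux)) {
    d1 <- ch$aux_dims[[1]]; d2 <- ch$aux_dims[[2]]
    ga1 <- upsample2_b(upsample2_b(g_aux[[1]], 2L * d1), d1)
    ga2 <- upsample2_b(g_aux[[2]], d2)
    grads$aux1 <- crossprod(ch$aux_in[[1]], ga1)
    grads$aux2 <- crossprod(ch$aux_in[[2]], ga2)
    aux_gx <- list(ga1 %*% t(p$aux1), ga2 %*% t(p$aux2))
  } else aux_gx <- list(NULL, NULL)
  gskips <- vector("list", 3L)  # indexed by encoder level
  for (j in 3:1) {
    if (j < 3 && !is.null(aux_gx[[j]])) gcur <- gcur + aux_gx[[j]]
    bb <- block_backward(p$dec[[j]], ch[[paste0("dec", j)]], gcur)
    grads$dec[[j]] <- bb$grads
    nup <- ch[[paste0("nup", j)]]
    gup <- bb$gx[, seq_len(nup), drop = FALSE]
    gskips[[4 - j]] <- bb$gx[, -seq_len(nup), drop = FALSE]
    ui <- ch[[paste0("upin", j)]]
    if (cfg$decoder_mode == "transpose") {
      tb <- tconv_b(ui$x, ui$dims, p$up[[j]]$w, gup)
      grads$up[[j]] <- list(w = tb$gw)
      gcur <- tb$gx
    } else {
      cb <- conv3_b(ui$ux, 2L * ui$dims, p$up[[j]]$w, gup)
      grads$up[[j]] <- list(w = cb$gw)
      gcur <- upsample2_b(cb$gx, ui$dims)
    }
  }
  # walk encoder backwards: level 4 gets gcur; levels 3..1 get pooled grad +
  # their skip gradient
  for (l in 4:1) {
    if (l == 4) g_in <- gcur
    else {
      g_in <- maxpool_b(ch[[paste0("pool", l)]], g_after_pool) + gskips[[l]]
    }
    bb <- block_backward(p$enc[[l]], ch[[paste0("enc", l)]], g_in)
    grads$enc[[l]] <- bb$grads
    g_after_pool <- bb$gx
  }
  grads
}

# ---- user-facing forward / prediction --------------------------------------

as_channel_matrix <- function(input, in_channels) {
  if (inherits(input, "windowed_input") || (is.array(input) && length(dim(input)) == 4L)) {
    d <- dim(input)
    if (d[4] != in_channels)
      stop("input has ", d[4], " channel(s) but the network expects ",
           in_channels)
    list(x = matrix(input, prod(d[1:3]), d[4]), dims = d[1:3])
  } else stop("input must be a 4D (nx,ny,nz,channels) array; see stack_windows()")
}

#' Run the network forward
#'
#' Maps a windowed multi-channel input to per-voxel class probabilities
#' (softmax). Spatial dimensions that are not divisible by
#' 2^(levels-1) = 8 are zero-padded symmetrically and the output is cropped
#' back. In training mode with deep supervision, auxiliary probability maps
#' (resampled to full resolution) are attached.
#'
#' @param network A \code{\link{resunet3d}}.
#' @param input A \code{\link{stack_windows}} result or 4D array with
#'   channel count matching the config.
#' @param training Logical; keep auxiliary outputs and caches.
#' @return Object of class \code{"probability_map"}: 4D array
#'   \code{(nx, ny, nz, num_classes)} summing to 1 over classes. In training
#'   mode a list with \code{probs}, \code{aux_probs} and internals.
#' @export
forward_pass <- function(network, input, training = FALSE) {
  stopifnot(inherits(network, "resunet3d"))
  cm <- as_channel_matrix(input, network$config$in_channels)
  pd <- pad_to_multiple(cm$x, cm$dims, 8L)
  fw <- resunet_forward_core(network, pd$x, pd$dims, training = training)
  if (!training) {
    pr <- softmax_rows(unpad_matrix(fw$logits, pd$dims, pd$pad))
    return(structure(array(pr, c(cm$dims, network$config$num_classes)),
                     class = "probability_map"))
  }
  probs <- softmax_rows(fw$logits)
  aux_probs <- NULL
  if (network$config$deep_supervision)
    aux_probs <- lapply(fw$aux_logits, softmax_rows)
  list(probs = probs, aux_probs = aux_probs, fw = fw, pad = pd$pad,
       dims = pd$dims, orig_dims = cm$dims)
}

#' Hard label map from a probability map
#'
#' Voxel-wise argmax with ties broken toward the lowest class index
#' (background first). Invariant to positive per-voxel rescaling.
#'
#' @param probs A \code{"probability_map"} (4D array, classes last).
#' @param spacing Voxel spacing for the returned \code{\link{label_map}}.
#' @return A \code{\link{label_map}} with codes \code{0..C-1}.
#' @export
predict_labels <- function(probs, spacing = c(1, 1, 2.5)) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  label_map(array(lab, d[1:3]), spacing)
}

#' Segment a CT volume with a network
#'
#' Convenience inference path: window the volume (multi-window for
#' 3-channel configs, baseline for 1-channel), run the network, and return
#' the argmax label map.
#'
#' @param object A \code{\link{resunet3d}}.
#' @param volume A \code{\link{ct_volume}}.
#' @param specs Optional list of \code{\link{window_spec}}s overriding the
#'   defaults implied by the input channel count.
#' @param ... Unused.
#' @return A \code{\link{label_map}}.
#' @export
predict.resunet3d <- function(object, volume, specs = NULL, ...) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(specs)) {
    specs <- if (object$config$in_channels == 3L) multi_window_set()
             else list(window_presets("baseline"))
  }
  win <- stack_windows(volume, specs)
  probs <- forward_pass(object, win, training = FALSE)
  predict_labels(probs, spacing = volume$spacing)
}
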