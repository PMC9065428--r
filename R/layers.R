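# Internal layer primitives for the 3D segmentation network. Feature maps
# are nvox x C matrices in x-fastest voxel order; every primitive has a
# matching analytic backward pass. 3x3x3 convolutions run in compiled code
# (im2col + BLAS); pooling, up-sampling and normalisation are vectorised R.

.grid_cache <- new.env(parent = emptyenv())

# linear indices (1-based) of the full-grid voxels at (2i+dx, 2j+dy, 2k+dz)
# for each of the 8 offsets, given the half-resolution grid dims
stride2_indices <- function(half_dims, full_dims) {
  key <- paste0("s2_", paste(half_dims, collapse = "x"))
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  g <- coord_grids(half_dims)
  nx <- full_dims[1]; ny <- full_dims[2]
  out <- vector("list", 8L)
  o <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    out[[o]] <- 1 + (2 * g$x + dx) + nx * ((2 * g$y + dy) + ny * (2 * g$z + dz))
    o <- o + 1L
  }
  .grid_cache[[key]] <- out
  out
}

# sparse trilinear x2 up-sampling operator (align-corners-false convention)
upsample2_matrix <- function(in_dims) {
  key <- paste0("up_", paste(in_dims, collapse = "x"))
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  out_dims <- 2L * in_dims
  g <- coord_grids(out_dims)
  nvo <- prod(out_dims)
  fx <- (g$x + 0.5) / 2 - 0.5
  fy <- (g$y + 0.5) / 2 - 0.5
  fz <- (g$z + 0.5) / 2 - 0.5
  x0 <- pmin(pmax(floor(fx), 0), in_dims[1] - 1)
  y0 <- pmin(pmax(floor(fy), 0), in_dims[2] - 1)
  z0 <- pmin(pmax(floor(fz), 0), in_dims[3] - 1)
  tx <- pmin(pmax(fx - x0, 0), 1); ty <- pmin(pmax(fy - y0, 0), 1)
  tz <- pmin(pmax(fz - z0, 0), 1)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- pmin(x0 + dx, in_dims[1] - 1)
    yi <- pmin(y0 + dy, in_dims[2] - 1)
    zi <- pmin(z0 + dz, in_dims[3] - 1)
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
         (if (dz) tz else 1 - tz)
    keep <- w > 0
    ii <- c(ii, which(keep))
    jj <- c(jj, 1 + xi[keep] + in_dims[1] * (yi[keep] + in_dims[2] * zi[keep]))
    vv <- c(vv, w[keep])
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nvo, prod(in_dims)))
  .grid_cache[[key]] <- S
  S
}

conv3_f <- function(x, dims, W) {
  .conv3_forward(x, as.integer(dims), W, numeric(ncol(W)))
}

conv3_b <- function(x, dims, W, gy) {
  .conv3_backward(x, as.integer(dims), W, gy)
}

# instance normalisation (affine), statistics over all voxels per channel
inorm_f <- function(x, g, b, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

inorm_b <- function(cache, g, gy) {
  n <- nrow(gy)
  gxhat <- sweep(gy, 2, g, "*")
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- sweep(sweep(gxhat, 2, m1, "-") - sweep(cache$xhat, 2, m2, "*"),
              2, cache$inv_sd, "*")
  list(gx = gx, gg = colSums(gy * cache$xhat), gb = colSums(gy))
}

# 2x2x2 max pooling; returns pooled map and the argmax row indices
maxpool_f <- function(x, dims) {
  half <- dims %/% 2L
  idx <- stride2_indices(half, dims)
  C <- ncol(x)
  best <- x[idx[[1]], , drop = FALSE]
  arg <- matrix(idx[[1]], nrow(best), C)
  for (o in 2:8) {
    cand <- x[idx[[o]], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- matrix(idx[[o]], nrow(best), C)[upd]
  }
  list(y = best, arg = arg, nvox_in = nrow(x))
}

maxpool_b <- function(cache, gy) {
  C <- ncol(gy)
  gx <- matrix(0, cache$nvox_in, C)
  li <- as.vector(cache$arg) +
    rep((seq_len(C) - 1) * cache$nvox_in, each = nrow(gy))
  gx[li] <- as.vector(gy)
  gx
}

# 2x2x2 stride-2 transpose convolution, bias-free; W is [Cin, Cout, 8]
tconv_f <- function(x, dims, W) {
  out_dims <- 2L * dims
  idx <- stride2_indices(dims, out_dims)
  y <- matrix(0, prod(out_dims), dim(W)[2])
  for (o in 1:8) y[idx[[o]], ] <- x %*% W[, , o]
  y
}

tconv_b <- function(x, dims, W, gy) {
  out_dims <- 2L * dims
  idx <- stride2_indices(dims, out_dims)
  gx <- matrix(0, nrow(x), dim(W)[1])
  gW <- array(0, dim(W))
  for (o in 1:8) {
    gyo <- gy[idx[[o]], , drop = FALSE]
    gx <- gx + gyo %*% t(W[, , o])
    gW[, , o] <- crossprod(x, gyo)
  }
  list(gx = gx, gw = gW)
}

upsample2_f <- function(x, dims) {
  S <- upsample2_matrix(as.integer(dims))
  as.matrix(S %*% x)
}

upsample2_b <- function(gy, dims) {
  S <- upsample2_matrix(as.integer(dims))
  as.matrix(Matrix::crossprod(S, gy))
}

softmax_rows <- function(z) {
  m <- z - apply(z, 1, max)
  e <- exp(m)
  e / rowSums(e)
}
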