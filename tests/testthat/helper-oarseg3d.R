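# Shared fixtures: tiny deterministic phantoms and independent oracles.

tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(seed = 42L))
    cache
  }
})

# independent brute-force surface-distance oracle: boundary voxels by
# explicit 6-neighbour loops, distances by all-pairs nearest foreground
brute_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!mask[x, y, z]) next
    nb <- c(
      if (x > 1) mask[x - 1, y, z] else FALSE,
      if (x < d[1]) mask[x + 1, y, z] else FALSE,
      if (y > 1) mask[x, y - 1, z] else FALSE,
      if (y < d[2]) mask[x, y + 1, z] else FALSE,
      if (z > 1) mask[x, y, z - 1] else FALSE,
      if (z < d[3]) mask[x, y, z + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(x, y, z))
  }
  out
}

brute_surface_distances <- function(pred, gold, spacing) {
  fg <- function(m) which(m, arr.ind = TRUE)
  mind <- function(pts, ref) {
    vapply(seq_len(nrow(pts)), function(i) {
      dd <- sweep(ref, 2, pts[i, ], "-")
      dd <- sweep(dd, 2, spacing, "*")
      sqrt(min(rowSums(dd * dd)))
    }, numeric(1))
  }
  d1 <- mind(brute_boundary(pred), fg(gold))
  d2 <- mind(brute_boundary(gold), fg(pred))
  c(d1, d2)
}

# independent scalar-loop loss oracles (direct transcription of the
# definitions; no vectorised shortcuts shared with the implementation)
oracle_soft_dice <- function(p, y, w) {
  C <- ncol(p); total <- 0
  for (l in 1:C) {
    num <- 0; dy <- 0; dp <- 0
    for (v in 1:nrow(p)) {
      num <- num + y[v, l] * p[v, l]
      dy <- dy + y[v, l]; dp <- dp + p[v, l]
    }
    total <- total + w[l] * (1 - (2 * num + 1) / (dy + dp + 1))
  }
  total
}

oracle_xe <- function(p, y, w, eps = 1e-7) {
  acc <- 0
  for (v in 1:nrow(p)) {
    l <- which(y[v, ] == 1)
    acc <- acc + w[l] * (-log(max(p[v, l], eps)))
  }
  acc / nrow(p)
}

oracle_explog <- function(p, y, w, gamma = 0.3, eps = 1e-7) {
  C <- ncol(p); t1 <- 0
  for (l in 1:C) {
    num <- 0; dy <- 0; dp <- 0
    for (v in 1:nrow(p)) {
      num <- num + y[v, l] * p[v, l]
      dy <- dy + y[v, l]; dp <- dp + p[v, l]
    }
    dice <- min(max((2 * num + 1) / (dy + dp + 1), eps), 1)
    t1 <- t1 + (-log(dice))^gamma
  }
  t1 <- t1 / C
  t2 <- 0
  for (v in 1:nrow(p)) {
    l <- which(y[v, ] == 1)
    t2 <- t2 + w[l] * (-log(max(p[v, l], eps)))^gamma
  }
  t1 + t2 / nrow(p)
}

random_simplex <- function(nvox, C) {
  m <- matrix(stats::runif(nvox * C, 0.01, 1), nvox, C)
  m / rowSums(m)
}

onehot_of <- function(lab, C) {
  m <- matrix(0, length(lab), C)
  m[cbind(seq_along(lab), lab + 1L)] <- 1
  m
}
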