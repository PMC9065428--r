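test_that("inverse-frequency weights reproduce exact hand-derived cases", {
  # frequencies 1/9 and 8/9 at alpha = 1/3: ratio 9^(1/3):(9/8)^(1/3) = 2:1
  lab <- array(c(rep(1L, 8), 0L), c(9, 1, 1))
  w <- inverse_frequency_weights(lab, alpha = 1/3, num_classes = 2)
  expect_equal(as.numeric(w), c(2/3, 1/3), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # equal frequencies give uniform weights for any alpha
  lab2 <- array(rep(0:2, each = 4), c(12, 1, 1))
  for (a in c(0, 1/3, 0.5, 1))
    expect_equal(as.numeric(inverse_frequency_weights(lab2, a, 3)),
                 rep(1/3, 3), tolerance = 1e-12)
  # alpha = 0 is uniform regardless of frequency
  expect_equal(as.numeric(inverse_frequency_weights(lab, 0, 2)),
               c(0.5, 0.5), tolerance = 1e-12)
  # an absent class is an error naming it
  expect_error(inverse_frequency_weights(lab, 1/3, num_classes = 3), "2")
})

test_that("all three losses vanish at a perfect binary prediction", {
  set.seed(2)
  lab <- sample(0:2, 60, replace = TRUE)
  y <- onehot_of(lab, 3)
  w <- rep(1/3, 3)
  expect_equal(weighted_soft_dice_loss(y, y, w)$total, 0)
  expect_equal(weighted_cross_entropy(y, y, w)$total, 0)
  expect_equal(wsd_plus_xe_loss(y, y, w)$total, 0)
  expect_equal(exp_log_loss(y, y, w)$total, 0)
})

test_that("soft Dice disjoint-mask closed form and empty-class behaviour", {
  for (n in 1:10) {
    # two disjoint single-class foregrounds of n voxels in a 2-class problem
    lab <- c(rep(1L, n), rep(0L, n))
    y <- onehot_of(lab, 2)
    p <- onehot_of(c(rep(0L, n), rep(1L, n)), 2)
    w <- c(0.4, 0.6)
    l <- weighted_soft_dice_loss(p, y, w)
    expect_equal(l$per_class[2], 0.6 * (1 - 1 / (2 * n + 1)), tolerance = 1e-12)
  }
  # class empty in both pred and target contributes exactly zero
  y <- onehot_of(c(0L, 0L), 3); p <- y
  expect_equal(weighted_soft_dice_loss(p, y, c(1/3, 1/3, 1/3))$per_class[2], 0)
})

test_that("cross-entropy closed forms and monotonicity", {
  C <- 6
  lab <- rep(0:5, each = 2)
  y <- onehot_of(lab, C)
  p <- matrix(1 / C, length(lab), C)
  w <- rep(1 / C, C)
  expect_equal(weighted_cross_entropy(p, y, w)$total, log(C) / C,
               tolerance = 1e-12)
  # decreasing the true-class probability strictly increases the loss
  p2 <- p; p2[1, 1] <- 0.05; p2[1, -1] <- 0.95 / 5
  expect_gt(weighted_cross_entropy(p2, y, w)$total,
            weighted_cross_entropy(p, y, w)$total)
})

test_that("combined loss components are bookkept and degenerate correctly", {
  set.seed(3)
  lab <- sample(0:2, 40, replace = TRUE)
  y <- onehot_of(lab, 3)
  p <- random_simplex(40, 3)
  w <- as.numeric(inverse_frequency_weights(array(lab, c(40, 1, 1)), 1/3, 3))
  l <- wsd_plus_xe_loss(p, y, w)
  expect_equal(l$components$dice + l$components$xe, l$total, tolerance = 1e-9)
  l0 <- wsd_plus_xe_loss(p, y, w, xe_coefficient = 0)
  expect_equal(l0$total, weighted_soft_dice_loss(p, y, w)$total,
               tolerance = 1e-12)
})

test_that("exponential-logarithmic loss matches its defining cases", {
  # a class with Dice = e^-1 contributes exactly 1 before class-averaging:
  # build a 1-class toy with smoothed dice e^-1 via direct construction
  d <- exp(-1)
  expect_equal((-log(d))^0.3, 1)
  # numeric monotonicity: moving probability mass to the true class lowers it
  y <- onehot_of(c(1L, 0L, 1L), 2)
  w <- c(0.5, 0.5)
  steps <- seq(0.2, 0.9, by = 0.1)
  vals <- vapply(steps, function(q) {
    p <- matrix(c(1 - q, q), 3, 2, byrow = TRUE)
    p[2, ] <- c(0.8, 0.2)
    exp_log_loss(p, y, w)$total
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("losses agree with independent scalar-loop oracles", {
  set.seed(4)
  for (rep in 1:5) {
    dims <- c(sample(2:5, 1), sample(2:5, 1), sample(2:4, 1))
    C <- sample(2:3, 1)
    nv <- prod(dims)
    lab <- sample(0:(C - 1), nv, replace = TRUE)
    y <- onehot_of(lab, C)
    p <- random_simplex(nv, C)
    w <- as.numeric(inverse_frequency_weights(array(lab, dims), 1/3, C))
    expect_equal(weighted_soft_dice_loss(p, y, w)$total,
                 oracle_soft_dice(p, y, w), tolerance = 1e-9)
    expect_equal(weighted_cross_entropy(p, y, w)$total,
                 oracle_xe(p, y, w), tolerance = 1e-9)
    expect_equal(exp_log_loss(p, y, w)$total,
                 oracle_explog(p, y, w), tolerance = 1e-9)
  }
})

test_that("losses are invariant under consistent class relabelling", {
  set.seed(5)
  lab <- sample(0:2, 30, replace = TRUE)
  y <- onehot_of(lab, 3)
  p <- random_simplex(30, 3)
  w <- c(0.2, 0.3, 0.5)
  perm <- c(3, 1, 2)
  for (f in list(weighted_soft_dice_loss, weighted_cross_entropy,
                 function(a, b, c) exp_log_loss(a, b, c))) {
    expect_equal(f(p[, perm], y[, perm], w[perm])$total, f(p, y, w)$total,
                 tolerance = 1e-12)
  }
})

test_that("analytic logit gradients match finite differences", {
  set.seed(6)
  lab <- c(0L, 1L, 2L)
  y <- onehot_of(lab, 3)
  z <- matrix(rnorm(9), 3, 3)
  w <- c(0.5, 0.3, 0.2)
  sm <- function(z) { e <- exp(z - apply(z, 1, max)); e / rowSums(e) }
  for (kind in c("wsd", "xe", "wsd_xe", "explog")) {
    g <- oarseg3d:::loss_grad_logits(kind, sm(z), y, w)
    for (probe in list(c(1, 1), c(2, 3), c(3, 2))) {
      h <- 1e-6
      zp <- z; zp[probe[1], probe[2]] <- zp[probe[1], probe[2]] + h
      zm <- z; zm[probe[1], probe[2]] <- zm[probe[1], probe[2]] - h
      fd <- (oarseg3d:::compute_loss(kind, sm(zp), y, w)$total -
             oarseg3d:::compute_loss(kind, sm(zm), y, w)$total) / (2 * h)
      expect_equal(g[probe[1], probe[2]], fd, tolerance = 1e-4)
    }
  }
})

test_that("deep-supervision aggregation honours its weight contract", {
  main <- weighted_soft_dice_loss(onehot_of(0L, 2), onehot_of(0L, 2), c(1, 0))
  expect_equal(deep_supervision_aggregate(main, list())$total, main$total)
  l <- 0.7
  agg <- deep_supervision_aggregate(l, list(l, l))
  expect_equal(agg$total, l, tolerance = 1e-12)
  agg0 <- deep_supervision_aggregate(0.4, list(9, 9), c(1, 0, 0))
  expect_equal(agg0$total, 0.4, tolerance = 1e-12)
  expect_error(deep_supervision_aggregate(0.4, list(1), c(1, 1, 1)), "weight")
})
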