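# Training objectives: weighted soft Dice, weighted cross-entropy, their
# linear combination, and the exponential-logarithmic loss, all over softmax
# probability maps with inverse-frequency class weights.

#' Inverse-frequency class weights
#'
#' Computes per-class weights \code{w_l = f_l^(-alpha) / sum_k f_k^(-alpha)}
#' where \code{f_l} is the voxel frequency of label \code{l} over a
#' collection of label maps. Background counts as class 0. The weights sum
#' to 1 by construction. \code{alpha = 1/3} is the default used with the
#' weighted soft-Dice loss; \code{alpha = 0.5} is used inside the
#' exponential-logarithmic loss.
#'
#' @param targets A \code{\link{label_map}}, integer array, or list of them.
#' @param alpha Non-negative exponent of the inverse frequency.
#' @param num_classes Number of classes including background.
#' @return Object of class \code{"class_weights"}: numeric vector of length
#'   \code{num_classes} summing to 1, with attribute \code{alpha}.
#' @examples
#' lab <- array(c(rep(0L, 8), 1L), c(3, 3, 1))
#' inverse_frequency_weights(lab, alpha = 1/3, num_classes = 2)  # (1/3, 2/3)
#' @export
inverse_frequency_weights <- function(targets, alpha = 1/3, num_classes = 6L) {
  if (!is.list(targets) || inherits(targets, "label_map")) targets <- list(targets)
  stopifnot(alpha >= 0, num_classes >= 2)
  counts <- numeric(num_classes)
  for (t in targets) {
    lab <- if (inherits(t, "label_map")) t$labels else t
    tb <- tabulate(as.integer(lab) + 1L, nbins = num_classes)
    counts <- counts + tb
  }
  if (any(counts == 0)) {
    missing_cls <- which(counts == 0) - 1L
    stop("class(es) ", paste(missing_cls, collapse = ", "),
         " absent from the targets; inverse-frequency weight undefined")
  }
  f <- counts / sum(counts)
  w <- f^(-alpha)
  w <- w / sum(w)
  structure(w, alpha = alpha, class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("Inverse-frequency class weights (alpha = %g):\n", attr(x, "alpha")))
  print(round(unclass(x), 5))
  invisible(x)
}

# internal: coerce prediction to nvox x C probability matrix
as_prob_matrix <- function(pred) {
  if (is.matrix(pred)) return(pred)
  d <- dim(pred)
  if (length(d) == 4L) return(matrix(pred, nrow = prod(d[1:3]), ncol = d[4]))
  stop("prediction must be a (nx,ny,nz,C) array or nvox x C matrix")
}

# internal: one-hot encode an integer label array -> nvox x C matrix
onehot_matrix <- function(labels, num_classes) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  v <- as.integer(lab)
  if (any(v < 0 | v >= num_classes)) stop("label codes outside [0, C-1]")
  m <- matrix(0, length(v), num_classes)
  m[cbind(seq_along(v), v + 1L)] <- 1
  m
}

check_loss_inputs <- function(p, y, weights) {
  if (!identical(dim(p), dim(y)))
    stop("geometry mismatch between prediction and target")
  if (length(weights) != ncol(p))
    stop("weights must cover all ", ncol(p), " classes")
}

# internal: per-class smoothed soft Dice (the +1 smoothing of the printed
# loss, reused repo-wide, including inside the exponential-logarithmic loss)
smoothed_soft_dice <- function(p, y) {
  num <- 2 * colSums(y * p) + 1
  den <- colSums(y) + colSums(p) + 1
  list(dice = num / den, num = num, den = den)
}

loss_value <- function(total, per_class = NULL, components = NULL) {
  structure(list(total = total, per_class = per_class,
                 components = components), class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("Loss: %.6g\n", x$total))
  if (!is.null(x$components))
    cat("  components:", paste(sprintf("%s=%.6g", names(x$components),
                                       unlist(x$components)), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted soft-Dice loss
#'
#' \code{L = sum_l w_l (1 - (2 sum_V y p + 1) / (sum_V y + sum_V p + 1))},
#' with the +1 smoothing in numerator and denominator. Zero at a perfect
#' binary prediction; a class empty in both prediction and target
#' contributes zero (the smoothing terms give Dice 1).
#'
#' @param pred Probability map: \code{(nx,ny,nz,C)} array or nvox x C matrix.
#' @param target Integer label array/\code{label_map} or one-hot matrix.
#' @param weights \code{\link{inverse_frequency_weights}} (or any
#'   non-negative per-class weights).
#' @return A \code{loss_value} with per-class terms.
#' @export
weighted_soft_dice_loss <- function(pred, target, weights) {
  p <- as_prob_matrix(pred)
  y <- if (is.matrix(target)) target else onehot_matrix(target, ncol(p))
  check_loss_inputs(p, y, weights)
  d <- smoothed_soft_dice(p, y)
  terms <- as.numeric(weights) * (1 - d$dice)
  loss_value(sum(terms), per_class = terms)
}

#' Weighted cross-entropy loss
#'
#' Mean over voxels of \code{w_l(x) * (-ln p_l(x))} where \code{l(x)} is the
#' true class of voxel x. Probabilities are clamped to \code{[epsilon, 1]}
#' before the logarithm.
#'
#' @inheritParams weighted_soft_dice_loss
#' @param epsilon Probability clamp before the logarithm.
#' @return A \code{loss_value}.
#' @export
weighted_cross_entropy <- function(pred, target, weights, epsilon = 1e-7) {
  p <- as_prob_matrix(pred)
  y <- if (is.matrix(target)) target else onehot_matrix(target, ncol(p))
  check_loss_inputs(p, y, weights)
  ptrue <- rowSums(p * y)
  wtrue <- as.numeric(y %*% as.numeric(weights))
  loss_value(mean(wtrue * (-log(pmax(ptrue, epsilon)))))
}

#' Combined weighted soft-Dice + cross-entropy loss
#'
#' Linear combination \code{dice_coefficient * wSD + xe_coefficient * wXE}
#' (defaults 1:1). Components are reported separately and sum to the total.
#'
#' @inheritParams weighted_cross_entropy
#' @param xe_coefficient,dice_coefficient Combination coefficients.
#' @return A \code{loss_value} with \code{components$dice},
#'   \code{components$xe}.
#' @export
wsd_plus_xe_loss <- function(pred, target, weights, xe_coefficient = 1,
                             dice_coefficient = 1, epsilon = 1e-7) {
  ld <- weighted_soft_dice_loss(pred, target, weights)
  lx <- weighted_cross_entropy(pred, target, weights, epsilon)
  loss_value(dice_coefficient * ld$total + xe_coefficient * lx$total,
             per_class = dice_coefficient * ld$per_class,
             components = list(dice = dice_coefficient * ld$total,
                               xe = xe_coefficient * lx$total))
}

#' Exponential logarithmic loss
#'
#' \code{L = E_l[(-ln Dice_l)^gamma] + E_x[w_l(x) (-ln p_l(x))^gamma]} with
#' \code{gamma = 0.3}. The first expectation is the unweighted mean over
#' classes of the smoothed soft Dice; the second is the mean over voxels of
#' the weighted negative log-likelihood term. Both Dice and probabilities
#' are clamped to \code{[epsilon, 1]} before the logarithm. Designed for
#' strongly class-imbalanced segmentation; use with
#' \code{\link{inverse_frequency_weights}} at \code{alpha = 0.5}.
#'
#' @inheritParams weighted_cross_entropy
#' @param gamma Exponent applied to both logarithmic terms.
#' @return A \code{loss_value} with \code{components$dice},
#'   \code{components$xe}.
#' @export
exp_log_loss <- function(pred, target, weights, gamma = 0.3, epsilon = 1e-7) {
  p <- as_prob_matrix(pred)
  y <- if (is.matrix(target)) target else onehot_matrix(target, ncol(p))
  check_loss_inputs(p, y, weights)
  d <- smoothed_soft_dice(p, y)
  dice_cl <- pmin(pmax(d$dice, epsilon), 1)
  t1 <- mean((-log(dice_cl))^gamma)
  ptrue <- pmax(rowSums(p * y), epsilon)
  wtrue <- as.numeric(y %*% as.numeric(weights))
  t2 <- mean(wtrue * (-log(ptrue))^gamma)
  loss_value(t1 + t2, per_class = (-log(dice_cl))^gamma,
             components = list(dice = t1, xe = t2))
}

#' Aggregate main and auxiliary (deep-supervision) losses
#'
#' Weighted sum of the main loss and the auxiliary losses from the
#' deep-supervision heads, with weights normalised to sum to 1. With no
#' auxiliaries the main loss is returned unchanged.
#'
#' @param main A \code{loss_value} (or scalar) for the full-resolution output.
#' @param auxiliaries List of \code{loss_value}s (or scalars), one per
#'   auxiliary output.
#' @param level_weights Numeric weights, length \code{1 + length(auxiliaries)}
#'   (main first); default equal.
#' @return A \code{loss_value}; components hold the normalised weights.
#' @export
deep_supervision_aggregate <- function(main, auxiliaries = list(),
                                       level_weights = NULL) {
  tot <- function(x) if (inherits(x, "loss_value")) x$total else as.numeric(x)
  vals <- c(tot(main), vapply(auxiliaries, tot, numeric(1)))
  if (is.null(level_weights)) level_weights <- rep(1, length(vals))
  if (length(level_weights) != length(vals))
    stop("need one weight per output (main + ", length(auxiliaries),
         " auxiliaries)")
  if (length(auxiliaries) == 0L)
    return(if (inherits(main, "loss_value")) main else loss_value(tot(main)))
  w <- level_weights / sum(level_weights)
  loss_value(sum(w * vals),
             components = list(weights = w, values = vals))
}

# ---- gradients w.r.t. logits (internal, used by the training loop and the
# finite-difference gradient tests) ------------------------------------------

# grad of loss w.r.t. probabilities, per loss kind; p, y are nvox x C
loss_grad_probs <- function(kind, p, y, weights, xe_coefficient = 1,
                            dice_coefficient = 1, gamma = 0.3,
                            epsilon = 1e-7) {
  w <- as.numeric(weights)
  nvox <- nrow(p)
  g <- matrix(0, nvox, ncol(p))
  if (kind %in% c("wsd", "wsd_xe")) {
    d <- smoothed_soft_dice(p, y)
    # dDice_l/dp_l(x) = (2 y - Dice_l) / den_l
    gd <- -sweep(sweep(2 * y, 2, d$dice, "-"), 2, d$den, "/")
    gd <- sweep(gd, 2, w, "*")
    coef <- if (kind == "wsd_xe") dice_coefficient else 1
    g <- g + coef * gd
  }
  if (kind %in% c("xe", "wsd_xe")) {
    ptrue <- rowSums(p * y)
    wtrue <- as.numeric(y %*% w)
    gx <- -y * (wtrue / pmax(ptrue, epsilon)) / nvox
    gx[rowSums(y * (p < epsilon)) > 0, ] <- 0  # clamped region: flat
    coef <- if (kind == "wsd_xe") xe_coefficient else 1
    g <- g + coef * gx
  }
  if (kind == "explog") {
    d <- smoothed_soft_dice(p, y)
    dice_cl <- pmin(pmax(d$dice, epsilon), 1)
    C <- ncol(p)
    # term1: (1/C) sum_l (-ln D_l)^gamma
    t <- pmax(-log(dice_cl), 1e-12)
    outer_fac <- (gamma / C) * t^(gamma - 1) / dice_cl  # d/dD of (-lnD)^g, sign -
    dDdp <- sweep(sweep(2 * y, 2, d$dice, "-"), 2, d$den, "/")
    g <- g - sweep(dDdp, 2, outer_fac * (dice_cl < 1), "*")
    # term2: (1/V) sum_x w (-ln p)^gamma
    ptrue <- pmax(rowSums(p * y), epsilon)
    wtrue <- as.numeric(y %*% w)
    tp <- pmax(-log(ptrue), 1e-12)
    fac <- gamma * wtrue * tp^(gamma - 1) / ptrue / nvox
    g <- g - y * fac * (rowSums(p * y) >= epsilon)
  }
  g
}

# chain rule through the per-voxel softmax: dL/dz = p * (g - sum_l p_l g_l)
softmax_backward <- function(p, g) {
  p * (g - rowSums(p * g))
}

# full gradient of a configured loss w.r.t. logits
loss_grad_logits <- function(kind, p, y, weights, ...) {
  g <- loss_grad_probs(kind, p, y, weights, ...)
  softmax_backward(p, g)
}

# evaluate a configured loss (internal dispatcher used by training)
compute_loss <- function(kind, p, y, weights, xe_coefficient = 1,
                         dice_coefficient = 1, gamma = 0.3, epsilon = 1e-7) {
  switch(kind,
    wsd = weighted_soft_dice_loss(p, y, weights),
    xe = weighted_cross_entropy(p, y, weights, epsilon),
    wsd_xe = wsd_plus_xe_loss(p, y, weights, xe_coefficient,
                              dice_coefficient, epsilon),
    explog = exp_log_loss(p, y, weights, gamma, epsilon),
    stop("unknown loss kind '", kind, "'"))
}
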