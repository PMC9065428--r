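# Training protocol: Adam with plateau learning-rate decay, early stopping,
# gradient accumulation (simulated batch of four at physical batch size
# one), deep-supervision loss aggregation with the network's learnable
# balance scalar, and the cross-validation fold harness.

#' Training configuration
#'
#' @param initial_lr Initial learning rate (default 1e-2).
#' @param lr_decay_factor Learning rate is divided by this on plateau
#'   (default 10).
#' @param plateau_patience_epochs Epochs without a new best validation loss
#'   before the learning rate decays (default 100).
#' @param max_epochs Hard cap on training epochs (default 1000).
#' @param early_stop_patience_epochs Epochs without improvement before
#'   training stops (default 250).
#' @param accumulation_steps Gradient accumulation steps; parameter updates
#'   use the mean of this many single-sample gradients (default 4,
#'   simulating a batch size of four at physical batch size one).
#' @param improvement_tol Minimum absolute decrease of the validation loss
#'   that counts as an improvement (guards against float noise).
#' @param seed Integer seed controlling all randomness in the loop.
#' @return Object of class \code{"train_config"}.
#' @export
train_config <- function(initial_lr = 1e-2, lr_decay_factor = 10,
                         plateau_patience_epochs = 100L, max_epochs = 1000L,
                         early_stop_patience_epochs = 250L,
                         accumulation_steps = 4L, improvement_tol = 1e-6,
                         seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 1,
            plateau_patience_epochs >= 1, max_epochs >= 1,
            early_stop_patience_epochs >= plateau_patience_epochs,
            accumulation_steps >= 1)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience_epochs =
                   as.integer(early_stop_patience_epochs),
                 accumulation_steps = as.integer(accumulation_steps),
                 improvement_tol = improvement_tol,
                 batch_size = 1L, seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-validation fold plan
#'
#' Deterministic (seeded) partition of \code{n_items} into \code{n_folds}
#' folds with held-out test sets, a fixed-size validation set and the
#' remainder for training. Test sets partition the items: with 34 items and
#' 5 folds the test sizes are 7,7,7,7,6 so every item is tested exactly
#' once (set \code{overlap_last = TRUE} for the alternative reading in
#' which the last fold reuses one item to reach equal test sizes).
#'
#' @param n_items Number of cases.
#' @param n_folds Number of folds (default 5).
#' @param val_size Validation cases per fold (default 3).
#' @param rng_seed Integer seed.
#' @param overlap_last Allow the last test fold to reuse one item so all
#'   test folds have equal size.
#' @return Object of class \code{"fold_plan"}: list of folds, each with
#'   \code{train}, \code{validation}, \code{test} index vectors.
#' @export
make_folds <- function(n_items, n_folds = 5L, val_size = 3L, rng_seed = 1L,
                       overlap_last = FALSE) {
  n_items <- as.integer(n_items); n_folds <- as.integer(n_folds)
  base <- n_items %/% n_folds
  extra <- n_items %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
  if (any(sizes < 1L)) stop("more folds than items")
  if (n_items - max(sizes) - val_size < 1L)
    stop("fold sizes infeasible: no training items left")
  set.seed(rng_seed)
  perm <- sample.int(n_items)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  folds <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- sort(perm[starts[k]:stops[k]])
    if (overlap_last && k == n_folds && length(test) < max(sizes)) {
      pool <- setdiff(perm, test)
      test <- sort(c(test, pool[seq_len(max(sizes) - length(test))]))
    }
    rest <- setdiff(perm, test)
    val <- sort(rest[seq_len(val_size)])
    train <- sort(setdiff(rest, val))
    folds[[k]] <- list(train = train, validation = val, test = test)
  }
  structure(folds, class = "fold_plan", n_items = n_items)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Cross-validation plan: %d folds over %d items\n",
              length(x), attr(x, "n_items")))
  for (k in seq_along(x))
    cat(sprintf("  fold %d: %d train / %d validation / %d test\n", k,
                length(x[[k]]$train), length(x[[k]]$validation),
                length(x[[k]]$test)))
  invisible(x)
}

# ---- schedule: pure functions of the validation-loss trace ------------------

# epochs since the last improvement, given the trace and tolerance
epochs_since_best <- function(val_losses, tol = 1e-6) {
  best <- Inf; since <- 0L
  for (v in val_losses) {
    if (v < best - tol) { best <- v; since <- 0L } else since <- since + 1L
  }
  since
}

#' Plateau learning-rate step
#'
#' Decays the learning rate by \code{lr_decay_factor} when the validation
#' loss has not improved for \code{plateau_patience_epochs}; the plateau
#' counter resets on decay (and on every new best).
#'
#' @param history A \code{training_history} (or list with
#'   \code{val_loss} and \code{lr} numeric vectors).
#' @param config A \code{\link{train_config}}.
#' @return New learning rate (scalar).
#' @export
lr_step <- function(history, config) {
  vl <- history$val_loss
  if (length(vl) < 1L) stop("need at least one recorded epoch")
  lr <- tail(history$lr, 1L)
  # epochs since last improvement, counted since the last decay
  last_decay <- {
    d <- which(diff(history$lr) < 0)
    if (length(d)) max(d) + 1L else 1L
  }
  window <- vl[last_decay:length(vl)]
  best_before <- if (last_decay > 1L) min(vl[1:(last_decay - 1L)]) else Inf
  since <- 0L; best <- best_before
  for (v in window) {
    if (v < best - config$improvement_tol) { best <- v; since <- 0L }
    else since <- since + 1L
  }
  if (since >= config$plateau_patience_epochs) lr / config$lr_decay_factor
  else lr
}

#' Early-stopping decision
#'
#' Stop when \code{max_epochs} is reached or the validation loss has not
#' improved for \code{early_stop_patience_epochs}.
#'
#' @inheritParams lr_step
#' @return List \code{(stop, reason)} with reason in
#'   \code{"max_epochs"}, \code{"early_stop"} or \code{NA}.
#' @export
should_stop <- function(history, config) {
  n <- length(history$val_loss)
  if (n >= config$max_epochs)
    return(list(stop = TRUE, reason = "max_epochs"))
  if (epochs_since_best(history$val_loss, config$improvement_tol) >=
      config$early_stop_patience_epochs)
    return(list(stop = TRUE, reason = "early_stop"))
  list(stop = FALSE, reason = NA_character_)
}

# ---- parameter-tree arithmetic and Adam ------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) { for (i in seq_along(a)) a[[i]] <- tree_map(f, a[[i]]); a }
  else f(a)
}

zero_like <- function(a) tree_map(function(x) x * 0, a)

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# ---- single-sample gradient (loss + backprop) ------------------------------

# Compute loss and full parameter gradient for one (windowed input, label)
# pair. Deep-supervision aggregation uses weights (1, s, s) with
# s = sigmoid(ds_lambda), normalised; the scalar's own gradient is included.
sample_gradient <- function(net, input, labels, loss_cfg, weights) {
  cfg <- net$config
  fw <- forward_pass(net, input, training = TRUE)
  nc <- cfg$num_classes
  y <- onehot_matrix(labels, nc)
  if (!is.null(fw$pad)) {
    # pad the target with background to match the padded grid
    lab_arr <- if (inherits(labels, "label_map")) labels$labels else labels
    pd <- pad_to_multiple(matrix(as.numeric(lab_arr), ncol = 1),
                          dim(lab_arr), 8L)
    y <- onehot_matrix(array(as.integer(pd$x), pd$dims), nc)
  }
  args <- list(xe_coefficient = loss_cfg$xe_coefficient %||% 1,
               dice_coefficient = loss_cfg$dice_coefficient %||% 1,
               gamma = loss_cfg$gamma %||% 0.3,
               epsilon = loss_cfg$epsilon %||% 1e-7)
  main_l <- do.call(compute_loss,
                    c(list(loss_cfg$kind, fw$probs, y, weights), args))
  g_main <- do.call(loss_grad_logits,
                    c(list(loss_cfg$kind, fw$probs, y, weights), args))
  if (cfg$deep_supervision) {
    aux_l <- lapply(fw$aux_probs, function(p)
      do.call(compute_loss, c(list(loss_cfg$kind, p, y, weights), args)))
    s <- 1 / (1 + exp(-net$params$ds_lambda))
    wts <- c(1, rep(s, length(aux_l)))
    wn <- wts / sum(wts)
    vals <- c(main_l$total, vapply(aux_l, function(l) l$total, numeric(1)))
    total <- sum(wn * vals)
    g_aux <- lapply(seq_along(aux_l), function(i)
      wn[i + 1] * do.call(loss_grad_logits,
                          c(list(loss_cfg$kind, fw$aux_probs[[i]], y, weights),
                            args)))
    grads <- resunet_backward_core(net, fw$fw, wn[1] * g_main, g_aux)
    # d total / d lambda through the normalised weights
    aux_mean <- mean(vals[-1]); na <- length(aux_l)
    dtot_ds <- (na * aux_mean - na * vals[1]) / (1 + na * s)^2
    grads$ds_lambda <- dtot_ds * s * (1 - s)
    grads$aux1 <- grads$aux1 %||% zero_like(net$params$aux1)
    grads$aux2 <- grads$aux2 %||% zero_like(net$params$aux2)
  } else {
    total <- main_l$total
    grads <- resunet_backward_core(net, fw$fw, g_main, NULL)
  }
  list(loss = total, main_loss = main_l$total, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order gradient tree to match the parameter tree layout
align_grads <- function(params, grads) {
  out <- params
  for (nm in names(params)) out[[nm]] <- grads[[nm]]
  out
}

#' Accumulate gradients over several samples and update once
#'
#' Computes single-sample gradients at a fixed parameter state for
#' \code{steps} consecutive samples, averages them, and applies one Adam
#' update — the update direction equals the mean of the per-sample
#' gradients (simulated batch of \code{steps} at physical batch size one).
#'
#' @param net A \code{\link{resunet3d}}.
#' @param samples List of \code{steps} lists with \code{input} (windowed
#'   array) and \code{labels}.
#' @param loss_cfg List with \code{kind} and loss options.
#' @param weights Class weights.
#' @param opt_state Adam state from \code{adam_init} (internal).
#' @param lr Learning rate.
#' @return List with updated \code{net}, \code{opt_state}, \code{losses}.
#' @export
accumulate_and_update <- function(net, samples, loss_cfg, weights,
                                  opt_state, lr) {
  acc <- NULL; losses <- numeric(0)
  for (s in samples) {
    sg <- sample_gradient(net, s$input, s$labels, loss_cfg, weights)
    g <- align_grads(net$params, sg$grads)
    acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
    losses <- c(losses, sg$loss)
  }
  acc <- tree_map(function(x) x / length(samples), acc)
  au <- adam_update(net$params, acc, opt_state, lr)
  net$params <- au$params
  list(net = net, opt_state = au$state, losses = losses, grad = acc)
}

#' Train the segmentation network
#'
#' The full training loop: per epoch, each training case is augmented
#' (unless \code{augment} is NULL), windowed, run forward with deep
#' supervision, the configured loss is aggregated and backpropagated, and
#' parameters update every \code{accumulation_steps} samples with Adam.
#' Validation (no augmentation, no auxiliaries in the reported loss) drives
#' the plateau learning-rate schedule and early stopping; the best
#' validation state is checkpointed and restored at the end.
#'
#' @param config A \code{\link{network_config}}.
#' @param cases List of training cases, each a list with \code{ct}
#'   (\code{ct_volume}) and \code{gold} (\code{label_map}) — e.g.
#'   \code{\link{generate_phantom}} results.
#' @param fold List with \code{train} and \code{validation} index vectors
#'   into \code{cases}.
#' @param loss_cfg List: \code{kind} in \code{wsd, xe, wsd_xe, explog} plus
#'   options (\code{alpha}, \code{xe_coefficient}, \code{gamma},
#'   \code{epsilon}).
#' @param augment An \code{\link{augmentation_policy}} or NULL to disable.
#' @param train_cfg A \code{\link{train_config}}.
#' @param window_specs Window list; defaults chosen from
#'   \code{config$in_channels}.
#' @param verbose Print one line per epoch.
#' @return Object of class \code{"oarseg_fit"}: list with \code{network}
#'   (best-validation state), \code{history} (a \code{training_history}
#'   data frame), \code{loss_cfg}, \code{weights}, \code{termination}.
#' @export
train_segmentation <- function(config, cases, fold,
                               loss_cfg = list(kind = "explog", alpha = 0.5),
                               augment = augmentation_policy(),
                               train_cfg = train_config(),
                               window_specs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "network_config"), length(fold$train) >= 1,
            length(fold$validation) >= 1)
  set.seed(train_cfg$seed)
  if (is.null(window_specs))
    window_specs <- if (config$in_channels == 3L) multi_window_set()
                    else list(window_presets("baseline"))
  net <- resunet3d(config, seed = train_cfg$seed)
  alpha <- loss_cfg$alpha %||% if (identical(loss_cfg$kind, "explog")) 0.5 else 1/3
  weights <- inverse_frequency_weights(
    lapply(cases[fold$train], function(cs) cs$gold),
    alpha = alpha, num_classes = config$num_classes)
  window_case <- function(cs) stack_windows(cs$ct, window_specs)
  val_inputs <- lapply(cases[fold$validation], window_case)
  val_targets <- lapply(cases[fold$validation], function(cs) cs$gold)
  opt_state <- adam_init(net$params)
  hist <- list(epoch = integer(0), train_loss = numeric(0),
               val_loss = numeric(0), lr = numeric(0))
  lr <- train_cfg$initial_lr
  best_val <- Inf; best_params <- net$params; best_epoch <- 0L
  termination <- "max_epochs"
  draw_counter <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_idx <- fold$train[sample.int(length(fold$train))]
    ep_losses <- numeric(0)
    i <- 1L
    while (i <= length(order_idx)) {
      take <- order_idx[i:min(i + train_cfg$accumulation_steps - 1L,
                              length(order_idx))]
      samples <- lapply(take, function(k) {
        cs <- cases[[k]]
        if (!is.null(augment)) {
          draw_counter <<- draw_counter + 1L
          rec <- sample_transform(augment,
                                  rng_seed = (train_cfg$seed %% 20000L) *
                                    100000L + draw_counter)
          tr <- apply_transform(cs$ct, cs$gold, rec,
                                lr_label_pairs = augment$lr_label_pairs)
          cs <- list(ct = tr$volume, gold = tr$labels)
        }
        list(input = stack_windows(cs$ct, window_specs), labels = cs$gold)
      })
      upd <- accumulate_and_update(net, samples, loss_cfg, weights,
                                   opt_state, lr)
      net <- upd$net; opt_state <- upd$opt_state
      ep_losses <- c(ep_losses, upd$losses)
      if (any(!is.finite(upd$losses))) {
        termination <- "diverged"
        break
      }
      i <- i + length(take)
    }
    # validation: configured loss on the main output only, no augmentation
    vls <- vapply(seq_along(val_inputs), function(k) {
      pr <- forward_pass(net, val_inputs[[k]], training = FALSE)
      y <- onehot_matrix(val_targets[[k]], config$num_classes)
      p <- matrix(pr, ncol = config$num_classes)
      compute_loss(loss_cfg$kind, p, y, weights,
                   xe_coefficient = loss_cfg$xe_coefficient %||% 1,
                   gamma = loss_cfg$gamma %||% 0.3,
                   epsilon = loss_cfg$epsilon %||% 1e-7)$total
    }, numeric(1))
    vl <- mean(vls)
    hist$epoch <- c(hist$epoch, epoch)
    hist$train_loss <- c(hist$train_loss, mean(ep_losses))
    hist$val_loss <- c(hist$val_loss, vl)
    hist$lr <- c(hist$lr, lr)
    if (verbose)
      message(sprintf("epoch %4d  train %.5f  val %.5f  lr %.2e",
                      epoch, mean(ep_losses), vl, lr))
    if (termination == "diverged") break
    if (vl < best_val - train_cfg$improvement_tol) {
      best_val <- vl; best_params <- net$params; best_epoch <- epoch
    }
    st <- should_stop(hist, train_cfg)
    if (st$stop) { termination <- st$reason; break }
    lr <- lr_step(hist, train_cfg)
  }
  net$params <- best_params
  history <- data.frame(epoch = hist$epoch, train_loss = hist$train_loss,
                        val_loss = hist$val_loss, lr = hist$lr)
  class(history) <- c("training_history", class(history))
  structure(list(network = net, history = history, loss_cfg = loss_cfg,
                 weights = weights, termination = termination,
                 best_epoch = best_epoch, best_val = best_val,
                 fold = fold, train_cfg = train_cfg),
            class = "oarseg_fit")
}

#' @export
print.oarseg_fit <- function(x, ...) {
  cat("Trained 3D Res-UNet segmentation model\n")
  print(x$network$config)
  cat(sprintf("  epochs run: %d; best validation loss %.5f at epoch %d (%s)\n",
              nrow(x$history), x$best_val, x$best_epoch, x$termination))
  invisible(x)
}

#' @export
summary.oarseg_fit <- function(object, ...) {
  h <- object$history
  cat("Training summary\n----------------\n")
  print(object)
  cat(sprintf("  final lr: %.2e; lr decays: %d\n", tail(h$lr, 1),
              sum(diff(h$lr) < 0)))
  cat(sprintf("  loss: %s; class weights: %s\n", object$loss_cfg$kind,
              paste(round(unclass(object$weights), 4), collapse = ", ")))
  invisible(object)
}

#' @export
plot.training_history <- function(x, ...) {
  graphics::plot(x$epoch, x$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(x$train_loss, x$val_loss), finite = TRUE), ...)
  graphics::lines(x$epoch, x$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.oarseg_fit <- function(x, ...) plot(x$history, ...)

#' @export
predict.oarseg_fit <- function(object, volume, ...) {
  predict(object$network, volume, ...)
}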