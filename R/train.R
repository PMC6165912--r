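#' Soft Dice loss
#'
#' Differentiable Dice-overlap loss used for all network training:
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`
#' with `eps = 1e-5` guarding empty masks. Because the loss normalises
#' by the total foreground mass it is insensitive to the extreme
#' foreground/background imbalance of small-organ segmentation.
#'
#' @param pred numeric array of foreground probabilities in \[0, 1\].
#' @param target binary array (0/1) of the same extents.
#' @param eps smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, target, eps = 1e-5) {
  if (length(pred) != length(target))
    stop("pred and target must have identical extents")
  s <- sum(pred * target)
  1 - (2 * s + eps) / (sum(pred) + sum(target) + eps)
}

# Gradient of soft_dice_loss w.r.t. pred.
soft_dice_grad <- function(pred, target, eps = 1e-5) {
  s <- sum(pred * target)
  denom <- sum(pred) + sum(target) + eps
  -(2 * target * denom - (2 * s + eps)) / denom^2
}

#' Map Hounsfield units to network inputs
#'
#' Fixed soft-tissue windowing: clamp to \[-160, 240\] HU and scale
#' affinely so that the window maps to \[-1, 1\] with 40 HU (typical
#' soft tissue) at zero. Keeping the map fixed (not per-volume
#' statistics) preserves the calibrated HU scale across cases.
#'
#' @param hu numeric array of Hounsfield units.
#' @return numeric array of the same shape.
#' @export
hu_normalize <- function(hu) {
  (pmin(pmax(hu, -160), 240) - 40) / 200
}

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    v <- flat[pos + seq_len(n)]
    if (!is.null(dim(skeleton[[nm]]))) dim(v) <- dim(skeleton[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

#' Train a U-Net with Adam on a stream of minibatches
#'
#' Generic CPU training loop. `batch_fn(step)` must return
#' `list(x = <list of [X,Y,Z,1] input arrays>, y = <list of matching
#' valid-centre 0/1 label arrays>)`; all members of one batch must share
#' extents. The per-step loss is the soft Dice loss pooled over the
#' minibatch (one overlap/mass sum across all patches), so pure
#' background patches retain a usable gradient.
#'
#' @param model a `unet` from [build_unet()].
#' @param batch_fn function of the step index returning one minibatch.
#' @param steps number of optimisation steps.
#' @param lr Adam learning rate: a scalar, or a function of the step
#'   index (for schedules such as a late decay).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param verbose print progress every `verbose` steps (0 = silent).
#' @return `list(model, loss)` with the per-step loss history.
#' @export
train_unet <- function(model, batch_fn, steps, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                       verbose = 0L) {
  stopifnot(inherits(model, "unet"))
  lr_fn <- if (is.function(lr)) lr else function(step) lr
  theta <- flatten_params(model$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  loss_hist <- numeric(steps)
  for (step in seq_len(steps)) {
    batch <- batch_fn(step)
    fw <- unet_forward(model, batch$x, train = TRUE, keep_cache = TRUE)
    model <- fw$model
    nb <- length(batch$x)
    # soft Dice pooled over the minibatch: overlap and mass sums run over
    # all patches jointly. A per-patch average would give empty-target
    # (pure background) patches a vanishing gradient (~eps / mass^2),
    # silencing exactly the samples the balanced batch composition adds
    # to suppress false positives.
    eps <- 1e-5
    pfgs <- lapply(seq_len(nb), function(i)
      array(fw$probs[[i]][, , , 2], dim = dim(fw$probs[[i]])[1:3]))
    S <- sum(vapply(seq_len(nb), function(i)
      sum(pfgs[[i]] * batch$y[[i]]), numeric(1)))
    P <- sum(vapply(pfgs, sum, numeric(1)))
    Tm <- sum(vapply(batch$y, sum, numeric(1)))
    denom <- P + Tm + eps
    loss_hist[step] <- 1 - (2 * S + eps) / denom
    dps <- lapply(seq_len(nb), function(i) {
      g <- -(2 * batch$y[[i]] * denom - (2 * S + eps)) / denom^2
      array(g, dim = c(dim(pfgs[[i]]), 1L))
    })
    grads <- unet_backward(model, fw$cache, dps)
    g <- flatten_params(grads[names(model$params)])
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^step)
    vh <- v / (1 - beta2^step)
    theta <- flatten_params(model$params) -
      lr_fn(step) * mh / (sqrt(vh) + adam_eps)
    model$params <- unflatten_params(theta, model$params)
    if (verbose > 0 && step %% verbose == 0)
      message(sprintf("step %d/%d  loss %.4f", step, steps,
                      mean(loss_hist[max(1, step - verbose + 1):step])))
  }
  list(model = model, loss = loss_hist)
}
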