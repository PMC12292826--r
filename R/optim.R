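# AdamW (decoupled weight decay) with a linear warm-up / linear decay
# learning-rate schedule.

adamw_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

# One in-place-style update; returns list(params, state). Decay applies to
# 2-D weight matrices only (biases, gains and embedded vectors exempt, the
# usual convention).
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$step <- state$step + 1L
  t <- state$step
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (!is.null(dim(params[[nm]])))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Learning rate under linear warm-up then linear decay to zero
#'
#' @param step Current optimizer step (1-based).
#' @param base_lr Peak learning rate.
#' @param max_steps Total scheduled steps.
#' @param warmup_frac Fraction of `max_steps` spent warming up (in `[0, 1)`).
#' @return The learning rate for this step.
#' @export
lr_at <- function(step, base_lr, max_steps, warmup_frac = 0.1) {
  stopifnot(warmup_frac >= 0, warmup_frac < 1, base_lr > 0, max_steps >= 1)
  w <- max(1, round(warmup_frac * max_steps))
  if (step <= w && warmup_frac > 0) return(base_lr * step / w)
  if (max_steps == w) return(base_lr)
  base_lr * max(0, (max_steps - step) / (max_steps - w))
}
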