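# Adam optimizer over a flat named list of tg_param tensors.

#' Adam optimizer state
#'
#' @param params Named list of `tg_tensor` parameters.
#' @param lr Learning rate.
#' @param beta1,beta2 Exponential decay rates for the moment estimates.
#' @param eps Numerical stabilizer.
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient;
#'   each step shrinks parameters by `lr * weight_decay` before the update.
#' @return An environment holding the optimizer state.
#' @keywords internal
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st
}

#' @rdname adam_init
#' @param state State from [adam_init()].
#' @export
adam_step <- function(params, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    if (state$wd > 0) p$value <- p$value * (1 - state$lr * state$wd)
    g <- p$grad
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$value <- p$value - state$lr * mhat / (sqrt(vhat) + state$eps)
    p$grad <- NULL
  }
  invisible(state)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Flatten all parameter values to one numeric vector (checkpoint/hash helper).
params_flatten <- function(params) unlist(lapply(params, function(p) as.numeric(p$value)))

params_restore <- function(params, flat) {
  off <- 0L
  for (p in params) {
    n <- length(p$value)
    v <- flat[(off + 1L):(off + n)]
    dim(v) <- dim(p$value)
    p$value <- v
    off <- off + n
  }
  invisible(params)
}

# Scale all gradients so their global L2 norm is at most `max_norm`.
clip_global_norm <- function(params, max_norm) {
  ss <- 0
  for (p in params) if (!is.null(p$grad)) ss <- ss + sum(p$grad^2)
  nrm <- sqrt(ss)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(nrm)
}
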