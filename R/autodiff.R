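# Reverse-mode autodifferentiation tape.
#
# Tensors are environments holding a numeric array ($value), an accumulated
# gradient ($grad) and a backward closure. Operations executed while a tape is
# active append their node; tg_backward() sweeps the tape in reverse creation
# order. Leaf parameters (tg_param) live off-tape; their gradients are written
# by the backward closures of the ops that consume them.

.tg <- new.env(parent = emptyenv())
.tg$tracing <- FALSE
.tg$tape <- NULL
.tg$n <- 0L

#' Start a fresh autodiff tape
#'
#' Clears any previously recorded operations and begins recording. Every
#' subsequent tensor operation involving a tracked tensor is appended to the
#' tape until [tg_backward()] (or the next `tg_tape_start()`) runs.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
tg_tape_start <- function() {
  .tg$tape <- vector("list", 1024L)
  .tg$n <- 0L
  .tg$tracing <- TRUE
  invisible(NULL)
}

tg_tape_stop <- function() {
  .tg$tracing <- FALSE
  .tg$tape <- NULL
  .tg$n <- 0L
  invisible(NULL)
}

tg_record <- function(node) {
  if (!.tg$tracing) return(invisible(node))
  n <- .tg$n + 1L
  if (n > length(.tg$tape)) .tg$tape <- c(.tg$tape, vector("list", length(.tg$tape)))
  .tg$tape[[n]] <- node
  .tg$n <- n
  invisible(node)
}

#' Create a tensor
#'
#' @param value Numeric array, matrix or vector.
#' @param requires_grad Should gradients accumulate into this tensor?
#' @return A `tg_tensor` (environment).
#' @keywords internal
#' @export
tg_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$track <- isTRUE(requires_grad)
  t$backward <- NULL
  class(t) <- "tg_tensor"
  t
}

#' @rdname tg_tensor
#' @export
tg_param <- function(value) tg_tensor(value, requires_grad = TRUE)

is_tensor <- function(x) inherits(x, "tg_tensor")
tg_v <- function(x) if (is_tensor(x)) x$value else x
tg_tracked <- function(x) is_tensor(x) && isTRUE(x$track)

tg_acc <- function(t, g) {
  if (!tg_tracked(t)) return(invisible(NULL))
  t$grad <- if (is.null(t$grad)) g else t$grad + g
  invisible(NULL)
}

# Build an op node: value, list of parents, backward closure taking the
# upstream gradient and accumulating into parents via tg_acc.
tg_op <- function(value, parents, backward) {
  tracked <- any(vapply(parents, tg_tracked, logical(1)))
  t <- tg_tensor(value, requires_grad = tracked)
  if (tracked) {
    t$backward <- backward
    tg_record(t)
  }
  t
}

#' Run the backward sweep from a scalar loss
#'
#' Seeds the loss gradient with 1 and propagates gradients through every
#' recorded operation in reverse order. Leaf parameters end up with non-NULL
#' `$grad`. The tape is left intact (call [tg_tape_start()] before the next
#' forward pass).
#' @param loss A scalar `tg_tensor` produced under an active tape.
#' @keywords internal
#' @export
tg_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (.tg$n == 0L) return(invisible(NULL))
  for (i in seq(.tg$n, 1L)) {
    node <- .tg$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node$grad)
  }
  invisible(NULL)
}

# ---- elementwise -----------------------------------------------------------

tg_add <- function(a, b) {
  av <- tg_v(a); bv <- tg_v(b)
  tg_op(av + bv, list(a, b), function(g) {
    if (tg_tracked(a)) tg_acc(a, if (length(av) == 1L && length(g) > 1L) sum(g) else g)
    if (tg_tracked(b)) tg_acc(b, if (length(bv) == 1L && length(g) > 1L) sum(g) else g)
  })
}

tg_sub <- function(a, b) {
  av <- tg_v(a); bv <- tg_v(b)
  tg_op(av - bv, list(a, b), function(g) {
    if (tg_tracked(a)) tg_acc(a, if (length(av) == 1L && length(g) > 1L) sum(g) else g)
    if (tg_tracked(b)) tg_acc(b, if (length(bv) == 1L && length(g) > 1L) sum(-g) else -g)
  })
}

tg_mul <- function(a, b) {
  av <- tg_v(a); bv <- tg_v(b)
  tg_op(av * bv, list(a, b), function(g) {
    if (tg_tracked(a)) tg_acc(a, if (length(av) == 1L && length(g) > 1L) sum(g * bv) else g * bv)
    if (tg_tracked(b)) tg_acc(b, if (length(bv) == 1L && length(g) > 1L) sum(g * av) else g * av)
  })
}

tg_div <- function(a, b) {
  av <- tg_v(a); bv <- tg_v(b)
  tg_op(av / bv, list(a, b), function(g) {
    if (tg_tracked(a)) tg_acc(a, if (length(av) == 1L && length(g) > 1L) sum(g / bv) else g / bv)
    if (tg_tracked(b)) {
      gb <- -g * av / (bv * bv)
      tg_acc(b, if (length(bv) == 1L && length(g) > 1L) sum(gb) else gb)
    }
  })
}

tg_scale <- function(x, s) {
  xv <- tg_v(x)
  tg_op(xv * s, list(x), function(g) tg_acc(x, g * s))
}

tg_sqrt <- function(x) {
  y <- sqrt(tg_v(x))
  tg_op(y, list(x), function(g) tg_acc(x, g * 0.5 / y))
}

tg_abs <- function(x) {
  xv <- tg_v(x)
  tg_op(abs(xv), list(x), function(g) tg_acc(x, g * sign(xv)))
}

tg_relu <- function(x) {
  xv <- tg_v(x)
  m <- xv > 0
  tg_op(xv * m, list(x), function(g) tg_acc(x, g * m))
}

# Exact GELU: x * pnorm(x); gradient pnorm(x) + x * dnorm(x).
tg_gelu <- function(x) {
  xv <- tg_v(x)
  p <- stats::pnorm(xv)
  tg_op(xv * p, list(x), function(g) tg_acc(x, g * (p + xv * stats::dnorm(xv))))
}

# ---- reductions ------------------------------------------------------------

tg_sum <- function(x) {
  xv <- tg_v(x)
  tg_op(sum(xv), list(x), function(g) tg_acc(x, array(as.numeric(g), dim = dim(xv) %||% length(xv))))
}

tg_mean <- function(x) {
  xv <- tg_v(x)
  n <- length(xv)
  tg_op(sum(xv) / n, list(x), function(g) tg_acc(x, array(as.numeric(g) / n, dim = dim(xv) %||% n)))
}

tg_colmeans <- function(x) {
  xv <- tg_v(x)
  n <- nrow(xv)
  tg_op(colMeans(xv), list(x), function(g) tg_acc(x, matrix(g, n, ncol(xv), byrow = TRUE) / n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- shape ops -------------------------------------------------------------

tg_reshape <- function(x, dims) {
  xv <- tg_v(x)
  odim <- dim(xv) %||% length(xv)
  y <- xv
  dim(y) <- dims
  tg_op(y, list(x), function(g) { dim(g) <- odim; tg_acc(x, g) })
}

# Gather rows of a matrix: rowidx gives, for each output row, the source row
# (0 = emit a zero row). rowidx must reference each source row at most once.
tg_rows <- function(x, rowidx) {
  xv <- tg_v(x)
  nc <- ncol(xv)
  y <- matrix(0, length(rowidx), nc)
  nz <- rowidx > 0L
  y[nz, ] <- xv[rowidx[nz], , drop = FALSE]
  tg_op(y, list(x), function(g) {
    gx <- matrix(0, nrow(xv), nc)
    gx[rowidx[nz], ] <- g[nz, , drop = FALSE]
    tg_acc(x, gx)
  })
}

tg_rowblock <- function(x, i0, n) {
  xv <- tg_v(x)
  tg_op(xv[i0:(i0 + n - 1L), , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[i0:(i0 + n - 1L), ] <- g
    tg_acc(x, gx)
  })
}

tg_rbind <- function(lst) {
  vals <- lapply(lst, tg_v)
  ns <- vapply(vals, nrow, integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  tg_op(do.call(rbind, vals), lst, function(g) {
    for (i in seq_along(lst)) {
      if (tg_tracked(lst[[i]]))
        tg_acc(lst[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

# ---- linear algebra --------------------------------------------------------

tg_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- tg_v(a); bv <- tg_v(b)
  y <- if (!ta && !tb) av %*% bv
  else if (ta && !tb) crossprod(av, bv)
  else if (!ta && tb) tcrossprod(av, bv)
  else t(bv %*% av)
  tg_op(y, list(a, b), function(g) {
    if (tg_tracked(a)) {
      ga <- if (!ta && !tb) tcrossprod(g, bv)
      else if (ta && !tb) tcrossprod(bv, g)
      else if (!ta && tb) g %*% bv
      else crossprod(bv, t(g))
      tg_acc(a, ga)
    }
    if (tg_tracked(b)) {
      gb <- if (!ta && !tb) crossprod(av, g)
      else if (ta && !tb) av %*% g
      else if (!ta && tb) crossprod(g, av)
      else tcrossprod(t(g), av)
      tg_acc(b, gb)
    }
  })
}

# x (n x cin) %*% W (cin x cout) + bias (cout)
tg_linear <- function(x, W, b) {
  xv <- tg_v(x); Wv <- tg_v(W); bv <- tg_v(b)
  y <- xv %*% Wv
  y <- y + rep(bv, each = nrow(y))
  tg_op(y, list(x, W, b), function(g) {
    if (tg_tracked(x)) tg_acc(x, tcrossprod(g, Wv))
    if (tg_tracked(W)) tg_acc(W, crossprod(xv, g))
    if (tg_tracked(b)) tg_acc(b, colSums(g))
  })
}

# LayerNorm across columns of an (n x c) matrix.
tg_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- tg_v(x); gv <- tg_v(gamma); bv <- tg_v(beta)
  c <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  n <- nrow(xv)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  tg_op(y, list(x, gamma, beta), function(g) {
    if (tg_tracked(gamma)) tg_acc(gamma, colSums(g * xhat))
    if (tg_tracked(beta)) tg_acc(beta, colSums(g))
    if (tg_tracked(x)) {
      dxhat <- g * rep(gv, each = n)
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      tg_acc(x, (dxhat - m1 - xhat * m2) * istd)
    }
  })
}

# Row softmax with optional additive mask (constant matrix, e.g. -1e9 entries).
tg_softmax <- function(x, mask = NULL) {
  xv <- tg_v(x)
  if (!is.null(mask)) xv <- xv + mask
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  y <- e / rowSums(e)
  tg_op(y, list(x), function(g) {
    tg_acc(x, y * (g - rowSums(g * y)))
  })
}

# ---- 3D convolution --------------------------------------------------------

conv3d_outdim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# x: (nx,ny,nz,cin) array (tensor or constant); W: (k,k,k,cin,cout); b: (cout)
tg_conv3d <- function(x, W, b, stride, pad) {
  xv <- tg_v(x); Wv <- tg_v(W); bv <- tg_v(b)
  xd <- as.integer(dim(xv))
  wd <- as.integer(dim(Wv))
  stopifnot(xd[4] == wd[4])
  stride <- as.integer(rep(stride, length.out = 3))
  pad <- as.integer(rep(pad, length.out = 3))
  y <- cpp_conv3d_fwd(xv, xd, Wv, wd, stride, pad, bv)
  od <- dim(y)
  tg_op(y, list(x, W, b), function(g) {
    if (tg_tracked(b)) {
      gm <- g
      dim(gm) <- c(prod(od[1:3]), od[4])
      tg_acc(b, colSums(gm))
    }
    if (tg_tracked(W)) tg_acc(W, cpp_conv3d_gw(xv, xd, g, wd, stride, pad))
    if (tg_tracked(x)) tg_acc(x, cpp_conv3d_gx(g, xd, Wv, wd, stride, pad))
  })
}

# Nearest-neighbour 2x upsampling of (nx,ny,nz,c) along the spatial axes.
# Backward sums each source voxel's 8 replicas (vectorized slice adds).
tg_upsample2 <- function(x) {
  xv <- tg_v(x)
  xd <- dim(xv)
  ix <- rep(seq_len(xd[1]), each = 2L)
  iy <- rep(seq_len(xd[2]), each = 2L)
  iz <- rep(seq_len(xd[3]), each = 2L)
  y <- xv[ix, iy, iz, , drop = FALSE]
  tg_op(y, list(x), function(g) {
    gx <- array(0, dim = xd)
    for (dx in 1:2) for (dy in 1:2) for (dz in 1:2) {
      gx <- gx + g[seq(dx, by = 2L, length.out = xd[1]),
                   seq(dy, by = 2L, length.out = xd[2]),
                   seq(dz, by = 2L, length.out = xd[3]), , drop = FALSE]
    }
    tg_acc(x, gx)
  })
}

# Crop the spatial axes of (nx,ny,nz,c) to `target` (keeps the leading block).
tg_crop_spatial <- function(x, target) {
  xv <- tg_v(x)
  xd <- dim(xv)
  if (all(xd[1:3] == target)) return(if (is_tensor(x)) x else tg_tensor(xv))
  y <- xv[seq_len(target[1]), seq_len(target[2]), seq_len(target[3]), , drop = FALSE]
  tg_op(y, list(x), function(g) {
    gx <- array(0, dim = xd)
    gx[seq_len(target[1]), seq_len(target[2]), seq_len(target[3]), ] <- g
    tg_acc(x, gx)
  })
}

# Select columns of a matrix (channel slicing for flattened feature grids).
tg_cols <- function(x, colidx) {
  xv <- tg_v(x)
  tg_op(xv[, colidx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, colidx] <- g
    tg_acc(x, gx)
  })
}

tg_cbind <- function(lst) {
  vals <- lapply(lst, tg_v)
  ns <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  tg_op(do.call(cbind, vals), lst, function(g) {
    for (i in seq_along(lst)) {
      if (tg_tracked(lst[[i]]))
        tg_acc(lst[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Mutual information (nats) of a joint probability matrix that sums to 1.
# d MI / d p_jk = log p_jk - log pm_j - log pf_k - 1 (constant offsets are
# irrelevant along the simplex the soft histogram lives on).
tg_mi_from_joint <- function(joint, eps = 1e-12) {
  jv <- tg_v(joint)
  pm <- rowSums(jv)
  pf <- colSums(jv)
  lp <- log(pmax(jv, eps))
  lm <- log(pmax(pm, eps))
  lf <- log(pmax(pf, eps))
  lsum <- outer(lm, rep(1, length(pf))) + outer(rep(1, length(pm)), lf)
  val <- sum(jv * (lp - lsum))
  tg_op(val, list(joint), function(g) {
    tg_acc(joint, g * (lp - lsum - 1))
  })
}
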