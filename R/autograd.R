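# Reverse-mode automatic differentiation over dense matrices.
#
# Design: operations accept either plain numeric matrices (constants) or
# "agnode" objects (tracked values). When no input is tracked, an operation
# returns a plain matrix -- the gradient-free path used for frozen teacher
# forwards costs no graph bookkeeping. When at least one input is tracked,
# the operation returns a new node holding the value, its tracked parents,
# and a backward closure mapping the output gradient to parent gradients.
#
# Granularity is deliberately coarse (whole linear layers, whole multi-head
# attention cores, whole losses) so that a toy transformer forward creates a
# few dozen nodes per batch rather than thousands.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

new_agnode <- function(value, parents, backward) {
  .ag_env$counter <- .ag_env$counter + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ag_env$counter
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  class(node) <- "agnode"
  node
}

is_agnode <- function(x) inherits(x, "agnode")

#' Extract the numeric value of a tracked or plain object
#'
#' @param x An `agnode` or a plain numeric array.
#' @return The underlying numeric value.
#' @keywords internal
ag_value <- function(x) if (is_agnode(x)) x$value else x

#' Create a trainable leaf node
#'
#' Wraps a numeric matrix or vector as a leaf of the autodiff graph; its
#' gradient is populated by [ag_backward()].
#'
#' @param value Numeric matrix or vector.
#' @return An `agnode` leaf.
#' @export
ag_param <- function(value) {
  new_agnode(value, parents = list(), backward = NULL)
}

# Keep only tracked parents; record which argument slots they came from.
.tracked <- function(...) {
  args <- list(...)
  keep <- vapply(args, is_agnode, logical(1))
  list(parents = args[keep], slots = which(keep))
}

# Build an output node (or return the plain value when nothing is tracked).
# backward_all(grad) must return a list of gradients for ALL argument slots
# (NULL allowed for constants); untracked slots are dropped.
.ag_op <- function(value, args, backward_all) {
  keep <- vapply(args, is_agnode, logical(1))
  if (!any(keep)) return(value)
  slots <- which(keep)
  new_agnode(value, parents = args[keep], backward = function(grad) {
    gs <- backward_all(grad)
    gs[slots]
  })
}

.accum <- function(node, g) {
  if (is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#'
#' Topologically sorts the graph reachable from `loss` and accumulates
#' gradients into every tracked node's `$grad` field (leaves created with
#' [ag_param()] end up holding the loss gradient with respect to their value).
#'
#' @param loss An `agnode` holding a scalar value.
#' @return Invisibly, the node.
#' @export
ag_backward <- function(loss) {
  stopifnot(is_agnode(loss), length(ag_value(loss)) == 1L)
  # iterative post-order DFS (graphs can be a few hundred nodes deep)
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  loss$grad <- 1
  for (i in seq(n_ord, 1L)) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) .accum(node$parents[[j]], gs[[j]])
  }
  invisible(loss)
}

#' Clear gradients on a list of leaf nodes
#' @param params List of `agnode` leaves.
#' @return Invisibly, the list.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise / linear algebra ops ---------------------------------------

ag_add <- function(a, b) {
  .ag_op(ag_value(a) + ag_value(b), list(a, b),
         function(g) list(g, g))
}

ag_scale <- function(a, s) {
  .ag_op(ag_value(a) * s, list(a),
         function(g) list(g * s))
}

# X %*% W + bias (bias broadcast over rows; bias may be NULL)
ag_linear <- function(X, W, b = NULL) {
  Xv <- ag_value(X); Wv <- ag_value(W)
  out <- Xv %*% Wv
  if (!is.null(b)) out <- .add_bias(out, ag_value(b))
  .ag_op(out, list(X, W, b), function(g) {
    list(g %*% t(Wv), crossprod(Xv, g), colSums(g))
  })
}

# X %*% t(W) + bias: used for weight-tied output heads
ag_tlinear <- function(X, W, b = NULL) {
  Xv <- ag_value(X); Wv <- ag_value(W)
  out <- tcrossprod(Xv, Wv)
  if (!is.null(b)) out <- .add_bias(out, ag_value(b))
  .ag_op(out, list(X, W, b), function(g) {
    list(g %*% Wv, crossprod(g, Xv), colSums(g))
  })
}

# Row-wise layer normalisation with learnable gain/bias.
ag_layernorm <- function(X, gain, bias, eps = 1e-5) {
  Xv <- ag_value(X); gv <- as.numeric(ag_value(gain)); bv <- as.numeric(ag_value(bias))
  d <- ncol(Xv)
  mu <- rowMeans(Xv)
  xc <- Xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- .add_bias(xhat * rep(gv, each = nrow(Xv)), bv)
  .ag_op(out, list(X, gain, bias), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    # d/dX of (x - mean) / sqrt(var + eps), per row
    s1 <- rowMeans(dxhat)
    s2 <- rowMeans(dxhat * xhat)
    dX <- inv * (dxhat - s1 - xhat * s2)
    list(dX, colSums(g * xhat), colSums(g))
  })
}

# GELU, sigmoid approximation: x * sigmoid(1.702 x) (cheap and smooth; the
# approximation error is far below the optimisation noise floor).
ag_gelu <- function(X) {
  Xv <- ag_value(X)
  S <- 1 / (1 + exp(-1.702 * Xv))
  out <- Xv * S
  .ag_op(out, list(X), function(g) {
    list(g * (S + 1.702 * Xv * S * (1 - S)))
  })
}

# Gather rows: out[i, ] = W[idx[i], ]
ag_rows <- function(W, idx) {
  Wv <- ag_value(W)
  idx <- as.integer(idx)
  out <- Wv[idx, , drop = FALSE]
  .ag_op(out, list(W), function(g) {
    dW <- matrix(0, nrow(Wv), ncol(Wv))
    agg <- rowsum(g, group = idx)
    dW[as.integer(rownames(agg)), ] <- agg
    list(dW)
  })
}

# Scatter rows: out has `n_out` rows; out[i, ] = src[map[i], ] where map[i] > 0,
# else the broadcast `fill` row vector. Used to insert mask tokens into the
# reconstruction decoder's input sequence.
ag_scatter_rows <- function(src, fill, map, n_out) {
  sv <- ag_value(src); fv <- as.numeric(ag_value(fill))
  map <- as.integer(map)
  d <- ncol(sv)
  out <- matrix(fv, n_out, d, byrow = TRUE)
  hit <- map > 0L
  out[hit, ] <- sv[map[hit], , drop = FALSE]
  .ag_op(out, list(src, fill), function(g) {
    dsrc <- matrix(0, nrow(sv), d)
    agg <- rowsum(g[hit, , drop = FALSE], group = map[hit])
    dsrc[as.integer(rownames(agg)), ] <- agg
    list(dsrc, colSums(g[!hit, , drop = FALSE]))
  })
}

# ---- multi-head attention core ----------------------------------------------

.row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

.add_bias <- function(X, b) X + rep(b, rep.int(nrow(X), length(b)))

# Q, K, V: stacked batches, (B*Sq) x d and (B*Sk) x d. Returns a two-element
# list: $ctx -- (B*Sq) x d context, and $attn -- row-stochastic attention
# stored as an Sq x Sk x h x B array (matrix dims first, so per-(head,
# sample) slices are contiguous). Both are graph outputs; the $attn node
# lets distillation losses propagate gradients into the softmaxed maps
# directly.
ag_attn_core <- function(Q, K, V, nheads, batch) {
  Qv <- ag_value(Q); Kv <- ag_value(K); Vv <- ag_value(V)
  d <- ncol(Qv)
  stopifnot(d %% nheads == 0L, nrow(Qv) %% batch == 0L, nrow(Kv) %% batch == 0L)
  dk <- d %/% nheads
  Sq <- nrow(Qv) %/% batch
  Sk <- nrow(Kv) %/% batch
  scale <- 1 / sqrt(dk)
  A <- array(0, dim = c(Sq, Sk, nheads, batch))
  ctx <- matrix(0, nrow(Qv), d)
  for (b in seq_len(batch)) {
    rq <- ((b - 1L) * Sq + 1L):(b * Sq)
    rk <- ((b - 1L) * Sk + 1L):(b * Sk)
    for (h in seq_len(nheads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      q <- Qv[rq, cols, drop = FALSE]
      k <- Kv[rk, cols, drop = FALSE]
      v <- Vv[rk, cols, drop = FALSE]
      Ab <- .row_softmax(tcrossprod(q, k) * scale)
      A[, , h, b] <- Ab
      ctx[rq, cols] <- Ab %*% v
    }
  }
  tracked <- is_agnode(Q) || is_agnode(K) || is_agnode(V)
  if (!tracked) return(list(ctx = ctx, attn = A))

  # gradient of scores S given gradient of A = softmax(S), per (b, h)
  softmax_back <- function(dA, Ab) Ab * (dA - rowSums(dA * Ab))

  ctx_node <- .ag_op(ctx, list(Q, K, V), function(g) {
    dQ <- matrix(0, nrow(Qv), d); dK <- matrix(0, nrow(Kv), d); dV <- matrix(0, nrow(Kv), d)
    for (b in seq_len(batch)) {
      rq <- ((b - 1L) * Sq + 1L):(b * Sq)
      rk <- ((b - 1L) * Sk + 1L):(b * Sk)
      for (h in seq_len(nheads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        Ab <- A[, , h, b]; if (is.null(dim(Ab))) dim(Ab) <- c(Sq, Sk)
        go <- g[rq, cols, drop = FALSE]
        v <- Vv[rk, cols, drop = FALSE]
        dV[rk, cols] <- crossprod(Ab, go)
        dS <- softmax_back(tcrossprod(go, v), Ab) * scale
        dQ[rq, cols] <- dS %*% Kv[rk, cols, drop = FALSE]
        dK[rk, cols] <- crossprod(dS, Qv[rq, cols, drop = FALSE])
      }
    }
    list(dQ, dK, dV)
  })
  attn_node <- .ag_op(A, list(Q, K), function(g) {
    dQ <- matrix(0, nrow(Qv), d); dK <- matrix(0, nrow(Kv), d)
    for (b in seq_len(batch)) {
      rq <- ((b - 1L) * Sq + 1L):(b * Sq)
      rk <- ((b - 1L) * Sk + 1L):(b * Sk)
      for (h in seq_len(nheads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        Ab <- A[, , h, b]; if (is.null(dim(Ab))) dim(Ab) <- c(Sq, Sk)
        dA <- g[, , h, b]; if (is.null(dim(dA))) dim(dA) <- c(Sq, Sk)
        dS <- softmax_back(dA, Ab) * scale
        dQ[rq, cols] <- dQ[rq, cols] + dS %*% Kv[rk, cols, drop = FALSE]
        dK[rk, cols] <- dK[rk, cols] + crossprod(dS, Qv[rq, cols, drop = FALSE])
      }
    }
    list(dQ, dK)
  })
  list(ctx = ctx_node, attn = attn_node)
}

# ---- losses -----------------------------------------------------------------

# Mean cross-entropy over rows of a logits matrix against integer class
# targets (1-based). Numerically stable log-sum-exp.
ag_cross_entropy <- function(logits, targets) {
  Lv <- ag_value(logits)
  targets <- as.integer(targets)
  stopifnot(nrow(Lv) == length(targets))
  n <- nrow(Lv)
  m <- apply(Lv, 1L, max)
  lse <- m + log(rowSums(exp(Lv - m)))
  picked <- Lv[cbind(seq_len(n), targets)]
  val <- mean(lse - picked)
  .ag_op(val, list(logits), function(g) {
    P <- exp(Lv - lse)  # row-softmax
    P[cbind(seq_len(n), targets)] <- P[cbind(seq_len(n), targets)] - 1
    list(g * P / n)
  })
}

# Mean squared error between two equally-shaped arrays.
ag_mse <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  stopifnot(length(av) == length(bv))
  diff <- av - bv
  val <- mean(diff * diff)
  .ag_op(val, list(a, b), function(g) {
    d <- g * 2 * diff / length(diff)
    list(d, -d)
  })
}

# Sum a list of scalars (plain numbers or scalar nodes).
ag_sum_scalars <- function(xs) {
  val <- sum(vapply(xs, function(x) as.numeric(ag_value(x)), numeric(1)))
  .ag_op(val, xs, function(g) rep(list(g), length(xs)))
}
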