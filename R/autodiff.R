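# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every intermediate quantity is a node (an environment) holding its value, a
# list of parent nodes and a backward function mapping the gradient of the
# loss w.r.t. this node onto gradients w.r.t. the parents. Nodes are recorded
# on a tape in creation order; ad_backward() sweeps the tape in reverse.
# Values are numeric matrices throughout (scalars are 1x1 matrices), so the
# per-op R overhead is amortized over whole-matrix BLAS calls.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Leaves. Constants never receive gradients; leaves (parameters and inputs
# that need gradients) do.
ad_leaf <- function(tape, value) {
  ad_node(tape, as_matrix2(value))
}

ad_const <- function(tape, value) {
  nd <- ad_node(tape, as_matrix2(value))
  nd$is_const <- TRUE
  nd
}

as_matrix2 <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (isTRUE(p$is_const) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

## -- elementary operations ---------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_div <- function(tape, a, b) {
  ad_node(tape, a$value / b$value, list(a, b), function(g) {
    list(g / b$value, -g * a$value / (b$value^2))
  })
}

# add a 1 x m bias row to every row of a (n x m)
ad_bias <- function(tape, a, b) {
  ad_node(tape, sweep(a$value, 2L, as.numeric(b$value), "+"), list(a, b),
    function(g) {
      list(g, matrix(colSums(g), 1L))
    })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) list(g * k))
}

ad_shift <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(g) list(g))
}

ad_neg <- function(tape, a) ad_scale(tape, a, -1)

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_node(tape, v, list(a), function(g) list(g * v))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), list(a), function(g) list(g / a$value))
}

ad_square <- function(tape, a) {
  ad_node(tape, a$value^2, list(a), function(g) list(2 * g * a$value))
}

ad_softplus <- function(tape, a) {
  x <- a$value
  v <- pmax(x, 0) + log1p(exp(-abs(x)))
  ad_node(tape, v, list(a), function(g) list(g * stats::plogis(x)))
}

ad_sigmoid <- function(tape, a) {
  v <- stats::plogis(a$value)
  ad_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_lgamma <- function(tape, a) {
  ad_node(tape, lgamma(a$value), list(a), function(g) list(g * digamma(a$value)))
}

ad_sum <- function(tape, a) {
  dm <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    matrix_g <- matrix(as.numeric(g), dm[1L], dm[2L])
    list(matrix_g)
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) list(t(g)))
}

# select columns idx of a
ad_cols <- function(tape, a, idx) {
  dm <- dim(a$value)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    full <- matrix(0, dm[1L], dm[2L])
    full[, idx] <- full[, idx] + g
    list(full)
  })
}

# multiply every column of a (n x m) by the column vector b (n x 1)
ad_mul_col <- function(tape, a, b) {
  bv <- as.numeric(b$value)
  ad_node(tape, a$value * bv, list(a, b), function(g) {
    list(g * bv, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

# row-wise softmax over columns
ad_softmax_rows <- function(tape, a) {
  x <- a$value
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

## -- composite helpers -------------------------------------------------------

ad_activation <- function(tape, a, act) {
  switch(act,
    tanh = ad_tanh(tape, a),
    softplus = ad_softplus(tape, a),
    identity = a,
    stop("unknown activation: ", act)
  )
}

# affine layer then activation; layer is list(W, b) of plain matrices which
# are wrapped as leaves and recorded in `params` (an environment collecting
# leaf nodes keyed by path) for gradient extraction.
ad_dense <- function(tape, x, layer_nodes, act) {
  h <- ad_bias(tape, ad_mm(tape, x, layer_nodes$W), layer_nodes$b)
  ad_activation(tape, h, act)
}

# strictly positive head: softplus with a small floor
ad_positive <- function(tape, a, floor = 1e-4) {
  ad_shift(tape, ad_softplus(tape, a), floor)
}
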