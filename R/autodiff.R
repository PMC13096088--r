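# Tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a base-R numeric matrix (scalars are 1x1).
# Nodes are environments holding $value, $grad, and a $backward closure that
# scatters the node's gradient into its parents. ag_backward() walks the tape
# in reverse creation order, so the graph must be built by a single forward
# pass (no in-place mutation of node values afterwards).
#
# The op set is exactly what the dual-branch network needs: matmul,
# broadcast add/mul, sigmoid/relu, row softmax, row layer-normalisation,
# row/column reductions, gathers (used for window partitioning, im2col
# convolution and head slicing) and a few scalar helpers for the losses.

#' @keywords internal
ag_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- vector("list", 512L)
  ctx$n <- 0L
  ctx$params <- new.env(parent = emptyenv())
  ctx
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

ag_node <- function(ctx, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$tape)) {
    ctx$tape <- c(ctx$tape, vector("list", length(ctx$tape)))
  }
  ctx$tape[[ctx$n]] <- nd
  nd
}

ag_const <- function(ctx, value) ag_node(ctx, as_mat(value))

# Parameters are cached by name so that reuse across frames/stages accumulates
# gradient on a single node.
ag_param <- function(ctx, value, name) {
  if (!is.null(ctx$params[[name]])) return(ctx$params[[name]])
  nd <- ag_node(ctx, as_mat(value))
  nd$is_param <- TRUE
  ctx$params[[name]] <- nd
  nd
}

ag_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(ctx, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(ctx$n, 1L)) {
    nd <- ctx$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ag_grads <- function(ctx) {
  out <- list()
  for (nm in ls(ctx$params)) {
    nd <- ctx$params[[nm]]
    out[[nm]] <- if (is.null(nd$grad)) {
      matrix(0, nrow(nd$value), ncol(nd$value))
    } else nd$grad
  }
  out
}

# --- broadcasting helpers -----------------------------------------------

# Supported shapes for elementwise binary ops with A an n x c matrix:
# B same shape, B 1 x c (row broadcast), B n x 1 (col broadcast), B 1 x 1.
bc_expand <- function(B, n, c) {
  if (nrow(B) == n && ncol(B) == c) return(B)
  if (nrow(B) == 1L && ncol(B) == c) return(matrix(B, n, c, byrow = TRUE))
  if (nrow(B) == n && ncol(B) == 1L) return(matrix(B, n, c))
  if (length(B) == 1L) return(matrix(B[1L], n, c))
  stop("incompatible shapes for broadcast: ", nrow(B), "x", ncol(B),
       " vs ", n, "x", c)
}

# Reduce a full-shape gradient back to the broadcast operand's shape.
bc_reduce <- function(G, nr, nc) {
  if (nrow(G) == nr && ncol(G) == nc) return(G)
  if (nr == 1L && nc == ncol(G)) return(matrix(colSums(G), 1L, nc))
  if (nr == nrow(G) && nc == 1L) return(matrix(rowSums(G), nr, 1L))
  if (nr == 1L && nc == 1L) return(matrix(sum(G), 1L, 1L))
  stop("cannot reduce gradient")
}

# --- core ops ------------------------------------------------------------

ag_matmul <- function(ctx, a, b) {
  v <- a$value %*% b$value
  ag_node(ctx, v, backward = function(g) {
    ag_accum(a, g %*% t(b$value))
    ag_accum(b, t(a$value) %*% g)
  })
}

ag_add <- function(ctx, a, b) {
  n <- nrow(a$value); c <- ncol(a$value)
  v <- a$value + bc_expand(b$value, n, c)
  ag_node(ctx, v, backward = function(g) {
    ag_accum(a, g)
    ag_accum(b, bc_reduce(g, nrow(b$value), ncol(b$value)))
  })
}

ag_sub <- function(ctx, a, b) ag_add(ctx, a, ag_scale(ctx, b, -1))

ag_mul <- function(ctx, a, b) {
  n <- nrow(a$value); c <- ncol(a$value)
  Bf <- bc_expand(b$value, n, c)
  v <- a$value * Bf
  ag_node(ctx, v, backward = function(g) {
    ag_accum(a, g * Bf)
    ag_accum(b, bc_reduce(g * a$value, nrow(b$value), ncol(b$value)))
  })
}

ag_div <- function(ctx, a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  v <- a$value / b$value
  ag_node(ctx, v, backward = function(g) {
    ag_accum(a, g / b$value)
    ag_accum(b, -g * a$value / (b$value^2))
  })
}

ag_scale <- function(ctx, a, k) {
  ag_node(ctx, a$value * k, backward = function(g) ag_accum(a, g * k))
}

ag_cadd <- function(ctx, a, k) {
  ag_node(ctx, a$value + k, backward = function(g) ag_accum(a, g))
}

ag_sigmoid <- function(ctx, a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(ctx, s, backward = function(g) ag_accum(a, g * s * (1 - s)))
}

ag_relu <- function(ctx, a) {
  m <- a$value > 0
  ag_node(ctx, a$value * m, backward = function(g) ag_accum(a, g * m))
}

ag_sqrt <- function(ctx, a) {
  s <- sqrt(a$value)
  ag_node(ctx, s, backward = function(g) ag_accum(a, g * 0.5 / s))
}

# log with a floor: gradient is zero below the floor.
ag_logclamp <- function(ctx, a, eps = 1e-8) {
  cl <- pmax(a$value, eps)
  ag_node(ctx, log(cl), backward = function(g) {
    ag_accum(a, ifelse(a$value > eps, g / a$value, 0))
  })
}

ag_softmax_rows <- function(ctx, a) {
  x <- a$value
  rm <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  x <- x - rm
  e <- exp(x)
  p <- e / rowSums(e)
  ag_node(ctx, p, backward = function(g) {
    ag_accum(a, p * (g - rowSums(g * p)))
  })
}

# Row-wise standardisation (layer-norm core, population variance).
ag_rownorm <- function(ctx, a, eps = 1e-5) {
  x <- a$value
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  ag_node(ctx, xhat, backward = function(g) {
    gm <- rowMeans(g)
    gx <- rowMeans(g * xhat)
    ag_accum(a, inv * (g - gm - xhat * gx))
  })
}

ag_mean_rows <- function(ctx, a) {   # n x c -> 1 x c
  n <- nrow(a$value)
  ag_node(ctx, matrix(colMeans(a$value), 1L), backward = function(g) {
    ag_accum(a, matrix(g, n, ncol(a$value), byrow = TRUE) / n)
  })
}

ag_max_rows <- function(ctx, a) {    # n x c -> 1 x c (per-column max)
  x <- a$value
  idx <- max.col(t(x), ties.method = "first")  # argmax row per column
  v <- x[cbind(idx, seq_len(ncol(x)))]
  ag_node(ctx, matrix(v, 1L), backward = function(g) {
    G <- matrix(0, nrow(x), ncol(x))
    G[cbind(idx, seq_len(ncol(x)))] <- g
    ag_accum(a, G)
  })
}

ag_rowmeans <- function(ctx, a) {    # n x c -> n x 1
  c <- ncol(a$value)
  ag_node(ctx, matrix(rowMeans(a$value), ncol = 1L), backward = function(g) {
    ag_accum(a, matrix(g, nrow(a$value), c) / c)
  })
}

ag_rowmax <- function(ctx, a) {      # n x c -> n x 1
  x <- a$value
  idx <- max.col(x, ties.method = "first")
  ag_node(ctx, matrix(x[cbind(seq_len(nrow(x)), idx)], ncol = 1L),
          backward = function(g) {
            G <- matrix(0, nrow(x), ncol(x))
            G[cbind(seq_len(nrow(x)), idx)] <- g
            ag_accum(a, G)
          })
}

ag_sum <- function(ctx, a) {
  ag_node(ctx, matrix(sum(a$value), 1L, 1L), backward = function(g) {
    ag_accum(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ag_mean_all <- function(ctx, a) {
  n <- length(a$value)
  ag_node(ctx, matrix(mean(a$value), 1L, 1L), backward = function(g) {
    ag_accum(a, matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

# Row gather; idx entries of 0 yield zero rows (used for conv zero-padding).
ag_gather_rows <- function(ctx, a, idx) {
  x <- a$value
  v <- matrix(0, length(idx), ncol(x))
  pos <- which(idx > 0L)
  v[pos, ] <- x[idx[pos], , drop = FALSE]
  ag_node(ctx, v, backward = function(g) {
    G <- matrix(0, nrow(x), ncol(x))
    if (length(pos)) {
      gr <- rowsum(g[pos, , drop = FALSE], group = idx[pos])
      rows <- as.integer(rownames(gr))
      G[rows, ] <- G[rows, ] + gr
    }
    ag_accum(a, G)
  })
}

ag_gather_cols <- function(ctx, a, idx) {
  x <- a$value
  ag_node(ctx, x[, idx, drop = FALSE], backward = function(g) {
    G <- matrix(0, nrow(x), ncol(x))
    G[, idx] <- G[, idx] + g
    ag_accum(a, G)
  })
}

ag_transpose <- function(ctx, a) {
  ag_node(ctx, t(a$value), backward = function(g) ag_accum(a, t(g)))
}

ag_cbind <- function(ctx, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1L))
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(ctx, v, backward = function(g) {
    for (i in seq_along(nodes)) {
      ag_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ag_rbind <- function(ctx, nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), integer(1L))
  v <- do.call(rbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(ctx, v, backward = function(g) {
    for (i in seq_along(nodes)) {
      ag_accum(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}
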