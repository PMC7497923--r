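# Minimal reverse-mode autodiff over dense numeric arrays.
#
# Nodes are environments holding a value and, when they participate in a
# differentiated graph, their parents and a vector-Jacobian product
# closure. Nodes are recorded on a tape in creation order (a valid
# topological order), and ag_backward() sweeps the tape in reverse.
# Constants short-circuit: an op whose parents are all constants returns
# a constant, so evaluation without gradients carries no tape overhead.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L

ag_tape_begin <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_clear <- function() {
  .ag$tape <- list()
  .ag$n <- 0L
  invisible(NULL)
}

ag_record <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", n))
  .ag$tape[[n]] <- node
  .ag$n <- n
  invisible(NULL)
}

ag_const <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$req <- FALSE
  n$grad <- NULL
  n
}

ag_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$req <- TRUE
  n$grad <- NULL
  n$parents <- NULL
  n$vjp <- NULL
  ag_record(n)
  n
}

# Generic op constructor: value already computed; vjp(g) returns a list
# of gradients aligned with parents (NULL entries allowed).
ag_op <- function(value, parents, vjp) {
  req <- FALSE
  for (p in parents) if (p$req) { req <- TRUE; break }
  if (!req) return(ag_const(value))
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$req <- TRUE
  n$grad <- NULL
  n$parents <- parents
  n$vjp <- vjp
  ag_record(n)
  n
}

ag_value <- function(node) node$value

# Reverse sweep from a scalar root. Parameter gradients are left on the
# ag_param nodes (field $grad); intermediate grads are freed as used.
ag_backward <- function(root) {
  if (!root$req) stop("root does not depend on any parameter")
  root$grad <- 1
  for (i in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (!p$req) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL
  }
  invisible(NULL)
}

# ------------------------------------------------------- elementwise ops

ag_add <- function(a, b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))

ag_addn <- function(nodes) {
  v <- nodes[[1]]$value
  for (i in seq_along(nodes)[-1]) v <- v + nodes[[i]]$value
  k <- length(nodes)
  ag_op(v, nodes, function(g) rep(list(g), k))
}

ag_sub <- function(a, b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_smul <- function(a, s)
  ag_op(a$value * s, list(a), function(g) list(g * s))

ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av / bv, list(a, b),
        function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_exp <- function(a) {
  v <- exp(a$value)
  ag_op(v, list(a), function(g) list(g * v))
}

ag_relu <- function(a) {
  v <- a$value
  pos <- v > 0
  v[!pos] <- 0
  ag_op(v, list(a), function(g) list(g * pos))
}

ag_tanh_scale <- function(a, s) {
  t <- tanh(a$value)
  ag_op(s * t, list(a), function(g) list(g * s * (1 - t * t)))
}

ag_clampmin <- function(a, lo) {
  v <- a$value
  open <- v > lo
  v[!open] <- lo
  ag_op(v, list(a), function(g) list(g * open))
}

# --------------------------------------------------------- scalar losses

ag_meanabs <- function(a, b) {
  d <- a$value - b$value
  n <- length(d)
  ag_op(sum(abs(d)) / n, list(a, b), function(g) {
    s <- sign(d) * (g / n)
    list(s, -s)
  })
}

# sum(x^2) / denom
ag_sumsq <- function(a, denom) {
  v <- a$value
  ag_op(sum(v * v) / denom, list(a),
        function(g) list((2 * g / denom) * v))
}

# Weighted sum of scalar nodes.
ag_wsum <- function(nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$value
  ag_op(v, nodes, function(g)
    lapply(seq_along(nodes), function(i) g * weights[i]))
}

# ------------------------------------------------------- structured ops

ag_conv3d <- function(x, w, b, stride, pad) {
  v <- cpp_conv3d_fw(x$value, w$value, b$value, stride, pad)
  xv <- x$value; wv <- w$value
  need_gx <- x$req
  ag_op(v, list(x, w, b), function(g) {
    bw <- cpp_conv3d_bw(xv, wv, g, stride, pad, need_gx)
    list(if (need_gx) bw$gx else NULL, bw$gw, bw$gb)
  })
}

ag_instnorm <- function(x, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  nc <- d[4]
  nsp <- prod(d[1:3])
  xm <- matrix(xv, nsp, nc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  isd <- 1 / sqrt(va + eps)
  yh <- sweep(xc, 2, isd, `*`)
  y <- array(yh, d)
  ag_op(y, list(x), function(g) {
    gm <- matrix(g, nsp, nc)
    t1 <- colMeans(gm)
    t2 <- colMeans(gm * yh)
    gx <- sweep(gm - rep(t1, each = nsp) - yh * rep(t2, each = nsp),
                2, isd, `*`)
    list(array(gx, d))
  })
}

ag_upsample <- function(x, factor) {
  ag_op(cpp_upsample_fw(x$value, factor), list(x),
        function(g) list(cpp_upsample_adj(g, factor)))
}

ag_shift <- function(x, off) {
  ag_op(cpp_shift3d(x$value, off), list(x),
        function(g) list(cpp_shift3d_adj(g, off)))
}

ag_boxsum <- function(x, half) {
  ag_op(cpp_boxsum3d(x$value, half), list(x),
        function(g) list(cpp_boxsum3d_adj(g, half)))
}

# Stack 3D nodes into a 4D array along a new last dimension.
ag_stack4 <- function(nodes) {
  d <- dim(nodes[[1]]$value)
  k <- length(nodes)
  v <- array(0, c(d, k))
  nsp <- prod(d)
  for (i in seq_len(k)) v[(i - 1) * nsp + seq_len(nsp)] <- nodes[[i]]$value
  ag_op(v, nodes, function(g) {
    lapply(seq_len(k), function(i)
      array(g[(i - 1) * nsp + seq_len(nsp)], d))
  })
}

# Extract one channel of a 4D array as a 3D node.
ag_slice4 <- function(x, c) {
  d <- dim(x$value)
  nsp <- prod(d[1:3])
  v <- array(x$value[(c - 1) * nsp + seq_len(nsp)], d[1:3])
  k <- d[4]
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    gx[(c - 1) * nsp + seq_len(nsp)] <- g
    list(gx)
  })
}

# Concatenate two 3D volumes into a 2-channel 4D array.
ag_concat2 <- function(a, b) {
  d <- dim(a$value)
  v <- array(c(a$value, b$value), c(d, 2L))
  nsp <- prod(d)
  ag_op(v, list(a, b), function(g)
    list(array(g[seq_len(nsp)], d), array(g[nsp + seq_len(nsp)], d)))
}

# y = x / max(x over last dim), per spatial voxel; ties send the
# normalization gradient to the first maximal entry.
ag_norm_max_last <- function(x) {
  xv <- x$value
  d <- dim(xv)
  k <- d[4]
  nsp <- prod(d[1:3])
  xm <- matrix(xv, nsp, k)
  am <- max.col(xm, ties.method = "first")
  m <- xm[cbind(seq_len(nsp), am)]
  y <- xm / m
  ag_op(array(y, d), list(x), function(g) {
    gm <- matrix(g, nsp, k)
    gx <- gm / m
    corr <- -rowSums(gm * xm) / (m * m)
    gx[cbind(seq_len(nsp), am)] <- gx[cbind(seq_len(nsp), am)] + corr
    list(array(gx, d))
  })
}

# Differentiable warp: out(x) = vol(x + f(x)), trilinear, edge clamped.
ag_warp <- function(vol, field) {
  v <- cpp_warp_fw(vol$value, field$value, FALSE)
  vv <- vol$value; fv <- field$value
  need_gv <- vol$req; need_gf <- field$req
  ag_op(v, list(vol, field), function(g) {
    bw <- cpp_warp_bw(vv, fv, g, need_gv, need_gf)
    list(if (need_gv) bw$gv else NULL, if (need_gf) bw$gf else NULL)
  })
}
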