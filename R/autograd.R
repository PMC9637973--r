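# Reverse-mode automatic differentiation on dense R arrays.
#
# The whole network runs on a small define-by-run tape: every operation
# computes its value eagerly and records a backward closure. Feature maps are
# arrays of dimension (channels, height, width, batch); convolutions are
# lowered to BLAS matrix products via im2col. Gradients are checked against
# central finite differences in the test suite.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L
.ag$grad_enabled <- TRUE
.ag$cache <- new.env(parent = emptyenv()) # interpolation matrices keyed by size

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

#' Wrap an array as an autodiff leaf node
#'
#' @param value numeric array (any dimension).
#' @param requires_grad accumulate a gradient for this node during backward?
#' @return an `ag_node` environment with fields `value` and (after backward)
#'   `grad`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- NULL
  node$backfn <- NULL
  node$requires_grad <- requires_grad
  node$id <- ag_next_id()
  class(node) <- "ag_node"
  node
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

# Internal constructor for non-leaf nodes. When gradients are disabled the
# tape is not recorded, so evaluation-mode forwards hold no intermediates.
ag_op <- function(value, parents, backfn) {
  node <- ag_tensor(value)
  if (.ag$grad_enabled) {
    node$parents <- parents
    node$backfn <- backfn
  }
  node
}

#' Evaluate an expression without recording the autodiff tape
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

ag_accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Backpropagate from a node
#'
#' Runs reverse-mode accumulation from `root` (usually a scalar loss).
#' Gradients end up in the `grad` field of every node with
#' `requires_grad = TRUE` that participated in the graph.
#' @keywords internal
ag_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = dim(root$value) %||% length(root$value))
  # iterative DFS post-order: children before parents in `order`
  order <- vector("list", 64L)
  norder <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$expanded) {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- nd
    } else if (is.null(visited[[key]])) {
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, expanded = TRUE)
      for (p in nd$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
        }
      }
    }
  }
  ag_accumulate(root, grad)
  for (i in seq_len(norder)) {
    nd <- order[[norder - i + 1L]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    pg <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(pg[[j]])) ag_accumulate(nd$parents[[j]], pg[[j]])
    }
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise ----

ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, k) {
  ag_op(a$value * k, list(a), function(g) list(g * k))
}

ag_relu <- function(a) {
  v <- a$value
  keep <- v > 0
  ag_op(v * keep, list(a), function(g) list(g * keep))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

# per-channel bias over an array whose first dimension is channels
ag_addbias <- function(x, b) {
  xv <- x$value
  cdim <- dim(xv)[1]
  ag_op(xv + as.vector(b$value), list(x, b), function(g) {
    list(g, rowSums(matrix(g, nrow = cdim)))
  })
}

ag_reshape <- function(x, new_dim) {
  old <- dim(x$value)
  v <- x$value
  dim(v) <- new_dim
  ag_op(v, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

# ---- dense linear algebra ----

# x: (d, n) matrix; W: (k, d); b: length-k vector or NULL
ag_linear <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  out <- Wv %*% xv
  if (!is.null(b)) {
    out <- out + as.vector(b$value)
    ag_op(out, list(x, W, b), function(g) {
      list(crossprod(Wv, g), tcrossprod(g, xv), rowSums(g))
    })
  } else {
    ag_op(out, list(x, W), function(g) {
      list(crossprod(Wv, g), tcrossprod(g, xv))
    })
  }
}

# batched matrix multiply on (p, q, n) arrays, optional transposes
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- a$value; bv <- b$value
  da_ <- dim(av); db_ <- dim(bv)
  n <- da_[3]
  slice <- function(x, d, i) matrix(x[, , i], d[1], d[2])
  f <- function(i) {
    A <- slice(av, da_, i); B <- slice(bv, db_, i)
    if (ta) A <- t(A)
    if (tb) B <- t(B)
    A %*% B
  }
  first <- f(1)
  out <- array(0, c(nrow(first), ncol(first), n))
  out[, , 1] <- first
  if (n > 1) for (i in 2:n) out[, , i] <- f(i)
  ag_op(out, list(a, b), function(g) {
    da <- array(0, da_); db <- array(0, db_)
    for (i in seq_len(n)) {
      G <- matrix(g[, , i], dim(g)[1], dim(g)[2])
      A <- slice(av, da_, i); B <- slice(bv, db_, i)
      Ae <- if (ta) t(A) else A
      Be <- if (tb) t(B) else B
      dAe <- tcrossprod(G, Be)
      dBe <- crossprod(Ae, G)
      da[, , i] <- if (ta) t(dAe) else dAe
      db[, , i] <- if (tb) t(dBe) else dBe
    }
    list(da, db)
  })
}

# row-wise softmax over the second dimension of a (p, q, n) array
ag_softmax_rows <- function(x) {
  xv <- x$value
  d <- dim(xv)
  v <- array(0, d)
  for (i in seq_len(d[3])) {
    m <- xv[, , i, drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, d[1], d[2])
    m <- m - apply(m, 1, max)
    e <- exp(m)
    v[, , i] <- e / rowSums(e)
  }
  ag_op(v, list(x), function(g) {
    dx <- array(0, d)
    for (i in seq_len(d[3])) {
      gi <- g[, , i, drop = TRUE]; vi <- v[, , i, drop = TRUE]
      if (!is.matrix(gi)) gi <- matrix(gi, d[1], d[2])
      if (!is.matrix(vi)) vi <- matrix(vi, d[1], d[2])
      dx[, , i] <- vi * (gi - rowSums(gi * vi))
    }
    list(dx)
  })
}

# ---- convolution ----

# zero padding of (c, h, w, n)
pad_chwn <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

conv_out_len <- function(len, k, stride, dilation, pad) {
  (len + 2 * pad - ((k - 1) * dilation + 1)) %/% stride + 1
}

#' 2-D convolution (im2col + BLAS)
#'
#' @param x `ag_node` with value (cin, h, w, n).
#' @param W `ag_node` with value (cout, cin, kh, kw).
#' @param b `ag_node` bias of length cout, or NULL.
#' @param stride,dilation,pad integers; `pad = "same"` keeps the spatial size
#'   for stride 1 (pad = dilation * (k - 1) / 2, odd kernels).
#' @keywords internal
ag_conv2d <- function(x, W, b = NULL, stride = 1L, dilation = 1L, pad = "same") {
  xv <- x$value; Wv <- W$value
  dw <- dim(Wv)
  cout <- dw[1]; cin <- dw[2]; kh <- dw[3]; kw <- dw[4]
  if (identical(pad, "same")) pad <- dilation * (kh - 1L) %/% 2L
  d <- dim(xv)
  stopifnot(d[1] == cin)
  oh <- conv_out_len(d[2], kh, stride, dilation, pad)
  ow <- conv_out_len(d[3], kw, stride, dilation, pad)
  if (oh < 1 || ow < 1) stop("convolution output would be empty: kernel/dilation too large for input")
  n <- d[4]
  xp <- pad_chwn(xv, pad)
  col <- array(0, c(cin, kh, kw, oh, ow, n))
  for (ki in seq_len(kh)) {
    ri <- (0:(oh - 1)) * stride + (ki - 1) * dilation + 1
    for (kj in seq_len(kw)) {
      ci <- (0:(ow - 1)) * stride + (kj - 1) * dilation + 1
      col[, ki, kj, , , ] <- xp[, ri, ci, , drop = FALSE]
    }
  }
  Colm <- matrix(col, nrow = cin * kh * kw)
  Wm <- matrix(Wv, nrow = cout)
  out <- Wm %*% Colm
  if (!is.null(b)) out <- out + as.vector(b$value)
  dim(out) <- c(cout, oh, ow, n)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, parents, function(g) {
    gm <- matrix(g, nrow = cout)
    dW <- tcrossprod(gm, Colm)
    dim(dW) <- dw
    dCol <- crossprod(Wm, gm)
    dim(dCol) <- c(cin, kh, kw, oh, ow, n)
    dxp <- array(0, dim(xp))
    for (ki in seq_len(kh)) {
      ri <- (0:(oh - 1)) * stride + (ki - 1) * dilation + 1
      for (kj in seq_len(kw)) {
        ci <- (0:(ow - 1)) * stride + (kj - 1) * dilation + 1
        dxp[, ri, ci, ] <- dxp[, ri, ci, ] + dCol[, ki, kj, , , ]
      }
    }
    dx <- if (pad > 0) {
      dxp[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3]), , drop = FALSE]
    } else dxp
    if (is.null(b)) list(dx, dW) else list(dx, dW, rowSums(gm))
  })
}

# ---- resizing ----

# half-pixel-centre linear interpolation matrix (out_len x in_len)
interp_matrix <- function(in_len, out_len) {
  key <- paste0("ip_", in_len, "_", out_len)
  m <- .ag$cache[[key]]
  if (!is.null(m)) return(m)
  m <- matrix(0, out_len, in_len)
  if (in_len == 1L) {
    m[, 1] <- 1
  } else {
    src <- ((seq_len(out_len) - 0.5) * in_len / out_len) - 0.5
    src <- pmin(pmax(src, 0), in_len - 1)
    i0 <- floor(src)
    fr <- src - i0
    for (i in seq_len(out_len)) {
      lo <- i0[i] + 1
      hi <- min(lo + 1, in_len)
      m[i, lo] <- m[i, lo] + (1 - fr[i])
      m[i, hi] <- m[i, hi] + fr[i]
    }
  }
  .ag$cache[[key]] <- m
  m
}

# apply matrix R along dimension k (2 or 3) of a (c, h, w, n) array
apply_along <- function(x, R, k) {
  d <- dim(x)
  perm <- switch(k - 1L, c(2, 1, 3, 4), c(3, 1, 2, 4))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- R %*% matrix(xp, nrow = dp[1])
  dim(y) <- c(nrow(R), dp[2], dp[3], dp[4])
  aperm(y, switch(k - 1L, c(2, 1, 3, 4), c(2, 3, 1, 4)))
}

#' Bilinear resize of a (c, h, w, n) feature block
#' @keywords internal
ag_resize_bilinear <- function(x, oh, ow) {
  xv <- x$value
  d <- dim(xv)
  if (d[2] == oh && d[3] == ow) return(x)
  Rh <- interp_matrix(d[2], oh)
  Rw <- interp_matrix(d[3], ow)
  v <- apply_along(apply_along(xv, Rh, 2L), Rw, 3L)
  ag_op(v, list(x), function(g) {
    list(apply_along(apply_along(g, t(Rw), 3L), t(Rh), 2L))
  })
}

# ---- pooling / gating ----

# global average pool: (c, h, w, n) -> (c, n)
ag_gap <- function(x) {
  xv <- x$value
  d <- dim(xv)
  hw <- d[2] * d[3]
  xm <- xv
  dim(xm) <- c(d[1], hw, d[4])
  v <- apply(xm, 3, rowMeans)
  if (!is.matrix(v)) v <- matrix(v, d[1], d[4])
  ag_op(v, list(x), function(g) {
    # g is (c, n); spread evenly over the h*w positions
    dx <- aperm(array(g / hw, c(d[1], d[4], hw)), c(1, 3, 2))
    dim(dx) <- d
    list(dx)
  })
}

# multiply channel c of x (c, h, w, n) by v[c, n]
ag_channel_scale <- function(x, v) {
  xv <- x$value; vv <- v$value
  d <- dim(xv)
  hw <- d[2] * d[3]
  vexp <- aperm(array(vv, c(d[1], d[4], hw)), c(1, 3, 2))
  dim(vexp) <- d
  ag_op(xv * vexp, list(x, v), function(g) {
    gx <- g * xv
    dim(gx) <- c(d[1], hw, d[4])
    dv <- apply(gx, 3, rowSums)
    if (!is.matrix(dv)) dv <- matrix(dv, d[1], d[4])
    list(g * vexp, dv)
  })
}

# concatenate along the channel (first) dimension
ag_concat_c <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  total <- sum(cs)
  out <- array(0, c(total, d1[2], d1[3], d1[4]))
  at <- 0L
  for (v in vals) {
    cc <- dim(v)[1]
    out[(at + 1):(at + cc), , , ] <- v
    at <- at + cc
  }
  ag_op(out, nodes, function(g) {
    res <- vector("list", length(nodes))
    at <- 0L
    for (j in seq_along(nodes)) {
      res[[j]] <- g[(at + 1):(at + cs[j]), , , , drop = FALSE]
      at <- at + cs[j]
    }
    res
  })
}

# ---- loss ----

#' Numerically stable binary cross-entropy from logits (mean over elements)
#' @keywords internal
ag_bce_logits <- function(z, y) {
  zv <- z$value
  n <- length(zv)
  # softplus(z) - z*y, with softplus(z) = max(z,0) + log1p(exp(-|z|))
  val <- sum(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv)))) / n
  ag_op(val, list(z), function(g) {
    s <- 1 / (1 + exp(-zv))
    list(array(as.numeric(g) * (s - y) / n, dim(zv)))
  })
}
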