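# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is an `ag_node`: an environment holding the
# forward value, accumulated gradient, parent nodes and a backward closure.
# Ops append nodes to a tape; ag_backward() walks the tape in reverse. When
# called on plain matrices (no tape), every op degrades to a fast pure
# evaluation - the same code paths serve training and inference.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

is_node <- function(x) inherits(x, "ag_node")

ag_val <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, tape, parents = list(), backward = NULL,
                     param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  class(nd) <- "ag_node"
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# leaf node for a trainable parameter (matrix) identified by name
ag_param <- function(value, name, tape) {
  new_node(value, tape, param = name)
}

accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# ---- ops ------------------------------------------------------------------

# X %*% W
ag_mm <- function(x, w, tape = NULL) {
  v <- ag_val(x) %*% ag_val(w)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, w), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, tcrossprod(g, ag_val(w)))
    if (is_node(w)) accum(w, crossprod(ag_val(x), g))
  })
}

# add a row vector (bias) to every row
ag_addrow <- function(x, b, tape = NULL) {
  xv <- ag_val(x)
  v <- sweep(xv, 2, as.vector(ag_val(b)), "+")
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, b), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, g)
    if (is_node(b)) accum(b, matrix(colSums(g), nrow = 1))
  })
}

ag_add <- function(x, y, tape = NULL) {
  v <- ag_val(x) + ag_val(y)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, y), function(self) {
    if (is_node(x)) accum(x, self$grad)
    if (is_node(y)) accum(y, self$grad)
  })
}

ag_mul <- function(x, y, tape = NULL) {
  xv <- ag_val(x); yv <- ag_val(y)
  v <- xv * yv
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, y), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, g * yv)
    if (is_node(y)) accum(y, g * xv)
  })
}

ag_scale <- function(x, a, tape = NULL) {
  v <- ag_val(x) * a
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * a)
  })
}

ag_relu <- function(x, tape = NULL) {
  xv <- ag_val(x)
  v <- xv * (xv > 0)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * (xv > 0))
  })
}

# numerically stable softplus log(1 + exp(x))
softplus_mat <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

ag_softplus <- function(x, tape = NULL) {
  xv <- ag_val(x)
  v <- softplus_mat(xv)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * stats::plogis(xv))
  })
}

# per-row root-mean-square of a B x n matrix -> B x 1 (plus eps)
ag_row_rms <- function(x, tape = NULL, eps = 1e-9) {
  xv <- ag_val(x)
  n <- ncol(xv)
  v <- matrix(sqrt(rowMeans(xv^2)) + eps, ncol = 1)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    g <- self$grad
    if (is_node(x))
      accum(x, (as.vector(g) / (n * (as.vector(v) - eps + 1e-300))) * xv)
  })
}

# divide each row of x by the per-row scalar s (B x 1)
ag_rowdiv <- function(x, s, tape = NULL) {
  xv <- ag_val(x); sv <- as.vector(ag_val(s))
  v <- xv / sv
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, s), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, g / sv)
    if (is_node(s))
      accum(s, matrix(-rowSums(g * xv) / sv^2, ncol = 1))
  })
}

# row-wise softmax over columns
ag_rowsoftmax <- function(x, tape = NULL) {
  xv <- ag_val(x)
  e <- exp(xv - apply(xv, 1, max))
  v <- e / rowSums(e)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, v * (g - rowSums(g * v)))
  })
}

# multiply each row of x by the per-row scalar s (B x 1)
ag_rowmul <- function(x, s, tape = NULL) {
  xv <- ag_val(x); sv <- as.vector(ag_val(s))
  v <- xv * sv
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, s), function(self) {
    g <- self$grad
    if (is_node(x)) accum(x, g * sv)
    if (is_node(s)) accum(s, matrix(rowSums(g * xv), ncol = 1))
  })
}

ag_log <- function(x, tape = NULL) {
  xv <- ag_val(x)
  v <- log(xv)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad / xv)
  })
}

# |x|: non-negativity rectification whose gradient never vanishes (the
# terminal map of the inverse operator; softplus's exponential tail can
# trap the decoder in a zero-output state under sparse L1 gradients)
ag_abs <- function(x, tape = NULL) {
  xv <- ag_val(x)
  v <- abs(xv)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * sign(xv))
  })
}

# a * asinh(x): the compressive scaling applied to perturbation inputs
ag_asinh_scale <- function(x, a, tape = NULL) {
  xv <- ag_val(x)
  v <- asinh(xv) * a
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * a / sqrt(1 + xv^2))
  })
}

# B x 252 perturbation rows -> (B*126) x 2 channel tokens (re, im),
# batch-grouped rows as ag_attention expects
ag_usc_tokens <- function(x, tape = NULL) {
  xv <- ag_val(x)
  b <- nrow(xv)
  v <- cbind(as.vector(t(xv[, 1:126, drop = FALSE])),
             as.vector(t(xv[, 127:252, drop = FALSE])))
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    g <- self$grad
    gx <- cbind(t(matrix(g[, 1], 126, b)), t(matrix(g[, 2], 126, b)))
    if (is_node(x)) accum(x, gx)
  })
}

ag_tanh <- function(x, tape = NULL) {
  v <- tanh(ag_val(x))
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x)) accum(x, self$grad * (1 - v^2))
  })
}

# column-wise concatenation
ag_cbind <- function(xs, tape = NULL) {
  vals <- lapply(xs, ag_val)
  v <- do.call(cbind, vals)
  if (is.null(tape)) return(v)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(v, tape, xs, function(self) {
    g <- self$grad
    for (i in seq_along(xs)) {
      if (is_node(xs[[i]]))
        accum(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# mean(weights * |x - target|): the weighted L1 losses of the training
# objectives in one op. weights/target are constant matrices.
ag_wmae <- function(x, target, weights = NULL, tape = NULL) {
  xv <- ag_val(x)
  d <- xv - target
  w <- if (is.null(weights)) 1 else weights
  v <- mean(w * abs(d))
  if (is.null(tape)) return(v)
  n <- length(d)
  new_node(matrix(v, 1, 1), tape, list(x), function(self) {
    if (is_node(x)) accum(x, as.numeric(self$grad) * w * sign(d) / n)
  })
}

# mean binary cross-entropy with logits: mean(softplus(z) - y * z)
ag_bce_logits <- function(z, y, tape = NULL) {
  zv <- ag_val(z)
  v <- mean(softplus_mat(zv) - y * zv)
  if (is.null(tape)) return(v)
  n <- length(zv)
  new_node(matrix(v, 1, 1), tape, list(z), function(self) {
    if (is_node(z))
      accum(z, as.numeric(self$grad) * (stats::plogis(zv) - y) / n)
  })
}

# scalar node combination a*x + b*y (for loss totals)
ag_axpby <- function(x, y, a = 1, b = 1, tape = NULL) {
  v <- a * ag_val(x) + b * ag_val(y)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x, y), function(self) {
    if (is_node(x)) accum(x, self$grad * a)
    if (is_node(y)) accum(y, self$grad * b)
  })
}

# Batched multi-head scaled dot-product attention.
# q: (B*nq) x d, k, v: (B*nk) x d stacked per batch item; softmax over keys
# within each item and head: softmax(Q K^T / sqrt(dk)) V.
ag_attention <- function(q, k, v, n_batch, n_heads, tape = NULL) {
  qv <- ag_val(q); kv <- ag_val(k); vv <- ag_val(v)
  d <- ncol(qv)
  stopifnot(d %% n_heads == 0)
  dk <- d %/% n_heads
  nq <- nrow(qv) %/% n_batch
  nk <- nrow(kv) %/% n_batch
  out <- matrix(0, nrow(qv), d)
  attn <- vector("list", n_batch * n_heads)
  for (bi in seq_len(n_batch)) {
    qi <- (bi - 1) * nq + seq_len(nq)
    ki <- (bi - 1) * nk + seq_len(nk)
    for (h in seq_len(n_heads)) {
      hc <- (h - 1) * dk + seq_len(dk)
      s <- tcrossprod(qv[qi, hc, drop = FALSE],
                      kv[ki, hc, drop = FALSE]) / sqrt(dk)
      s <- exp(s - apply(s, 1, max))
      a <- s / rowSums(s)
      attn[[(bi - 1) * n_heads + h]] <- a
      out[qi, hc] <- a %*% vv[ki, hc, drop = FALSE]
    }
  }
  if (is.null(tape)) return(out)
  new_node(out, tape, list(q, k, v), function(self) {
    g <- self$grad
    gq <- if (is_node(q)) matrix(0, nrow(qv), d)
    gk <- if (is_node(k)) matrix(0, nrow(kv), d)
    gv <- if (is_node(v)) matrix(0, nrow(kv), d)
    for (bi in seq_len(n_batch)) {
      qi <- (bi - 1) * nq + seq_len(nq)
      ki <- (bi - 1) * nk + seq_len(nk)
      for (h in seq_len(n_heads)) {
        hc <- (h - 1) * dk + seq_len(dk)
        a <- attn[[(bi - 1) * n_heads + h]]
        go <- g[qi, hc, drop = FALSE]
        vb <- vv[ki, hc, drop = FALSE]
        if (!is.null(gv)) gv[ki, hc] <- gv[ki, hc] + crossprod(a, go)
        ga <- tcrossprod(go, vb)
        gs <- a * (ga - rowSums(ga * a))
        if (!is.null(gq))
          gq[qi, hc] <- gq[qi, hc] +
            gs %*% kv[ki, hc, drop = FALSE] / sqrt(dk)
        if (!is.null(gk))
          gk[ki, hc] <- gk[ki, hc] +
            crossprod(gs, qv[qi, hc, drop = FALSE]) / sqrt(dk)
      }
    }
    if (!is.null(gq)) accum(q, gq)
    if (!is.null(gk)) accum(k, gk)
    if (!is.null(gv)) accum(v, gv)
  })
}

# Reshape between the B x (nt*d) feature layout (token t occupies columns
# (t-1)*d+1 .. t*d) and the (B*nt) x d token layout with rows grouped by
# batch item (row (b-1)*nt + t), as ag_attention expects.
ag_to_tokens <- function(x, n_tokens, tape = NULL) {
  xv <- ag_val(x)
  b <- nrow(xv); d <- ncol(xv) %/% n_tokens
  v <- matrix(aperm(array(xv, c(b, d, n_tokens)), c(3, 1, 2)),
              b * n_tokens, d)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    g <- self$grad
    gx <- matrix(aperm(array(g, c(n_tokens, b, d)), c(2, 3, 1)),
                 b, d * n_tokens)
    if (is_node(x)) accum(x, gx)
  })
}

ag_from_tokens <- function(x, n_batch, tape = NULL) {
  xv <- ag_val(x)
  nt <- nrow(xv) %/% n_batch; d <- ncol(xv)
  v <- matrix(aperm(array(xv, c(nt, n_batch, d)), c(2, 3, 1)),
              n_batch, nt * d)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    g <- self$grad
    gx <- matrix(aperm(array(g, c(n_batch, d, nt)), c(3, 1, 2)),
                 n_batch * nt, d)
    if (is_node(x)) accum(x, gx)
  })
}

# ---- backward pass and parameter-gradient collection ----------------------

ag_backward <- function(loss, tape) {
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      g <- nd$grad
      if (is.null(grads[[nd$param]])) grads[[nd$param]] <- g
      else grads[[nd$param]] <- grads[[nd$param]] + g
    }
  }
  grads
}

# Lesion-centric radial-basis expansion: out[b, v] = sum_k a[b, k] *
# phi_k[b, v] with a (B x K) predicted coefficients and phi a list of K
# constant B x V matrices built around each case's mask center. Weight
# sharing across voxels enters through the basis, mirroring the spatial
# inductive bias a convolutional decoder would provide.
ag_radial <- function(a, phi, tape = NULL) {
  av <- ag_val(a)
  v <- radial_forward_cpp(av, phi)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(a), function(self) {
    if (is_node(a)) accum(a, radial_backward_cpp(self$grad, phi))
  })
}

# Fixed separable 3-D Gaussian smoothing applied to each row of a
# B x (nx*ny*nz) matrix (rows are flattened volumes in grid order).
# kernels = list(Kx, Ky, Kz) of per-axis smoothing matrices.
ag_blur_rows <- function(x, dims, kernels, tape = NULL) {
  v <- blur_rows_cpp(ag_val(x), dims[1], dims[2], dims[3],
                     kernels[[1]], kernels[[2]], kernels[[3]], FALSE)
  if (is.null(tape)) return(v)
  new_node(v, tape, list(x), function(self) {
    if (is_node(x))
      accum(x, blur_rows_cpp(self$grad, dims[1], dims[2], dims[3],
                             kernels[[1]], kernels[[2]], kernels[[3]], TRUE))
  })
}

# per-axis smoothing matrix with edge-replicated Gaussian kernel
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-half, half), 1L), n)
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + kern[t]
  }
  K
}

# ---- Adam optimizer -------------------------------------------------------
#
# State and parameters are updated in place through the compiled kernel, so
# the caller must own the parameter matrices exclusively (train() deep-copies
# the bundle's parameters before its first step).

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  class(e) <- "adam_state"
  e
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- grads[[nm]] * 0
      state$v[[nm]] <- grads[[nm]] * 0
    }
    adam_update_inplace(params[[nm]], state$m[[nm]], state$v[[nm]],
                        grads[[nm]], lr, beta1, beta2, eps, bc1, bc2)
  }
  invisible(params)
}

deep_copy_params <- function(params) lapply(params, function(m) m + 0)
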