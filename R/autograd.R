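# Reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment accumulating nodes in creation order; backward()
# walks it in reverse.  Every node value is a numeric matrix (scalars are
# 1x1).  Parameters are long-lived environments that can be replayed onto a
# fresh tape each training step, so optimizer state survives across steps.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = list(), backward = NULL) {
  if (is.null(dim(val))) val <- matrix(val, nrow = 1L)
  id <- tape$n + 1L
  if (id > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$id <- id
  nd$tape <- tape
  tape$nodes[[id]] <- nd
  tape$n <- id
  nd
}

# Constants never receive gradients.
ad_const <- function(tape, val) {
  nd <- ad_node(tape, val)
  nd$is_const <- TRUE
  nd
}

is_ad_node <- function(x) is.environment(x) && !is.null(x$val)

# Coerce a plain matrix argument to a constant node on the same tape as `ref`.
as_node <- function(x, ref) {
  if (is_ad_node(x)) x else ad_const(ref$tape, x)
}

accumulate_grad <- function(node, g) {
  if (isTRUE(node$is_const)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node.
ad_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad, nd)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) accumulate_grad(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

## ---- primitive ops ---------------------------------------------------------

v_add <- function(a, b) {
  b <- as_node(b, a); a <- as_node(a, b)
  ad_node(a$tape, a$val + b$val, list(a, b), function(g, nd) list(g, g))
}

v_sub <- function(a, b) {
  b <- as_node(b, a); a <- as_node(a, b)
  ad_node(a$tape, a$val - b$val, list(a, b), function(g, nd) list(g, -g))
}

# X (n x d) + bias row vector b (1 x d), broadcast over rows.
v_addbias <- function(x, b) {
  ad_node(x$tape, sweep(x$val, 2L, as.numeric(b$val), "+"), list(x, b),
          function(g, nd) list(g, matrix(colSums(g), 1L)))
}

v_mul <- function(a, b) {
  b <- as_node(b, a); a <- as_node(a, b)
  ad_node(a$tape, a$val * b$val, list(a, b),
          function(g, nd) list(g * nd$parents[[2]]$val, g * nd$parents[[1]]$val))
}

v_div <- function(a, b) {
  b <- as_node(b, a); a <- as_node(a, b)
  ad_node(a$tape, a$val / b$val, list(a, b),
          function(g, nd) {
            av <- nd$parents[[1]]$val; bv <- nd$parents[[2]]$val
            list(g / bv, -g * av / (bv * bv))
          })
}

v_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(g, nd) list(g * s))
}

v_mm <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, list(a, b),
          function(g, nd) list(g %*% t(nd$parents[[2]]$val),
                               crossprod(nd$parents[[1]]$val, g)))
}

v_relu <- function(a) {
  ad_node(a$tape, pmax(a$val, 0), list(a),
          function(g, nd) list(g * (nd$parents[[1]]$val > 0)))
}

v_leakyrelu <- function(a, slope = 0.01) {
  v <- a$val
  pos <- v > 0
  ad_node(a$tape, v * (pos + slope * !pos), list(a),
          function(g, nd) list(g * (pos + slope * !pos)))
}

v_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  nd <- ad_node(a$tape, s, list(a), function(g, nd) list(g * nd$val * (1 - nd$val)))
  nd
}

v_silu <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, a$val * s, list(a),
          function(g, nd) {
            x <- nd$parents[[1]]$val
            sg <- 1 / (1 + exp(-x))
            list(g * (sg + x * sg * (1 - sg)))
          })
}

v_abs <- function(a) {
  ad_node(a$tape, abs(a$val), list(a),
          function(g, nd) list(g * sign(nd$parents[[1]]$val)))
}

v_square <- function(a) {
  ad_node(a$tape, a$val^2, list(a), function(g, nd) list(2 * g * nd$parents[[1]]$val))
}

v_sqrt <- function(a) {
  r <- sqrt(a$val)
  nd <- ad_node(a$tape, r, list(a), function(g, nd) list(g / (2 * nd$val)))
  nd
}

v_exp <- function(a) {
  nd <- ad_node(a$tape, exp(a$val), list(a), function(g, nd) list(g * nd$val))
  nd
}

v_sum <- function(a) {
  ad_node(a$tape, matrix(sum(a$val), 1L, 1L), list(a),
          function(g, nd) list(matrix(g[1L], nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))))
}

v_mean <- function(a) {
  n <- length(a$val)
  ad_node(a$tape, matrix(mean(a$val), 1L, 1L), list(a),
          function(g, nd) list(matrix(g[1L] / n, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))))
}

# Select rows (gather); backward scatter-adds into the source.
v_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ad_node(a$tape, a$val[idx, , drop = FALSE], list(a),
          function(g, nd) {
            src <- nd$parents[[1]]$val
            out <- matrix(0, nrow(src), ncol(src))
            acc <- rowsum(g, group = idx, reorder = FALSE)
            out[as.integer(rownames(acc)), ] <- acc
            list(out)
          })
}

# Select columns; backward scatters into the source width.
v_cols <- function(a, idx) {
  idx <- as.integer(idx)
  ad_node(a$tape, a$val[, idx, drop = FALSE], list(a),
          function(g, nd) {
            src <- nd$parents[[1]]$val
            out <- matrix(0, nrow(src), ncol(src))
            out[, idx] <- out[, idx] + g
            list(out)
          })
}

# Sum rows of `a` by group index (scatter-add); groups 1..ngroups.
# Empty groups yield zero rows.
v_rowsum_by <- function(a, idx, ngroups) {
  idx <- as.integer(idx)
  out <- matrix(0, ngroups, ncol(a$val))
  acc <- rowsum(a$val, group = idx, reorder = FALSE)
  out[as.integer(rownames(acc)), ] <- acc
  ad_node(a$tape, out, list(a),
          function(g, nd) list(g[idx, , drop = FALSE]))
}

v_concat_cols <- function(...) {
  args <- list(...)
  widths <- vapply(args, function(x) ncol(x$val), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(args[[1]]$tape, do.call(cbind, lapply(args, function(x) x$val)), args,
          function(g, nd) {
            lapply(seq_along(nd$parents), function(k) g[, starts[k]:ends[k], drop = FALSE])
          })
}

v_concat_rows <- function(...) {
  args <- list(...)
  hs <- vapply(args, function(x) nrow(x$val), integer(1))
  ends <- cumsum(hs); starts <- ends - hs + 1L
  ad_node(args[[1]]$tape, do.call(rbind, lapply(args, function(x) x$val)), args,
          function(g, nd) lapply(seq_along(nd$parents),
                                 function(k) g[starts[k]:ends[k], , drop = FALSE]))
}

v_transpose <- function(a) {
  ad_node(a$tape, t(a$val), list(a), function(g, nd) list(t(g)))
}

# Row-wise softmax (optionally after adding a constant mask matrix).
v_softmax_rows <- function(a, mask = NULL) {
  z <- a$val
  if (!is.null(mask)) z <- z + mask
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  nd <- ad_node(a$tape, p, list(a),
                function(g, nd) {
                  pv <- nd$val
                  list((g - rowSums(g * pv)) * pv)
                })
  nd
}

# Softmax over groups of a column vector (n x 1): entries within the same
# group sum to 1.  Used for atom-attention pooling.
v_softmax_groups <- function(a, idx, ngroups) {
  idx <- as.integer(idx)
  z <- as.numeric(a$val)
  mx <- tapply(z, idx, max)[as.character(idx)]
  e <- exp(z - mx)
  denom <- rowsum(matrix(e), group = idx, reorder = FALSE)
  dd <- numeric(ngroups); dd[as.integer(rownames(denom))] <- denom
  p <- e / dd[idx]
  nd <- ad_node(a$tape, matrix(p), list(a),
                function(g, nd) {
                  pv <- as.numeric(nd$val)
                  gp <- as.numeric(g) * pv
                  s <- rowsum(matrix(gp), group = idx, reorder = FALSE)
                  sv <- numeric(ngroups); sv[as.integer(rownames(s))] <- s
                  list(matrix(gp - pv * sv[idx]))
                })
  nd
}

# Fused, numerically stable cross-entropy over rows of a logits matrix.
# target: integer class per row; weight: per-row loss weight.
# Returns (scalar_sum_node).  Caller divides by the valid-token count.
v_crossentropy_sum <- function(logits, target, weight) {
  z <- logits$val
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  n <- nrow(z)
  picked <- z[cbind(seq_len(n), target)]
  losses <- (lse - picked) * weight
  ad_node(logits$tape, matrix(sum(losses), 1L, 1L), list(logits),
          function(g, nd) {
            p <- exp(z - lse)   # softmax rows
            p[cbind(seq_len(n), target)] <- p[cbind(seq_len(n), target)] - 1
            list(g[1L] * p * weight)
          })
}

# Row-wise layer normalization with learnable gain/offset (1 x d each).
v_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, as.numeric(gamma$val), "*"), 2L, as.numeric(beta$val), "+")
  nd <- ad_node(x$tape, out, list(x, gamma, beta),
                function(g, nd) {
                  d <- ncol(g)
                  gam <- as.numeric(nd$parents[[2]]$val)
                  gxh <- sweep(g, 2L, gam, "*")
                  gx <- inv * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
                  list(gx,
                       matrix(colSums(g * xhat), 1L),
                       matrix(colSums(g), 1L))
                })
  nd
}

# Batch normalization over columns.  `state` is an environment holding
# running_mean / running_var; training mode uses batch statistics and
# updates the running averages, evaluation mode uses the stored ones so
# outputs are batch-independent.
v_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  xv <- x$val
  if (training && nrow(xv) > 1L) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2L, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    n <- nrow(xv)
    unb <- va * n / max(1, n - 1)
    state$running_var <- (1 - momentum) * state$running_var + momentum * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- sweep(xv, 2L, mu)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, as.numeric(gamma$val), "*"), 2L, as.numeric(beta$val), "+")
  use_batch <- training && nrow(xv) > 1L
  nd <- ad_node(x$tape, out, list(x, gamma, beta),
                function(g, nd) {
                  gam <- as.numeric(nd$parents[[2]]$val)
                  gxh <- sweep(g, 2L, gam, "*")
                  if (use_batch) {
                    gx <- sweep(gxh - matrix(colMeans(gxh), nrow(g), ncol(g), byrow = TRUE) -
                                  xhat * matrix(colMeans(gxh * xhat), nrow(g), ncol(g), byrow = TRUE),
                                2L, inv, "*")
                  } else {
                    gx <- sweep(gxh, 2L, inv, "*")
                  }
                  list(gx,
                       matrix(colSums(g * xhat), 1L),
                       matrix(colSums(g), 1L))
                })
  nd
}

# Inverted dropout; active only in training mode.
v_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- matrix(rbinom(length(x$val), 1L, 1 - p), nrow(x$val)) / (1 - p)
  ad_node(x$tape, x$val * mask, list(x), function(g, nd) list(g * mask))
}

# Rotary position encoding applied to row vectors: even/odd column pairs
# (2i-1, 2i) of row p are rotated by angle p * theta_i.  cosm/sinm are
# precomputed constant matrices of the same shape as x.
rotate_half <- function(m) {
  d <- ncol(m)
  i1 <- seq(1L, d, by = 2L); i2 <- seq(2L, d, by = 2L)
  out <- m
  out[, i1] <- -m[, i2]
  out[, i2] <- m[, i1]
  out
}

rotate_half_adj <- function(m) {
  d <- ncol(m)
  i1 <- seq(1L, d, by = 2L); i2 <- seq(2L, d, by = 2L)
  out <- m
  out[, i1] <- m[, i2]
  out[, i2] <- -m[, i1]
  out
}

v_rotary <- function(x, cosm, sinm) {
  ad_node(x$tape, x$val * cosm + rotate_half(x$val) * sinm, list(x),
          function(g, nd) list(g * cosm + rotate_half_adj(g * sinm)))
}

# Cosine similarity between two 1 x d row-vector nodes (scalar node).
v_cosine <- function(a, b, eps = 1e-12) {
  av <- as.numeric(a$val); bv <- as.numeric(b$val)
  na <- sqrt(sum(av^2)) + eps; nb <- sqrt(sum(bv^2)) + eps
  dt <- sum(av * bv)
  cs <- dt / (na * nb)
  ad_node(a$tape, matrix(cs, 1L, 1L), list(a, b),
          function(g, nd) {
            g1 <- g[1L] * (bv / (na * nb) - cs * av / na^2)
            g2 <- g[1L] * (av / (na * nb) - cs * bv / nb^2)
            list(matrix(g1, 1L), matrix(g2, 1L))
          })
}

# Fixed per-dimension standardization of representation inputs, learned
# from the training representations and stored with a model.  A plain
# differentiable affine map; identity when `scaler` is NULL.
fit_input_scaler <- function(reps) {
  list(center = colMeans(reps), scale = pmax(apply(reps, 2L, sd), 1e-8))
}

apply_input_scaler <- function(scaler, node, tape) {
  if (is.null(scaler)) return(node)
  centered <- v_addbias(node, ad_const(tape, matrix(-scaler$center, 1L)))
  v_mul(centered, ad_const(tape, matrix(1 / scaler$scale, nrow(node$val),
                                        length(scaler$scale), byrow = TRUE)))
}

## ---- parameters, initialization, optimizer ---------------------------------

# A parameter store is an environment: $val matrix, plus AdamW state.
new_param <- function(val, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$name <- name
  p$m <- NULL
  p$v <- NULL
  p
}

# Put a parameter onto a tape for this forward pass.
use_param <- function(tape, p) {
  nd <- ad_node(tape, p$val)
  nd$param <- p
  nd
}

# Kaiming-uniform fan-in initialization (rectifier layers).
init_kaiming <- function(fan_in, fan_out) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Xavier/Glorot uniform (sigmoid/tanh layers).
init_xavier <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Linear layer parameter pair.
new_linear <- function(fan_in, fan_out, init = c("kaiming", "xavier"), bias = TRUE,
                       name = NULL) {
  init <- match.arg(init)
  W <- if (init == "kaiming") init_kaiming(fan_in, fan_out) else init_xavier(fan_in, fan_out)
  out <- list(W = new_param(W, paste0(name, ".W")))
  if (bias) out$b <- new_param(matrix(0, 1L, fan_out), paste0(name, ".b"))
  out
}

# Apply a linear layer on the tape.
ap_linear <- function(tape, lin, x) {
  y <- v_mm(x, use_param(tape, lin$W))
  if (!is.null(lin$b)) y <- v_addbias(y, use_param(tape, lin$b))
  y
}

new_batchnorm <- function(d, name = NULL) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(d)
  st$running_var <- rep(1, d)
  list(gamma = new_param(matrix(1, 1L, d), paste0(name, ".gamma")),
       beta = new_param(matrix(0, 1L, d), paste0(name, ".beta")),
       state = st)
}

ap_batchnorm <- function(tape, bn, x, training) {
  v_batchnorm(x, use_param(tape, bn$gamma), use_param(tape, bn$beta),
              bn$state, training)
}

new_layernorm <- function(d, name = NULL) {
  list(gamma = new_param(matrix(1, 1L, d), paste0(name, ".gamma")),
       beta = new_param(matrix(0, 1L, d), paste0(name, ".beta")))
}

ap_layernorm <- function(tape, ln, x) {
  v_layernorm(x, use_param(tape, ln$gamma), use_param(tape, ln$beta))
}

# Collect all parameter stores from a nested list structure.
# (Parameter stores carry $val and $name; batch-norm running-stat
# environments carry $running_mean and are excluded.)
collect_params <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$val) && is.null(x$running_mean)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# Read gradients accumulated on a tape back onto (param, grad) pairs,
# summing over repeated uses of the same parameter (e.g. shared
# message-passing weights used once per round).
tape_param_grads <- function(tape) {
  params <- list(); grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$param) || is.null(nd$grad)) next
    hit <- 0L
    for (k in seq_along(params)) if (identical(params[[k]], nd$param)) { hit <- k; break }
    if (hit == 0L) {
      params[[length(params) + 1L]] <- nd$param
      grads[[length(grads) + 1L]] <- nd$grad
    } else {
      grads[[hit]] <- grads[[hit]] + nd$grad
    }
  }
  Map(function(p, g) list(param = p, grad = g), params, grads)
}

# One decoupled-weight-decay Adam step over (param, grad) pairs.
adamw_step <- function(pairs, lr, weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, t = 1L, grad_clip = Inf) {
  for (pg in pairs) {
    p <- pg$param; g <- pg$grad
    if (is.finite(grad_clip)) {
      nrm <- sqrt(sum(g * g))
      if (nrm > grad_clip) g <- g * (grad_clip / nrm)
    }
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$val)
  }
  invisible(NULL)
}
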