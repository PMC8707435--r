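# Internal neural-network engine.
#
# Activations are per-sample, channels-first arrays: 1D data is a
# (channels x length) matrix, 3D data a (channels x depth x height x width)
# array, and post-flatten data a plain vector. A batch is a list of such
# arrays. Every layer implements a forward pass returning (out, cache) and
# a backward pass returning (dx, grads); gradients are verified against
# finite differences in the test suite.

#' Gaussian error linear unit (tanh approximation)
#'
#' `GELU(x) = x * P(X <= x)` for standard normal X, evaluated with the
#' standard tanh approximation
#' `0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))`.
#'
#' @param x Numeric vector or array.
#' @return GELU applied elementwise, same shape as `x`.
#' @export
gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  s <- sqrt(2 / pi)
  u <- s * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * s * (1 + 3 * 0.044715 * x^2)
}

#' Softmax over a numeric vector
#' @param z Numeric vector of logits.
#' @return Probabilities in (0, 1) summing to 1.
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## ---- layer constructors -------------------------------------------------

he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

layer_conv1d <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad),
       params = list(W = he_init(out_ch, in_ch * kernel), b = numeric(out_ch)))
}

layer_conv3d <- function(in_ch, out_ch, kernel) {
  stopifnot(length(kernel) == 3)
  list(type = "conv3d", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel),
       params = list(W = he_init(out_ch, in_ch * prod(kernel)),
                     b = numeric(out_ch)))
}

layer_bn <- function(n_ch, momentum = 0.1, eps = 1e-5) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(n_ch)
  state$running_var <- rep(1, n_ch)
  list(type = "bn", n_ch = n_ch, momentum = momentum, eps = eps,
       state = state,
       params = list(gamma = rep(1, n_ch), beta = numeric(n_ch)))
}

layer_gelu <- function() list(type = "gelu", params = list())

layer_prelu <- function(n_ch, init = 0.25) {
  list(type = "prelu", n_ch = n_ch, params = list(a = rep(init, n_ch)))
}

layer_dropout <- function(p) list(type = "dropout", p = p, params = list())

layer_dense <- function(n_in, n_out, init_scale = 1) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = he_init(n_out, n_in) * init_scale,
                     b = numeric(n_out)))
}

layer_avgpool1d <- function(kernel) {
  list(type = "avgpool1d", kernel = as.integer(kernel), params = list())
}

layer_globalavg1d <- function() list(type = "globalavg1d", params = list())

layer_maxpool3d <- function(kernel) {
  stopifnot(length(kernel) == 3)
  list(type = "maxpool3d", kernel = as.integer(kernel), params = list())
}

layer_adaptiveavg3d <- function(out_dim) {
  stopifnot(length(out_dim) == 3)
  list(type = "adaptiveavg3d", out_dim = as.integer(out_dim), params = list())
}

layer_flatten <- function() list(type = "flatten", params = list())

# Residual block: conv-BN-GELU-conv-BN on the main path, identity or
# (1-kernel conv)-BN projection on the skip path when shape changes, then
# GELU of the sum.
layer_residual1d <- function(in_ch, out_ch, kernel, stride) {
  main <- list(layer_conv1d(in_ch, out_ch, kernel, stride),
               layer_bn(out_ch),
               layer_gelu(),
               layer_conv1d(out_ch, out_ch, kernel, 1L),
               layer_bn(out_ch))
  skip <- if (in_ch != out_ch || stride != 1L) {
    list(layer_conv1d(in_ch, out_ch, 1L, stride, pad = 0L), layer_bn(out_ch))
  } else list()
  list(type = "residual1d", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel), stride = as.integer(stride),
       main = main, skip = skip, params = list())
}

## ---- forward ------------------------------------------------------------

# flatten an array to (channels x N) keeping channels first (dim 1)
as_cmat <- function(x) {
  d <- dim(x)
  if (is.null(d)) matrix(x, nrow = length(x)) else matrix(x, nrow = d[1])
}

# need_cache = FALSE enables a memory-lean evaluation path: no caches are
# retained and batch norm / PReLU run as single-pass C++ kernels, which is
# what makes a full-size 3D forward fit in memory.
nn_forward <- function(layer, xs, training = FALSE, need_cache = training) {
  switch(layer$type,
    conv1d = {
      out <- lapply(xs, function(x)
        conv1d_fwd(x, layer$params$W, layer$params$b, layer$kernel,
                   layer$stride, layer$pad))
      list(out = out, cache = list(xs = xs))
    },
    conv3d = {
      out <- lapply(xs, function(x)
        conv3d_fwd(x, dim(x), layer$params$W, layer$params$b,
                   layer$kernel[1], layer$kernel[2], layer$kernel[3]))
      list(out = out, cache = list(xs = xs))
    },
    bn = nn_forward_bn(layer, xs, training, need_cache),
    gelu = list(out = lapply(xs, gelu), cache = list(xs = xs)),
    prelu = {
      out <- lapply(xs, function(x) prelu_fwd_cpp(x, layer$params$a))
      list(out = out, cache = list(xs = xs))
    },
    dropout = {
      if (!training || layer$p <= 0)
        return(list(out = xs, cache = list(masks = NULL)))
      masks <- lapply(xs, function(x) {
        m <- array(runif(length(x)) >= layer$p,
                   dim = if (is.null(dim(x))) length(x) else dim(x))
        m / (1 - layer$p)
      })
      list(out = Map(`*`, xs, masks), cache = list(masks = masks))
    },
    dense = {
      out <- lapply(xs, function(x)
        drop(layer$params$W %*% as.numeric(x)) + layer$params$b)
      list(out = out, cache = list(xs = xs))
    },
    avgpool1d = {
      k <- layer$kernel
      out <- lapply(xs, function(x) {
        L <- ncol(x); Lo <- L %/% k
        x <- x[, seq_len(Lo * k), drop = FALSE]
        dim(x) <- c(nrow(x), k, Lo)
        apply(x, c(1, 3), mean)
      })
      list(out = out, cache = list(in_len = vapply(xs, ncol, integer(1)),
                                   n_ch = nrow(xs[[1]])))
    },
    globalavg1d = {
      out <- lapply(xs, rowMeans)
      list(out = out, cache = list(in_len = vapply(xs, ncol, integer(1))))
    },
    maxpool3d = {
      res <- lapply(xs, function(x)
        maxpool3d_fwd(x, dim(x), layer$kernel[1], layer$kernel[2],
                      layer$kernel[3]))
      list(out = lapply(res, `[[`, "y"),
           cache = list(argmax = lapply(res, `[[`, "argmax"),
                        xdims = lapply(xs, dim)))
    },
    adaptiveavg3d = {
      out <- lapply(xs, function(x) adaptive_avg3d(x, layer$out_dim))
      list(out = out, cache = list(xdims = lapply(xs, dim)))
    },
    flatten = {
      list(out = lapply(xs, as.numeric),
           cache = list(dims = lapply(xs, dim)))
    },
    residual1d = {
      main <- forward_layers(layer$main, xs, training, need_cache)
      skip <- if (length(layer$skip) > 0)
        forward_layers(layer$skip, xs, training, need_cache)
      else list(out = xs, caches = NULL)
      pre <- Map(`+`, main$out, skip$out)
      list(out = lapply(pre, gelu),
           cache = if (need_cache)
             list(main = main$caches, skip = skip$caches, pre = pre))
    },
    stop("unknown layer type: ", layer$type))
}

nn_forward_bn <- function(layer, xs, training, need_cache = training) {
  if (!training && !need_cache) {
    # single-pass affine with running statistics; no intermediates kept
    inv_std <- 1 / sqrt(layer$state$running_var + layer$eps)
    a <- layer$params$gamma * inv_std
    bb <- layer$params$beta - layer$state$running_mean * a
    return(list(out = lapply(xs, function(x) channel_affine_cpp(x, a, bb)),
                cache = NULL))
  }
  mats <- lapply(xs, as_cmat)
  if (training) {
    big <- do.call(cbind, mats)
    m <- rowMeans(big)
    v <- rowMeans((big - m)^2)
    st <- layer$state
    st$running_mean <- (1 - layer$momentum) * st$running_mean + layer$momentum * m
    st$running_var <- (1 - layer$momentum) * st$running_var + layer$momentum * v
  } else {
    m <- layer$state$running_mean
    v <- layer$state$running_var
  }
  inv_std <- 1 / sqrt(v + layer$eps)
  g <- layer$params$gamma
  b <- layer$params$beta
  out <- vector("list", length(xs))
  xhat <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    xh <- (mats[[i]] - m) * inv_std
    y <- g * xh + b
    dim(y) <- if (is.null(dim(xs[[i]]))) NULL else dim(xs[[i]])
    out[[i]] <- y
    xhat[[i]] <- xh
  }
  list(out = out,
       cache = list(xhat = xhat, inv_std = inv_std, training = training,
                    dims = lapply(xs, dim)))
}

adaptive_avg3d <- function(x, out_dim) {
  d <- dim(x)
  if (all(d[2:4] == out_dim)) return(x)
  bounds <- function(n, o) {
    lo <- floor((seq_len(o) - 1) * n / o) + 1
    hi <- floor(seq_len(o) * n / o)
    cbind(lo, hi)
  }
  bd <- bounds(d[2], out_dim[1]); bh <- bounds(d[3], out_dim[2])
  bw <- bounds(d[4], out_dim[3])
  out <- array(0, dim = c(d[1], out_dim))
  for (i in seq_len(out_dim[1]))
    for (j in seq_len(out_dim[2]))
      for (k in seq_len(out_dim[3])) {
        blk <- x[, bd[i, 1]:bd[i, 2], bh[j, 1]:bh[j, 2], bw[k, 1]:bw[k, 2],
                 drop = FALSE]
        out[, i, j, k] <- apply(blk, 1, mean)
      }
  out
}

forward_layers <- function(layers, xs, training = FALSE,
                           need_cache = training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- nn_forward(layers[[i]], xs, training, need_cache)
    xs <- res$out
    if (need_cache) caches[[i]] <- res$cache
  }
  list(out = xs, caches = caches)
}

## ---- backward -----------------------------------------------------------

nn_backward <- function(layer, cache, dys) {
  switch(layer$type,
    conv1d = {
      res <- Map(function(x, dy)
        conv1d_bwd(x, layer$params$W, dy, layer$kernel, layer$stride,
                   layer$pad),
        cache$xs, dys)
      list(dx = lapply(res, `[[`, "dx"),
           grads = list(W = Reduce(`+`, lapply(res, `[[`, "dW")),
                        b = Reduce(`+`, lapply(res, function(r) drop(r$db)))))
    },
    conv3d = {
      res <- Map(function(x, dy)
        conv3d_bwd(x, dim(x), layer$params$W, dy, layer$kernel[1],
                   layer$kernel[2], layer$kernel[3]),
        cache$xs, dys)
      list(dx = lapply(res, `[[`, "dx"),
           grads = list(W = Reduce(`+`, lapply(res, `[[`, "dW")),
                        b = Reduce(`+`, lapply(res, function(r) drop(r$db)))))
    },
    bn = nn_backward_bn(layer, cache, dys),
    gelu = list(dx = Map(function(x, dy) dy * gelu_grad(x), cache$xs, dys),
                grads = list()),
    prelu = {
      a <- layer$params$a
      dx <- Map(function(x, dy) {
        am <- array(a, dim = if (is.null(dim(x))) length(x) else dim(x))
        dy * ifelse(x > 0, 1, am)
      }, cache$xs, dys)
      da <- Reduce(`+`, Map(function(x, dy) {
        m <- as_cmat(dy * x * (x <= 0))
        rowSums(m)
      }, cache$xs, dys))
      list(dx = dx, grads = list(a = da))
    },
    dropout = {
      if (is.null(cache$masks)) return(list(dx = dys, grads = list()))
      list(dx = Map(`*`, dys, cache$masks), grads = list())
    },
    dense = {
      W <- layer$params$W
      dx <- lapply(dys, function(dy) drop(crossprod(W, dy)))
      dW <- Reduce(`+`, Map(function(x, dy) tcrossprod(dy, as.numeric(x)),
                            cache$xs, dys))
      db <- Reduce(`+`, dys)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    avgpool1d = {
      k <- layer$kernel
      dx <- Map(function(dy, L) {
        C <- nrow(dy); Lo <- ncol(dy)
        full <- matrix(0, C, L)
        expand <- dy[, rep(seq_len(Lo), each = k), drop = FALSE] / k
        full[, seq_len(Lo * k)] <- expand
        full
      }, dys, cache$in_len)
      list(dx = dx, grads = list())
    },
    globalavg1d = {
      dx <- Map(function(dy, L) matrix(dy, length(dy), L) / L,
                dys, cache$in_len)
      list(dx = dx, grads = list())
    },
    maxpool3d = {
      dx <- Map(function(dy, am, xd) maxpool3d_bwd(dy, am, xd),
                dys, cache$argmax, cache$xdims)
      list(dx = dx, grads = list())
    },
    adaptiveavg3d = {
      dx <- Map(function(dy, xd) adaptive_avg3d_bwd(dy, xd, layer$out_dim),
                dys, cache$xdims)
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- Map(function(dy, d) { dim(dy) <- d; dy }, dys, cache$dims)
      list(dx = dx, grads = list())
    },
    residual1d = {
      dpre <- Map(function(pre, dy) dy * gelu_grad(pre), cache$pre, dys)
      back_main <- backward_layers(layer$main, cache$main, dpre)
      if (length(layer$skip) > 0) {
        back_skip <- backward_layers(layer$skip, cache$skip, dpre)
        dx <- Map(`+`, back_main$dx, back_skip$dx)
        skip_grads <- back_skip$grads
      } else {
        dx <- Map(`+`, back_main$dx, dpre)
        skip_grads <- list()
      }
      list(dx = dx, grads = list(main = back_main$grads, skip = skip_grads))
    },
    stop("unknown layer type: ", layer$type))
}

nn_backward_bn <- function(layer, cache, dys) {
  g <- layer$params$gamma
  inv_std <- cache$inv_std
  dmats <- lapply(dys, as_cmat)
  xhat <- cache$xhat
  dgamma <- Reduce(`+`, Map(function(dy, xh) rowSums(dy * xh), dmats, xhat))
  dbeta <- Reduce(`+`, lapply(dmats, rowSums))
  if (!cache$training) {
    dx <- Map(function(dy, d) {
      out <- dy * g * inv_std
      dim(out) <- d
      out
    }, dmats, cache$dims)
    return(list(dx = dx, grads = list(gamma = dgamma, beta = dbeta)))
  }
  N <- sum(vapply(dmats, ncol, integer(1)))
  dxhat <- Map(function(dy) dy * g, dmats)
  sum_dxhat <- Reduce(`+`, lapply(dxhat, rowSums))
  sum_dxhat_xhat <- Reduce(`+`, Map(function(dxh, xh) rowSums(dxh * xh),
                                    dxhat, xhat))
  dx <- Map(function(dxh, xh, d) {
    out <- inv_std / N * (N * dxh - sum_dxhat - xh * sum_dxhat_xhat)
    dim(out) <- d
    out
  }, dxhat, xhat, cache$dims)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

adaptive_avg3d_bwd <- function(dy, xdim, out_dim) {
  if (all(xdim[2:4] == out_dim)) return(dy)
  bounds <- function(n, o) {
    lo <- floor((seq_len(o) - 1) * n / o) + 1
    hi <- floor(seq_len(o) * n / o)
    cbind(lo, hi)
  }
  bd <- bounds(xdim[2], out_dim[1]); bh <- bounds(xdim[3], out_dim[2])
  bw <- bounds(xdim[4], out_dim[3])
  dx <- array(0, dim = xdim)
  for (i in seq_len(out_dim[1]))
    for (j in seq_len(out_dim[2]))
      for (k in seq_len(out_dim[3])) {
        nblk <- (bd[i, 2] - bd[i, 1] + 1) * (bh[j, 2] - bh[j, 1] + 1) *
          (bw[k, 2] - bw[k, 1] + 1)
        dx[, bd[i, 1]:bd[i, 2], bh[j, 1]:bh[j, 2], bw[k, 1]:bw[k, 2]] <-
          dx[, bd[i, 1]:bd[i, 2], bh[j, 1]:bh[j, 2], bw[k, 1]:bw[k, 2]] +
          dy[, i, j, k] / nblk
      }
  dx
}

backward_layers <- function(layers, caches, dys) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- nn_backward(layers[[i]], caches[[i]], dys)
    dys <- res$dx
    grads[[i]] <- res$grads
  }
  list(dx = dys, grads = grads)
}

## ---- optimizer ----------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(layer) {
    st <- list(params = lapply(layer$params, function(p) {
      z <- p
      z[] <- 0
      list(m = z, v = z)
    }))
    if (layer$type == "residual1d") {
      st$main <- adam_init(layer$main)
      st$skip <- adam_init(layer$skip)
    }
    st
  })
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        weight_decay = 0) {
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    g <- grads[[i]]
    if (layer$type == "residual1d") {
      up_m <- adam_update(layer$main, g$main, state[[i]]$main, lr, t,
                          beta1, beta2, eps, weight_decay)
      up_s <- adam_update(layer$skip, g$skip, state[[i]]$skip, lr, t,
                          beta1, beta2, eps, weight_decay)
      layer$main <- up_m$layers; state[[i]]$main <- up_m$state
      layer$skip <- up_s$layers; state[[i]]$skip <- up_s$state
      layers[[i]] <- layer
      next
    }
    for (pn in names(layer$params)) {
      gp <- g[[pn]]
      if (is.null(gp)) next
      ps <- state[[i]]$params[[pn]]
      ps$m <- beta1 * ps$m + (1 - beta1) * gp
      ps$v <- beta2 * ps$v + (1 - beta2) * gp^2
      mhat <- ps$m / (1 - beta1^t)
      vhat <- ps$v / (1 - beta2^t)
      # decoupled weight decay on weight matrices only (never on biases,
      # batch-norm scales/offsets, or PReLU slopes)
      decay <- if (weight_decay > 0 && pn == "W") weight_decay else 0
      layer$params[[pn]] <- layer$params[[pn]] * (1 - lr * decay) -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]]$params[[pn]] <- ps
    }
    layers[[i]] <- layer
  }
  list(layers = layers, state = state)
}
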