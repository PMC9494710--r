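# Training engine: parameter initialisation, forward/backward passes and
# optimiser steps over the layer graph declared by an emg_architecture.
# Conv and LSTM passes run through the RcppArmadillo kernels; the glue,
# classifier head and optimisers are plain R. Batches are arrays with
# dim (time, channels*maps, batch) at the conv stage and (batch, features)
# in the classifier head. All randomness (init, shuffling, dropout) draws
# from R's RNG so a single seed fixes the whole run.

glorot <- function(dims, fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -l, l), dim = dims)
}

# Materialise one weight array set per parameterised layer.
nn_init <- function(arch) {
  shapes <- arch_shapes(arch)
  n_in_maps <- arch$input_shape[3]
  params <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    dims_in <- shapes$dims_in[[i]]
    params[i] <- list(switch(l$kind,   # [i] <- list(): keep NULL slots
      conv = {
        k <- prod(l$kernel)
        p <- list(W = glorot(c(k * n_in_maps, l$n_out),
                             k * n_in_maps, k * l$n_out),
                  b = numeric(l$n_out))
        n_in_maps <- l$n_out
        p
      },
      lstm = {
        f_in <- dims_in[2]
        h <- l$units
        b <- numeric(4 * h)
        b[(h + 1):(2 * h)] <- 1  # forget-gate bias
        list(Wx = glorot(c(f_in, 4 * h), f_in, h),
             Wh = glorot(c(h, 4 * h), h, h),
             b = b)
      },
      dense = list(W = glorot(c(dims_in[1], l$n_out), dims_in[1], l$n_out),
                   b = numeric(l$n_out)),
      NULL
    ))
  }
  params
}

# Number of weights the engine materialises (the framework's own count).
engine_param_count <- function(params) {
  sum(vapply(params, function(p) {
    if (is.null(p)) 0 else sum(vapply(p, length, numeric(1)))
  }, numeric(1)))
}

lstm_seq_output <- function(Hs) {
  tn <- dim(Hs)[3] - 1L
  aperm(Hs[, , 2:(tn + 1), drop = FALSE], c(3, 1, 2))
}

# Forward pass. X: array (T, C, B). Returns logits (B x K) and per-layer
# caches for the backward pass. Dropout is active only when training = TRUE.
nn_forward <- function(arch, params, X, training = FALSE,
                       shapes = arch_shapes(arch)) {
  caches <- vector("list", length(arch$layers))
  cur <- X
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    p <- params[[i]]
    res <- switch(l$kind,
      conv = {
        pads <- conv_pads(l$kernel, l$padding)
        ch <- shapes$dims_in[[i]][2]
        out <- cpp_conv2d_fwd(cur, p$W, p$b, ch, dim(cur)[2] %/% ch,
                              l$kernel[1], l$kernel[2],
                              pads["pt0"], pads["pt1"],
                              pads["pc0"], pads["pc1"])
        list(out = out, cache = list(X = cur))
      },
      maxpool = {
        if (l$pool == 1L) list(out = cur, cache = NULL)
        else maxpool_fwd(cur, l$pool)
      },
      reshape = list(out = cur, cache = NULL),
      flatten = {
        f <- prod(dim(cur)[1:2])
        list(out = t(matrix(cur, nrow = f)), cache = list(dims = dim(cur)))
      },
      lstm = {
        st <- cpp_lstm_fwd(cur, p$Wx, p$Wh, p$b)
        out <- if (l$return_seq) lstm_seq_output(st$Hs)
               else t(st$Hs[, , dim(st$Hs)[3]])
        list(out = out, cache = c(st, list(X = cur)))
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- matrix(rbinom(length(cur), 1, 1 - l$rate) / (1 - l$rate),
                         nrow = nrow(cur))
          list(out = cur * mask, cache = list(mask = mask))
        } else list(out = cur, cache = NULL)
      },
      dense = list(out = sweep(cur %*% p$W, 2, p$b, "+"),
                   cache = list(X = cur)),
      leaky_relu = {
        neg <- cur < 0
        list(out = cur * (1 + (l$alpha - 1) * neg),
             cache = list(neg = neg))
      },
      softmax = list(out = cur, cache = NULL)  # fused with the loss
    )
    caches[i] <- list(res$cache)   # keep NULL slots
    cur <- res$out
  }
  list(logits = cur, caches = caches)
}

maxpool_fwd <- function(X, pool) {
  d <- dim(X)
  to <- d[1] %/% pool
  Xc <- X[1:(to * pool), , , drop = FALSE]
  out <- array(-Inf, c(to, d[2], d[3]))
  amax <- array(1L, c(to, d[2], d[3]))
  for (k in 1:pool) {
    cand <- Xc[seq(k, to * pool, by = pool), , , drop = FALSE]
    upd <- cand > out
    amax[upd] <- k
    out[upd] <- cand[upd]
  }
  list(out = out, cache = list(amax = amax, dims = d, pool = pool))
}

maxpool_bwd <- function(d_out, cache) {
  dX <- array(0, cache$dims)
  to <- dim(d_out)[1]
  for (k in 1:cache$pool) {
    sel <- cache$amax == k
    rows <- seq(k, to * cache$pool, by = cache$pool)
    slab <- array(0, dim(d_out))
    slab[sel] <- d_out[sel]
    dX[rows, , ] <- dX[rows, , , drop = FALSE] + slab
  }
  dX
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and gradient w.r.t. logits. y: integer labels 1..K.
softmax_xent <- function(logits, y) {
  p <- softmax_probs(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n, probs = p)
}

# Backward pass from dlogits; returns grads shaped like params.
nn_backward <- function(arch, params, caches, dlogits,
                        shapes = arch_shapes(arch)) {
  grads <- vector("list", length(arch$layers))
  d <- dlogits
  for (i in rev(seq_along(arch$layers))) {
    l <- arch$layers[[i]]
    p <- params[[i]]
    cache <- caches[[i]]
    d <- switch(l$kind,
      softmax = d,
      leaky_relu = d * (1 + (l$alpha - 1) * cache$neg),
      dense = {
        grads[[i]] <- list(W = t(cache$X) %*% d, b = colSums(d))
        d %*% t(p$W)
      },
      dropout = if (is.null(cache)) d else d * cache$mask,
      lstm = {
        tn <- dim(cache$X)[1]
        h <- l$units
        b_sz <- dim(cache$X)[3]
        dH <- array(0, c(h, b_sz, tn))
        if (l$return_seq) {
          dH <- aperm(d, c(2, 3, 1))
        } else {
          dH[, , tn] <- t(d)
        }
        res <- cpp_lstm_bwd(cache$X, p$Wx, p$Wh, cache$Hs, cache$Cs,
                            cache$Gs, dH)
        grads[[i]] <- list(Wx = res$dWx, Wh = res$dWh, b = as.numeric(res$db))
        res$dX
      },
      flatten = array(t(d), cache$dims),
      reshape = d,
      maxpool = if (is.null(cache)) d else maxpool_bwd(d, cache),
      conv = {
        pads <- conv_pads(l$kernel, l$padding)
        ch <- shapes$dims_in[[i]][2]
        res <- cpp_conv2d_bwd(cache$X, p$W, d, ch, dim(cache$X)[2] %/% ch,
                              l$kernel[1], l$kernel[2],
                              pads["pt0"], pads["pt1"],
                              pads["pc0"], pads["pc1"],
                              i > 1)
        grads[[i]] <- list(W = res$dW, b = as.numeric(res$db))
        res$dX
      }
    )
  }
  grads
}

# Rescale all gradients jointly so their global L2 norm is at most max_norm.
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- sum(vapply(grads, function(g) {
    if (is.null(g)) 0 else sum(vapply(g, function(w) sum(w^2), numeric(1)))
  }, numeric(1)))
  norm <- sqrt(sq)
  if (norm <= max_norm) return(grads)
  scale <- max_norm / norm
  lapply(grads, function(g) {
    if (is.null(g)) NULL else lapply(g, function(w) w * scale)
  })
}

opt_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) list(m = array(0, dim(w) %||% length(w)),
                               v = array(0, dim(w) %||% length(w))))
  })
}

opt_step <- function(params, grads, state, lr, optimizer, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-3,
                     momentum = 0.9) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (optimizer == "ADAM") {
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
        state[[i]][[nm]] <- st
      } else {  # SGDM
        st <- state[[i]][[nm]]
        st$m <- momentum * st$m - lr * g
        params[[i]][[nm]] <- params[[i]][[nm]] + st$m
        state[[i]][[nm]] <- st
      }
    }
  }
  list(params = params, state = state)
}
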