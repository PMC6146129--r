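# Minimal reverse-mode automatic differentiation on matrices.
#
# Both neural models in this package (the char-CNN + BiLSTM tagger and the
# multi-window CNN relation classifier) are expressed as compositions of
# matrix operations recorded on a tape; gradients are obtained by a single
# reverse sweep. Values are plain base-R matrices; a "node" is an
# environment holding the forward value, an accumulated gradient and a
# backward closure. Trainable parameters live outside any tape in
# `ad_param` environments so several forward passes can contribute
# gradients to the same parameter before an optimizer step.
#
# The two computationally heavy building blocks -- the LSTM recurrence and
# windowed convolution + max-over-time pooling -- are fused ops with
# hand-derived backward passes (batched over timesteps / windows), which
# keeps tapes short and the per-node interpreter overhead negligible; both
# are validated against finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bk <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @noRd
ad_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim(value))
  p$ms <- NULL   # RMSProp second-moment accumulator, allocated lazily
  p
}

p_accum <- function(p, g) {
  p$grad <- p$grad + g
  invisible(NULL)
}

ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_node(tape, x)
}

# Bring a parameter onto a tape; the backward closure writes straight into
# the parameter's gradient accumulator.
ad_use <- function(tape, p) {
  ad_node(tape, p$value, function(g) p_accum(p, g))
}

ad_matmul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, av %*% bv, function(g) {
    ad_accum(a, tcrossprod(g, bv))
    ad_accum(b, crossprod(av, g))
  })
}

# Elementwise add; `b` may be a 1-row matrix broadcast over the rows of `a`.
ad_add <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(av) > 1L
  val <- if (broadcast) av + rep(bv, each = nrow(av)) else av + bv
  ad_node(tape, val, function(g) {
    ad_accum(a, g)
    ad_accum(b, if (broadcast) matrix(colSums(g), 1L) else g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, av * bv, function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  })
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), function(g) {
    for (k in seq_along(nodes)) {
      ad_accum(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

# Row gather (embedding lookup) straight from a parameter; backward
# scatter-adds into the parameter, merging repeated indices.
ad_embed <- function(tape, p, idx) {
  ad_node(tape, p$value[idx, , drop = FALSE], function(g) {
    acc <- rowsum(g, group = idx)
    rows <- as.integer(rownames(acc))
    p$grad[rows, ] <- p$grad[rows, , drop = FALSE] + acc
    invisible(NULL)
  })
}

#' @noRd
softmax_rows <- function(q) {
  q <- q - apply(q, 1L, max)
  e <- exp(q)
  e / rowSums(e)
}

# Mean categorical cross-entropy over the rows of a logit matrix.
# `target` is an integer class index per row. Returns a 1x1 node; the row
# probabilities are kept on the node for callers that need them.
ad_mean_xent <- function(tape, logits, target) {
  p <- softmax_rows(logits$val)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), target)], 1e-12)))
  nd <- ad_node(tape, matrix(loss, 1L, 1L), function(g) {
    y <- array(0, dim(p))
    y[cbind(seq_len(n), target)] <- 1
    ad_accum(logits, (p - y) * (g[1L, 1L] / n))
  })
  nd$probs <- p
  nd
}

## ---- fused LSTM -------------------------------------------------------------

# One direction of an LSTM over the rows of input node X (n x in_dim),
# returning the hidden-state matrix H (n x pi). Gate order in the fused
# weight matrices Wx (in_dim x 4pi), Wh (pi x 4pi), b (1 x 4pi) is
# input / forget / output / candidate. `reverse` runs the recurrence from
# the last row to the first. Wx, Wh, b are ad_param environments; their
# gradients are accumulated directly (batched over timesteps).
ad_lstm <- function(tape, X, Wx, Wh, b, reverse = FALSE) {
  Xv <- X$val
  n <- nrow(Xv); pi <- nrow(Wh$value)
  ord <- if (reverse) n:1L else 1:n
  si <- 1:pi; sf <- pi + si; so <- 2L * pi + si; sg <- 3L * pi + si
  XW <- Xv %*% Wx$value                       # hoisted input contribution
  Whv <- Wh$value; bv <- as.numeric(b$value)
  I <- F_ <- O <- G <- C <- Tc <- Hprev <- Cprev <- matrix(0, n, pi)
  H <- matrix(0, n, pi)
  h <- c_ <- numeric(pi)
  for (k in seq_len(n)) {
    t <- ord[k]
    z <- XW[t, ] + h %*% Whv + bv
    zi <- 1 / (1 + exp(-z[si])); zf <- 1 / (1 + exp(-z[sf]))
    zo <- 1 / (1 + exp(-z[so])); zg <- tanh(z[sg])
    Hprev[t, ] <- h; Cprev[t, ] <- c_
    c_ <- zf * c_ + zi * zg
    tc <- tanh(c_)
    h <- zo * tc
    I[t, ] <- zi; F_[t, ] <- zf; O[t, ] <- zo; G[t, ] <- zg
    C[t, ] <- c_; Tc[t, ] <- tc; H[t, ] <- h
  }
  ad_node(tape, H, function(gH) {
    dZ <- matrix(0, n, 4L * pi)
    dh_carry <- dc_carry <- numeric(pi)
    for (k in rev(seq_len(n))) {
      t <- ord[k]
      dh <- gH[t, ] + dh_carry
      do_ <- dh * Tc[t, ]
      dc <- dc_carry + dh * O[t, ] * (1 - Tc[t, ]^2)
      di <- dc * G[t, ]; df <- dc * Cprev[t, ]; dg <- dc * I[t, ]
      dZ[t, si] <- di * I[t, ] * (1 - I[t, ])
      dZ[t, sf] <- df * F_[t, ] * (1 - F_[t, ])
      dZ[t, so] <- do_ * O[t, ] * (1 - O[t, ])
      dZ[t, sg] <- dg * (1 - G[t, ]^2)
      dh_carry <- as.numeric(dZ[t, ] %*% t(Whv))
      dc_carry <- dc * F_[t, ]
    }
    p_accum(Wx, crossprod(Xv, dZ))
    p_accum(Wh, crossprod(Hprev, dZ))
    p_accum(b, matrix(colSums(dZ), 1L))
    ad_accum(X, tcrossprod(dZ, Wx$value))
  })
}

## ---- fused windowed convolution + max pooling -------------------------------

# Convolution of width-`w` filters over each row segment of B (a node),
# with ReLU activation and per-segment max-over-time pooling. Segments are
# row ranges [seg_start[s], seg_end[s]] (every segment at least `w` rows).
# W (w*ncol(B) x kappa) and bias b (1 x kappa) are ad_param environments.
# Returns an S x kappa node (one pooled row per segment).
ad_conv_pool <- function(tape, B, seg_start, seg_end, W, b, w) {
  Bv <- B$val
  d <- ncol(Bv); S <- length(seg_start)
  win_start <- unlist(lapply(seq_len(S), function(s) {
    seg_start[s]:(seg_end[s] - w + 1L)
  }))
  win_seg <- rep(seq_len(S), seg_end - seg_start - w + 2L)
  Win <- do.call(cbind, lapply(0:(w - 1L), function(k) {
    Bv[win_start + k, , drop = FALSE]
  }))
  pre <- Win %*% W$value + rep(b$value, each = nrow(Win))
  act <- pre * (pre > 0)
  kappa <- ncol(act)
  U <- matrix(0, S, kappa)
  arg <- matrix(0L, S, kappa)  # row of `act` achieving each segment max
  for (s in seq_len(S)) {
    rows <- which(win_seg == s)
    sub <- act[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    arg[s, ] <- rows[am]
    U[s, ] <- sub[cbind(am, seq_len(kappa))]
  }
  ad_node(tape, U, function(gU) {
    dact <- array(0, dim(act))
    dact[cbind(as.integer(arg), rep(seq_len(kappa), each = S))] <- as.numeric(gU)
    dpre <- dact * (pre > 0)
    p_accum(W, crossprod(Win, dpre))
    p_accum(b, matrix(colSums(dpre), 1L))
    dWin <- tcrossprod(dpre, W$value)
    dB <- array(0, dim(Bv))
    for (k in 0:(w - 1L)) {
      acc <- rowsum(dWin[, (k * d + 1L):((k + 1L) * d), drop = FALSE],
                    group = win_start + k)
      rows <- as.integer(rownames(acc))
      dB[rows, ] <- dB[rows, , drop = FALSE] + acc
    }
    ad_accum(B, dB)
  })
}

# Reverse sweep. `seed` scales the loss gradient, letting several
# per-example tapes contribute 1/batch each to shared parameters.
ad_backward <- function(tape, loss, seed = 1) {
  loss$grad <- matrix(seed, 1L, 1L)
  for (i in tape$n:1L) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$bk) && !is.null(nd$grad)) nd$bk(nd$grad)
  }
  invisible(NULL)
}

## ---- parameter collections and optimizers ----------------------------------

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

global_grad_norm <- function(params) {
  sqrt(sum(vapply(params, function(p) sum(p$grad^2), numeric(1))))
}

# SGD step with global-norm gradient clipping.
sgd_step <- function(params, lr, clip = 5) {
  gn <- global_grad_norm(params)
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (p in params) p$value <- p$value - lr * scale * p$grad
  zero_grads(params)
}

rmsprop_step <- function(params, lr, rho = 0.9, eps = 1e-8, clip = 5) {
  gn <- global_grad_norm(params)
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (p in params) {
    g <- p$grad * scale
    if (is.null(p$ms)) p$ms <- array(0, dim(p$value))
    p$ms <- rho * p$ms + (1 - rho) * g * g
    p$value <- p$value - lr * g / (sqrt(p$ms) + eps)
  }
  zero_grads(params)
}

## ---- initializers -----------------------------------------------------------

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

embedding_init <- function(nr, nc, scale = 0.05) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# Deep-copy current parameter values (checkpointing).
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snapshot) {
  for (nm in names(snapshot)) params[[nm]]$value <- snapshot[[nm]]
  invisible(NULL)
}
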