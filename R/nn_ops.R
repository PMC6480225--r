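# Numeric primitives for the 1-D convolutional network.
#
# Activations are dense arrays [batch, length, channels]. Convolutions are
# realized as k matrix products (one per kernel tap) on strided slices of
# the zero-padded input, which keeps the inner loop inside BLAS. Each
# forward function returns the output plus the cache its backward needs.
# "same" padding follows the usual convention: output length ceil(L/stride),
# total padding (out-1)*stride + k - L split left/right with the extra
# sample on the right. Max-pooling pads with -Inf so padded positions never
# win the max.

conv_geometry <- function(L, k, stride, padding) {
  if (padding == "same") {
    L_out <- as.integer(ceiling(L / stride))
    pad_total <- max((L_out - 1L) * stride + k - L, 0L)
    pad_left <- pad_total %/% 2L
  } else {
    L_out <- as.integer((L - k) %/% stride + 1L)
    pad_left <- 0L
    pad_total <- 0L
  }
  list(L_out = L_out, pad_left = pad_left,
       pad_right = pad_total - pad_left)
}

pad_length_axis <- function(X, pad_left, pad_right, fill = 0) {
  if (pad_left == 0 && pad_right == 0) return(X)
  d <- dim(X)
  Xp <- array(fill, dim = c(d[1], d[2] + pad_left + pad_right, d[3]))
  Xp[, pad_left + seq_len(d[2]), ] <- X
  Xp
}

# W: array [k, C_in, C_out]; b: numeric C_out
conv1d_forward <- function(X, W, b, stride, padding) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C_in <- d[3]
  k <- dim(W)[1]; C_out <- dim(W)[3]
  stopifnot(dim(W)[2] == C_in)
  g <- conv_geometry(L, k, stride, padding)
  if (g$L_out < 1) {
    stop("convolution output length < 1 (input ", L, ", kernel ", k,
         ", stride ", stride, ")", call. = FALSE)
  }
  Xp <- pad_length_axis(X, g$pad_left, g$pad_right)
  starts <- (seq_len(g$L_out) - 1L) * stride
  Y_mat <- matrix(b, nrow = B * g$L_out, ncol = C_out, byrow = TRUE)
  for (t in seq_len(k)) {
    Xs <- Xp[, starts + t, , drop = FALSE]
    dim(Xs) <- c(B * g$L_out, C_in)
    Y_mat <- Y_mat + Xs %*% matrix(W[t, , ], C_in, C_out)
  }
  Y <- array(Y_mat, dim = c(B, g$L_out, C_out))
  list(Y = Y, cache = list(Xp = Xp, W = W, stride = stride, starts = starts,
                           pad_left = g$pad_left, L = L, B = B,
                           C_in = C_in, C_out = C_out, k = k,
                           L_out = g$L_out))
}

conv1d_backward <- function(cache, dY) {
  with(cache, {
    dY_mat <- matrix(dY, nrow = B * L_out, ncol = C_out)
    db <- colSums(dY_mat)
    dW <- array(0, dim = dim(W))
    dXp <- array(0, dim = dim(Xp))
    for (t in seq_len(k)) {
      Xs <- Xp[, starts + t, , drop = FALSE]
      dim(Xs) <- c(B * L_out, C_in)
      dW[t, , ] <- crossprod(Xs, dY_mat)
      dXs <- dY_mat %*% t(matrix(W[t, , ], C_in, C_out))
      dXp[, starts + t, ] <- dXp[, starts + t, , drop = FALSE] +
        array(dXs, dim = c(B, L_out, C_in))
    }
    list(dX = dXp[, pad_left + seq_len(L), , drop = FALSE], dW = dW, db = db)
  })
}

maxpool1d_forward <- function(X, size, stride, padding) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  g <- conv_geometry(L, size, stride, padding)
  if (g$L_out < 1) {
    stop("pooling output length < 1 (input ", L, ", pool ", size,
         ", stride ", stride, ")", call. = FALSE)
  }
  Xp <- pad_length_axis(X, g$pad_left, g$pad_right, fill = -Inf)
  starts <- (seq_len(g$L_out) - 1L) * stride
  Y <- array(-Inf, dim = c(B, g$L_out, C))
  winner <- array(1L, dim = c(B, g$L_out, C))
  for (t in seq_len(size)) {
    Xs <- Xp[, starts + t, , drop = FALSE]
    better <- Xs > Y
    Y[better] <- Xs[better]
    winner[better] <- t
  }
  list(Y = Y, cache = list(winner = winner, starts = starts, size = size,
                           pad_left = g$pad_left, L = L,
                           Lp = dim(Xp)[2], B = B, C = C))
}

maxpool1d_backward <- function(cache, dY) {
  with(cache, {
    dXp <- array(0, dim = c(B, Lp, C))
    for (t in seq_len(size)) {
      contrib <- dY * (winner == t)
      dXp[, starts + t, ] <- dXp[, starts + t, , drop = FALSE] + contrib
    }
    list(dX = dXp[, pad_left + seq_len(L), , drop = FALSE])
  })
}

relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_backward <- function(cache, dY) dY * cache

# X: matrix [B, F]; W: [F, U]; b: numeric U
dense_forward <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, cache = list(X = X, W = W))
}

dense_backward <- function(cache, dY) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# Row-wise numerically stable soft-max
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Inverted dropout: mask scaled by 1/keep so inference needs no rescaling
dropout_mask <- function(dims, keep_prob) {
  if (keep_prob >= 1) return(NULL)
  mask <- matrix(stats::rbinom(prod(dims), 1, keep_prob), dims[1], dims[2])
  mask / keep_prob
}
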