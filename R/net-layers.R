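# Low-level layer primitives for the 1-D residual network.
#
# A batch is a matrix X of shape [C, L*B] (channels x positions, samples
# concatenated along columns; column (b-1)*L + t is position t of sample b)
# plus an integer vector of valid lengths. Convolutions are unpadded; the
# valid length shrinks through the network by the usual floor rules and
# columns beyond a sample's valid length are kept at zero after every layer
# so that batch statistics and pooling never see padding.

conv_len <- function(len, K, S) {
  out <- (len - K) %/% S + 1L
  pmax(out, 0L)
}

# logical column mask: TRUE where position <= valid length of its sample
col_mask <- function(L, len) {
  B <- length(len)
  seqs <- rep(seq_len(L), times = B)
  seqs <= rep(len, each = L)
}

zero_invalid <- function(X, cm) {
  if (!all(cm)) X[, !cm] <- 0
  X
}

conv_forward <- function(X, W, b, K, S, L_in, B) {
  L_out <- conv_len(L_in, K, S)
  stopifnot(L_out >= 1L)
  Y <- cpp_conv_forward(X, W, b, K, S, B)
  list(Y = Y, X = X, W = W, L_out = L_out, K = K, S = S)
}

conv_backward <- function(dY, cache, L_in, B) {
  cpp_conv_backward(cache$X, cache$W, dY, cache$K, cache$S, B)
}

no_mat <- matrix(0, 0, 0)

bn_forward <- function(X, gamma, beta, mmean, mvar, cm, training,
                       eps = 1e-3, momentum = 0.9) {
  if (training) {
    st <- cpp_row_stats_masked(X, cm)
    mu <- st$mean
    va <- st$var
    istd <- 1 / sqrt(va + eps)
    Y <- cpp_row_affine(X, no_mat, gamma * istd, numeric(0),
                        beta - gamma * mu * istd, cm, FALSE)
    list(Y = Y, X = X, mu = mu, istd = istd, nv = st$n,
         mmean = momentum * mmean + (1 - momentum) * mu,
         mvar = momentum * mvar + (1 - momentum) * va)
  } else {
    istd <- 1 / sqrt(mvar + eps)
    Y <- cpp_row_affine(X, no_mat, gamma * istd, numeric(0),
                        beta - gamma * mmean * istd, cm, FALSE)
    list(Y = Y)
  }
}

bn_backward <- function(dY, cache, gamma, cm) {
  dots <- cpp_row_dots_masked(dY, cache$X, cm)
  dbeta <- dots$sum
  dgamma <- cache$istd * (dots$sum_xprod - cache$mu * dots$sum)
  m_dy <- dgamma / cache$nv
  m_d <- dbeta / cache$nv
  gi <- gamma * cache$istd
  dX <- cpp_row_affine(dY, cache$X, gi, -gi * cache$istd * m_dy,
                       gi * (cache$istd * cache$mu * m_dy - m_d), cm,
                       FALSE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  if (is.matrix(X)) cpp_relu_forward(X) else pmax(X, 0)
}

relu_backward <- function(dY, A) {
  cpp_relu_backward(dY, A)
}

# masked global average pooling: [C, L*B] -> [C, B]
pool_forward <- function(X, L, B, len) {
  cpp_pool_forward(X, L, B, as.integer(len))
}

pool_backward <- function(dP, L, B, len, C) {
  cpp_pool_backward(dP, L, B, as.integer(len))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# per-sample crop to the first L_new positions: [C, L*B] -> [C, L_new*B]
crop_cols <- function(X, L, L_new, B) {
  cpp_crop_cols(X, L, L_new, B)
}

# inverse of crop_cols for gradients
uncrop_cols <- function(dY, L, L_new, B, C) {
  cpp_uncrop_cols(dY, L, L_new, B)
}
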