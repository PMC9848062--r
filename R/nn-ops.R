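# Matrix-level neural primitives. Each op returns its output plus the cache
# needed for the reverse pass; backward functions return gradients w.r.t.
# inputs and parameters. All state is plain R matrices so the whole model is
# deterministic and dependency-free.

.linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, X = X)
}

.linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W),
       dW = t(cache$X) %*% dY,
       db = colSums(dY))
}

.relu_fwd <- function(X) list(Y = pmax(X, 0), mask = X > 0)
.relu_bwd <- function(dY, cache) dY * cache$mask

.softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

.softmax_rows_bwd <- function(dY, Y) {
  (dY - rowSums(dY * Y)) * Y
}

# Row-wise layer normalization with learned gain/bias over channels.
.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat * rep(1, nrow(X)) %o% g, 2, b, "+")
  list(Y = Y, xhat = xhat, inv = inv, g = g)
}

.layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# Gated linear unit over the channel dimension: [a | b] -> a * sigmoid(b).
.glu_fwd <- function(X) {
  C2 <- ncol(X)
  if (C2 %% 2L != 0L) {
    rlang::abort("GLU input must have an even channel count.",
                 class = "cpinet_config_error")
  }
  h <- C2 %/% 2L
  a <- X[, seq_len(h), drop = FALSE]
  s <- 1 / (1 + exp(-X[, h + seq_len(h), drop = FALSE]))
  list(Y = a * s, a = a, s = s)
}

.glu_bwd <- function(dY, cache) {
  da <- dY * cache$s
  db <- dY * cache$a * cache$s * (1 - cache$s)
  cbind(da, db)
}

# Same-padding 1D convolution expressed as a gather + matrix product.
# idx is the L x k matrix of source positions (0 = zero pad).
.conv_idx <- function(L, k) {
  offs <- seq_len(k) - 1L - (k - 1L) %/% 2L
  idx <- outer(seq_len(L), offs, "+")
  idx[idx < 1L | idx > L] <- 0L
  idx
}

.conv1d_fwd <- function(X, W, b, idx) {
  L <- nrow(X); Cin <- ncol(X); k <- ncol(idx)
  Xpad <- rbind(numeric(Cin), X)  # row 1 = zero pad
  Xunf <- matrix(0, L, k * Cin)
  for (j in seq_len(k)) {
    Xunf[, (j - 1L) * Cin + seq_len(Cin)] <- Xpad[idx[, j] + 1L, , drop = FALSE]
  }
  Y <- sweep(Xunf %*% W, 2, b, "+")
  list(Y = Y, Xunf = Xunf, idx = idx, Cin = Cin)
}

.conv1d_bwd <- function(dY, cache, W) {
  idx <- cache$idx; Cin <- cache$Cin
  L <- nrow(dY); k <- ncol(idx)
  dXunf <- dY %*% t(W)
  dW <- t(cache$Xunf) %*% dY
  db <- colSums(dY)
  dXpad <- matrix(0, L + 1L, Cin)
  for (j in seq_len(k)) {
    rows <- idx[, j] + 1L
    dXpad[rows, ] <- dXpad[rows, ] + dXunf[, (j - 1L) * Cin + seq_len(Cin),
                                           drop = FALSE]
  }
  list(dX = dXpad[-1L, , drop = FALSE], dW = dW, db = db)
}

# Scaled dot-product attention with learned affine projections and an output
# projection. `scaling` follows the transformer convention 1/sqrt(C/d); the
# literal energy scale C/d is available as a configuration switch.
.attn_scale <- function(C, d, scaling) {
  if (scaling == "literal") C / d else 1 / sqrt(C / d)
}

.attention_fwd <- function(Qin, KVin, p, n_heads = 1L, scaling = "sqrt") {
  if (any(!is.finite(Qin)) || any(!is.finite(KVin))) {
    rlang::abort("Non-finite attention inputs.", class = "cpinet_numeric_error")
  }
  lq <- .linear_fwd(Qin, p$Wq, p$bq)
  lk <- .linear_fwd(KVin, p$Wk, p$bk)
  lv <- .linear_fwd(KVin, p$Wv, p$bv)
  C <- ncol(lq$Y)
  if (C %% n_heads != 0L) {
    rlang::abort("Attention dim must be divisible by the head count.",
                 class = "cpinet_config_error")
  }
  hd <- C %/% n_heads
  scal <- .attn_scale(C, n_heads, scaling)
  heads <- vector("list", n_heads)
  O <- matrix(0, nrow(Qin), C)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * hd + seq_len(hd)
    Qh <- lq$Y[, cols, drop = FALSE]
    Kh <- lk$Y[, cols, drop = FALSE]
    Vh <- lv$Y[, cols, drop = FALSE]
    S <- (Qh %*% t(Kh)) * scal
    E <- .softmax_rows(S)
    O[, cols] <- E %*% Vh
    heads[[h]] <- list(E = E, Qh = Qh, Kh = Kh, Vh = Vh, cols = cols)
  }
  lo <- .linear_fwd(O, p$Wo, p$bo)
  list(Y = lo$Y,
       energy = lapply(heads, `[[`, "E"),
       cache = list(lq = lq, lk = lk, lv = lv, lo = lo, heads = heads,
                    scal = scal, C = C, n_heads = n_heads))
}

.attention_bwd <- function(dY, cache, p) {
  cc <- cache$cache
  g_o <- .linear_bwd(dY, cc$lo, p$Wo)
  dO <- g_o$dX
  C <- cc$C
  dQ <- matrix(0, nrow(dO), C)
  dK <- matrix(0, nrow(cc$lk$Y), C)
  dV <- matrix(0, nrow(cc$lv$Y), C)
  for (hh in cc$heads) {
    dOh <- dO[, hh$cols, drop = FALSE]
    dE <- dOh %*% t(hh$Vh)
    dV[, hh$cols] <- t(hh$E) %*% dOh
    dS <- .softmax_rows_bwd(dE, hh$E)
    dQ[, hh$cols] <- (dS %*% hh$Kh) * cc$scal
    dK[, hh$cols] <- (t(dS) %*% hh$Qh) * cc$scal
  }
  g_q <- .linear_bwd(dQ, cc$lq, p$Wq)
  g_k <- .linear_bwd(dK, cc$lk, p$Wk)
  g_v <- .linear_bwd(dV, cc$lv, p$Wv)
  list(dQin = g_q$dX,
       dKVin = g_k$dX + g_v$dX,
       grads = list(Wq = g_q$dW, bq = g_q$db,
                    Wk = g_k$dW, bk = g_k$db,
                    Wv = g_v$dW, bv = g_v$db,
                    Wo = g_o$dW, bo = g_o$db))
}

# reshape a 1-D vector into n_tokens contiguous chunks (rows)
.to_tokens <- function(x, n_tokens) {
  if (length(x) %% n_tokens != 0L) {
    rlang::abort("Vector length is not divisible by n_tokens.",
                 class = "cpinet_config_error")
  }
  matrix(x, nrow = n_tokens, byrow = TRUE)
}

.from_tokens <- function(M) as.vector(t(M))

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}
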