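## Internal neural-network engine.
##
## Parameters live in a flat named list of numeric arrays; gradients mirror
## that structure.  Token activations are carried as a (N*p) x d matrix in
## sample-major row order (row (s-1)*p + k is token k of sample s); the
## public API converts to/from the N x d x p tensor layout.

LN_EPS <- 1e-5

## fan-in-scaled uniform draw (weights and biases), fully seed-determined
## by the caller's RNG state
init_lin <- function(n_in, n_out) {
  b <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -b, b), n_in, n_out),
       b = stats::runif(n_out, -b, b))
}

## add a bias row-vector to every row (column-major recycling)
addb <- function(X, b) X + rep(b, each = nrow(X))

gelu <- function(x) x * stats::pnorm(x)
dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## ---- parameter initialization -------------------------------------------

## widths: m * n_k per pathway; head_in depends on pooling
nn_init_params <- function(cfg, widths) {
  d <- cfg$embed_dim
  par <- list()
  for (k in seq_along(widths)) {
    bnd <- 1 / sqrt(widths[k])
    par[[sprintf("enc%d.W", k)]] <-
      matrix(stats::runif(d * widths[k], -bnd, bnd), d, widths[k])
    par[[sprintf("enc%d.b", k)]] <- stats::runif(d, -bnd, bnd)
  }
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("blk%d.", l)
    par[[paste0(pre, "ln1.g")]] <- rep(1, d)
    par[[paste0(pre, "ln1.b")]] <- rep(0, d)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      lin <- init_lin(d, d)
      par[[paste0(pre, nm)]] <- lin$W
      par[[paste0(pre, sub("W", "b", nm))]] <- lin$b
    }
    par[[paste0(pre, "ln2.g")]] <- rep(1, d)
    par[[paste0(pre, "ln2.b")]] <- rep(0, d)
    l1 <- init_lin(d, cfg$mlp_hidden)
    l2 <- init_lin(cfg$mlp_hidden, d)
    par[[paste0(pre, "W1")]] <- l1$W; par[[paste0(pre, "b1")]] <- l1$b
    par[[paste0(pre, "W2")]] <- l2$W; par[[paste0(pre, "b2")]] <- l2$b
  }
  head_in <- if (cfg$pooling == "flatten") d * length(widths) else d
  dims <- c(head_in, cfg$head_hidden, cfg$output_dim)
  for (i in seq_len(length(dims) - 1L)) {
    lin <- init_lin(dims[i], dims[i + 1L])
    par[[sprintf("head%d.W", i)]] <- lin$W
    par[[sprintf("head%d.b", i)]] <- lin$b
  }
  par
}

## ---- layer norm ----------------------------------------------------------

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd <- sqrt(rowMeans(Xc * Xc) + LN_EPS)
  xhat <- Xc / sd
  Y <- addb(xhat * rep(g, each = nrow(X)), b)
  list(Y = Y, xhat = xhat, sd = sd)
}

ln_bwd <- function(dY, g, cache) {
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sd
  list(dX = dX,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

## ---- transformer block ---------------------------------------------------

## pre-norm residual block over p tokens per sample:
##   x + MHSA(LN(x)), then + MLP(LN(.))
## Compiled kernels (src/blocks.cpp) carry the block math; these wrappers
## keep the flat parameter list and cache conventions on the R side.
block_fwd <- function(Tm, par, pre, N, p, n_heads, keep_cache = TRUE) {
  block_fwd_cpp(Tm, par, pre, N, p, n_heads, keep_cache)
}

block_bwd <- function(dout, par, pre, cache, N, p, n_heads, gr) {
  res <- block_bwd_cpp(dout, par, pre, cache, N, p, n_heads)
  g <- lapply(res$gr, function(x)
    if (is.matrix(x) && nrow(x) == 1L) as.vector(x) else x)
  gr[names(g)] <- g
  list(dTm = res$dTm, gr = gr)
}

## ---- full forward --------------------------------------------------------

## A_list: per-pathway input matrices (N x m*n_k).  drop_mask: logical keep
## vector of length p (TRUE = keep); NULL in evaluation mode.
nn_forward <- function(par, cfg, A_list, training = FALSE, drop_mask = NULL,
                       keep_cache = FALSE) {
  N <- nrow(A_list[[1]])
  p <- length(A_list)
  d <- cfg$embed_dim
  H0 <- matrix(0, N * p, d)
  for (k in seq_len(p)) {
    idx <- (seq_len(N) - 1L) * p + k
    H0[idx, ] <- addb(tcrossprod(A_list[[k]], par[[sprintf("enc%d.W", k)]]),
                      par[[sprintf("enc%d.b", k)]])
  }
  fac <- NULL
  Tm <- H0
  if (training && cfg$pathway_dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- stats::runif(p) >= cfg$pathway_dropout
    fac <- rep(as.numeric(drop_mask) / (1 - cfg$pathway_dropout), N)
    Tm <- H0 * fac
  }
  blocks <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    blocks[[l]] <- block_fwd(Tm, par, sprintf("blk%d.", l), N, p, cfg$n_heads,
                             keep_cache = keep_cache)
    Tm <- blocks[[l]]$out
  }
  if (cfg$pooling == "flatten") {
    b <- array(t(Tm), dim = c(d, p, N))
    pooled <- t(matrix(b, d * p, N))
  } else {
    grp <- rep(seq_len(N), each = p)
    pooled <- rowsum(Tm, grp) / p
  }
  ## head MLP (ReLU between hidden layers, linear output)
  nh <- length(cfg$head_hidden) + 1L
  hin <- vector("list", nh)
  hpre <- vector("list", nh)
  X <- pooled
  for (i in seq_len(nh)) {
    hin[[i]] <- X
    Z <- addb(X %*% par[[sprintf("head%d.W", i)]], par[[sprintf("head%d.b", i)]])
    hpre[[i]] <- Z
    X <- if (i < nh) pmax(Z, 0) else Z
  }
  out <- X
  res <- list(out = out, drop_mask = drop_mask)
  if (keep_cache)
    res$cache <- list(A_list = A_list, H0 = H0, fac = fac, blocks = blocks,
                      tokens = Tm, pooled = pooled, hin = hin, hpre = hpre,
                      N = N, p = p)
  res
}

nn_backward <- function(par, cfg, cache, dout) {
  N <- cache$N; p <- cache$p; d <- cfg$embed_dim
  gr <- list()
  nh <- length(cfg$head_hidden) + 1L
  dX <- dout
  for (i in rev(seq_len(nh))) {
    if (i < nh) dX <- dX * (cache$hpre[[i]] > 0)
    gr[[sprintf("head%d.W", i)]] <- crossprod(cache$hin[[i]], dX)
    gr[[sprintf("head%d.b", i)]] <- colSums(dX)
    dX <- dX %*% t(par[[sprintf("head%d.W", i)]])
  }
  dpooled <- dX
  if (cfg$pooling == "flatten") {
    dTm <- matrix(0, N * p, d)
    for (k in seq_len(p)) {
      idx <- (seq_len(N) - 1L) * p + k
      dTm[idx, ] <- dpooled[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
    }
  } else {
    grp <- rep(seq_len(N), each = p)
    dTm <- dpooled[grp, , drop = FALSE] / p
  }
  for (l in rev(seq_len(cfg$n_layers))) {
    bb <- block_bwd(dTm, par, sprintf("blk%d.", l), cache$blocks[[l]],
                    N, p, cfg$n_heads, gr)
    dTm <- bb$dTm
    gr <- bb$gr
  }
  if (!is.null(cache$fac)) dTm <- dTm * cache$fac
  for (k in seq_len(p)) {
    idx <- (seq_len(N) - 1L) * p + k
    dHk <- dTm[idx, , drop = FALSE]
    gr[[sprintf("enc%d.W", k)]] <- crossprod(dHk, cache$A_list[[k]])
    gr[[sprintf("enc%d.b", k)]] <- colSums(dHk)
  }
  gr
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(par) {
  zero <- lapply(par, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

## A parameter whose gradient is exactly zero receives an exactly-zero
## update (its moments stay at zero), so untouched weights are preserved
## bit-for-bit when weight_decay is 0.
adam_step <- function(par, gr, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- gr[[nm]]
    if (is.null(g)) next
    if (is.matrix(g) && !is.matrix(par[[nm]])) g <- as.vector(g)
    if (weight_decay > 0) g <- g + weight_decay * par[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, state = st)
}

## tensor layout conversions: flat (N*p) x d  <->  array N x d x p
flat_to_tensor <- function(X, N, p) {
  d <- ncol(X)
  aperm(array(t(X), dim = c(d, p, N)), c(3L, 1L, 2L))
}

tensor_to_flat <- function(a) {
  N <- dim(a)[1]; d <- dim(a)[2]; p <- dim(a)[3]
  t(matrix(aperm(a, c(2L, 3L, 1L)), d, p * N))
}
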