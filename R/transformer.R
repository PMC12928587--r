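# Forward and backward passes of the toy transformer, written directly in
# matrix algebra. Minibatches are processed as one stacked row matrix with
# block-diagonal attention (each sequence attends only to itself), which
# keeps the linear algebra in large BLAS calls. The backward pass returns
# gradients with respect to the *effective* (mask-multiplied) weights,
# which is exactly what both weight pretraining (mask absent) and mask
# learning (chain rule through the Hadamard product) consume.

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  n <- nrow(x); d <- ncol(x)
  mu <- .rowMeans(x, n, d)
  xc <- x - mu                      # vector recycles down rows
  v <- .rowMeans(xc * xc, n, d)
  sd <- sqrt(v + LN_EPS)
  xhat <- xc / sd
  y <- xhat * row_broadcast(g, n) + row_broadcast(b, n)
  list(y = y, cache = list(xhat = xhat, sd = sd, g = g))
}

layernorm_bwd <- function(dy, cache) {
  n <- nrow(dy); d <- ncol(dy)
  xhat <- cache$xhat
  dxhat <- dy * row_broadcast(cache$g, n)
  m1 <- .rowMeans(dxhat, n, d)
  m2 <- .rowMeans(dxhat * xhat, n, d)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, dg = .colSums(dy * xhat, n, d), db = .colSums(dy, n, d))
}

# tanh-approximation GELU (the BERT variant); the forward pass caches the
# tanh term so the backward pass needs no further special functions.
GELU_C <- sqrt(2 / pi)
gelu_fwd <- function(z) {
  u <- tanh(GELU_C * (z + 0.044715 * z^3))
  list(y = 0.5 * z * (1 + u), u = u)
}
gelu_grad <- function(z, u) {
  0.5 * (1 + u) + 0.5 * z * (1 - u * u) * GELU_C * (1 + 3 * 0.044715 * z^2)
}

# Forward pass over a list of token sequences, stacked row-wise. Returns
# `probs` (sum(L) x 20), `rows` (per-sequence row ranges) and, optionally,
# every intermediate needed by toy_backward_batch().
toy_forward_batch <- function(params, hyper, tokens_list, want_cache = FALSE) {
  lens <- lengths(tokens_list)
  if (any(lens < 1L)) stop("empty token sequence", call. = FALSE)
  if (max(lens) > hyper$max_len) {
    stop("sequence length ", max(lens), " exceeds model max_len ",
         hyper$max_len, call. = FALSE)
  }
  N <- sum(lens)
  ends <- cumsum(lens)
  rows <- Map(function(e, l) (e - l + 1L):e, ends, lens)
  tokens_cat <- unlist(tokens_list, use.names = FALSE)
  pos_cat <- unlist(lapply(lens, seq_len), use.names = FALSE)
  d <- hyper$width; nh <- hyper$heads; dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  x <- params$tok_emb[tokens_cat, , drop = FALSE] +
    params$pos_emb[pos_cat, , drop = FALSE]
  caches <- if (want_cache) vector("list", hyper$depth) else NULL
  for (b in seq_len(hyper$depth)) {
    p <- params$blocks[[b]]
    ln1 <- layernorm_fwd(x, p$ln1_g, p$ln1_b)
    h1 <- ln1$y
    Q <- h1 %*% p$Wq + row_broadcast(p$bq, N)
    K <- h1 %*% p$Wk + row_broadcast(p$bk, N)
    V <- h1 %*% p$Wv + row_broadcast(p$bv, N)
    A_all <- vector("list", length(rows))
    concat <- matrix(0, N, d)
    for (si in seq_along(rows)) {
      rr <- rows[[si]]
      A_heads <- vector("list", nh)
      for (hd in seq_len(nh)) {
        cols <- (hd - 1L) * dh + seq_len(dh)
        S <- tcrossprod(Q[rr, cols, drop = FALSE], K[rr, cols, drop = FALSE]) * scale
        A <- softmax_rows(S)
        A_heads[[hd]] <- A
        concat[rr, cols] <- A %*% V[rr, cols, drop = FALSE]
      }
      A_all[[si]] <- A_heads
    }
    attn <- concat %*% p$Wo + row_broadcast(p$bo, N)
    x_mid <- x + attn
    ln2 <- layernorm_fwd(x_mid, p$ln2_g, p$ln2_b)
    h2 <- ln2$y
    Z <- h2 %*% p$W1 + row_broadcast(p$b1, N)
    gl <- gelu_fwd(Z)
    G <- gl$y
    x <- x_mid + G %*% p$W2 + row_broadcast(p$b2, N)
    if (want_cache) {
      caches[[b]] <- list(ln1 = ln1$cache, h1 = h1, Q = Q, K = K, V = V,
                          A_all = A_all, concat = concat,
                          ln2 = ln2$cache, h2 = h2, Z = Z, G = G, U = gl$u)
    }
  }
  lnf <- layernorm_fwd(x, params$lnf_g, params$lnf_b)
  hf <- lnf$y
  logits <- hf %*% params$W_head + row_broadcast(params$b_head, N)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, rows = rows)
  if (want_cache) {
    out$cache <- list(tokens_cat = tokens_cat, pos_cat = pos_cat, N = N,
                      rows = rows, caches = caches, lnf = lnf$cache, hf = hf,
                      params = params)
  }
  out
}

# Single-sequence convenience wrapper (probs only, rows dropped).
toy_forward <- function(params, hyper, tokens, want_cache = FALSE) {
  out <- toy_forward_batch(params, hyper, list(tokens), want_cache = want_cache)
  out
}

# Backward pass from a gradient at the stacked output logits (N x 20).
# Returns a gradient structure mirroring `params`.
toy_backward_batch <- function(hyper, cache, dlogits) {
  params <- cache$params
  N <- cache$N; d <- hyper$width; nh <- hyper$heads; dh <- d %/% nh
  rows <- cache$rows
  scale <- 1 / sqrt(dh)
  g <- list()
  g$W_head <- crossprod(cache$hf, dlogits)
  g$b_head <- colSums(dlogits)
  dhf <- tcrossprod(dlogits, params$W_head)
  lb <- layernorm_bwd(dhf, cache$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  g$blocks <- vector("list", hyper$depth)
  for (b in rev(seq_len(hyper$depth))) {
    p <- params$blocks[[b]]
    cc <- cache$caches[[b]]
    gb <- list()
    # feed-forward branch
    dF <- dx
    gb$W2 <- crossprod(cc$G, dF)
    gb$b2 <- colSums(dF)
    dG <- tcrossprod(dF, p$W2)
    dZ <- dG * gelu_grad(cc$Z, cc$U)
    gb$W1 <- crossprod(cc$h2, dZ)
    gb$b1 <- colSums(dZ)
    dh2 <- tcrossprod(dZ, p$W1)
    lb2 <- layernorm_bwd(dh2, cc$ln2)
    gb$ln2_g <- lb2$dg; gb$ln2_b <- lb2$db
    dx_mid <- dx + lb2$dx
    # attention branch
    dO <- dx_mid
    gb$Wo <- crossprod(cc$concat, dO)
    gb$bo <- colSums(dO)
    dconcat <- tcrossprod(dO, p$Wo)
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (si in seq_along(rows)) {
      rr <- rows[[si]]
      for (hd in seq_len(nh)) {
        cols <- (hd - 1L) * dh + seq_len(dh)
        A <- cc$A_all[[si]][[hd]]
        dOh <- dconcat[rr, cols, drop = FALSE]
        Vh <- cc$V[rr, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rr, cols] <- crossprod(A, dOh)
        dS <- A * (dA - .rowSums(dA * A, nrow(dA), ncol(dA)))
        dQ[rr, cols] <- (dS %*% cc$K[rr, cols, drop = FALSE]) * scale
        dK[rr, cols] <- crossprod(dS, cc$Q[rr, cols, drop = FALSE]) * scale
      }
    }
    gb$Wq <- crossprod(cc$h1, dQ); gb$bq <- colSums(dQ)
    gb$Wk <- crossprod(cc$h1, dK); gb$bk <- colSums(dK)
    gb$Wv <- crossprod(cc$h1, dV); gb$bv <- colSums(dV)
    dh1 <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
    lb1 <- layernorm_bwd(dh1, cc$ln1)
    gb$ln1_g <- lb1$dg; gb$ln1_b <- lb1$db
    dx <- dx_mid + lb1$dx
    g$blocks[[b]] <- gb
  }
  # embeddings: scatter-add stacked rows back to embedding rows
  dtok <- matrix(0, nrow(params$tok_emb), d)
  acc <- rowsum(dx, group = cache$tokens_cat)
  dtok[as.integer(rownames(acc)), ] <- acc
  g$tok_emb <- dtok
  dpos <- matrix(0, nrow(params$pos_emb), d)
  accp <- rowsum(dx, group = cache$pos_cat)
  dpos[as.integer(rownames(accp)), ] <- accp
  g$pos_emb <- dpos
  g
}

toy_backward <- function(hyper, cache, dlogits) {
  toy_backward_batch(hyper, cache, dlogits)
}

# ---- gradient-structure arithmetic -----------------------------------------

zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# Recurse by name where names exist (sub-lists may order their elements
# differently), by position otherwise (the unnamed per-block list).
tree_keys <- function(x) if (is.null(names(x))) seq_along(x) else names(x)

add_grads <- function(a, b) {
  if (is.list(a)) {
    out <- a
    for (k in tree_keys(a)) out[[k]] <- add_grads(a[[k]], b[[k]])
    return(out)
  }
  a + b
}

scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

# Chain rule through the Hadamard mask: dL/dm_i = dL/dW_eff_i * W_i, where
# W is the *stored* (unmasked) weight. Returns the flat length-K vector.
mask_grad_from_weight_grads <- function(model, grads) {
  man <- maskable_index(model)
  out <- numeric(attr(man, "K"))
  for (r in seq_len(nrow(man))) {
    W <- model$params$blocks[[man$layer[r]]][[man$module[r]]]
    gW <- grads$blocks[[man$layer[r]]][[man$module[r]]]
    out[man$offset[r] + seq_len(man$length[r])] <- as.vector(gW * W)
  }
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(template) {
  list(m = zero_grads(template), v = zero_grads(template), t = 0L)
}

adam_update_leaf <- function(x, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step_tree <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  step <- function(x, g, m, v) {
    if (is.list(x)) {
      for (k in tree_keys(x)) {
        res <- step(x[[k]], g[[k]], m[[k]], v[[k]])
        x[[k]] <- res$x; m[[k]] <- res$m; v[[k]] <- res$v
      }
      return(list(x = x, m = m, v = v))
    }
    adam_update_leaf(x, g, m, v, lr, state$t)
  }
  res <- step(params, grads, state$m, state$v)
  list(params = res$x, state = list(m = res$m, v = res$v, t = state$t))
}

# Flat-vector Adam (used for mask logits).
adam_step_flat <- function(x, g, state, lr) {
  state$t <- state$t + 1L
  res <- adam_update_leaf(x, g, state$m, state$v, lr, state$t)
  list(x = res$x, state = list(m = res$m, v = res$v, t = state$t))
}

adam_init_flat <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)
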