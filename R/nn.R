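# Minimal seeded neural-net machinery for the base text classifiers.
#
# Documents are handled as flattened doc-major matrices: a batch of B encoded
# documents padded to L tokens becomes a (B*L) x d matrix whose row
# (b-1)*L + t holds the embedding of token t of document b. Convolutions are
# im2col + one BLAS matmul; positions beyond a document's true length are
# kept at zero (or -Inf masked inside max-pooling). All gradients are derived
# by hand and verified against finite differences in the test suite.
#
# Class coding at the output layer: column 1 = negative, column 2 = positive.

nn_init_dense <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

nn_init_embedding <- function(n_rows, d) {
  E <- matrix(stats::rnorm(n_rows * d, sd = 0.1), n_rows, d)
  E[1L, ] <- 0 # padding row stays zero forever (its gradient is zeroed too)
  E
}

# scatter-add token gradients into embedding rows; ids_flat are 0-based ids
grad_embedding <- function(dX, ids_flat, n_rows) {
  keep <- !is.na(ids_flat)
  g <- rowsum(dX[keep, , drop = FALSE], group = ids_flat[keep])
  dE <- matrix(0, n_rows, ncol(dX))
  rows <- as.integer(rownames(g)) + 1L
  dE[rows, ] <- g
  dE[1L, ] <- 0
  dE
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# returns mean cross-entropy and d(loss)/d(logits); y is 0/1
softmax_ce <- function(logits, y) {
  probs <- softmax_rows(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}

# ---- convolution helpers -------------------------------------------------

# k index vectors (length B*Lout) into rbind(X, zero-row) for each window slot;
# memoised, since the same (B, L, k, pad) recurs every batch
conv_idx_cache <- new.env(parent = emptyenv())

conv_idx <- function(B, L, k, pad) {
  key <- sprintf("%d_%d_%d_%d", B, L, k, pad)
  hit <- conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- conv_idx_build(B, L, k, pad)
  if (length(ls(conv_idx_cache)) > 200L) {
    rm(list = ls(conv_idx_cache), envir = conv_idx_cache)
  }
  conv_idx_cache[[key]] <- out
  out
}

conv_idx_build <- function(B, L, k, pad) {
  Lout <- L + 2L * pad - k + 1L
  stopifnot(Lout >= 1L)
  zrow <- B * L + 1L
  docoff <- (seq_len(B) - 1L) * L
  starts <- seq_len(Lout) - pad # 1-based token position of window slot 1
  idx <- vector("list", k)
  for (o in 0:(k - 1L)) {
    tpos <- starts + o
    m <- outer(tpos, docoff, "+")
    m[tpos < 1L | tpos > L, ] <- zrow
    idx[[o + 1L]] <- as.vector(m)
  }
  list(idx = idx, Lout = Lout, zrow = zrow)
}

conv_forward <- function(X, B, L, K, bias, k, pad) {
  ci <- conv_idx(B, L, k, pad)
  d <- ncol(X)
  Xz <- rbind(X, 0)
  Wm <- matrix(0, B * ci$Lout, k * d)
  for (o in seq_len(k)) {
    Wm[, ((o - 1L) * d + 1L):(o * d)] <- Xz[ci$idx[[o]], , drop = FALSE]
  }
  Z <- Wm %*% K
  Z <- sweep(Z, 2L, bias, "+")
  list(Z = Z, Wm = Wm, ci = ci, k = k, d = d, B = B, L = L, pad = pad)
}

conv_backward <- function(fwd, dZ) {
  dK <- crossprod(fwd$Wm, dZ)
  dbias <- colSums(dZ)
  k <- fwd$k
  d <- fwd$d
  F_ <- ncol(dZ)
  # input gradient as a transposed convolution: im2col over dZ with padding
  # k-1-pad against the offset-flipped, transposed kernel — one BLAS matmul
  # instead of a scatter pass
  ci2 <- conv_idx(fwd$B, fwd$ci$Lout, k, k - 1L - fwd$pad)
  dZz <- rbind(dZ, 0)
  Wm2 <- matrix(0, fwd$B * ci2$Lout, k * F_)
  for (o in seq_len(k)) {
    Wm2[, ((o - 1L) * F_ + 1L):(o * F_)] <- dZz[ci2$idx[[o]], , drop = FALSE]
  }
  Kflip <- matrix(0, k * F_, d)
  for (o in seq_len(k)) {
    rows <- ((k - o) * d + 1L):((k - o + 1L) * d)
    Kflip[((o - 1L) * F_ + 1L):(o * F_), ] <- t(fwd$K_used[rows, , drop = FALSE])
  }
  list(dX = Wm2 %*% Kflip, dK = dK, dbias = dbias)
}

# zero activations at positions beyond each document's true length
zero_invalid <- function(Z, B, L, lens) {
  tpos <- rep(seq_len(L), B)
  doc <- rep(seq_len(B), each = L)
  Z[tpos > lens[doc], ] <- 0
  Z
}

# ---- pooling -------------------------------------------------------------

# global max over valid positions; returns pooled (B x F) and argmax positions.
# The (B*L) x F doc-major matrix reinterprets as L x (B*F) column-major, so
# one masked max.col pass covers every (document, filter) pair.
global_maxpool <- function(Z, B, L, valid_lens) {
  F_ <- ncol(Z)
  A <- matrix(Z, nrow = L)
  mask <- outer(seq_len(L), valid_lens, ">")
  A[rep(as.vector(mask), F_)] <- -Inf
  am <- max.col(t(A), ties.method = "first")
  pooled <- A[(seq_along(am) - 1L) * L + am]
  pooled[!is.finite(pooled)] <- 0
  list(pooled = matrix(pooled, B, F_), argmax = matrix(am, B, F_))
}

global_maxpool_backward <- function(dpooled, argmax, B, L, F_) {
  dZ <- matrix(0, B * L, F_)
  rows <- (seq_len(B) - 1L) * L
  lin <- (rows + argmax) + (rep(seq_len(F_), each = B) - 1L) * (B * L)
  dZ[lin] <- dpooled
  dZ
}

# stride-2 size-2 max pooling with length masking (the pyramid halving step)
pool2_forward <- function(Z, B, L, lens) {
  F_ <- ncol(Z)
  Lout <- as.integer(ceiling(L / 2))
  tpos <- rep(seq_len(L), B)
  doc <- rep(seq_len(B), each = L)
  Zm <- Z
  Zm[tpos > lens[doc], ] <- -Inf
  zrow <- B * L + 1L
  Zz <- rbind(Zm, -Inf)
  docoff <- (seq_len(B) - 1L) * L
  pa <- 2L * seq_len(Lout) - 1L
  pb <- 2L * seq_len(Lout)
  ma <- outer(pa, docoff, "+")
  mb <- outer(pb, docoff, "+")
  mb[pb > L, ] <- zrow
  ja <- as.vector(ma)
  jb <- as.vector(mb)
  Za <- Zz[ja, , drop = FALSE]
  Zb <- Zz[jb, , drop = FALSE]
  takeb <- Zb > Za
  P <- Za
  P[takeb] <- Zb[takeb]
  lens_out <- pmax(as.integer(ceiling(lens / 2)), 1L)
  opos <- rep(seq_len(Lout), B)
  odoc <- rep(seq_len(B), each = Lout)
  invalid_out <- opos > lens_out[odoc]
  P[invalid_out | !is.finite(P)] <- 0
  list(P = P, takeb = takeb, ja = ja, jb = jb, Lout = Lout,
       lens_out = lens_out, invalid_out = invalid_out, zrow = zrow)
}

pool2_backward <- function(fwd, dP, B, L) {
  F_ <- ncol(dP)
  dP[fwd$invalid_out, ] <- 0
  nout <- length(fwd$ja)
  Ja <- matrix(fwd$ja, nout, F_)
  Jb <- matrix(fwd$jb, nout, F_)
  R <- Ja
  R[fwd$takeb] <- Jb[fwd$takeb]
  dZ <- matrix(0, B * L, F_)
  keep <- R != fwd$zrow & dP != 0
  lin <- R[keep] + (rep(seq_len(F_), each = nout)[as.vector(keep)] - 1L) * (B * L)
  dZ[lin] <- dP[keep]
  dZ
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- architectures -------------------------------------------------------

# Each architecture implements:
#   <arch>_init(vocab_size, config)              -> named list of parameters
#   <arch>_forward(params, ids, lens, config)    -> list(logits, cache)
#   <arch>_backward(params, cache, dlogits)      -> named list of gradients
# ids: B x L integer matrix of 0-based token ids (0 = pad); lens: true lengths.

fasttext_hash <- function(a, b, buckets) {
  ((a * 2654435761 + b * 97) %% buckets)
}

fasttext_init <- function(vocab_size, config) {
  d <- config$embedding_dim
  list(E = nn_init_embedding(vocab_size + config$hash_buckets, d),
       W = nn_init_dense(d, 2L),
       b = rep(0, 2L))
}

fasttext_token_rows <- function(ids, lens, config, vocab_size) {
  B <- nrow(ids)
  L <- ncol(ids)
  doc <- rep(seq_len(B), each = L)
  tpos <- rep(seq_len(L), B)
  uni <- as.vector(t(ids))
  uni_valid <- tpos <= lens[doc]
  n_bi <- pmax(lens - 1L, 0L)
  if (L >= 2L && config$ngram >= 2L) {
    a <- as.vector(t(ids[, -L, drop = FALSE]))
    b <- as.vector(t(ids[, -1L, drop = FALSE]))
    bdoc <- rep(seq_len(B), each = L - 1L)
    bpos <- rep(seq_len(L - 1L), B)
    bi_valid <- bpos <= (lens[bdoc] - 1L)
    bi <- vocab_size + fasttext_hash(a, b, config$hash_buckets)
  } else {
    bi <- integer(0); bdoc <- integer(0); bi_valid <- logical(0)
    n_bi <- rep(0L, B)
  }
  list(
    rows = c(uni[uni_valid], bi[bi_valid]),
    doc = c(doc[uni_valid], bdoc[bi_valid]),
    total = lens + if (config$ngram >= 2L) n_bi else 0L
  )
}

fasttext_forward <- function(params, ids, lens, config) {
  B <- nrow(ids)
  tok <- fasttext_token_rows(ids, lens, config,
                             nrow(params$E) - config$hash_buckets)
  S <- rowsum(params$E[tok$rows + 1L, , drop = FALSE], group = tok$doc)
  # rowsum orders groups numerically; every doc has >= 1 token
  h <- S[order(as.integer(rownames(S))), , drop = FALSE] / tok$total
  logits <- sweep(h %*% params$W, 2L, params$b, "+")
  list(logits = logits, cache = list(h = h, tok = tok, B = B))
}

fasttext_backward <- function(params, cache, dlogits) {
  dW <- crossprod(cache$h, dlogits)
  db <- colSums(dlogits)
  dh <- dlogits %*% t(params$W)
  tok <- cache$tok
  contrib <- dh[tok$doc, , drop = FALSE] / cache$tok$total[tok$doc]
  dE <- grad_embedding(contrib, tok$rows, nrow(params$E))
  list(E = dE, W = dW, b = db)
}

textcnn_init <- function(vocab_size, config) {
  d <- config$embedding_dim
  F_ <- config$n_filters
  params <- list(E = nn_init_embedding(vocab_size, d))
  for (k in config$kernel_sizes) {
    params[[paste0("K", k)]] <- nn_init_dense(k * d, F_)
    params[[paste0("bk", k)]] <- rep(0, F_)
  }
  params$W <- nn_init_dense(length(config$kernel_sizes) * F_, 2L)
  params$b <- rep(0, 2L)
  params
}

textcnn_forward <- function(params, ids, lens, config) {
  B <- nrow(ids)
  L <- ncol(ids)
  flat <- as.vector(t(ids))
  X <- params$E[flat + 1L, , drop = FALSE]
  F_ <- config$n_filters
  caches <- list()
  pooled_all <- matrix(0, B, 0)
  for (k in config$kernel_sizes) {
    fwd <- conv_forward(X, B, L, params[[paste0("K", k)]],
                        params[[paste0("bk", k)]], k, pad = 0L)
    fwd$K_used <- params[[paste0("K", k)]]
    A <- pmax(fwd$Z, 0)
    valid <- pmax(lens - k + 1L, 1L)
    mp <- global_maxpool(A, B, fwd$ci$Lout, valid)
    caches[[as.character(k)]] <- list(fwd = fwd, relu_mask = fwd$Z > 0,
                                      mp = mp, Lout = fwd$ci$Lout)
    pooled_all <- cbind(pooled_all, mp$pooled)
  }
  logits <- sweep(pooled_all %*% params$W, 2L, params$b, "+")
  list(logits = logits,
       cache = list(caches = caches, pooled = pooled_all, flat = flat,
                    B = B, L = L, F_ = F_))
}

textcnn_backward <- function(params, cache, dlogits) {
  B <- cache$B
  L <- cache$L
  F_ <- cache$F_
  grads <- list()
  grads$W <- crossprod(cache$pooled, dlogits)
  grads$b <- colSums(dlogits)
  dpooled <- dlogits %*% t(params$W)
  dX <- matrix(0, B * L, ncol(params$E))
  col0 <- 0L
  for (k in names(cache$caches)) {
    cc <- cache$caches[[k]]
    dp <- dpooled[, (col0 + 1L):(col0 + F_), drop = FALSE]
    col0 <- col0 + F_
    dA <- global_maxpool_backward(dp, cc$mp$argmax, B, cc$Lout, F_)
    dZ <- dA * cc$relu_mask
    bk <- conv_backward(cc$fwd, dZ)
    grads[[paste0("K", k)]] <- bk$dK
    grads[[paste0("bk", k)]] <- bk$dbias
    dX <- dX + bk$dX
  }
  grads$E <- grad_embedding(dX, cache$flat, nrow(params$E))
  grads
}

dpcnn_init <- function(vocab_size, config) {
  d <- config$embedding_dim
  F_ <- config$n_filters
  params <- list(E = nn_init_embedding(vocab_size, d),
                 K0 = nn_init_dense(3L * d, F_), b0 = rep(0, F_))
  for (i in seq_len(config$n_blocks)) {
    params[[paste0("K1_", i)]] <- nn_init_dense(3L * F_, F_)
    params[[paste0("b1_", i)]] <- rep(0, F_)
    params[[paste0("K2_", i)]] <- nn_init_dense(3L * F_, F_)
    params[[paste0("b2_", i)]] <- rep(0, F_)
  }
  params$W <- nn_init_dense(F_, 2L)
  params$b <- rep(0, 2L)
  params
}

dpcnn_forward <- function(params, ids, lens, config) {
  B <- nrow(ids)
  L <- ncol(ids)
  flat <- as.vector(t(ids))
  X <- params$E[flat + 1L, , drop = FALSE]
  f0 <- conv_forward(X, B, L, params$K0, params$b0, 3L, pad = 1L)
  f0$K_used <- params$K0
  Z <- zero_invalid(f0$Z, B, L, lens)
  blocks <- list()
  curL <- L
  curlens <- lens
  for (i in seq_len(config$n_blocks)) {
    pf <- pool2_forward(Z, B, curL, curlens)
    Zp <- pf$P
    pL <- pf$Lout
    plens <- pf$lens_out
    A1 <- pmax(Zp, 0)
    f1 <- conv_forward(A1, B, pL, params[[paste0("K1_", i)]],
                       params[[paste0("b1_", i)]], 3L, pad = 1L)
    f1$K_used <- params[[paste0("K1_", i)]]
    C1 <- zero_invalid(f1$Z, B, pL, plens)
    A2 <- pmax(C1, 0)
    f2 <- conv_forward(A2, B, pL, params[[paste0("K2_", i)]],
                       params[[paste0("b2_", i)]], 3L, pad = 1L)
    f2$K_used <- params[[paste0("K2_", i)]]
    C2 <- zero_invalid(f2$Z, B, pL, plens)
    blocks[[i]] <- list(pf = pf, inL = curL, inlens = curlens,
                        f1 = f1, f2 = f2, Zp = Zp, C1 = C1,
                        pL = pL, plens = plens)
    Z <- Zp + C2
    curL <- pL
    curlens <- plens
  }
  mp <- global_maxpool(Z, B, curL, curlens)
  logits <- sweep(mp$pooled %*% params$W, 2L, params$b, "+")
  list(logits = logits,
       cache = list(f0 = f0, blocks = blocks, mp = mp, flat = flat,
                    B = B, L = L, lens = lens, curL = curL))
}

dpcnn_backward <- function(params, cache, dlogits) {
  B <- cache$B
  F_ <- ncol(cache$mp$pooled)
  grads <- list()
  grads$W <- crossprod(cache$mp$pooled, dlogits)
  grads$b <- colSums(dlogits)
  dpooled <- dlogits %*% t(params$W)
  dZ <- global_maxpool_backward(dpooled, cache$mp$argmax, B, cache$curL, F_)
  for (i in rev(seq_along(cache$blocks))) {
    bl <- cache$blocks[[i]]
    tpos <- rep(seq_len(bl$pL), B)
    doc <- rep(seq_len(B), each = bl$pL)
    inval <- tpos > bl$plens[doc]
    dC2 <- dZ
    dC2[inval, ] <- 0
    b2 <- conv_backward(bl$f2, dC2)
    grads[[paste0("K2_", i)]] <- b2$dK
    grads[[paste0("b2_", i)]] <- b2$dbias
    dC1 <- b2$dX * (bl$C1 > 0)
    dC1[inval, ] <- 0
    b1 <- conv_backward(bl$f1, dC1)
    grads[[paste0("K1_", i)]] <- b1$dK
    grads[[paste0("b1_", i)]] <- b1$dbias
    dZp <- dZ + b1$dX * (bl$Zp > 0)
    dZ <- pool2_backward(bl$pf, dZp, B, bl$inL)
  }
  dZ0 <- zero_invalid(dZ, B, cache$L, cache$lens)
  b0 <- conv_backward(cache$f0, dZ0)
  grads$K0 <- b0$dK
  grads$b0 <- b0$dbias
  grads$E <- grad_embedding(b0$dX, cache$flat, nrow(params$E))
  grads
}

# deterministic fast test double: logistic regression on normalised
# bag-of-words counts (convex, so seed differences only shift the start)
dummy_init <- function(vocab_size, config) {
  list(W = matrix(0, vocab_size, 2L), b = rep(0, 2L))
}

dummy_bow <- function(ids, lens, vocab_size) {
  B <- nrow(ids)
  L <- ncol(ids)
  doc <- rep(seq_len(B), each = L)
  tpos <- rep(seq_len(L), B)
  flat <- as.vector(t(ids))
  valid <- tpos <= lens[doc]
  lin <- doc[valid] + flat[valid] * B
  counts <- matrix(tabulate(lin, nbins = B * vocab_size), B, vocab_size)
  counts / lens
}

dummy_forward <- function(params, ids, lens, config) {
  Xb <- dummy_bow(ids, lens, nrow(params$W))
  logits <- sweep(Xb %*% params$W, 2L, params$b, "+")
  list(logits = logits, cache = list(Xb = Xb))
}

dummy_backward <- function(params, cache, dlogits) {
  list(W = crossprod(cache$Xb, dlogits), b = colSums(dlogits))
}

nn_arch <- function(architecture) {
  switch(architecture,
         fasttext = list(init = fasttext_init, forward = fasttext_forward,
                         backward = fasttext_backward),
         textcnn = list(init = textcnn_init, forward = textcnn_forward,
                        backward = textcnn_backward),
         dpcnn = list(init = dpcnn_init, forward = dpcnn_forward,
                      backward = dpcnn_backward),
         dummy = list(init = dummy_init, forward = dummy_forward,
                      backward = dummy_backward),
         stop("unknown architecture: ", architecture, call. = FALSE))
}
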