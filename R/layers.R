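# Neural-network layer primitives with explicit forward caches and
# hand-written backward passes. The attention operations follow the scaled
# dot-product formulation; all backward passes are verified against finite
# differences in the test suite.

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

# gradient of row-softmax: A = softmax(S); given dA, return dS
softmax_rows_bwd <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, softmax along rows.
#'
#' @param Q n x d_k query matrix.
#' @param K m x d_k key matrix.
#' @param V m x d_v value matrix.
#' @return n x d_v attention output.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  softmax_rows(Q %*% t(K) / sqrt(ncol(Q))) %*% V
}

#' Reciprocal attention over a protein and a peptide stream
#'
#' One query/key product serves both directions: the protein update is
#' `softmax(Q K'/sqrt(d_k)) V_pep` and the peptide update is
#' `softmax(K Q'/sqrt(d_k)) V_prot`, so the unnormalized (pre-softmax)
#' protein-to-peptide and peptide-to-protein attention matrices are exact
#' transposes of one another.
#'
#' @param Q n x d_k protein queries; `K` m x d_k peptide keys.
#' @param V_prot n x d_v protein values; `V_pep` m x d_v peptide values.
#' @param K,V_prot,V_pep see above.
#' @return list with `prot` (n x d_v), `pep` (m x d_v), and the shared
#'   pre-softmax `logits_prot` (n x m) and `logits_pep` (= t(logits_prot)).
#' @export
reciprocal_attention <- function(Q, K, V_prot, V_pep) {
  S <- Q %*% t(K) / sqrt(ncol(Q))
  St <- t(S)
  list(prot = softmax_rows(S) %*% V_pep,
       pep = softmax_rows(St) %*% V_prot,
       logits_prot = S, logits_pep = St)
}

# --- linear / layernorm / dropout / ffn -------------------------------

lin_fwd <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, "+"), X = X)
}
lin_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = t(cache$X) %*% dY, db = colSums(dY))
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"),
       xhat = xhat, inv = inv)
}
ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  xhat <- cache$xhat
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

drop_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}
drop_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

ffn_fwd <- function(X, pm) {
  l1 <- lin_fwd(X, pm$W1, pm$b1)
  H <- pmax(l1$out, 0)
  l2 <- lin_fwd(H, pm$W2, pm$b2)
  list(out = l2$out, l1 = l1, H = H, l2 = l2)
}
ffn_bwd <- function(dY, cache, pm) {
  b2 <- lin_bwd(dY, cache$l2, pm$W2)
  dH <- b2$dX * (cache$l1$out > 0)
  b1 <- lin_bwd(dH, cache$l1, pm$W1)
  list(dX = b1$dX,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

# --- multi-head dense attention (peptide self-attention, seq-mode
#     protein self-attention) -------------------------------------------

mha_dense_fwd <- function(Xq, Xkv, pm, heads) {
  hc <- vector("list", heads)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    Q <- Xq %*% pm[[paste0("Wq.", h)]]
    K <- Xkv %*% pm[[paste0("Wk.", h)]]
    V <- Xkv %*% pm[[paste0("Wv.", h)]]
    S <- Q %*% t(K) / sqrt(ncol(Q))
    A <- softmax_rows(S)
    outs[[h]] <- A %*% V
    hc[[h]] <- list(Q = Q, K = K, V = V, A = A)
  }
  cat_ <- do.call(cbind, outs)
  lo <- lin_fwd(cat_, pm$Wo, pm$bo)
  list(out = lo$out, heads = hc, lo = lo, Xq = Xq, Xkv = Xkv)
}

mha_dense_bwd <- function(dY, cache, pm, heads) {
  bo <- lin_bwd(dY, cache$lo, pm$Wo)
  d_v <- ncol(cache$heads[[1L]]$V)
  dXq <- 0; dXkv <- 0
  grads <- list(Wo = bo$dW, bo = bo$db)
  for (h in seq_len(heads)) {
    hcache <- cache$heads[[h]]
    dO <- bo$dX[, ((h - 1L) * d_v + 1L):(h * d_v), drop = FALSE]
    A <- hcache$A
    dV <- t(A) %*% dO
    dA <- dO %*% t(hcache$V)
    dZ <- softmax_rows_bwd(A, dA) / sqrt(ncol(hcache$Q))
    dQ <- dZ %*% hcache$K
    dK <- t(dZ) %*% hcache$Q
    grads[[paste0("Wq.", h)]] <- t(cache$Xq) %*% dQ
    grads[[paste0("Wk.", h)]] <- t(cache$Xkv) %*% dK
    grads[[paste0("Wv.", h)]] <- t(cache$Xkv) %*% dV
    dXq <- dXq + dQ %*% t(pm[[paste0("Wq.", h)]])
    dXkv <- dXkv + dK %*% t(pm[[paste0("Wk.", h)]]) + dV %*% t(pm[[paste0("Wv.", h)]])
  }
  list(dXq = dXq, dXkv = dXkv, grads = grads)
}

# --- multi-head graph attention (struct-mode protein stream) ------------

# Node i attends over its k graph neighbors; keys and values are computed
# from the concatenation of the neighbor embedding and the edge features.
mha_graph_fwd <- function(H, graph, pm, heads) {
  L <- nrow(H); k <- graph$k
  Hcat <- cbind(H[graph$idx_nbr, , drop = FALSE], graph$efeat)
  hc <- vector("list", heads)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    Q <- H %*% pm[[paste0("Wq.", h)]]
    K <- Hcat %*% pm[[paste0("Wk.", h)]]
    V <- Hcat %*% pm[[paste0("Wv.", h)]]
    z_e <- rowSums(Q[graph$idx_src, , drop = FALSE] * K) / sqrt(ncol(Q))
    Z <- matrix(z_e, L, k, byrow = TRUE)
    A <- softmax_rows(Z)                    # per-node weights over neighbors
    w_e <- as.vector(t(A))
    O <- rowsum(V * w_e, graph$idx_src, reorder = TRUE)
    outs[[h]] <- O
    hc[[h]] <- list(Q = Q, K = K, V = V, A = A, w_e = w_e)
  }
  cat_ <- do.call(cbind, outs)
  lo <- lin_fwd(cat_, pm$Wo, pm$bo)
  list(out = lo$out, heads = hc, lo = lo, H = H, Hcat = Hcat)
}

scatter_add_rows <- function(M, idx, n) {
  r <- rowsum(M, idx, reorder = TRUE)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(r)), ] <- r
  out
}

mha_graph_bwd <- function(dY, cache, pm, graph, heads) {
  bo <- lin_bwd(dY, cache$lo, pm$Wo)
  d_v <- ncol(cache$heads[[1L]]$V)
  L <- nrow(cache$H); d_model <- ncol(cache$H)
  dH <- 0; dHcat_total <- 0
  grads <- list(Wo = bo$dW, bo = bo$db)
  for (h in seq_len(heads)) {
    hcache <- cache$heads[[h]]
    dO <- bo$dX[, ((h - 1L) * d_v + 1L):(h * d_v), drop = FALSE]
    dO_e <- dO[graph$idx_src, , drop = FALSE]
    dV <- dO_e * hcache$w_e
    dw_e <- rowSums(dO_e * hcache$V)
    dA <- matrix(dw_e, L, graph$k, byrow = TRUE)
    dZ <- softmax_rows_bwd(hcache$A, dA)
    dz_e <- as.vector(t(dZ)) / sqrt(ncol(hcache$Q))
    dQ <- scatter_add_rows(dz_e * hcache$K, graph$idx_src, L)
    dK <- dz_e * hcache$Q[graph$idx_src, , drop = FALSE]
    grads[[paste0("Wq.", h)]] <- t(cache$H) %*% dQ
    grads[[paste0("Wk.", h)]] <- t(cache$Hcat) %*% dK
    grads[[paste0("Wv.", h)]] <- t(cache$Hcat) %*% dV
    dH <- dH + dQ %*% t(pm[[paste0("Wq.", h)]])
    dHcat_total <- dHcat_total + dK %*% t(pm[[paste0("Wk.", h)]]) +
      dV %*% t(pm[[paste0("Wv.", h)]])
  }
  dH <- dH + scatter_add_rows(dHcat_total[, seq_len(d_model), drop = FALSE],
                              graph$idx_nbr, L)
  list(dX = dH, grads = grads)
}

# --- multi-head reciprocal attention ------------------------------------

mha_recip_fwd <- function(Hp, Hq, pm, heads) {
  hc <- vector("list", heads)
  outp <- vector("list", heads); outq <- vector("list", heads)
  for (h in seq_len(heads)) {
    Q <- Hp %*% pm[[paste0("Wq.", h)]]
    K <- Hq %*% pm[[paste0("Wk.", h)]]
    Vp <- Hp %*% pm[[paste0("Wvp.", h)]]
    Vq <- Hq %*% pm[[paste0("Wvq.", h)]]
    S <- Q %*% t(K) / sqrt(ncol(Q))
    St <- t(S)
    Ap <- softmax_rows(S)
    Aq <- softmax_rows(St)
    outp[[h]] <- Ap %*% Vq
    outq[[h]] <- Aq %*% Vp
    hc[[h]] <- list(Q = Q, K = K, Vp = Vp, Vq = Vq, Ap = Ap, Aq = Aq,
                    logits_prot = S, logits_pep = St)
  }
  lop <- lin_fwd(do.call(cbind, outp), pm$Wop, pm$bop)
  loq <- lin_fwd(do.call(cbind, outq), pm$Woq, pm$boq)
  list(out_p = lop$out, out_q = loq$out, heads = hc, lop = lop, loq = loq,
       Hp = Hp, Hq = Hq)
}

mha_recip_bwd <- function(dYp, dYq, cache, pm, heads) {
  bop <- lin_bwd(dYp, cache$lop, pm$Wop)
  boq <- lin_bwd(dYq, cache$loq, pm$Woq)
  d_v <- ncol(cache$heads[[1L]]$Vp)
  dHp <- 0; dHq <- 0
  grads <- list(Wop = bop$dW, bop = bop$db, Woq = boq$dW, boq = boq$db)
  for (h in seq_len(heads)) {
    hcache <- cache$heads[[h]]
    cols <- ((h - 1L) * d_v + 1L):(h * d_v)
    dOp <- bop$dX[, cols, drop = FALSE]
    dOq <- boq$dX[, cols, drop = FALSE]
    dVq <- t(hcache$Ap) %*% dOp
    dAp <- dOp %*% t(hcache$Vq)
    dVp <- t(hcache$Aq) %*% dOq
    dAq <- dOq %*% t(hcache$Vp)
    dZ <- (softmax_rows_bwd(hcache$Ap, dAp) +
             t(softmax_rows_bwd(hcache$Aq, dAq))) / sqrt(ncol(hcache$Q))
    dQ <- dZ %*% hcache$K
    dK <- t(dZ) %*% hcache$Q
    grads[[paste0("Wq.", h)]] <- t(cache$Hp) %*% dQ
    grads[[paste0("Wk.", h)]] <- t(cache$Hq) %*% dK
    grads[[paste0("Wvp.", h)]] <- t(cache$Hp) %*% dVp
    grads[[paste0("Wvq.", h)]] <- t(cache$Hq) %*% dVq
    dHp <- dHp + dQ %*% t(pm[[paste0("Wq.", h)]]) + dVp %*% t(pm[[paste0("Wvp.", h)]])
    dHq <- dHq + dK %*% t(pm[[paste0("Wk.", h)]]) + dVq %*% t(pm[[paste0("Wvq.", h)]])
  }
  list(dHp = dHp, dHq = dHq, grads = grads)
}

# sinusoidal positional encoding (peptide stream)
positional_encoding <- function(L, d) {
  pos <- seq_len(L)
  i <- seq_len(d)
  angle <- outer(pos, 1 / (10000 ^ ((i - i %% 2) / d)))
  out <- matrix(0, L, d)
  odd <- i %% 2 == 1
  out[, odd] <- sin(angle[, odd, drop = FALSE])
  out[, !odd] <- cos(angle[, !odd, drop = FALSE])
  out
}
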