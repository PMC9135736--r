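# Shared fixtures (memoised: complex generation involves SASA verification
# and is the slowest part of the suite) and independent oracle
# implementations used across test files.

.fx_cache <- new.env(parent = emptyenv())

fx_binder <- function(seed, verify_bsa = FALSE) {
  key <- sprintf("b%d_%d", seed, verify_bsa)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_complex(fixture_spec(seed = seed,
                                                  verify_bsa = verify_bsa))
  .fx_cache[[key]]
}

fx_decoy <- function(seed) {
  key <- sprintf("d%d", seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_complex(fixture_spec(seed = seed,
                                                  patch_distance = 10))
  .fx_cache[[key]]
}

tiny_config <- function(dropout = 0, mode = "struct", heads = 2L,
                        n_blocks = 2L) {
  model_config(mode, d_model = 8L, d_i = 8L, d_k = 6L, d_v = 7L,
               heads = heads, n_blocks = n_blocks, dropout = dropout,
               embedder = "mock")
}

demo_config <- function() {
  model_config("struct", d_model = 32L, d_i = 32L, d_k = 16L, d_v = 32L,
               heads = 2L, n_blocks = 2L, dropout = 0.2, embedder = "mock")
}

# model-ready inputs for a complex record under a given config
model_inputs <- function(cfg, rec, k = 8L) {
  g <- build_residue_graph(rec$receptor, k = k)
  pin <- g$nodes
  if (cfg$lm_dim > 0L)
    pin <- cbind(pin, embed_protein(paste(g$aa, collapse = ""),
                                    embedder_spec(cfg$embedder)))
  list(pin = pin, graph = g,
       pep = one_hot_sequence(structure_sequence(rec$partner)),
       labels = rec$labels[g$kept])
}

# --- independent oracles ------------------------------------------------

# Gram-Schmidt oracle for the local frame, written directly from the
# projection formulas (no shared code with local_frame()).
oracle_frame_basis <- function(N, CA, C) {
  u1 <- C - CA
  e1 <- u1 / sqrt(sum(u1^2))
  u2 <- (N - CA) - sum((N - CA) * e1) * e1
  e2 <- u2 / sqrt(sum(u2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

# rotation-matrix -> quaternion oracle via the Davenport K-matrix
# eigenvector method (independent of the Shepperd branching used in the
# implementation)
oracle_quat <- function(R) {
  K <- matrix(c(
    R[1,1]+R[2,2]+R[3,3], R[3,2]-R[2,3], R[1,3]-R[3,1], R[2,1]-R[1,2],
    R[3,2]-R[2,3], R[1,1]-R[2,2]-R[3,3], R[2,1]+R[1,2], R[1,3]+R[3,1],
    R[1,3]-R[3,1], R[2,1]+R[1,2], R[2,2]-R[1,1]-R[3,3], R[3,2]+R[2,3],
    R[2,1]-R[1,2], R[1,3]+R[3,1], R[3,2]+R[2,3], R[3,3]-R[1,1]-R[2,2]),
    4, 4, byrow = TRUE) / 3
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, which.max(ev$values)]
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

# explicit double-loop softmax-attention oracle
oracle_attention <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K); dk <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# brute-force all-pairs binding annotation
oracle_annotate <- function(receptor, partner, cutoff = 6) {
  ra <- pepsite:::structure_atoms(receptor)
  pa <- pepsite:::structure_atoms(partner)
  flags <- rep(FALSE, length(receptor$aa))
  for (i in seq_len(nrow(ra$xyz)))
    for (j in seq_len(nrow(pa$xyz)))
      if (sqrt(sum((ra$xyz[i, ] - pa$xyz[j, ])^2)) <= cutoff)
        flags[ra$residue[i]] <- TRUE
  flags
}

# O(P*N) pair-counting ROC AUC oracle, ties counted one half
oracle_auc <- function(probs, labels) {
  labels <- as.logical(labels)
  pos <- probs[labels]; neg <- probs[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

random_rigid <- function() {
  list(R = pepsite:::random_rotation(), t = stats::rnorm(3, sd = 20))
}
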