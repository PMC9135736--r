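# The attention network: scaled dot attention, reciprocal symmetry, graph
# attention, block wiring, forward-pass contracts and gradient correctness.

test_that("scaled_dot_attention matches its closed forms and a loop oracle", {
  set.seed(1)
  # zero queries/keys: uniform softmax -> column means of V
  V <- matrix(rnorm(10), 5, 2)
  out <- scaled_dot_attention(matrix(0, 4, 3), matrix(0, 5, 3), V)
  expect_equal(out, matrix(colMeans(V), 4, 2, byrow = TRUE), tolerance = 1e-12)
  # single key: every row equals the single value row
  out1 <- scaled_dot_attention(matrix(rnorm(12), 4, 3), matrix(rnorm(3), 1, 3),
                               matrix(c(2, -1), 1, 2))
  expect_equal(out1, matrix(c(2, -1), 4, 2, byrow = TRUE), tolerance = 1e-12)
  # 50 random instances against the double-loop oracle
  worst <- 0
  for (rep in 1:50) {
    n <- sample(2:6, 1); m <- sample(2:7, 1); dk <- sample(2:5, 1)
    dv <- sample(2:5, 1)
    Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(m * dk), m)
    V <- matrix(rnorm(m * dv), m)
    worst <- max(worst, max(abs(scaled_dot_attention(Q, K, V) -
                                  oracle_attention(Q, K, V))))
  }
  expect_lt(worst, 1e-10)
})

test_that("reciprocal attention logits are exact transposes and match the formulas", {
  set.seed(2)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(m * 4), m)
    Vp <- matrix(rnorm(n * 3), n); Vq <- matrix(rnorm(m * 3), m)
    ra <- reciprocal_attention(Q, K, Vp, Vq)
    expect_identical(ra$logits_pep, t(ra$logits_prot))
    worst <- max(worst,
                 max(abs(ra$prot - oracle_attention(Q, K, Vq))),
                 max(abs(ra$pep - oracle_attention(K, Q, Vp))))
  }
  expect_lt(worst, 1e-10)
  # n = 1: peptide softmax over one protein residue -> rows equal V_prot
  ra1 <- reciprocal_attention(matrix(rnorm(4), 1), matrix(rnorm(12), 3),
                              matrix(c(5, -2, 1), 1), matrix(rnorm(9), 3))
  expect_equal(ra1$pep, matrix(c(5, -2, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("reciprocal symmetry holds at every block and head of a forward pass", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 3)
  inp <- model_inputs(cfg, fx_binder(42), k = 6)
  fwd <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep,
                                  keep_cache = TRUE)
  for (b in seq_len(cfg$n_blocks)) {
    for (h in seq_len(cfg$heads)) {
      hc <- fwd$cache$blocks[[b]]$rec$heads[[h]]
      expect_identical(hc$logits_pep, t(hc$logits_prot))
    }
  }
})

test_that("multi-head attention keeps shapes and is deterministic in eval mode", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 5)
  inp <- model_inputs(cfg, fx_binder(42), k = 6)
  f1 <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep)
  f2 <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep)
  expect_identical(f1$probs, f2$probs)
  expect_identical(dim(f1$Hp), c(nrow(inp$pin), cfg$d_model))
  expect_identical(dim(f1$Hq), c(nrow(inp$pep), cfg$d_model))
  expect_true(all(f1$probs >= 0 & f1$probs <= 1))
  expect_length(f1$probs, nrow(inp$pin))
})

test_that("single-head multi-head path equals the bare attention plus output projection", {
  set.seed(6)
  X <- matrix(rnorm(5 * 8), 5, 8)
  pm <- list("Wq.1" = matrix(rnorm(8 * 4), 8, 4),
             "Wk.1" = matrix(rnorm(8 * 4), 8, 4),
             "Wv.1" = matrix(rnorm(8 * 3), 8, 3),
             Wo = matrix(rnorm(3 * 8), 3, 8), bo = rnorm(8))
  got <- pepsite:::mha_dense_fwd(X, X, pm, heads = 1L)$out
  want <- scaled_dot_attention(X %*% pm$"Wq.1", X %*% pm$"Wk.1",
                               X %*% pm$"Wv.1") %*% pm$Wo
  want <- sweep(want, 2, pm$bo, "+")
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("graph attention weights normalize and reduce to dense attention", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 7)
  rec <- fx_binder(42)
  g <- build_residue_graph(rec$receptor, k = 100)   # k >= L-1: full graph
  H <- matrix(rnorm(nrow(g$nodes) * cfg$d_model), nrow(g$nodes))
  pm <- pepsite:::pget(m$params, "b1.pat.")
  out <- pepsite:::mha_graph_fwd(H, g, pm, cfg$heads)
  for (h in seq_len(cfg$heads))
    expect_equal(rowSums(out$heads[[h]]$A), rep(1, nrow(H)), tolerance = 1e-6)
  # zero the edge features: graph attention must equal dense self-attention
  # with the self-pair masked out (oracle computed by explicit masking)
  g0 <- g; g0$efeat[] <- 0
  out0 <- pepsite:::mha_graph_fwd(H, g0, pm, cfg$heads)
  L <- nrow(H)
  for (h in seq_len(cfg$heads)) {
    Q <- H %*% pm[[paste0("Wq.", h)]]
    K <- cbind(H, matrix(0, L, g$d_edge)) %*% pm[[paste0("Wk.", h)]]
    V <- cbind(H, matrix(0, L, g$d_edge)) %*% pm[[paste0("Wv.", h)]]
    S <- Q %*% t(K) / sqrt(ncol(Q))
    diag(S) <- -Inf
    dense <- pepsite:::softmax_rows(S) %*% V
    got <- rowsum(out0$heads[[h]]$V * out0$heads[[h]]$w_e, g0$idx_src)
    expect_equal(unname(got), unname(dense), tolerance = 1e-10)
  }
})

test_that("struct-mode predictions are invariant to rigid motions and permuting the graph", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 8)
  rec <- fx_binder(43)
  p0 <- predict_binding(m, rec$receptor, "GAGAG", k = 8)$prob
  set.seed(9)
  for (rep in 1:5) {
    rt <- random_rigid()
    p1 <- predict_binding(m, pepsite:::transform_structure(rec$receptor, rt$R, rt$t),
                          "GAGAG", k = 8)$prob
    expect_lt(max(abs(p1 - p0)), 1e-5)
  }
})

test_that("blocks near-identity under zero sublayer output weights", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 10)
  # zero every sublayer output projection: residual path dominates and each
  # post-norm block becomes layer normalization of its input
  for (nm in grep("(Wo|Wop|Woq|ffp\\.W2|ffs\\.W2)$", names(m$params), value = TRUE))
    m$params[[nm]][] <- 0
  inp <- model_inputs(cfg, fx_binder(42), k = 6)
  fwd <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep,
                                  keep_cache = TRUE)
  # with zero sublayer outputs the pre-norm residual input passes through:
  # check the first block's first sublayer is pure LN of its input
  li <- fwd$cache$li_p$out
  ln1 <- fwd$cache$blocks[[1]]$ln_p1
  manual <- t(apply(li, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(ln1$out, manual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("peptide permutation leaves protein probabilities unchanged without positional encodings", {
  cfg <- model_config("struct", d_model = 8L, d_i = 8L, d_k = 6L, d_v = 7L,
                      heads = 2L, n_blocks = 2L, dropout = 0,
                      embedder = "mock", pep_positions = FALSE)
  m <- init_model(cfg, seed = 12)
  inp <- model_inputs(cfg, fx_binder(42), k = 6)
  set.seed(13)
  perm <- sample(nrow(inp$pep))
  f0 <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep)
  f1 <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph,
                                 inp$pep[perm, , drop = FALSE])
  expect_equal(f1$probs, f0$probs, tolerance = 1e-10)
  expect_equal(f1$Hq, f0$Hq[perm, ], tolerance = 1e-10)
})

test_that("analytic gradients match finite differences across all layer types", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 20)
  inp <- model_inputs(cfg, fx_binder(42), k = 5)
  cw <- c(1.2, 0.8)
  fwd <- pepsite:::pepnet_forward(m$params, cfg, inp$pin, inp$graph, inp$pep,
                                  keep_cache = TRUE)
  dlog <- pepsite:::weighted_ce_grad(fwd$probs2, inp$labels, cw, 1.3)
  G <- pepsite:::pepnet_backward(m$params, cfg, inp$graph, fwd, dlog)
  loss_fn <- function(P) {
    f <- pepsite:::pepnet_forward(P, cfg, inp$pin, inp$graph, inp$pep)
    weighted_ce_loss(f$probs2, inp$labels, cw, 1.3)
  }
  set.seed(21)
  nms <- c("prot_in.W", "pep_in.b", "b1.pat.Wq.1", "b1.pat.Wk.2", "b1.pat.Wo",
           "b1.sat.Wv.1", "b1.rec.Wk.1", "b1.rec.Wvp.2", "b1.rec.Woq",
           "b1.ln_p2.g", "b2.ffs.W1", "b2.ln_s3.b", "out.W", "b2.rec.Wq.1")
  eps <- 1e-6
  for (nm in nms) {
    i <- sample(length(m$params[[nm]]), 1)
    P2 <- m$params; P2[[nm]][i] <- P2[[nm]][i] + eps
    P3 <- m$params; P3[[nm]][i] <- P3[[nm]][i] - eps
    num <- (loss_fn(P2) - loss_fn(P3)) / (2 * eps)
    expect_equal(G[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("forward pass regression snapshot is stable", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 99)
  h <- make_helix(32, seed = 99)
  g <- build_residue_graph(h, k = 6)
  pin <- cbind(g$nodes, embed_protein(paste(g$aa, collapse = ""),
                                      embedder_spec("mock")))
  fwd <- pepsite:::pepnet_forward(m$params, cfg, pin, g,
                                  one_hot_sequence("GGGGG"))
  # frozen from a verified run of this configuration
  expect_equal(fwd$probs[1:5],
               c(0.4708157069, 0.6063597285, 0.4767694877,
                 0.1832498941, 0.5705720967),
               tolerance = 1e-6)
})

test_that("empty peptide input is rejected with guidance", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 1)
  expect_error(predict_binding(m, fx_binder(42)$receptor, ""),
               "poly-glycine")
})
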