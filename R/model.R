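# The two-stream binding-site prediction network: stacked blocks of protein
# graph- (or sequence-) self-attention, peptide self-attention, reciprocal
# cross-attention and position-wise feed-forward layers, post-norm residual
# wiring, with a final two-class projection of the protein stream to
# per-residue binding probabilities.

#' Model hyperparameter configuration
#'
#' Defaults are the published working point: embedding dimension 64,
#' feed-forward hidden dimension 64, query/key dimension 64, value
#' dimension 128, 6 attention heads, 6 reciprocal-module repetitions,
#' dropout 0.2.
#'
#' @param mode `"struct"` (residue-graph protein input) or `"seq"`
#'   (sequence-embedding protein input).
#' @param d_model,d_i,d_k,d_v,heads,n_blocks,dropout architecture
#'   hyperparameters (see Description).
#' @param embedder language-model adapter for the protein sequence:
#'   `"mock"` (deterministic 32-dim), `"onehot"`, or `"none"` (struct mode
#'   only: graph features alone).
#' @param d_node,d_edge residue-graph feature dimensions (must match the
#'   featurizer; defaults 46/88).
#' @param pep_positions add sinusoidal positional encodings to the peptide
#'   stream (default `TRUE`).
#' @return list of class `model_config`.
#' @export
model_config <- function(mode = c("struct", "seq"), d_model = 64L, d_i = 64L,
                         d_k = 64L, d_v = 128L, heads = 6L, n_blocks = 6L,
                         dropout = 0.2, embedder = "mock", d_node = 46L,
                         d_edge = 88L, pep_positions = TRUE) {
  mode <- match.arg(mode)
  stopifnot(d_model >= 1L, d_i >= 1L, d_k >= 1L, d_v >= 1L, heads >= 1L,
            n_blocks >= 1L, dropout >= 0, dropout < 1)
  lm_dim <- switch(embedder, mock = 32L, onehot = 21L, none = 0L,
                   protbert = 1024L,
                   stop("unknown embedder: ", embedder))
  if (mode == "seq" && lm_dim == 0L)
    stop("seq mode requires a sequence embedder")
  d_prot_in <- if (mode == "struct") d_node + lm_dim else lm_dim
  cfg <- list(mode = mode, d_model = as.integer(d_model),
              d_i = as.integer(d_i), d_k = as.integer(d_k),
              d_v = as.integer(d_v), heads = as.integer(heads),
              n_blocks = as.integer(n_blocks), dropout = dropout,
              embedder = embedder, lm_dim = lm_dim,
              d_node = as.integer(d_node), d_edge = as.integer(d_edge),
              d_prot_in = as.integer(d_prot_in),
              pep_positions = isTRUE(pep_positions))
  class(cfg) <- "model_config"
  cfg
}

xavier <- function(fin, fout) {
  a <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -a, a), fin, fout)
}

#' Initialize a model with Xavier-uniform weights
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the weight draw.
#' @return list of class `pep_model` with `config` and the flat named
#'   parameter list `params`.
#' @export
init_model <- function(config, seed = 1L) {
  set.seed(seed)
  d_model <- config$d_model; d_k <- config$d_k; d_v <- config$d_v
  heads <- config$heads
  d_kv_in <- if (config$mode == "struct") d_model + config$d_edge else d_model
  P <- list()
  P[["prot_in.W"]] <- xavier(config$d_prot_in, d_model)
  P[["prot_in.b"]] <- numeric(d_model)
  P[["pep_in.W"]] <- xavier(21L, d_model)
  P[["pep_in.b"]] <- numeric(d_model)
  for (b in seq_len(config$n_blocks)) {
    pre <- sprintf("b%d.", b)
    for (h in seq_len(heads)) {
      P[[paste0(pre, "pat.Wq.", h)]] <- xavier(d_model, d_k)
      P[[paste0(pre, "pat.Wk.", h)]] <- xavier(d_kv_in, d_k)
      P[[paste0(pre, "pat.Wv.", h)]] <- xavier(d_kv_in, d_v)
      P[[paste0(pre, "sat.Wq.", h)]] <- xavier(d_model, d_k)
      P[[paste0(pre, "sat.Wk.", h)]] <- xavier(d_model, d_k)
      P[[paste0(pre, "sat.Wv.", h)]] <- xavier(d_model, d_v)
      P[[paste0(pre, "rec.Wq.", h)]] <- xavier(d_model, d_k)
      P[[paste0(pre, "rec.Wk.", h)]] <- xavier(d_model, d_k)
      P[[paste0(pre, "rec.Wvp.", h)]] <- xavier(d_model, d_v)
      P[[paste0(pre, "rec.Wvq.", h)]] <- xavier(d_model, d_v)
    }
    P[[paste0(pre, "pat.Wo")]] <- xavier(heads * d_v, d_model)
    P[[paste0(pre, "pat.bo")]] <- numeric(d_model)
    P[[paste0(pre, "sat.Wo")]] <- xavier(heads * d_v, d_model)
    P[[paste0(pre, "sat.bo")]] <- numeric(d_model)
    P[[paste0(pre, "rec.Wop")]] <- xavier(heads * d_v, d_model)
    P[[paste0(pre, "rec.bop")]] <- numeric(d_model)
    P[[paste0(pre, "rec.Woq")]] <- xavier(heads * d_v, d_model)
    P[[paste0(pre, "rec.boq")]] <- numeric(d_model)
    P[[paste0(pre, "ffp.W1")]] <- xavier(d_model, config$d_i)
    P[[paste0(pre, "ffp.b1")]] <- numeric(config$d_i)
    P[[paste0(pre, "ffp.W2")]] <- xavier(config$d_i, d_model)
    P[[paste0(pre, "ffp.b2")]] <- numeric(d_model)
    P[[paste0(pre, "ffs.W1")]] <- xavier(d_model, config$d_i)
    P[[paste0(pre, "ffs.b1")]] <- numeric(config$d_i)
    P[[paste0(pre, "ffs.W2")]] <- xavier(config$d_i, d_model)
    P[[paste0(pre, "ffs.b2")]] <- numeric(d_model)
    for (ln in c("ln_p1", "ln_s1", "ln_p2", "ln_s2", "ln_p3", "ln_s3")) {
      P[[paste0(pre, ln, ".g")]] <- rep(1, d_model)
      P[[paste0(pre, ln, ".b")]] <- numeric(d_model)
    }
  }
  P[["out.W"]] <- xavier(d_model, 2L)
  P[["out.b"]] <- numeric(2L)
  m <- list(config = config, params = P)
  class(m) <- "pep_model"
  m
}

#' @export
print.pep_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1L)))
  cat(sprintf("<pep_model> mode=%s, d_model=%d, %d blocks, %d heads, %d parameters\n",
              x$config$mode, x$config$d_model, x$config$n_blocks,
              x$config$heads, np))
  invisible(x)
}

# extract parameters under a prefix, names stripped of the prefix
pget <- function(P, prefix) {
  sel <- startsWith(names(P), prefix)
  out <- P[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

# full forward pass; `pin` is the protein input matrix (graph node features
# + optional LM embedding in struct mode, embedding alone in seq mode)
pepnet_forward <- function(params, config, pin, graph, pep_onehot,
                           train = FALSE, keep_cache = FALSE) {
  heads <- config$heads
  cache <- if (keep_cache) list() else NULL
  li_p <- lin_fwd(pin, params[["prot_in.W"]], params[["prot_in.b"]])
  li_q <- lin_fwd(pep_onehot, params[["pep_in.W"]], params[["pep_in.b"]])
  Hp <- li_p$out
  Hq <- li_q$out
  if (config$pep_positions)
    Hq <- Hq + positional_encoding(nrow(Hq), config$d_model)
  if (keep_cache) { cache$li_p <- li_p; cache$li_q <- li_q }
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    pre <- sprintf("b%d.", b)
    bc <- list()
    # 1. protein self/graph attention
    if (config$mode == "struct") {
      at <- mha_graph_fwd(Hp, graph, pget(params, paste0(pre, "pat.")), heads)
    } else {
      at <- mha_dense_fwd(Hp, Hp, pget(params, paste0(pre, "pat.")), heads)
    }
    dp <- drop_fwd(at$out, config$dropout, train)
    lnp1 <- ln_fwd(Hp + dp$out, params[[paste0(pre, "ln_p1.g")]],
                   params[[paste0(pre, "ln_p1.b")]])
    bc$pat <- at; bc$pat_drop <- dp; bc$ln_p1 <- lnp1
    Hp <- lnp1$out
    # 2. peptide self-attention
    at <- mha_dense_fwd(Hq, Hq, pget(params, paste0(pre, "sat.")), heads)
    dq <- drop_fwd(at$out, config$dropout, train)
    lns1 <- ln_fwd(Hq + dq$out, params[[paste0(pre, "ln_s1.g")]],
                   params[[paste0(pre, "ln_s1.b")]])
    bc$sat <- at; bc$sat_drop <- dq; bc$ln_s1 <- lns1
    Hq <- lns1$out
    # 3. reciprocal attention
    rc <- mha_recip_fwd(Hp, Hq, pget(params, paste0(pre, "rec.")), heads)
    dp2 <- drop_fwd(rc$out_p, config$dropout, train)
    dq2 <- drop_fwd(rc$out_q, config$dropout, train)
    lnp2 <- ln_fwd(Hp + dp2$out, params[[paste0(pre, "ln_p2.g")]],
                   params[[paste0(pre, "ln_p2.b")]])
    lns2 <- ln_fwd(Hq + dq2$out, params[[paste0(pre, "ln_s2.g")]],
                   params[[paste0(pre, "ln_s2.b")]])
    bc$rec <- rc; bc$rec_drop_p <- dp2; bc$rec_drop_q <- dq2
    bc$ln_p2 <- lnp2; bc$ln_s2 <- lns2
    Hp <- lnp2$out; Hq <- lns2$out
    # 4. position-wise feed-forward on each stream
    fp <- ffn_fwd(Hp, pget(params, paste0(pre, "ffp.")))
    lnp3 <- ln_fwd(Hp + fp$out, params[[paste0(pre, "ln_p3.g")]],
                   params[[paste0(pre, "ln_p3.b")]])
    fs <- ffn_fwd(Hq, pget(params, paste0(pre, "ffs.")))
    lns3 <- ln_fwd(Hq + fs$out, params[[paste0(pre, "ln_s3.g")]],
                   params[[paste0(pre, "ln_s3.b")]])
    bc$ffp <- fp; bc$ln_p3 <- lnp3; bc$ffs <- fs; bc$ln_s3 <- lns3
    Hp <- lnp3$out; Hq <- lns3$out
    if (keep_cache) blocks[[b]] <- bc
  }
  lo <- lin_fwd(Hp, params[["out.W"]], params[["out.b"]])
  probs2 <- softmax_rows(lo$out)
  if (keep_cache) { cache$blocks <- blocks; cache$lo <- lo; cache$probs2 <- probs2 }
  # reciprocal logits of the last forward, per block/head (kept regardless
  # of keep_cache only when caching; tests use keep_cache = TRUE)
  list(probs = unname(probs2[, 2L]), probs2 = probs2, logits = lo$out,
       Hp = Hp, Hq = Hq, cache = cache)
}

# backward pass; dlogits is the gradient of the loss wrt the final 2-class
# logits. Returns the flat named gradient list.
pepnet_backward <- function(params, config, graph, fwd, dlogits) {
  heads <- config$heads
  G <- list()
  addg <- function(prefix, gl) {
    for (nm in names(gl)) {
      key <- paste0(prefix, nm)
      G[[key]] <<- if (is.null(G[[key]])) gl[[nm]] else G[[key]] + gl[[nm]]
    }
  }
  cache <- fwd$cache
  bo <- lin_bwd(dlogits, cache$lo, params[["out.W"]])
  addg("out.", list(W = bo$dW, b = bo$db))
  dHp <- bo$dX
  dHq <- matrix(0, nrow(fwd$Hq), ncol(fwd$Hq))
  for (b in rev(seq_len(config$n_blocks))) {
    pre <- sprintf("b%d.", b)
    bc <- cache$blocks[[b]]
    # 4. feed-forward sublayers (post-norm residual)
    l3 <- ln_bwd(dHp, bc$ln_p3, params[[paste0(pre, "ln_p3.g")]])
    addg(paste0(pre, "ln_p3."), list(g = l3$dg, b = l3$db))
    fb <- ffn_bwd(l3$dX, bc$ffp, pget(params, paste0(pre, "ffp.")))
    addg(paste0(pre, "ffp."), fb$grads)
    dHp <- l3$dX + fb$dX
    l3q <- ln_bwd(dHq, bc$ln_s3, params[[paste0(pre, "ln_s3.g")]])
    addg(paste0(pre, "ln_s3."), list(g = l3q$dg, b = l3q$db))
    fbq <- ffn_bwd(l3q$dX, bc$ffs, pget(params, paste0(pre, "ffs.")))
    addg(paste0(pre, "ffs."), fbq$grads)
    dHq <- l3q$dX + fbq$dX
    # 3. reciprocal attention
    l2 <- ln_bwd(dHp, bc$ln_p2, params[[paste0(pre, "ln_p2.g")]])
    addg(paste0(pre, "ln_p2."), list(g = l2$dg, b = l2$db))
    l2q <- ln_bwd(dHq, bc$ln_s2, params[[paste0(pre, "ln_s2.g")]])
    addg(paste0(pre, "ln_s2."), list(g = l2q$dg, b = l2q$db))
    dp2 <- drop_bwd(l2$dX, bc$rec_drop_p)
    dq2 <- drop_bwd(l2q$dX, bc$rec_drop_q)
    rb <- mha_recip_bwd(dp2, dq2, bc$rec, pget(params, paste0(pre, "rec.")), heads)
    addg(paste0(pre, "rec."), rb$grads)
    dHp <- l2$dX + rb$dHp
    dHq <- l2q$dX + rb$dHq
    # 2. peptide self-attention
    l1q <- ln_bwd(dHq, bc$ln_s1, params[[paste0(pre, "ln_s1.g")]])
    addg(paste0(pre, "ln_s1."), list(g = l1q$dg, b = l1q$db))
    dsat <- drop_bwd(l1q$dX, bc$sat_drop)
    sb <- mha_dense_bwd(dsat, bc$sat, pget(params, paste0(pre, "sat.")), heads)
    addg(paste0(pre, "sat."), sb$grads)
    dHq <- l1q$dX + sb$dXq + sb$dXkv
    # 1. protein attention
    l1 <- ln_bwd(dHp, bc$ln_p1, params[[paste0(pre, "ln_p1.g")]])
    addg(paste0(pre, "ln_p1."), list(g = l1$dg, b = l1$db))
    dpat <- drop_bwd(l1$dX, bc$pat_drop)
    if (config$mode == "struct") {
      gb <- mha_graph_bwd(dpat, bc$pat, pget(params, paste0(pre, "pat.")),
                          graph, heads)
      dHp <- l1$dX + gb$dX
      addg(paste0(pre, "pat."), gb$grads)
    } else {
      gb <- mha_dense_bwd(dpat, bc$pat, pget(params, paste0(pre, "pat.")), heads)
      dHp <- l1$dX + gb$dXq + gb$dXkv
      addg(paste0(pre, "pat."), gb$grads)
    }
  }
  bi_p <- lin_bwd(dHp, cache$li_p, params[["prot_in.W"]])
  addg("prot_in.", list(W = bi_p$dW, b = bi_p$db))
  bi_q <- lin_bwd(dHq, cache$li_q, params[["pep_in.W"]])
  addg("pep_in.", list(W = bi_q$dW, b = bi_q$db))
  G
}

# --- user-facing prediction ---------------------------------------------

# build the model-ready protein input for a structure (or sequence)
prepare_protein_input <- function(model, protein, k = 30L) {
  cfg <- model$config
  if (cfg$mode == "struct") {
    if (inherits(protein, "protein_structure")) {
      graph <- build_residue_graph(protein, k = k)
      seqs <- paste(graph$aa, collapse = "")
    } else if (inherits(protein, "residue_graph")) {
      graph <- protein
      seqs <- paste(graph$aa, collapse = "")
    } else stop("struct mode requires a protein_structure or residue_graph")
    pin <- graph$nodes
    if (cfg$lm_dim > 0L)
      pin <- cbind(pin, embed_protein(seqs, embedder_spec(cfg$embedder)))
    list(pin = pin, graph = graph, aa = graph$aa)
  } else {
    seqs <- if (inherits(protein, "protein_structure"))
      structure_sequence(protein) else protein
    stopifnot(is.character(seqs))
    list(pin = embed_protein(seqs, embedder_spec(cfg$embedder)), graph = NULL,
         aa = strsplit(seqs, "")[[1L]])
  }
}

#' Predict per-residue peptide-binding probabilities
#'
#' Runs the network in evaluation mode (dropout off; two calls are
#' bit-identical) on a protein (structure in `"struct"` mode, sequence in
#' `"seq"` mode) and a peptide sequence.
#'
#' @param model a trained (or initialized) `pep_model`.
#' @param protein a [protein_structure()], a prebuilt [build_residue_graph()]
#'   result, or a sequence string (seq mode).
#' @param peptide peptide sequence (non-empty); use
#'   [peptide_agnostic_predict()] for the poly-glycine probe.
#' @param k graph neighbor count when featurizing a structure (default 30).
#' @return data.frame with columns `residue`, `aa`, `prob`.
#' @export
predict_binding <- function(model, protein, peptide, k = 30L) {
  stopifnot(inherits(model, "pep_model"))
  if (!is.character(peptide) || nchar(peptide) < 1L)
    stop("peptide must be a non-empty sequence; use peptide_agnostic_predict() ",
         "for a poly-glycine probe")
  pi_ <- prepare_protein_input(model, protein, k = k)
  fwd <- pepnet_forward(model$params, model$config, pi_$pin, pi_$graph,
                        one_hot_sequence(peptide), train = FALSE)
  data.frame(residue = seq_along(pi_$aa), aa = pi_$aa, prob = fwd$probs)
}
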