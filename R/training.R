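# Training: weighted cross-entropy with inverse-frequency class weights and
# inverse-cluster-size example weights, Adam optimization one complex per
# iteration, validation-loss early stopping, and transfer of pre-trained
# weights into a fine-tuning run.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4 for
#' structure-mode pre-training and fine-tuning (1e-5 for sequence-mode
#' fine-tuning), iteration caps of 150,000 (pre-training) and 35,000
#' (fine-tuning), early stopping on the validation loss. At desk scale the
#' validation loss is evaluated every `eval_every` iterations with a
#' patience counted in evaluations.
#'
#' @param phase `"pretrain"` (class weights only) or `"finetune"` (class
#'   and inverse-cluster example weights).
#' @param lr Adam learning rate (> 0); default 1e-4, the structure-mode
#'   value (use 1e-5 for sequence-mode fine-tuning).
#' @param max_iters iteration cap; default 150,000 for pretrain, 35,000 for
#'   finetune.
#' @param eval_every validation cadence in iterations (default 50).
#' @param patience evaluations without validation improvement before
#'   stopping (default 10).
#' @param seed RNG seed controlling shuffling, dropout and initialization
#'   order.
#' @return list of class `train_config`.
#' @export
train_config <- function(phase = c("finetune", "pretrain"), lr = 1e-4,
                         max_iters = NULL, eval_every = 50L, patience = 10L,
                         seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(lr > 0)
  if (is.null(max_iters))
    max_iters <- if (phase == "pretrain") 150000L else 35000L
  out <- list(phase = phase, lr = lr, max_iters = as.integer(max_iters),
              eval_every = as.integer(eval_every),
              patience = as.integer(patience), seed = as.integer(seed))
  class(out) <- "train_config"
  out
}

#' Inverse-frequency class weights
#'
#' Weights each class by the inverse of its frequency in the pooled labels,
#' normalized so the two weights average to 1 (a 50/50 dataset gives
#' (1, 1); 10 percent binding gives a binding/non-binding ratio of 9).
#'
#' @param labels logical (or 0/1) vector pooled over the dataset.
#' @return named numeric `c(nonbinding, binding)`.
#' @export
class_weights <- function(labels) {
  labels <- as.logical(labels)
  f1 <- mean(labels)
  if (f1 <= 0 || f1 >= 1)
    stop("both classes must be present to compute class weights")
  w <- c(nonbinding = 1 / (1 - f1), binding = 1 / f1)
  w / mean(w)
}

#' Inverse-cluster-size example weights
#'
#' Each record is weighted by the inverse of the number of records in its
#' sequence cluster, so every cluster contributes equally (the weights sum
#' to the number of clusters).
#'
#' @param cluster cluster id per record.
#' @return numeric weight per record.
#' @export
example_weights <- function(cluster) {
  sz <- table(cluster)
  as.numeric(1 / sz[as.character(cluster)])
}

#' Weighted cross-entropy loss
#'
#' Mean over residues of `example_w * class_w[label] * (-log p_label)`.
#' With all weights 1 this is the plain cross-entropy.
#'
#' @param probs2 n x 2 matrix of class probabilities (columns: non-binding,
#'   binding).
#' @param labels logical/0-1 vector of length n.
#' @param class_w length-2 class weights (non-binding, binding).
#' @param example_w scalar record weight.
#' @return scalar loss.
#' @export
weighted_ce_loss <- function(probs2, labels, class_w = c(1, 1), example_w = 1) {
  labels <- as.integer(as.logical(labels))
  p <- probs2[cbind(seq_along(labels), labels + 1L)]
  mean(example_w * class_w[labels + 1L] * (-log(pmax(p, 1e-300))))
}

# gradient of weighted_ce_loss wrt the 2-class logits (softmax folded in)
weighted_ce_grad <- function(probs2, labels, class_w = c(1, 1), example_w = 1) {
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  (probs2 - Y) * (example_w * class_w[labels + 1L] / n)
}

# featurize one complex into a model-ready training record
prepare_record <- function(model, record, k = 30L, example_w = 1) {
  pi_ <- prepare_protein_input(model, record$receptor, k = k)
  labels <- record$labels
  if (model$config$mode == "struct") labels <- labels[pi_$graph$kept]
  list(id = record$id, pin = pi_$pin, graph = pi_$graph,
       pep = one_hot_sequence(structure_sequence(record$partner)),
       labels = labels, example_w = example_w)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1 ^ st$t
  c2 <- 1 - beta2 ^ st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

record_loss <- function(model, rec, class_w, use_example_w, train = FALSE,
                        keep_cache = FALSE) {
  fwd <- pepnet_forward(model$params, model$config, rec$pin, rec$graph,
                        rec$pep, train = train, keep_cache = keep_cache)
  ew <- if (use_example_w) rec$example_w else 1
  list(fwd = fwd,
       loss = weighted_ce_loss(fwd$probs2, rec$labels, class_w, ew),
       ew = ew)
}

#' Train a model on prepared records
#'
#' One complex per iteration (cycling through a seeded shuffle of the
#' training set), Adam updates, validation loss evaluated every
#' `eval_every` iterations; the best-validation parameter set is kept and
#' training stops after `patience` evaluations without improvement or at
#' the iteration cap. Class weights are computed from the pooled training
#' labels; inverse-cluster example weights are applied during fine-tuning
#' only. Fully deterministic given `config$seed`.
#'
#' @param model an initialized `pep_model`.
#' @param train_records,val_records lists of records from
#'   `prepare_record()` (or [complex_record()]s, which are prepared
#'   automatically).
#' @param config a [train_config()].
#' @param k graph neighbor count used when records need featurizing.
#' @return list with the trained `model` (best-validation weights),
#'   `history` (data.frame: iteration, train_loss, val_loss) and
#'   `stopped_at`.
#' @export
train_model <- function(model, train_records, val_records, config, k = 30L) {
  stopifnot(inherits(model, "pep_model"), inherits(config, "train_config"))
  set.seed(config$seed)
  prep <- function(r) if (inherits(r, "complex_record"))
    prepare_record(model, r, k = k) else r
  train_records <- lapply(train_records, prep)
  val_records <- lapply(val_records, prep)
  all_labels <- unlist(lapply(train_records, `[[`, "labels"))
  cw <- class_weights(all_labels)
  use_ew <- config$phase == "finetune"
  st <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params)
  bad <- 0L
  hist_it <- integer(0); hist_tr <- numeric(0); hist_val <- numeric(0)
  ord <- sample(seq_along(train_records))
  pos <- 0L
  for (it in seq_len(config$max_iters)) {
    pos <- pos + 1L
    if (pos > length(ord)) { ord <- sample(seq_along(train_records)); pos <- 1L }
    rec <- train_records[[ord[pos]]]
    rl <- record_loss(model, rec, cw, use_ew, train = TRUE, keep_cache = TRUE)
    if (!is.finite(rl$loss))
      stop(sprintf("non-finite training loss at iteration %d (record %s)",
                   it, rec$id))
    dlog <- weighted_ce_grad(rl$fwd$probs2, rec$labels, cw, rl$ew)
    grads <- pepnet_backward(model$params, model$config, rec$graph, rl$fwd, dlog)
    upd <- adam_step(model$params, grads, st, config$lr)
    model$params <- upd$params; st <- upd$state
    if (it %% config$eval_every == 0L || it == config$max_iters) {
      vl <- mean(vapply(val_records, function(vr)
        record_loss(model, vr, cw, use_ew)$loss, numeric(1L)))
      tl <- rl$loss
      hist_it <- c(hist_it, it); hist_tr <- c(hist_tr, tl)
      hist_val <- c(hist_val, vl)
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = model$params)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  }
  model$params <- best$params
  list(model = model,
       history = data.frame(iteration = hist_it, train_loss = hist_tr,
                            val_loss = hist_val),
       best_val_loss = best$loss, stopped_at = max(hist_it))
}

#' Load pre-trained weights into a model (transfer learning)
#'
#' All parameter tensors are copied from the checkpoint; mode or shape
#' mismatches raise an error naming the offending tensors.
#'
#' @param checkpoint a `pep_model` (or the list returned by
#'   [load_checkpoint()]).
#' @param model the architecture-compatible target model.
#' @return `model` with the checkpoint's weights.
#' @export
transfer_weights <- function(checkpoint, model) {
  if (checkpoint$config$mode != model$config$mode)
    stop(sprintf("checkpoint mode '%s' does not match model mode '%s'",
                 checkpoint$config$mode, model$config$mode))
  src <- checkpoint$params; dst <- model$params
  missing <- setdiff(names(dst), names(src))
  if (length(missing))
    stop("checkpoint is missing tensors: ", paste(missing, collapse = ", "))
  bad <- names(dst)[vapply(names(dst), function(nm)
    !identical(dim(src[[nm]]), dim(dst[[nm]])) ||
      length(src[[nm]]) != length(dst[[nm]]), logical(1L))]
  if (length(bad))
    stop("shape mismatch for tensors: ", paste(bad, collapse = ", "))
  model$params <- src[names(dst)]
  model
}

#' Save / load a model checkpoint
#'
#' The weight bundle is written as an RDS file and a human-readable JSON
#' sidecar (`<path>.json`) records the configuration and tensor shapes.
#'
#' @param model a `pep_model`.
#' @param path output path for the weight bundle.
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model[c("config", "params")], path)
  sidecar <- list(config = unclass(model$config),
                  tensors = lapply(model$params, function(p)
                    if (is.matrix(p)) dim(p) else length(p)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file does not exist: ", path)
  x <- readRDS(path)
  class(x$config) <- "model_config"
  m <- list(config = x$config, params = x$params)
  class(m) <- "pep_model"
  m
}
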