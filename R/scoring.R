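# Peptide-agnostic scanning and the binder score: the alpha-weighted
# combination of the mean of the top-n residue binding probabilities with a
# Gaussian prior density on the binding-site fraction n/N, maximized over n.

#' Fit the Gaussian prior on the binding-site fraction
#'
#' Sample mean and standard deviation of the per-protein fraction of
#' binding residues across the training set.
#'
#' @param label_masks list of per-protein logical label vectors.
#' @return list of class `gaussian_prior` with `mu` and `sigma`.
#' @export
fit_prior <- function(label_masks) {
  stopifnot(length(label_masks) >= 2L)
  fr <- vapply(label_masks, function(x) mean(as.logical(x)), numeric(1L))
  sg <- stats::sd(fr)
  if (!is.finite(sg) || sg <= 0)
    stop("binding fractions have zero variance; cannot fit a Gaussian prior")
  out <- list(mu = mean(fr), sigma = sg)
  class(out) <- "gaussian_prior"
  out
}

#' Peptide-binding-module score of a protein
#'
#' `score(n) = alpha * mean(top-n probabilities) + (1 - alpha) * pdf(n/N)`
#' where the pdf is the fitted Gaussian prior on the binding-site fraction;
#' the score is maximized over n = 1..N (the smallest maximizing n is
#' reported on ties). With alpha = 1 the score reduces to the maximum
#' residue probability (n* = 1); with alpha = 0, n* makes n/N closest to
#' the prior mode.
#'
#' @param probs per-residue binding probabilities (length N >= 1).
#' @param prior a [fit_prior()] result (or list with `mu`, `sigma`).
#' @param alpha weighting factor in \[0, 1\]; reference calibrations from
#'   the published models are 0.955 (structure) and 0.965 (sequence).
#' @return list of class `binding_site_score`: `score`, `n_star`, `alpha`,
#'   `N`.
#' @export
site_score <- function(probs, prior, alpha = 0.955) {
  N <- length(probs)
  stopifnot(N >= 1L, alpha >= 0, alpha <= 1)
  sorted <- sort(probs, decreasing = TRUE)
  top_mean <- cumsum(sorted) / seq_len(N)
  pdf <- stats::dnorm(seq_len(N) / N, prior$mu, prior$sigma)
  s <- alpha * top_mean + (1 - alpha) * pdf
  n_star <- which.max(s)
  out <- list(score = s[n_star], n_star = n_star, alpha = alpha, N = N)
  class(out) <- "binding_site_score"
  out
}

#' Peptide-agnostic prediction with a poly-glycine probe
#'
#' Forward pass with a poly-glycine peptide of length `probe_len`
#' (default 10), scoring the protein's intrinsic propensity to bind
#' peptides without a known partner.
#'
#' @param model a trained `pep_model`.
#' @param protein structure (struct mode) or sequence (seq mode).
#' @param probe_len probe length (default 10).
#' @param k graph neighbor count for featurization.
#' @return data.frame as from [predict_binding()].
#' @export
peptide_agnostic_predict <- function(model, protein, probe_len = 10L, k = 30L) {
  stopifnot(probe_len >= 1L)
  predict_binding(model, protein, strrep("G", probe_len), k = k)
}

#' Calibrate the score weighting against per-protein prediction quality
#'
#' Grid search over alpha in {0, grid_step, ..., 1} maximizing the
#' correlation between each validation protein's score and the MCC of its
#' prediction (confidence should track correctness). Ties prefer the
#' smaller alpha.
#'
#' @param per_protein_probs list of per-protein probability vectors.
#' @param per_protein_mcc MCC per protein (length >= 3, finite).
#' @param prior a [fit_prior()] result.
#' @param grid_step alpha grid spacing (default 0.005).
#' @param method correlation type: `"pearson"` (default) or `"spearman"`.
#' @return the calibrated alpha.
#' @export
calibrate_alpha <- function(per_protein_probs, per_protein_mcc, prior,
                            grid_step = 0.005, method = "pearson") {
  stopifnot(length(per_protein_probs) == length(per_protein_mcc),
            length(per_protein_mcc) >= 3L, all(is.finite(per_protein_mcc)))
  alphas <- seq(0, 1, by = grid_step)
  cors <- vapply(alphas, function(a) {
    sc <- vapply(per_protein_probs, function(p) site_score(p, prior, a)$score,
                 numeric(1L))
    if (stats::sd(sc) < 1e-300) return(NA_real_)
    stats::cor(sc, per_protein_mcc, method = method)
  }, numeric(1L))
  if (all(is.na(cors)))
    stop("scores are constant at every alpha; cannot calibrate")
  alphas[which.max(cors)]   # first (smallest alpha) on ties
}

#' Rank candidate proteins by binder score
#'
#' Sorts descending by score (stable: ties keep input order) and flags
#' candidates scoring above the mean of a reference score set (e.g. known
#' peptide-recognition modules).
#'
#' @param scored data.frame with columns `id` and `score`.
#' @param reference_scores numeric vector of reference scores.
#' @return `scored` reordered, with added `rank` and `above_reference`.
#' @export
rank_candidates <- function(scored, reference_scores) {
  stopifnot(is.data.frame(scored), all(c("id", "score") %in% names(scored)))
  ord <- order(-scored$score)   # radix: stable for ties
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$above_reference <- out$score > mean(reference_scores)
  rownames(out) <- NULL
  out
}
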