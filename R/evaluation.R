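# Evaluation metrics and structural comparisons: ROC AUC, Matthews
# correlation, top-k hit, Kabsch superposition RMSD and the conformational-
# change annotation.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a random
#' positive outranks a random negative, ties counted one half.
#'
#' @param probs numeric scores.
#' @param labels logical/0-1 ground truth; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("ROC AUC undefined: both classes must be present")
  r <- rank(probs)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Matthews correlation coefficient
#'
#' Standard MCC of a binary confusion table; returns 0 when any marginal is
#' zero (common convention).
#'
#' @param pred logical/0-1 predictions.
#' @param labels logical/0-1 ground truth.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(pred, labels) {
  pred <- as.logical(pred); labels <- as.logical(labels)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Binary metric report at a probability threshold
#'
#' @param probs per-residue probabilities.
#' @param labels ground truth.
#' @param threshold binding-class probability cutoff (default 0.5).
#' @param k top-k for the hit flag (default 10).
#' @return list: `roc_auc`, `mcc`, `top_k_hit`, `threshold`, `counts`.
#' @export
metric_report <- function(probs, labels, threshold = 0.5, k = 10L) {
  labels <- as.logical(labels)
  pred <- probs >= threshold
  list(roc_auc = roc_auc(probs, labels), mcc = mcc(pred, labels),
       top_k_hit = top_k_hit(probs, labels, k), threshold = threshold,
       counts = c(TP = sum(pred & labels), FP = sum(pred & !labels),
                  TN = sum(!pred & !labels), FN = sum(!pred & labels)))
}

#' Top-k hit flag
#'
#' `TRUE` iff at least one true binding residue is among the k
#' highest-probability residues (ties broken by residue index).
#'
#' @param probs per-residue probabilities (length >= k).
#' @param labels ground truth.
#' @param k number of top residues to inspect (default 10).
#' @return logical flag.
#' @export
top_k_hit <- function(probs, labels, k = 10L) {
  stopifnot(length(probs) >= k)
  ord <- order(-probs, seq_along(probs))
  any(as.logical(labels)[ord[seq_len(k)]])
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition via SVD with the reflection-free
#' determinant correction, then coordinate RMSD.
#'
#' @param a,b n x 3 coordinate matrices (same n >= 3).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("point counts differ")
  stopifnot(nrow(a) >= 3L, ncol(a) == 3L, ncol(b) == 3L)
  a0 <- sweep(a, 2L, colMeans(a))
  b0 <- sweep(b, 2L, colMeans(b))
  s <- svd(t(b0) %*% a0)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a0 - b0 %*% R)^2)))
}

#' Conformational-change annotation of a peptide
#'
#' A peptide is flagged as undergoing a conformational change when its
#' CA-RMSD to any reference conformation of the same sequence is at least
#' `cutoff` (2.5 Angstrom, inclusive).
#'
#' @param peptide_ca n x 3 CA coordinates.
#' @param reference_ca_sets list of reference n x 3 CA coordinate sets;
#'   references with a mismatching point count are skipped with a warning.
#' @param cutoff RMSD threshold (default 2.5).
#' @return logical flag.
#' @export
conformational_change <- function(peptide_ca, reference_ca_sets, cutoff = 2.5) {
  stopifnot(length(reference_ca_sets) >= 1L)
  usable <- 0L
  for (ref in reference_ca_sets) {
    if (nrow(ref) != nrow(peptide_ca)) {
      warning("reference with mismatching length skipped")
      next
    }
    usable <- usable + 1L
    if (kabsch_rmsd(peptide_ca, ref) >= cutoff) return(TRUE)
  }
  if (usable == 0L) stop("no usable reference conformations")
  FALSE
}
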