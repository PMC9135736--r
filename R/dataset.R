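# Dataset construction: binding-residue annotation, Shrake-Rupley solvent-
# accessible surface area, the numeric complex filters, sequence-identity
# clustering and leakage-free train/validation splitting.

#' A receptor-partner complex record
#'
#' The training unit: a receptor chain paired with a peptide (or fragment)
#' chain, with per-receptor-residue binding labels.
#'
#' @param receptor,partner [protein_structure()] objects.
#' @param resolution crystallographic resolution (Angstrom) or `NA`.
#' @param id record identifier.
#' @param bsa buried surface area (A^2) if already computed.
#' @param cluster sequence-cluster id (filled by the clustering step).
#' @param labels optional logical vector; computed with the 6 A rule when
#'   omitted.
#' @return list of class `complex_record`.
#' @export
complex_record <- function(receptor, partner, resolution = NA_real_,
                           id = "complex", bsa = NA_real_, cluster = NA,
                           labels = NULL) {
  if (is.null(labels)) labels <- annotate_binding_residues(receptor, partner)
  stopifnot(length(labels) == length(receptor$aa))
  out <- list(receptor = receptor, partner = partner, labels = labels,
              resolution = resolution, bsa = bsa, cluster = cluster, id = id)
  class(out) <- "complex_record"
  out
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf(
    "<complex_record> %s: receptor %s (%d aa), partner %s (%d aa), %d binding residues%s%s\n",
    x$id, x$receptor$chain_id, length(x$receptor$aa),
    x$partner$chain_id, length(x$partner$aa), sum(x$labels),
    if (is.na(x$resolution)) "" else sprintf(", resolution %.2f A", x$resolution),
    if (is.na(x$bsa)) "" else sprintf(", BSA %.0f A^2", x$bsa)))
  invisible(x)
}

#' Annotate binding residues by the 6 Angstrom heavy-atom rule
#'
#' A receptor residue is a binding residue iff any of its heavy atoms lies
#' within `cutoff` of any heavy atom of the partner chain.
#'
#' @param receptor,partner [protein_structure()] objects.
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @return logical vector, one flag per receptor residue.
#' @export
annotate_binding_residues <- function(receptor, partner, cutoff = 6.0) {
  ra <- structure_atoms(receptor)
  pa <- structure_atoms(partner)
  flags <- rep(FALSE, length(receptor$aa))
  if (is.null(pa$xyz) || nrow(pa$xyz) == 0L) return(flags)
  d2 <- outer(rowSums(ra$xyz^2), rowSums(pa$xyz^2), "+") -
    2 * ra$xyz %*% t(pa$xyz)
  hit <- apply(d2 <= cutoff^2 + 1e-12, 1L, any)
  flags[unique(ra$residue[hit])] <- TRUE
  flags
}

# --- Shrake-Rupley SASA ------------------------------------------------

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20)

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point counting: each atom is inflated by the probe radius,
#' covered with a deterministic quasi-uniform point set, and the accessible
#' fraction is the share of points not buried inside any neighboring
#' inflated sphere.
#'
#' @param xyz n x 3 heavy-atom coordinates (Angstrom).
#' @param elem length-n element symbols; unknown elements get a 1.8 A van
#'   der Waals radius with a warning.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 960).
#' @return numeric vector of per-atom areas (A^2).
#' @export
shrake_rupley_sasa <- function(xyz, elem, probe = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(elem) == n)
  r <- VDW_RADII[toupper(elem)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elem[is.na(r)]), collapse = ", "),
            ": using default radius 1.8 A")
    r[is.na(r)] <- 1.8
  }
  R <- r + probe
  pts <- sphere_points(n_points)
  # neighbor candidates via squared distances
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(p, 2L, xyz[j, ])^2)
      free <- free & dj2 > R[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  area
}

# total SASA of one or several structures taken together
sasa_total <- function(structures, probe = 1.4, n_points = 960L) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  at <- lapply(structures, structure_atoms)
  xyz <- do.call(rbind, lapply(at, `[[`, "xyz"))
  elem <- unlist(lapply(at, `[[`, "elem"))
  sum(shrake_rupley_sasa(xyz, elem, probe, n_points))
}

#' Buried surface area of a two-chain complex
#'
#' `BSA = SASA(A) + SASA(B) - SASA(A union B)` (the unhalved two-body
#' formula), in A^2. Symmetric in its arguments by construction.
#'
#' @param a,b [protein_structure()] objects.
#' @param probe,n_points passed to [shrake_rupley_sasa()].
#' @return buried area (A^2).
#' @export
buried_surface_area <- function(a, b, probe = 1.4, n_points = 960L) {
  sasa_total(a, probe, n_points) + sasa_total(b, probe, n_points) -
    sasa_total(list(a, b), probe, n_points)
}

# --- complex filters ---------------------------------------------------

#' Filter putative peptide-protein complexes
#'
#' Keeps a record iff: resolution 2.5 A or better (numeric <= 2.5; records
#' with missing resolution are excluded with a logged reason), receptor
#' longer than 30 residues, partner 25 residues or fewer, and buried surface
#' area at least 400 A^2.
#'
#' @param records list of [complex_record()]; each must carry `resolution`
#'   and `bsa` (computed beforehand).
#' @param max_resolution,min_receptor_len,max_partner_len,min_bsa the four
#'   rule thresholds.
#' @return list with `kept` (surviving records) and `log` (data.frame of
#'   excluded ids and reasons).
#' @export
filter_peptide_complexes <- function(records, max_resolution = 2.5,
                                     min_receptor_len = 31L,
                                     max_partner_len = 25L, min_bsa = 400) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    why <- character(0)
    if (is.na(r$resolution)) {
      why <- c(why, "missing resolution")
    } else if (r$resolution > max_resolution) {
      why <- c(why, sprintf("resolution %.2f > %.2f", r$resolution, max_resolution))
    }
    if (length(r$receptor$aa) < min_receptor_len)
      why <- c(why, sprintf("receptor length %d <= 30", length(r$receptor$aa)))
    if (length(r$partner$aa) > max_partner_len)
      why <- c(why, sprintf("partner length %d > 25", length(r$partner$aa)))
    if (is.na(r$bsa) || r$bsa < min_bsa)
      why <- c(why, sprintf("BSA %.1f < %.0f", r$bsa, min_bsa))
    keep[i] <- length(why) == 0L
    if (!keep[i]) { ids <- c(ids, r$id); reasons <- c(reasons, paste(why, collapse = "; ")) }
  }
  list(kept = records[keep],
       log = data.frame(id = ids, reason = reasons, stringsAsFactors = FALSE))
}

# --- sequence identity, clustering, splitting --------------------------

#' Global pairwise sequence identity and coverage
#'
#' Needleman-Wunsch global alignment (via Biostrings). Identity is the
#' fraction of matching positions over aligned columns where both sequences
#' have a residue (gap columns excluded); coverage is the number of such
#' columns relative to the shorter sequence.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return named numeric vector `c(identity, coverage)` in percent.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  mat <- matrix(0L, 26L, 26L, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1L
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  both <- p != "-" & s != "-"
  ncols <- sum(both)
  if (ncols == 0L) return(c(identity = 0, coverage = 0))
  c(identity = 100 * sum(p[both] == s[both]) / ncols,
    coverage = 100 * ncols / min(nchar(a), nchar(b)))
}

#' Greedy centroid clustering by sequence identity
#'
#' Longest-first greedy clustering: sequences are visited in order of
#' decreasing length (ties keep input order); each is assigned to the first
#' existing centroid whose pairwise identity is at least `threshold`,
#' otherwise it founds a new cluster.
#'
#' @param seqs character vector of sequences.
#' @param threshold identity threshold in percent (default 30).
#' @return list with `cluster` (integer id per input sequence) and
#'   `centroids` (indices of the cluster founders).
#' @export
greedy_cluster <- function(seqs, threshold = 30) {
  stopifnot(length(seqs) >= 1L)
  ord <- order(-nchar(seqs))
  cluster <- integer(length(seqs))
  centroids <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      pid <- pairwise_identity(seqs[centroids[ci]], seqs[i])["identity"]
      if (pid >= threshold) { cluster[i] <- ci; assigned <- TRUE; break }
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      cluster[i] <- length(centroids)
    }
  }
  list(cluster = cluster, centroids = centroids)
}

#' Split clusters into train and validation sets
#'
#' Shuffles cluster ids with the given seed and assigns whole clusters to
#' splits (90/10 by cluster count by default), so no cluster ever spans both
#' splits.
#'
#' @param cluster integer cluster id per record.
#' @param train_frac fraction of clusters assigned to training.
#' @param seed RNG seed.
#' @return list with `train`/`val` (record indices), `cluster_split`
#'   (named map cluster -> split) and `seed`.
#' @export
split_clusters <- function(cluster, train_frac = 0.9, seed = 1L) {
  ucl <- unique(cluster)
  if (length(ucl) < 2L) stop("need at least 2 clusters to split")
  set.seed(seed)
  ucl <- sample(ucl)
  n_train <- max(1L, min(length(ucl) - 1L, floor(train_frac * length(ucl))))
  train_cl <- ucl[seq_len(n_train)]
  split <- ifelse(ucl %in% train_cl, "train", "val")
  names(split) <- as.character(ucl)
  list(train = which(cluster %in% train_cl),
       val = which(!cluster %in% train_cl),
       cluster_split = split, seed = seed)
}

#' Remove test sequences redundant with a reference set
#'
#' Two stages: (1) drop any test sequence with more than `id_thresh` percent
#' identity at `cov_thresh` percent or more coverage to any reference
#' sequence; (2) cluster the survivors at `centroid_thresh` percent identity
#' and keep only each cluster's centroid.
#'
#' @param test_seqs,reference_seqs character vectors.
#' @param id_thresh,cov_thresh redundancy thresholds in percent (30/70).
#' @param centroid_thresh final clustering threshold in percent (90).
#' @return indices into `test_seqs` of the kept sequences.
#' @export
deduplicate_test <- function(test_seqs, reference_seqs, id_thresh = 30,
                             cov_thresh = 70, centroid_thresh = 90) {
  survive <- vapply(test_seqs, function(ts) {
    for (rs in reference_seqs) {
      pc <- pairwise_identity(ts, rs)
      if (pc["identity"] > id_thresh && pc["coverage"] >= cov_thresh)
        return(FALSE)
    }
    TRUE
  }, logical(1L), USE.NAMES = FALSE)
  idx <- which(survive)
  if (length(idx) == 0L) return(integer(0))
  cl <- greedy_cluster(test_seqs[idx], threshold = centroid_thresh)
  sort(idx[cl$centroids])
}

# --- fragment scanning -------------------------------------------------

#' Scan a partner chain for receptor-binding fragments
#'
#' Scores every contiguous 5-25 residue window of the partner chain by a
#' simplified interface score: minus the number of heavy-atom pairs within
#' `contact_cutoff` between the window and the receptor (more negative =
#' larger interface, the sign mimicking an interface energy). This score is
#' deliberately NOT an energy model; it is a contact-count stand-in with the
#' same filtering semantics.
#'
#' @param receptor [protein_structure()] with at least 50 residues.
#' @param partner [protein_structure()] with at least `min_len` residues.
#' @param min_len,max_len window length range (5-25).
#' @param contact_cutoff heavy-atom contact distance (default 5 A).
#' @return data.frame of all windows (`start`, `len`, `score`, `best`,
#'   where `best` marks the best-scoring window of each length, ties to the
#'   earliest start).
#' @export
scan_fragments <- function(receptor, partner, min_len = 5L, max_len = 25L,
                           contact_cutoff = 5.0) {
  if (length(receptor$aa) < 50L) stop("receptor must have at least 50 residues")
  Lp <- length(partner$aa)
  if (Lp < min_len) stop("partner shorter than the minimum fragment length")
  ra <- structure_atoms(receptor); pa <- structure_atoms(partner)
  d2 <- outer(rowSums(pa$xyz^2), rowSums(ra$xyz^2), "+") -
    2 * pa$xyz %*% t(ra$xyz)
  contact <- d2 < contact_cutoff^2
  per_res <- vapply(seq_len(Lp), function(i)
    sum(contact[pa$residue == i, , drop = FALSE]), numeric(1L))
  cum <- c(0, cumsum(per_res))
  rows <- list()
  for (len in min_len:min(max_len, Lp)) {
    starts <- seq_len(Lp - len + 1L)
    score <- -(cum[starts + len] - cum[starts])
    best <- which.min(score)  # most negative, earliest on ties
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts, len = len, score = score,
      best = seq_along(starts) == best)
  }
  do.call(rbind, rows)
}

#' Filter fragment complexes by interface score and buried surface area
#'
#' Keeps a fragment iff its interface score is no more than one reference
#' standard deviation above the reference mean (the peptide-complex score
#' distribution) and its BSA is at least 400 A^2.
#'
#' @param fragments data.frame with columns `score` and `bsa`.
#' @param ref_mean,ref_sd mean and SD of the peptide-complex score
#'   distribution.
#' @param min_bsa BSA threshold (default 400).
#' @return the surviving rows of `fragments`.
#' @export
filter_fragments <- function(fragments, ref_mean, ref_sd, min_bsa = 400) {
  keep <- fragments$score <= ref_mean + ref_sd & fragments$bsa >= min_bsa
  fragments[keep, , drop = FALSE]
}
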