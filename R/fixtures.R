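# Deterministic synthetic peptide-protein complexes for offline testing.
#
# Fixtures are ideal alpha-helices built by internal-coordinate chain
# extension (phi = -57, psi = -47, omega = 180 degrees; standard backbone
# bond lengths/angles), so torsions, CA-CA spacings and rise are known by
# construction. Realism is not the goal: the generator reproduces the
# *statistical and geometric structure* the pipeline depends on -- chain
# lengths, 6 A heavy-atom contacts, buried surface area above the dataset
# threshold, and controllable sequence-identity families.

HELIX_PHI <- -57 * pi / 180
HELIX_PSI <- -47 * pi / 180
HELIX_OMEGA <- pi

# residues carrying the plantable binding signature vs the neutral pool
SIGNATURE_AA <- c("F", "W", "Y", "L", "I", "V")
NEUTRAL_AA <- c("D", "E", "K", "R", "S", "T", "N", "Q", "A", "H")

#' Ideal alpha-helix fixture structure
#'
#' Builds an ideal helical backbone (N, CA, C, O plus a CB-like side-chain
#' carbon for non-glycine residues) with phi = -57 deg, psi = -47 deg,
#' omega = 180 deg, giving the canonical ~1.5 A rise per residue and ~3.8 A
#' consecutive CA-CA distance. The sequence is drawn uniformly from the 20
#' canonical amino acids unless supplied.
#'
#' @param n_res number of residues (>= 2).
#' @param seed RNG seed (sequence sampling only; geometry is deterministic).
#' @param seq optional character vector of one-letter codes, length `n_res`.
#' @param chain_id chain identifier (default "A").
#' @return a [protein_structure()].
#' @export
make_helix <- function(n_res, seed = 1L, seq = NULL, chain_id = "A") {
  stopifnot(n_res >= 2L)
  if (is.null(seq)) {
    set.seed(seed)
    seq <- sample(AA1, n_res, replace = TRUE)
  }
  stopifnot(length(seq) == n_res)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_CaCb <- 1.53
  a_NCaC <- 111.2 * pi / 180; a_CaCN <- 116.2 * pi / 180
  a_CNCa <- 121.7 * pi / 180; a_CaCO <- 120.5 * pi / 180
  a_NCaCb <- 110.5 * pi / 180
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(b_NCa, 0, 0)
  C[1L, ] <- CA[1L, ] + b_CaC * c(-cos(a_NCaC), sin(a_NCaC), 0)
  for (i in 2:n_res) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         b_CN, a_CaCN, HELIX_PSI)
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          b_NCa, a_CNCa, HELIX_OMEGA)
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         b_CaC, a_NCaC, HELIX_PHI)
  }
  sc <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the next amide nitrogen
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_CO, a_CaCO,
                         HELIX_PSI + pi)
    if (seq[i] != "G") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], b_CaCb, a_NCaCb,
                       122.5 * pi / 180)
      m <- matrix(cb, 1L, 3L)
      rownames(m) <- "CB"
      sc[[i]] <- list(xyz = m, elem = "C")
    }
  }
  protein_structure(chain_id, seq, N, CA, C, O, sc)
}

# First principal axis of the CA trace (unit vector).
helix_axis <- function(s) {
  X <- sweep(s$CA, 2L, colMeans(s$CA))
  v <- svd(X, nu = 0L, nv = 1L)$v[, 1L]
  vunit(v)
}

# Rotation matrix carrying unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  w <- vcross(u, v)
  s <- vnorm(w); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- vunit(vcross(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(2 * outer(p, p) - diag(3))
  }
  K <- matrix(c(0, -w[3L], w[2L], w[3L], 0, -w[1L], -w[2L], w[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

min_heavy_distance <- function(a, b) {
  A <- structure_atoms(a)$xyz; B <- structure_atoms(b)$xyz
  min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
}

#' Specification of a synthetic peptide-protein complex
#'
#' @param receptor_len receptor chain length (> 30).
#' @param peptide_len peptide chain length (<= 25).
#' @param patch_center receptor residue index at the center of the intended
#'   contact patch (default: chain midpoint).
#' @param patch_distance target minimum heavy-atom distance (Angstrom)
#'   between the chains: below 6 plants a binder, above 8 a decoy.
#' @param seed RNG seed; the fixture is deterministic given the seed.
#' @param resolution nominal resolution tag carried by the record.
#' @param signature if `TRUE`, contact residues get side-chain identities
#'   from a hydrophobic signature set and the rest from a neutral set, so a
#'   model can learn the planted binding site from sequence features.
#' @param verify_bsa if `TRUE` (default for binders), the generator checks
#'   that the buried surface area exceeds 400 A^2 and retries otherwise.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(receptor_len = 40L, peptide_len = 16L,
                         patch_center = NULL, patch_distance = 3.0,
                         seed = 1L, resolution = 1.8,
                         signature = TRUE,
                         verify_bsa = patch_distance < 6) {
  stopifnot(receptor_len > 30L, peptide_len <= 25L, peptide_len >= 2L,
            patch_distance > 0)
  if (is.null(patch_center)) patch_center <- receptor_len %/% 2L
  out <- list(receptor_len = as.integer(receptor_len),
              peptide_len = as.integer(peptide_len),
              patch_center = as.integer(patch_center),
              patch_distance = patch_distance, seed = as.integer(seed),
              resolution = resolution, signature = signature,
              verify_bsa = verify_bsa)
  class(out) <- "fixture_spec"
  out
}

#' Generate a synthetic peptide-protein complex
#'
#' Places a peptide helix alongside the receptor helix, against the face of
#' the residue `patch_center`, at the requested minimum heavy-atom distance
#' (binders < 6 A guarantee at least one labelled contact residue; decoys
#' > 8 A guarantee none). Binding labels are computed with the package's 6 A
#' heavy-atom rule, and binder fixtures are verified to bury more than
#' 400 A^2 of surface area at generation time.
#'
#' @param spec a [fixture_spec()].
#' @param max_retries placement attempts before giving up (default 100).
#' @return a [complex_record()] whose `labels` are the exact 6 A annotation;
#'   the attribute-free list also carries `contact_patch` (labelled residue
#'   indices) and `bsa` (for verified binders).
#' @export
make_complex <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  rec_seq_seed <- sample.int(2^30, 1L)
  pep_seq_seed <- sample.int(2^30, 1L)
  receptor <- make_helix(spec$receptor_len, seed = rec_seq_seed, chain_id = "A")
  peptide <- make_helix(spec$peptide_len, seed = pep_seq_seed, chain_id = "B")
  axis <- helix_axis(receptor)
  ca_c <- receptor$CA[spec$patch_center, ]
  ctr <- colMeans(receptor$CA)
  radial <- ca_c - (ctr + sum((ca_c - ctr) * axis) * axis)
  dir0 <- vunit(radial)
  pep0 <- transform_structure(peptide,
                              rotation_between(helix_axis(peptide), axis))
  pep_ctr <- colMeans(structure_atoms(pep0)$xyz)
  target <- spec$patch_distance
  binder <- target < 6

  rec_xyz <- structure_atoms(receptor)$xyz
  rec_sq <- rowSums(rec_xyz^2)
  spin_about <- function(s, w, theta) {
    ct <- cos(theta); st <- sin(theta)
    K <- matrix(c(0, -w[3L], w[2L], w[3L], 0, -w[1L], -w[2L], w[1L], 0),
                3L, 3L, byrow = TRUE)
    Rs <- diag(3) + st * K + (1 - ct) * K %*% K
    pc <- colMeans(structure_atoms(s)$xyz)
    transform_structure(s, Rs, pc - as.numeric(Rs %*% pc))
  }
  for (attempt in seq_len(max_retries)) {
    dir <- dir0
    if (attempt > 1L) {   # seeded jitter on retry
      dir <- vunit(dir0 + stats::rnorm(3L, sd = 0.05 * attempt))
    }
    # scan the peptide's azimuth about its own axis and keep the spin with
    # the largest heavy-atom contact count at the target separation, so the
    # chains meet face-on rather than at a few protruding side-chain tips
    best <- NULL
    for (theta in seq(0, 330, by = 30) * pi / 180) {
      pspin <- spin_about(pep0, axis, theta)
      pxyz <- structure_atoms(pspin)$xyz
      pctr <- colMeans(pxyz)
      mindist_at <- function(t) {
        P <- sweep(pxyz, 2L, ca_c + dir * t - pctr, "+")
        min(sqrt(pmax(0, outer(rec_sq, rowSums(P^2), "+") -
                        2 * rec_xyz %*% t(P))))
      }
      lo <- 1; hi <- 60
      for (iter in 1:50) {
        mid <- (lo + hi) / 2
        md <- mindist_at(mid)
        if (md < target) lo <- mid else hi <- mid
        if (abs(md - target) < 0.02) break
      }
      tfin <- (lo + hi) / 2
      P <- sweep(pxyz, 2L, ca_c + dir * tfin - pctr, "+")
      npairs <- sum(outer(rec_sq, rowSums(P^2), "+") -
                      2 * rec_xyz %*% t(P) < 36)
      if (is.null(best) || npairs > best$npairs) {
        best <- list(npairs = npairs, pspin = pspin, shift = ca_c + dir * tfin - pctr)
      }
    }
    pep <- transform_structure(best$pspin, diag(3), best$shift)
    md <- min_heavy_distance(receptor, pep)
    labels <- annotate_binding_residues(receptor, pep)
    if (binder && !any(labels)) next
    if (!binder && md < 8) next
    if (spec$signature) {
      sig_seed <- spec$seed * 1000L + attempt
      set.seed(sig_seed)
      aa <- sample(NEUTRAL_AA, spec$receptor_len, replace = TRUE)
      if (binder) aa[labels] <- sample(SIGNATURE_AA, sum(labels), replace = TRUE)
      receptor$aa <- aa
    }
    bsa <- NA_real_
    if (spec$verify_bsa) {
      bsa <- buried_surface_area(receptor, pep)
      if (binder && bsa <= 400) next
    }
    rec <- complex_record(receptor, pep, resolution = spec$resolution,
                          id = sprintf("fx_seed%d", spec$seed), bsa = bsa)
    rec$contact_patch <- which(labels)
    rec$spec <- spec
    return(rec)
  }
  stop("fixture placement failed after ", max_retries, " retries")
}

#' Synthetic sequence family with controlled pairwise identity
#'
#' Members are generated by substituting a fraction `1 - sqrt(t)` of a
#' seeded ancestor's positions independently per member (t = target pairwise
#' identity), which makes the *pairwise* member identity concentrate around
#' the target.
#'
#' @param n_members family size.
#' @param within_identity target pairwise identity in percent (0, 100].
#' @param seed RNG seed (a different seed gives a different ancestor).
#' @param len sequence length (default 100).
#' @return character vector of sequences.
#' @export
make_sequence_family <- function(n_members, within_identity, seed = 1L,
                                 len = 100L) {
  stopifnot(within_identity > 0, within_identity <= 100, n_members >= 1L)
  set.seed(seed)
  ancestor <- sample(AA1, len, replace = TRUE)
  q <- 1 - sqrt(within_identity / 100)
  n_mut <- round(len * q)
  vapply(seq_len(n_members), function(m) {
    s <- ancestor
    if (n_mut > 0L) {
      pos <- sample.int(len, n_mut)
      for (p in pos) s[p] <- sample(setdiff(AA1, s[p]), 1L)
    }
    paste(s, collapse = "")
  }, character(1L))
}
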