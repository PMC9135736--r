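# Rotation- and translation-invariant residue-graph featurization.
#
# Every residue gets a local orthonormal frame built from its backbone; all
# geometric quantities (inter-residue directions, relative frame rotations,
# side-chain centroid directions) are expressed in these frames, so the
# resulting node/edge features are invariant under any global rigid motion
# of the structure.

# Default radial-basis layout: 16 centers uniform on [0, 20] A for CA-CA
# distances, 16 centers on [0, 8] A for CA -> side-chain centroid distances;
# width = center spacing in both cases.
default_rbf_centers <- function(n = 16L, dmax = 20) seq(0, dmax, length.out = n)

#' Gaussian radial-basis encoding of a distance
#'
#' `entry_c = exp(-(d - c)^2 / (2 w^2))` for each center `c`.
#'
#' @param d non-negative distance (Angstrom); may be a vector.
#' @param centers RBF center positions (Angstrom).
#' @param width Gaussian width (Angstrom), > 0.
#' @return matrix `length(d)` x `length(centers)` (a vector drops to the
#'   single row for scalar `d`).
#' @export
rbf_encode <- function(d, centers = default_rbf_centers(), width = centers[2L] - centers[1L]) {
  stopifnot(all(d >= 0), width > 0)
  out <- exp(-outer(d, centers, "-")^2 / (2 * width^2))
  if (length(d) == 1L) out <- drop(out)
  out
}

#' Local backbone coordinate frame at a residue
#'
#' Gram–Schmidt on (C - CA, N - CA): the first axis points along C - CA, the
#' second is the orthogonalized N - CA direction, the third their cross
#' product, giving a right-handed orthonormal basis with origin at the CA.
#'
#' @param N,CA,C backbone coordinates (length-3 vectors, Angstrom).
#' @return list with `origin` (CA) and `basis` (3 x 3, axes in columns).
#' @export
local_frame <- function(N, CA, C) {
  if (anyNA(c(N, CA, C))) stop("missing backbone atom: frame undefined")
  e1 <- vunit(C - CA)
  v2 <- N - CA
  v2 <- v2 - sum(v2 * e1) * e1
  if (vnorm(v2) < 1e-8) stop("degenerate backbone geometry: frame undefined")
  e2 <- vunit(v2)
  e3 <- vcross(e1, e2)
  list(origin = CA, basis = cbind(e1, e2, e3, deparse.level = 0L))
}

#' Relative rotation between two local frames as a unit quaternion
#'
#' Returns the quaternion `q = (w, x, y, z)` with `R(q) = basis_i' %*%
#' basis_j`, i.e. the rotation carrying frame i onto frame j expressed in
#' frame i. The sign ambiguity of the double cover is resolved by requiring
#' a non-negative scalar part.
#'
#' @param frame_i,frame_j frames from [local_frame()].
#' @return numeric length-4 unit quaternion.
#' @export
frame_quaternion <- function(frame_i, frame_j) {
  rotmat_to_quat(t(frame_i$basis) %*% frame_j$basis)
}

#' Backbone torsion angles of a chain
#'
#' Computes per-residue (phi, psi, omega) with the usual conventions:
#' `phi_i = C(i-1)-N(i)-CA(i)-C(i)`, `psi_i = N(i)-CA(i)-C(i)-N(i+1)`,
#' `omega_i = CA(i-1)-C(i-1)-N(i)-CA(i)`. Angles that are undefined at the
#' termini, across a chain break (consecutive CA-CA distance above
#' `break_cutoff`), or for degenerate (collinear) geometry are `NA` and are
#' encoded as `(sin, cos) = (0, 0)`.
#'
#' @param s a [protein_structure()] of length >= 2.
#' @param break_cutoff CA-CA distance (Angstrom) above which consecutive
#'   residues are treated as a chain break (default 4.5).
#' @return list with `angles` (L x 3 matrix of radians, `NA` = undefined)
#'   and `encoded` (L x 6 matrix: sin/cos of phi, psi, omega).
#' @export
backbone_dihedrals <- function(s, break_cutoff = 4.5) {
  L <- length(s$aa)
  if (L < 2L) stop("need at least 2 residues for backbone dihedrals")
  gap_after <- rep(FALSE, L)   # break between i and i+1
  for (i in seq_len(L - 1L)) {
    d <- vnorm(s$CA[i + 1L, ] - s$CA[i, ])
    gap_after[i] <- !is.finite(d) || d > break_cutoff
  }
  ang <- matrix(NA_real_, L, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(L)) {
    if (i > 1L && !gap_after[i - 1L]) {
      ang[i, "phi"] <- tryCatch(
        dihedral_angle(s$C[i - 1L, ], s$N[i, ], s$CA[i, ], s$C[i, ]),
        error = function(e) NA_real_)
      ang[i, "omega"] <- tryCatch(
        dihedral_angle(s$CA[i - 1L, ], s$C[i - 1L, ], s$N[i, ], s$CA[i, ]),
        error = function(e) NA_real_)
    }
    if (i < L && !gap_after[i]) {
      ang[i, "psi"] <- tryCatch(
        dihedral_angle(s$N[i, ], s$CA[i, ], s$C[i, ], s$N[i + 1L, ]),
        error = function(e) NA_real_)
    }
  }
  enc <- matrix(0, L, 6L)
  colnames(enc) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi",
                     "sin_omega", "cos_omega")
  for (j in 1:3) {
    ok <- !is.na(ang[, j])
    enc[ok, 2L * j - 1L] <- sin(ang[ok, j])
    enc[ok, 2L * j] <- cos(ang[ok, j])
  }
  list(angles = ang, encoded = enc)
}

#' Side-chain centroid features of a residue
#'
#' The centroid of the side-chain heavy atoms is expressed in the residue's
#' local frame: a unit direction vector (zero for glycine / no side-chain
#' heavy atoms, whose distance is then encoded at 0) plus an RBF encoding of
#' the CA-to-centroid distance.
#'
#' @param sidechain side-chain block (`list(xyz, elem)`) or `NULL`.
#' @param frame the residue's [local_frame()].
#' @param centers,width RBF layout for the centroid distance (default 16
#'   centers on \[0, 8\] Angstrom, width = spacing).
#' @return list with `direction` (length 3) and `dist_rbf`.
#' @export
sidechain_centroid_features <- function(sidechain, frame,
                                        centers = default_rbf_centers(16L, 8),
                                        width = centers[2L] - centers[1L]) {
  if (is.null(sidechain) || nrow(sidechain$xyz) == 0L) {
    return(list(direction = c(0, 0, 0),
                dist_rbf = rbf_encode(0, centers, width)))
  }
  centroid <- colMeans(sidechain$xyz)
  v <- centroid - frame$origin
  d <- vnorm(v)
  dir <- if (d < 1e-9) c(0, 0, 0) else as.numeric(t(frame$basis) %*% (v / d))
  list(direction = dir, dist_rbf = rbf_encode(d, centers, width))
}

# Residue-level sequence-offset encoding: offset j - i clipped to [-32, 32],
# one-hot over 65 positions.
relpos_onehot <- function(offset, clip = 32L) {
  off <- max(-clip, min(clip, offset))
  v <- numeric(2L * clip + 1L)
  v[off + clip + 1L] <- 1
  v
}

#' Build the k-nearest-neighbor residue graph of a structure
#'
#' Nodes carry the amino-acid one-hot (21), the sin/cos backbone dihedrals
#' (6), the side-chain centroid direction in the local frame (3) and the RBF
#' encoding of the centroid distance (16). Edges from residue i to each of
#' its k nearest neighbors j (by CA-CA distance, ties broken by lower
#' residue index, self excluded) carry the CA-CA distance RBF (16), the unit
#' direction to j in frame i (3), the unit quaternion of the relative frame
#' rotation (4) and a one-hot sequence-offset encoding (65). All features
#' are invariant under global rigid motions.
#'
#' Residues missing any of N/CA/C are flagged and excluded from the graph.
#'
#' @param s a [protein_structure()] with at least 2 graph-admissible
#'   residues.
#' @param k neighbor count (default 30); each node gets `min(k, L - 1)`
#'   neighbors.
#' @param rbf_centers,rbf_width RBF layout for CA-CA distances.
#' @param relpos_clip sequence-offset clip (default 32 -> 65-dim one-hot).
#' @return object of class `residue_graph`: `nodes` (L x 46), `nbr`
#'   (L x k_eff neighbor indices, ascending distance), `efeat`
#'   (edge-level matrix, rows ordered as `idx_src`/`idx_nbr`), `aa`,
#'   `kept` (indices of admitted residues in the input structure).
#' @export
build_residue_graph <- function(s, k = 30L,
                                rbf_centers = default_rbf_centers(),
                                rbf_width = rbf_centers[2L] - rbf_centers[1L],
                                relpos_clip = 32L) {
  keep <- which(stats::complete.cases(s$N) & stats::complete.cases(s$CA) &
                  stats::complete.cases(s$C))
  dropped <- setdiff(seq_along(s$aa), keep)
  L <- length(keep)
  if (L < 2L) stop("structure too short to build a residue graph (need >= 2 residues)")
  frames <- lapply(keep, function(i) local_frame(s$N[i, ], s$CA[i, ], s$C[i, ]))
  CA <- s$CA[keep, , drop = FALSE]
  dih <- backbone_dihedrals(s)$encoded[keep, , drop = FALSE]
  aa_idx <- match(s$aa[keep], AA_ALPHABET)
  onehot <- matrix(0, L, 21L)
  onehot[cbind(seq_len(L), aa_idx)] <- 1
  sc_cent <- default_rbf_centers(16L, 8)
  sc_dir <- matrix(0, L, 3L); sc_rbf <- matrix(0, L, 16L)
  for (i in seq_len(L)) {
    f <- sidechain_centroid_features(s$sidechain[[keep[i]]], frames[[i]], sc_cent)
    sc_dir[i, ] <- f$direction
    sc_rbf[i, ] <- f$dist_rbf
  }
  nodes <- cbind(onehot, dih, sc_dir, sc_rbf)

  D <- as.matrix(stats::dist(CA))
  # distances are quantized to 1e-6 A before sorting so that exact or
  # floating-point-level ties resolve deterministically by lower residue
  # index, keeping the neighbor order stable under global rigid motions
  Dq <- round(D * 1e6)
  k_eff <- as.integer(min(k, L - 1L))
  nbr <- matrix(0L, L, k_eff)
  for (i in seq_len(L)) {
    ord <- order(Dq[i, -i], setdiff(seq_len(L), i))[seq_len(k_eff)]
    nbr[i, ] <- setdiff(seq_len(L), i)[ord]
  }
  idx_src <- rep(seq_len(L), each = k_eff)
  idx_nbr <- as.integer(t(nbr))
  E <- length(idx_src)
  d_edge <- length(rbf_centers) + 3L + 4L + (2L * relpos_clip + 1L)
  efeat <- matrix(0, E, d_edge)
  for (e in seq_len(E)) {
    i <- idx_src[e]; j <- idx_nbr[e]
    dir_g <- vunit(CA[j, ] - CA[i, ])
    dir_l <- as.numeric(t(frames[[i]]$basis) %*% dir_g)
    q <- frame_quaternion(frames[[i]], frames[[j]])
    efeat[e, ] <- c(rbf_encode(D[i, j], rbf_centers, rbf_width),
                    dir_l, q,
                    relpos_onehot(keep[j] - keep[i], relpos_clip))
  }
  g <- list(nodes = nodes, nbr = nbr, efeat = efeat,
            idx_src = idx_src, idx_nbr = idx_nbr,
            k = k_eff, aa = s$aa[keep], kept = keep, dropped = dropped,
            d_node = ncol(nodes), d_edge = d_edge)
  class(g) <- "residue_graph"
  g
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes (%d features), k = %d, %d edge features\n",
              nrow(x$nodes), x$d_node, x$k, x$d_edge))
  invisible(x)
}
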