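# Dataset construction: the 6 A binding-label rule, Shrake-Rupley SASA and
# buried surface area, the four peptide-complex filters, identity/
# clustering/splitting, and fragment scanning.

test_that("binding annotation respects the 6 A threshold boundary", {
  # plant a lone partner atom at a controlled gap from the receptor's
  # nearest atom along an outward direction, so the gap IS the minimum
  # heavy-atom distance
  mk <- function(gap) {
    h <- make_helix(33, seed = 1)
    at <- pepsite:::structure_atoms(h)
    pfar <- colMeans(at$xyz) + c(100, 0, 0)
    d <- sqrt(rowSums(sweep(at$xyz, 2, pfar)^2))
    i0 <- which.min(d)
    u <- pfar - at$xyz[i0, ]; u <- u / sqrt(sum(u^2))
    target <- at$xyz[i0, ] + gap * u
    stopifnot(abs(min(sqrt(rowSums(sweep(at$xyz, 2, target)^2))) - gap) < 1e-9)
    probe <- pepsite:::transform_structure(make_helix(2, seed = 2, chain_id = "B"),
                                           diag(3), c(500, 0, 0))
    probe$sidechain[[1]] <- list(xyz = matrix(target, 1, 3), elem = "C")
    list(rec = h, probe = probe, res = at$residue[i0])
  }
  near <- mk(5.9)
  expect_true(annotate_binding_residues(near$rec, near$probe)[near$res])
  far <- mk(6.1)
  expect_false(any(annotate_binding_residues(far$rec, far$probe)))
})

test_that("binding annotation equals the brute-force all-pairs oracle", {
  for (s in c(42, 43)) {
    rec <- fx_binder(s)
    expect_identical(annotate_binding_residues(rec$receptor, rec$partner),
                     oracle_annotate(rec$receptor, rec$partner))
  }
  # empty partner -> all false
  empty <- make_helix(2, seed = 1, chain_id = "B")
  empty$N[] <- NA; empty$CA[] <- NA; empty$C[] <- NA; empty$O[] <- NA
  empty$sidechain <- vector("list", 2L)
  expect_false(any(annotate_binding_residues(fx_binder(42)$receptor, empty)))
})

test_that("contact labels are symmetric between the two chains", {
  rec <- fx_binder(44)
  a_to_b <- annotate_binding_residues(rec$receptor, rec$partner)
  b_to_a <- annotate_binding_residues(rec$partner, rec$receptor)
  # the contact relation is symmetric: each side has contacts iff the other does
  expect_identical(any(a_to_b), any(b_to_a))
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  for (el in c("C", "O", "S")) {
    r <- pepsite:::VDW_RADII[[el]]
    a <- shrake_rupley_sasa(matrix(0, 1, 3), el)
    expect_lt(abs(a - 4 * pi * (r + 1.4)^2) / (4 * pi * (r + 1.4)^2), 0.02)
  }
  expect_warning(shrake_rupley_sasa(matrix(0, 1, 3), "ZZ"), "default radius")
})

test_that("SASA is additive for far-apart atoms and matches a high-density oracle", {
  iso <- shrake_rupley_sasa(matrix(0, 1, 3), "C")
  two_far <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c("C", "C"))
  expect_equal(sum(two_far), 2 * iso, tolerance = 1e-9)
  # overlapping pair against a refined 4000-point evaluation
  xyz <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  a960 <- sum(shrake_rupley_sasa(xyz, c("C", "N")))
  a4000 <- sum(shrake_rupley_sasa(xyz, c("C", "N"), n_points = 4000L))
  expect_lt(abs(a960 - a4000) / a4000, 0.03)
})

test_that("buried surface area: separated chains ~0, symmetric, binder > 400", {
  a <- make_helix(8, seed = 1)
  b <- pepsite:::transform_structure(make_helix(6, seed = 2, chain_id = "B"),
                                     diag(3), c(100, 0, 0))
  expect_lt(abs(buried_surface_area(a, b)), 5)
  rec <- fx_binder(42, verify_bsa = TRUE)
  expect_gt(rec$bsa, 400)
  b1 <- buried_surface_area(rec$receptor, rec$partner)
  b2 <- buried_surface_area(rec$partner, rec$receptor)
  expect_identical(b1, b2)
})

test_that("peptide-complex filter removes exactly the planted violations", {
  good <- function(seed) {
    r <- fx_binder(seed)
    r$bsa <- 450; r$resolution <- 2.0
    r
  }
  records <- lapply(c(1, 2, 3, 4, 5, 6), good)
  for (i in seq_along(records)) records[[i]]$id <- paste0("ok", i)
  # plant one violation of each rule
  v1 <- good(7); v1$resolution <- 3.1; v1$id <- "bad_resolution"
  v2 <- good(8); v2$receptor$aa <- v2$receptor$aa[1:20]
  v2$receptor$N <- v2$receptor$N[1:20, ]; v2$receptor$CA <- v2$receptor$CA[1:20, ]
  v2$receptor$C <- v2$receptor$C[1:20, ]; v2$receptor$O <- v2$receptor$O[1:20, ]
  v2$receptor$sidechain <- v2$receptor$sidechain[1:20]
  v2$receptor$resno <- v2$receptor$resno[1:20]; v2$id <- "bad_receptor_len"
  v3 <- good(9)
  long <- make_helix(26, seed = 9, chain_id = "B")
  v3$partner <- long; v3$id <- "bad_partner_len"
  v4 <- good(10); v4$bsa <- 350; v4$id <- "bad_bsa"
  out <- filter_peptide_complexes(c(records, list(v1, v2, v3, v4)))
  expect_identical(length(out$kept), 6L)
  expect_setequal(out$log$id, c("bad_resolution", "bad_receptor_len",
                                "bad_partner_len", "bad_bsa"))
  # boundaries: resolution exactly 2.5 kept; partner length 26 excluded;
  # missing resolution excluded with a logged reason
  b1 <- good(11); b1$resolution <- 2.5
  expect_identical(length(filter_peptide_complexes(list(b1))$kept), 1L)
  b2 <- good(12); b2$resolution <- NA_real_
  res <- filter_peptide_complexes(list(b2))
  expect_identical(length(res$kept), 0L)
  expect_match(res$log$reason, "missing resolution")
})

test_that("filter outcome is independent of record order", {
  recs <- lapply(1:4, function(s) {
    r <- fx_binder(s); r$bsa <- 450; r$resolution <- 2.0; r$id <- paste0("r", s); r
  })
  recs[[2]]$bsa <- 100
  recs[[3]]$resolution <- 4
  ids1 <- vapply(filter_peptide_complexes(recs)$kept, `[[`, character(1), "id")
  ids2 <- vapply(filter_peptide_complexes(rev(recs))$kept, `[[`, character(1), "id")
  expect_setequal(ids1, ids2)
})

test_that("pairwise identity and coverage follow the alignment definitions", {
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIK"),
               c(identity = 100, coverage = 100))
  expect_identical(unname(pairwise_identity("AAAA", "TTTT")["identity"]), 0)
  expect_equal(unname(pairwise_identity("ACDEFGHIK", "ACDEFGHIV")["identity"]),
               100 * 8 / 9, tolerance = 1e-9)
})

test_that("greedy clustering recovers planted families exactly", {
  expect_identical(greedy_cluster(rep("ACDEFGH", 4))$cluster, rep(1L, 4))
  fams <- lapply(1:3, function(i) make_sequence_family(4, 90, seed = i * 7))
  seqs <- unlist(fams)
  truth <- rep(1:3, each = 4)
  cl <- greedy_cluster(seqs, threshold = 30)
  expect_identical(length(unique(cl$cluster)), 3L)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1.0)
  # unreachable threshold -> singletons
  cl101 <- greedy_cluster(seqs, threshold = 101)
  expect_identical(length(unique(cl101$cluster)), length(seqs))
})

test_that("cluster splitting is leak-free, seeded and sized 90/10", {
  cl <- rep(1:10, times = sample(1:4, 10, replace = TRUE))
  sp <- split_clusters(cl, seed = 3)
  expect_identical(length(unique(cl[sp$train])), 9L)
  expect_identical(length(unique(cl[sp$val])), 1L)
  expect_length(intersect(cl[sp$train], cl[sp$val]), 0L)
  sp2 <- split_clusters(cl, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_clusters(rep(1L, 5)), "at least 2 clusters")
})

test_that("test-set deduplication removes redundancy then keeps centroids", {
  train <- make_sequence_family(2, 100, seed = 1)[1]
  # identical to training -> removed; unrelated survivors at 95% identity
  # collapse to one centroid
  survivors <- make_sequence_family(2, 95, seed = 99)
  unrelated <- make_sequence_family(1, 100, seed = 500)
  test <- c(train, survivors, unrelated)
  kept <- deduplicate_test(test, train)
  expect_false(1L %in% kept)
  expect_identical(sum(kept %in% c(2L, 3L)), 1L)
  expect_true(4L %in% kept)
  # empty overlap: everything survives stage one
  kept2 <- deduplicate_test(unrelated, train)
  expect_identical(kept2, 1L)
})

test_that("fragment scan scores windows by contacts and finds the planted patch", {
  rec50 <- make_helix(55, seed = 5)
  far <- pepsite:::transform_structure(make_helix(25, seed = 6, chain_id = "B"),
                                       diag(3), c(100, 100, 0))
  fr <- scan_fragments(rec50, far)
  expect_true(all(fr$score == 0))
  expect_identical(nrow(fr), 231L)   # sum over l = 5..25 of (25 - l + 1)
  # planted contact: a binder complex, receptor grown to >= 50 residues by
  # keeping its peptide in place
  rec <- fx_binder(45)
  big <- make_helix(55, seed = 45)
  fr2 <- scan_fragments(big, rec$partner,
                        min_len = 5L, max_len = length(rec$partner$aa))
  patch_res <- which(annotate_binding_residues(rec$partner, big, cutoff = 5))
  if (length(patch_res) > 0) {
    best8 <- fr2[fr2$len == 8 & fr2$best, ]
    covered <- seq(best8$start, best8$start + 7)
    expect_true(any(patch_res %in% covered))
  }
  expect_error(scan_fragments(make_helix(20, seed = 1), far), "at least 50")
})

test_that("fragment filter boundary at mean + 1 SD is inclusive", {
  frags <- data.frame(score = c(-10, 0.99, 1.01, -5, -8),
                      bsa = c(500, 500, 500, 300, 450))
  kept <- filter_fragments(frags, ref_mean = 0, ref_sd = 1)
  # score 0.99 kept, 1.01 removed, low-BSA removed
  expect_identical(kept$score, c(-10, 0.99, -8))
  planted <- data.frame(score = c(-3, -2, -1), bsa = c(500, 420, 410))
  expect_identical(nrow(filter_fragments(planted, 0, 1)), 3L)
})
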