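# The protein-structure container used throughout the package: an ordered
# chain of residues with backbone (N, CA, C, O) and side-chain heavy-atom
# coordinates. Kept deliberately light-weight (plain matrices) because the
# featurizer and the SASA code iterate over it heavily.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA1, "X")   # 21st class: UNK

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR", X = "UNK")

#' Construct a protein structure object
#'
#' @param chain_id single character chain identifier.
#' @param aa character vector of one-letter residue codes (`X` = unknown).
#' @param N,CA,C,O L x 3 backbone coordinate matrices (Angstrom). `O` may
#'   contain `NA` rows; `N`, `CA`, `C` must be finite for a residue to be
#'   admitted to the residue graph.
#' @param sidechain list (length L) of side-chain heavy-atom blocks, each a
#'   list with `xyz` (m x 3 matrix) and `elem` (length-m element symbols);
#'   `NULL` entries mean no side-chain heavy atoms (glycine).
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @param resno optional author residue numbers (defaults to `1:L`).
#' @return an object of class `protein_structure`.
#' @export
protein_structure <- function(chain_id, aa, N, CA, C, O = NULL,
                              sidechain = NULL, resolution = NA_real_,
                              resno = NULL) {
  L <- length(aa)
  stopifnot(L >= 1L, nrow(CA) == L, nrow(N) == L, nrow(C) == L)
  if (is.null(O)) O <- matrix(NA_real_, L, 3L)
  if (is.null(sidechain)) sidechain <- vector("list", L)
  if (is.null(resno)) resno <- seq_len(L)
  if (any(diff(resno) <= 0)) stop("residue indices must be strictly increasing")
  aa <- toupper(aa)
  aa[!aa %in% AA_ALPHABET] <- "X"
  s <- list(chain_id = chain_id, aa = aa, N = N, CA = CA, C = C, O = O,
            sidechain = sidechain, resolution = resolution, resno = resno)
  class(s) <- "protein_structure"
  s
}

#' @export
length.protein_structure <- function(x) length(x$aa)

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> chain %s, %d residues, resolution %s\n",
              x$chain_id, length(x$aa),
              ifelse(is.na(x$resolution), "NA", format(x$resolution))))
  invisible(x)
}

#' One-letter sequence of a structure
#' @param s a `protein_structure`.
#' @return character scalar.
#' @export
structure_sequence <- function(s) paste(s$aa, collapse = "")

# All heavy atoms of a structure as a flat table.
# Returns list(xyz = n x 3, elem = character, residue = integer index).
structure_atoms <- function(s) {
  L <- length(s$aa)
  xyz <- list(); elem <- list(); res <- list()
  bb_names <- c("N", "C", "C", "O")   # elements of N, CA, C, O
  for (i in seq_len(L)) {
    bb <- rbind(s$N[i, ], s$CA[i, ], s$C[i, ], s$O[i, ])
    keep <- stats::complete.cases(bb)
    xyz[[length(xyz) + 1L]] <- bb[keep, , drop = FALSE]
    elem[[length(elem) + 1L]] <- bb_names[keep]
    res[[length(res) + 1L]] <- rep.int(i, sum(keep))
    sc <- s$sidechain[[i]]
    if (!is.null(sc) && nrow(sc$xyz) > 0L) {
      xyz[[length(xyz) + 1L]] <- sc$xyz
      elem[[length(elem) + 1L]] <- sc$elem
      res[[length(res) + 1L]] <- rep.int(i, nrow(sc$xyz))
    }
  }
  list(xyz = do.call(rbind, xyz), elem = unlist(elem),
       residue = unlist(res))
}

# Apply a rigid motion to every atom of a structure.
transform_structure <- function(s, R, t = c(0, 0, 0)) {
  s$N <- apply_rigid(s$N, R, t)
  s$CA <- apply_rigid(s$CA, R, t)
  s$C <- apply_rigid(s$C, R, t)
  ok <- stats::complete.cases(s$O)
  s$O[ok, ] <- apply_rigid(s$O[ok, , drop = FALSE], R, t)
  s$sidechain <- lapply(s$sidechain, function(sc) {
    if (is.null(sc) || nrow(sc$xyz) == 0L) return(sc)
    sc$xyz <- apply_rigid(sc$xyz, R, t)
    sc
  })
  s
}

#' Read a protein chain from a PDB or mmCIF file
#'
#' Uses the first model of multi-model files; for alternate locations the
#' highest-occupancy conformer is kept (ties resolved in favour of altloc
#' 'A'). Waters and hetero ligands are ignored; hydrogens are dropped.
#' Non-canonical residues map to the unknown class `X`.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain chain identifier; default: first protein chain in the file.
#' @param resolution optional resolution override (Angstrom); by default the
#'   value is not parsed from the header and is `NA`.
#' @return a [protein_structure()].
#' @export
read_structure <- function(path, chain = NULL, resolution = NA_real_) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  at <- if (ext == "cif") {
    read_mmcif_atoms(path)
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)$atom
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, " in ", path)
  # altloc: keep highest occupancy, tie -> 'A' (blank sorts before letters);
  # residue order is preserved (numeric resno, then insertion code)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$insert[is.na(at$insert)] <- ""
  at <- at[order(at$resno, at$insert, at$elety, -at$o, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]
  at <- at[order(at$resno, at$insert), , drop = FALSE]
  elem <- at$elesy
  if (all(is.na(elem) | elem == "")) elem <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  at <- at[toupper(elem) != "H", , drop = FALSE]
  rid <- paste(at$resno, at$insert, sep = "|")
  ures <- unique(rid)
  L <- length(ures)
  aa <- character(L)
  Nm <- CAm <- Cm <- Om <- matrix(NA_real_, L, 3L)
  sc <- vector("list", L)
  resno <- integer(L)
  for (i in seq_len(L)) {
    sub <- at[rid == ures[i], , drop = FALSE]
    resno[i] <- sub$resno[1L]
    a1 <- suppressWarnings(bio3d::aa321(sub$resid[1L]))
    aa[i] <- if (is.na(a1) || !a1 %in% AA1) "X" else a1
    getxyz <- function(name) {
      j <- which(sub$elety == name)
      if (length(j)) as.numeric(sub[j[1L], c("x", "y", "z")]) else rep(NA_real_, 3L)
    }
    Nm[i, ] <- getxyz("N"); CAm[i, ] <- getxyz("CA")
    Cm[i, ] <- getxyz("C"); Om[i, ] <- getxyz("O")
    side <- sub[!sub$elety %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
    if (nrow(side)) {
      el <- side$elesy
      if (all(is.na(el) | el == "")) el <- substr(gsub("[0-9]", "", side$elety), 1L, 1L)
      sc[[i]] <- list(xyz = as.matrix(side[, c("x", "y", "z")]),
                      elem = toupper(el))
    }
  }
  # enforce strictly increasing residue numbering (insertion codes collapse
  # onto sequential indices)
  if (any(diff(resno) <= 0)) resno <- seq_len(L)
  protein_structure(chain, aa, Nm, CAm, Cm, Om, sc,
                    resolution = resolution, resno = resno)
}

# Minimal mmCIF _atom_site reader. Parses the atom_site loop into the same
# column layout as bio3d's PDB atom table so both formats share one code
# path downstream. Handles the standard whitespace-delimited rows written
# by gemmi/PDB software; first model only.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  start <- max(tag_idx) + 1L
  end <- start
  while (end <= length(lines)) {
    l <- trimws(lines[end])
    if (l == "" || startsWith(l, "#") || startsWith(l, "_") ||
        startsWith(l, "loop_")) break
    end <- end + 1L
  }
  rows <- strsplit(trimws(lines[start:(end - 1L)]), "[[:space:]]+")
  bad <- vapply(rows, length, integer(1L)) != length(tags)
  rows <- rows[!bad]
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  get <- function(name, alt = NULL, default = NA_character_) {
    if (name %in% tags) return(m[, name])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(default, nrow(m))
  }
  clean <- function(x) { x[x %in% c(".", "?")] <- ""; x }
  at <- data.frame(
    type = get("group_PDB", default = "ATOM"),
    elety = clean(get("auth_atom_id", "label_atom_id")),
    resid = clean(get("auth_comp_id", "label_comp_id")),
    chain = clean(get("auth_asym_id", "label_asym_id")),
    resno = suppressWarnings(as.integer(clean(get("auth_seq_id", "label_seq_id")))),
    insert = clean(get("pdbx_PDB_ins_code")),
    alt = clean(get("label_alt_id")),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    o = suppressWarnings(as.numeric(clean(get("occupancy")))),
    elesy = clean(get("type_symbol")),
    model = suppressWarnings(as.integer(clean(get("pdbx_PDB_model_num")))),
    stringsAsFactors = FALSE)
  at$elety <- gsub('"', "", at$elety)
  if (any(!is.na(at$model))) at <- at[at$model == at$model[!is.na(at$model)][1L] |
                                        is.na(at$model), , drop = FALSE]
  at
}

#' Write a structure (or several chains) as a PDB file
#'
#' Emits standard fixed-column ATOM records (3-decimal coordinates,
#' occupancy 1.00, B-factor 0.00) with one TER per chain.
#'
#' @param structures a `protein_structure` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  serial <- 0L
  fmt_name <- function(x) if (nchar(x) < 4L) sprintf(" %-3s", x) else x
  for (s in structures) {
    L <- length(s$aa)
    for (i in seq_len(L)) {
      res3 <- AA3[[s$aa[i]]]
      emit <- function(name, xyz, el) {
        if (anyNA(xyz)) return(invisible())
        serial <<- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, fmt_name(name), res3, s$chain_id, s$resno[i],
          xyz[1L], xyz[2L], xyz[3L], 1, 0, el), con)
      }
      emit("N", s$N[i, ], "N"); emit("CA", s$CA[i, ], "C")
      emit("C", s$C[i, ], "C"); emit("O", s$O[i, ], "O")
      scb <- s$sidechain[[i]]
      if (!is.null(scb) && nrow(scb$xyz) > 0L) {
        nm <- rownames(scb$xyz)
        if (is.null(nm)) nm <- paste0(scb$elem, "B")   # CB-like naming
        for (j in seq_len(nrow(scb$xyz)))
          emit(nm[j], scb$xyz[j, ], scb$elem[j])
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
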