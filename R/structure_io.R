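# PDB ingestion into the C-beta-centered chain representation, virtual C-beta
# construction, training-set selection filters, and sequence-identity culling.

#' Construct a ChainModel
#'
#' A `ChainModel` is one chain reduced to the C-beta representation: per
#' residue a type code (20-letter alphabet), a C-alpha coordinate and a
#' C-beta coordinate (virtual for glycine).
#'
#' @param chain_id Chain identifier (string).
#' @param types Character vector of three-letter residue types (see
#'   [AA_THREE]).
#' @param ca,cb Numeric n x 3 coordinate matrices (angstroms).
#' @param metadata List; recognised fields: `resolution` (A), `r_value`,
#'   `experimental_method`, `author_resseq` (integer vector).
#' @param flags List of completeness flags filled by [read_chain()]:
#'   `n_incomplete`, `n_nonstandard`, `missing_internal`, `has_ions`.
#' @return Object of class `ChainModel`.
#' @export
chain_model <- function(chain_id, types, ca, cb, metadata = list(), flags = list()) {
  ca <- as.matrix(ca); cb <- as.matrix(cb)
  storage.mode(ca) <- "double"; storage.mode(cb) <- "double"
  n <- length(types)
  stopifnot(
    is.character(types),
    nrow(ca) == n, ncol(ca) == 3,
    nrow(cb) == n, ncol(cb) == 3
  )
  if (!all(types %in% AA_THREE)) {
    stop("nonstandard residue type in ChainModel: ",
         paste(unique(setdiff(types, AA_THREE)), collapse = ", "))
  }
  if (n > 0) {
    if (!all(is.finite(ca)) || !all(is.finite(cb))) {
      stop("non-finite coordinates in ChainModel")
    }
    dcb <- sqrt(rowSums((cb - ca)^2))
    if (any(dcb <= 0.5 | dcb >= 3.0)) {
      stop("Ca-Cb distance outside (0.5, 3.0) A for residue(s) ",
           paste(which(dcb <= 0.5 | dcb >= 3.0), collapse = ", "))
    }
  }
  md <- list(
    resolution = NA_real_, r_value = NA_real_,
    experimental_method = NA_character_, length = n,
    author_resseq = seq_len(n)
  )
  md[names(metadata)] <- metadata
  md$length <- n
  fl <- list(n_incomplete = 0L, n_nonstandard = 0L,
             missing_internal = FALSE, has_ions = FALSE, virtual_cb = integer(0))
  fl[names(flags)] <- flags
  structure(
    list(chain_id = chain_id, types = types, ca = ca, cb = cb,
         metadata = md, flags = fl),
    class = "ChainModel"
  )
}

#' @export
length.ChainModel <- function(x) length(x$types)

#' @export
print.ChainModel <- function(x, ...) {
  cat(sprintf(
    "ChainModel %s: %d residues (%s...)\n", x$chain_id, length(x),
    paste(utils::head(x$types, 5), collapse = "-")
  ))
  invisible(x)
}

#' One-letter sequence of a ChainModel
#' @param chain A [chain_model()].
#' @return Single string.
#' @export
chain_sequence <- function(chain) {
  paste(AA_ONE[chain$types], collapse = "")
}

#' Build a virtual C-beta atom from backbone N, CA, C
#'
#' Places C-beta at ideal tetrahedral geometry in the N-CA-C frame with
#' L-amino-acid chirality: bond CA-CB = 1.53 A, angle N-CA-CB = 110.5 deg,
#' dihedral C-N-CA-CB = -122.8 deg (internal-coordinate / NeRF placement).
#'
#' @param n,ca,c Numeric 3-vectors (A); must be finite and non-collinear.
#' @return Numeric 3-vector: the virtual C-beta position.
#' @export
build_virtual_cb <- function(n, ca, c) {
  stopifnot(length(n) == 3, length(ca) == 3, length(c) == 3)
  if (!all(is.finite(c(n, ca, c)))) stop("degenerate backbone geometry")
  # NeRF: place D given chain a-b-c with bond |c-D|, angle b-c-D, dihedral a-b-c-D
  a <- c; b <- n; cc <- ca
  L <- 1.53
  ang <- 110.5 * pi / 180
  tor <- 122.8 * pi / 180
  bc <- cc - b
  ab <- b - a
  nbc <- sqrt(sum(bc^2))
  if (nbc < 1e-6 || sqrt(sum(ab^2)) < 1e-6) stop("degenerate backbone geometry")
  bc <- bc / nbc
  nrm <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-6) stop("degenerate backbone geometry")
  nrm <- nrm / nn
  m2 <- c(
    nrm[2] * bc[3] - nrm[3] * bc[2],
    nrm[3] * bc[1] - nrm[1] * bc[3],
    nrm[1] * bc[2] - nrm[2] * bc[1]
  )
  d2 <- c(-L * cos(ang), L * sin(ang) * cos(tor), -L * sin(ang) * sin(tor))
  cc + d2[1] * bc + d2[2] * m2 + d2[3] * nrm
}

# ---------------------------------------------------------------------------
# PDB parsing

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

pdb_lines <- function(pdb_source) {
  if (length(pdb_source) == 1 && !grepl("\n", pdb_source) && file.exists(pdb_source)) {
    readLines(pdb_source, warn = FALSE)
  } else {
    unlist(strsplit(as.character(pdb_source), "\n", fixed = TRUE), use.names = FALSE)
  }
}

parse_pdb_metadata <- function(lines) {
  method <- NA_character_
  resolution <- NA_real_
  r_value <- NA_real_
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) method <- trimws(substr(ex[1], 11, nchar(ex[1])))
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*(?= +ANGSTROM)", rl[1], perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }
  rv <- grep("^REMARK   3.*R VALUE.*\\(WORKING SET\\)", lines, value = TRUE)
  if (length(rv)) {
    m <- regmatches(rv[1], regexpr(":\\s*([0-9.]+)", rv[1]))
    if (length(m)) r_value <- as.numeric(sub(":\\s*", "", m))
  }
  list(experimental_method = method, resolution = resolution, r_value = r_value)
}

parse_atom_records <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  ln <- lines[sel]
  if (!length(ln)) {
    return(data.frame(
      record = character(0), name = character(0), altloc = character(0),
      resname = character(0), chain = character(0), resseq = integer(0),
      icode = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
      occ = numeric(0)
    ))
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    record = trimws(substr(ln, 1, 6)),
    name = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resseq = suppressWarnings(as.integer(substr(ln, 23, 26))),
    icode = substr(ln, 27, 27),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    occ = occ,
    stringsAsFactors = FALSE
  )
}

detect_ions <- function(atoms) {
  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  if (!nrow(het)) return(FALSE)
  key <- paste(het$chain, het$resseq, het$icode, het$resname)
  sizes <- table(key)
  single <- names(sizes)[sizes == 1]
  if (!length(single)) return(FALSE)
  resn <- vapply(strsplit(single, " ", fixed = TRUE), function(p) p[length(p)], "")
  any(!(resn %in% WATER_RESNAMES))
}

# Highest-occupancy altloc per atom name; tie -> first in file.
resolve_altlocs <- function(res_atoms) {
  if (nrow(res_atoms) <= 1) return(res_atoms)
  keep <- unlist(lapply(split(seq_len(nrow(res_atoms)), res_atoms$name), function(ix) {
    ix[which.max(res_atoms$occ[ix])]
  }), use.names = FALSE)
  res_atoms[sort(keep), , drop = FALSE]
}

#' Chain identifiers present in a PDB source
#' @param pdb_source Path to a PDB file or PDB-format text.
#' @return Character vector of chain ids with ATOM records.
#' @export
pdb_chain_ids <- function(pdb_source) {
  atoms <- parse_atom_records(pdb_lines(pdb_source))
  unique(atoms$chain[atoms$record == "ATOM"])
}

#' Read one chain of a PDB file into the C-beta representation
#'
#' Keeps one residue per standard amino acid with a usable C-beta center:
#' the CB atom when present, otherwise a virtual C-beta built from N, CA, C
#' via [build_virtual_cb()]. Altlocs resolve to the highest occupancy (tie:
#' first in file). Residues that are nonstandard, or that lack the atoms
#' needed for a C-beta center, are excluded and counted in the completeness
#' flags, which feed [passes_training_filters()]:
#' \itemize{
#'   \item `n_incomplete`: residues missing CA, or missing CB on a non-glycine
#'     residue, or missing CB with no N/C to build one;
#'   \item `n_nonstandard`: residues outside the 20-letter alphabet;
#'   \item `missing_internal`: gaps in author residue numbering strictly
#'     between the first and last observed residue;
#'   \item `has_ions`: any monoatomic HETATM species (waters exempt).
#' }
#'
#' @param pdb_source Path to a PDB file, or PDB-format text.
#' @param chain_id Chain identifier (single character).
#' @return A [chain_model()].
#' @export
read_chain <- function(pdb_source, chain_id) {
  if (length(chain_id) != 1 || is.na(chain_id)) stop("chain not found: ", chain_id)
  lines <- pdb_lines(pdb_source)
  md <- parse_pdb_metadata(lines)
  atoms <- parse_atom_records(lines)
  has_ions <- detect_ions(atoms)
  ch <- atoms[atoms$record == "ATOM" & atoms$chain == chain_id, , drop = FALSE]
  if (!nrow(ch)) stop("chain not found: ", chain_id)

  key <- paste(ch$resseq, ch$icode, sep = "|")
  ukey <- unique(key)
  n_res <- length(ukey)
  types <- character(n_res); ca <- matrix(NA_real_, n_res, 3)
  cb <- matrix(NA_real_, n_res, 3)
  keep <- logical(n_res)
  n_incomplete <- 0L; n_nonstandard <- 0L
  virtual_cb <- integer(0)
  resseq_all <- integer(n_res)

  for (r in seq_along(ukey)) {
    res <- resolve_altlocs(ch[key == ukey[r], , drop = FALSE])
    resseq_all[r] <- res$resseq[1]
    resn <- res$resname[1]
    if (!(resn %in% AA_THREE)) {
      n_nonstandard <- n_nonstandard + 1L
      next
    }
    getxyz <- function(nm) {
      i <- match(nm, res$name)
      if (is.na(i)) NULL else c(res$x[i], res$y[i], res$z[i])
    }
    p_ca <- getxyz("CA"); p_cb <- getxyz("CB")
    p_n <- getxyz("N"); p_c <- getxyz("C")
    if (is.null(p_ca)) {
      n_incomplete <- n_incomplete + 1L
      next
    }
    if (is.null(p_cb)) {
      if (is.null(p_n) || is.null(p_c)) {
        n_incomplete <- n_incomplete + 1L
        next
      }
      p_cb <- build_virtual_cb(p_n, p_ca, p_c)
      virtual_cb <- c(virtual_cb, sum(keep) + 1L)
      if (resn != "GLY") n_incomplete <- n_incomplete + 1L
    }
    keep[r] <- TRUE
    i <- sum(keep)
    types[i] <- resn
    ca[i, ] <- p_ca
    cb[i, ] <- p_cb
  }

  m <- sum(keep)
  if (m == 0) stop("chain ", chain_id, " has no usable residues")
  gaps <- diff(sort(unique(resseq_all)))
  missing_internal <- any(gaps > 1)

  chain_model(
    chain_id = chain_id,
    types = types[seq_len(m)],
    ca = ca[seq_len(m), , drop = FALSE],
    cb = cb[seq_len(m), , drop = FALSE],
    metadata = c(md, list(author_resseq = resseq_all[keep])),
    flags = list(
      n_incomplete = n_incomplete, n_nonstandard = n_nonstandard,
      missing_internal = missing_internal, has_ions = has_ions,
      virtual_cb = virtual_cb
    )
  )
}

#' Write a ChainModel as PDB-format text
#'
#' Emits CA and CB ATOM records per residue (the package's representation),
#' plus EXPDTA / REMARK 2 / REMARK 3 headers carrying the metadata, so that
#' [read_chain()] round-trips coordinates to PDB precision (1e-3 A) and type
#' codes exactly.
#'
#' @param chain A [chain_model()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of PDB lines, invisibly when `path` is given.
#' @export
write_chain_pdb <- function(chain, path = NULL) {
  md <- chain$metadata
  out <- character(0)
  if (!is.na(md$experimental_method)) {
    out <- c(out, sprintf("EXPDTA    %s", md$experimental_method))
  }
  if (!is.na(md$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.", md$resolution))
  }
  if (!is.na(md$r_value)) {
    out <- c(out, sprintf("REMARK   3   R VALUE            (WORKING SET) : %5.3f", md$r_value))
  }
  n <- length(chain)
  resseq <- md$author_resseq
  if (length(resseq) != n) resseq <- seq_len(n)
  serial <- 1L
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  cid <- substr(chain$chain_id, 1, 1)
  for (i in seq_len(n)) {
    out <- c(out,
      sprintf(fmt, serial, "CA", chain$types[i], cid, resseq[i],
              chain$ca[i, 1], chain$ca[i, 2], chain$ca[i, 3], 1, 0),
      sprintf(fmt, serial + 1L, "CB", chain$types[i], cid, resseq[i],
              chain$cb[i, 1], chain$cb[i, 2], chain$cb[i, 3], 1, 0)
    )
    serial <- serial + 2L
  }
  out <- c(out, "END")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# ---------------------------------------------------------------------------
# Training-set selection filters

#' Filter report
#' @param reasons Character vector of failed-criterion labels.
#' @return Object of class `FilterReport`: `passed` is `TRUE` iff `reasons`
#'   is empty.
#' @export
filter_report <- function(reasons = character(0)) {
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  if (x$passed) cat("FilterReport: passed\n")
  else cat("FilterReport: failed (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Training-set selection filters for X-ray chains
#'
#' A chain passes iff it is an X-ray structure with crystallographic
#' resolution strictly better (smaller) than `resolution_max`, R-value
#' strictly better than `r_value_max`, at least `min_length` residues, no
#' incomplete/modified/nonstandard residues, missing residues confined to the
#' termini, and no co-crystallized ions.
#'
#' @param chain A [chain_model()] with populated metadata and flags.
#' @param resolution_max Resolution threshold (A), strict. Default 2.1.
#' @param r_value_max R-value threshold, strict. Default 0.2.
#' @param min_length Minimum residue count. Default 50.
#' @return A [filter_report()].
#' @export
passes_training_filters <- function(chain, resolution_max = 2.1,
                                    r_value_max = 0.2, min_length = 50L) {
  md <- chain$metadata
  if (is.na(md$experimental_method) || is.na(md$resolution) || is.na(md$r_value)) {
    stop("metadata incomplete")
  }
  fl <- chain$flags
  reasons <- character(0)
  if (!grepl("X-RAY", toupper(md$experimental_method), fixed = TRUE)) {
    reasons <- c(reasons, "not_xray")
  }
  if (!(md$resolution < resolution_max)) reasons <- c(reasons, "resolution")
  if (!(md$r_value < r_value_max)) reasons <- c(reasons, "r_value")
  if (length(chain) < min_length) reasons <- c(reasons, "length")
  if (fl$n_incomplete > 0L) reasons <- c(reasons, "incomplete_residues")
  if (fl$n_nonstandard > 0L) reasons <- c(reasons, "nonstandard_residues")
  if (isTRUE(fl$missing_internal)) reasons <- c(reasons, "internal_missing_residues")
  if (isTRUE(fl$has_ions)) reasons <- c(reasons, "ions")
  filter_report(reasons)
}

#' Write filter reports as tab-separated text
#' @param chains List of [chain_model()]s.
#' @param reports List of [filter_report()]s, parallel to `chains`.
#' @param path Output path.
#' @export
write_filter_reports <- function(chains, reports, path) {
  df <- data.frame(
    chain_id = vapply(chains, function(ch) ch$chain_id, ""),
    passed = vapply(reports, function(r) r$passed, TRUE),
    reasons = vapply(reports, function(r) paste(r$reasons, collapse = ","), "")
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# ---------------------------------------------------------------------------
# Sequence-identity culling

#' Global-alignment sequence identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5)
#' with identity defined as identical aligned positions divided by the length
#' of the shorter sequence.
#'
#' @param s1,s2 One-letter amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(s1, s2) {
  if (identical(s1, s2)) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::pid(aln, type = "PID3") / 100
}

#' Greedy sequence-identity culling
#'
#' Processes chains best resolution first (ties and missing resolutions keep
#' input order) and greedily retains a chain iff its global-alignment
#' identity to every already-retained chain is strictly below `threshold`.
#' Deterministic given the input.
#'
#' @param chains List of [chain_model()]s.
#' @param threshold Identity threshold in (0, 1]. Default 0.4.
#' @return The retained subset, in original input order.
#' @export
cull_by_identity <- function(chains, threshold = 0.4) {
  stopifnot(length(chains) >= 1, threshold > 0, threshold <= 1)
  res <- vapply(chains, function(ch) {
    r <- ch$metadata$resolution
    if (is.null(r) || is.na(r)) Inf else r
  }, 0)
  ord <- order(res)  # stable: ties keep input order
  seqs <- vapply(chains, chain_sequence, "")
  kept <- integer(0)
  for (i in ord) {
    ok <- all(vapply(kept, function(k) seq_identity(seqs[i], seqs[k]) < threshold, TRUE))
    if (ok) kept <- c(kept, i)
  }
  chains[sort(kept)]
}
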