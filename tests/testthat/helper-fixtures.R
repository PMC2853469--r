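# Shared fixture builders and independent brute-force oracles.

# --- PDB text builders ------------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resseq, xyz,
                          occ = 1, record = "ATOM  ", altloc = " ") {
  sprintf("%s%5d  %-3s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, altloc, resname, chain, resseq,
          xyz[1], xyz[2], xyz[3], occ, 0)
}

# Ideal residue backbone at a given C-alpha offset: local frame coordinates
# from the alanine rigid group, translated.
ideal_residue_atoms <- function(resname, chain, resseq, offset, serial,
                                with_cb = TRUE) {
  local <- list(
    N = c(-0.525, 1.363, 0), CA = c(0, 0, 0), C = c(1.526, 0, 0),
    CB = c(-0.529, -0.774, -1.205)
  )
  nms <- c("N", "CA", "C", if (with_cb) "CB")
  lines <- character(0)
  for (k in seq_along(nms)) {
    lines <- c(lines, pdb_atom_line(serial + k - 1L, nms[k], resname, chain,
                                    resseq, local[[nms[k]]] + offset))
  }
  lines
}

# Minimal parseable PDB: one chain of ideal residues spaced along x, with
# metadata headers. `with_cb` may be a logical vector per residue.
make_pdb_text <- function(resnames, chain = "A",
                          resolution = 1.8, r_value = 0.18,
                          method = "X-RAY DIFFRACTION",
                          with_cb = rep(TRUE, length(resnames)),
                          resseq = seq_along(resnames),
                          extra_lines = character(0)) {
  lines <- c(
    sprintf("EXPDTA    %s", method),
    sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.", resolution),
    sprintf("REMARK   3   R VALUE            (WORKING SET) : %5.3f", r_value)
  )
  serial <- 1L
  for (i in seq_along(resnames)) {
    res <- ideal_residue_atoms(resnames[i], chain, resseq[i],
                               c(5 * (i - 1), 0, 0), serial, with_cb[i])
    serial <- serial + length(res)
    lines <- c(lines, res)
  }
  c(lines, extra_lines, "END")
}

# --- direct ChainModel fixtures --------------------------------------------

# Chain with explicit C-beta positions; C-alpha offset by `dirs` (unit rows).
tiny_chain <- function(types, cb, dirs = NULL, chain_id = "T") {
  cb <- as.matrix(cb)
  if (is.null(dirs)) {
    dirs <- matrix(rep(c(0, 0, 1), nrow(cb)), ncol = 3, byrow = TRUE)
  }
  chain_model(chain_id, types, cb - 1.53 * dirs, cb,
              metadata = list(resolution = 1.5, r_value = 0.15,
                              experimental_method = "X-RAY DIFFRACTION"))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_chain <- function(chain, rot, shift) {
  chain$ca <- chain$ca %*% t(rot) + matrix(shift, nrow(chain$ca), 3, byrow = TRUE)
  chain$cb <- chain$cb %*% t(rot) + matrix(shift, nrow(chain$cb), 3, byrow = TRUE)
  chain
}

# --- independent oracles ----------------------------------------------------

# Double-loop recount of ordered in-range pairs (scalar path throughout).
oracle_counts <- function(chain, binning, oriented = TRUE) {
  no <- if (oriented) 3L else 1L
  a <- array(0L, c(20, 20, no, binning$n_bins))
  n <- length(chain)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((chain$cb[i, ] - chain$cb[j, ])^2))
    if (d >= binning$max_distance) next
    if (sqrt(sum((chain$ca[i, ] - chain$ca[j, ])^2)) < 1e-9) next
    k <- if (d < binning$first_bin_upper) 0L else {
      1L + floor((d - binning$first_bin_upper) / binning$bin_width)
    }
    cl <- if (!oriented) 1L else {
      av <- chain$cb[i, ] - chain$ca[i, ]
      bv <- chain$cb[j, ] - chain$ca[j, ]
      cv <- chain$ca[j, ] - chain$ca[i, ]
      if (sum(av * bv) > 0) 1L else if (sum(av * cv) > 0) 2L else 3L
    }
    ii <- match(chain$types[i], AA_THREE)
    jj <- match(chain$types[j], AA_THREE)
    a[ii, jj, cl, k + 1L] <- a[ii, jj, cl, k + 1L] + 1L
  }
  a
}

# Double-loop model score against an energy table.
oracle_score <- function(chain, table) {
  b <- table$binning
  no <- if (table$oriented) 3L else 1L
  total <- 0
  n <- length(chain)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((chain$cb[i, ] - chain$cb[j, ])^2))
    if (d >= b$max_distance) next
    k <- if (d < b$first_bin_upper) 0L else {
      1L + floor((d - b$first_bin_upper) / b$bin_width)
    }
    cl <- if (!table$oriented) 1L else {
      av <- chain$cb[i, ] - chain$ca[i, ]
      bv <- chain$cb[j, ] - chain$ca[j, ]
      cv <- chain$ca[j, ] - chain$ca[i, ]
      if (sum(av * bv) > 0) 1L else if (sum(av * cv) > 0) 2L else 3L
    }
    total <- total + table$energy[match(chain$types[i], AA_THREE),
                                  match(chain$types[j], AA_THREE), cl, k + 1L]
  }
  total
}

# All permutations of a vector (exhaustive shuffle enumeration, length <= 6).
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (p in perms_of(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
  }
  out
}

# Random energy table over a reduced alphabet (for scoring oracles).
random_energy_table <- function(binning, oriented, types = AA_THREE[1:5],
                                variant = if (oriented) "RF_CB_SRS_OD" else "RF_CB_SRS") {
  no <- if (oriented) 3L else 1L
  e <- array(0, c(20, 20, no, binning$n_bins))
  act <- match(types, AA_THREE)
  e[act, act, , ] <- rnorm(length(act)^2 * no * binning$n_bins)
  energy_table(e, variant, binning)
}
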