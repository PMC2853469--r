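# PDB ingestion, virtual C-beta construction, training filters, identity
# culling.

test_that("read_chain builds one residue per standard amino acid with Cb present", {
  txt <- make_pdb_text(c("ALA", "GLY", "SER"), with_cb = c(TRUE, FALSE, TRUE))
  ch <- read_chain(txt, "A")
  expect_s3_class(ch, "ChainModel")
  expect_length(ch, 3)
  expect_identical(ch$types, c("ALA", "GLY", "SER"))
  expect_true(all(is.finite(ch$cb)))
  # the Gly without a CB atom gets the independent geometric construction
  lines <- txt[grepl("^ATOM", txt) & grepl("GLY", txt)]
  coords <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))
  }))
  names_ <- trimws(substr(lines, 13, 16))
  vcb <- build_virtual_cb(coords[names_ == "N", ], coords[names_ == "CA", ],
                          coords[names_ == "C", ])
  expect_equal(ch$cb[2, ], vcb, tolerance = 1e-9)
  expect_identical(ch$flags$virtual_cb, 2L)
  expect_identical(ch$flags$n_incomplete, 0L)
})

test_that("read_chain flags incomplete and nonstandard residues and missing chain", {
  # residue 2 lacks CA: drop every GLY atom line containing " CA "
  txt <- make_pdb_text(c("ALA", "GLY", "SER"))
  txt <- txt[!(grepl("GLY", txt) & grepl(" CA ", txt))]
  ch <- read_chain(txt, "A")
  expect_length(ch, 2)
  expect_identical(ch$flags$n_incomplete, 1L)

  txt2 <- make_pdb_text(c("ALA", "MSE", "SER"))
  ch2 <- read_chain(txt2, "A")
  expect_length(ch2, 2)
  expect_identical(ch2$flags$n_nonstandard, 1L)

  expect_error(read_chain(make_pdb_text("ALA"), "B"), "chain not found")
})

test_that("read_chain resolves altlocs to highest occupancy and detects ions", {
  base <- make_pdb_text(c("ALA", "SER"))
  # demote the original CA of residue 1 to occupancy 0.30, then add altloc
  # copies: B at 0.90 and C tying at 0.90 (tie resolves to first in file)
  ca1 <- which(grepl("^ATOM", base) & grepl(" CA ", base) & grepl("ALA", base))[1]
  substr(base[ca1], 55, 60) <- "  0.30"
  alt_b <- pdb_atom_line(98, "CA", "ALA", "A", 1, c(0.5, 0, 0), occ = 0.9,
                         altloc = "B")
  alt_c <- pdb_atom_line(99, "CA", "ALA", "A", 1, c(0.7, 0, 0), occ = 0.9,
                         altloc = "C")
  txt <- append(base, c(alt_b, alt_c), after = ca1)
  ch <- read_chain(txt, "A")
  expect_equal(ch$ca[1, 1], 0.5)

  ion <- pdb_atom_line(100, "ZN", "ZN", "A", 90, c(30, 30, 30), record = "HETATM")
  wat <- pdb_atom_line(101, "O", "HOH", "A", 91, c(32, 32, 32), record = "HETATM")
  expect_true(read_chain(c(base, ion), "A")$flags$has_ions)
  expect_false(read_chain(c(base, wat), "A")$flags$has_ions)
})

test_that("internal numbering gaps are flagged, terminal-only gaps are not", {
  with_gap <- make_pdb_text(c("ALA", "SER", "LEU"), resseq = c(1, 2, 9))
  expect_true(read_chain(with_gap, "A")$flags$missing_internal)
  no_gap <- make_pdb_text(c("ALA", "SER", "LEU"), resseq = c(7, 8, 9))
  expect_false(read_chain(no_gap, "A")$flags$missing_internal)
})

test_that("build_virtual_cb has ideal bond length, L-chirality and equivariance", {
  # ideal alanine rigid-group frame reproduces the reference CB position
  N <- c(-0.525, 1.363, 0); CA <- c(0, 0, 0); C <- c(1.526, 0, 0)
  expect_equal(build_virtual_cb(N, CA, C), c(-0.529, -0.774, -1.205),
               tolerance = 5e-3)
  set.seed(41)
  for (k in 1:200) {
    ca <- rnorm(3, sd = 5)
    n <- ca + rnorm(3); c_ <- ca + rnorm(3)
    # skip near-collinear draws (they must error instead, tested below)
    u <- n - ca; v <- c_ - ca
    cr <- c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
    if (sqrt(sum(cr^2)) < 1e-3) next
    cb <- build_virtual_cb(n, ca, c_)
    expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 1e-6)
    # signed volume of (n-ca, c-ca, cb-ca) is positive for L-configuration
    expect_gt(det(cbind(n - ca, c_ - ca, cb - ca)), 0)
    # rigid-motion equivariance
    rot <- random_rotation(); shift <- rnorm(3, sd = 10)
    cb2 <- build_virtual_cb(rot %*% n + shift, rot %*% ca + shift,
                            rot %*% c_ + shift)
    expect_equal(as.numeric(cb2), as.numeric(rot %*% cb + shift),
                 tolerance = 1e-9)
  }
  expect_error(build_virtual_cb(CA, CA, C), "degenerate backbone geometry")
  expect_error(build_virtual_cb(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
               "degenerate backbone geometry")
})

test_that("PDB round trip preserves coordinates to 1e-3 A and types exactly", {
  set.seed(7)
  ch <- generate_chain(12, uniform_composition(), seed = NULL, chain_id = "A")
  back <- read_chain(write_chain_pdb(ch), "A")
  expect_identical(back$types, ch$types)
  expect_equal(back$ca, ch$ca, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$cb, ch$cb, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("training filters apply the strict thresholds", {
  mk <- function(resolution = 2.0, r_value = 0.19, n = 60,
                 method = "X-RAY DIFFRACTION", flags = list()) {
    ch <- tiny_chain(rep("ALA", n), cbind(seq_len(n) * 5, 0, 0))
    ch$metadata$resolution <- resolution
    ch$metadata$r_value <- r_value
    ch$metadata$experimental_method <- method
    ch$flags[names(flags)] <- flags
    ch
  }
  expect_true(passes_training_filters(mk())$passed)
  expect_identical(passes_training_filters(mk(resolution = 2.1))$reasons, "resolution")
  expect_identical(passes_training_filters(mk(r_value = 0.2))$reasons, "r_value")
  expect_identical(passes_training_filters(mk(n = 49))$reasons, "length")
  expect_identical(passes_training_filters(mk(method = "SOLUTION NMR"))$reasons,
                   "not_xray")
  expect_identical(
    passes_training_filters(mk(flags = list(missing_internal = TRUE)))$reasons,
    "internal_missing_residues"
  )
  expect_false(passes_training_filters(mk(flags = list(has_ions = TRUE)))$passed)
  expect_false(passes_training_filters(mk(flags = list(n_incomplete = 1L)))$passed)
  expect_false(passes_training_filters(mk(flags = list(n_nonstandard = 2L)))$passed)
  bad <- mk(); bad$metadata$r_value <- NA_real_
  expect_error(passes_training_filters(bad), "metadata incomplete")
})

test_that("filter logic is monotone in the thresholds", {
  set.seed(11)
  for (k in 1:30) {
    n <- sample(30:80, 1)
    ch <- tiny_chain(rep("ALA", n), cbind(seq_len(n) * 5, 0, 0))
    ch$metadata$resolution <- runif(1, 1.5, 2.5)
    ch$metadata$r_value <- runif(1, 0.15, 0.25)
    ch$metadata$experimental_method <- "X-RAY DIFFRACTION"
    strict <- passes_training_filters(ch, 2.1, 0.2, 50)
    relaxed <- passes_training_filters(ch, 2.5, 0.25, 30)
    if (strict$passed) expect_true(relaxed$passed)
  }
})

test_that("identity culling retains a greedy sub-threshold set", {
  mk_seq_chain <- function(one_letter, resolution) {
    types <- names(AA_ONE)[match(strsplit(one_letter, "")[[1]], AA_ONE)]
    ch <- tiny_chain(types, cbind(seq_along(types) * 5, 0, 0))
    ch$metadata$resolution <- resolution
    ch
  }
  a <- mk_seq_chain("ACDEFGHIKL", 1.5)
  b <- mk_seq_chain("ACDEFGHIKL", 2.0)  # identical to a
  expect_length(cull_by_identity(list(a, b), 0.4), 1)

  c1 <- mk_seq_chain("AAAAAAAAAA", 1.5)
  c2 <- mk_seq_chain("WWWWWWWWWW", 1.5)  # zero identical positions
  expect_length(cull_by_identity(list(c1, c2), 0.4), 2)

  # 5 equal-length point-mutant sequences: oracle identity = hamming matches
  base <- "ACDEFGHIKLMNPQRSTVWY"
  seqs <- c(
    base,
    "ACDEFGHIKLMNPQRSTVWV",  # 19/20 = 0.95 vs base
    "WCDEFGHIKLYNPQRSTVAY",  # 17/20 = 0.85 vs base
    "AAAAAAHIKLMNPQRSTVWY",  # 15/20 = 0.75 vs base
    "YWVTSRQPNMLKIHGFEDCA"   # scrambled
  )
  res <- c(1.1, 1.2, 1.3, 1.4, 1.5)
  chains <- Map(mk_seq_chain, seqs, res)
  # independent oracle: hamming identity matrix + the same greedy rule
  ident <- function(x, y) {
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }
  kept_oracle <- integer(0)
  for (i in order(res)) {
    if (all(vapply(kept_oracle, function(k) ident(seqs[i], seqs[k]) < 0.4, TRUE))) {
      kept_oracle <- c(kept_oracle, i)
    }
  }
  kept_pkg <- cull_by_identity(chains, 0.4)
  expect_setequal(
    vapply(kept_pkg, chain_sequence, ""),
    seqs[kept_oracle]
  )
})
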