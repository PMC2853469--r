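# Reference (expected) counts: classic all-type averaging, and the Shuffled
# Reference State (SRS) via Monte Carlo label shuffling or its exact
# closed-form expectation.

#' Construct an ExpectedTable
#'
#' Reference-state expectations on the same index space as a
#' [pair_count_table()]. All constructors conserve the observed per-condition
#' totals: summing `expected` over type pairs within each (orientation, bin)
#' reproduces the observed geometry exactly.
#'
#' @param expected Non-negative numeric array `(20, 20, n_orient, n_bins)`.
#' @param binning A [distance_binning()].
#' @param oriented Logical.
#' @param method One of `"CLASSIC"`, `"SRS_MC"`, `"SRS_EXACT"`.
#' @param n_shuffles,seed Monte Carlo provenance (SRS_MC only).
#' @param n_chains Number of chains behind the expectation.
#' @return Object of class `ExpectedTable`.
#' @export
expected_table <- function(expected, binning, oriented, method,
                           n_shuffles = NA_integer_, seed = NA_integer_,
                           n_chains = 0L) {
  method <- match.arg(method, c("CLASSIC", "SRS_MC", "SRS_EXACT"))
  dims <- count_dims(binning, oriented)
  stopifnot(identical(dim(expected), as.integer(dims)), all(expected >= 0))
  dimnames(expected) <- count_dimnames(binning, oriented)
  structure(
    list(expected = expected, binning = binning, oriented = oriented,
         method = method, n_shuffles = n_shuffles, seed = seed,
         n_chains = as.integer(n_chains)),
    class = "ExpectedTable"
  )
}

#' @export
print.ExpectedTable <- function(x, ...) {
  cat(sprintf("ExpectedTable (%s): %s, %d bins, total mass %.1f\n",
              x$method, if (x$oriented) "oriented" else "non-oriented",
              x$binning$n_bins, sum(x$expected)))
  invisible(x)
}

#' Classic reference state (all-type averaging)
#'
#' Expected counts are the observed per-condition totals redistributed over
#' ordered type pairs with weights `w_ij` = (observed ordered pairs of type
#' (i, j)) / (all observed pairs): every type pair is assigned the same
#' distance/orientation profile shape — the average over all residue types.
#'
#' @param obs A non-empty [pair_count_table()].
#' @return An [expected_table()] with method `"CLASSIC"`.
#' @export
classic_reference <- function(obs) {
  stopifnot(inherits(obs, "PairCountTable"))
  grand <- sum(obs$counts)
  if (grand == 0) stop("empty count table")
  w <- apply(obs$counts, c(1, 2), sum) / grand
  totals <- totals_by_condition(obs)
  expected <- outer(w, totals)
  expected_table(expected, obs$binning, obs$oriented, "CLASSIC",
                 n_chains = obs$n_chains)
}

# Exact expectation contribution of one chain under uniform label
# permutation: each ordered position pair (p, q) lands in its fixed
# (orientation, bin) slot and carries P(label_p = i, label_q = j) =
# c_i c_j / (n (n-1)) for i != j, c_i (c_i - 1) / (n (n-1)) for i = j.
srs_exact_chain <- function(chain, binning, oriented) {
  n <- length(chain)
  no <- orient_dim(oriented)
  if (n < 2) return(array(0, count_dims(binning, oriented)))
  geo <- chain_pair_geometry(chain, binning)
  o <- if (oriented) geo$cls else rep(1L, length(geo$i))
  slot <- o + no * geo$bin
  pos_pairs <- matrix(tabulate(slot, nbins = no * binning$n_bins),
                      no, binning$n_bins)
  comp <- chain_composition(chain)
  w2 <- (outer(comp, comp) - diag(comp, N_TYPES)) / (n * (n - 1))
  outer(w2, pos_pairs)
}

#' Shuffled Reference State: exact expectation
#'
#' Closed-form expectation of the within-chain label shuffle: coordinates
#' (hence all distances and orientation classes) stay fixed while residue
#' identities are permuted uniformly. Identical in expectation to
#' [shuffled_reference_mc()] with no sampling noise; the recommended
#' production path.
#'
#' @param chains List of [chain_model()]s.
#' @param binning A [distance_binning()].
#' @param oriented Logical.
#' @return An [expected_table()] with method `"SRS_EXACT"`.
#' @export
shuffled_reference_exact <- function(chains, binning = distance_binning(),
                                     oriented = TRUE) {
  stopifnot(length(chains) >= 1)
  expected <- array(0, count_dims(binning, oriented))
  for (chain in chains) {
    expected <- expected + srs_exact_chain(chain, binning, oriented)
  }
  expected_table(expected, binning, oriented, "SRS_EXACT",
                 n_chains = length(chains))
}

#' Shuffled Reference State: Monte Carlo label shuffling
#'
#' For each shuffle, residue type labels are permuted uniformly at random
#' within each chain (Fisher-Yates via `sample()`) while all coordinates stay
#' fixed; the expectation is the mean of the shuffled count tables. One
#' master seed derives the per-shuffle seeds deterministically.
#'
#' @param chains List of [chain_model()]s.
#' @param binning A [distance_binning()].
#' @param oriented Logical.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Master seed.
#' @param keep_shuffles If `TRUE`, attach the per-shuffle count arrays as
#'   attribute `"shuffles"` (small fixtures only).
#' @return An [expected_table()] with method `"SRS_MC"`.
#' @export
shuffled_reference_mc <- function(chains, binning = distance_binning(),
                                  oriented = TRUE, n_shuffles = 1000L,
                                  seed = 1L, keep_shuffles = FALSE) {
  stopifnot(length(chains) >= 1, n_shuffles >= 1)
  no <- orient_dim(oriented)
  nb <- binning$n_bins
  ncell <- N_TYPES^2 * no * nb
  # fixed geometry per chain; only labels move between shuffles
  geos <- lapply(chains, function(chain) {
    if (length(chain) < 2) return(NULL)
    geo <- chain_pair_geometry(chain, binning)
    o <- if (oriented) geo$cls else rep(1L, length(geo$i))
    list(i = geo$i, j = geo$j, n = length(chain),
         base = N_TYPES^2 * (o - 1L) + N_TYPES^2 * no * geo$bin,
         ti = aa_index(chain$types))
  })
  geos <- geos[!vapply(geos, is.null, TRUE)]
  set.seed(seed)
  shuffle_seeds <- sample.int(.Machine$integer.max, n_shuffles)
  acc <- numeric(ncell)
  acc2 <- numeric(ncell)
  shuffles <- if (keep_shuffles) vector("list", n_shuffles) else NULL
  for (s in seq_len(n_shuffles)) {
    set.seed(shuffle_seeds[s])
    lin <- unlist(lapply(geos, function(g) {
      perm <- g$ti[sample.int(g$n)]
      perm[g$i] + N_TYPES * (perm[g$j] - 1L) + g$base
    }), use.names = FALSE)
    tab <- tabulate(lin, nbins = ncell)
    acc <- acc + tab
    acc2 <- acc2 + tab * tab
    if (keep_shuffles) {
      shuffles[[s]] <- array(tab, count_dims(binning, oriented))
    }
  }
  out <- expected_table(
    array(acc / n_shuffles, count_dims(binning, oriented)),
    binning, oriented, "SRS_MC",
    n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
    n_chains = length(chains)
  )
  # per-cell standard error of the Monte Carlo mean
  v <- pmax(acc2 / n_shuffles - (acc / n_shuffles)^2, 0)
  attr(out, "mc_se") <- array(sqrt(v / n_shuffles),
                              count_dims(binning, oriented))
  if (keep_shuffles) attr(out, "shuffles") <- shuffles
  out
}

#' Write an expected table as tab-separated text
#' @param x An [expected_table()].
#' @param path Output path.
#' @export
write_expected <- function(x, path) {
  hdr <- header_kv(
    format = "srspot_expected_v1",
    first_bin_upper = x$binning$first_bin_upper,
    bin_width = x$binning$bin_width,
    max_distance = x$binning$max_distance,
    oriented = x$oriented,
    method = x$method,
    n_shuffles = x$n_shuffles,
    seed = x$seed,
    n_chains = x$n_chains
  )
  write_table_body(x$expected, path, hdr, "expected")
  invisible(path)
}

#' Read an expected table written by [write_expected()]
#' @param path Input path.
#' @return An [expected_table()].
#' @export
read_expected <- function(path) {
  lines <- readLines(path)
  kv <- parse_header_kv(lines)
  if (!identical(unname(kv["format"]), "srspot_expected_v1")) {
    stop("unsupported format version")
  }
  binning <- distance_binning(
    as.numeric(kv["first_bin_upper"]), as.numeric(kv["bin_width"]),
    as.numeric(kv["max_distance"])
  )
  oriented <- as.logical(kv["oriented"])
  df <- read.delim(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"),
                   stringsAsFactors = FALSE)
  expected <- array(0, count_dims(binning, oriented))
  if (nrow(df)) {
    oi <- match(df$orientation, orient_dimnames(oriented))
    expected[cbind(aa_index(df$type_i), aa_index(df$type_j), oi, df$bin + 1L)] <-
      df$expected
  }
  expected_table(expected, binning, oriented, kv[["method"]],
                 n_shuffles = suppressWarnings(as.integer(kv["n_shuffles"])),
                 seed = suppressWarnings(as.integer(kv["seed"])),
                 n_chains = as.integer(kv["n_chains"]))
}
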