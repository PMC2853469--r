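# Accumulation of observed ordered-pair counts over chains into the
# (type_i, type_j, orientation, distance-bin) table.

orient_dim <- function(oriented) if (oriented) 3L else 1L

orient_dimnames <- function(oriented) if (oriented) ORIENT_LABELS else "ALL"

count_dims <- function(binning, oriented) {
  c(N_TYPES, N_TYPES, orient_dim(oriented), binning$n_bins)
}

count_dimnames <- function(binning, oriented) {
  list(AA_THREE, AA_THREE, orient_dimnames(oriented),
       paste0("b", seq_len(binning$n_bins) - 1L))
}

#' Construct a PairCountTable
#'
#' Observed ordered-pair counts indexed by (type_i, type_j, orientation
#' class, distance bin). Usually produced by [accumulate_counts()] /
#' [merge_counts()]; the constructor is exposed for building small tables in
#' tests and examples.
#'
#' @param counts Non-negative integer array, dims
#'   `(20, 20, n_orient, n_bins)` with `n_orient` 3 (oriented) or 1.
#' @param binning A [distance_binning()].
#' @param oriented Logical; whether counts are split by orientation class.
#' @param n_chains Number of chains accumulated.
#' @param composition Integer matrix `n_chains x 20` of per-chain residue
#'   type counts.
#' @param n_skipped Ordered pairs skipped for degenerate geometry.
#' @return Object of class `PairCountTable`.
#' @export
pair_count_table <- function(counts, binning, oriented, n_chains = 0L,
                             composition = NULL, n_skipped = 0L) {
  dims <- count_dims(binning, oriented)
  stopifnot(identical(dim(counts), as.integer(dims)), all(counts >= 0))
  if (is.null(composition)) {
    composition <- matrix(0L, 0L, N_TYPES, dimnames = list(NULL, AA_THREE))
  }
  dimnames(counts) <- count_dimnames(binning, oriented)
  structure(
    list(counts = counts, binning = binning, oriented = oriented,
         n_chains = as.integer(n_chains), composition = composition,
         n_skipped = as.integer(n_skipped)),
    class = "PairCountTable"
  )
}

#' @export
print.PairCountTable <- function(x, ...) {
  cat(sprintf(
    "PairCountTable: %s, %d bins, %d chains, %d pairs counted\n",
    if (x$oriented) "oriented (3 classes)" else "non-oriented",
    x$binning$n_bins, x$n_chains, sum(x$counts)
  ))
  invisible(x)
}

empty_pair_count_table <- function(binning, oriented) {
  pair_count_table(
    array(0L, count_dims(binning, oriented)), binning, oriented
  )
}

#' Counts summed over type pairs, per (orientation, bin) condition
#' @param x A [pair_count_table()] or expected table.
#' @return Matrix `n_orient x n_bins`.
#' @export
totals_by_condition <- function(x) {
  a <- if (inherits(x, "PairCountTable")) x$counts else x$expected
  apply(a, c(3, 4), sum)
}

# All in-range ordered pairs of a chain: indices, orientation class (1:3) and
# 0-based distance bin. Degenerate pairs (coincident C-alphas) are skipped
# and tallied. Residues are assumed to satisfy the ChainModel invariants
# (finite coordinates, |cb-ca| > 0.5).
chain_pair_geometry <- function(chain, binning) {
  n <- length(chain)
  ca <- chain$ca; cb <- chain$cb
  d <- as.matrix(dist(cb))
  inr <- d < binning$max_distance
  diag(inr) <- FALSE
  dca <- as.matrix(dist(ca))
  deg <- inr & (dca < 1e-9)
  inr <- inr & !deg
  idx <- which(inr, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(list(i = integer(0), j = integer(0), cls = integer(0),
                bin = integer(0), n_degenerate = sum(deg)))
  }
  a <- cb - ca
  ab <- tcrossprod(a)                      # ab[i,j] = a_i . a_j
  ac <- tcrossprod(a, ca) - rowSums(a * ca) # ac[i,j] = a_i . (ca_j - ca_i)
  list(
    i = idx[, 1], j = idx[, 2],
    cls = orient_from_dots(ab[idx], ac[idx]),
    bin = distance_bin(d[idx], binning),
    n_degenerate = sum(deg)
  )
}

chain_composition <- function(chain) {
  comp <- tabulate(aa_index(chain$types), N_TYPES)
  names(comp) <- AA_THREE
  comp
}

#' Accumulate ordered-pair counts for one chain
#'
#' Every ordered residue pair (i, j), i != j — sequence neighbours included,
#' as no minimal sequence separation is imposed — with C-beta distance below
#' the binning cutoff contributes one count to
#' `counts[type_i, type_j, class(i->j), bin(d)]`. With `oriented = FALSE`
#' all contributions collapse into a single orientation slot.
#'
#' @param chain A [chain_model()].
#' @param binning A [distance_binning()].
#' @param oriented Logical, default `TRUE`.
#' @return A [pair_count_table()] for this chain (empty if fewer than 2
#'   residues).
#' @export
accumulate_counts <- function(chain, binning = distance_binning(), oriented = TRUE) {
  comp <- matrix(chain_composition(chain), 1L, N_TYPES,
                 dimnames = list(NULL, AA_THREE))
  if (length(chain) < 2) {
    tab <- empty_pair_count_table(binning, oriented)
    tab$n_chains <- 1L
    tab$composition <- comp
    return(tab)
  }
  geo <- chain_pair_geometry(chain, binning)
  ti <- aa_index(chain$types)
  no <- orient_dim(oriented)
  o <- if (oriented) geo$cls else rep(1L, length(geo$i))
  lin <- ti[geo$i] + N_TYPES * (ti[geo$j] - 1L) +
    N_TYPES^2 * (o - 1L) + N_TYPES^2 * no * geo$bin
  counts <- array(tabulate(lin, nbins = N_TYPES^2 * no * binning$n_bins),
                  count_dims(binning, oriented))
  pair_count_table(counts, binning, oriented, n_chains = 1L,
                   composition = comp, n_skipped = geo$n_degenerate)
}

#' Merge count tables
#'
#' Elementwise sum over tables sharing binning and orientation dimensions;
#' chain counts and compositions are concatenated.
#'
#' @param tables List of [pair_count_table()]s.
#' @return A merged [pair_count_table()].
#' @export
merge_counts <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!same_binning(t$binning, ref$binning) || t$oriented != ref$oriented) {
      stop("count table dimension mismatch (binning or orientation)")
    }
  }
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  pair_count_table(
    counts, ref$binning, ref$oriented,
    n_chains = sum(vapply(tables, `[[`, 0L, "n_chains")),
    composition = do.call(rbind, lapply(tables, `[[`, "composition")),
    n_skipped = sum(vapply(tables, `[[`, 0L, "n_skipped"))
  )
}

#' Accumulate counts over a list of chains
#' @param chains List of [chain_model()]s.
#' @inheritParams accumulate_counts
#' @return A merged [pair_count_table()].
#' @export
accumulate_counts_all <- function(chains, binning = distance_binning(),
                                  oriented = TRUE) {
  merge_counts(lapply(chains, accumulate_counts, binning = binning,
                      oriented = oriented))
}

# ---------------------------------------------------------------------------
# Tabular text serialization (shared by counts and expected tables)

write_table_body <- function(a, path, header, value_name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  nz <- which(a != 0, arr.ind = TRUE)
  df <- data.frame(
    type_i = AA_THREE[nz[, 1]], type_j = AA_THREE[nz[, 2]],
    orientation = dimnames(a)[[3]][nz[, 3]],
    bin = nz[, 4] - 1L,
    value = a[nz]
  )
  names(df)[5] <- value_name
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(df)
}

header_kv <- function(...) {
  kv <- list(...)
  paste0("#", names(kv), "\t", vapply(kv, as.character, ""))
}

parse_header_kv <- function(lines) {
  h <- lines[startsWith(lines, "#")]
  parts <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)
  stats::setNames(
    vapply(parts, function(p) paste(p[-1], collapse = "\t"), ""),
    vapply(parts, `[[`, "", 1)
  )
}

#' Write a count table as tab-separated text
#' @param x A [pair_count_table()].
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  hdr <- c(
    header_kv(
      format = "srspot_counts_v1",
      first_bin_upper = x$binning$first_bin_upper,
      bin_width = x$binning$bin_width,
      max_distance = x$binning$max_distance,
      oriented = x$oriented,
      n_chains = x$n_chains,
      n_skipped = x$n_skipped
    ),
    apply(x$composition, 1, function(r) paste0("#chain_composition\t", paste(r, collapse = ",")))
  )
  write_table_body(x$counts, path, hdr, "count")
  invisible(path)
}

#' Read a count table written by [write_counts()]
#' @param path Input path.
#' @return A [pair_count_table()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  kv <- parse_header_kv(lines)
  if (!identical(unname(kv["format"]), "srspot_counts_v1")) {
    stop("unsupported format version")
  }
  binning <- distance_binning(
    as.numeric(kv["first_bin_upper"]), as.numeric(kv["bin_width"]),
    as.numeric(kv["max_distance"])
  )
  oriented <- as.logical(kv["oriented"])
  comp_lines <- lines[startsWith(lines, "#chain_composition")]
  comp <- if (length(comp_lines)) {
    do.call(rbind, lapply(strsplit(sub("^#chain_composition\t", "", comp_lines), ","),
                          as.integer))
  } else NULL
  if (!is.null(comp)) colnames(comp) <- AA_THREE
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  counts <- array(0L, count_dims(binning, oriented))
  if (nrow(df)) {
    oi <- match(df$orientation, orient_dimnames(oriented))
    counts[cbind(aa_index(df$type_i), aa_index(df$type_j), oi, df$bin + 1L)] <-
      as.integer(df$count)
  }
  pair_count_table(counts, binning, oriented,
                   n_chains = as.integer(kv["n_chains"]),
                   composition = comp,
                   n_skipped = as.integer(kv["n_skipped"]))
}
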