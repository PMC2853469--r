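# Distance binning and the three-class orientation classification of ordered
# residue pairs.

#' Distance binning scheme
#'
#' The first bin spans `[0, first_bin_upper)` angstroms and every subsequent
#' bin spans `bin_width` angstroms, up to (but excluding) `max_distance`.
#' Bins are half-open `[lo, hi)`, so a distance exactly at a boundary falls in
#' the upper bin.
#'
#' @param first_bin_upper Upper edge of the first bin (A). Default 4.
#' @param bin_width Width of every subsequent bin (A). Default 1.
#' @param max_distance Interaction cutoff (A); distances at or beyond it are
#'   out of range. Default 20.
#' @return An object of class `DistanceBinning` with fields
#'   `first_bin_upper`, `bin_width`, `max_distance`, `n_bins`.
#' @export
distance_binning <- function(first_bin_upper = 4, bin_width = 1, max_distance = 20) {
  stopifnot(
    is.numeric(first_bin_upper), first_bin_upper > 0,
    is.numeric(bin_width), bin_width > 0,
    is.numeric(max_distance), max_distance > first_bin_upper
  )
  k <- (max_distance - first_bin_upper) / bin_width
  if (abs(k - round(k)) > 1e-9) {
    stop("max_distance - first_bin_upper must be an integer multiple of bin_width")
  }
  structure(
    list(
      first_bin_upper = first_bin_upper,
      bin_width = bin_width,
      max_distance = max_distance,
      n_bins = 1L + as.integer(round(k))
    ),
    class = "DistanceBinning"
  )
}

#' @export
print.DistanceBinning <- function(x, ...) {
  cat(sprintf(
    "DistanceBinning: [0,%g) then %g-A bins up to %g A (%d bins)\n",
    x$first_bin_upper, x$bin_width, x$max_distance, x$n_bins
  ))
  invisible(x)
}

same_binning <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

bin_edges <- function(binning) {
  c(0, binning$first_bin_upper + binning$bin_width * seq(0L, binning$n_bins - 1L))
}

#' Map distances to bin indices
#'
#' Vectorised. Returns 0-based bin indices: bin 0 is `[0, first_bin_upper)`,
#' bin k >= 1 is `[first_bin_upper + (k-1) w, first_bin_upper + k w)`.
#' Distances at or beyond `max_distance` return `NA` (out of range).
#'
#' @param d Numeric vector of distances (A), all non-negative.
#' @param binning A [distance_binning()] object.
#' @return Integer vector of 0-based bin indices, `NA` for out-of-range.
#' @export
distance_bin <- function(d, binning = distance_binning()) {
  stopifnot(is.numeric(d), inherits(binning, "DistanceBinning"))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  idx <- ifelse(
    d < binning$first_bin_upper,
    0,
    1 + floor((d - binning$first_bin_upper) / binning$bin_width)
  )
  idx[d >= binning$max_distance] <- NA
  as.integer(idx)
}

# Internal vectorised classifier on precomputed dot products.
# ab = a.b, ac = a.c; ties (<= 0) resolve to the "non-positive" branch.
orient_from_dots <- function(ab, ac) {
  ifelse(ab > 0, 1L, ifelse(ac > 0, 2L, 3L))
}

#' Orientation class of an ordered residue pair
#'
#' With a = cb_i - ca_i (side-chain direction of residue i), b = cb_j - ca_j,
#' and c = ca_j - ca_i: the interaction i -> j is `PARALLEL` if a.b > 0;
#' `ANTIPARALLEL_FACING` if a.b <= 0 and a.c > 0; `ANTIPARALLEL_AWAY` if both
#' products are non-positive. Note the classification is not symmetric in
#' (i, j) except for the parallel class.
#'
#' @param ca_i,cb_i,ca_j,cb_j Numeric 3-vectors, or n x 3 matrices for
#'   vectorised use (rows are pairs).
#' @return Character vector of labels from [ORIENT_LABELS].
#' @export
orientation_class <- function(ca_i, cb_i, ca_j, cb_j) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  ca_i <- as_m(ca_i); cb_i <- as_m(cb_i); ca_j <- as_m(ca_j); cb_j <- as_m(cb_j)
  a <- cb_i - ca_i
  b <- cb_j - ca_j
  cc <- ca_j - ca_i
  n2 <- function(m) rowSums(m * m)
  if (any(n2(a) < 1e-18) || any(n2(b) < 1e-18) || any(n2(cc) < 1e-18)) {
    stop("degenerate orientation geometry")
  }
  ORIENT_LABELS[orient_from_dots(rowSums(a * b), rowSums(a * cc))]
}
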