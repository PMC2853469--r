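# Boltzmann inversion of observed vs reference frequencies with Sippl
# sparse-count smoothing; the four RF_CB energy-table variants; model scoring;
# energy-table serialization.

VARIANTS <- c("RF_CB", "RF_CB_OD", "RF_CB_SRS", "RF_CB_SRS_OD")

variant_oriented <- function(variant) grepl("_OD$", variant)
variant_srs <- function(variant) grepl("_SRS", variant)

#' Sippl smoothing parameters
#' @param sigma Unitless weight per observation; default 1/50 (Sippl's
#'   original value).
#' @return Object of class `SmoothingParams`.
#' @export
smoothing_params <- function(sigma = 1 / 50) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  structure(list(sigma = sigma), class = "SmoothingParams")
}

#' Sippl sparse-count smoothing of a frequency profile
#'
#' Blends the observed conditional distribution over distance bins with the
#' reference profile, weighted by the number of observations m:
#' `f' = g / (1 + m sigma) + f_obs * m sigma / (1 + m sigma)`.
#' With m = 0 the reference is returned exactly (an empty count gets the
#' average of all interaction types); as m grows f' converges to f_obs.
#'
#' @param f_obs Observed distribution over bins (normalized when m > 0).
#' @param m Observation count (non-negative scalar).
#' @param g Reference distribution over bins (normalized).
#' @param params A [smoothing_params()].
#' @return Smoothed, normalized distribution over bins.
#' @export
smooth_frequencies <- function(f_obs, m, g, params = smoothing_params()) {
  stopifnot(length(f_obs) == length(g), length(m) == 1, m >= 0)
  if (abs(sum(g) - 1) > 1e-6) stop("reference distribution g must be normalized")
  if (m > 0 && abs(sum(f_obs) - 1) > 1e-6) {
    stop("observed distribution f_obs must be normalized when m > 0")
  }
  w <- m * params$sigma / (1 + m * params$sigma)
  (1 - w) * g + w * f_obs
}

#' Construct an EnergyTable
#'
#' Energies in kT units on the (type_i, type_j, orientation, bin) index
#' space. Usually produced by [build_energy_table()].
#'
#' @param energy Finite numeric array `(20, 20, n_orient, n_bins)`.
#' @param variant One of `"RF_CB"`, `"RF_CB_OD"`, `"RF_CB_SRS"`,
#'   `"RF_CB_SRS_OD"`.
#' @param binning A [distance_binning()].
#' @param smoothing A [smoothing_params()].
#' @param provenance List: training summary (`n_chains`, `method`,
#'   `n_shuffles`, `seed`).
#' @return Object of class `EnergyTable`.
#' @export
energy_table <- function(energy, variant, binning,
                         smoothing = smoothing_params(), provenance = list()) {
  variant <- match.arg(variant, VARIANTS)
  oriented <- variant_oriented(variant)
  dims <- count_dims(binning, oriented)
  stopifnot(identical(dim(energy), as.integer(dims)))
  if (!all(is.finite(energy))) stop("non-finite energies")
  dimnames(energy) <- count_dimnames(binning, oriented)
  pr <- list(n_chains = NA_integer_, method = NA_character_,
             n_shuffles = NA_integer_, seed = NA_integer_)
  pr[names(provenance)] <- provenance
  structure(
    list(energy = energy, variant = variant, binning = binning,
         oriented = oriented, smoothing = smoothing, provenance = pr),
    class = "EnergyTable"
  )
}

#' @export
print.EnergyTable <- function(x, ...) {
  cat(sprintf(
    "EnergyTable %s: %d bins, sigma = %g, trained on %s chains (%s)\n",
    x$variant, x$binning$n_bins, x$smoothing$sigma,
    x$provenance$n_chains, x$provenance$method
  ))
  invisible(x)
}

#' Build an energy table from observed and expected counts
#'
#' Boltzmann inversion per cell:
#' `E[i,j,o,b] = -ln( f'_obs(b | i,j,o) / f_ref(b | i,j,o) )`, where both
#' frequencies are conditional distributions over distance bins within each
#' (type_i, type_j, orientation) cell, and `f'_obs` is Sippl-smoothed toward
#' `f_ref` (so empty cells give E = 0, and no division by zero can occur).
#' Cells whose reference mass is zero in a bin must also have zero smoothed
#' observed mass there (E = 0); a nonzero observation over a zero reference
#' is an error.
#'
#' @param obs A [pair_count_table()].
#' @param expected An [expected_table()] on the same index space, with a
#'   method matching the variant (CLASSIC for RF_CB/RF_CB_OD, SRS for the
#'   _SRS variants).
#' @param params A [smoothing_params()].
#' @param variant Potential variant label; its `_OD` suffix must agree with
#'   the tables' orientation dimension.
#' @return An [energy_table()].
#' @export
build_energy_table <- function(obs, expected, params = smoothing_params(),
                               variant = "RF_CB_SRS_OD") {
  variant <- match.arg(variant, VARIANTS)
  stopifnot(inherits(obs, "PairCountTable"), inherits(expected, "ExpectedTable"))
  if (!same_binning(obs$binning, expected$binning) ||
      obs$oriented != expected$oriented) {
    stop("observed and expected tables do not share an index space")
  }
  if (variant_oriented(variant) != obs$oriented) {
    stop("variant ", variant, " requires oriented = ", variant_oriented(variant))
  }
  if (variant_srs(variant) != (expected$method %in% c("SRS_MC", "SRS_EXACT"))) {
    stop("variant ", variant, " requires a ",
         if (variant_srs(variant)) "shuffled" else "classic", " reference state")
  }
  nb <- obs$binning$n_bins
  obs_m <- matrix(obs$counts, ncol = nb)   # rows: (i, j, o) cells
  ref_m <- matrix(expected$expected, ncol = nb)
  m_cell <- rowSums(obs_m)
  ref_tot <- rowSums(ref_m)

  bad_cell <- ref_tot == 0 & m_cell > 0
  if (any(bad_cell)) {
    loc <- cell_location(which(bad_cell)[1], obs$oriented, obs$binning)
    stop("reference mass zero with observed mass nonzero at cell (",
         loc, ")")
  }

  E <- matrix(0, nrow(obs_m), nb)
  act <- ref_tot > 0
  f_ref <- ref_m[act, , drop = FALSE] / ref_tot[act]
  f_obs <- obs_m[act, , drop = FALSE] /
    ifelse(m_cell[act] > 0, m_cell[act], 1)
  w <- m_cell[act] * params$sigma / (1 + m_cell[act] * params$sigma)
  f_s <- (1 - w) * f_ref + w * f_obs

  zero_ref <- f_ref == 0
  if (any(zero_ref & f_s > 0)) {
    hit <- which(zero_ref & f_s > 0, arr.ind = TRUE)[1, ]
    loc <- cell_location(which(act)[hit[1]], obs$oriented, obs$binning)
    stop("reference mass zero with observed mass nonzero at cell (",
         loc, "), bin ", hit[2] - 1L)
  }
  Ea <- matrix(0, sum(act), nb)
  pos <- !zero_ref
  Ea[pos] <- -log(f_s[pos] / f_ref[pos])
  E[act, ] <- Ea

  energy_table(
    array(E, count_dims(obs$binning, obs$oriented)), variant, obs$binning,
    smoothing = params,
    provenance = list(n_chains = obs$n_chains, method = expected$method,
                      n_shuffles = expected$n_shuffles, seed = expected$seed)
  )
}

cell_location <- function(cell, oriented, binning) {
  no <- orient_dim(oriented)
  cell <- cell - 1L
  i <- cell %% N_TYPES
  j <- (cell %/% N_TYPES) %% N_TYPES
  o <- cell %/% (N_TYPES^2)
  paste(AA_THREE[i + 1], AA_THREE[j + 1], orient_dimnames(oriented)[o + 1],
        sep = ", ")
}

#' Derive a potential from training chains
#'
#' Convenience pipeline: accumulate counts over the chains, build the
#' reference state implied by the variant (classic averaging, or the exact /
#' Monte Carlo shuffled reference), and invert to an energy table.
#'
#' @param chains List of [chain_model()]s (already filtered).
#' @param variant One of `"RF_CB"`, `"RF_CB_OD"`, `"RF_CB_SRS"`,
#'   `"RF_CB_SRS_OD"`.
#' @param binning A [distance_binning()].
#' @param sigma Sippl smoothing weight; default 1/50.
#' @param srs_method `"exact"` (default) or `"mc"` for the SRS variants.
#' @param n_shuffles,seed Monte Carlo parameters when `srs_method = "mc"`
#'   (defaults 1000 shuffles).
#' @return An [energy_table()].
#' @export
train_potential <- function(chains, variant = "RF_CB_SRS_OD",
                            binning = distance_binning(), sigma = 1 / 50,
                            srs_method = c("exact", "mc"),
                            n_shuffles = 1000L, seed = 1L) {
  variant <- match.arg(variant, VARIANTS)
  srs_method <- match.arg(srs_method)
  oriented <- variant_oriented(variant)
  obs <- accumulate_counts_all(chains, binning, oriented)
  expected <- if (!variant_srs(variant)) {
    classic_reference(obs)
  } else if (srs_method == "exact") {
    shuffled_reference_exact(chains, binning, oriented)
  } else {
    shuffled_reference_mc(chains, binning, oriented, n_shuffles, seed)
  }
  build_energy_table(obs, expected, smoothing_params(sigma), variant)
}

#' Score a protein model with an energy table
#'
#' Sums table energies over all ordered residue pairs with in-range C-beta
#' distance; out-of-range and degenerate pairs are skipped and tallied so
#' that `n_pairs_scored + n_pairs_skipped` equals the number of ordered
#' pairs n(n-1).
#'
#' @param chain A [chain_model()].
#' @param table An [energy_table()].
#' @return Object of class `ModelScore`: `total_energy` (kT),
#'   `n_pairs_scored`, `n_pairs_skipped`.
#' @export
score_model <- function(chain, table) {
  stopifnot(inherits(chain, "ChainModel"), inherits(table, "EnergyTable"))
  n <- length(chain)
  total_pairs <- n * (n - 1L)
  if (n < 2) {
    return(structure(list(total_energy = 0, n_pairs_scored = 0L,
                          n_pairs_skipped = 0L), class = "ModelScore"))
  }
  geo <- chain_pair_geometry(chain, table$binning)
  ti <- aa_index(chain$types)
  no <- orient_dim(table$oriented)
  o <- if (table$oriented) geo$cls else rep(1L, length(geo$i))
  lin <- ti[geo$i] + N_TYPES * (ti[geo$j] - 1L) +
    N_TYPES^2 * (o - 1L) + N_TYPES^2 * no * geo$bin
  scored <- length(lin)
  structure(
    list(total_energy = sum(table$energy[lin]),
         n_pairs_scored = scored,
         n_pairs_skipped = total_pairs - scored),
    class = "ModelScore"
  )
}

#' @export
print.ModelScore <- function(x, ...) {
  cat(sprintf("ModelScore: %.3f kT over %d pairs (%d skipped)\n",
              x$total_energy, x$n_pairs_scored, x$n_pairs_skipped))
  invisible(x)
}

#' Write an energy table to tabular text
#'
#' Self-describing format: `#key<TAB>value` header recording variant,
#' binning, smoothing and provenance, then one row per cell
#' (type_i, type_j, orientation, bin_lo, bin_hi, energy).
#'
#' @param table An [energy_table()].
#' @param path Output path.
#' @export
write_energy_table <- function(table, path) {
  b <- table$binning
  hdr <- header_kv(
    format = "srspot_energy_v1",
    variant = table$variant,
    first_bin_upper = b$first_bin_upper,
    bin_width = b$bin_width,
    max_distance = b$max_distance,
    sigma = format(table$smoothing$sigma, digits = 17),
    n_chains = table$provenance$n_chains,
    method = table$provenance$method,
    n_shuffles = table$provenance$n_shuffles,
    seed = table$provenance$seed
  )
  edges <- bin_edges(b)
  no <- orient_dim(table$oriented)
  idx <- expand.grid(i = seq_len(N_TYPES), j = seq_len(N_TYPES),
                     o = seq_len(no), b = seq_len(b$n_bins))
  df <- data.frame(
    type_i = AA_THREE[idx$i], type_j = AA_THREE[idx$j],
    orientation = orient_dimnames(table$oriented)[idx$o],
    bin_lo = edges[idx$b], bin_hi = edges[idx$b + 1L],
    energy = format(table$energy[as.matrix(idx)], digits = 17)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Read an energy table written by [write_energy_table()]
#' @param path Input path.
#' @return An [energy_table()].
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  kv <- parse_header_kv(lines)
  if (is.na(kv["format"]) || !identical(unname(kv["format"]), "srspot_energy_v1")) {
    stop("unsupported format version: ", kv["format"])
  }
  variant <- match.arg(kv[["variant"]], VARIANTS)
  binning <- distance_binning(
    as.numeric(kv["first_bin_upper"]), as.numeric(kv["bin_width"]),
    as.numeric(kv["max_distance"])
  )
  oriented <- variant_oriented(variant)
  body <- lines[!startsWith(lines, "#")]
  df <- tryCatch(
    read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop("malformed energy table body: ", conditionMessage(e))
  )
  n_expect <- N_TYPES^2 * orient_dim(oriented) * binning$n_bins
  if (nrow(df) != n_expect) {
    stop("row count mismatch: declared binning implies ", n_expect,
         " rows, found ", nrow(df))
  }
  if (anyNA(suppressWarnings(as.numeric(df$energy)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$energy))))[1]
    stop("malformed energy value at body row ", bad)
  }
  df$energy <- as.numeric(df$energy)
  energy <- array(0, count_dims(binning, oriented))
  oi <- match(df$orientation, orient_dimnames(oriented))
  if (anyNA(oi)) stop("malformed orientation label in energy table")
  bi <- distance_bin(df$bin_lo + 1e-9, binning) + 1L
  energy[cbind(aa_index(df$type_i), aa_index(df$type_j), oi, bi)] <- df$energy
  energy_table(
    energy, variant, binning,
    smoothing = smoothing_params(as.numeric(kv["sigma"])),
    provenance = list(
      n_chains = suppressWarnings(as.integer(kv["n_chains"])),
      method = unname(kv["method"]),
      n_shuffles = suppressWarnings(as.integer(kv["n_shuffles"])),
      seed = suppressWarnings(as.integer(kv["seed"]))
    )
  )
}
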