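# Synthetic chains, interacting ensembles with known ground-truth pair
# energies (for potential-recovery oracles), and synthetic decoy benchmarks.

#' Default synthetic composition
#'
#' Uniform over a subset of the 20-letter alphabet (default: all 20).
#' @param types Character vector of three-letter codes.
#' @return Named probability vector over [AA_THREE] members.
#' @export
uniform_composition <- function(types = AA_THREE) {
  stopifnot(all(types %in% AA_THREE))
  stats::setNames(rep(1 / length(types), length(types)), types)
}

#' Generate a compact synthetic chain
#'
#' Places n C-beta centers by self-avoiding random placement (hard-core
#' minimum distance `min_dist`) inside a sphere whose radius gives a
#' protein-like point density, so the mean nearest-neighbour C-beta distance
#' comes out near 5 A. C-alpha sits 1.53 A from each C-beta in a random
#' direction (optionally biased toward +z so orientation-dependent variants
#' have recoverable signal). Types are drawn from `composition`.
#'
#' @param n Number of residues (>= 2).
#' @param composition Named probability vector over residue types.
#' @param seed Optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @param min_dist Hard-core minimum C-beta distance (A); default 4.
#' @param density Point density (residues per cubic A); default 0.006,
#'   protein-like.
#' @param orientation_bias Probability in `[0, 1]` that a residue's
#'   Ca->Cb direction is the +z axis instead of uniform; default 0.
#' @param chain_id Chain identifier.
#' @param max_tries Placement attempts per residue before giving up.
#' @return A [chain_model()] (metadata marks the chain as synthetic but
#'   carries filter-passing values so the training pipeline runs end to end).
#' @export
generate_chain <- function(n, composition = uniform_composition(), seed = NULL,
                           min_dist = 4.0, density = 0.006,
                           orientation_bias = 0, chain_id = "SYN",
                           max_tries = 5000L) {
  stopifnot(n >= 2, abs(sum(composition) - 1) < 1e-6)
  if (!is.null(seed)) set.seed(seed)
  radius <- (3 * n / (4 * pi * density))^(1 / 3)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- rnorm(3)
      p <- u / sqrt(sum(u^2)) * radius * runif(1)^(1 / 3)
      if (i == 1 ||
          min(sqrt(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - p)^2))) >= min_dist) {
        pts[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible density: could not place residue ", i)
  }
  types <- sample(names(composition), n, replace = TRUE, prob = composition)
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  biased <- runif(n) < orientation_bias
  dirs[biased, ] <- matrix(rep(c(0, 0, 1), sum(biased)), ncol = 3, byrow = TRUE)
  ca <- pts - 1.53 * dirs  # Ca -> Cb direction is `dirs`
  chain_model(
    chain_id, types, ca, pts,
    metadata = list(resolution = 1.5, r_value = 0.15,
                    experimental_method = "X-RAY DIFFRACTION (SYNTHETIC)")
  )
}

#' Ground truth for the potential-recovery oracle
#'
#' Known pair energies driving the Gibbs label dynamics of
#' [generate_interacting_ensemble()], plus the generating composition and
#' ensemble dimensions.
#'
#' @param pair_energy Finite numeric array `(20, 20, n_orient, n_bins)`
#'   (kT), symmetric in its first two indices; `n_orient` 1 or 3.
#' @param composition Named probability vector over residue types.
#' @param chain_length Residues per chain.
#' @param n_chains Number of chains.
#' @param seed Integer seed.
#' @param binning A [distance_binning()] matching the last dimension.
#' @return Object of class `GroundTruth`.
#' @export
ground_truth <- function(pair_energy, composition, chain_length, n_chains,
                         seed, binning = distance_binning()) {
  d <- dim(pair_energy)
  stopifnot(
    length(d) == 4, d[1] == N_TYPES, d[2] == N_TYPES,
    d[3] %in% c(1L, 3L), d[4] == binning$n_bins,
    all(is.finite(pair_energy)),
    chain_length >= 2, n_chains >= 1,
    abs(sum(composition) - 1) < 1e-6
  )
  if (max(abs(pair_energy - aperm(pair_energy, c(2, 1, 3, 4)))) > 1e-9) {
    stop("pair_energy must be symmetric in (type_i, type_j)")
  }
  structure(
    list(pair_energy = pair_energy, composition = composition,
         chain_length = as.integer(chain_length),
         n_chains = as.integer(n_chains), seed = as.integer(seed),
         binning = binning, oriented = d[3] == 3L),
    class = "GroundTruth"
  )
}

#' Sparse helper to build a ground-truth energy array
#'
#' @param entries Data frame with columns `type_i`, `type_j`, `bin`
#'   (0-based), `energy`, and optionally `orientation` (label or "ALL").
#'   Entries are applied symmetrically in (type_i, type_j).
#' @param binning A [distance_binning()].
#' @param oriented Logical; `FALSE` gives a single orientation slot.
#' @return Energy array suitable for [ground_truth()].
#' @export
ground_truth_energy <- function(entries, binning = distance_binning(),
                                oriented = FALSE) {
  a <- array(0, count_dims(binning, oriented))
  for (r in seq_len(nrow(entries))) {
    i <- aa_index(entries$type_i[r]); j <- aa_index(entries$type_j[r])
    o <- if (oriented && !is.null(entries$orientation)) {
      match(entries$orientation[r], ORIENT_LABELS)
    } else seq_len(orient_dim(oriented))
    b <- entries$bin[r] + 1L
    a[i, j, o, b] <- entries$energy[r]
    a[j, i, o, b] <- entries$energy[r]
  }
  a
}

# Shared core: run the label-swap sampler on one chain's fixed geometry.
# The Hamiltonian counts each unordered contact once: because the pair list
# is ordered (both directions present) and the truth is symmetric, this is
# half the ordered-pair sum, so the Boltzmann enrichment of a single contact
# is exp(-E) and recovered per-ordered-pair energies match the truth 1:1.
run_label_sampler <- function(chain, pair_energy, binning, oriented,
                              burnin_sweeps, n_samples, sample_every) {
  geo <- chain_pair_geometry(chain, binning)
  o <- if (oriented) geo$cls else rep(1L, length(geo$i))
  no <- if (oriented) 3L else 1L
  off <- N_TYPES^2 * ((o - 1L) + no * geo$bin)
  gibbs_label_swap_cpp(
    aa_index(chain$types) - 1L, geo$i - 1L, geo$j - 1L, off,
    as.numeric(pair_energy) / 2, N_TYPES,
    as.integer(burnin_sweeps), as.integer(n_samples), as.integer(sample_every)
  )
}

#' Hamiltonian of a label arrangement under ground-truth pair energies
#'
#' The energy targeted by the label-swap sampler: half the sum over ordered
#' in-range pairs of `pair_energy[type_i, type_j, class(i->j), bin]`, i.e.
#' each unordered contact counted once (directional slots averaged for
#' orientation-dependent truths). Used by detailed-balance oracles.
#'
#' @param chain A [chain_model()] providing the fixed geometry.
#' @param pair_energy Energy array `(20, 20, n_orient, n_bins)`.
#' @param binning A [distance_binning()].
#' @param types Optional label vector overriding `chain$types`.
#' @return Scalar energy (kT).
#' @export
label_energy <- function(chain, pair_energy, binning = distance_binning(),
                         types = chain$types) {
  oriented <- dim(pair_energy)[3] == 3L
  geo <- chain_pair_geometry(chain, binning)
  o <- if (oriented) geo$cls else rep(1L, length(geo$i))
  no <- if (oriented) 3L else 1L
  ti <- aa_index(types)
  lin <- ti[geo$i] + N_TYPES * (ti[geo$j] - 1L) +
    N_TYPES^2 * (o - 1L) + N_TYPES^2 * no * geo$bin
  sum(pair_energy[lin]) / 2
}

#' Sample label arrangements of one chain from the Boltzmann distribution
#'
#' Runs the composition-preserving label-swap Metropolis chain on the fixed
#' coordinates of `chain`, targeting P(labels) proportional to
#' exp(-sum over ordered in-range pairs of pair_energy), and returns
#' post-burn-in label snapshots. Used for detailed-balance checks.
#'
#' @param chain A [chain_model()].
#' @param pair_energy Energy array `(20, 20, n_orient, n_bins)`.
#' @param binning A [distance_binning()].
#' @param burnin_sweeps Sweeps before sampling (each sweep proposes n swaps).
#' @param n_samples Number of snapshots.
#' @param sample_every Sweeps between snapshots.
#' @return Integer matrix `n_samples x n` of 1-based type indices, with
#'   attribute `"acceptance_rate"`.
#' @export
sample_label_ensemble <- function(chain, pair_energy,
                                  binning = distance_binning(),
                                  burnin_sweeps = 100L, n_samples = 1000L,
                                  sample_every = 1L) {
  oriented <- dim(pair_energy)[3] == 3L
  res <- run_label_sampler(chain, pair_energy, binning, oriented,
                           burnin_sweeps, n_samples, sample_every)
  out <- res$samples + 1L
  attr(out, "acceptance_rate") <- res$acceptance_rate
  out
}

#' Generate an interacting ensemble with known pair energies
#'
#' For each chain, coordinates come from [generate_chain()]; type labels are
#' then re-equilibrated by composition-preserving label-swap Metropolis
#' sweeps targeting the Boltzmann distribution of the ground-truth pair
#' energies. Because swaps preserve each chain's composition, the Shuffled
#' Reference State conditions on exactly the generator's null, making
#' energy recovery a clean oracle.
#'
#' @param truth A [ground_truth()].
#' @param burnin_sweeps Equilibration sweeps per chain; default 300.
#' @param density,min_dist,orientation_bias Passed to [generate_chain()].
#' @return List of [chain_model()]s with attribute `"diagnostics"` (mean
#'   acceptance rate).
#' @export
generate_interacting_ensemble <- function(truth, burnin_sweeps = 300L,
                                          density = 0.006, min_dist = 4.0,
                                          orientation_bias = 0) {
  stopifnot(inherits(truth, "GroundTruth"))
  set.seed(truth$seed)
  chains <- vector("list", truth$n_chains)
  acc <- numeric(truth$n_chains)
  for (k in seq_len(truth$n_chains)) {
    ch <- generate_chain(truth$chain_length, truth$composition, seed = NULL,
                         min_dist = min_dist, density = density,
                         orientation_bias = orientation_bias,
                         chain_id = sprintf("SYN%04d", k))
    res <- run_label_sampler(ch, truth$pair_energy, truth$binning,
                             truth$oriented, burnin_sweeps, 0L, 1L)
    ch$types <- AA_THREE[res$types + 1L]
    acc[k] <- res$acceptance_rate
    chains[[k]] <- ch
  }
  attr(chains, "diagnostics") <- list(mean_acceptance_rate = mean(acc))
  chains
}

#' Generate a synthetic decoy benchmark
#'
#' Draws per-target GDT_TS values in `quality_range` (guaranteeing at least
#' one model at 65 or better, the admission rule for real decoy sets) and
#' energies with a controllable energy-quality correlation:
#' `energy = -rho * standardized(GDT_TS) + sqrt(1 - rho^2) * noise`.
#'
#' @param n_targets Number of targets.
#' @param models_per_target Models per target.
#' @param quality_range GDT_TS range, upper bound >= 65.
#' @param rho Target energy-quality (anti)correlation in `[-1, 1]`; at
#'   rho = 1 the lowest energy always picks the best model.
#' @param seed Integer seed.
#' @param include_native Add a native record (GDT_TS 100) per target.
#' @return List with `sets` (list of [decoy_set()]s) and `energies` (data
#'   frame `target_id`, `model_id`, `energy`).
#' @export
generate_decoy_benchmark <- function(n_targets, models_per_target,
                                     quality_range = c(40, 90), rho = 1,
                                     seed = 1L, include_native = FALSE) {
  stopifnot(rho >= -1, rho <= 1, models_per_target >= 2,
            quality_range[2] >= 65)
  set.seed(seed)
  sets <- vector("list", n_targets)
  energies <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    tid <- sprintf("T%03d", t)
    g <- runif(models_per_target, quality_range[1], quality_range[2])
    if (max(g) < 65) g[which.max(g)] <- runif(1, 65, quality_range[2])
    ids <- sprintf("%s_M%02d", tid, seq_along(g))
    z <- (g - mean(g)) / stats::sd(g)
    e <- -rho * z + sqrt(1 - rho^2) * rnorm(length(g))
    if (include_native) {
      zn <- (100 - mean(g)) / stats::sd(g)
      ids <- c(ids, paste0(tid, "_native"))
      g <- c(g, 100)
      e <- c(e, -rho * zn + sqrt(1 - rho^2) * rnorm(1))
      nat <- c(rep(FALSE, length(g) - 1), TRUE)
    } else {
      nat <- rep(FALSE, length(g))
    }
    sets[[t]] <- decoy_set(tid, ids, g, nat)
    energies[[t]] <- data.frame(target_id = tid, model_id = ids, energy = e,
                                stringsAsFactors = FALSE)
  }
  list(sets = sets, energies = do.call(rbind, energies))
}
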