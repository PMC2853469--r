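# Decoy-evaluation machinery: GDT_TS combination, 2.5-unit binned ranking
# with the native-present rank-2 rule, summary statistics, decoy-set
# selection filters, and pairwise one-tailed Wilcoxon comparisons.

#' GDT_TS from its four cutoff percentages
#'
#' `(GDT_P1 + GDT_P2 + GDT_P4 + GDT_P8) / 4`, where GDT_Pn is the percent of
#' residues superposable under a distance cutoff of n angstroms. The percents
#' must be non-decreasing in the cutoff.
#'
#' @param p1,p2,p4,p8 Percentages in `[0, 100]` with `p1 <= p2 <= p4 <= p8`.
#' @return GDT_TS score in `[0, 100]`. Vectorised.
#' @export
gdt_ts <- function(p1, p2, p4, p8) {
  v <- cbind(p1, p2, p4, p8)
  if (any(v < 0 | v > 100)) stop("GDT_Pn percentages must lie in [0, 100]")
  if (any(p1 > p2 | p2 > p4 | p4 > p8)) {
    stop("inconsistent cutoff percents: GDT_P1 <= GDT_P2 <= GDT_P4 <= GDT_P8 required")
  }
  (p1 + p2 + p4 + p8) / 4
}

#' Construct a DecoySet
#'
#' One target's models with GDT_TS values and an optional native entry
#' (at most one; natives have GDT_TS 100 by definition).
#'
#' @param target_id Target identifier.
#' @param model_id Character vector of model identifiers (unique).
#' @param gdt_ts Numeric GDT_TS scores in `[0, 100]`.
#' @param is_native Logical vector; at most one `TRUE`.
#' @return Object of class `DecoySet` with a `records` data frame.
#' @export
decoy_set <- function(target_id, model_id, gdt_ts, is_native = rep(FALSE, length(model_id))) {
  stopifnot(
    length(model_id) == length(gdt_ts), length(model_id) == length(is_native),
    !anyDuplicated(model_id), all(gdt_ts >= 0 & gdt_ts <= 100)
  )
  if (sum(is_native) > 1) stop("at most one native record per decoy set")
  if (any(is_native) && any(gdt_ts[is_native] != 100)) {
    stop("native records have GDT_TS = 100 by definition")
  }
  if (sum(!is_native) < 1) stop("a decoy set needs at least one non-native model")
  structure(
    list(target_id = target_id,
         records = data.frame(model_id = as.character(model_id),
                              gdt_ts = gdt_ts, is_native = is_native,
                              stringsAsFactors = FALSE)),
    class = "DecoySet"
  )
}

#' @export
print.DecoySet <- function(x, ...) {
  cat(sprintf("DecoySet %s: %d models%s, GDT_TS %.1f-%.1f\n",
              x$target_id, sum(!x$records$is_native),
              if (any(x$records$is_native)) " + native" else "",
              min(x$records$gdt_ts), max(x$records$gdt_ts)))
  invisible(x)
}

#' GDT_TS-binned ranks within a decoy set
#'
#' Scores are binned in `bin_width` GDT_TS units anchored at the set's
#' highest GDT_TS (100 when the native is present); bin numbers are the
#' ranks, starting from 1 for models within `bin_width` of the top.
#'
#' @param set A [decoy_set()].
#' @param bin_width GDT_TS units per bin; default 2.5.
#' @return Named integer vector of ranks (by model_id).
#' @export
assign_ranks <- function(set, bin_width = 2.5) {
  g <- set$records$gdt_ts
  g_max <- max(g)
  ranks <- 1L + as.integer(floor((g_max - g) / bin_width + 1e-9))
  stats::setNames(ranks, set$records$model_id)
}

#' Rank of the minimum-energy selection
#'
#' Selects the lowest-energy record (ties broken by lexicographic model_id)
#' and returns its GDT_TS-binned rank.
#'
#' In `without_native` mode, the native (if any) is excluded and ranks come
#' from [assign_ranks()] over the models only. In `with_native` mode the
#' native competes: selecting it returns rank 1; selecting any model returns
#' 1 + its rank among the non-natives, so the best non-native gets rank 2
#' regardless of the number of empty bins separating it from the native.
#'
#' @param set A [decoy_set()].
#' @param energies Named numeric vector (by model_id) covering every record
#'   in scope; lower is better.
#' @param mode `"without_native"` (default) or `"with_native"`.
#' @param bin_width GDT_TS units per bin; default 2.5.
#' @return Integer rank (>= 1).
#' @export
rank_of_selection <- function(set, energies,
                              mode = c("without_native", "with_native"),
                              bin_width = 2.5) {
  mode <- match.arg(mode)
  rec <- set$records
  if (mode == "with_native" && !any(rec$is_native)) {
    stop("with_native mode requires a native record in the set")
  }
  scope <- if (mode == "with_native") rec else rec[!rec$is_native, , drop = FALSE]
  miss <- setdiff(scope$model_id, names(energies))
  if (length(miss)) {
    stop("energies missing for model(s): ", paste(miss, collapse = ", "))
  }
  e <- energies[scope$model_id]
  cand <- scope$model_id[e == min(e)]
  selected <- sort(cand)[1]

  nonnat <- rec[!rec$is_native, , drop = FALSE]
  sub <- decoy_set(set$target_id, nonnat$model_id, nonnat$gdt_ts)
  ranks_nn <- assign_ranks(sub, bin_width)
  if (mode == "without_native") {
    unname(ranks_nn[selected])
  } else if (rec$is_native[match(selected, rec$model_id)]) {
    1L
  } else {
    unname(ranks_nn[selected]) + 1L
  }
}

#' Summarize selection ranks over many decoy sets
#'
#' @param sets List of [decoy_set()]s.
#' @param energies Either a data frame with columns `target_id`, `model_id`,
#'   `energy`, or a named list of per-target named energy vectors.
#' @param mode `"without_native"` (default) or `"with_native"`.
#' @param bin_width GDT_TS units per bin; default 2.5.
#' @return Object of class `RankSummary`: `per_target_rank` (named),
#'   `average_rank`, `ranked_1_count` (targets whose selection has rank 1 in
#'   `without_native` mode, or whose native is selected in `with_native`
#'   mode), `mode`, `n_targets`.
#' @export
summarize_ranks <- function(sets, energies,
                            mode = c("without_native", "with_native"),
                            bin_width = 2.5) {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 1)
  get_e <- function(set) {
    if (is.data.frame(energies)) {
      sub <- energies[energies$target_id == set$target_id, , drop = FALSE]
      stats::setNames(sub$energy, sub$model_id)
    } else {
      energies[[set$target_id]]
    }
  }
  ranks <- vapply(sets, function(s) rank_of_selection(s, get_e(s), mode, bin_width), 1L)
  names(ranks) <- vapply(sets, `[[`, "", "target_id")
  structure(
    list(per_target_rank = ranks,
         average_rank = mean(ranks),
         ranked_1_count = sum(ranks == 1L),
         mode = mode, n_targets = length(sets)),
    class = "RankSummary"
  )
}

#' @export
print.RankSummary <- function(x, ...) {
  cat(sprintf("RankSummary (%s): average rank %.2f, ranked 1 in %d/%d targets\n",
              x$mode, x$average_rank, x$ranked_1_count, x$n_targets))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Paired one-tailed Wilcoxon signed-rank test

#' Paired one-tailed Wilcoxon signed-rank test (a lower than b)
#'
#' Tests the one-sided alternative that the paired values in `ranks_a` are
#' located lower than those in `ranks_b`. Zero differences are dropped
#' (classic treatment); tied absolute differences receive average ranks. For
#' up to 25 effective pairs the null distribution of the positive-rank sum
#' is enumerated exactly over all 2^n sign assignments; above that a normal
#' approximation with continuity and tie correction is used.
#'
#' @param ranks_a,ranks_b Paired numeric vectors of equal length.
#' @param exact_max Largest n for exact enumeration; default 25.
#' @return Object of class `WilcoxonResult`: `p_value`, `statistic` (W+),
#'   `n_effective`, `n_zeros`, `method`, `direction`.
#' @export
wilcoxon_one_tailed <- function(ranks_a, ranks_b, exact_max = 25L) {
  stopifnot(length(ranks_a) == length(ranks_b))
  d <- ranks_a - ranks_b
  d <- d[d != 0]
  n <- length(d)
  out <- list(p_value = 1, statistic = NA_real_, n_effective = n,
              n_zeros = length(ranks_a) - n, method = "degenerate",
              direction = "a_lower")
  if (n == 0) {
    warning("all paired differences are zero; no evidence of difference")
    return(structure(out, class = "WilcoxonResult"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signrank_exact_tail_cpp(r, w_pos)
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- pnorm((w_pos - mu + 0.5) / sqrt(sigma2))
    method <- "normal_approximation"
  }
  out$p_value <- min(max(p, 0), 1)
  out$statistic <- w_pos
  out$method <- method
  structure(out, class = "WilcoxonResult")
}

#' @export
print.WilcoxonResult <- function(x, ...) {
  cat(sprintf("Wilcoxon one-tailed (a lower): W+ = %s, n = %d, p = %.4g (%s)\n",
              format(x$statistic), x$n_effective, x$p_value, x$method))
  invisible(x)
}

#' Pairwise one-tailed Wilcoxon significance matrix
#'
#' Entry (r, c) is the one-tailed p-value that the per-target ranks of
#' scoring function r are lower than those of scoring function c.
#'
#' @param rank_lists Named list of per-target rank vectors, all aligned to
#'   the same targets.
#' @param blank_below Display threshold: in the formatted copy, p-values
#'   below it are blanked (only non-significant pairs shown, mirroring the
#'   usual display convention). Default 0.05.
#' @return Numeric matrix of p-values (diagonal `NA`) with attribute
#'   `"display"`: a character matrix with entries below `blank_below`
#'   blanked.
#' @export
significance_matrix <- function(rank_lists, blank_below = 0.05) {
  nm <- names(rank_lists)
  stopifnot(!is.null(nm), length(unique(lengths(rank_lists))) == 1)
  k <- length(rank_lists)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (r in seq_len(k)) for (c in seq_len(k)) {
    if (r == c) next
    p[r, c] <- suppressWarnings(
      wilcoxon_one_tailed(rank_lists[[r]], rank_lists[[c]])$p_value
    )
  }
  disp <- ifelse(is.na(p) | p < blank_below, "", sprintf("%.3f", p))
  dimnames(disp) <- dimnames(p)
  attr(p, "display") <- disp
  p
}

# ---------------------------------------------------------------------------
# Decoy-set selection

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Select a representative decoy set from candidate models
#'
#' Applies the four selection rules: (i) keep all-atom models only; (ii)
#' reject the target unless some model reaches GDT_TS `min_best_gdt` (65.0)
#' or better; (iii) keep the most populated length cluster (exact-length
#' grouping; ties keep the longer length); (iv) bin the survivors by GDT_TS
#' in `bin_width` increments and keep one seeded-random representative per
#' occupied bin.
#'
#' @param candidates Data frame with columns `model_id`, `gdt_ts`, `length`,
#'   and optionally `all_atom` (logical, default all `TRUE`).
#' @param seed Integer seed for the per-bin random representative.
#' @param target_id Target identifier for the resulting set.
#' @param min_best_gdt Admission threshold on the best model; default 65.
#' @param bin_width GDT_TS units per selection bin; default 2.5.
#' @return A list with `set` (a [decoy_set()], or `NULL` when rejected),
#'   `rejected` (logical) and `reason`.
#' @export
select_decoys <- function(candidates, seed, target_id = "target",
                          min_best_gdt = 65, bin_width = 2.5) {
  stopifnot(nrow(candidates) >= 1,
            all(c("model_id", "gdt_ts", "length") %in% names(candidates)))
  if (is.null(candidates$all_atom)) candidates$all_atom <- TRUE
  cand <- candidates[candidates$all_atom, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(set = NULL, rejected = TRUE, reason = "no_all_atom_models"))
  }
  if (max(cand$gdt_ts) < min_best_gdt) {
    return(list(set = NULL, rejected = TRUE, reason = "best_model_below_threshold"))
  }
  sizes <- table(cand$length)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  keep_len <- max(best)  # tie between equally populated clusters -> longer
  cand <- cand[cand$length == keep_len, , drop = FALSE]
  bins <- floor(cand$gdt_ts / bin_width)
  picks <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(cand)), bins), function(ix) {
      ix[sample.int(length(ix), 1)]
    }), use.names = FALSE)
  })
  picks <- sort(picks)
  list(
    set = decoy_set(target_id, cand$model_id[picks], cand$gdt_ts[picks]),
    rejected = FALSE, reason = NA_character_
  )
}

# ---------------------------------------------------------------------------
# Manifest and score-file I/O

#' Write decoy sets as a tab-separated manifest
#' @param sets List of [decoy_set()]s.
#' @param path Output path.
#' @export
write_decoy_manifest <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    cbind(target_id = s$target_id, s$records)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a decoy manifest written by [write_decoy_manifest()]
#' @param path Input path.
#' @return Named list of [decoy_set()]s (by target_id).
#' @export
read_decoy_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "model_id", "gdt_ts")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$is_native)) df$is_native <- FALSE
  sets <- lapply(split(df, df$target_id), function(sub) {
    decoy_set(sub$target_id[1], sub$model_id, sub$gdt_ts, as.logical(sub$is_native))
  })
  sets[unique(df$target_id)]
}

#' Write a score file (model_id, energy, n_pairs_scored)
#' @param df Data frame with at least `model_id` and `energy`.
#' @param path Output path.
#' @export
write_score_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a score file written by [write_score_file()]
#' @param path Input path.
#' @return Data frame with `model_id`, `energy` (and extra columns).
#' @export
read_score_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("model_id", "energy") %in% names(df))) {
    stop("score file must have columns model_id and energy")
  }
  df
}
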