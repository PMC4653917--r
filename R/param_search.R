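#' Exhaustive grid search over decision parameters
#'
#' Re-runs the model-selection procedure: enumerate every combination of
#' candidate decision parameters (and initial-position rule), simulate a
#' cohort for each, summarise it with the behavior statistics, and score the
#' summary against reference statistics. The published selection explored
#' alpha_c (0.125, 0.25, 0.5), beta_c (2.8, 3.3, 3.8, 4.3), alpha_r (0.125,
#' 0.25, 0.5), beta_r = beta_c - (0.4, 0.8, 1.2, 1.6), phi_c (30, 60, 80),
#' dphi_c (10, 30, 60) and initial positions below -3, -2 or -1 mm, with
#' 3000 model worms per combination.
#'
#' @name param_search
NULL

#' Candidate parameter grid
#'
#' Finite value lists for each decision parameter; `beta_r_offset` is applied
#' as `beta_r = beta_c - offset`. Defaults are the published grid (the full
#' Cartesian product has 3 * 4 * 3 * 4 * 3 * 3 * 3 = 3888 combinations).
#'
#' @param alpha_c,beta_c,alpha_r,phi_c,dphi_c Numeric vectors of candidate
#'   values.
#' @param beta_r_offset Positive offsets subtracted from `beta_c`.
#' @param init_x_max Upper bounds (exclusive, mm, < 0) for the initial
#'   position; each is used with `init_x_min = init_x_max - 1`.
#' @return A `parameter_grid` object.
#' @export
parameter_grid <- function(alpha_c = c(0.125, 0.25, 0.5),
                           beta_c = c(2.8, 3.3, 3.8, 4.3),
                           alpha_r = c(0.125, 0.25, 0.5),
                           beta_r_offset = c(0.4, 0.8, 1.2, 1.6),
                           phi_c = c(30, 60, 80),
                           dphi_c = c(10, 30, 60),
                           init_x_max = c(-3, -2, -1)) {
  lists <- list(
    alpha_c = alpha_c, beta_c = beta_c, alpha_r = alpha_r,
    beta_r_offset = beta_r_offset, phi_c = phi_c, dphi_c = dphi_c,
    init_x_max = init_x_max
  )
  for (nm in names(lists)) {
    if (!length(lists[[nm]]) || !is.numeric(lists[[nm]])) {
      stop(sprintf("`%s` must be a non-empty numeric vector", nm),
        call. = FALSE
      )
    }
  }
  if (any(beta_r_offset <= 0)) {
    stop("`beta_r_offset` values must be positive", call. = FALSE)
  }
  structure(lists, class = "parameter_grid")
}

#' Enumerate a parameter grid
#'
#' Full Cartesian product of the candidate lists in deterministic
#' lexicographic order (the first field varies slowest, in the order the
#' value lists are given).
#'
#' @param grid A `parameter_grid`.
#' @return A data frame with one row per combination: `alpha_c`, `beta_c`,
#'   `alpha_r`, `beta_r_offset`, `beta_r`, `phi_c`, `dphi_c`, `init_x_max`;
#'   the number of combinations is `nrow()`.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  # expand.grid varies the first factor fastest; feed fields reversed so the
  # first grid field varies slowest (lexicographic order)
  df <- expand.grid(rev(unclass(grid)), KEEP.OUT.ATTRS = FALSE)
  df <- df[, rev(names(df)), drop = FALSE]
  df$beta_r <- df$beta_c - df$beta_r_offset
  rownames(df) <- NULL
  df[, c(
    "alpha_c", "beta_c", "alpha_r", "beta_r_offset", "beta_r",
    "phi_c", "dphi_c", "init_x_max"
  )]
}

#' Reference summary statistics for scoring
#'
#' Bundles the statistics a candidate cohort is compared against: the
#' angle-binned reversal ratios, the per-maneuver distance summaries and the
#' overall reversal fraction.
#'
#' @param events A collapsed event table.
#' @param width,min_count Binning options passed to [bin_choice_ratio()].
#' @param bin Distance bin width passed to [distance_summary()].
#' @return A `reference_stats` list with `choice`, `distance`,
#'   `reversal_fraction`, `n_events`.
#' @export
reference_stats <- function(events, width = 10, min_count = 15, bin = 0.2) {
  events <- drop_step_capped(events)
  structure(
    list(
      choice = suppressWarnings(
        bin_choice_ratio(events, width = width, min_count = min_count)
      ),
      distance = distance_summary(events, bin = bin),
      reversal_fraction = if (nrow(events)) {
        mean(events$maneuver == "reversal")
      } else {
        NA_real_
      },
      n_events = nrow(events)
    ),
    class = "reference_stats"
  )
}

#' Score candidate statistics against a reference
#'
#' Weighted mismatch score (lower is better, 0 only for a perfect
#' statistical match):
#' `w_ratio * RMSE(binned reversal ratios over bins unflagged in both)` +
#' `w_mean_rev * |difference of mean reversal distances|` +
#' `w_mean_curve * |difference of mean curve distances|` +
#' `w_rev_frac * |difference of overall reversal fractions|`.
#' A candidate missing a maneuver class present in the reference scores
#' `Inf`.
#'
#' @param candidate,ref `reference_stats` objects (see [reference_stats()]).
#' @param weights Named numeric vector with entries `ratio`, `mean_rev`,
#'   `mean_curve`, `rev_frac` (default all 1).
#' @return Non-negative score.
#' @export
score_params <- function(candidate, ref,
                         weights = c(
                           ratio = 1, mean_rev = 1,
                           mean_curve = 1, rev_frac = 1
                         )) {
  w <- c(ratio = 1, mean_rev = 1, mean_curve = 1, rev_frac = 1)
  w[names(weights)] <- weights
  if (all(w == 0)) {
    warning("all weights are zero; the score is degenerate", call. = FALSE)
  }
  cb <- candidate$choice$bins
  rb <- ref$choice$bins
  keep <- !cb$flagged & !rb$flagged
  if (!any(keep)) {
    stop("no bins are unflagged in both candidate and reference; ",
      "score undefined",
      call. = FALSE
    )
  }
  dr <- cb$reversal_ratio[keep] - rb$reversal_ratio[keep]
  # an unflagged bin with no events at all counts as a total mismatch
  rmse <- if (anyNA(dr)) Inf else sqrt(mean(dr^2))
  d_mean <- function(cls) {
    m_ref <- ref$distance[[cls]]$mean
    m_can <- candidate$distance[[cls]]$mean
    if (is.na(m_ref)) {
      return(0) # class absent from the reference: nothing to match
    }
    if (is.na(m_can)) {
      return(Inf)
    }
    abs(m_can - m_ref)
  }
  w[["ratio"]] * rmse +
    w[["mean_rev"]] * d_mean("reversal") +
    w[["mean_curve"]] * d_mean("curve") +
    w[["rev_frac"]] * abs(
      candidate$reversal_fraction - ref$reversal_fraction
    )
}

#' Run the grid search
#'
#' For every combination in the grid: simulate a cohort of `n_per_combo`
#' model worms, summarise it, and score it against the reference statistics.
#' Combinations whose cohorts are entirely step-capped score `Inf` with a
#' warning. Fully reproducible under the master seed: per-combination seeds
#' are drawn once from the master seed, and each cohort derives per-trial
#' seeds from its own.
#'
#' @param grid A `parameter_grid`.
#' @param field A `gradient_field`.
#' @param cfg A `sim_config`; its `init_x_max`/`init_x_min` are overridden
#'   per combination.
#' @param ref A `reference_stats` object.
#' @param n_per_combo Trials per combination (default 3000, the published
#'   cohort size).
#' @param seed Master seed.
#' @param weights Passed to [score_params()].
#' @return A data frame (one row per combination, best score first) with the
#'   parameter columns of [enumerate_grid()] plus `score`,
#'   `reversal_fraction`, `mean_dist_reversal`, `mean_dist_curve`,
#'   `pearson_r`, `n_escaped`, and the original combination index `combo`.
#' @export
grid_search <- function(grid, field, cfg, ref, n_per_combo = 3000, seed = 1,
                        weights = c(
                          ratio = 1, mean_rev = 1,
                          mean_curve = 1, rev_frac = 1
                        )) {
  stopifnot(inherits(ref, "reference_stats"))
  combos <- enumerate_grid(grid)
  if (n_per_combo < 30) {
    warning("n_per_combo < 30: scores will be unstable", call. = FALSE)
  }
  set.seed(as.integer(seed))
  combo_seeds <- sample.int(2^30, nrow(combos))
  res <- combos
  res$combo <- seq_len(nrow(combos))
  res$score <- NA_real_
  res$reversal_fraction <- NA_real_
  res$mean_dist_reversal <- NA_real_
  res$mean_dist_curve <- NA_real_
  res$pearson_r <- NA_real_
  res$n_escaped <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    p <- decision_params(
      alpha_c = combos$alpha_c[i], beta_c = combos$beta_c[i],
      alpha_r = combos$alpha_r[i], beta_r = combos$beta_r[i],
      phi_c = combos$phi_c[i], dphi_c = combos$dphi_c[i]
    )
    cfg_i <- cfg
    cfg_i$init_x_max <- combos$init_x_max[i]
    cfg_i$init_x_min <- combos$init_x_max[i] - 1
    ev <- run_cohort(n_per_combo, field, p, cfg_i, seed = combo_seeds[i])
    esc <- ev[ev$terminated == "escaped", , drop = FALSE]
    res$n_escaped[i] <- nrow(esc)
    if (nrow(esc) == 0L) {
      warning(sprintf("combination %d: all trials step-capped", i),
        call. = FALSE
      )
      res$score[i] <- Inf
      next
    }
    cand <- reference_stats(esc,
      width = 10, min_count = ref$choice$min_count, bin = 0.2
    )
    res$score[i] <- score_params(cand, ref, weights)
    res$reversal_fraction[i] <- cand$reversal_fraction
    res$mean_dist_reversal[i] <- cand$distance$reversal$mean
    res$mean_dist_curve[i] <- cand$distance$curve$mean
    res$pearson_r[i] <- cand$choice$pearson_r
  }
  res[order(res$score, res$combo), , drop = FALSE]
}
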