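#' Avoidance-behavior statistics
#'
#' Descriptive and inferential statistics over avoidance-event tables
#' (simulated or real-worm style): collapsing the four observed maneuver
#' classes into reversal vs curve, keeping only the first event of a serial
#' avoidance run, angle-binned choice ratios with a Pearson correlation,
#' distance histograms, and the F / Student's t comparisons of variances and
#' means.
#'
#' An event table is a data frame with at least `maneuver`, `angle_deg`
#' (acute encounter angle in degrees, 0-90) and `distance_mm` (signed
#' distance from the acidic border); optional columns include `worm_id`,
#' `time_s`, `sequence_index` and the simulator's `terminated` flag.
#'
#' @name behavior_stats
NULL

.reversal_labels <- c("long_reversal", "short_reversal", "reversal")
.curve_labels <- c("gradual_curve", "deep_curve", "curve")

# drop step-capped simulator rows before computing statistics
drop_step_capped <- function(events, include_step_cap = FALSE) {
  if (!include_step_cap && "terminated" %in% names(events)) {
    events <- events[events$terminated == "escaped", , drop = FALSE]
  }
  events
}

#' Collapse maneuver subtypes into reversal vs curve
#'
#' Long and short reversal are collectively reversal avoidance; gradual and
#' deep curve are collectively curve avoidance. Already-collapsed labels pass
#' through, so the operation is idempotent.
#'
#' @param events An event table with a `maneuver` column.
#' @return The table with `maneuver` in `{"reversal", "curve"}`.
#' @export
collapse_maneuvers <- function(events) {
  m <- events$maneuver
  known <- m %in% c(.reversal_labels, .curve_labels) | is.na(m)
  if (!all(known)) {
    bad <- which(!known)
    stop(
      sprintf(
        "unknown maneuver label(s) %s at row(s) %s",
        paste(unique(m[bad]), collapse = ", "),
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  events$maneuver <- ifelse(m %in% .reversal_labels, "reversal",
    ifelse(m %in% .curve_labels, "curve", m)
  )
  events
}

#' Keep only the first event of each serial avoidance run
#'
#' After a failed escape, worms repeat avoidance maneuvers; only the first
#' occurrence of such a serial run enters the statistics.
#'
#' @param events An event table with a `sequence_index` column (1 = first of
#'   a run).
#' @return The filtered table.
#' @export
first_occurrence_filter <- function(events) {
  if (!"sequence_index" %in% names(events)) {
    stop("`events` must have a `sequence_index` column", call. = FALSE)
  }
  events[events$sequence_index == 1, , drop = FALSE]
}

#' Angle-binned choice ratio and its correlation with the encounter angle
#'
#' Bins events by encounter angle (default every 10 degrees over 0-90;
#' half-open bins, last bin closed) and computes the per-bin reversal ratio
#' reversal / (reversal + curve). Bins with fewer than `min_count` events are
#' flagged and excluded from the Pearson correlation between bin midpoints
#' and reversal ratio (two-sided p from the t transform with k - 2 df over
#' the unflagged bins).
#'
#' @param events A collapsed event table (`maneuver` in reversal/curve).
#' @param width Bin width in degrees (default 10).
#' @param min_count Minimum events per bin for inclusion in the correlation
#'   (default 15).
#' @param include_step_cap Include step-capped simulator rows (default FALSE).
#' @return A `choice_summary` list: `bins` (data frame with `lo`, `hi`,
#'   `mid`, `n_reversal`, `n_curve`, `n`, `reversal_ratio`, `flagged`),
#'   `pearson_r`, `p_value`, `n_events`.
#' @export
bin_choice_ratio <- function(events, width = 10, min_count = 15,
                             include_step_cap = FALSE) {
  events <- drop_step_capped(events, include_step_cap)
  if (nrow(events) &&
    !all(events$maneuver %in% c("reversal", "curve"))) {
    stop(
      "events must be collapsed to reversal/curve first ",
      "(see collapse_maneuvers())",
      call. = FALSE
    )
  }
  if (nrow(events) && any(events$angle_deg < 0 | events$angle_deg > 90)) {
    stop("`angle_deg` must lie in [0, 90]", call. = FALSE)
  }
  edges <- seq(0, 90, by = width)
  k <- length(edges) - 1L
  # half-open [lo, hi); the last bin is closed at 90
  idx <- pmin(findInterval(events$angle_deg, edges), k)
  n_rev <- tabulate(idx[events$maneuver == "reversal"], nbins = k)
  n_cur <- tabulate(idx[events$maneuver == "curve"], nbins = k)
  n <- n_rev + n_cur
  bins <- data.frame(
    lo = edges[-length(edges)],
    hi = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    n_reversal = n_rev,
    n_curve = n_cur,
    n = n,
    reversal_ratio = ifelse(n > 0, n_rev / n, NA_real_),
    flagged = n < min_count
  )
  keep <- !bins$flagged
  if (sum(keep) >= 3) {
    ct <- stats::cor.test(bins$mid[keep], bins$reversal_ratio[keep],
      method = "pearson"
    )
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    warning(
      "fewer than 3 bins with >= ", min_count,
      " events; correlation undefined",
      call. = FALSE
    )
    r <- NA_real_
    p <- NA_real_
  }
  structure(
    list(
      bins = bins, pearson_r = r, p_value = p,
      n_events = nrow(events), min_count = min_count
    ),
    class = "choice_summary"
  )
}

#' @export
print.choice_summary <- function(x, ...) {
  cat("<choice_summary> ", x$n_events, " events\n", sep = "")
  print(x$bins, row.names = FALSE)
  cat(sprintf(
    "Pearson r = %.3f, p = %.3g (bins with < %d events excluded)\n",
    x$pearson_r, x$p_value, x$min_count
  ))
  invisible(x)
}

#' Per-maneuver distance histograms and summary statistics
#'
#' For each maneuver class, the signed border distances are binned every
#' `bin` mm (bins aligned to multiples of the width, half-open `[lo, hi)`),
#' and the mean, SD (n - 1 denominator), and quartiles are reported.
#'
#' @param events A collapsed event table.
#' @param bin Histogram bin width in mm (default 0.2).
#' @param include_step_cap Include step-capped simulator rows (default FALSE).
#' @return A `distance_summary`: named list (one element per maneuver class
#'   present in `{"reversal", "curve"}`) of lists with `n`, `mean`, `sd`,
#'   `quartiles` and a `histogram` data frame (`lo`, `hi`, `count`). Classes
#'   with no events get `n = 0` and NA statistics.
#' @export
distance_summary <- function(events, bin = 0.2, include_step_cap = FALSE) {
  events <- drop_step_capped(events, include_step_cap)
  stopifnot(bin > 0)
  out <- lapply(c(reversal = "reversal", curve = "curve"), function(cls) {
    d <- events$distance_mm[events$maneuver == cls]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n == 0L) {
      return(list(
        n = 0L, mean = NA_real_, sd = NA_real_,
        quartiles = rep(NA_real_, 3),
        histogram = data.frame(lo = numeric(0), hi = numeric(0), count = integer(0))
      ))
    }
    # align bins to multiples of the width; small eps guards against
    # values that sit on an edge only through floating-point noise
    i <- floor(d / bin + 1e-9)
    tab <- table(i)
    lo <- as.numeric(names(tab)) * bin
    list(
      n = n,
      mean = mean(d),
      sd = if (n >= 2) stats::sd(d) else NA_real_,
      quartiles = unname(stats::quantile(d, c(0.25, 0.5, 0.75))),
      histogram = data.frame(
        lo = lo, hi = lo + bin, count = as.integer(tab)
      )
    )
  })
  structure(out, class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  for (cls in names(x)) {
    s <- x[[cls]]
    cat(sprintf(
      "%s: n = %d, mean = %.3f mm, SD = %.3f mm\n",
      cls, s$n, s$mean, s$sd
    ))
  }
  invisible(x)
}

#' Two-sided F test for equality of variances
#'
#' F is the larger sample variance over the smaller; the two-sided p-value
#' comes from the F distribution with (n - 1, n - 1) degrees of freedom
#' (numerator = the sample with the larger variance).
#'
#' @param a,b Numeric samples, each with n >= 2.
#' @return A list with `F`, `df1`, `df2`, `p_value`, `var_a`, `var_b`.
#' @export
compare_variances <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va >= vb) {
    f <- va / vb
    df1 <- length(a) - 1L
    df2 <- length(b) - 1L
  } else {
    f <- vb / va
    df1 <- length(b) - 1L
    df2 <- length(a) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(F = f, df1 = df1, df2 = df2, p_value = p, var_a = va, var_b = vb)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Classical Student's t with pooled variance (not Welch), two-sided.
#'
#' @param a,b Numeric samples, each with n >= 2.
#' @return A list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_means <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
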