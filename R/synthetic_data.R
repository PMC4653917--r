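#' Synthetic inputs for the analysis pipeline
#'
#' The raw assay videos behind the real-worm event tables are not deposited,
#' so every stage of the pipeline is exercised against synthetic stand-ins:
#' strip-style gradient profiles emulating the measured plates, and event
#' tables with the statistical structure the analysis assumes (angle-
#' dependent reversal probability, curve events in less acidic territory
#' than reversal events, serial avoidance runs).
#'
#' @name synthetic_data
NULL

#' Generate a strip-style gradient profile
#'
#' Emulates the plate measurement: six 1-mm agar strips spanning -3 to +3 mm
#' around the color border, each measured at its centre (-2.5, -1.5, ...,
#' +2.5 mm). The underlying profile is linear with the given steepness,
#' anchored at pH 4.0 at the border; a small uniform measurement jitter is
#' added and monotonicity re-enforced by sorting, so the profile always
#' feeds [fit_gradient()] without error.
#'
#' @param steepness Gradient steepness in pH per mm (> 0).
#' @param seed Optional seed for the jitter.
#' @param noise Half-width of the uniform measurement jitter in pH units
#'   (default 0.05; 0 gives the exact linear profile).
#' @param border_ph pH at the border (default 4.0).
#' @return A data frame with columns `distance_mm`, `ph` (a
#'   `gradient_profile`), with the generating condition in the `label`
#'   attribute.
#' @examples
#' pr <- generate_gradient_profile(0.5, seed = 1)
#' field <- fit_gradient(pr)
#' @export
generate_gradient_profile <- function(steepness, seed = NULL, noise = 0.05,
                                      border_ph = 4) {
  if (!(steepness > 0)) stop("`steepness` must be > 0", call. = FALSE)
  if (noise < 0) stop("`noise` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- seq(-2.5, 2.5, by = 1)
  ph <- border_ph - steepness * d
  if (noise > 0) {
    ph <- ph + stats::runif(length(d), -noise, noise)
    ph <- sort(ph, decreasing = TRUE)
  }
  structure(
    data.frame(distance_mm = d, ph = ph),
    label = sprintf("synthetic strips, %.3g pH/mm", steepness),
    class = c("gradient_profile", "data.frame")
  )
}

#' Generative model for real-worm-style event tables
#'
#' Parameters of the synthetic event generator. Defaults emulate the wild-
#' type pattern: the reversal probability rises from about 0.05 at border-
#' parallel encounters to about 0.9 at head-on ones, curve events sit in
#' less acidic territory (more negative signed distance) than reversal
#' events, and events arrive in serial runs with geometric length.
#'
#' @param n_events Number of events to generate.
#' @param intercept,slope Logit-scale intercept and per-degree slope of
#'   P(reversal | encounter angle).
#' @param mu_rev,mu_curve Mean signed distances (mm) of reversal and curve
#'   events; must satisfy `mu_curve < mu_rev`.
#' @param sigma Distance SD in mm (> 0); smaller values mimic steeper
#'   gradients.
#' @param serial_p Per-event probability that a serial avoidance run
#'   continues with another event (in [0, 1)).
#' @param span Half-width of the plate in mm; distances are truncated to
#'   `[-span, span]`.
#' @return A `synthetic_event_model` list.
#' @export
synthetic_event_model <- function(n_events = 500, intercept = -3,
                                  slope = 0.06, mu_rev = 0.4,
                                  mu_curve = -0.6, sigma = 0.3,
                                  serial_p = 0.3, span = 3) {
  if (!(n_events >= 0)) stop("`n_events` must be >= 0", call. = FALSE)
  if (!(mu_curve < mu_rev)) {
    stop("`mu_curve` must be < `mu_rev` (curve fires in less acidic ",
      "territory)",
      call. = FALSE
    )
  }
  if (!(sigma > 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (serial_p < 0 || serial_p >= 1) {
    stop("`serial_p` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_events = as.integer(n_events), intercept = intercept, slope = slope,
      mu_rev = mu_rev, mu_curve = mu_curve, sigma = sigma,
      serial_p = serial_p, span = span
    ),
    class = "synthetic_event_model"
  )
}

# encounter angles with flux-weighted density on the encounter-angle scale:
# f(a) proportional to 1 - cos(a) on [0, 90] degrees (a = 90 - |theta_0|,
# theta_0 ~ 1 - |sin|): head-on encounters are the most frequent
sample_encounter_angles <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) / 0.3))
    a <- stats::runif(m, 0, 90)
    u <- stats::runif(m)
    out <- c(out, a[u < 1 - cospi(a / 180)])
  }
  out[seq_len(n)]
}

#' Generate a real-worm-style avoidance event table
#'
#' Draws encounter angles from the flux-weighted density, assigns maneuvers
#' by a logistic model in the angle, draws signed distances from per-maneuver
#' normals truncated to the plate span, and groups events into serial runs of
#' geometric length (`sequence_index` marks the position within a run).
#'
#' @param model A `synthetic_event_model`.
#' @param seed Seed for the generator.
#' @return An event table data frame with columns `worm_id`, `time_s`,
#'   `angle_deg`, `distance_mm`, `maneuver` (reversal/curve),
#'   `sequence_index`.
#' @examples
#' ev <- generate_event_table(synthetic_event_model(200), seed = 1)
#' summary(bin_choice_ratio(ev)$bins$reversal_ratio)
#' @export
generate_event_table <- function(model, seed = 1) {
  stopifnot(inherits(model, "synthetic_event_model"))
  set.seed(as.integer(seed))
  n <- model$n_events
  if (n == 0L) {
    return(data.frame(
      worm_id = integer(0), time_s = numeric(0), angle_deg = numeric(0),
      distance_mm = numeric(0), maneuver = character(0),
      sequence_index = integer(0), stringsAsFactors = FALSE
    ))
  }
  # serial-run lengths: 1 + geometric(continuation prob serial_p)
  run_len <- integer(0)
  while (sum(run_len) < n) {
    run_len <- c(run_len, 1L + stats::rgeom(n, prob = 1 - model$serial_p))
  }
  run_len <- run_len[cumsum(run_len) - run_len < n] # runs that start in 1..n
  seq_idx <- unlist(lapply(run_len, seq_len))[seq_len(n)]
  worm_id <- rep(seq_along(run_len), run_len)[seq_len(n)]

  angle <- sample_encounter_angles(n)
  p_rev <- stats::plogis(model$intercept + model$slope * angle)
  maneuver <- ifelse(stats::runif(n) < p_rev, "reversal", "curve")
  mu <- ifelse(maneuver == "reversal", model$mu_rev, model$mu_curve)
  dist <- stats::rnorm(n, mu, model$sigma)
  # truncate to the plate span by resampling
  bad <- which(abs(dist) > model$span)
  while (length(bad)) {
    dist[bad] <- stats::rnorm(length(bad), mu[bad], model$sigma)
    bad <- bad[abs(dist[bad]) > model$span]
  }
  data.frame(
    worm_id = worm_id,
    time_s = cumsum(stats::rexp(n, rate = 1 / 30)),
    angle_deg = angle,
    distance_mm = dist,
    maneuver = maneuver,
    sequence_index = seq_idx,
    stringsAsFactors = FALSE
  )
}
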