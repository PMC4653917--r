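#' The two-distinct-threshold model worm
#'
#' A point worm moves at constant speed on a virtual plate carrying an acidic
#' pH gradient. A sensor held ahead of the body (and swung alternately left
#' and right) samples the local pH every time step. Two stochastic
#' reorientation mechanisms — curve (klinotaxis, a gradual directed turn) and
#' reversal (klinokinesis, an abrupt large random turn) — each fire with a
#' sigmoid probability of the sensed pH, centred on its own threshold:
#'
#'   p_c(C) = 1 / (1 + exp((C - beta_c) / alpha_c))
#'   p_r(C) = 1 / (1 + exp((C - beta_r) / alpha_r))
#'
#' with beta_r more acidic than beta_c, so curves begin in milder acid and
#' reversals fire only deeper in. A trial ends when a reorientation leaves the
#' worm heading away from the acid; the maneuver that achieved the escape,
#' together with the heading and signed border distance immediately before
#' it, is the recorded avoidance event.
#'
#' @name simulator
NULL

#' Decision-process parameters
#'
#' Parameters of the two sigmoid decision functions and of the curve turn
#' magnitude.
#'
#' @param alpha_c Spread (pH units) of the curve sigmoid; > 0.
#' @param beta_c Centre (threshold pH) of the curve sigmoid.
#' @param alpha_r Spread (pH units) of the reversal sigmoid; > 0.
#' @param beta_r Centre (threshold pH) of the reversal sigmoid. The model
#'   expects `beta_r < beta_c` (reversal threshold deeper in the acid); a
#'   violation is warned about, not forbidden.
#' @param phi_c Mean curve turn magnitude in degrees.
#' @param dphi_c SD of the curve turn magnitude in degrees; >= 0.
#' @return A `decision_params` object (named list).
#' @examples
#' optimal_params()  # the published best-fitting set
#' @export
decision_params <- function(alpha_c, beta_c, alpha_r, beta_r, phi_c, dphi_c) {
  for (nm in c("alpha_c", "beta_c", "alpha_r", "beta_r", "phi_c", "dphi_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (alpha_c <= 0) stop("`alpha_c` must be > 0", call. = FALSE)
  if (alpha_r <= 0) stop("`alpha_r` must be > 0", call. = FALSE)
  if (dphi_c < 0) stop("`dphi_c` must be >= 0", call. = FALSE)
  if (beta_r >= beta_c) {
    warning(
      "beta_r >= beta_c: reversal threshold is not deeper in the acid ",
      "than the curve threshold",
      call. = FALSE
    )
  }
  structure(
    list(
      alpha_c = alpha_c, beta_c = beta_c,
      alpha_r = alpha_r, beta_r = beta_r,
      phi_c = phi_c, dphi_c = dphi_c
    ),
    class = "decision_params"
  )
}

#' The published best-fitting parameter set
#'
#' alpha_c 0.5, beta_c 4.3, alpha_r 0.5, beta_r = beta_c - 1.6 = 2.7,
#' phi_c 30, dphi_c 10; used with initial positions below -2 mm.
#'
#' @return A `decision_params` object.
#' @export
optimal_params <- function() {
  decision_params(
    alpha_c = 0.5, beta_c = 4.3,
    alpha_r = 0.5, beta_r = 4.3 - 1.6,
    phi_c = 30, dphi_c = 10
  )
}

#' Kinematic and protocol configuration
#'
#' @param speed Locomotion speed in mm/s (constant; default 0.15).
#' @param dt Time step in s (default 0.8).
#' @param sensor_offset Distance of the pH sensor ahead of the positional
#'   point, in mm (default 0.51).
#' @param sensor_swing_deg Amplitude of the alternating lateral sensor swing
#'   in degrees (default 30). The sensor samples alternately on the left and
#'   right of the heading each step.
#' @param reversal_mean_deg Mean reorientation magnitude after reversal
#'   (default 137).
#' @param reversal_sd_deg SD of the reversal reorientation (default 8).
#' @param init_x_max Upper bound (exclusive) of the initial signed distance,
#'   in mm; must be < 0 (the worm starts on the less acidic side; default -2,
#'   i.e. "initial position < -2.0 mm").
#' @param init_x_min Lower bound of the initial signed distance (default
#'   `init_x_max - 1`).
#' @param max_steps Step cap per trial (default 10000, i.e. 2.2 simulated
#'   hours at dt = 0.8 s).
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(speed = 0.15, dt = 0.8, sensor_offset = 0.51,
                       sensor_swing_deg = 30,
                       reversal_mean_deg = 137, reversal_sd_deg = 8,
                       init_x_max = -2, init_x_min = init_x_max - 1,
                       max_steps = 10000) {
  if (!(speed > 0)) stop("`speed` must be > 0", call. = FALSE)
  if (!(dt > 0)) stop("`dt` must be > 0", call. = FALSE)
  if (sensor_offset < 0) stop("`sensor_offset` must be >= 0", call. = FALSE)
  if (reversal_sd_deg < 0) stop("`reversal_sd_deg` must be >= 0", call. = FALSE)
  if (!(init_x_max < 0)) {
    stop("`init_x_max` must be < 0 (start on the less acidic side)",
      call. = FALSE
    )
  }
  if (!(init_x_min < init_x_max)) {
    stop("`init_x_min` must be < `init_x_max`", call. = FALSE)
  }
  if (!(max_steps >= 1)) stop("`max_steps` must be >= 1", call. = FALSE)
  structure(
    list(
      speed = speed, dt = dt, sensor_offset = sensor_offset,
      sensor_swing_deg = sensor_swing_deg,
      reversal_mean_deg = reversal_mean_deg,
      reversal_sd_deg = reversal_sd_deg,
      init_x_max = init_x_max, init_x_min = init_x_min,
      max_steps = as.integer(max_steps)
    ),
    class = "sim_config"
  )
}

#' Sigmoid decision probabilities
#'
#' `p_curve()` and `p_reversal()` give the per-step probability that a curve
#' or reversal is triggered at sensed pH `C`. Both are strictly decreasing in
#' `C` (more acid, higher probability), equal 1/2 at their centres, and
#' saturate to 0/1 for extreme arguments without overflow.
#'
#' @param C Sensed pH value(s).
#' @param params A `decision_params` object.
#' @return Probability in (0, 1) (0 or 1 only at saturation).
#' @export
p_curve <- function(C, params) {
  stats::plogis((params$beta_c - C) / params$alpha_c)
}

#' @rdname p_curve
#' @export
p_reversal <- function(C, params) {
  stats::plogis((params$beta_r - C) / params$alpha_r)
}

#' Sample initial headings from the flux-weighted 1 - |sin(theta)| density
#'
#' Headings are measured from the border normal (0 degrees = straight toward
#' the acid). The initial direction theta_0 in (-90, 90] is drawn with density
#' proportional to 1 - |sin(theta)|: maximal for head-on approach, zero for
#' border-parallel headings. Implemented by rejection sampling against the
#' uniform envelope.
#'
#' @param n Number of draws.
#' @return Numeric vector of headings in degrees.
#' @export
sample_initial_direction <- function(n = 1) {
  out <- numeric(0)
  # acceptance rate is 1 - 2/pi ~ 0.36; draw in batches
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) / 0.3))
    theta <- stats::runif(m, -90, 90)
    u <- stats::runif(m)
    out <- c(out, theta[u < 1 - abs(sinpi(theta / 180))])
  }
  out[seq_len(n)]
}

# analytic CDF of the normalized 1 - |sin| density on (-90, 90], degrees
initial_direction_cdf <- function(theta_deg) {
  t <- pmin(90, pmax(-90, theta_deg)) * pi / 180
  total <- pi - 2
  # integral of (1 - |sin s|) ds from -pi/2 to t
  below <- ifelse(
    t < 0,
    (t + pi / 2) - (cos(t) - 0),
    (pi / 2 - 1) + (t - (1 - cos(t)))
  )
  below / total
}

#' Normalize a heading to (-180, 180] degrees
#' @param heading_deg Heading(s) in degrees.
#' @return Normalized heading(s).
#' @export
normalize_heading <- function(heading_deg) {
  h <- ((heading_deg + 180) %% 360) - 180
  ifelse(h <= -180, h + 360, h)
}

#' Position of the pH sensor
#'
#' The sensor sits `sensor_offset` mm ahead of the positional point along the
#' heading rotated by the swing amplitude toward the current swing side
#' (left = +rotation toward +y when heading 0, right = -rotation).
#'
#' @param position Length-2 numeric `(x, y)` in mm.
#' @param heading_deg Heading in degrees from the border normal.
#' @param swing_side `"left"` or `"right"`; alternates every step during a
#'   trial.
#' @param cfg A `sim_config`.
#' @return Length-2 numeric sensor position `(x, y)`.
#' @export
sensor_position <- function(position, heading_deg, swing_side, cfg) {
  sgn <- if (identical(swing_side, "left")) 1 else -1
  a <- (heading_deg + sgn * cfg$sensor_swing_deg) / 180
  position + cfg$sensor_offset * c(cospi(a), sinpi(a))
}

#' One stochastic decision step
#'
#' Draws two independent Bernoulli variables with success probabilities
#' `p_reversal(C)` and `p_curve(C)`; if both fire at the same time point,
#' reversal wins. Hence P(reversal) = p_r and P(curve) = p_c * (1 - p_r).
#'
#' @param C Sensed pH.
#' @param params A `decision_params`.
#' @return One of `"none"`, `"curve"`, `"reversal"`.
#' @export
decide <- function(C, params) {
  u_r <- stats::runif(1)
  u_c <- stats::runif(1)
  if (u_r < p_reversal(C, params)) {
    "reversal"
  } else if (u_c < p_curve(C, params)) {
    "curve"
  } else {
    "none"
  }
}

#' Apply a reorientation to a heading
#'
#' Reorientations are instantaneous, in-place heading changes. The magnitude
#' is drawn from Normal(137, 8) degrees for a reversal (side chosen uniformly
#' at random) or Normal(phi_c, dphi_c) for a curve (side given by
#' `side`, the less acidic side from the pH comparison).
#'
#' @param heading_deg Heading before the reorientation.
#' @param kind `"curve"` or `"reversal"`.
#' @param params A `decision_params`.
#' @param cfg A `sim_config`.
#' @param side For curves: `"left"` or `"right"`, the side to turn toward.
#'   Ignored for reversals.
#' @return The new heading, normalized to (-180, 180].
#' @export
apply_reorientation <- function(heading_deg, kind, params, cfg,
                                side = c("left", "right")) {
  if (kind == "reversal") {
    mag <- stats::rnorm(1, cfg$reversal_mean_deg, cfg$reversal_sd_deg)
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
  } else {
    side <- match.arg(side)
    mag <- stats::rnorm(1, params$phi_c, params$dphi_c)
    sgn <- if (side == "left") 1 else -1
  }
  normalize_heading(heading_deg + sgn * mag)
}

#' Run one model-worm trial
#'
#' The worm starts at a uniform random signed distance in
#' `[init_x_min, init_x_max)`, y = 0, with a heading drawn from the
#' flux-weighted initial-direction density. Each step it advances
#' `speed * dt` along its heading, alternates the sensor swing side, samples
#' the pH at the sensor, and makes the stochastic curve/reversal decision.
#' A curve turns toward the side whose sample among the current and previous
#' step was less acidic (ties, and a first-step curve, pick a side uniformly
#' at random). After any reorientation, the trial ends if the new heading
#' points away from the acid (negative component along the border normal);
#' otherwise the worm continues. The signed distance and heading immediately
#' before the terminal reorientation are recorded.
#'
#' The caller controls the RNG state (e.g. `set.seed()` before the call);
#' [run_cohort()] derives a per-trial seed from its master seed.
#'
#' @param field A `gradient_field`.
#' @param params A `decision_params`.
#' @param cfg A `sim_config`.
#' @param keep_path If `TRUE`, record the positional point at every step and
#'   return it as a `path` matrix (start position in row 1).
#' @return A `trial_result` list: `maneuver` ("curve"/"reversal", NA if
#'   step-capped), `final_position`, `heading_before`, `signed_distance`,
#'   `steps`, `elapsed` (s), `terminated` ("escaped"/"step_cap"), and
#'   optionally `path`.
#' @export
run_trial <- function(field, params, cfg, keep_path = FALSE) {
  stopifnot(
    inherits(field, "gradient_field"),
    inherits(params, "decision_params"),
    inherits(cfg, "sim_config")
  )
  ph_fun <- field$fun
  v_dt <- cfg$speed * cfg$dt
  off <- cfg$sensor_offset
  swing <- cfg$sensor_swing_deg

  x <- stats::runif(1, cfg$init_x_min, cfg$init_x_max)
  y <- 0
  heading <- sample_initial_direction(1)
  side <- -1 # becomes +1 (left) on the first step after the flip below
  prev_c <- NA_real_
  path <- if (keep_path) matrix(c(x, y), ncol = 2) else NULL

  for (step in seq_len(cfg$max_steps)) {
    x <- x + v_dt * cospi(heading / 180)
    y <- y + v_dt * sinpi(heading / 180)
    if (keep_path) path <- rbind(path, c(x, y))
    side <- -side
    sens_a <- (heading + side * swing) / 180
    C <- ph_fun(x + off * cospi(sens_a))
    u_r <- stats::runif(1)
    u_c <- stats::runif(1)
    kind <- if (u_r < stats::plogis((params$beta_r - C) / params$alpha_r)) {
      "reversal"
    } else if (u_c < stats::plogis((params$beta_c - C) / params$alpha_c)) {
      "curve"
    } else {
      "none"
    }
    if (kind != "none") {
      heading_before <- heading
      if (kind == "curve") {
        sgn <- if (is.na(prev_c) || C == prev_c) {
          if (stats::runif(1) < 0.5) 1 else -1
        } else if (C > prev_c) {
          side # current sample is less acidic: turn to the current side
        } else {
          -side
        }
        mag <- stats::rnorm(1, params$phi_c, params$dphi_c)
      } else {
        sgn <- if (stats::runif(1) < 0.5) 1 else -1
        mag <- stats::rnorm(1, cfg$reversal_mean_deg, cfg$reversal_sd_deg)
      }
      heading <- normalize_heading(heading + sgn * mag)
      if (cospi(heading / 180) < 0) {
        return(structure(
          list(
            maneuver = kind,
            final_position = c(x, y),
            heading_before = heading_before,
            signed_distance = x,
            steps = step,
            elapsed = step * cfg$dt,
            terminated = "escaped",
            path = path
          ),
          class = "trial_result"
        ))
      }
    }
    prev_c <- C
  }
  structure(
    list(
      maneuver = NA_character_,
      final_position = c(x, y),
      heading_before = heading,
      signed_distance = x,
      steps = cfg$max_steps,
      elapsed = cfg$max_steps * cfg$dt,
      terminated = "step_cap",
      path = path
    ),
    class = "trial_result"
  )
}

#' Encounter angle from a pre-reorientation heading
#'
#' The acute angle between the heading and the border line, in degrees:
#' 0 = parallel to the border, 90 = perpendicular (head-on).
#'
#' @param heading_deg Heading(s) in degrees from the border normal.
#' @return Angle(s) in `[0, 90]`.
#' @export
encounter_angle <- function(heading_deg) {
  a <- abs(normalize_heading(heading_deg))
  90 - pmin(a, 180 - a)
}

#' Run a cohort of independent model-worm trials
#'
#' Runs `n` trials with per-trial seeds derived deterministically from the
#' master seed (`seed + trial index`), so cohorts are reproducible and
#' order-independent. Returns one avoidance event per trial as a data frame
#' in the event-table schema; step-capped trials are flagged in the
#' `terminated` column (they carry no maneuver) and their count is attached
#' as the `n_step_cap` attribute.
#'
#' @param n Number of trials (>= 0).
#' @param field A `gradient_field`.
#' @param params A `decision_params`.
#' @param cfg A `sim_config`.
#' @param seed Master seed (integer).
#' @return A data frame with columns `trial_id`, `maneuver`, `angle_deg`,
#'   `distance_mm`, `elapsed_s`, `terminated`.
#' @examples
#' g <- make_parametric_gradient()
#' ev <- run_cohort(50, g, optimal_params(), sim_config(), seed = 1)
#' table(ev$maneuver)
#' @export
run_cohort <- function(n, field, params, cfg = sim_config(), seed = 1) {
  n <- as.integer(n)
  seed <- as.integer(seed)
  stopifnot(n >= 0)
  out <- data.frame(
    trial_id = integer(n),
    maneuver = character(n),
    angle_deg = numeric(n),
    distance_mm = numeric(n),
    elapsed_s = numeric(n),
    terminated = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    set.seed((as.numeric(seed) + i) %% 2147483647)
    tr <- run_trial(field, params, cfg)
    out$trial_id[i] <- i
    out$maneuver[i] <- tr$maneuver
    out$angle_deg[i] <- encounter_angle(tr$heading_before)
    out$distance_mm[i] <- tr$signed_distance
    out$elapsed_s[i] <- tr$elapsed
    out$terminated[i] <- tr$terminated
  }
  attr(out, "n_step_cap") <- sum(out$terminated == "step_cap")
  out
}
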