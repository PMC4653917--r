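# shared fixtures for the test suite

# three-knot measured-style profile: pH 6 at -3 mm, 4 at the border, 3 at +3
demo_points <- function() {
  data.frame(distance_mm = c(-3, 0, 3), ph = c(6, 4, 3))
}

demo_field <- function() fit_gradient(demo_points())

# steep field spanning both sigmoid centers (4.3 and 2.7) within the worms'
# penetration range; used for threshold-signature properties
steep_field <- function(slope = 3) {
  make_parametric_gradient(
    border_ph = 4, slope = slope, span = 6, far_ph = 6, near_ph = 2
  )
}

# a small hand-built collapsed event table
demo_events <- function() {
  data.frame(
    maneuver = c("reversal", "curve", "reversal", "curve", "curve"),
    angle_deg = c(85, 5, 45, 15, 44),
    distance_mm = c(0.1, -0.5, 0.3, -0.7, -0.2),
    stringsAsFactors = FALSE
  )
}
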