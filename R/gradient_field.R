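#' Piecewise-linear pH gradient fields
#'
#' The assay plate carries a one-dimensional acidic pH gradient perpendicular
#' to a straight color border (the bromophenol-blue yellow/blue transition,
#' about pH 4.0). Positions are given as signed distance from the border in
#' mm: positive inside the acidic region, negative on the less acidic side.
#' A `gradient_field` maps any signed distance to a pH value by linear
#' interpolation between measured (or generated) knots, clamped to the end
#' values outside the measured span, so the field is defined everywhere a
#' model worm can wander.
#'
#' @name gradient_field
NULL

new_gradient_field <- function(distance, ph, label = "") {
  structure(
    list(
      distance = as.numeric(distance),
      ph = as.numeric(ph),
      label = as.character(label)[1],
      fun = stats::approxfun(distance, ph, rule = 2)
    ),
    class = "gradient_field"
  )
}

#' Fit a clamped piecewise-linear gradient field to measured points
#'
#' Builds the virtual pH field from strip measurements: a monotone
#' (non-increasing in distance) linear interpolant through the points,
#' constant beyond the outermost knots.
#'
#' @param points A two-column data frame or matrix of
#'   `(distance_mm, ph)` pairs, or a `gradient_profile` as returned by
#'   [generate_gradient_profile()]. At least 2 points with distinct
#'   distances; pH must not increase with distance.
#' @param label Free-text condition label (e.g. buffer/HCl recipe).
#' @return A `gradient_field` object.
#' @examples
#' f <- fit_gradient(data.frame(d = c(-3, 0, 3), ph = c(6, 4, 3)))
#' ph_at(f, c(0, 0))      # 4 at the border
#' ph_at(f, c(-1.5, 2))   # 5, midway on the far segment
#' @export
fit_gradient <- function(points, label = "") {
  pts <- as.data.frame(points)
  if (ncol(pts) < 2L) {
    stop("`points` must have two columns: distance (mm) and pH", call. = FALSE)
  }
  d <- as.numeric(pts[[1]])
  ph <- as.numeric(pts[[2]])
  if (length(d) < 2L) {
    stop("at least 2 gradient points are required", call. = FALSE)
  }
  if (anyNA(d) || anyNA(ph)) {
    stop("gradient points must be finite (no NA)", call. = FALSE)
  }
  o <- order(d)
  d <- d[o]
  ph <- ph[o]
  if (any(diff(d) <= 0)) {
    stop("distances must be distinct", call. = FALSE)
  }
  if (any(diff(ph) > 0)) {
    stop(
      "pH must be non-increasing with distance (acid on the positive side)",
      call. = FALSE
    )
  }
  if (missing(label) && !is.null(attr(points, "label"))) {
    label <- attr(points, "label")
  }
  new_gradient_field(d, ph, label)
}

#' Evaluate a gradient field at a 2-D position
#'
#' The border is the line x = 0, so only the x coordinate (signed distance)
#' matters; y is ignored.
#'
#' @param field A `gradient_field`.
#' @param position Either a length-2 numeric `(x, y)` or a two-column matrix
#'   of positions.
#' @return pH value(s) at the given position(s).
#' @export
ph_at <- function(field, position) {
  stopifnot(inherits(field, "gradient_field"))
  if (is.matrix(position)) {
    x <- position[, 1]
  } else {
    x <- position[1]
  }
  field$fun(x)
}

#' Evaluate a gradient field at signed distances
#'
#' Vectorised evaluation on the signed-distance axis (mm from the border,
#' positive into the acid).
#'
#' @param field A `gradient_field`.
#' @param distance Numeric vector of signed distances in mm.
#' @return pH values.
#' @export
ph_at_distance <- function(field, distance) {
  stopifnot(inherits(field, "gradient_field"))
  field$fun(as.numeric(distance))
}

#' Construct a parametric gradient field
#'
#' Synthetic stand-in for a measured strip profile: pH falls linearly with
#' signed distance at `slope`, anchored at `border_ph` at the border
#' (distance 0), clamped to `far_ph` on the less acidic side and `near_ph`
#' inside the acid, and held constant beyond `span` mm either side.
#'
#' @param border_ph pH at the color border (default 4.0, the yellow/blue
#'   transition of bromophenol blue).
#' @param slope Gradient steepness in pH units per mm (> 0).
#' @param span Half-extent of the ramp in mm; the field is constant outside
#'   `[-span, span]`.
#' @param far_ph Plateau pH on the less acidic side (`far_ph > border_ph`).
#' @param near_ph Plateau pH deep in the acid (`near_ph < border_ph`).
#' @param label Condition label.
#' @return A `gradient_field`.
#' @examples
#' g <- make_parametric_gradient(4, 0.5, 6, 6, 3)
#' ph_at_distance(g, c(-100, -2, 0, 100))  # 6, 5, 4, 3
#' @export
make_parametric_gradient <- function(border_ph = 4, slope = 0.5, span = 6,
                                     far_ph = 6, near_ph = 3, label = "") {
  if (!(slope > 0)) stop("`slope` must be > 0", call. = FALSE)
  if (!(span > 0)) stop("`span` must be > 0", call. = FALSE)
  if (!(far_ph > border_ph && border_ph > near_ph)) {
    stop("need far_ph > border_ph > near_ph", call. = FALSE)
  }
  knots <- c(
    -span,
    -(far_ph - border_ph) / slope,
    0,
    (border_ph - near_ph) / slope,
    span
  )
  knots <- sort(unique(pmin(span, pmax(-span, knots))))
  ph <- pmin(far_ph, pmax(near_ph, border_ph - slope * knots))
  new_gradient_field(knots, ph, label)
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(
    "<gradient_field>",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    "\n  ", length(x$distance), " knots over [",
    min(x$distance), ", ", max(x$distance), "] mm, pH ",
    max(x$ph), " -> ", min(x$ph), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write gradient profiles as CSV
#'
#' Two-column CSV `distance_mm,ph` with a header; the condition label is
#' stored in a `# label:` comment line above the header.
#'
#' @param field A `gradient_field` (for writing).
#' @param path File path.
#' @return `read_gradient_csv()` returns a `gradient_field`;
#'   `write_gradient_csv()` returns `path` invisibly.
#' @export
write_gradient_csv <- function(field, path) {
  stopifnot(inherits(field, "gradient_field"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(field$label)) {
    writeLines(paste0("# label: ", field$label), con)
  }
  writeLines("distance_mm,ph", con)
  writeLines(
    paste(
      formatC(field$distance, format = "fg", digits = 6),
      formatC(field$ph, format = "fg", digits = 6),
      sep = ","
    ),
    con
  )
  invisible(path)
}

#' @rdname write_gradient_csv
#' @export
read_gradient_csv <- function(path) {
  lines <- readLines(path)
  label <- ""
  lab_line <- grep("^#\\s*label:", lines)
  if (length(lab_line)) {
    label <- trimws(sub("^#\\s*label:", "", lines[lab_line[1]]))
  }
  df <- utils::read.csv(text = lines, comment.char = "#")
  fit_gradient(df[, c("distance_mm", "ph")], label = label)
}
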