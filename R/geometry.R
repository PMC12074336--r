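#' Bed and sensor-array geometry
#'
#' Describes the monitoring geometry: the ceiling-to-floor height, the
#' sensor-to-bed distance of each sensor row, the bed footprint and the
#' ultrasonic beam angle. Defaults reproduce the reference installation
#' (ceiling height 2.8 m; upper/middle/lower rows at 2.2 / 2.1 / 1.9 m above
#' the bed surface; 22 degree beam).
#'
#' @param ceiling_floor_height_m Ceiling-to-floor height in metres.
#' @param sensor_to_target_m Named numeric vector with elements `upper`,
#'   `middle` and `lower`: distance from each sensor row to the bed surface,
#'   in metres. Each must be positive and no larger than the ceiling height.
#' @param bed_length_m,bed_width_m Bed footprint in metres.
#' @param beam_angle_deg Ultrasonic beam angle in degrees, strictly between
#'   0 and 90.
#'
#' @return An object of class `bed_geometry` (a validated list).
#' @export
#' @examples
#' geom <- bed_geometry()
#' beam_coverage_table(geom)
bed_geometry <- function(ceiling_floor_height_m = 2.8,
                         sensor_to_target_m = c(upper = 2.2, middle = 2.1,
                                                lower = 1.9),
                         bed_length_m = 2.0,
                         bed_width_m = 0.9,
                         beam_angle_deg = 22) {
  check_number(ceiling_floor_height_m, "ceiling_floor_height_m",
               min = 0, strict_min = TRUE)
  check_number(bed_length_m, "bed_length_m", min = 0, strict_min = TRUE)
  check_number(bed_width_m, "bed_width_m", min = 0, strict_min = TRUE)
  check_number(beam_angle_deg, "beam_angle_deg", min = 0, max = 90,
               strict_min = TRUE, strict_max = TRUE)
  rows <- c("upper", "middle", "lower")
  if (!is.numeric(sensor_to_target_m) ||
      !setequal(names(sensor_to_target_m), rows)) {
    abort("`sensor_to_target_m` must be named with 'upper', 'middle', 'lower'")
  }
  sensor_to_target_m <- sensor_to_target_m[rows]
  if (any(sensor_to_target_m <= 0) ||
      any(sensor_to_target_m > ceiling_floor_height_m)) {
    abort("sensor-to-target distances must be positive and not exceed the ceiling height")
  }
  structure(
    list(ceiling_floor_height_m = ceiling_floor_height_m,
         sensor_to_target_m = sensor_to_target_m,
         bed_length_m = bed_length_m,
         bed_width_m = bed_width_m,
         beam_angle_deg = beam_angle_deg),
    class = "bed_geometry"
  )
}

#' @export
print.bed_geometry <- function(x, ...) {
  cat("<bed_geometry>\n")
  cat("  ceiling-floor height:", x$ceiling_floor_height_m, "m\n")
  cat("  sensor rows (m to bed):",
      paste(names(x$sensor_to_target_m), x$sensor_to_target_m,
            sep = "=", collapse = ", "), "\n")
  cat("  bed:", x$bed_length_m, "x", x$bed_width_m, "m;",
      "beam angle:", x$beam_angle_deg, "deg\n")
  invisible(x)
}

#' Beam coverage on the bed surface
#'
#' Width of bed surface covered by an ultrasonic beam of the given angle from
#' a sensor mounted `height_m` above the target: `tan(angle) * height`,
#' expressed in whole centimetres truncated toward zero. Truncation (rather
#' than rounding) is the declared convention; it reproduces the reference
#' coverages 88 / 84 / 76 cm for rows at 2.2 / 2.1 / 1.9 m with a 22 degree
#' beam.
#'
#' @param height_m Sensor-to-target distance in metres (> 0).
#' @param angle_deg Beam angle in degrees, in `[0, 90)`.
#' @return Coverage in whole centimetres (integer-valued numeric).
#' @export
#' @examples
#' beam_coverage_cm(2.2, 22) # 88
beam_coverage_cm <- function(height_m, angle_deg) {
  check_number(height_m, "height_m", min = 0, strict_min = TRUE)
  check_number(angle_deg, "angle_deg", min = 0, max = 90, strict_max = TRUE)
  trunc(tan(angle_deg * pi / 180) * height_m * 100)
}

#' Per-row beam coverage table
#'
#' @param geometry A [bed_geometry()] object.
#' @return A tibble with one row per sensor row: `row`, `height_m`,
#'   `coverage_cm`.
#' @export
beam_coverage_table <- function(geometry = bed_geometry()) {
  stopifnot(inherits(geometry, "bed_geometry"))
  h <- geometry$sensor_to_target_m
  tibble::tibble(
    row = names(h),
    height_m = unname(h),
    coverage_cm = unname(vapply(h, beam_coverage_cm, numeric(1),
                                angle_deg = geometry$beam_angle_deg))
  )
}

#' Pipeline latency model
#'
#' Parameters of the pipelined processing latency model: number of pipeline
#' stages `S`, clock period `Tclk` in nanoseconds, and number of iterations
#' `N`. Defaults are the reference configuration (S = 12, Tclk = 10 ns,
#' N = 40).
#'
#' @param stages Pipeline stage count `S` (positive integer).
#' @param clk_ns Clock period in ns (positive).
#' @param iterations Iteration count `N` (positive integer).
#' @return An object of class `latency_model`.
#' @export
latency_model <- function(stages = 12, clk_ns = 10, iterations = 40) {
  check_number(stages, "stages", min = 1)
  check_number(clk_ns, "clk_ns", min = 0, strict_min = TRUE)
  check_number(iterations, "iterations", min = 1)
  structure(list(stages = stages, clk_ns = clk_ns, iterations = iterations),
            class = "latency_model")
}

#' Latency of one pipeline iteration
#'
#' `S * Tclk`: the time one data item spends traversing all pipeline stages.
#'
#' @param model A [latency_model()].
#' @return Latency in nanoseconds.
#' @export
#' @examples
#' per_iteration_latency_ns(latency_model()) # 120
per_iteration_latency_ns <- function(model = latency_model()) {
  stopifnot(inherits(model, "latency_model"))
  model$stages * model$clk_ns
}

#' Total pipelined latency
#'
#' `(N + S - 1) * Tclk`: total time to push `N` items through an `S`-stage
#' pipeline, with a new item entering every clock once the pipe is full.
#'
#' @param model A [latency_model()].
#' @return Total latency in nanoseconds.
#' @export
#' @examples
#' pipeline_latency_ns(latency_model()) # 510
pipeline_latency_ns <- function(model = latency_model()) {
  stopifnot(inherits(model, "latency_model"))
  (model$iterations + model$stages - 1) * model$clk_ns
}

#' Classification accuracy and error rate
#'
#' `accuracy = 100 * correct / total`, `error = 100 - accuracy`.
#'
#' @param correct Number of correct predictions (0 <= correct <= total).
#' @param total Total number of predictions (> 0).
#' @return A one-row tibble: `correct`, `total`, `accuracy_pct`, `error_pct`.
#' @export
#' @examples
#' accuracy_report(39, 40) # 97.5% accurate, 2.5% error
accuracy_report <- function(correct, total) {
  check_number(total, "total", min = 1)
  check_number(correct, "correct", min = 0, max = total)
  acc <- 100 * correct / total
  tibble::tibble(correct = correct, total = total,
                 accuracy_pct = acc, error_pct = 100 - acc)
}
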