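#' Bounded capture FIFO
#'
#' Software model of the hardware capture memory: a strict first-in
#' first-out buffer of sensor frames, 6 channels wide, `depth` frames deep
#' (default 40), each stored distance representable in `word_bits` bits
#' (default 20). Pushing into a full FIFO evicts exactly the single oldest
#' frame.
#'
#' @param depth Maximum number of frames held (default 40).
#' @param word_bits Word width in bits; every stored value must satisfy
#'   `0 <= value < 2^word_bits`.
#' @return An object of class `capture_fifo`.
#' @export
#' @examples
#' f <- capture_fifo()
#' f <- push_frame(f, rep(22000, 6))
#' fifo_occupancy(f)
capture_fifo <- function(depth = 40, word_bits = 20) {
  check_number(depth, "depth", min = 1)
  check_number(word_bits, "word_bits", min = 1)
  structure(
    list(width = 6L, depth = as.integer(depth),
         word_bits = as.integer(word_bits),
         data = matrix(numeric(0), ncol = 6,
                       dimnames = list(NULL, sensor_channels()))),
    class = "capture_fifo"
  )
}

#' @rdname capture_fifo
#' @param fifo A `capture_fifo`.
#' @param frame Numeric vector of six distances (canonical channel order) or
#'   a one-row frame tibble with the channel columns.
#' @export
push_frame <- function(fifo, frame) {
  stopifnot(inherits(fifo, "capture_fifo"))
  vals <- frame_values(frame)
  limit <- 2^fifo$word_bits
  if (any(vals < 0) || any(vals >= limit) || any(vals != round(vals))) {
    abort(paste0("frame values must be whole numbers in [0, 2^",
                 fifo$word_bits, ") before insertion"))
  }
  data <- rbind(fifo$data, vals)
  if (nrow(data) > fifo$depth) {
    data <- data[-1, , drop = FALSE]  # evict the single oldest frame
  }
  rownames(data) <- NULL
  fifo$data <- data
  fifo
}

#' @rdname capture_fifo
#' @export
fifo_occupancy <- function(fifo) nrow(fifo$data)

#' @rdname capture_fifo
#' @export
fifo_frames <- function(fifo) {
  tibble::as_tibble(fifo$data)
}

#' @export
print.capture_fifo <- function(x, ...) {
  cat("<capture_fifo> ", fifo_occupancy(x), "/", x$depth, " frames, ",
      x$width, " channels, ", x$word_bits, "-bit words\n", sep = "")
  invisible(x)
}

frame_values <- function(frame) {
  ch <- sensor_channels()
  if (is.data.frame(frame)) {
    if (!all(ch %in% names(frame)) || nrow(frame) != 1L) {
      abort("frame must be a one-row table with the six channel columns")
    }
    vals <- as.numeric(frame[1, ch])
  } else {
    if (!is.numeric(frame) || length(frame) != 6L) {
      abort("frame must hold exactly six channel values")
    }
    vals <- as.numeric(frame)
  }
  setNames(vals, ch)
}

channel_matrix <- function(frames) {
  ch <- sensor_channels()
  if (is.matrix(frames)) {
    stopifnot(all(ch %in% colnames(frames)))
    return(frames[, ch, drop = FALSE])
  }
  if (!is.data.frame(frames) || !all(ch %in% names(frames))) {
    abort("frames must contain the six channel columns UBL..LLR")
  }
  as.matrix(frames[, ch])
}

#' Windowed mean distance with previous-vs-current feedback
#'
#' Arithmetic mean of one channel over a window of frames, compared against
#' the previous window's mean: the feedback flag is `"stable"` when the two
#' means agree within `tolerance_tmm`, `"changed"` otherwise (and `NA` when
#' no previous mean is supplied). This is the mean-distance-finder feedback
#' used to decide whether a normalization baseline still holds.
#'
#' @param window Frames (tibble or matrix with channel columns), at least one.
#' @param channel One of [sensor_channels()].
#' @param prev_mean Previous window mean (tenths of mm), or `NULL`.
#' @param tolerance_tmm Drift tolerance in tenths of mm (default 50 = 5 mm).
#' @return List with `mean` and `feedback`.
#' @export
mean_distance <- function(window, channel, prev_mean = NULL,
                          tolerance_tmm = 50) {
  if (!channel %in% sensor_channels()) {
    abort(paste0("unknown channel '", channel, "'"))
  }
  m <- channel_matrix(window)
  if (nrow(m) == 0L) abort("window must contain at least one frame")
  cur <- mean(m[, channel])
  feedback <- if (is.null(prev_mean)) {
    NA_character_
  } else if (abs(prev_mean - cur) <= tolerance_tmm) "stable" else "changed"
  list(mean = cur, feedback = feedback)
}

#' Early (empty-bed) normalization
#'
#' Per-channel mean distance of an empty-bed stream: the reference each
#' occupied-bed reading is compared against.
#'
#' @param frames Empty-bed frames (tibble with channel columns), >= 1 row.
#' @return Named numeric vector of six means (tenths of mm).
#' @export
early_normalize <- function(frames) {
  m <- channel_matrix(frames)
  if (nrow(m) == 0L) abort("early normalization needs at least one frame")
  colMeans(m)
}

#' Encoded (per-posture) normalization
#'
#' Per-posture, per-channel mean distances learned from a labelled subject
#' session. Every posture label in `labels` (default: all 12) must be
#' present in the data.
#'
#' @param frames Labelled frames: a tibble with the channel columns and a
#'   `label` column, or a `plm_session` (labels taken from its truth).
#' @param labels Labels that must be covered.
#' @return A tibble with `posture` and one mean column per channel.
#' @export
encoded_normalize <- function(frames, labels = posture_labels()) {
  if (inherits(frames, "plm_session")) {
    frames <- dplyr::mutate(frames$frames, label = frames$truth$posture$label)
  }
  if (!"label" %in% names(frames)) {
    abort("encoded normalization needs a `label` column")
  }
  missing <- setdiff(labels, unique(frames$label))
  if (length(missing)) {
    abort(paste0("no frames for posture label(s): ",
                 paste(missing, collapse = ", ")))
  }
  frames |>
    dplyr::group_by(posture = .data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sensor_channels()), mean),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$posture, labels))
}

#' Normalization baseline container
#'
#' Bundles the early (empty-bed) per-channel means, the encoded per-posture
#' means and the occupancy margin used for binarization.
#'
#' @param early Named numeric vector from [early_normalize()].
#' @param encoded Optional tibble from [encoded_normalize()].
#' @param occupancy_margin_tmm Margin in tenths of mm (default 1000 =
#'   100 mm): a channel counts as occupied when it reads at least this much
#'   nearer than its empty-bed baseline.
#' @return An object of class `plm_baseline`.
#' @export
plm_baseline <- function(early, encoded = NULL, occupancy_margin_tmm = 1000) {
  ch <- sensor_channels()
  if (!is.numeric(early) || !all(ch %in% names(early))) {
    abort("`early` must be a named vector covering the six channels")
  }
  if (any(early[ch] < SENSOR_MIN_TMM) || any(early[ch] > SENSOR_MAX_TMM)) {
    abort("early baseline distances must lie within the sensor range")
  }
  check_number(occupancy_margin_tmm, "occupancy_margin_tmm", min = 0,
               strict_min = TRUE)
  structure(list(early = early[ch], encoded = encoded,
                 occupancy_margin_tmm = occupancy_margin_tmm),
            class = "plm_baseline")
}

#' @export
print.plm_baseline <- function(x, ...) {
  cat("<plm_baseline> early (tmm):",
      paste(names(x$early), round(x$early), sep = "=", collapse = " "), "\n")
  cat("  encoded postures:", if (is.null(x$encoded)) 0 else nrow(x$encoded),
      "; occupancy margin:", x$occupancy_margin_tmm, "tmm\n")
  invisible(x)
}

#' Six-bit occupancy pattern of a frame
#'
#' One bit per channel in canonical order: 1 when the channel reads at least
#' `margin` nearer than its empty-bed baseline (a body part under the beam),
#' else 0. These binary array patterns are the compact references used for
#' posture matching.
#'
#' @param frame Six distances (vector or one-row tibble).
#' @param baseline A [plm_baseline()].
#' @param margin Occupancy margin in tenths of mm; defaults to the
#'   baseline's margin.
#' @return Integer vector of six bits, named by channel, with attribute
#'   `key` — the pattern read as a binary number, UBL as the most
#'   significant bit.
#' @export
#' @examples
#' b <- plm_baseline(early_normalize(
#'   empty_bed_session(sim_config(duration_s = 5, noise_sd_mm = 0))))
#' binarize(b$early - c(0, 0, 0, 0, 2000, 2000), b)
binarize <- function(frame, baseline, margin = baseline$occupancy_margin_tmm) {
  stopifnot(inherits(baseline, "plm_baseline"))
  vals <- frame_values(frame)
  bits <- as.integer(baseline$early - vals >= margin)
  names(bits) <- sensor_channels()
  attr(bits, "key") <- pattern_key(bits)
  bits
}

#' @rdname binarize
#' @param bits Six-bit 0/1 vector in canonical channel order.
#' @export
pattern_key <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(length(bits) == 6L, all(bits %in% c(0L, 1L)))
  as.integer(sum(bits * 2L^(5:0)))
}

#' Feature vector of one analysis window
#'
#' Deterministic M = 24 summary of a one-second window (4 frames at 4 Hz):
#' per channel, the normalized mean (empty-bed baseline minus window mean),
#' the raw window mean, the window variance (population convention, divide
#' by n) and the occupancy bit of the window mean. Feature names are
#' `norm_`, `mean_`, `var_`, `occ_` crossed with the channel names.
#'
#' @param window Exactly `window_frames` frames (tibble or matrix).
#' @param baseline A [plm_baseline()].
#' @param window_frames Required window length in frames (default 4).
#' @return Named numeric vector of 24 features.
#' @export
build_feature_vector <- function(window, baseline, window_frames = 4) {
  stopifnot(inherits(baseline, "plm_baseline"))
  m <- channel_matrix(window)
  if (nrow(m) != window_frames) {
    abort(paste0("analysis window must hold exactly ", window_frames,
                 " frames"))
  }
  ch <- sensor_channels()
  mu <- colMeans(m)
  pvar <- colMeans(m^2) - mu^2          # population variance
  pvar[pvar < 0] <- 0                   # guard against fp round-off
  norm <- baseline$early[ch] - mu
  occ <- as.numeric(norm >= baseline$occupancy_margin_tmm)
  setNames(c(norm, mu, pvar, occ),
           c(paste0("norm_", ch), paste0("mean_", ch),
             paste0("var_", ch), paste0("occ_", ch)))
}

#' Feature names of the window feature vector
#' @return Character vector of the 24 feature names.
#' @export
feature_names <- function() {
  ch <- sensor_channels()
  c(paste0("norm_", ch), paste0("mean_", ch),
    paste0("var_", ch), paste0("occ_", ch))
}

#' Window features for a whole session
#'
#' Splits a frame stream into consecutive non-overlapping one-second
#' analysis windows and computes [build_feature_vector()] for each; trailing
#' frames that do not fill a window are dropped.
#'
#' @param frames Frame tibble (schema of [simulate_session()]).
#' @param baseline A [plm_baseline()].
#' @param window_s Window length in seconds (default 1).
#' @param sample_rate_hz Sampling rate (default 4).
#' @return Tibble with `window`, `t_s` (window start) and the 24 feature
#'   columns.
#' @export
build_features <- function(frames, baseline, window_s = 1,
                           sample_rate_hz = 4) {
  wf <- as.integer(round(window_s * sample_rate_hz))
  m <- channel_matrix(frames)
  n_win <- nrow(m) %/% wf
  if (n_win < 1L) abort("stream shorter than one analysis window")
  rows <- lapply(seq_len(n_win), function(w) {
    build_feature_vector(m[((w - 1) * wf + 1):(w * wf), , drop = FALSE],
                         baseline, window_frames = wf)
  })
  feat <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(
    tibble::tibble(window = seq_len(n_win) - 1L,
                   t_s = (seq_len(n_win) - 1L) * window_s),
    feat
  )
}
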