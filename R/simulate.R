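#' The twelve sleep-posture labels
#'
#' Six base poses (supine, prone, fetal-left, fetal-right, log-left,
#' log-right), each in a `static` and a `variant` (time-variant) form, giving
#' the 12-label posture vocabulary used throughout the package. The base-pose
#' names follow common sleep-posture taxonomies; classification relies on
#' label identity only.
#'
#' @return Character vector of the 12 labels, `"<pose>_<variant>"`.
#' @export
#' @examples
#' posture_labels()
posture_labels <- function() {
  poses <- c("supine", "prone", "fetal_left", "fetal_right",
             "log_left", "log_right")
  as.vector(t(outer(poses, c("static", "variant"), paste, sep = "_")))
}

base_poses <- function() unique(sub("_(static|variant)$", "", posture_labels()))

split_posture_label <- function(label) {
  if (!label %in% posture_labels()) {
    abort(paste0("unknown posture label '", label, "'"))
  }
  list(pose = sub("_(static|variant)$", "", label),
       variant = sub("^.*_", "", label))
}

#' Default body-thickness offsets per pose and channel
#'
#' For each base pose, the expected body-thickness offset (metres) under each
#' sensor channel: a channel over an occupied body region reads its mounting
#' height minus this offset; an offset of 0 means the channel sees the empty
#' bed. The defaults place the torso and limbs plausibly for each pose and
#' keep the pose baselines mutually well separated.
#'
#' @return A tibble with a `pose` column and one numeric column per channel.
#' @export
pose_offsets <- function() {
  tibble::tribble(
    ~pose,          ~UBL, ~UBR, ~MBL, ~MBR, ~LLL, ~LLR,
    "supine",       0.25, 0.25, 0.22, 0.22, 0.15, 0.15,
    "prone",        0.20, 0.20, 0.25, 0.25, 0.12, 0.12,
    "fetal_left",   0.28, 0.06, 0.30, 0.08, 0.28, 0.02,
    "fetal_right",  0.06, 0.28, 0.08, 0.30, 0.02, 0.28,
    "log_left",     0.26, 0.00, 0.24, 0.00, 0.18, 0.00,
    "log_right",    0.00, 0.26, 0.00, 0.24, 0.00, 0.18
  )
}

#' Expected per-channel distances for a posture
#'
#' The deterministic generative baseline of a posture: each channel returns
#' its row's mounting height minus the pose's body-thickness offset under
#' that channel (the empty-bed distance where the offset is 0). The static
#' and time-variant forms of a pose share the same baseline; the variant
#' form differs only in its within-window dynamics.
#'
#' @param label One of [posture_labels()].
#' @param geometry A [bed_geometry()].
#' @param offsets Offset table as returned by [pose_offsets()].
#' @return Named numeric vector of six distances in tenths of a millimetre,
#'   canonical channel order.
#' @export
#' @examples
#' posture_profile("supine_static", bed_geometry())
posture_profile <- function(label, geometry = bed_geometry(),
                            offsets = pose_offsets()) {
  parts <- split_posture_label(label)
  row <- offsets[offsets$pose == parts$pose, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(paste0("pose '", parts$pose, "' not present in the offset table"))
  }
  ch <- sensor_channels()
  mount <- geometry$sensor_to_target_m[channel_rows()[ch]]
  prof <- (unname(mount) - as.numeric(row[1, ch])) * TMM_PER_M
  setNames(prof, ch)
}

empty_bed_profile <- function(geometry = bed_geometry()) {
  ch <- sensor_channels()
  setNames(unname(geometry$sensor_to_target_m[channel_rows()[ch]]) * TMM_PER_M,
           ch)
}

#' Simulation configuration
#'
#' Full description of a synthetic sleep session: geometry, sampling,
#' noise/drift, the posture schedule, and the limb-movement episodes to
#' inject on the lower-limb channels.
#'
#' Episodes are specified in whole seconds. One episode is a periodic series
#' of `movement_count` movements, each `movement_duration_s` long, with
#' successive movement onsets `inter_movement_interval_s` apart, starting at
#' `onset_s`. During a movement the limb alternates once per second between a
#' dip of `magnitude_mm` toward the sensor and its resting position; after
#' the movement it relaxes back to rest in steps of `return_step_mm` per
#' second (a sub-threshold glide, so only the movement seconds themselves
#' register as motion).
#'
#' @param geometry A [bed_geometry()].
#' @param sample_rate_hz Sampling rate; the reference system samples at 4 Hz.
#' @param duration_s Session length in whole seconds.
#' @param noise_sd_mm Per-frame, per-channel Gaussian sensor noise sd (mm).
#' @param baseline_drift_mm Linear environmental drift over the whole
#'   session (mm), applied to every channel.
#' @param posture_schedule Tibble `start_s`, `label`: posture from each start
#'   time (whole seconds, strictly increasing, first = 0) until the next.
#' @param episodes Tibble `limb` (`"left"`, `"right"` or `"both"`),
#'   `onset_s`, `movement_count`, `movement_duration_s`,
#'   `inter_movement_interval_s`, `magnitude_mm`. May have zero rows.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param offsets Pose offset table, see [pose_offsets()].
#' @param oscillation_amplitude_mm Amplitude of the slow body oscillation of
#'   time-variant postures (mm); kept small so it never looks like a limb
#'   movement.
#' @param oscillation_period_s Period of that oscillation (s).
#' @param return_step_mm Per-second relaxation step after a movement (mm).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = bed_geometry(),
                       sample_rate_hz = 4,
                       duration_s = 120,
                       noise_sd_mm = 3,
                       baseline_drift_mm = 0,
                       posture_schedule = tibble::tibble(start_s = 0,
                                                         label = "supine_static"),
                       episodes = empty_episodes(),
                       seed = 1L,
                       offsets = pose_offsets(),
                       oscillation_amplitude_mm = 15,
                       oscillation_period_s = 6,
                       return_step_mm = 40) {
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(noise_sd_mm, "noise_sd_mm", min = 0)
  check_number(baseline_drift_mm, "baseline_drift_mm", min = 0)
  check_number(oscillation_amplitude_mm, "oscillation_amplitude_mm", min = 0)
  check_number(oscillation_period_s, "oscillation_period_s", min = 0,
               strict_min = TRUE)
  check_number(return_step_mm, "return_step_mm", min = 0, strict_min = TRUE)
  n_frames <- sample_rate_hz * duration_s
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("sample_rate_hz * duration_s must be a whole frame count")
  }
  if (duration_s != round(duration_s)) {
    abort("duration_s must be a whole number of seconds")
  }
  sched <- tibble::as_tibble(posture_schedule)
  if (!all(c("start_s", "label") %in% names(sched)) || nrow(sched) < 1L) {
    abort("posture_schedule needs columns start_s, label and at least one row")
  }
  if (sched$start_s[1] != 0 || is.unsorted(sched$start_s, strictly = TRUE)) {
    abort("schedule start times must strictly increase from 0")
  }
  if (any(sched$start_s != round(sched$start_s)) ||
      any(sched$start_s >= duration_s)) {
    abort("schedule start times must be whole seconds inside the session")
  }
  bad <- setdiff(sched$label, posture_labels())
  if (length(bad)) {
    abort(paste0("unknown posture labels in schedule: ",
                 paste(bad, collapse = ", ")))
  }
  epi <- tibble::as_tibble(episodes)
  validate_episodes(epi, duration_s)
  structure(
    list(geometry = geometry, sample_rate_hz = sample_rate_hz,
         duration_s = duration_s, noise_sd_mm = noise_sd_mm,
         baseline_drift_mm = baseline_drift_mm,
         posture_schedule = sched, episodes = epi, seed = as.integer(seed),
         offsets = offsets,
         oscillation_amplitude_mm = oscillation_amplitude_mm,
         oscillation_period_s = oscillation_period_s,
         return_step_mm = return_step_mm),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
empty_episodes <- function() {
  tibble::tibble(limb = character(), onset_s = numeric(),
                 movement_count = numeric(), movement_duration_s = numeric(),
                 inter_movement_interval_s = numeric(),
                 magnitude_mm = numeric())
}

validate_episodes <- function(epi, duration_s) {
  req <- c("limb", "onset_s", "movement_count", "movement_duration_s",
           "inter_movement_interval_s", "magnitude_mm")
  if (!all(req %in% names(epi))) {
    abort(paste0("episode table must have columns: ",
                 paste(req, collapse = ", ")))
  }
  if (nrow(epi) == 0L) return(invisible(epi))
  if (!all(epi$limb %in% c("left", "right", "both"))) {
    abort("episode limb must be 'left', 'right' or 'both'")
  }
  whole <- c("onset_s", "movement_count", "movement_duration_s",
             "inter_movement_interval_s")
  for (col in whole) {
    if (any(epi[[col]] != round(epi[[col]]))) {
      abort(paste0("episode ", col, " must be whole-valued"))
    }
  }
  if (any(epi$onset_s < 1)) {
    abort("episode onset_s must be >= 1 (motion is defined against the previous second)")
  }
  if (any(epi$movement_count < 1) || any(epi$movement_duration_s < 1) ||
      any(epi$magnitude_mm <= 0)) {
    abort("episode counts, durations and magnitudes must be positive")
  }
  if (any(epi$movement_duration_s >= epi$inter_movement_interval_s)) {
    abort("movement_duration_s must be < inter_movement_interval_s")
  }
  last_end <- epi$onset_s + (epi$movement_count - 1) * epi$inter_movement_interval_s +
    epi$movement_duration_s
  if (any(last_end > duration_s)) {
    abort("all episode activity must fit inside the session")
  }
  # reject movements that overlap on the same limb: the kinematic model
  # assigns one displacement per limb per second
  for (side in c("left", "right")) {
    secs <- movement_seconds(epi, side)
    if (anyDuplicated(secs)) {
      abort(paste0("episodes overlap on the ", side, " limb"))
    }
  }
  invisible(epi)
}

# all (second, dip-phase) pairs of movements touching a limb side
movement_seconds <- function(epi, side) {
  rows <- epi[epi$limb %in% c(side, "both"), , drop = FALSE]
  if (nrow(rows) == 0L) return(integer())
  unlist(purrr::pmap(rows, function(onset_s, movement_count,
                                    movement_duration_s,
                                    inter_movement_interval_s, ...) {
    onsets <- onset_s + (seq_len(movement_count) - 1) * inter_movement_interval_s
    unlist(lapply(onsets, function(o) o + seq_len(movement_duration_s) - 1))
  }))
}

# per-second limb displacement (tmm, >= 0 toward the sensor) and the
# ground-truth motion mask for one limb side
limb_displacement <- function(epi, side, n_seconds, return_step_tmm) {
  disp <- numeric(n_seconds)
  fixed <- rep(NA_real_, n_seconds)
  moving <- logical(n_seconds)
  rows <- epi[epi$limb %in% c(side, "both"), , drop = FALSE]
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      mag <- r$magnitude_mm * 10
      onsets <- r$onset_s + (seq_len(r$movement_count) - 1) *
        r$inter_movement_interval_s
      for (o in onsets) {
        for (j in seq_len(r$movement_duration_s) - 1) {
          sec <- o + j            # seconds are 0-based
          fixed[sec + 1] <- if (j %% 2 == 0) mag else 0
          moving[sec + 1] <- TRUE
        }
      }
    }
  }
  for (s in seq_len(n_seconds)) {
    if (moving[s]) {
      disp[s] <- fixed[s]
    } else if (s > 1) {
      disp[s] <- max(0, disp[s - 1] - return_step_tmm)
    }
  }
  list(disp = disp, moving = moving)
}

label_at_second <- function(schedule, secs) {
  idx <- findInterval(secs, schedule$start_s)
  schedule$label[idx]
}

#' Simulate a six-channel sleep session with ground truth
#'
#' Generates the frame stream a ceiling-mounted six-sensor ultrasonic array
#' would record over a sleep session: per-frame posture baselines from the
#' schedule, slow body oscillation for time-variant postures, limb-movement
#' dips on the LLL/LLR channels from the episode table, Gaussian sensor
#' noise and linear drift; readings are quantized to tenths of a millimetre
#' and clamped to the 2 cm - 4 m sensor range. Identical seeds give
#' bit-identical sessions.
#'
#' @param config A [sim_config()].
#' @return An object of class `plm_session`: a list with
#'   \describe{
#'     \item{frames}{tibble `frame`, `t_s`, `UBL` ... `LLR` (tenths of mm).}
#'     \item{truth}{list with `posture` (per-frame label), `flags`
#'       (per-second ground-truth motion flags `t_s`, `flag_LLL`,
#'       `flag_LLR`), `episodes` (the injected episode table) and
#'       `transitions` (posture-change seconds).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sess <- simulate_session(sim_config(duration_s = 30, seed = 7))
#' head(sess$frames)
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_frames <- as.integer(round(config$sample_rate_hz * config$duration_s))
  n_seconds <- as.integer(config$duration_s)
  ch <- sensor_channels()
  t_s <- (seq_len(n_frames) - 1) / config$sample_rate_hz
  frame_sec <- pmin(floor(t_s), n_seconds - 1)

  # posture baselines per frame
  labels <- label_at_second(config$posture_schedule, frame_sec)
  profiles <- vapply(posture_labels(), posture_profile, numeric(6),
                     geometry = config$geometry, offsets = config$offsets)
  base <- t(profiles[, labels, drop = FALSE])   # n_frames x 6

  # time-variant postures: slow deterministic oscillation on occupied channels
  amp <- config$oscillation_amplitude_mm * 10
  if (amp > 0) {
    variant <- endsWith(labels, "_variant")
    if (any(variant)) {
      occ <- t(vapply(labels, function(l) {
        p <- split_posture_label(l)$pose
        as.numeric(config$offsets[config$offsets$pose == p, ch]) > 0
      }, logical(6)))
      phase <- matrix((seq_along(ch) - 1) * pi / 3, nrow = n_frames,
                      ncol = 6, byrow = TRUE)
      osc <- amp * sin(2 * pi * t_s / config$oscillation_period_s + phase)
      base <- base + (variant * occ) * osc
    }
  }

  # limb-movement displacements on the lower-limb channels
  step_tmm <- config$return_step_mm * 10
  left <- limb_displacement(config$episodes, "left", n_seconds, step_tmm)
  right <- limb_displacement(config$episodes, "right", n_seconds, step_tmm)
  base[, "LLL"] <- base[, "LLL"] - left$disp[frame_sec + 1]
  base[, "LLR"] <- base[, "LLR"] - right$disp[frame_sec + 1]

  readings <- withr::with_seed(config$seed, {
    noise <- if (config$noise_sd_mm > 0) {
      matrix(rnorm(n_frames * 6, sd = config$noise_sd_mm * 10),
             nrow = n_frames)
    } else 0
    drift <- if (config$baseline_drift_mm > 0 && n_frames > 1) {
      seq(0, config$baseline_drift_mm * 10, length.out = n_frames)
    } else 0
    base + noise + drift
  })
  readings <- pmin(pmax(round(readings), SENSOR_MIN_TMM), SENSOR_MAX_TMM)
  colnames(readings) <- ch
  frames <- dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n_frames) - 1L, t_s = t_s),
    tibble::as_tibble(readings)
  )

  # ground truth: movement seconds plus posture-transition seconds on limbs
  # whose baseline steps between the two poses
  flag_l <- as.integer(left$moving)
  flag_r <- as.integer(right$moving)
  transitions <- integer()
  sched <- config$posture_schedule
  if (nrow(sched) > 1) {
    for (i in 2:nrow(sched)) {
      sec <- sched$start_s[i]
      transitions <- c(transitions, sec)
      prev <- posture_profile(sched$label[i - 1], config$geometry,
                              config$offsets)
      cur <- posture_profile(sched$label[i], config$geometry, config$offsets)
      if (cur[["LLL"]] != prev[["LLL"]]) flag_l[sec + 1] <- 1L
      if (cur[["LLR"]] != prev[["LLR"]]) flag_r[sec + 1] <- 1L
    }
  }
  truth <- list(
    posture = tibble::tibble(frame = frames$frame, t_s = t_s, label = labels),
    flags = tibble::tibble(t_s = seq_len(n_seconds) - 1L,
                           flag_LLL = flag_l, flag_LLR = flag_r),
    episodes = config$episodes,
    transitions = transitions
  )
  structure(list(frames = frames, truth = truth, config = config),
            class = "plm_session")
}

#' @export
print.plm_session <- function(x, ...) {
  cat("<plm_session>", nrow(x$frames), "frames @",
      x$config$sample_rate_hz, "Hz (", x$config$duration_s, "s );",
      nrow(x$truth$episodes), "injected episode(s)\n")
  invisible(x)
}

#' Simulate an empty-bed calibration stream
#'
#' Frames recorded with no subject on the bed: each channel reads its
#' mounting height to the bed surface, plus sensor noise and drift. Used to
#' build the early (empty-bed) normalization baseline.
#'
#' @param config A [sim_config()] (posture schedule and episodes ignored).
#' @return A frame tibble in the same schema as [simulate_session()].
#' @export
empty_bed_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_frames <- as.integer(round(config$sample_rate_hz * config$duration_s))
  t_s <- (seq_len(n_frames) - 1) / config$sample_rate_hz
  base <- matrix(empty_bed_profile(config$geometry), nrow = n_frames,
                 ncol = 6, byrow = TRUE)
  readings <- withr::with_seed(config$seed, {
    noise <- if (config$noise_sd_mm > 0) {
      matrix(rnorm(n_frames * 6, sd = config$noise_sd_mm * 10),
             nrow = n_frames)
    } else 0
    drift <- if (config$baseline_drift_mm > 0 && n_frames > 1) {
      seq(0, config$baseline_drift_mm * 10, length.out = n_frames)
    } else 0
    base + noise + drift
  })
  readings <- pmin(pmax(round(readings), SENSOR_MIN_TMM), SENSOR_MAX_TMM)
  colnames(readings) <- sensor_channels()
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n_frames) - 1L, t_s = t_s),
    tibble::as_tibble(readings)
  )
}

#' Preset limb-movement scenarios
#'
#' Named simulation presets covering the experiment taxonomy used to
#' exercise the detector:
#' \describe{
#'   \item{exp1}{both-limb series plus individual left and right series.}
#'   \item{exp2}{a left-limb-only series of eight one-second movements.}
#'   \item{exp3}{a right-limb series plus a both-limb series.}
#'   \item{exp4}{one unbroken constant-movement run far exceeding the
#'     maximum event duration — non-PLMD by the constant-movement rule.}
#'   \item{pose_change}{no episodes; a single posture change whose
#'     lower-limb baseline steps flag both limbs for one instant — excluded
#'     as a pose change, not PLMD.}
#' }
#'
#' @param seed Seed stored into every preset.
#' @param noise_sd_mm Sensor noise sd, default 0 (clean ground-truth runs).
#' @return Named list of [sim_config()] objects.
#' @export
scenario_library <- function(seed = 1L, noise_sd_mm = 0) {
  series <- function(limb, onset, count, interval, dur = 1, mag = 150) {
    tibble::tibble(limb = limb, onset_s = onset, movement_count = count,
                   movement_duration_s = dur,
                   inter_movement_interval_s = interval, magnitude_mm = mag)
  }
  list(
    exp1 = sim_config(
      duration_s = 240, noise_sd_mm = noise_sd_mm, seed = seed,
      episodes = dplyr::bind_rows(
        series("both", onset = 20, count = 6, interval = 15),
        series("right", onset = 105, count = 5, interval = 10),
        series("left", onset = 130, count = 4, interval = 12)
      )
    ),
    exp2 = sim_config(
      duration_s = 180, noise_sd_mm = noise_sd_mm, seed = seed,
      episodes = series("left", onset = 20, count = 8, interval = 10)
    ),
    exp3 = sim_config(
      duration_s = 240, noise_sd_mm = noise_sd_mm, seed = seed,
      episodes = dplyr::bind_rows(
        series("right", onset = 20, count = 6, interval = 10),
        series("both", onset = 100, count = 4, interval = 12)
      )
    ),
    exp4 = sim_config(
      duration_s = 180, noise_sd_mm = noise_sd_mm, seed = seed,
      episodes = series("both", onset = 20, count = 1, interval = 121,
                        dur = 120)
    ),
    pose_change = sim_config(
      duration_s = 120, noise_sd_mm = noise_sd_mm, seed = seed,
      posture_schedule = tibble::tibble(
        start_s = c(0, 60),
        label = c("supine_static", "fetal_left_static"))
    )
  )
}

#' Posture schedule cycling through all labels
#'
#' Convenience schedule for classifier training sessions: every label in
#' `labels` held for `seconds_per_label`, in the given order.
#'
#' @param seconds_per_label Dwell time per label (whole seconds).
#' @param labels Labels to cycle through, default all 12.
#' @return A schedule tibble suitable for [sim_config()].
#' @export
posture_schedule_all <- function(seconds_per_label = 20,
                                 labels = posture_labels()) {
  tibble::tibble(
    start_s = (seq_along(labels) - 1) * seconds_per_label,
    label = labels
  )
}
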