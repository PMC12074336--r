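#' Detector configuration
#'
#' Thresholds and bounds governing limb-movement detection and PLMD
#' confirmation. A limb is flagged as moving in a second when the absolute
#' difference between its current and previous one-second window means
#' exceeds `movement_threshold_tmm`. Flagged runs become movement events;
#' events survive the pose-change and constant-movement exclusions and are
#' confirmed as a PLM series when at least `min_series` of them occur with
#' inter-event gaps of at most `max_interval_s` and durations within
#' `[min_event_units, max_event_units]`. The stage is assigned from
#' confirmed events per hour: below the first element of
#' `stage_breaks_per_hour` is early, below the second middle, otherwise
#' high.
#'
#' @param movement_threshold_tmm Motion threshold in tenths of mm
#'   (default 1000 = 100 mm).
#' @param window_s Analysis window length in seconds (1 unit = 1 window).
#' @param min_event_units,max_event_units Allowed event duration in units.
#' @param min_series Events needed to confirm a PLM series (default 4).
#' @param max_interval_s Maximum gap between successive events of a series.
#' @param stage_breaks_per_hour Two increasing break points on confirmed
#'   events per hour (default 25, 50).
#' @param duration_fifo_capacity Capacity of the circular buffer of recent
#'   confirmed durations (default 8).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(movement_threshold_tmm = 1000,
                            window_s = 1,
                            min_event_units = 1,
                            max_event_units = 40,
                            min_series = 4,
                            max_interval_s = 90,
                            stage_breaks_per_hour = c(25, 50),
                            duration_fifo_capacity = 8) {
  check_number(movement_threshold_tmm, "movement_threshold_tmm", min = 0,
               strict_min = TRUE)
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  check_number(min_event_units, "min_event_units", min = 1)
  check_number(max_event_units, "max_event_units", min = min_event_units,
               strict_min = TRUE)
  check_number(min_series, "min_series", min = 1)
  check_number(max_interval_s, "max_interval_s", min = 0, strict_min = TRUE)
  if (length(stage_breaks_per_hour) != 2L ||
      diff(stage_breaks_per_hour) <= 0) {
    abort("stage_breaks_per_hour must be two increasing values")
  }
  check_number(duration_fifo_capacity, "duration_fifo_capacity", min = 1)
  structure(
    list(movement_threshold_tmm = movement_threshold_tmm,
         window_s = window_s,
         min_event_units = min_event_units,
         max_event_units = max_event_units,
         min_series = min_series,
         max_interval_s = max_interval_s,
         stage_breaks_per_hour = stage_breaks_per_hour,
         duration_fifo_capacity = duration_fifo_capacity),
    class = "detector_config"
  )
}

#' Balanced binary search tree over reference patterns
#'
#' Feature-matching structure: reference six-bit occupancy patterns (their
#' whole-number keys, see [pattern_key()]) mapped to posture labels, stored
#' as a balanced binary search tree built by recursive median splitting.
#' Lookup of a key walks the tree in O(log k).
#'
#' @param keys Integer pattern keys (distinct).
#' @param labels Posture label per key.
#' @return An object of class `plm_bst`.
#' @export
#' @examples
#' bst <- bst_build(c(3L, 48L, 63L), c("legs", "torso", "supine_static"))
#' bst_lookup(bst, 48L)
bst_build <- function(keys, labels) {
  stopifnot(length(keys) == length(labels))
  keys <- as.integer(keys)
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)]
    abort(paste0("duplicate reference pattern key(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  ord <- order(keys)
  keys <- keys[ord]
  labels <- labels[ord]
  nodes <- new.env(parent = emptyenv())
  nodes$rows <- list()
  build <- function(lo, hi) {
    if (lo > hi) return(NA_integer_)
    mid <- (lo + hi) %/% 2L
    id <- length(nodes$rows) + 1L
    nodes$rows[[id]] <- list(id = id, key = keys[mid], label = labels[mid],
                             left = NA_integer_, right = NA_integer_)
    left <- build(lo, mid - 1L)
    right <- build(mid + 1L, hi)
    nodes$rows[[id]]$left <- left
    nodes$rows[[id]]$right <- right
    id
  }
  root <- if (length(keys)) build(1L, length(keys)) else NA_integer_
  tbl <- if (length(nodes$rows)) {
    dplyr::bind_rows(lapply(nodes$rows, tibble::as_tibble))
  } else {
    tibble::tibble(id = integer(), key = integer(), label = character(),
                   left = integer(), right = integer())
  }
  structure(list(nodes = tbl, root = root), class = "plm_bst")
}

#' @rdname bst_build
#' @param bst A `plm_bst`.
#' @param key Integer pattern key to look up.
#' @return `bst_lookup()`: the stored label, or `NA_character_` on a miss.
#' @export
bst_lookup <- function(bst, key) {
  stopifnot(inherits(bst, "plm_bst"))
  node <- bst$root
  nk <- bst$nodes$key; nl <- bst$nodes$left; nr <- bst$nodes$right
  while (!is.na(node)) {
    if (key == nk[node]) return(bst$nodes$label[node])
    node <- if (key < nk[node]) nl[node] else nr[node]
  }
  NA_character_
}

#' @rdname bst_build
#' @export
bst_keys <- function(bst) {
  inorder <- function(node) {
    if (is.na(node)) return(integer())
    c(inorder(bst$nodes$left[node]), bst$nodes$key[node],
      inorder(bst$nodes$right[node]))
  }
  inorder(bst$root)
}

#' Build the reference BST from encoded baselines
#'
#' Binarizes each trained posture's encoded per-channel means against the
#' early baseline and stores the resulting pattern keys in a BST. Postures
#' whose patterns collide (occupancy alone cannot tell them apart) are
#' dropped with a warning — those postures resolve through the forest
#' fallback instead.
#'
#' @param baseline A [plm_baseline()] with an encoded table.
#' @return A `plm_bst`.
#' @export
reference_bst <- function(baseline) {
  stopifnot(inherits(baseline, "plm_baseline"))
  if (is.null(baseline$encoded)) abort("baseline has no encoded table")
  keys <- vapply(seq_len(nrow(baseline$encoded)), function(i) {
    pattern_key(binarize(baseline$encoded[i, ], baseline))
  }, integer(1))
  labels <- baseline$encoded$posture
  dup_keys <- unique(keys[duplicated(keys)])
  if (length(dup_keys)) {
    drop <- keys %in% dup_keys
    warn(paste0("dropping ", sum(drop),
                " posture(s) with ambiguous occupancy patterns; ",
                "they fall back to the forest"))
    keys <- keys[!drop]
    labels <- labels[!drop]
  }
  bst_build(keys, labels)
}

#' Match a posture by pattern, falling back to the forest
#'
#' Exact BST hits return the stored label without consulting the forest; on
#' a miss the forest classifies the window's feature vector.
#'
#' @param bst A `plm_bst` (may be empty or `NULL`).
#' @param pattern Six-bit pattern from [binarize()] (or its integer key).
#' @param forest A [train_forest()] fit (may be `NULL`).
#' @param x Feature vector for the fallback.
#' @return Posture label, or `NA_character_` when neither source matches.
#' @export
match_posture <- function(bst, pattern, forest = NULL, x = NULL) {
  key <- if (length(pattern) == 6L) pattern_key(pattern) else as.integer(pattern)
  if (!is.null(bst)) {
    hit <- bst_lookup(bst, key)
    if (!is.na(hit)) return(hit)
  }
  if (!is.null(forest) && !is.null(x)) {
    return(forest_predict(forest, x)$label)
  }
  NA_character_
}

#' Per-limb fusion measurement between consecutive windows
#'
#' Motion magnitude statistic: the absolute difference between the current
#' and previous one-second window means of each lower-limb channel.
#'
#' @param prev_window,cur_window Consecutive windows of frames (equal-length
#'   tibbles or matrices with the channel columns).
#' @return Named numeric: `LLL` and `LLR` magnitudes in tenths of mm.
#' @export
fusion_measurement <- function(prev_window, cur_window) {
  p <- channel_matrix(prev_window)
  q <- channel_matrix(cur_window)
  if (nrow(p) == 0L || nrow(q) == 0L || nrow(p) != nrow(q)) {
    abort("fusion measurement needs two non-empty windows of equal length")
  }
  c(LLL = abs(mean(q[, "LLL"]) - mean(p[, "LLL"])),
    LLR = abs(mean(q[, "LLR"]) - mean(p[, "LLR"])))
}

#' Per-second limb motion flags
#'
#' Splits the 4 Hz stream into one-second windows and flags each lower limb
#' in second `t` (t >= 1) when its [fusion_measurement()] magnitude against
#' second `t - 1` exceeds the movement threshold. Second 0 has no previous
#' window and is never flagged.
#'
#' @param frames Frame tibble (schema of [simulate_session()]).
#' @param config A [detector_config()].
#' @param sample_rate_hz Sampling rate (default 4).
#' @return A tibble of class `plm_limb_flags`: `t_s`, `flag_LLL`,
#'   `flag_LLR`.
#' @export
limb_flags <- function(frames, config = detector_config(),
                       sample_rate_hz = 4) {
  wf <- as.integer(round(config$window_s * sample_rate_hz))
  m <- channel_matrix(frames)
  n_win <- nrow(m) %/% wf
  if (n_win < 2L) abort("need at least two seconds of data")
  win_mean <- function(chan) {
    v <- m[seq_len(n_win * wf), chan]
    colMeans(matrix(v, nrow = wf))
  }
  mu_l <- win_mean("LLL")
  mu_r <- win_mean("LLR")
  thr <- config$movement_threshold_tmm
  flag_l <- c(0L, as.integer(abs(diff(mu_l)) > thr))
  flag_r <- c(0L, as.integer(abs(diff(mu_r)) > thr))
  out <- tibble::tibble(t_s = (seq_len(n_win) - 1L) * config$window_s,
                        flag_LLL = flag_l, flag_LLR = flag_r)
  class(out) <- c("plm_limb_flags", class(out))
  out
}

runs_of_ones <- function(x) {
  if (!length(x)) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  tibble::tibble(start = starts[keep] - 1L, length = r$lengths[keep])
}

#' Extract movement events from limb flags
#'
#' Partitions each flagged second into `both` (both limbs moving), `left` or
#' `right`, then turns maximal runs of each category into movement events.
#' A partially overlapping left and right run therefore splits into a `both`
#' event plus single-limb residuals. TLM (time of limb movement) is the sum
#' of all event durations, so a both-limb second counts one unit.
#'
#' @param flags A [limb_flags()] tibble (columns `t_s`, `flag_LLL`,
#'   `flag_LLR`).
#' @return List with `events` (tibble `limb`, `start_s`, `duration_units`,
#'   ordered by start) and `tlm` (total units).
#' @export
extract_events <- function(flags) {
  l <- as.integer(flags$flag_LLL)
  r <- as.integer(flags$flag_LLR)
  t0 <- as.integer(flags$t_s[1])
  cats <- list(
    both = as.integer(l == 1L & r == 1L),
    left = as.integer(l == 1L & r == 0L),
    right = as.integer(l == 0L & r == 1L)
  )
  events <- purrr::imap_dfr(cats, function(v, nm) {
    runs <- runs_of_ones(v)
    tibble::tibble(limb = rep(nm, nrow(runs)),
                   start_s = t0 + runs$start,
                   duration_units = runs$length)
  })
  events <- dplyr::arrange(events, .data$start_s, .data$limb)
  list(events = events, tlm = sum(events$duration_units))
}

#' Circular buffer of recent confirmed durations
#'
#' Fixed-capacity FIFO holding the most recent confirmed movement durations
#' for adjacent-window comparison; once full, each push overwrites the
#' oldest entry (circular shift).
#'
#' @param capacity Maximum entries held (default 8).
#' @return An object of class `duration_fifo`.
#' @export
#' @examples
#' d <- duration_fifo(3)
#' d <- dfifo_push(d, c(1, 2, 3, 4))
#' dfifo_values(d) # 2 3 4
duration_fifo <- function(capacity = 8) {
  check_number(capacity, "capacity", min = 1)
  structure(list(capacity = as.integer(capacity), values = numeric(0)),
            class = "duration_fifo")
}

#' @rdname duration_fifo
#' @param fifo A `duration_fifo`.
#' @param x Duration value(s) to push, oldest first.
#' @export
dfifo_push <- function(fifo, x) {
  stopifnot(inherits(fifo, "duration_fifo"))
  v <- c(fifo$values, as.numeric(x))
  if (length(v) > fifo$capacity) {
    v <- v[(length(v) - fifo$capacity + 1L):length(v)]
  }
  fifo$values <- v
  fifo
}

#' @rdname duration_fifo
#' @export
dfifo_values <- function(fifo) fifo$values

#' Decision fusion: from movement events to a PLMD result
#'
#' Applies the exclusion rules, confirms PLM series and assigns status and
#' stage:
#' \enumerate{
#'   \item Pose-change exclusion: a single-unit both-limb event whose second
#'     coincides with a posture-label change is a pose change, not PLMD.
#'   \item Constant-movement exclusion: an event longer than
#'     `max_event_units` (or shorter than `min_event_units`) is discarded.
#'   \item Series confirmation: per limb side (left side = left + both
#'     events; right side = right + both), events chain while successive
#'     gaps are at most `max_interval_s`; a chain of at least `min_series`
#'     events confirms that side.
#' }
#' Status is the confirmed side(s) (`none`, `left`, `right`, `both`); the
#' stage comes from confirmed events per hour; TLM is the summed duration of
#' confirmed events; the duration FIFO retains the most recent confirmed
#' durations.
#'
#' @param events Event tibble from [extract_events()].
#' @param config A [detector_config()].
#' @param session_s Session length in seconds (for the events-per-hour
#'   rate).
#' @param transitions Posture-change seconds (numeric vector), if known.
#' @param durations A [duration_fifo()] to continue filling (fresh one by
#'   default).
#' @return An object of class `plm_result`; see [analyze_stream()].
#' @export
decision_fusion <- function(events, config = detector_config(), session_s,
                            transitions = numeric(),
                            durations = duration_fifo(config$duration_fifo_capacity)) {
  check_number(session_s, "session_s", min = 0, strict_min = TRUE)
  events <- tibble::as_tibble(events)
  exclusions <- tibble::tibble(reason = character(), limb = character(),
                               start_s = numeric(), duration_units = numeric())
  keep <- rep(TRUE, nrow(events))
  if (nrow(events)) {
    pose_change <- events$limb == "both" & events$duration_units == 1 &
      events$start_s %in% transitions
    too_long <- events$duration_units > config$max_event_units
    too_short <- events$duration_units < config$min_event_units
    note <- function(mask, reason) {
      if (any(mask)) {
        tibble::tibble(reason = reason, limb = events$limb[mask],
                       start_s = events$start_s[mask],
                       duration_units = events$duration_units[mask])
      } else NULL
    }
    exclusions <- dplyr::bind_rows(
      note(pose_change, "pose_change"),
      note(too_long & !pose_change, "constant_movement"),
      note(too_short & !pose_change, "below_min_duration"),
      exclusions
    )
    keep <- !(pose_change | too_long | too_short)
  }
  candidates <- events[keep, , drop = FALSE]

  confirm_side <- function(side) {
    ev <- candidates[candidates$limb %in% c(side, "both"), , drop = FALSE]
    if (nrow(ev) == 0L) return(ev)
    ev <- dplyr::arrange(ev, .data$start_s)
    gap <- ev$start_s[-1] - (ev$start_s[-nrow(ev)] +
                               ev$duration_units[-nrow(ev)] * config$window_s)
    chain <- cumsum(c(0, as.integer(gap > config$max_interval_s)))
    ev$chain <- chain
    sizes <- table(chain)
    ok <- as.integer(names(sizes)[sizes >= config$min_series])
    ev[ev$chain %in% ok, c("limb", "start_s", "duration_units"), drop = FALSE]
  }
  left_conf <- confirm_side("left")
  right_conf <- confirm_side("right")
  status <- if (nrow(left_conf) && nrow(right_conf)) {
    "both"
  } else if (nrow(left_conf)) {
    "left"
  } else if (nrow(right_conf)) "right" else "none"

  confirmed <- dplyr::distinct(dplyr::bind_rows(left_conf, right_conf)) |>
    dplyr::arrange(.data$start_s, .data$limb)
  tlm <- sum(confirmed$duration_units)
  rate_per_h <- nrow(confirmed) / (session_s / 3600)
  stage <- if (status == "none") {
    "not-applicable"
  } else if (rate_per_h < config$stage_breaks_per_hour[1]) {
    "early"
  } else if (rate_per_h < config$stage_breaks_per_hour[2]) {
    "middle"
  } else "high"
  durations <- dfifo_push(durations, confirmed$duration_units)

  structure(
    list(status = status, stage = stage, tlm = tlm,
         episodes = confirmed, all_events = events,
         exclusions = exclusions, events_per_hour = rate_per_h,
         session_s = session_s, durations = durations),
    class = "plm_result"
  )
}

#' @export
print.plm_result <- function(x, ...) {
  cat("<plm_result> status:", x$status, "| stage:", x$stage,
      "| TLM:", x$tlm, "units |", nrow(x$episodes), "confirmed event(s),",
      nrow(x$exclusions), "excluded\n")
  invisible(x)
}

#' Event-type unit-count report
#'
#' Units of movement per event type over a session — the static row counts
#' the seconds with no limb motion.
#'
#' @param result A `plm_result`.
#' @param confirmed_only Count only confirmed events (default `FALSE`:
#'   all extracted events, the detector's observational view).
#' @return Tibble `event_type` (static, left, right, both), `count_units`.
#' @export
event_report <- function(result, confirmed_only = FALSE) {
  ev <- if (confirmed_only) result$episodes else result$all_events
  units <- vapply(c("left", "right", "both"), function(l) {
    sum(ev$duration_units[ev$limb == l])
  }, numeric(1))
  static <- result$session_s - sum(units)
  tibble::tibble(event_type = c("static", "left", "right", "both"),
                 count_units = c(static, unname(units)))
}

#' Analyze a sleep-session stream for PLMD
#'
#' End-to-end detector driver: iterates one-second windows over the 4 Hz
#' stream, identifies the posture of each window (supplied labels, BST
#' pattern match, forest fallback — in that order of preference), flags
#' per-second lower-limb motion, extracts movement events, and runs
#' [decision_fusion()] with the posture-transition seconds, closing the
#' analysis with the final posture segment.
#'
#' @param frames Frame tibble (schema of [simulate_session()]), at least two
#'   seconds long.
#' @param config A [detector_config()].
#' @param baseline A [plm_baseline()] (needed for posture matching).
#' @param forest Optional [train_forest()] fit for posture fallback.
#' @param bst Optional [reference_bst()] pattern matcher.
#' @param posture_labels Optional per-second posture labels (character, one
#'   per window) overriding classification.
#' @param sample_rate_hz Sampling rate (default 4).
#' @return A `plm_result` with an added `postures` tibble (`t_s`, `label`)
#'   and `report` (the [event_report()] table).
#' @export
analyze_stream <- function(frames, config = detector_config(),
                           baseline = NULL, forest = NULL, bst = NULL,
                           posture_labels = NULL, sample_rate_hz = 4) {
  wf <- as.integer(round(config$window_s * sample_rate_hz))
  m <- channel_matrix(frames)
  n_win <- nrow(m) %/% wf
  if (n_win < 2L) abort("stream shorter than two analysis windows")

  # posture timeline, one label per window
  if (is.null(posture_labels)) {
    if (!is.null(baseline) && (!is.null(bst) || !is.null(forest))) {
      feats <- build_features(frames, baseline, window_s = config$window_s,
                              sample_rate_hz = sample_rate_hz)
      fmat <- as.matrix(feats[, feature_names()])
      posture_labels <- vapply(seq_len(n_win), function(w) {
        win <- m[((w - 1) * wf + 1):(w * wf), , drop = FALSE]
        pattern <- binarize(colMeans(win), baseline)
        lbl <- match_posture(bst, pattern, forest, fmat[w, ])
        if (is.na(lbl)) "unknown" else lbl
      }, character(1))
    } else {
      posture_labels <- rep("unknown", n_win)
    }
  }
  if (length(posture_labels) != n_win) {
    abort("posture_labels must supply one label per analysis window")
  }
  secs <- (seq_len(n_win) - 1L) * config$window_s
  transitions <- secs[-1][posture_labels[-1] != posture_labels[-n_win]]

  flags <- limb_flags(frames, config, sample_rate_hz = sample_rate_hz)
  ext <- extract_events(flags)
  result <- decision_fusion(ext$events, config,
                            session_s = n_win * config$window_s,
                            transitions = transitions)
  result$flags <- flags
  result$tlm_observed <- ext$tlm
  result$postures <- tibble::tibble(t_s = secs, label = posture_labels)
  result$report <- event_report(result)
  result
}

#' Tidy the confirmed episodes of a PLMD result
#'
#' @param x A `plm_result`.
#' @param ... Unused.
#' @return Tibble of confirmed events: `limb`, `start_s`, `duration_units`.
#' @method tidy plm_result
#' @export
tidy.plm_result <- function(x, ...) {
  tibble::as_tibble(x$episodes)
}

#' One-row summary of a PLMD result
#'
#' @param x A `plm_result`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `stage`, `tlm`, `n_confirmed`,
#'   `n_excluded`, `events_per_hour`, `session_s`.
#' @method glance plm_result
#' @export
glance.plm_result <- function(x, ...) {
  tibble::tibble(status = x$status, stage = x$stage, tlm = x$tlm,
                 n_confirmed = nrow(x$episodes),
                 n_excluded = nrow(x$exclusions),
                 events_per_hour = x$events_per_hour,
                 session_s = x$session_s)
}
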