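frame_schema <- function() c("frame", "t_s", sensor_channels())

#' Read and write frame streams
#'
#' Frame CSVs use the schema `frame,t_s,UBL,UBR,MBL,MBR,LLL,LLR` with
#' distances in tenths of a millimetre. `read_frames()` validates the
#' header, cell types and the 2 cm - 4 m sensor range, reporting the
#' offending line on failure; `write_frames()` followed by `read_frames()`
#' is the identity on valid streams.
#'
#' @param path CSV file path.
#' @param frames Frame tibble to write.
#' @return `read_frames()`: a frame tibble. `write_frames()`: `path`,
#'   invisibly.
#' @export
read_frames <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(frame_schema(), names(raw))
  if (length(missing)) {
    abort(paste0("frame file ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(lapply(raw[frame_schema()], function(col) {
    suppressWarnings(as.numeric(col))
  }))
  for (col in frame_schema()) {
    bad <- which(is.na(out[[col]]))
    if (length(bad)) {
      abort(paste0("frame file ", path, ", line ", bad[1] + 1,
                   ": non-numeric value in column ", col))
    }
  }
  for (col in sensor_channels()) {
    bad <- which(out[[col]] < SENSOR_MIN_TMM | out[[col]] > SENSOR_MAX_TMM)
    if (length(bad)) {
      abort(paste0("frame file ", path, ", line ", bad[1] + 1, ": ", col,
                   " = ", out[[col]][bad[1]],
                   " outside the sensor range [", SENSOR_MIN_TMM, ", ",
                   SENSOR_MAX_TMM, "]"))
    }
  }
  out$frame <- as.integer(out$frame)
  out
}

#' @rdname read_frames
#' @export
write_frames <- function(frames, path) {
  stopifnot(all(frame_schema() %in% names(frames)))
  readr::write_csv(frames[frame_schema()], path, progress = FALSE)
  invisible(path)
}

#' Write session ground truth
#'
#' Two CSVs: per-second truth (`t_s,posture,flag_LLL,flag_LLR`) and the
#' episode table (`limb,onset_s,count,duration_s,interval_s`).
#'
#' @param session A `plm_session`.
#' @param truth_path,episodes_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(session, truth_path, episodes_path) {
  stopifnot(inherits(session, "plm_session"))
  flags <- session$truth$flags
  posture <- label_at_second(session$config$posture_schedule, flags$t_s)
  readr::write_csv(
    tibble::tibble(t_s = flags$t_s, posture = posture,
                   flag_LLL = flags$flag_LLL, flag_LLR = flags$flag_LLR),
    truth_path, progress = FALSE)
  epi <- session$truth$episodes
  readr::write_csv(
    tibble::tibble(limb = epi$limb, onset_s = epi$onset_s,
                   count = epi$movement_count,
                   duration_s = epi$movement_duration_s,
                   interval_s = epi$inter_movement_interval_s),
    episodes_path, progress = FALSE)
  invisible(c(truth_path, episodes_path))
}

#' Read and write normalization baselines
#'
#' The early baseline is stored as `channel,early`; the encoded table as
#' `posture,UBL,...,LLR`.
#'
#' @param baseline A [plm_baseline()].
#' @param early_path,encoded_path CSV paths (`encoded_path` optional).
#' @param occupancy_margin_tmm Margin restored into the read baseline.
#' @return `write_baseline()`: paths, invisibly. `read_baseline()`: a
#'   [plm_baseline()].
#' @export
write_baseline <- function(baseline, early_path, encoded_path = NULL) {
  stopifnot(inherits(baseline, "plm_baseline"))
  readr::write_csv(
    tibble::tibble(channel = names(baseline$early),
                   early = unname(baseline$early)),
    early_path, progress = FALSE)
  if (!is.null(encoded_path) && !is.null(baseline$encoded)) {
    readr::write_csv(baseline$encoded, encoded_path, progress = FALSE)
  }
  invisible(c(early_path, encoded_path))
}

#' @rdname write_baseline
#' @export
read_baseline <- function(early_path, encoded_path = NULL,
                          occupancy_margin_tmm = 1000) {
  early_tbl <- readr::read_csv(early_path, col_types = "cd", progress = FALSE)
  early <- setNames(early_tbl$early, early_tbl$channel)
  encoded <- if (!is.null(encoded_path)) {
    readr::read_csv(encoded_path,
                    col_types = readr::cols(posture = "c",
                                            .default = "d"),
                    progress = FALSE)
  } else NULL
  plm_baseline(early, encoded, occupancy_margin_tmm)
}

#' Persist a trained forest as versioned JSON
#'
#' The document stores the forest configuration, the fixed class order and,
#' per tree, its feature subset and full node list, so a forest round-trips
#' exactly.
#'
#' @param forest A [train_forest()] fit.
#' @param path JSON file path.
#' @return `write_model()`: `path`, invisibly. `read_model()`: the
#'   reconstructed `plm_forest`.
#' @export
write_model <- function(forest, path) {
  stopifnot(inherits(forest, "plm_forest"))
  doc <- list(
    format = "plmwatch-forest", version = 1L,
    feature_names = forest$feature_names, classes = forest$classes,
    trees = forest$trees, mtry = forest$mtry, M = forest$M, n = forest$n,
    seed = forest$seed,
    members = lapply(forest$members, function(mem) {
      list(features = mem$features,
           nodes = as.list(as.data.frame(mem$tree)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "plmwatch-forest") || doc$version != 1) {
    abort(paste0(path, " is not a version-1 plmwatch forest document"))
  }
  members <- lapply(seq_len(doc$trees), function(i) {
    mem <- if (is.data.frame(doc$members)) {
      list(features = doc$members$features[[i]],
           nodes = doc$members$nodes[i, ])
    } else doc$members[[i]]
    nodes <- tibble::as_tibble(lapply(mem$nodes, unlist))
    nodes$leaf <- as.logical(nodes$leaf)
    nodes$threshold <- as.numeric(nodes$threshold)
    for (col in c("id", "left", "right")) {
      nodes[[col]] <- as.integer(nodes[[col]])
    }
    tree <- structure(nodes, class = c("plm_tree", class(nodes)),
                      features = as.integer(mem$features),
                      classes = doc$classes)
    list(tree = tree, features = as.integer(mem$features))
  })
  structure(
    list(members = members, feature_names = doc$feature_names,
         classes = doc$classes, trees = as.integer(doc$trees),
         mtry = as.integer(doc$mtry), M = as.integer(doc$M),
         n = as.integer(doc$n), seed = as.integer(doc$seed)),
    class = "plm_forest"
  )
}

#' Write a PLMD result as JSON and its unit-count report as CSV
#'
#' @param result A `plm_result`.
#' @param json_path Result JSON path (`NULL` to skip).
#' @param report_path Report CSV path (`event_type,count_units`; `NULL` to
#'   skip).
#' @return Invisibly, the written paths.
#' @export
write_result <- function(result, json_path = NULL, report_path = NULL) {
  stopifnot(inherits(result, "plm_result"))
  if (!is.null(json_path)) {
    doc <- list(
      status = result$status, stage = result$stage, tlm = result$tlm,
      events_per_hour = result$events_per_hour,
      session_s = result$session_s,
      episodes = as.list(as.data.frame(result$episodes)),
      exclusions = as.list(as.data.frame(result$exclusions)),
      report = as.list(as.data.frame(event_report(result)))
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(report_path)) {
    readr::write_csv(event_report(result), report_path, progress = FALSE)
  }
  invisible(c(json_path, report_path))
}
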