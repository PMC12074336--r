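# shared fixture builders -------------------------------------------------

# frame tibble from a matrix (or a single row recycled)
make_frames <- function(mat, rate = 4) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- sensor_channels()
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(nrow(mat)) - 1L,
                   t_s = (seq_len(nrow(mat)) - 1L) / rate),
    tibble::as_tibble(mat)
  )
}

# constant-reading stream: n seconds at 4 Hz of the given six distances
constant_stream <- function(values, seconds, rate = 4) {
  make_frames(matrix(rep(values, each = seconds * rate), ncol = 6), rate)
}

zero_noise_config <- function(duration_s = 60, episodes = empty_episodes(),
                              schedule = NULL, seed = 1L) {
  args <- list(duration_s = duration_s, noise_sd_mm = 0,
               episodes = episodes, seed = seed)
  if (!is.null(schedule)) args$posture_schedule <- schedule
  do.call(sim_config, args)
}

default_baseline <- function(margin = 1000) {
  plm_baseline(empty_bed_profile_fixture(), occupancy_margin_tmm = margin)
}

empty_bed_profile_fixture <- function() {
  stats::setNames(c(22000, 22000, 21000, 21000, 19000, 19000),
                  sensor_channels())
}

# brute-force TLM: seconds in which at least one limb is flagged
brute_tlm <- function(flag_l, flag_r) {
  sum(flag_l == 1L | flag_r == 1L)
}

# Minimal achievable training error of ANY fully-grown binary decision tree
# on binary features, by exhaustive enumeration of the input patterns: a
# fully grown tree can split on every feature and so realize any labelling
# of the distinct patterns; the best it can do on duplicates is the
# majority label of each pattern group.
min_error_oracle <- function(x, y) {
  key <- apply(x, 1, paste, collapse = ",")
  sum(vapply(split(seq_along(y), key), function(idx) {
    length(idx) - max(table(y[idx]))
  }, numeric(1)))
}

# random tiny binary-feature dataset (n <= 8, M <= 3)
random_tiny_dataset <- function() {
  n <- sample(2:8, 1)
  M <- sample(1:3, 1)
  x <- matrix(sample(0:1, n * M, replace = TRUE), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(M))))
  y <- factor(sample(c("A", "B"), n, replace = TRUE), levels = c("A", "B"))
  list(x = x, y = y)
}

# random valid zero-noise scenario: episodes placed in disjoint time blocks
# so the injected event table is exactly the expected detector output
random_scenario <- function() {
  n_epi <- sample(1:3, 1)
  block_len <- 60
  duration <- 20 + n_epi * block_len
  episodes <- purrr::map_dfr(seq_len(n_epi), function(k) {
    start <- 10 + (k - 1) * block_len
    dur <- sample(1:3, 1)
    interval <- dur + sample(5:10, 1)
    count <- sample(2:4, 1)
    tibble::tibble(limb = sample(c("left", "right", "both"), 1),
                   onset_s = start, movement_count = count,
                   movement_duration_s = dur,
                   inter_movement_interval_s = interval,
                   magnitude_mm = sample(c(150, 200, 250), 1))
  })
  zero_noise_config(duration_s = duration, episodes = episodes)
}

# expected event table implied by an episode specification
episodes_to_events <- function(episodes) {
  ev <- purrr::pmap_dfr(episodes, function(limb, onset_s, movement_count,
                                           movement_duration_s,
                                           inter_movement_interval_s, ...) {
    tibble::tibble(
      limb = limb,
      start_s = onset_s + (seq_len(movement_count) - 1) *
        inter_movement_interval_s,
      duration_units = movement_duration_s
    )
  })
  dplyr::arrange(ev, start_s, limb)
}
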