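#' Illumination protocols
#'
#' A PAPA-SPT experiment interleaves continuous red imaging light with brief
#' reactivation pulses of violet (direct reactivation, DR) and green
#' (proximity-assisted photoactivation, PAPA) light, synchronized to the
#' camera. A protocol is an ordered list of phases, each delivering one pulse
#' per frame of a given channel for a given number of frames, repeated for a
#' number of cycles. The compact field notation "250 R [2 ms]" means 250
#' frames each carrying a 2 ms red pulse; a stimulation frame may also carry
#' a concurrent red pulse, written "1 V [7 ms] + R [7 ms]".
#'
#' Frames are indexed from 0 and analysis windows are half-open
#' `[start, end)`. The pulse frame itself is excluded from its post-pulse
#' window: reactivated molecules are counted from the following frame.
#'
#' @param channel One of `"R"`, `"G"`, `"V"`, `"OFF"` (case-insensitive;
#'   `"red"`, `"green"`, `"violet"`, `"off"` also accepted).
#' @param n_frames Number of frames in the phase (positive integer).
#' @param pulse_ms Pulse duration per frame, ms.
#' @param red_ms Concurrent red pulse duration for non-red phases, ms.
#' @return `illumination_phase()` returns a one-row tibble;
#'   `illumination_protocol()` returns a `papa_protocol` object.
#' @examples
#' p <- parse_protocol(
#'   "10 cycles of 250 R [2 ms], 1 V [7 ms], 500 R [2 ms], 1 G [7 ms], 250 R [2 ms]")
#' n_frames(p)
#' post_pulse_windows(p, "V")
#' @export
illumination_phase <- function(channel, n_frames, pulse_ms, red_ms = 0) {
  channel <- normalize_channel(channel)
  if (length(n_frames) != 1 || is.na(n_frames) || n_frames < 1 ||
      n_frames != as.integer(n_frames)) {
    abort("`n_frames` must be a positive integer.")
  }
  if (pulse_ms < 0 || red_ms < 0) abort("pulse durations must be >= 0")
  if (channel == "R" && red_ms > 0) {
    abort("for a red phase the red dose is `pulse_ms`; leave `red_ms` at 0")
  }
  tibble(channel = channel, n_frames = as.integer(n_frames),
         pulse_ms = as.numeric(pulse_ms), red_ms = as.numeric(red_ms))
}

normalize_channel <- function(channel) {
  ch <- toupper(as.character(channel))
  map <- c(R = "R", RED = "R", G = "G", GREEN = "G",
           V = "V", VIOLET = "V", OFF = "OFF")
  out <- unname(map[ch])
  if (any(is.na(out))) {
    abort(paste0("unknown channel token: ",
                 paste(unique(ch[is.na(out)]), collapse = ", ")))
  }
  out
}

#' @rdname illumination_phase
#' @param phases A tibble of phases (rows from [illumination_phase()]), or a
#'   list of such rows; order defines the within-cycle order.
#' @param n_cycles Number of repeats of the phase list.
#' @param frame_interval_ms Camera frame interval, ms (default 7.48).
#' @param pre_shelving_s Continuous red exposure, in seconds, applied before
#'   frame 0 to shelve/bleach receivers (default 0).
#' @export
illumination_protocol <- function(phases, n_cycles = 1,
                                  frame_interval_ms = 7.48,
                                  pre_shelving_s = 0) {
  if (is.list(phases) && !is.data.frame(phases)) phases <- bind_rows(phases)
  phases <- as_tibble(phases)
  needed <- c("channel", "n_frames", "pulse_ms")
  if (!all(needed %in% names(phases))) {
    abort("`phases` needs columns channel, n_frames, pulse_ms")
  }
  if (is.null(phases$red_ms)) phases$red_ms <- 0
  phases$channel <- normalize_channel(phases$channel)
  if (frame_interval_ms <= 0) abort("`frame_interval_ms` must be > 0")
  if (n_cycles < 1) abort("`n_cycles` must be >= 1")
  if (any(phases$n_frames < 1)) abort("phase `n_frames` must be >= 1")
  if (any(phases$pulse_ms < 0) || any(phases$red_ms < 0)) {
    abort("pulse durations must be >= 0")
  }
  if (any(phases$pulse_ms + phases$red_ms > frame_interval_ms + 1e-9)) {
    abort("pulse longer than the frame interval")
  }
  structure(
    list(phases = phases, n_cycles = as.integer(n_cycles),
         frame_interval_ms = frame_interval_ms,
         pre_shelving_s = pre_shelving_s,
         schedule = build_schedule(phases, n_cycles)),
    class = "papa_protocol")
}

# Per-frame dose table for the whole movie (frame is 0-based).
build_schedule <- function(phases, n_cycles) {
  k <- nrow(phases)
  phase_id <- rep(rep(seq_len(k), phases$n_frames), n_cycles)
  per_cycle <- sum(phases$n_frames)
  total <- per_cycle * n_cycles
  ch <- phases$channel[phase_id]
  pulse <- phases$pulse_ms[phase_id]
  red_extra <- phases$red_ms[phase_id]
  tibble(
    frame = seq_len(total) - 1L,
    cycle = rep(seq_len(n_cycles) - 1L, each = per_cycle),
    phase = phase_id,
    red_ms = ifelse(ch == "R", pulse, red_extra),
    green_ms = ifelse(ch == "G", pulse, 0),
    violet_ms = ifelse(ch == "V", pulse, 0))
}

#' @rdname illumination_phase
#' @param protocol A `papa_protocol`.
#' @export
n_frames <- function(protocol) nrow(protocol$schedule)

#' @export
print.papa_protocol <- function(x, ...) {
  cat("<papa_protocol> ", format_protocol(x), "\n", sep = "")
  cat("  frames: ", n_frames(x), " @ ", x$frame_interval_ms, " ms/frame",
      if (x$pre_shelving_s > 0)
        paste0("; pre-shelving ", x$pre_shelving_s, " s red"),
      "\n", sep = "")
  invisible(x)
}

#' Parse and serialize the bracket notation for illumination protocols
#'
#' `parse_protocol()` reads strings such as
#' `"10 cycles of 250 R [2 ms], 1 V [7 ms], 500 R [2 ms], 1 G [7 ms], 250 R [2 ms]"`
#' and mixed stimulation frames such as `"1 V [7 ms] + R [7 ms]"`.
#' `format_protocol()` is its inverse; `parse_protocol(format_protocol(p))`
#' reproduces `p`'s phases and cycle count.
#'
#' @param spec A protocol description string.
#' @inheritParams illumination_phase
#' @return A `papa_protocol`.
#' @export
parse_protocol <- function(spec, frame_interval_ms = 7.48,
                           pre_shelving_s = 0) {
  m <- regmatches(spec, regexec("^\\s*(\\d+)\\s+cycles?\\s+of\\s+(.+)$", spec))[[1]]
  if (length(m) == 0) {
    abort("protocol must look like '<n> cycles of <frames> <channel> [<ms> ms], ...'")
  }
  n_cycles <- as.integer(m[2])
  parts <- trimws(strsplit(m[3], ",")[[1]])
  phase_re <- paste0(
    "^(\\d+)\\s+([A-Za-z]+)\\s*\\[\\s*([0-9.]+)\\s*ms\\s*\\]",
    "(?:\\s*\\+\\s*R\\s*\\[\\s*([0-9.]+)\\s*ms\\s*\\])?$")
  phases <- purrr::map(parts, function(p) {
    pm <- regmatches(p, regexec(phase_re, p))[[1]]
    if (length(pm) == 0) abort(paste0("cannot parse phase: '", p, "'"))
    illumination_phase(
      channel = pm[3], n_frames = as.integer(pm[2]),
      pulse_ms = as.numeric(pm[4]),
      red_ms = if (nzchar(pm[5])) as.numeric(pm[5]) else 0)
  })
  illumination_protocol(bind_rows(phases), n_cycles = n_cycles,
                        frame_interval_ms = frame_interval_ms,
                        pre_shelving_s = pre_shelving_s)
}

#' @rdname parse_protocol
#' @param protocol A `papa_protocol`.
#' @export
format_protocol <- function(protocol) {
  ph <- protocol$phases
  fmt_num <- function(x) sub("\\.?0+$", "", formatC(x, format = "f", digits = 6))
  phase_txt <- purrr::pmap_chr(ph, function(channel, n_frames, pulse_ms, red_ms) {
    txt <- paste0(n_frames, " ", channel, " [", fmt_num(pulse_ms), " ms]")
    if (red_ms > 0) txt <- paste0(txt, " + R [", fmt_num(red_ms), " ms]")
    txt
  })
  paste0(protocol$n_cycles,
         if (protocol$n_cycles == 1) " cycle of " else " cycles of ",
         paste(phase_txt, collapse = ", "))
}

#' Illumination doses delivered during given frames
#'
#' @param protocol A `papa_protocol`.
#' @param frame 0-based frame index (vectorized).
#' @return A tibble with columns `frame`, `channel`, `dose_ms`, one row per
#'   nonzero dose delivered during each requested frame.
#' @export
frame_channels <- function(protocol, frame) {
  sch <- protocol$schedule
  if (any(frame < 0 | frame >= nrow(sch))) abort("frame out of range")
  rows <- sch[match(frame, sch$frame), ]
  out <- bind_rows(
    tibble(frame = rows$frame, channel = "R", dose_ms = rows$red_ms),
    tibble(frame = rows$frame, channel = "G", dose_ms = rows$green_ms),
    tibble(frame = rows$frame, channel = "V", dose_ms = rows$violet_ms))
  out <- out[out$dose_ms > 0, ]
  arrange(out, .data$frame, .data$channel)
}

#' Frames carrying a reactivation pulse of a given channel
#'
#' @inheritParams frame_channels
#' @param channel `"G"` or `"V"` (aliases `"green"`, `"violet"`).
#' @return Integer vector of 0-based frame indices.
#' @export
pulse_frames <- function(protocol, channel) {
  channel <- normalize_channel(channel)
  if (!channel %in% c("G", "V")) abort("`channel` must be G or V")
  dose <- if (channel == "G") protocol$schedule$green_ms else protocol$schedule$violet_ms
  protocol$schedule$frame[dose > 0]
}

#' Post-pulse analysis windows
#'
#' Trajectory segments are classified by the reactivation pulse they follow:
#' localizations within the first `window` frames after a green pulse are
#' PAPA, after a violet pulse DR. Windows are half-open `[p + 1, p + 1 + window)`
#' for a pulse at frame `p`, clipped at the end of the movie. A window that
#' would contain another reactivation pulse signals an unsupported protocol
#' and is an error.
#'
#' @inheritParams pulse_frames
#' @param window Window length in frames (default 30).
#' @return A tibble with columns `channel`, `pulse_frame`, `start`, `end`.
#' @export
post_pulse_windows <- function(protocol, channel, window = 30) {
  channel <- normalize_channel(channel)
  if (window < 1) abort("`window` must be >= 1")
  pf <- pulse_frames(protocol, channel)
  total <- n_frames(protocol)
  out <- tibble(channel = channel, pulse_frame = pf,
                start = pf + 1L, end = pmin(pf + 1L + as.integer(window), total))
  out <- out[out$start < out$end, ]
  all_pulses <- sort(c(pulse_frames(protocol, "G"), pulse_frames(protocol, "V")))
  for (i in seq_len(nrow(out))) {
    inside <- all_pulses >= out$start[i] & all_pulses < out$end[i]
    if (any(inside)) {
      abort("post-pulse window overlaps another reactivation pulse; shorten `window`")
    }
  }
  out
}

#' Read and write protocol files
#'
#' Protocols are stored as YAML or JSON with keys `cycles`,
#' `phases: [{channel, frames, pulse_ms, red_ms}]`, `frame_interval_ms`,
#' `pre_shelving_s`. The format is chosen by file extension.
#'
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_protocol()` returns a `papa_protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  spec <- switch(tolower(tools::file_ext(path)),
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    abort("protocol files must be .yaml/.yml/.json"))
  phases <- bind_rows(purrr::map(spec$phases, function(p) {
    illumination_phase(p$channel, p$frames, p$pulse_ms, p$red_ms %||% 0)
  }))
  illumination_protocol(
    phases, n_cycles = spec$cycles %||% 1,
    frame_interval_ms = spec$frame_interval_ms %||% 7.48,
    pre_shelving_s = spec$pre_shelving_s %||% 0)
}

#' @rdname read_protocol
#' @param protocol A `papa_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  spec <- list(
    cycles = protocol$n_cycles,
    phases = purrr::pmap(protocol$phases,
      function(channel, n_frames, pulse_ms, red_ms) {
        list(channel = channel, frames = n_frames,
             pulse_ms = pulse_ms, red_ms = red_ms)
      }),
    frame_interval_ms = protocol$frame_interval_ms,
    pre_shelving_s = protocol$pre_shelving_s)
  switch(tolower(tools::file_ext(path)),
    yaml = , yml = yaml::write_yaml(spec, path),
    json = jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA),
    abort("protocol files must be .yaml/.yml/.json"))
  invisible(path)
}
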