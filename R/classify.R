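#' Split trajectories into PAPA and DR segments
#'
#' Localizations falling inside the first `window` frames after a green
#' pulse become PAPA segments; after a violet pulse, DR segments.
#' Localizations outside all windows are dropped, so a trajectory spanning a
#' window boundary contributes only its in-window portion. Each (source
#' trajectory, window) combination becomes a new segment with its own id; a
#' long-lived molecule can therefore contribute segments to several windows.
#' Segments with fewer than `min_locs` localizations carry no displacement
#' information and are discarded (counts are reported via a message).
#'
#' @param trajectories A trajectory tibble with `trajectory`, `frame`,
#'   `x_um`, `y_um` (extra columns preserved).
#' @param protocol The `papa_protocol` the movie was acquired with.
#' @param window Post-pulse window length in frames (default 30).
#' @param min_locs Minimum localizations per retained segment (default 2).
#' @param quiet Suppress the discarded-segment message.
#' @return A tibble of segments: `trajectory` (new segment id), `class`
#'   (`"PAPA"` or `"DR"`), `source_trajectory`, `pulse_frame`, `frame`,
#'   `x_um`, `y_um`, plus any extra input columns.
#' @export
split_trajectories <- function(trajectories, protocol, window = 30,
                               min_locs = 2, quiet = FALSE) {
  traj <- as_tibble(trajectories)
  wins <- bind_rows(post_pulse_windows(protocol, "G", window),
                    post_pulse_windows(protocol, "V", window))
  out_proto <- tibble(
    trajectory = integer(), class = character(),
    source_trajectory = integer(), pulse_frame = integer())
  if (nrow(wins) == 0 || nrow(traj) == 0) {
    extras <- traj[0, setdiff(names(traj), c("trajectory")), drop = FALSE]
    return(bind_cols(out_proto, extras[0, setdiff(names(extras),
                                                  names(out_proto))]))
  }
  wins <- arrange(wins, .data$start)
  # windows are disjoint (post_pulse_windows guarantees no pulse inside one,
  # hence no window can start inside another for >=1-frame pulse spacing)
  idx <- findInterval(traj$frame, wins$start)
  inside <- idx >= 1 & traj$frame < wins$end[pmax(idx, 1)]
  seg <- traj[inside, ]
  widx <- idx[inside]
  seg$class <- ifelse(wins$channel[widx] == "G", "PAPA", "DR")
  seg$pulse_frame <- wins$pulse_frame[widx]
  seg$source_trajectory <- seg$trajectory
  key <- paste(seg$source_trajectory, widx)
  seg$trajectory <- match(key, unique(key))
  seg <- arrange(seg, .data$trajectory, .data$frame)

  sizes <- count(seg, .data$trajectory, .data$class, name = "n_locs")
  short <- sizes[sizes$n_locs < min_locs, ]
  if (nrow(short) && !quiet) {
    message(sprintf(
      "discarded %d segment(s) with < %d localizations (PAPA: %d, DR: %d)",
      nrow(short), min_locs, sum(short$class == "PAPA"),
      sum(short$class == "DR")))
  }
  seg <- seg[!seg$trajectory %in% short$trajectory, ]
  front <- c("trajectory", "class", "source_trajectory", "pulse_frame",
             "frame", "x_um", "y_um")
  seg[, c(front, setdiff(names(seg), front))]
}

#' Equalize PAPA and DR trajectory counts
#'
#' Diffusion spectra of PAPA and DR trajectories are compared side by side
#' on equal trajectory numbers: the larger class is randomly subsampled
#' without replacement down to the size of the smaller one.
#'
#' @param segments Output of [split_trajectories()] (must contain both
#'   classes).
#' @param seed Optional integer seed; the subsample is deterministic given
#'   the seed.
#' @return The input tibble with equal numbers of PAPA and DR segments.
#' @export
balance_classes <- function(segments, seed = NULL) {
  seg <- as_tibble(segments)
  ids <- distinct(seg, .data$class, .data$trajectory)
  n_by <- count(ids, .data$class, name = "n")
  if (nrow(n_by) < 2 || any(n_by$n == 0)) {
    abort("both PAPA and DR segments are required to balance")
  }
  n_min <- min(n_by$n)
  pick <- function() {
    keep <- ids |>
      group_by(.data$class) |>
      slice(sample.int(n(), n_min)) |>
      ungroup()
    seg[seg$trajectory %in% keep$trajectory &
          paste(seg$trajectory, seg$class) %in%
            paste(keep$trajectory, keep$class), ]
  }
  if (is.null(seed)) pick() else withr::with_seed(seed, pick())
}

#' Select well-separated reference molecules
#'
#' Keeps localizations whose nearest neighbor is at least `min_separation`
#' away (both members of a close pair are dropped). Used to pick isolated
#' fluorophores in the first movie frame for single-molecule reactivation
#' scoring.
#'
#' @param localizations A tibble of positions; coordinate columns are
#'   `x_px`/`y_px` when present, else `x_um`/`y_um`.
#' @param min_separation Minimum nearest-neighbor distance (same units as
#'   the coordinates; the reference analysis uses 8 pixels).
#' @return The subset of rows passing the isolation test, with a `ref` id
#'   column.
#' @export
select_isolated <- function(localizations, min_separation = 8) {
  locs <- as_tibble(localizations)
  cols <- pick_coord_cols(locs)
  if (nrow(locs) <= 1) {
    locs$ref <- seq_len(nrow(locs))
    return(locs)
  }
  d <- as.matrix(dist(locs[, cols]))
  diag(d) <- Inf
  keep <- apply(d, 1, min) >= min_separation
  out <- locs[keep, ]
  out$ref <- seq_len(nrow(out))
  out
}

pick_coord_cols <- function(df) {
  if (all(c("x_px", "y_px") %in% names(df))) c("x_px", "y_px")
  else if (all(c("x_um", "y_um") %in% names(df))) c("x_um", "y_um")
  else abort("need coordinate columns x_px/y_px or x_um/y_um")
}

#' Score single-molecule fluorescence persistence at fixed positions
#'
#' A reference molecule is scored fluorescent in a frame if at least one
#' localization lies within `radius` of its initial position. The surviving
#' fraction per frame is the mean over reference molecules.
#'
#' @param localizations A tibble with `frame` and coordinate columns.
#' @param references Output of [select_isolated()] (fixed positions with a
#'   `ref` column).
#' @param radius Match radius in coordinate units (the reference analysis
#'   uses 4 pixels).
#' @param frames Frames to score; defaults to `0:max(localizations$frame)`.
#' @return A list of class `papa_persistence` with `series` (tibble `ref`,
#'   `frame`, `fluorescent`) and `surviving` (tibble `frame`, `fraction`).
#' @export
score_persistence <- function(localizations, references, radius = 4,
                              frames = NULL) {
  locs <- as_tibble(localizations)
  cols <- pick_coord_cols(references)
  frames <- frames %||%
    (if (nrow(locs)) 0:max(locs$frame) else integer(0))
  rx <- references[[cols[1]]]; ry <- references[[cols[2]]]
  series <- purrr::map(frames, function(f) {
    fl <- locs[locs$frame == f, ]
    hit <- if (nrow(fl) == 0) rep(FALSE, length(rx)) else {
      dx <- outer(rx, fl[[cols[1]]], "-")
      dy <- outer(ry, fl[[cols[2]]], "-")
      apply(dx^2 + dy^2 <= radius^2, 1, any)
    }
    tibble(ref = references$ref, frame = f, fluorescent = hit)
  })
  series <- bind_rows(series)
  surviving <- series |>
    group_by(.data$frame) |>
    summarise(fraction = mean(.data$fluorescent), .groups = "drop")
  structure(list(series = series, surviving = surviving),
            class = "papa_persistence")
}

#' @export
print.papa_persistence <- function(x, ...) {
  cat("<papa_persistence> ", dplyr::n_distinct(x$series$ref),
      " molecules x ", dplyr::n_distinct(x$series$frame), " frames\n", sep = "")
  invisible(x)
}
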