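#' Detect single-molecule spots in one image
#'
#' Candidate pixels are local maxima of a band-pass (difference-of-Gaussians)
#' filtered image whose estimated integrated photon count exceeds
#' `threshold`. Sub-pixel positions come from least-squares fitting of a 2-D
#' Gaussian (fixed width `psf_sigma_px`) in a 9x9 window, falling back to an
#' intensity-weighted centroid when the fit fails. Detections closer than
#' `2 * psf_sigma_px` are merged, keeping the brighter one.
#'
#' @param image 2-D numeric matrix of pixel counts.
#' @param psf_sigma_px Expected PSF sigma in pixels.
#' @param threshold Detection threshold in estimated photons (background
#'   subtracted).
#' @return A tibble `x_px`, `y_px`, `intensity` (estimated photons), `score`
#'   (band-pass peak response). Coordinates are in pixel units with pixel
#'   centers at half-integers.
#' @export
detect_spots <- function(image, psf_sigma_px = 1, threshold = 100) {
  if (length(dim(image)) != 2) abort("`image` must be a 2-D matrix")
  if (!all(is.finite(image))) abort("`image` must be finite")
  img <- image * 1.0
  bg_blur <- EBImage::gblur(img, sigma = max(2.5 * psf_sigma_px, 2))
  bp <- EBImage::gblur(img, sigma = psf_sigma_px) - bg_blur

  ny <- nrow(img); nx <- ncol(img)
  # 3x3 local maxima, excluding a 1-px border
  is_max <- matrix(FALSE, ny, nx)
  core_y <- 2:(ny - 1); core_x <- 2:(nx - 1)
  center <- bp[core_y, core_x]
  ok <- matrix(TRUE, length(core_y), length(core_x))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & (center >= bp[core_y + dy, core_x + dx])
  }
  is_max[core_y, core_x] <- ok & (center > 0)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_spots())

  half <- 4L
  spots <- purrr::map(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    y0 <- max(1, cy - half); y1 <- min(ny, cy + half)
    x0 <- max(1, cx - half); x1 <- min(nx, cx + half)
    win <- img[y0:y1, x0:x1]
    # background from the window border ring, where the PSF contributes
    # little, rather than the smoothed image (which includes spot light)
    ring <- win[row(win) %in% c(1, nrow(win)) | col(win) %in% c(1, ncol(win))]
    bg <- median(ring)
    photons <- sum(win - bg)
    if (photons < threshold) return(NULL)
    fit <- fit_gaussian_2d(win, psf_sigma_px, bg)
    tibble(x_px = x0 - 1 + fit$x, y_px = y0 - 1 + fit$y,
           intensity = photons, score = bp[cy, cx])
  })
  spots <- bind_rows(spots)
  if (nrow(spots) == 0) return(empty_spots())
  merge_close_spots(spots, 2 * psf_sigma_px)
}

empty_spots <- function() {
  tibble(x_px = numeric(), y_px = numeric(),
         intensity = numeric(), score = numeric())
}

# Least-squares Gaussian (fixed sigma) on a window; coordinates are relative
# to the window origin, pixel centers at half-integers.
fit_gaussian_2d <- function(win, sigma, bg) {
  ny <- nrow(win); nx <- ncol(win)
  yy <- rep(seq_len(ny) - 0.5, times = nx)
  xx <- rep(seq_len(nx) - 0.5, each = ny)
  z <- as.vector(win)
  w <- pmax(z - bg, 0)
  cx <- sum(w * xx) / max(sum(w), 1e-12)
  cy <- sum(w * yy) / max(sum(w), 1e-12)
  fit <- tryCatch({
    df <- data.frame(z = z, xx = xx, yy = yy)
    m <- suppressWarnings(
      nls(z ~ b + A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * sigma^2)),
          data = df,
          start = list(b = bg, A = max(z) - bg, x0 = cx, y0 = cy),
          control = list(warnOnly = TRUE, maxiter = 50)))
    cf <- coef(m)
    if (cf[["x0"]] < 0 || cf[["x0"]] > nx || cf[["y0"]] < 0 || cf[["y0"]] > ny) {
      NULL
    } else list(x = cf[["x0"]], y = cf[["y0"]])
  }, error = function(e) NULL)
  fit %||% list(x = cx, y = cy)
}

merge_close_spots <- function(spots, min_dist) {
  spots <- arrange(spots, dplyr::desc(.data$intensity))
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      j <- (i + 1):nrow(spots)
      d <- sqrt((spots$x_px[j] - spots$x_px[i])^2 +
                  (spots$y_px[j] - spots$y_px[i])^2)
      keep[j][d < min_dist] <- FALSE
    }
  }
  arrange(spots[keep, ], .data$x_px, .data$y_px)
}

#' Localize every frame of a movie
#'
#' @param movie A `papa_movie` or array `[row, col, frame]`.
#' @param pixel_size_um Pixel size used to add `x_um`, `y_um` columns; taken
#'   from the movie's camera attribute when present.
#' @inheritParams detect_spots
#' @return A tibble `frame` (0-based), `x_px`, `y_px`, `x_um`, `y_um`,
#'   `intensity`, `score`.
#' @export
localize_movie <- function(movie, psf_sigma_px = 1, threshold = 100,
                           pixel_size_um = NULL) {
  cam <- attr(movie, "camera")
  pixel_size_um <- pixel_size_um %||% (cam$pixel_size_um %||% 1)
  frames <- purrr::map(seq_len(dim(movie)[3]), function(f) {
    sp <- detect_spots(movie[, , f], psf_sigma_px, threshold)
    if (nrow(sp)) sp$frame <- f - 1L
    sp
  })
  out <- bind_rows(frames)
  if (nrow(out) == 0) {
    return(tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
                  x_um = numeric(), y_um = numeric(),
                  intensity = numeric(), score = numeric()))
  }
  out$x_um <- out$x_px * pixel_size_um
  out$y_um <- out$y_px * pixel_size_um
  select(out, "frame", "x_px", "y_px", "x_um", "y_um", "intensity", "score")
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbor linking: for each frame transition, candidate
#' (track, detection) pairs within `max_disp_um` are assigned in ascending
#' order of distance (ties broken by detection coordinates, so the result
#' does not depend on input row order); unmatched detections start new
#' trajectories. Tracks may bridge gaps up to `max_gap` frames.
#'
#' The default `max_disp_um = 1.5` at 7.48 ms/frame covers the fastest
#' state considered here (D = 8.3 um^2/s) to beyond 4 SD of its per-frame
#' jump.
#'
#' @param localizations A tibble with `frame`, `x_um`, `y_um` (extra columns
#'   are preserved).
#' @param max_disp_um Maximum linking displacement, um.
#' @param max_gap Maximum bridged frame gap (default 0).
#' @return The input tibble with a `trajectory` column, sorted by
#'   trajectory and frame.
#' @export
link_trajectories <- function(localizations, max_disp_um = 1.5, max_gap = 0) {
  locs <- as_tibble(localizations)
  req <- c("frame", "x_um", "y_um")
  miss <- setdiff(req, names(locs))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(locs) == 0) {
    locs$trajectory <- integer()
    return(locs)
  }
  ord <- order(locs$frame, locs$x_um, locs$y_um)
  locs <- locs[ord, ]
  traj <- integer(nrow(locs))
  next_id <- 1L
  # active tracks: id, last x, y, frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  for (f in sort(unique(locs$frame))) {
    idx <- which(locs$frame == f)
    live <- which(act_f >= f - 1L - max_gap & act_f < f)
    assigned_det <- rep(FALSE, length(idx))
    assigned_trk <- rep(FALSE, length(live))
    if (length(live) && length(idx)) {
      dx <- outer(act_x[live], locs$x_um[idx], "-")
      dy <- outer(act_y[live], locs$y_um[idx], "-")
      dmat <- sqrt(dx^2 + dy^2)
      pairs <- which(dmat <= max_disp_um, arr.ind = TRUE)
      if (nrow(pairs)) {
        dvals <- dmat[pairs]
        o <- order(dvals, locs$x_um[idx[pairs[, 2]]], locs$y_um[idx[pairs[, 2]]])
        for (p in o) {
          ti <- pairs[p, 1]; di <- pairs[p, 2]
          if (assigned_trk[ti] || assigned_det[di]) next
          assigned_trk[ti] <- TRUE; assigned_det[di] <- TRUE
          id <- act_id[live[ti]]
          traj[idx[di]] <- id
          act_x[live[ti]] <- locs$x_um[idx[di]]
          act_y[live[ti]] <- locs$y_um[idx[di]]
          act_f[live[ti]] <- f
        }
      }
    }
    new <- which(!assigned_det)
    if (length(new)) {
      ids <- next_id + seq_along(new) - 1L
      traj[idx[new]] <- ids
      act_id <- c(act_id, ids)
      act_x <- c(act_x, locs$x_um[idx[new]])
      act_y <- c(act_y, locs$y_um[idx[new]])
      act_f <- c(act_f, rep(f, length(new)))
      next_id <- next_id + length(new)
    }
  }
  locs$trajectory <- traj
  arrange(locs, .data$trajectory, .data$frame)
}

#' Read and write trajectory tables
#'
#' CSV round-trips are lossless for all columns; unknown columns are
#' preserved. Required columns are `trajectory`, `frame`, `x_um`, `y_um`.
#' Files whose frames are unsorted within a trajectory are sorted on read
#' with a warning.
#'
#' @param path CSV file path.
#' @return `read_trajectories()` returns a tibble; `write_trajectories()`
#'   returns `path` invisibly.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("trajectory", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(paste("trajectory file missing required columns:",
                paste(miss, collapse = ", ")))
  }
  if (nrow(df) > 1) {
    unsorted <- df |>
      group_by(.data$trajectory) |>
      summarise(bad = is.unsorted(.data$frame), .groups = "drop") |>
      pull(.data$bad) |>
      any()
    if (unsorted) {
      warning("frames unsorted within trajectory; sorting")
      df <- arrange(df, .data$trajectory, .data$frame)
    }
  }
  df
}

#' @rdname read_trajectories
#' @param trajectories A trajectory tibble.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(as_tibble(trajectories), path)
  invisible(path)
}
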