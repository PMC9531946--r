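#' Total field-of-view intensity per frame
#'
#' Sums all pixels of every movie frame; no background subtraction is
#' applied (raw "sawtooth" traces are analyzed as acquired).
#'
#' @param movie A `papa_movie` or array `[row, col, frame]`.
#' @param protocol Optional `papa_protocol` to attach to the trace.
#' @return A `papa_trace` tibble: `frame` (0-based), `intensity`.
#' @export
total_intensity <- function(movie, protocol = NULL) {
  vals <- apply(movie, 3, sum)
  new_trace(tibble(frame = seq_along(vals) - 1L, intensity = vals),
            protocol %||% attr(movie, "protocol"))
}

#' Average intensity traces across cells
#'
#' @param traces A list of `papa_trace` tibbles of equal length, or one
#'   tibble with columns `frame`, `intensity`, `cell`.
#' @return A `papa_trace` tibble of the frame-by-frame arithmetic mean.
#' @export
average_traces <- function(traces) {
  if (is.data.frame(traces)) {
    df <- as_tibble(traces)
    if (!"cell" %in% names(df)) return(df)
    proto <- attr(traces, "protocol")
    out <- df |>
      group_by(.data$frame) |>
      summarise(intensity = mean(.data$intensity), .groups = "drop")
    return(new_trace(out, proto))
  }
  lens <- vapply(traces, nrow, integer(1))
  if (length(unique(lens)) != 1) abort("traces must have equal length")
  proto <- attr(traces[[1]], "protocol")
  m <- vapply(traces, function(tr) tr$intensity, numeric(lens[1]))
  new_trace(tibble(frame = traces[[1]]$frame, intensity = rowMeans(m)), proto)
}

#' Per-pulse intensity increase
#'
#' For each reactivation pulse at frame `p`, the response is the mean
#' intensity over the `w_post` frames after the pulse minus the mean over
#' the `w_pre` frames before it:
#' `mean(trace[p+1 .. p+w_post]) - mean(trace[p-w_pre .. p-1])`.
#' Windows that would collide with another reactivation pulse or run off
#' the movie are an error. `skip_first` drops the first pulse of each cycle
#' for each channel (used when the first response of a cycle is saturated
#' differently from later ones).
#'
#' @param trace A `papa_trace` tibble (or any tibble with `frame`,
#'   `intensity`).
#' @param protocol The acquisition `papa_protocol`; defaults to the trace's
#'   attached protocol.
#' @param channel Channels to evaluate (default both `"G"` and `"V"`).
#' @param w_pre,w_post Window lengths in frames (default 10 each).
#' @param skip_first Drop each cycle's first pulse per channel.
#' @return A `papa_pulse_response` tibble: `channel`, `cycle`,
#'   `pulse_frame`, `increase`.
#' @export
pulse_response <- function(trace, protocol = NULL, channel = c("G", "V"),
                           w_pre = 10, w_post = 10, skip_first = FALSE) {
  protocol <- protocol %||% attr(trace, "protocol")
  if (is.null(protocol)) abort("no protocol supplied or attached to trace")
  channel <- normalize_channel(channel)
  intensity <- trace$intensity[order(trace$frame)]
  total <- length(intensity)
  all_pulses <- sort(unique(c(pulse_frames(protocol, "G"),
                              pulse_frames(protocol, "V"))))
  sch <- protocol$schedule
  rows <- purrr::map(channel, function(ch) {
    pf <- pulse_frames(protocol, ch)
    if (length(pf) == 0) return(NULL)
    cyc <- sch$cycle[match(pf, sch$frame)]
    if (skip_first) {  # drop each cycle's first pulse of this channel
      keep <- duplicated(cyc)
      pf <- pf[keep]; cyc <- cyc[keep]
    }
    inc <- vapply(pf, function(p) {
      pre <- (p - w_pre):(p - 1)
      post <- (p + 1):(p + w_post)
      if (min(pre) < 0 || max(post) >= total) {
        abort("pulse-response window runs outside the movie")
      }
      others <- setdiff(all_pulses, p)
      if (any(others %in% c(pre, post))) {
        abort("pulse-response window collides with another pulse")
      }
      mean(intensity[post + 1]) - mean(intensity[pre + 1])
    }, numeric(1))
    tibble(channel = ch, cycle = cyc, pulse_frame = pf, increase = inc)
  })
  out <- bind_rows(rows)
  structure(out, class = c("papa_pulse_response", class(tibble())),
            w_pre = w_pre, w_post = w_post)
}

#' PAPA/DR ratio of a pulse response
#'
#' The ratio of the mean green-pulse intensity increase to the mean
#' violet-pulse increase: a normalized proximity signal that cancels
#' cell-to-cell variation in labeled protein concentration.
#'
#' @param response A `papa_pulse_response` from [pulse_response()].
#' @return `mean(green increases) / mean(violet increases)`.
#' @export
papa_dr_ratio <- function(response) {
  g <- response$increase[response$channel == "G"]
  v <- response$increase[response$channel == "V"]
  if (length(g) == 0 || length(v) == 0) {
    abort("need at least one green and one violet pulse")
  }
  mean(g) / mean(v)
}

#' Linear reactivation rate from ratio vs. pulse duration
#'
#' For short pulses the PAPA/DR ratio grows linearly with the green pulse
#' duration; the relative reactivation rate is the slope of a least-squares
#' fit through the origin (`y = a x`), inverse-variance weighted when
#' standard errors are supplied.
#'
#' @param data A tibble with columns `pulse_ms` and `ratio`, optionally
#'   `se`.
#' @return A `papa_linear_rate` object: `slope`, `se`, `r_squared`
#'   (through-origin convention: `1 - SS_res / sum(y^2)`), `n`, and the
#'   data.
#' @export
fit_linear_rate <- function(data) {
  df <- as_tibble(data)
  if (!all(c("pulse_ms", "ratio") %in% names(df))) {
    abort("`data` needs columns pulse_ms and ratio")
  }
  if (nrow(df) < 2) abort("at least two pulse durations are required")
  w <- if ("se" %in% names(df)) 1 / df$se^2 else rep(1, nrow(df))
  slope <- sum(w * df$pulse_ms * df$ratio) / sum(w * df$pulse_ms^2)
  res <- df$ratio - slope * df$pulse_ms
  ss_tot <- sum(w * df$ratio^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(w * res^2) / ss_tot
  se <- sqrt(sum(w * res^2) / max(nrow(df) - 1, 1) / sum(w * df$pulse_ms^2))
  structure(list(slope = slope, se = se, r_squared = r2, n = nrow(df),
                 data = df),
            class = "papa_linear_rate")
}

#' @export
print.papa_linear_rate <- function(x, ...) {
  cat(sprintf("<papa_linear_rate> slope %.4g (se %.2g), R^2 %.3f, n = %d\n",
              x$slope, x$se, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_linear_rate
#' @param fit,reference `papa_linear_rate` fits; the relative rate is
#'   `fit$slope / reference$slope`.
#' @export
relative_rate <- function(fit, reference) fit$slope / reference$slope

#' Summed intensity of one protocol phase
#'
#' @param trace A `papa_trace` tibble.
#' @param protocol The acquisition protocol.
#' @param phase 1-based phase index within the cycle.
#' @param cycle 0-based cycle index (default 0).
#' @return Summed intensity over the frames of that phase occurrence.
#' @export
phase_intensity <- function(trace, protocol = NULL, phase, cycle = 0) {
  protocol <- protocol %||% attr(trace, "protocol")
  sch <- protocol$schedule
  sel <- sch$frame[sch$phase == phase & sch$cycle == cycle]
  if (length(sel) == 0) abort("no such phase/cycle")
  sum(trace$intensity[match(sel, trace$frame)])
}

#' Fractional reactivation from a five-phase shelving protocol
#'
#' In the reference kinetics protocol, phases 1, 3, and 5 measure intensity
#' before shelving, after shelving, and after a violet reactivation train.
#' Fractional reactivation is the recovered signal normalized by the signal
#' lost to shelving/bleaching: `(i5 - i3) / (i1 - i3)`.
#'
#' @param i1,i3,i5 Phase intensities (summed or mean; any common scale).
#' @return Fraction of the shelved/bleached signal recovered.
#' @export
fractional_reactivation <- function(i1, i3, i5) {
  if (i1 <= i3) abort("no shelving occurred (i1 <= i3); fraction undefined")
  (i5 - i3) / (i1 - i3)
}

#' @rdname fractional_reactivation
#' @param trace,protocol Trace and five-phase protocol; intensities are the
#'   summed phase intensities of phases 1, 3, and 5.
#' @export
measure_reactivation <- function(trace, protocol = NULL) {
  protocol <- protocol %||% attr(trace, "protocol")
  fractional_reactivation(
    phase_intensity(trace, protocol, 1),
    phase_intensity(trace, protocol, 3),
    phase_intensity(trace, protocol, 5))
}

#' Saturating single-exponential fit of reactivation vs. dose
#'
#' Fits `f(x) = A (1 - exp(-k x))` to fractional-reactivation measurements
#' as a function of reactivation dose (e.g. number of violet frames).
#'
#' @param data A tibble with columns `dose` and `fraction`.
#' @return A `papa_exp_fit`: `amplitude`, `rate`, their standard errors,
#'   the covariance matrix, and the data. All-zero fractions return
#'   amplitude 0.
#' @export
fit_exponential_reactivation <- function(data) {
  df <- as_tibble(data)
  if (!all(c("dose", "fraction") %in% names(df))) {
    abort("`data` needs columns dose and fraction")
  }
  if (nrow(df) < 3) abort("at least three dose points are required")
  if (all(df$fraction == 0)) {
    return(structure(list(amplitude = 0, rate = NA_real_,
                          se_amplitude = 0, se_rate = NA_real_,
                          vcov = NULL, data = df),
                     class = "papa_exp_fit"))
  }
  a0 <- max(df$fraction)
  pos <- df$fraction > 0 & df$fraction < a0
  k0 <- if (any(pos)) {
    # linearized start from the smallest positive dose response
    i <- which(pos)[1]
    max(-log(1 - df$fraction[i] / (a0 * 1.05)) / df$dose[i], 1e-6)
  } else 1 / max(df$dose)
  m <- suppressWarnings(
    nls(fraction ~ A * (1 - exp(-k * dose)), data = df,
        start = list(A = a0, k = k0),
        control = list(warnOnly = TRUE, maxiter = 200)))
  cf <- coef(m)
  vc <- tryCatch(vcov(m), error = function(e) matrix(NA, 2, 2))
  structure(list(amplitude = cf[["A"]], rate = cf[["k"]],
                 se_amplitude = sqrt(vc[1, 1]), se_rate = sqrt(vc[2, 2]),
                 vcov = vc, data = df),
            class = "papa_exp_fit")
}

#' @export
print.papa_exp_fit <- function(x, ...) {
  cat(sprintf("<papa_exp_fit> A = %.4g, k = %.4g per dose unit\n",
              x$amplitude, x$rate))
  invisible(x)
}

#' Localization-rate trace
#'
#' Number of localizations per frame, averaged over cells when a `cell`
#' column is present: the localization-space analogue of the intensity
#' sawtooth.
#'
#' @param localizations A tibble with a `frame` column (localizations or
#'   trajectory rows), optionally `cell`.
#' @param n_frames Trace length; defaults to the attached protocol's length
#'   or `max(frame) + 1`.
#' @param protocol Optional protocol to attach.
#' @return A `papa_trace` tibble `frame`, `intensity` (localizations per
#'   frame per cell).
#' @export
localization_rate_trace <- function(localizations, n_frames = NULL,
                                    protocol = NULL) {
  locs <- as_tibble(localizations)
  n_frames <- n_frames %||%
    (if (!is.null(protocol)) nrow(protocol$schedule)
     else if (nrow(locs)) max(locs$frame) + 1L else 0L)
  n_cells <- if ("cell" %in% names(locs) && nrow(locs)) {
    dplyr::n_distinct(locs$cell)
  } else 1L
  counts <- tabulate(locs$frame + 1L, nbins = n_frames)
  new_trace(tibble(frame = seq_len(n_frames) - 1L,
                   intensity = counts / n_cells), protocol)
}
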