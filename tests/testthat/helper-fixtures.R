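# Shared fixtures built in code.

# the standard 10-cycle alternating-pulse protocol
demo_protocol <- function(pre_shelving_s = 0) {
  parse_protocol(
    paste("10 cycles of 250 R [2 ms], 1 V [7 ms], 500 R [2 ms],",
          "1 G [7 ms], 250 R [2 ms]"),
    pre_shelving_s = pre_shelving_s)
}

# Direct two-state trajectory generator, independent of the photophysics
# simulator: n tracks, geometric length (mean mean_len frames, >= 2),
# static bound/free assignment.
gen_two_state_tracks <- function(n, f_bound, d_bound = 0.01, d_free = 8.3,
                                 sigma = 0.035, dt_ms = 7.48,
                                 mean_len = 8, seed = 1) {
  withr::with_seed(seed, {
    dt <- dt_ms / 1000
    len <- pmax(stats::rgeom(n, 1 / (mean_len - 1)) + 2L, 2L)
    bound <- stats::runif(n) < f_bound
    d <- ifelse(bound, d_bound, d_free)
    rows <- lapply(seq_len(n), function(i) {
      steps <- len[i] - 1L
      x <- cumsum(c(0, stats::rnorm(steps, 0, sqrt(2 * d[i] * dt))))
      y <- cumsum(c(0, stats::rnorm(steps, 0, sqrt(2 * d[i] * dt))))
      tibble::tibble(
        trajectory = i, frame = seq_len(len[i]) - 1L,
        x_um = x + stats::rnorm(len[i], 0, sigma),
        y_um = y + stats::rnorm(len[i], 0, sigma),
        bound = bound[i])
    })
    dplyr::bind_rows(rows)
  })
}

# tracks at one diffusion coefficient
gen_single_d_tracks <- function(n, d, sigma = 0.035, dt_ms = 7.48,
                                mean_len = 8, seed = 1) {
  gen_two_state_tracks(n, f_bound = 1, d_bound = d, d_free = d,
                       sigma = sigma, dt_ms = dt_ms, mean_len = mean_len,
                       seed = seed)
}
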