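#' Fixed grid of diffusion coefficients
#'
#' The diffusion spectrum is inferred over a fixed ascending array of
#' diffusion coefficients; the default is 100 log-spaced values from 0.01
#' to 100 um^2/s. The grid minimum acts as the "bound" anchor: with a
#' localization error of sigma, states slower than roughly sigma^2/dt are
#' unresolvable and their mass accumulates at the grid floor.
#'
#' @param d_values Ascending diffusion coefficients, um^2/s.
#' @param sigma_loc Assumed localization error SD per axis, um (fixed known
#'   input, not estimated).
#' @param frame_interval_ms Frame interval, ms.
#' @return A `papa_grid` object.
#' @export
diffusion_grid <- function(d_values = 10^seq(log10(0.01), log10(100),
                                             length.out = 100),
                           sigma_loc = 0.035, frame_interval_ms = 7.48) {
  if (is.unsorted(d_values, strictly = TRUE)) {
    abort("`d_values` must be strictly increasing")
  }
  if (any(d_values < 0) || sigma_loc < 0 || frame_interval_ms <= 0) {
    abort("grid parameters out of range")
  }
  structure(list(d_values = d_values, sigma_loc = sigma_loc,
                 frame_interval_ms = frame_interval_ms),
            class = "papa_grid")
}

# mean squared 2-D displacement per frame for diffusion d on this grid
grid_b <- function(d, sigma_loc, frame_interval_ms) {
  4 * (d * frame_interval_ms / 1000 + sigma_loc^2)
}

# Per-trajectory displacement summaries: consecutive-frame squared jumps
# only (gap-spanning displacements are excluded from the likelihood).
jump_summaries <- function(trajectories) {
  traj <- as_tibble(trajectories)
  req <- c("trajectory", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(traj))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  traj <- arrange(traj, .data$trajectory, .data$frame)
  traj |>
    group_by(.data$trajectory) |>
    summarise(
      n_jumps = sum(diff(.data$frame) == 1),
      sum_r2 = sum(((diff(.data$x_um))^2 + (diff(.data$y_um))^2)[
        diff(.data$frame) == 1]),
      .groups = "drop") |>
    filter(.data$n_jumps > 0)
}

#' Displacement log-likelihood of trajectories at given diffusion
#' coefficients
#'
#' Under 2-D Brownian motion with localization error, the squared
#' consecutive-frame displacement r^2 is exponentially distributed with
#' mean `b = 4 (D dt + sigma^2)`; a trajectory's log-likelihood at D is
#' `sum_i (-log b - r2_i / b)`. Jumps within a trajectory are treated as
#' independent given its state (the standard state-array approximation).
#'
#' @param trajectories A trajectory tibble (`trajectory`, `frame`, `x_um`,
#'   `y_um`).
#' @param d Diffusion coefficient(s), um^2/s.
#' @param sigma_loc Localization error SD, um.
#' @param frame_interval_ms Frame interval, ms.
#' @return A tibble `trajectory`, `d`, `n_jumps`, `loglik` (one row per
#'   trajectory x d combination).
#' @export
jump_loglik <- function(trajectories, d, sigma_loc = 0.035,
                        frame_interval_ms = 7.48) {
  js <- jump_summaries(trajectories)
  if (nrow(js) == 0) abort("no consecutive-frame displacements available")
  out <- tidyr::expand_grid(js, d = d)
  b <- grid_b(out$d, sigma_loc, frame_interval_ms)
  out$loglik <- -out$n_jumps * log(b) - out$sum_r2 / b
  select(out, "trajectory", "d", "n_jumps", "loglik")
}

# loglik matrix (trajectories x grid states) from summaries
loglik_matrix <- function(js, d_values, sigma_loc, frame_interval_ms) {
  b <- grid_b(d_values, sigma_loc, frame_interval_ms)
  -outer(js$n_jumps, log(b)) - outer(js$sum_r2, 1 / b)
}

# One EM pass given log-occupations; returns responsibilities and objective.
em_responsibilities <- function(LL, log_w) {
  lr <- sweep(LL, 2, log_w, "+")
  m <- apply(lr, 1, max)
  r <- exp(lr - m)
  rs <- rowSums(r)
  list(resp = r / rs, logmarg = sum(m + log(rs)))
}

#' Infer a diffusion spectrum by expectation-maximization
#'
#' Fits a mixture over the fixed grid of diffusion coefficients: each
#' trajectory belongs to one grid state, jumps within a trajectory are
#' conditionally independent, and the state occupations carry a symmetric
#' Dirichlet(`prior_alpha`) prior. Occupations are estimated by MAP-EM over
#' per-trajectory responsibilities, starting from the uniform distribution;
#' with the default flat prior (`prior_alpha = 1`) this is maximum
#' likelihood. The log-posterior is non-decreasing over iterations and is
#' recorded in the result.
#'
#' @param trajectories A trajectory tibble; trajectories contribute their
#'   consecutive-frame displacements (at least one is required).
#' @param grid A [diffusion_grid()].
#' @param prior_alpha Symmetric Dirichlet concentration (default 1, flat).
#' @param max_iter Maximum EM iterations (default 1000). `max_iter = 0`
#'   returns the uniform initialization.
#' @param tol Convergence tolerance on the maximum occupation change.
#' @return A `papa_spectrum` object: `spectrum` (tibble `d`, `occupation`),
#'   `n_trajectories`, `n_jumps`, `converged`, `n_iter`, `log_posterior`
#'   (trace), and the `grid`.
#' @export
infer_spectrum <- function(trajectories, grid = diffusion_grid(),
                           prior_alpha = 1, max_iter = 1000, tol = 1e-6) {
  stopifnot(inherits(grid, "papa_grid"))
  if (prior_alpha < 1) abort("`prior_alpha` must be >= 1 for MAP-EM")
  js <- jump_summaries(trajectories)
  if (nrow(js) == 0) abort("no trajectories with usable jumps")
  J <- length(grid$d_values)
  N <- nrow(js)
  LL <- loglik_matrix(js, grid$d_values, grid$sigma_loc,
                      grid$frame_interval_ms)
  w <- rep(1 / J, J)
  lp <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- em_responsibilities(LL, log(w))
    lp <- c(lp, e$logmarg + (prior_alpha - 1) * sum(log(pmax(w, 1e-300))))
    nj <- colSums(e$resp)
    w_new <- nj + prior_alpha - 1
    w_new <- w_new / sum(w_new)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(
    list(spectrum = tibble(d = grid$d_values, occupation = w),
         n_trajectories = N, n_jumps = sum(js$n_jumps),
         converged = converged, n_iter = iter, log_posterior = lp,
         grid = grid),
    class = "papa_spectrum")
}

#' @export
print.papa_spectrum <- function(x, ...) {
  cat("<papa_spectrum> ", length(x$grid$d_values), " states, ",
      x$n_trajectories, " trajectories (", x$n_jumps, " jumps); ",
      if (x$converged) "converged" else "not converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

#' Fit a reduced fixed-state model
#'
#' Maximum-likelihood state fractions for a small fixed set of diffusion
#' coefficients (the local maxima of the full spectrum), e.g. the two-state
#' bound/free set `{0.01, 8.3}` um^2/s or the three-state sets
#' `{0.01, 2.1, 13.2}` and `{0.01, 1.3, 15.8}`. Same mixture model and EM
#' as [infer_spectrum()], with a flat prior.
#'
#' @param trajectories A trajectory tibble.
#' @param d_states At least two fixed diffusion coefficients, um^2/s.
#' @param sigma_loc Localization error SD, um.
#' @param frame_interval_ms Frame interval, ms.
#' @param max_iter,tol EM controls.
#' @return A `papa_reduced_fit` object: `fractions` (tibble `d`,
#'   `fraction`), `loglik`, `n_trajectories`, `n_jumps`, `converged`.
#' @export
fit_reduced <- function(trajectories, d_states = c(0.01, 8.3),
                        sigma_loc = 0.035, frame_interval_ms = 7.48,
                        max_iter = 1000, tol = 1e-8) {
  if (length(d_states) < 2) abort("at least two fixed states are required")
  grid <- diffusion_grid(sort(d_states), sigma_loc, frame_interval_ms)
  fit <- infer_spectrum(trajectories, grid, prior_alpha = 1,
                        max_iter = max_iter, tol = tol)
  structure(
    list(fractions = rename(fit$spectrum, fraction = "occupation"),
         loglik = tail(fit$log_posterior, 1),
         n_trajectories = fit$n_trajectories, n_jumps = fit$n_jumps,
         converged = fit$converged),
    class = "papa_reduced_fit")
}

#' @export
print.papa_reduced_fit <- function(x, ...) {
  cat("<papa_reduced_fit>\n")
  print(x$fractions)
  invisible(x)
}

#' Fraction bound from a diffusion spectrum
#'
#' Sums the occupation at grid states strictly below the threshold
#' diffusion coefficient (0.15 um^2/s by default), interpreted as the
#' chromatin-bound fraction.
#'
#' @param spectrum A `papa_spectrum`, `papa_reduced_fit`, or tibble with
#'   columns `d` and `occupation`/`fraction`.
#' @param threshold Diffusion coefficient threshold, um^2/s.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_bound <- function(spectrum, threshold = 0.15) {
  df <- spectrum_table(spectrum)
  if (threshold < min(df$d) || threshold > max(df$d)) {
    abort("`threshold` must lie within the grid range")
  }
  sum(df$occupation[df$d < threshold])
}

spectrum_table <- function(spectrum) {
  if (inherits(spectrum, "papa_spectrum")) return(spectrum$spectrum)
  if (inherits(spectrum, "papa_reduced_fit")) {
    return(rename(spectrum$fractions, occupation = "fraction"))
  }
  df <- as_tibble(spectrum)
  if ("fraction" %in% names(df) && !"occupation" %in% names(df)) {
    df <- rename(df, occupation = "fraction")
  }
  if (!all(c("d", "occupation") %in% names(df))) {
    abort("need a spectrum with columns `d` and `occupation`")
  }
  df
}

#' Local maxima of a diffusion spectrum
#'
#' @param spectrum A `papa_spectrum` or spectrum tibble.
#' @param min_occupation Ignore peaks carrying less mass than this.
#' @return A tibble `d`, `occupation` at the local maxima (endpoints count
#'   when they exceed their single neighbor).
#' @export
spectrum_peaks <- function(spectrum, min_occupation = 0.01) {
  df <- spectrum_table(spectrum)
  occ <- df$occupation
  n <- length(occ)
  left <- c(-Inf, occ[-n])
  right <- c(occ[-1], -Inf)
  is_peak <- occ > left & occ >= right & occ >= min_occupation
  df[is_peak, ]
}
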