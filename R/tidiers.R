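#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per estimated component/parameter; `glance()`
#' returns a one-row model summary, following the broom conventions.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name papaspt-tidiers
NULL

#' @rdname papaspt-tidiers
#' @export
tidy.papa_spectrum <- function(x, ...) {
  rename(x$spectrum, d_um2_s = "d")
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_spectrum <- function(x, ...) {
  tibble(n_trajectories = x$n_trajectories, n_jumps = x$n_jumps,
         n_states = length(x$grid$d_values),
         fraction_bound = fraction_bound(x),
         converged = x$converged, n_iter = x$n_iter,
         log_posterior = tail(x$log_posterior, 1) %||% NA_real_)
}

#' @rdname papaspt-tidiers
#' @export
tidy.papa_reduced_fit <- function(x, ...) {
  rename(x$fractions, d_um2_s = "d")
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_reduced_fit <- function(x, ...) {
  tibble(n_trajectories = x$n_trajectories, n_jumps = x$n_jumps,
         n_states = nrow(x$fractions), loglik = x$loglik,
         converged = x$converged)
}

#' @rdname papaspt-tidiers
#' @export
tidy.papa_mixture_fit <- function(x, ...) {
  tibble(component = x$labels, fraction = c(x$f_a, x$f_b))
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_mixture_fit <- function(x, ...) {
  tibble(f_a = x$f_a, f_b = x$f_b, ratio = x$f_a / x$f_b,
         residual = x$residual)
}

#' @rdname papaspt-tidiers
#' @export
tidy.papa_linear_rate <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope, std.error = x$se)
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_linear_rate <- function(x, ...) {
  tibble(slope = x$slope, r.squared = x$r_squared, n = x$n)
}

#' @rdname papaspt-tidiers
#' @export
tidy.papa_exp_fit <- function(x, ...) {
  tibble(term = c("amplitude", "rate"),
         estimate = c(x$amplitude, x$rate),
         std.error = c(x$se_amplitude, x$se_rate))
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_exp_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, rate = x$rate, n = nrow(x$data))
}

#' @rdname papaspt-tidiers
#' @export
tidy.papa_lifetime <- function(x, ...) {
  tibble(term = "tau_ns", estimate = x$tau_ns, std.error = x$se_ns)
}

#' @rdname papaspt-tidiers
#' @export
glance.papa_lifetime <- function(x, ...) {
  tibble(tau_ns = x$tau_ns, se_ns = x$se_ns, n_photons = x$n_photons,
         loglik = x$loglik)
}
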