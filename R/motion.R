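#' Two-state Brownian motion model
#'
#' Molecules are either chromatin-bound (diffusion coefficient `d_bound`)
#' or free (`d_free`); a fraction `f_bound` is bound. With `k_switch = 0`
#' (default) the assignment is static per molecule; with `k_switch > 0`
#' molecules interconvert with total switching rate `k_switch` per second,
#' partitioned so the stationary bound fraction equals `f_bound`.
#' Per-axis displacements over one frame are Normal(0, 2 D dt); observed
#' positions add independent Normal(0, sigma_loc^2) localization error per
#' axis. Motion is confined to a square field of view with reflecting
#' boundaries.
#'
#' @param d_free Free-state diffusion coefficient, um^2/s.
#' @param d_bound Bound-state diffusion coefficient, um^2/s.
#' @param f_bound Fraction of molecules in the bound state.
#' @param k_switch Total bound<->free switching rate per second (0 = static).
#' @param sigma_loc Localization error SD per axis, um.
#' @param frame_interval_ms Frame interval, ms.
#' @param fov_um Side length of the square field of view, um.
#' @return A `papa_motion` parameter object.
#' @export
motion_model <- function(d_free = 8.3, d_bound = 0.01, f_bound = 0,
                         k_switch = 0, sigma_loc = 0.035,
                         frame_interval_ms = 7.48, fov_um = 20) {
  if (f_bound < 0 || f_bound > 1) abort("`f_bound` must be in [0, 1]")
  if (d_free < 0 || d_bound < 0 || sigma_loc < 0 || k_switch < 0) {
    abort("`d_free`, `d_bound`, `sigma_loc`, `k_switch` must be >= 0")
  }
  if (frame_interval_ms <= 0 || fov_um <= 0) {
    abort("`frame_interval_ms` and `fov_um` must be > 0")
  }
  structure(list(d_free = d_free, d_bound = d_bound, f_bound = f_bound,
                 k_switch = k_switch, sigma_loc = sigma_loc,
                 frame_interval_ms = frame_interval_ms, fov_um = fov_um),
            class = "papa_motion")
}

# Reflecting boundaries on [0, L]: fold the free path with a triangle wave.
fold_reflect <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' Simulate observed trajectories from a photophysics simulation
#'
#' Positions are propagated as Brownian motion at each molecule's diffusion
#' coefficient, including through dark periods (variance scales with the
#' frame gap), and reflected at the field-of-view boundary. Localizations
#' are emitted only on frames where the molecule is bright and (by default)
#' the frame carries a red excitation dose. Runs of localizations separated
#' by more than `max_gap + 1` frames are split into separate trajectories.
#'
#' @param motion A [motion_model()], or a named list of motion models keyed
#'   by component label for mixtures with component-specific dynamics.
#' @param states A `papa_states` object from [simulate_photophysics()].
#' @param seed Optional integer seed.
#' @param max_gap Frame gaps up to this size stay within one trajectory
#'   (default 0: any dark frame splits).
#' @param emit_on_red If `TRUE` (default) localizations require a red dose
#'   in the frame, since the receiver is excited by red light only.
#' @return A `papa_trajectories` tibble: `trajectory`, `frame`, `x_um`,
#'   `y_um`, plus ground-truth columns `molecule`, `component`,
#'   `double_labeled`, `bound`, `d_true`. Attributes carry `sigma_loc`,
#'   `frame_interval_ms`, and `fov_um`.
#' @export
simulate_trajectories <- function(motion, states, seed = NULL, max_gap = 0,
                                  emit_on_red = TRUE) {
  stopifnot(inherits(states, "papa_states"))
  run <- function() run_trajectories(motion, states, max_gap, emit_on_red)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

run_trajectories <- function(motion, states, max_gap, emit_on_red) {
  mols <- states$molecules
  single <- inherits(motion, "papa_motion")
  if (!single) {
    if (!all(unique(mols$component) %in% names(motion))) {
      abort("`motion` list must be named by component label")
    }
    ref <- motion[[1]]
  } else {
    ref <- motion
  }
  dt_s <- ref$frame_interval_ms / 1000
  L <- ref$fov_um
  sigma <- ref$sigma_loc

  # localization frames per molecule
  iv <- bright_intervals(states)
  red_ok <- if (emit_on_red) states$protocol$schedule$red_ms > 0 else
    rep(TRUE, n_frames(states$protocol))
  loc <- tidyr::uncount(iv, weights = .data$end - .data$start, .id = "off")
  loc$frame <- loc$start + loc$off - 1L
  loc <- loc[red_ok[loc$frame + 1L], c("molecule", "frame")]
  if (nrow(loc) == 0) {
    return(empty_trajectories(sigma, ref$frame_interval_ms, L))
  }
  loc <- arrange(loc, .data$molecule, .data$frame)

  # per-molecule dynamics
  n_mol <- nrow(mols)
  get_model <- function(comp) if (single) motion else motion[[comp]]
  comps <- unique(mols$component)
  fb_by <- setNames(vapply(comps, function(cc) get_model(cc)$f_bound,
                           numeric(1)), comps)
  db_by <- setNames(vapply(comps, function(cc) get_model(cc)$d_bound,
                           numeric(1)), comps)
  df_by <- setNames(vapply(comps, function(cc) get_model(cc)$d_free,
                           numeric(1)), comps)
  bound0 <- runif(n_mol) < fb_by[mols$component]
  d_of <- function(comp, bound) {
    ifelse(bound, db_by[comp], df_by[comp])
  }

  k_sw <- if (single) motion$k_switch else
    max(vapply(motion, function(m) m$k_switch, numeric(1)))
  loc$gap <- ifelse(loc$molecule == lag(loc$molecule, default = -1L),
                    loc$frame - lag(loc$frame, default = 0L), NA_integer_)
  first <- is.na(loc$gap)

  if (k_sw > 0) {
    # resolve binding state at each localization time by per-molecule CTMC
    loc$bound <- resolve_switching(loc, mols, get_model, bound0, dt_s)
  } else {
    loc$bound <- bound0[loc$molecule]
  }
  loc$component <- mols$component[loc$molecule]
  loc$double_labeled <- mols$double_labeled[loc$molecule]
  loc$d_true <- d_of(loc$component, loc$bound)

  # Brownian propagation: increments between consecutive localizations of the
  # same molecule have per-axis variance 2 D dt gap; first appearance uniform.
  n <- nrow(loc)
  sd_step <- sqrt(2 * loc$d_true * dt_s * ifelse(first, 0, loc$gap))
  dx <- rnorm(n, 0, sd_step); dy <- rnorm(n, 0, sd_step)
  dx[first] <- runif(sum(first), 0, L)
  dy[first] <- runif(sum(first), 0, L)
  gm <- loc$molecule
  x_true <- fold_reflect(stats::ave(dx, gm, FUN = cumsum), L)
  y_true <- fold_reflect(stats::ave(dy, gm, FUN = cumsum), L)

  loc$x_um <- x_true + rnorm(n, 0, sigma)
  loc$y_um <- y_true + rnorm(n, 0, sigma)

  new_run <- first | loc$gap > (1L + max_gap)
  loc$trajectory <- cumsum(new_run)
  out <- select(loc, "trajectory", "frame", "x_um", "y_um", "molecule",
                "component", "double_labeled", "bound", "d_true")
  new_trajectories(out, sigma, ref$frame_interval_ms, L)
}

# Binding state at observation times for switching dynamics: two-state chain
# sampled at localization times with analytic transition probabilities.
resolve_switching <- function(loc, mols, get_model, bound0, dt_s) {
  bound <- logical(nrow(loc))
  idx <- split(seq_len(nrow(loc)), loc$molecule)
  for (mol_chr in names(idx)) {
    ii <- idx[[mol_chr]]
    mol <- loc$molecule[ii[1]]
    m <- get_model(mols$component[mol])
    if (m$k_switch == 0) { bound[ii] <- bound0[mol]; next }
    k_on <- m$k_switch * m$f_bound      # free -> bound
    k_off <- m$k_switch * (1 - m$f_bound)
    b <- bound0[mol]
    prev_f <- loc$frame[ii[1]]
    bound[ii[1]] <- b
    for (j in ii[-1]) {
      tau <- (loc$frame[j] - prev_f) * dt_s
      ksum <- k_on + k_off
      p_eq <- k_on / ksum
      decay <- exp(-ksum * tau)
      p_bound <- p_eq + (as.numeric(b) - p_eq) * decay
      b <- runif(1) < p_bound
      bound[j] <- b
      prev_f <- loc$frame[j]
    }
  }
  bound
}

new_trajectories <- function(df, sigma_loc, frame_interval_ms, fov_um) {
  structure(as_tibble(df),
            class = c("papa_trajectories", class(tibble())),
            sigma_loc = sigma_loc, frame_interval_ms = frame_interval_ms,
            fov_um = fov_um)
}

empty_trajectories <- function(sigma_loc, frame_interval_ms, fov_um) {
  new_trajectories(
    tibble(trajectory = integer(), frame = integer(),
           x_um = numeric(), y_um = numeric(), molecule = integer(),
           component = character(), double_labeled = logical(),
           bound = logical(), d_true = numeric()),
    sigma_loc, frame_interval_ms, fov_um)
}
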