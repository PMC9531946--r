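#' Receiver photophysics model
#'
#' Per-molecule Markov model of the receiver fluorophore with states
#' bright, dark (reversible, "shelved"), and bleached (absorbing). Kinetics
#' are expressed as rate constants per millisecond of delivered light dose;
#' the per-frame transition probability for dose `d` ms is
#' `1 - exp(-k * d)`, the discrete-frame approximation of first-order
#' kinetics. Only a fraction of receivers (`shelvable_fraction`) can enter
#' the dark state at all; the rest photobleach directly.
#'
#' Green light reactivates a dark receiver at `k_papa_green` when the
#' molecule carries an unbleached sender fluorophore (PAPA), and at the
#' residual `k_papa_bg_green` otherwise. Violet light reactivates at
#' `k_dr_violet` regardless of the sender (direct reactivation, DR).
#'
#' @param k_shelve_red Bright -> dark rate per ms of red dose (shelvable
#'   molecules only).
#' @param k_bleach_red Bright -> bleached rate per ms of red dose.
#' @param shelvable_fraction Fraction of receivers able to enter the dark
#'   state; default 0.10.
#' @param k_dr_violet Dark -> bright rate per ms of violet dose.
#' @param k_papa_green Dark -> bright rate per ms of green dose for
#'   molecules with a live sender.
#' @param k_papa_bg_green Residual dark -> bright rate per ms of green dose
#'   without a sender.
#' @param p_spont_per_frame Spontaneous dark -> bright probability per frame.
#' @param k_sender_bleach_green Sender bleaching rate per ms of green dose.
#' @param k_dark_bleach_red Optional dark -> bleached rate per ms of red
#'   dose; default 0 (the dark state is recoverable only).
#' @return A `papa_photophysics` parameter object.
#' @export
photophysics_model <- function(k_shelve_red = 0.015,
                               k_bleach_red = 8e-4,
                               shelvable_fraction = 0.10,
                               k_dr_violet = 0.5,
                               k_papa_green = 0.3,
                               k_papa_bg_green = 0.002,
                               p_spont_per_frame = 1e-4,
                               k_sender_bleach_green = 0.01,
                               k_dark_bleach_red = 0) {
  pars <- list(k_shelve_red = k_shelve_red, k_bleach_red = k_bleach_red,
               shelvable_fraction = shelvable_fraction,
               k_dr_violet = k_dr_violet, k_papa_green = k_papa_green,
               k_papa_bg_green = k_papa_bg_green,
               p_spont_per_frame = p_spont_per_frame,
               k_sender_bleach_green = k_sender_bleach_green,
               k_dark_bleach_red = k_dark_bleach_red)
  bad <- names(pars)[vapply(pars, function(x) x < 0, logical(1))]
  if (length(bad)) abort(paste("negative rate(s):", paste(bad, collapse = ", ")))
  if (shelvable_fraction > 1) abort("`shelvable_fraction` must be in [0, 1]")
  if (p_spont_per_frame > 1) abort("`p_spont_per_frame` must be in [0, 1]")
  structure(pars, class = "papa_photophysics")
}

#' Labeling model
#'
#' Describes the simulated molecule population: how many molecules of each
#' component, and which fraction of each carries a sender dye in addition to
#' the receiver ("double-labeled"). Double-labeled molecules are assigned
#' deterministically (the first `round(fraction * n)` ids of each
#' component), so the labeled count is exact.
#'
#' @param n_molecules Molecule count per component (vectorized).
#' @param fraction_double_labeled Fraction of each component carrying a
#'   sender (vectorized with `n_molecules`).
#' @param component Component identity label(s), e.g. `c("A", "B")`.
#' @return A tibble with columns `molecule`, `component`, `double_labeled`.
#' @examples
#' labeling_model(c(100, 100), c(1, 0), c("NLS-like", "H2B-like"))
#' @export
labeling_model <- function(n_molecules, fraction_double_labeled = 1,
                           component = "A") {
  k <- length(n_molecules)
  fraction_double_labeled <- rep_len(fraction_double_labeled, k)
  component <- rep_len(component, k)
  if (any(n_molecules < 1)) abort("`n_molecules` must be positive")
  if (any(fraction_double_labeled < 0 | fraction_double_labeled > 1)) {
    abort("`fraction_double_labeled` must be in [0, 1]")
  }
  per <- purrr::map(seq_len(k), function(i) {
    n <- n_molecules[i]
    n_dl <- round(fraction_double_labeled[i] * n)
    tibble(component = component[i],
           double_labeled = seq_len(n) <= n_dl)
  })
  out <- bind_rows(per)
  out$molecule <- seq_len(nrow(out))
  select(out, "molecule", "component", "double_labeled")
}

# state codes used throughout
STATE_BRIGHT <- 1L
STATE_DARK <- 2L
STATE_BLEACHED <- 3L
state_labels <- c("BRIGHT", "DARK", "BLEACHED")

#' Simulate receiver photophysics under an illumination protocol
#'
#' Runs the per-molecule bright/dark/bleached Markov chain frame by frame.
#' The doses of frame `f` drive at most one transition per molecule, taking
#' effect at frame `f + 1` (a molecule reactivated by a pulse at frame `p`
#' is bright from frame `p + 1`). `pre_shelving_s` of continuous red light
#' is applied analytically as an equivalent red dose before frame 0.
#' Sender status at the start of a frame governs PAPA reactivation in that
#' frame; senders bleach under green light.
#'
#' State histories are returned as an event log (initial state per molecule
#' plus one row per transition) rather than a dense molecule-by-frame
#' matrix; use [state_matrix()] or [bright_intervals()] for derived views.
#'
#' @param model A [photophysics_model()].
#' @param labeling A [labeling_model()] tibble.
#' @param protocol A [illumination_protocol()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `papa_states` object: list with `events` (tibble `molecule`,
#'   `frame`, `state`, `cause`), `init` (state at frame 0), `n_bright`
#'   (per-frame bright count), `molecules` (labeling plus `shelvable` and
#'   `sender_bleach_frame`), and the `protocol`.
#' @export
simulate_photophysics <- function(model, labeling, protocol, seed = NULL) {
  stopifnot(inherits(model, "papa_photophysics"),
            inherits(protocol, "papa_protocol"))
  if (!is.data.frame(labeling) ||
      !all(c("molecule", "component", "double_labeled") %in% names(labeling))) {
    abort("`labeling` must be a labeling_model() tibble")
  }
  if (n_frames(protocol) < 1) abort("protocol must have at least one frame")
  if (is.null(seed)) run_states(model, labeling, protocol)
  else withr::with_seed(seed, run_states(model, labeling, protocol))
}

# Actual implementation (simulate_photophysics above delegates here so the
# initial-state vector is kept without recomputation).
run_states <- function(model, labeling, protocol) {
  n <- nrow(labeling)
  sch <- protocol$schedule
  total <- nrow(sch)
  shelvable <- runif(n) < model$shelvable_fraction
  k_sh <- ifelse(shelvable, model$k_shelve_red, 0)
  k_bl <- model$k_bleach_red

  state <- rep(STATE_BRIGHT, n)
  r0 <- protocol$pre_shelving_s * 1000
  if (r0 > 0) {
    ktot <- k_sh + k_bl
    p_left <- 1 - exp(-ktot * r0)
    left <- runif(n) < p_left
    frac_dark <- ifelse(ktot > 0, k_sh / pmax(ktot, 1e-300), 0)
    to_dark <- runif(n) < frac_dark
    state[left] <- STATE_BLEACHED
    state[left & to_dark] <- STATE_DARK
  }
  init <- state

  sender_alive <- labeling$double_labeled
  sender_bleach_frame <- rep(NA_integer_, n)
  n_bright <- integer(total)
  ev_mol <- vector("list", total); ev_state <- vector("list", total)
  ev_cause <- vector("list", total); ev_frame <- vector("list", total)
  h_spont <- -log1p(-model$p_spont_per_frame)

  red <- sch$red_ms; green <- sch$green_ms; violet <- sch$violet_ms
  for (f in seq_len(total)) {
    n_bright[f] <- sum(state == STATE_BRIGHT)
    new_mol <- integer(0); new_state <- integer(0); new_cause <- character(0)

    if (red[f] > 0) {
      ib <- which(state == STATE_BRIGHT)
      if (length(ib)) {
        ktot <- k_sh[ib] + k_bl
        p_leave <- 1 - exp(-ktot * red[f])
        leave <- runif(length(ib)) < p_leave
        if (any(leave)) {
          il <- ib[leave]
          dark <- runif(length(il)) < k_sh[il] / (k_sh[il] + k_bl)
          new_mol <- c(new_mol, il)
          new_state <- c(new_state, ifelse(dark, STATE_DARK, STATE_BLEACHED))
          new_cause <- c(new_cause, ifelse(dark, "shelve", "bleach"))
        }
      }
    }

    idark <- which(state == STATE_DARK)
    if (length(idark)) {
      h_v <- model$k_dr_violet * violet[f]
      kp <- ifelse(labeling$double_labeled[idark] & sender_alive[idark],
                   model$k_papa_green, model$k_papa_bg_green)
      h_g <- kp * green[f]
      h_db <- model$k_dark_bleach_red * red[f]
      h_tot <- h_v + h_g + h_spont + h_db
      if (any(h_tot > 0)) {
        p_leave <- 1 - exp(-h_tot)
        leave <- runif(length(idark)) < p_leave
        if (any(leave)) {
          il <- idark[leave]
          ht <- h_tot[leave]
          u <- runif(length(il)) * ht
          hv <- rep(h_v, length(il))
          hg <- h_g[leave]
          cause <- ifelse(u < hv, "V",
                          ifelse(u < hv + hg, "G",
                                 ifelse(u < hv + hg + h_spont, "S", "darkbleach")))
          new_mol <- c(new_mol, il)
          new_state <- c(new_state,
                         ifelse(cause == "darkbleach", STATE_BLEACHED, STATE_BRIGHT))
          new_cause <- c(new_cause, cause)
        }
      }
    }

    if (green[f] > 0 && model$k_sender_bleach_green > 0) {
      isen <- which(sender_alive)
      if (length(isen)) {
        p_sb <- 1 - exp(-model$k_sender_bleach_green * green[f])
        blch <- runif(length(isen)) < p_sb
        if (any(blch)) {
          sender_alive[isen[blch]] <- FALSE
          sender_bleach_frame[isen[blch]] <- f - 1L
        }
      }
    }

    if (length(new_mol) && f < total) {
      state[new_mol] <- new_state
      ev_mol[[f]] <- new_mol
      ev_state[[f]] <- new_state
      ev_cause[[f]] <- new_cause
      ev_frame[[f]] <- rep.int(f, length(new_mol))
    }
  }

  events <- tibble(
    molecule = as.integer(unlist(ev_mol)),
    frame = as.integer(unlist(ev_frame)),
    state = as.integer(unlist(ev_state)),
    cause = as.character(unlist(ev_cause)))
  molecules <- labeling
  molecules$shelvable <- shelvable
  molecules$sender_bleach_frame <- sender_bleach_frame
  structure(
    list(events = events, init = init, n_bright = n_bright,
         molecules = molecules, protocol = protocol),
    class = "papa_states")
}

#' @export
print.papa_states <- function(x, ...) {
  tot <- length(x$n_bright)
  cat("<papa_states> ", nrow(x$molecules), " molecules x ", tot, " frames; ",
      nrow(x$events), " transitions\n", sep = "")
  cat("  bright at frame 0: ", x$n_bright[1],
      "; at last frame: ", x$n_bright[tot], "\n", sep = "")
  invisible(x)
}

#' Dense state matrix view of a photophysics simulation
#'
#' Materializes the molecule-by-frame state matrix (values 1 = BRIGHT,
#' 2 = DARK, 3 = BLEACHED) from the event log. Intended for small
#' simulations; errors above ~5e7 cells.
#'
#' @param states A `papa_states` object.
#' @return Integer matrix `n_molecules` x `n_frames`.
#' @export
state_matrix <- function(states) {
  n <- nrow(states$molecules)
  total <- length(states$n_bright)
  if (as.double(n) * total > 5e7) {
    abort("state matrix would exceed 5e7 cells; use bright_intervals() instead")
  }
  m <- matrix(rep(states$init, total), nrow = n, ncol = total)
  ev <- states$events
  if (nrow(ev)) {
    ev <- arrange(ev, .data$frame)
    for (i in seq_len(nrow(ev))) {
      m[ev$molecule[i], (ev$frame[i] + 1L):total] <- ev$state[i]
    }
  }
  m
}

#' Bright intervals per molecule
#'
#' @param states A `papa_states` object.
#' @return A tibble `molecule`, `start`, `end` of half-open frame intervals
#'   `[start, end)` during which the molecule is bright.
#' @export
bright_intervals <- function(states) {
  total <- length(states$n_bright)
  ev <- states$events
  base <- tibble(molecule = seq_len(nrow(states$molecules)),
                 frame = 0L, state = states$init)
  tl <- bind_rows(base, select(ev, "molecule", "frame", "state"))
  tl <- arrange(tl, .data$molecule, .data$frame)
  tl <- group_by(tl, .data$molecule)
  tl <- mutate(tl, until = dplyr::lead(.data$frame, default = total))
  tl <- ungroup(tl)
  br <- filter(tl, .data$state == STATE_BRIGHT, .data$until > .data$frame)
  tibble(molecule = br$molecule, start = br$frame, end = br$until)
}

#' Tally reactivation events by trigger
#'
#' @param states A `papa_states` object.
#' @return A tibble `cause`, `n` counting dark-to-bright transitions caused
#'   by violet (`V`), green (`G`), and spontaneous (`S`) pathways.
#' @export
reactivation_counts <- function(states) {
  ev <- filter(states$events, .data$state == STATE_BRIGHT)
  count(ev, .data$cause, name = "n")
}

#' Simulate a summed field-of-view intensity trace
#'
#' Per-frame total intensity is a Poisson draw around
#' `n_bright * photons_per_bright_frame + background` on frames that carry a
#' red dose (the receiver is excited by red light only); frames without red
#' light contribute background alone. With reactivation pulses present this
#' reproduces the characteristic "sawtooth" trace.
#'
#' @param states A `papa_states` object.
#' @param photons_per_bright_frame Expected photons per bright molecule per
#'   red-illuminated frame.
#' @param background Expected background photons summed over the field of
#'   view per frame.
#' @param seed Optional integer seed.
#' @return A `papa_trace` tibble with columns `frame`, `intensity`; the
#'   protocol is carried as an attribute.
#' @export
simulate_intensity_trace <- function(states, photons_per_bright_frame = 300,
                                     background = 2000, seed = NULL) {
  sch <- states$protocol$schedule
  expected <- ifelse(sch$red_ms > 0,
                     states$n_bright * photons_per_bright_frame, 0) + background
  draw <- function() rpois(length(expected), expected)
  intensity <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_trace(tibble(frame = sch$frame, intensity = as.numeric(intensity)),
            states$protocol)
}

new_trace <- function(df, protocol) {
  structure(df, class = c("papa_trace", class(tibble())),
            protocol = protocol)
}
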