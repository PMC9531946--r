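# Independent oracles used to freeze expected values.

# Per-trajectory log-likelihood of a fixed-state mixture computed through
# dexp() on squared displacements (independent of the package's loglik
# path), then brute-force search over the fraction simplex at `step`
# resolution.
oracle_traj_loglik <- function(tracks, d, sigma, dt_ms) {
  dt <- dt_ms / 1000
  b <- 4 * (d * dt + sigma^2)
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  by_tr <- split(tracks, tracks$trajectory)
  t(vapply(by_tr, function(tr) {
    dxy <- diff(tr$x_um)^2 + diff(tr$y_um)^2
    keep <- diff(tr$frame) == 1
    r2 <- dxy[keep]
    vapply(b, function(bj) sum(stats::dexp(r2, rate = 1 / bj, log = TRUE)),
           numeric(1))
  }, numeric(length(d))))
}

oracle_simplex_fit <- function(tracks, d_states, sigma = 0.035,
                               dt_ms = 7.48, step = 0.01) {
  ll <- oracle_traj_loglik(tracks, d_states, sigma, dt_ms)
  k <- length(d_states)
  grid1 <- seq(0, 1, by = step)
  if (k == 2) {
    fracs <- cbind(grid1, 1 - grid1)
  } else if (k == 3) {
    fr <- expand.grid(f1 = grid1, f2 = grid1)
    fr <- fr[fr$f1 + fr$f2 <= 1 + 1e-12, ]
    fracs <- cbind(fr$f1, fr$f2, pmax(1 - fr$f1 - fr$f2, 0))
  } else stop("oracle supports 2 or 3 states")
  obj <- apply(fracs, 1, function(w) {
    lw <- log(pmax(w, 1e-300))
    sum(apply(ll, 1, function(li) {
      m <- max(li + lw); m + log(sum(exp(li + lw - m)))
    }))
  })
  fracs[which.max(obj), ]
}

# method-of-moments diffusion estimate from consecutive-frame jumps
oracle_moment_d <- function(tracks, sigma = 0.035, dt_ms = 7.48) {
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  by_tr <- split(tracks, tracks$trajectory)
  r2 <- unlist(lapply(by_tr, function(tr) {
    (diff(tr$x_um)^2 + diff(tr$y_um)^2)[diff(tr$frame) == 1]
  }))
  (mean(r2) / 4 - sigma^2) / (dt_ms / 1000)
}
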