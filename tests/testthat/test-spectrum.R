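test_that("jump log-likelihood has its closed-form values", {
  # b = 4 (D dt + sigma^2) = 1 when D = 0, sigma = 0.5
  still <- tibble::tibble(trajectory = 1L, frame = 0:1,
                          x_um = c(0, 0), y_um = c(0, 0))
  ll0 <- jump_loglik(still, d = 0, sigma_loc = 0.5)
  expect_equal(ll0$loglik, 0)
  one <- tibble::tibble(trajectory = 1L, frame = 0:1,
                        x_um = c(0, 1), y_um = c(0, 0))
  ll1 <- jump_loglik(one, d = 0, sigma_loc = 0.5)
  expect_equal(ll1$loglik, -1)
  # gap jumps are excluded
  gap <- tibble::tibble(trajectory = 1L, frame = c(0, 2, 3),
                        x_um = c(0, 5, 5.1), y_um = 0)
  expect_equal(jump_loglik(gap, 1)$n_jumps, 1)
})

test_that("grid maximum likelihood agrees with the moment estimator", {
  tracks <- gen_single_d_tracks(1500, d = 2, mean_len = 8, seed = 41)
  d_grid <- seq(1, 3, by = 0.01)
  ll <- jump_loglik(tracks, d_grid) |>
    dplyr::group_by(d) |>
    dplyr::summarise(total = sum(loglik))
  d_ml <- ll$d[which.max(ll$total)]
  d_mom <- oracle_moment_d(tracks)
  expect_lt(abs(d_ml - 2) / 2, 0.05)
  expect_lt(abs(d_ml - d_mom), 0.05)
})

test_that("a single-state population is recovered on its grid point", {
  tracks <- gen_single_d_tracks(800, d = 1, mean_len = 10, seed = 42)
  grid <- diffusion_grid(10^seq(-2, 2, by = 0.05))
  sp <- infer_spectrum(tracks, grid)
  i1 <- which(abs(grid$d_values - 1) < 1e-9)
  mass <- sum(sp$spectrum$occupation[(i1 - 1):(i1 + 1)])
  expect_gte(mass, 0.8)
})

test_that("immobile molecules land at the grid minimum", {
  tracks <- gen_single_d_tracks(600, d = 0, sigma = 0.035, seed = 43)
  sp <- infer_spectrum(tracks)
  expect_gte(sum(sp$spectrum$occupation[sp$spectrum$d < 0.05]), 0.9)
  pk <- spectrum_peaks(sp, 0.05)
  expect_equal(pk$d[1], 0.01)
})

test_that("zero EM iterations return the uniform prior", {
  tracks <- gen_single_d_tracks(20, d = 1, seed = 44)
  sp <- infer_spectrum(tracks, max_iter = 0)
  expect_true(all(abs(sp$spectrum$occupation - 1 / 100) < 1e-12))
  expect_false(sp$converged)
})

test_that("reduced two-state fits recover the bound fraction", {
  tracks <- gen_two_state_tracks(2000, f_bound = 0.7, seed = 45)
  fit <- fit_reduced(tracks, c(0.01, 8.3))
  fb <- fit$fractions$fraction[fit$fractions$d == 0.01]
  expect_lt(abs(fb - 0.7), 0.05)
  # all-free boundary case
  free <- gen_two_state_tracks(800, f_bound = 0, seed = 46)
  fit_free <- fit_reduced(free, c(0.01, 8.3))
  expect_lte(fit_free$fractions$fraction[1], 0.05)
  # alternative published state sets are accepted
  for (ds in list(c(0.01, 2.1, 13.2), c(0.01, 1.3, 15.8), c(0.01, 4.4))) {
    f <- fit_reduced(tracks, ds)
    expect_equal(sum(f$fractions$fraction), 1, tolerance = 1e-9)
  }
  expect_error(fit_reduced(tracks, 0.01), "two")
})

test_that("EM is monotone, normalized, and input-order invariant", {
  tracks <- gen_two_state_tracks(300, f_bound = 0.5, seed = 47)
  sp <- infer_spectrum(tracks, max_iter = 200)
  expect_true(all(diff(sp$log_posterior) > -1e-6))
  expect_equal(sum(sp$spectrum$occupation), 1, tolerance = 1e-9)
  expect_true(all(sp$spectrum$occupation >= 0))
  # permutation of rows
  perm <- tracks[withr::with_seed(1, sample.int(nrow(tracks))), ]
  sp_perm <- infer_spectrum(perm, max_iter = 200)
  expect_equal(sp_perm$spectrum$occupation, sp$spectrum$occupation,
               tolerance = 1e-8)
  # duplicating the whole input leaves the spectrum unchanged
  dup <- dplyr::bind_rows(tracks,
                          dplyr::mutate(tracks, trajectory = trajectory + 1e6))
  sp_dup <- infer_spectrum(dup, max_iter = 200)
  expect_equal(sp_dup$spectrum$occupation, sp$spectrum$occupation,
               tolerance = 1e-6)
})

test_that("EM matches brute-force simplex search on tiny instances", {
  for (seed in 1:3) {
    tracks <- gen_two_state_tracks(5, f_bound = 0.5, mean_len = 4,
                                   seed = seed)
    em <- fit_reduced(tracks, c(0.01, 8.3))
    oracle <- oracle_simplex_fit(tracks, c(0.01, 8.3))
    expect_lt(max(abs(em$fractions$fraction - oracle)), 0.02)
  }
  tracks3 <- gen_two_state_tracks(5, f_bound = 0.4, d_free = 13.2,
                                  mean_len = 4, seed = 9)
  em3 <- fit_reduced(tracks3, c(0.01, 2.1, 13.2))
  or3 <- oracle_simplex_fit(tracks3, c(0.01, 2.1, 13.2))
  expect_lt(max(abs(em3$fractions$fraction - or3)), 0.02)
})

test_that("fraction bound sums occupations strictly below the threshold", {
  all_bound <- tibble::tibble(d = c(0.01, 8.3), occupation = c(1, 0))
  expect_equal(fraction_bound(all_bound), 1)
  all_free <- tibble::tibble(d = c(0.01, 8.3), occupation = c(0, 1))
  expect_equal(fraction_bound(all_free), 0)
  at_thr <- tibble::tibble(d = c(0.01, 0.15, 8.3),
                           occupation = c(0.3, 0.5, 0.2))
  expect_equal(fraction_bound(at_thr, 0.15), 0.3)  # strict inequality
  expect_error(fraction_bound(all_bound, 1000), "grid range")

  mix <- gen_two_state_tracks(1500, f_bound = 0.6, seed = 48)
  sp <- infer_spectrum(mix)
  expect_lt(abs(fraction_bound(sp) - 0.6), 0.05)
})

test_that("degenerate inputs are rejected with clear errors", {
  single <- tibble::tibble(trajectory = 1L, frame = 0L, x_um = 0, y_um = 0)
  expect_error(infer_spectrum(single), "jumps")
  expect_error(jump_loglik(single, 1), "displacements")
})
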