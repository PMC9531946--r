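zero_model <- function(...) {
  photophysics_model(k_shelve_red = 0, k_bleach_red = 0, k_dr_violet = 0,
                     k_papa_green = 0, k_papa_bg_green = 0,
                     p_spont_per_frame = 0, k_sender_bleach_green = 0, ...)
}

test_that("with all rates zero every molecule stays bright", {
  p <- demo_protocol()
  st <- simulate_photophysics(zero_model(), labeling_model(50), p, seed = 1)
  expect_equal(nrow(st$events), 0)
  expect_true(all(st$n_bright == 50))
  expect_equal(bright_intervals(st),
               tibble::tibble(molecule = 1:50, start = 0L,
                              end = n_frames(p)))
})

test_that("saturating rates shelve everything and one violet pulse recovers it", {
  p <- parse_protocol("1 cycle of 250 R [2 ms], 1 V [7 ms], 50 R [2 ms]")
  m <- photophysics_model(k_shelve_red = 50, k_bleach_red = 0,
                          shelvable_fraction = 1, k_dr_violet = 50,
                          p_spont_per_frame = 0)
  st <- simulate_photophysics(m, labeling_model(100), p, seed = 2)
  sm <- state_matrix(st)
  expect_true(all(sm[, 250] == 2L))  # frame 249: all dark
  expect_true(all(sm[, 252] == 1L))  # frame 251: all bright again
})

test_that("long red exposure matches the competing-risks closed form", {
  # fraction ever-dark ~= shelvable * k_sh / (k_sh + k_bl)
  p <- parse_protocol("1 cycle of 600 R [7 ms]")
  m <- photophysics_model(k_shelve_red = 0.01, k_bleach_red = 0.005,
                          shelvable_fraction = 0.3, p_spont_per_frame = 0)
  st <- simulate_photophysics(m, labeling_model(20000), p, seed = 3)
  ever_dark <- length(unique(
    st$events$molecule[st$events$cause == "shelve"]))
  expected <- 0.3 * 0.01 / 0.015
  expect_lt(abs(ever_dark / 20000 - expected), 0.01)
})

test_that("state occupancy is conserved at every frame", {
  p <- parse_protocol("2 cycles of 50 R [2 ms], 1 V [7 ms], 50 R [2 ms]")
  st <- simulate_photophysics(photophysics_model(), labeling_model(200), p,
                              seed = 4)
  sm <- state_matrix(st)
  counts <- apply(sm, 2, function(col) sum(col %in% 1:3))
  expect_true(all(counts == 200))
  # n_bright bookkeeping agrees with the dense view
  expect_equal(colSums(sm == 1L), st$n_bright)
})

test_that("green reactivations increase with labeling and PAPA rate", {
  p <- demo_protocol(pre_shelving_s = 10)
  greens <- vapply(c(0, 0.5, 1), function(fdl) {
    st <- simulate_photophysics(photophysics_model(),
                                labeling_model(3000, fdl), p, seed = 5)
    sum(st$events$cause == "G")
  }, numeric(1))
  expect_true(all(diff(greens) > 0))

  greens_k <- vapply(c(0.002, 0.05, 0.3), function(kp) {
    st <- simulate_photophysics(photophysics_model(k_papa_green = kp),
                                labeling_model(3000, 1), p, seed = 5)
    sum(st$events$cause == "G")
  }, numeric(1))
  expect_true(all(diff(greens_k) > 0))
})

test_that("equal PAPA and background rates make labeling irrelevant", {
  p <- demo_protocol(pre_shelving_s = 10)
  m <- photophysics_model(k_papa_green = 0.05, k_papa_bg_green = 0.05,
                          k_sender_bleach_green = 0)
  st1 <- simulate_photophysics(m, labeling_model(1000, 1), p, seed = 6)
  st0 <- simulate_photophysics(m, labeling_model(1000, 0), p, seed = 6)
  expect_equal(st1$events[c("molecule", "frame", "state")],
               st0$events[c("molecule", "frame", "state")])
  expect_equal(st1$n_bright, st0$n_bright)
})

test_that("simulations are reproducible given a seed", {
  p <- demo_protocol(pre_shelving_s = 5)
  a <- simulate_photophysics(photophysics_model(), labeling_model(500), p,
                             seed = 7)
  b <- simulate_photophysics(photophysics_model(), labeling_model(500), p,
                             seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$n_bright, b$n_bright)
  tr_a <- simulate_intensity_trace(a, seed = 8)
  tr_b <- simulate_intensity_trace(b, seed = 8)
  expect_identical(tr_a$intensity, tr_b$intensity)
})

test_that("pre-shelving populates the dark pool before frame 0", {
  p <- parse_protocol("1 cycle of 10 R [2 ms]", pre_shelving_s = 10)
  st <- simulate_photophysics(photophysics_model(), labeling_model(20000), p,
                              seed = 9)
  frac_dark0 <- mean(st$init == 2L)
  expect_lt(abs(frac_dark0 - 0.1 * 0.015 / 0.0158), 0.01)
  expect_lt(st$n_bright[1] / 20000, 0.01)
})

test_that("intensity traces track the bright-count bookkeeping", {
  p <- parse_protocol("1 cycle of 200 R [2 ms], 1 V [7 ms], 100 R [2 ms]",
                      pre_shelving_s = 0)
  m <- photophysics_model(p_spont_per_frame = 0)
  st <- simulate_photophysics(m, labeling_model(5000), p, seed = 10)
  tr <- simulate_intensity_trace(st, photons_per_bright_frame = 300,
                                 background = 0, seed = 11)
  # flat segment: constant bright count gives a flat trace up to Poisson noise
  zm <- simulate_photophysics(zero_model(), labeling_model(400), p, seed = 1)
  zt <- simulate_intensity_trace(zm, 300, background = 0, seed = 2)
  on_red <- p$schedule$red_ms > 0
  expect_lt(abs(mean(zt$intensity[on_red]) - 400 * 300), 4 * sqrt(400 * 300 / sum(on_red)))
  # step across the violet pulse equals photons * gained bright molecules
  nb <- st$n_bright
  pf <- pulse_frames(p, "V")           # 0-based pulse frame
  gained <- nb[pf + 2] - nb[pf + 1]    # state pf+1 minus state pf
  expect_gt(gained, 0)
  step <- tr$intensity[pf + 2] - tr$intensity[pf]  # frame pf+1 vs pf-1
  expect_lt(abs(step - 300 * gained),
            5 * sqrt(300 * (nb[pf + 2] + nb[pf])) + 1)
})
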