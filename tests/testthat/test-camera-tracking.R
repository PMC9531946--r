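px <- 0.16  # um per pixel used throughout these tests

test_that("an empty field renders pure background", {
  cam <- camera_model(img_size_px = 24, background_photons_per_pixel = 5)
  mv <- render_movie(tibble::tibble(frame = integer(), x_um = numeric(),
                                    y_um = numeric()),
                     cam, n_frames = 20, seed = 1)
  expect_lt(abs(mean(mv) - 5), 4 * sqrt(5 / length(mv)))
  cam0 <- camera_model(img_size_px = 24, photons_per_bright_frame = 0,
                       background_photons_per_pixel = 5)
  mv0 <- render_movie(tibble::tibble(frame = 0L, x_um = 2, y_um = 2), cam0,
                      n_frames = 20, seed = 2)
  expect_lt(abs(mean(mv0) - mean(mv)), 0.2)
})

test_that("the rendered PSF centroid matches the true position", {
  cam <- camera_model(img_size_px = 24, background_photons_per_pixel = 0,
                      photons_per_bright_frame = 500)
  truth <- c(x = 11.4, y = 9.7)  # pixels
  tr <- tibble::tibble(frame = 0:199, x_um = truth["x"] * px,
                       y_um = truth["y"] * px)
  mv <- render_movie(tr, cam, seed = 3)
  avg <- apply(mv, c(1, 2), mean)
  xs <- col(avg) - 0.5; ys <- row(avg) - 0.5
  cx <- sum(avg * xs) / sum(avg); cy <- sum(avg * ys) / sum(avg)
  expect_lt(abs(cx - truth["x"]), 0.1)
  expect_lt(abs(cy - truth["y"]), 0.1)
})

test_that("total intensity sums pixels exactly and matches bookkeeping", {
  mv <- array(0, dim = c(4, 4, 3))
  expect_equal(total_intensity(mv)$intensity, c(0, 0, 0))
  mv2 <- array(7, dim = c(5, 5, 2))
  expect_equal(total_intensity(mv2)$intensity, c(175, 175))

  cam <- camera_model(img_size_px = 32, background_photons_per_pixel = 1,
                      photons_per_bright_frame = 400)
  tr <- tibble::tibble(frame = rep(0:9, each = 2),
                       x_um = rep(c(1.5, 3.5), 10),
                       y_um = rep(c(1.5, 3.5), 10))
  mv3 <- render_movie(tr, cam, seed = 4)
  expected <- 2 * 400 + 32^2
  got <- total_intensity(mv3)$intensity
  expect_true(all(abs(got - expected) < 5 * sqrt(expected)))
})

test_that("spot detection recovers position, handles blanks and pairs", {
  cam <- camera_model(img_size_px = 32)
  tr <- tibble::tibble(frame = 0L, x_um = 10.3 * px, y_um = 7.8 * px)
  mv <- render_movie(tr, cam, n_frames = 1, seed = 5)
  sp <- detect_spots(mv[, , 1], psf_sigma_px = 1, threshold = 100)
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$x_px - 10.3)^2 + (sp$y_px - 7.8)^2), 0.15)

  blank <- matrix(0, 32, 32)
  expect_equal(nrow(detect_spots(blank, 1, 100)), 0)

  tr2 <- tibble::tibble(frame = c(0L, 0L), x_um = c(5, 25) * px,
                        y_um = c(5, 25) * px)
  mv2 <- render_movie(tr2, cam, n_frames = 1, seed = 6)
  expect_equal(nrow(detect_spots(mv2[, , 1], 1, 100)), 2)

  expect_error(detect_spots(array(0, c(3, 3, 3)), 1, 100), "2-D")
})

test_that("detection recall is high for bright molecules", {
  cam <- camera_model(img_size_px = 48, photons_per_bright_frame = 300,
                      background_photons_per_pixel = 5)
  set.seed(7)
  n <- 9
  centers <- tidyr::expand_grid(gx = c(10, 24, 38), gy = c(10, 24, 38))
  tr <- tidyr::expand_grid(frame = 0:9, mol = seq_len(n)) |>
    dplyr::mutate(x_um = rep((centers$gx + runif(n, -3, 3)) * px, 10),
                  y_um = rep((centers$gy + runif(n, -3, 3)) * px, 10))
  mv <- render_movie(tr, cam, seed = 8)
  locs <- localize_movie(mv, psf_sigma_px = 1, threshold = 100)
  recall <- locs |>
    dplyr::group_by(frame) |>
    dplyr::summarise(found = dplyr::n()) |>
    dplyr::summarise(r = mean(found) / n) |>
    dplyr::pull(r)
  expect_gte(recall, 0.9)
})

test_that("linking reconstructs simple cases without identity swaps", {
  # one molecule across all frames
  one <- tibble::tibble(frame = 0:9, x_um = 2 + 0.01 * (0:9), y_um = 3)
  lk <- link_trajectories(one, max_disp_um = 1)
  expect_equal(dplyr::n_distinct(lk$trajectory), 1)

  # two immobile molecules far apart
  two <- dplyr::bind_rows(
    tibble::tibble(frame = 0:9, x_um = 1, y_um = 1, truth = 1),
    tibble::tibble(frame = 0:9, x_um = 6, y_um = 6, truth = 2))
  lk2 <- link_trajectories(two, max_disp_um = 1)
  expect_equal(dplyr::n_distinct(lk2$trajectory), 2)
  swaps <- lk2 |>
    dplyr::group_by(trajectory) |>
    dplyr::summarise(pure = dplyr::n_distinct(truth) == 1)
  expect_true(all(swaps$pure))

  # a gap larger than max_gap splits; bridging joins
  gap <- tibble::tibble(frame = c(0:4, 7:9), x_um = 1, y_um = 1)
  expect_equal(dplyr::n_distinct(
    link_trajectories(gap, 1, max_gap = 0)$trajectory), 2)
  expect_equal(dplyr::n_distinct(
    link_trajectories(gap, 1, max_gap = 2)$trajectory), 1)
})

test_that("linking is invariant to within-frame input order", {
  set.seed(9)
  locs <- tidyr::expand_grid(frame = 0:19, mol = 1:6) |>
    dplyr::mutate(x_um = rep(runif(6, 0, 10), 20) + rnorm(120, 0, 0.05),
                  y_um = rep(runif(6, 0, 10), 20) + rnorm(120, 0, 0.05))
  a <- link_trajectories(locs, 1)
  b <- link_trajectories(locs[sample.int(nrow(locs)), ], 1)
  key <- function(df) {
    df |>
      dplyr::arrange(frame, x_um, y_um) |>
      dplyr::group_by(trajectory) |>
      dplyr::summarise(sig = paste(frame, round(x_um, 9), round(y_um, 9),
                                   collapse = ";")) |>
      dplyr::pull(sig) |>
      sort()
  }
  expect_equal(key(a), key(b))
})

test_that("tracked synthetic movies reproduce ground-truth links", {
  p <- parse_protocol("1 cycle of 20 R [2 ms]")
  m <- photophysics_model(k_shelve_red = 0, k_bleach_red = 0,
                          p_spont_per_frame = 0)
  st <- simulate_photophysics(m, labeling_model(c(6, 6), c(1, 0), c("A", "B")),
                              p, seed = 10)
  mo <- list(A = motion_model(f_bound = 0, fov_um = 7.2, d_free = 2),
             B = motion_model(f_bound = 1, fov_um = 7.2))
  truth <- simulate_trajectories(mo, st, seed = 11)
  cam <- camera_model(img_size_px = 48, photons_per_bright_frame = 400,
                      background_photons_per_pixel = 3)
  mv <- render_movie(truth, cam, n_frames = 20, seed = 12)
  locs <- localize_movie(mv, 1, threshold = 120)
  lk <- link_trajectories(locs, max_disp_um = 1.5)
  # match each detection to the nearest true molecule in its frame
  matched <- lk |>
    dplyr::left_join(truth, by = "frame", suffix = c("", "_t"),
                     relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((x_um - x_um_t)^2 + (y_um - y_um_t)^2)) |>
    dplyr::group_by(trajectory, frame, x_um, y_um) |>
    dplyr::slice_min(d, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(d < 0.3)
  link_ok <- matched |>
    dplyr::arrange(trajectory, frame) |>
    dplyr::group_by(trajectory) |>
    dplyr::summarise(ok = sum(diff(molecule) == 0 & diff(frame) == 1),
                     total = sum(diff(frame) == 1)) |>
    dplyr::summarise(frac = sum(ok) / sum(total)) |>
    dplyr::pull(frac)
  expect_gte(link_ok, 0.9)
})

test_that("trajectory CSV round-trips and validates its schema", {
  tr <- tibble::tibble(trajectory = c(1L, 1L, 2L), frame = c(0L, 1L, 0L),
                       x_um = c(0.1, 0.2, 3), y_um = c(1, 1.1, 2),
                       extra = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(tr, f)
  back <- read_trajectories(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  # empty file with header
  writeLines("trajectory,frame,x_um,y_um", f)
  expect_equal(nrow(read_trajectories(f)), 0)

  # missing required columns named in the error
  writeLines(c("trajectory,frame,x_um", "1,0,0.5"), f)
  expect_error(read_trajectories(f), "y_um")

  # unsorted frames sorted with a warning
  bad <- tibble::tibble(trajectory = 1L, frame = c(2L, 0L, 1L),
                        x_um = 1:3, y_um = 1:3)
  write_trajectories(bad, f)
  expect_warning(fixed <- read_trajectories(f), "unsorted")
  expect_equal(fixed$frame, 0:2)
})

test_that("movies round-trip through 16-bit TIFF", {
  cam <- camera_model(img_size_px = 16, background_photons_per_pixel = 3)
  mv <- render_movie(tibble::tibble(frame = 0:2, x_um = 1.2, y_um = 1.2),
                     cam, seed = 13)
  f <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, f)
  back <- read_movie(f)
  expect_equal(dim(back), dim(mv))
  expect_true(all(abs(back - mv) == 0))
})
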