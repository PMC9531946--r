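make_track <- function(id, frames, x = 1, y = 1) {
  tibble::tibble(trajectory = id, frame = as.integer(frames),
                 x_um = x + 0.001 * seq_along(frames), y_um = y)
}

test_that("trajectories are clipped to post-pulse windows and classed", {
  p <- demo_protocol()  # violet window [251, 281), green window [752, 782)
  tr <- dplyr::bind_rows(
    make_track(1, 252:260),   # fully inside violet window
    make_track(2, 240:260),   # straddles window start
    make_track(3, 100:120),   # outside all windows
    make_track(4, 755:760))   # inside green window
  seg <- split_trajectories(tr, p, window = 30, quiet = TRUE)
  s1 <- seg[seg$source_trajectory == 1, ]
  expect_true(all(s1$class == "DR"))
  expect_equal(s1$frame, 252:260)
  s2 <- seg[seg$source_trajectory == 2, ]
  expect_equal(s2$frame, 251:260)
  expect_true(all(s2$class == "DR"))
  expect_false(3 %in% seg$source_trajectory)
  expect_true(all(seg$class[seg$source_trajectory == 4] == "PAPA"))
  # segments reference their source pulse
  expect_equal(unique(s2$pulse_frame), 250)
})

test_that("segments never share localizations across classes", {
  p <- demo_protocol()
  set.seed(1)
  tr <- dplyr::bind_rows(lapply(1:50, function(i) {
    start <- sample(0:990, 1) * 10
    make_track(i, start:(start + 40))
  }))
  seg <- split_trajectories(tr, p, quiet = TRUE)
  if (nrow(seg)) {
    key <- paste(seg$source_trajectory, seg$frame)
    expect_equal(anyDuplicated(key), 0)
    wins <- rbind(post_pulse_windows(p, "G"), post_pulse_windows(p, "V"))
    in_win <- vapply(seg$frame, function(f) {
      sum(f >= wins$start & f < wins$end) == 1
    }, logical(1))
    expect_true(all(in_win))
  }
})

test_that("a long-lived molecule contributes one segment per window", {
  p <- demo_protocol()
  tr <- make_track(1, 0:2000)  # spans the violet and green windows of cycle 1
  seg <- split_trajectories(tr, p, quiet = TRUE)
  # windows hit: V@250, G@751, V@1252, G@1753
  expect_equal(dplyr::n_distinct(seg$trajectory), 4)
  expect_setequal(unique(seg$class), c("PAPA", "DR"))
})

test_that("segments with fewer than min_locs localizations are dropped", {
  p <- demo_protocol()
  tr <- dplyr::bind_rows(make_track(1, 251), make_track(2, 251:252))
  expect_message(seg <- split_trajectories(tr, p), "discarded 1 segment")
  expect_equal(unique(seg$source_trajectory), 2)
})

test_that("balancing subsamples the larger class without replacement", {
  p <- demo_protocol()
  tr <- dplyr::bind_rows(
    lapply(1:100, function(i) make_track(i, 251:253)),          # DR
    lapply(101:350, function(i) make_track(i, 752:754)))       # PAPA
  seg <- split_trajectories(tr, p, quiet = TRUE)
  bal <- balance_classes(seg, seed = 42)
  counts <- dplyr::count(dplyr::distinct(bal, class, trajectory), class)
  expect_equal(counts$n, c(100, 100))
  # DR side untouched
  expect_setequal(unique(bal$source_trajectory[bal$class == "DR"]), 1:100)
  # subsample without replacement: ids unique
  ids <- bal$trajectory[bal$class == "PAPA"]
  expect_equal(anyDuplicated(unique(ids)), 0)
  # determinism
  bal2 <- balance_classes(seg, seed = 42)
  expect_identical(as.data.frame(bal), as.data.frame(bal2))
  # equal sizes: identity
  seg_eq <- split_trajectories(
    dplyr::bind_rows(lapply(1:20, function(i) make_track(i, 251:253)),
                     lapply(21:40, function(i) make_track(i, 752:754))),
    p, quiet = TRUE)
  expect_equal(nrow(balance_classes(seg_eq, seed = 1)), nrow(seg_eq))
})

test_that("PAPA segments are enriched for double-labeled molecules", {
  p <- demo_protocol(pre_shelving_s = 10)
  m <- photophysics_model()
  lab <- labeling_model(c(1500, 1500), c(1, 0), c("A", "B"))
  st <- simulate_photophysics(m, lab, p, seed = 21)
  mo <- list(A = motion_model(f_bound = 0), B = motion_model(f_bound = 1))
  tr <- simulate_trajectories(mo, st, seed = 22)
  seg <- split_trajectories(tr, p, quiet = TRUE)
  by_class <- seg |>
    dplyr::distinct(class, trajectory, double_labeled) |>
    dplyr::group_by(class) |>
    dplyr::summarise(p_dl = mean(double_labeled))
  expect_gt(by_class$p_dl[by_class$class == "PAPA"],
            by_class$p_dl[by_class$class == "DR"])
})

test_that("isolation filtering keeps only well-separated molecules", {
  three <- tibble::tibble(x_px = c(0, 10, 20), y_px = 0)
  expect_equal(nrow(select_isolated(three, 8)), 3)
  pair <- tibble::tibble(x_px = c(0, 5), y_px = 0)
  expect_equal(nrow(select_isolated(pair, 8)), 0)
  set.seed(30)
  field <- tibble::tibble(x_px = runif(60, 0, 100), y_px = runif(60, 0, 100))
  kept <- select_isolated(field, 8)
  if (nrow(kept) > 1) {
    dmin <- min(dist(kept[, c("x_px", "y_px")]))
    expect_gte(dmin, 8)
  }
})

test_that("persistence scoring follows presence within the match radius", {
  refs <- select_isolated(tibble::tibble(x_px = c(10, 40), y_px = 10), 8)
  locs <- dplyr::bind_rows(
    tibble::tibble(frame = 0:14, x_px = 10.5, y_px = 10.2),   # molecule 1 always on
    tibble::tibble(frame = c(0:4, 10:14), x_px = 40, y_px = 10))  # off frames 5-9
  ps <- score_persistence(locs, refs, radius = 4)
  m1 <- ps$series[ps$series$ref == 1, ]
  expect_true(all(m1$fluorescent))
  m2 <- ps$series[ps$series$ref == 2, ]
  expect_equal(m2$frame[!m2$fluorescent], 5:9)
  expect_equal(ps$surviving$fraction[ps$surviving$frame == 7], 0.5)
  # empty frame: all false
  ps2 <- score_persistence(locs[locs$frame < 15, ], refs, radius = 4,
                           frames = 0:20)
  expect_true(all(!ps2$series$fluorescent[ps2$series$frame == 20]))
})
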