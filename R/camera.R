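#' Camera model
#'
#' Pixelated rendering of localizations with an integrated 2-D Gaussian
#' point-spread function and Poisson shot noise. Coordinates map as
#' `x_px = x_um / pixel_size_um`, with pixel `j` (1-based) covering
#' `[j - 1, j)` in pixel units, so a pixel's center is at `j - 0.5`.
#'
#' @param pixel_size_um Pixel size, um (default 0.16).
#' @param psf_sigma_um PSF standard deviation, um (default one pixel).
#' @param photons_per_bright_frame Expected total photons per molecule per
#'   frame.
#' @param background_photons_per_pixel Expected background photons per pixel
#'   per frame.
#' @param img_size_px Image side length in pixels.
#' @return A `papa_camera` parameter object.
#' @export
camera_model <- function(pixel_size_um = 0.16, psf_sigma_um = 0.16,
                         photons_per_bright_frame = 300,
                         background_photons_per_pixel = 2,
                         img_size_px = 64) {
  vals <- c(pixel_size_um, psf_sigma_um, photons_per_bright_frame,
            background_photons_per_pixel, img_size_px)
  if (any(vals < 0)) abort("camera parameters must be >= 0")
  structure(list(pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
                 photons_per_bright_frame = photons_per_bright_frame,
                 background_photons_per_pixel = background_photons_per_pixel,
                 img_size_px = as.integer(img_size_px)),
            class = "papa_camera")
}

#' Render localizations into a synthetic movie
#'
#' Each localization deposits an integrated 2-D Gaussian with total expected
#' photons `photons_per_bright_frame`; every pixel is then drawn from a
#' Poisson distribution around signal plus background.
#'
#' @param trajectories A `papa_trajectories` tibble (or any tibble with
#'   `frame`, `x_um`, `y_um`).
#' @param camera A [camera_model()].
#' @param n_frames Number of frames to render; defaults to `max(frame) + 1`.
#' @param seed Optional integer seed.
#' @return A `papa_movie`: integer array `[row, col, frame]` with the camera
#'   model attached as an attribute.
#' @export
render_movie <- function(trajectories, camera, n_frames = NULL, seed = NULL) {
  stopifnot(inherits(camera, "papa_camera"))
  if (is.null(n_frames)) {
    n_frames <- if (nrow(trajectories)) max(trajectories$frame) + 1L else 1L
  }
  run <- function() {
    npx <- camera$img_size_px
    sig <- camera$psf_sigma_um / camera$pixel_size_um
    edges <- 0:npx
    movie <- array(0, dim = c(npx, npx, n_frames))
    if (nrow(trajectories)) {
      xs <- trajectories$x_um / camera$pixel_size_um
      ys <- trajectories$y_um / camera$pixel_size_um
      for (i in seq_len(nrow(trajectories))) {
        f <- trajectories$frame[i] + 1L
        if (f > n_frames) next
        px <- diff(pnorm(edges, mean = xs[i], sd = sig))
        py <- diff(pnorm(edges, mean = ys[i], sd = sig))
        movie[, , f] <- movie[, , f] +
          camera$photons_per_bright_frame * outer(py, px)
      }
    }
    movie <- movie + camera$background_photons_per_pixel
    noisy <- array(rpois(length(movie), movie), dim = dim(movie))
    structure(noisy, class = "papa_movie", camera = camera)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.papa_movie <- function(x, ...) {
  d <- dim(x)
  cat("<papa_movie> ", d[1], " x ", d[2], " px, ", d[3], " frames\n", sep = "")
  invisible(x)
}

#' Read and write movies as multi-page TIFF
#'
#' Movies are written as 16-bit unsigned multi-page TIFF (counts are stored
#' directly; values above 65535 are clipped with a warning).
#'
#' @param movie A `papa_movie` or numeric array `[row, col, frame]`.
#' @param path TIFF file path.
#' @return `read_movie()` returns a `papa_movie` (integer counts);
#'   `write_movie()` returns `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  if (any(movie > 65535)) {
    warning("pixel values above 65535 clipped for 16-bit TIFF")
    movie[movie > 65535] <- 65535
  }
  pages <- purrr::map(seq_len(dim(movie)[3]), function(f) movie[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  structure(arr, class = "papa_movie")
}
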