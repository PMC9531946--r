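#' Simulate a TCSPC decay histogram
#'
#' Photon arrival times are drawn from Exponential(`tau_ns`) and histogrammed
#' into `n_bins` bins of `bin_width_ns`; arrivals beyond the record length
#' `n_bins * bin_width_ns` are dropped and the truncated count is flagged on
#' the result.
#'
#' @param tau_ns Fluorescence lifetime, ns (> 0).
#' @param n_photons Number of photons to draw.
#' @param bin_width_ns Histogram bin width, ns.
#' @param n_bins Number of bins (record length = `n_bins * bin_width_ns`).
#' @param seed Optional integer seed; the same seed reproduces the
#'   histogram bit for bit.
#' @return A `papa_decay` object: tibble `time_ns` (lower bin edge),
#'   `counts`, with `bin_width_ns` and `n_truncated` attributes.
#' @export
simulate_flim_decay <- function(tau_ns, n_photons, bin_width_ns = 0.05,
                                n_bins = 512, seed = NULL) {
  if (tau_ns <= 0) abort("`tau_ns` must be > 0")
  run <- function() {
    t_max <- n_bins * bin_width_ns
    arrivals <- if (n_photons > 0) rexp(n_photons, rate = 1 / tau_ns) else numeric(0)
    kept <- arrivals[arrivals < t_max]
    counts <- tabulate(pmin(floor(kept / bin_width_ns) + 1L, n_bins),
                       nbins = n_bins)
    new_decay(counts, bin_width_ns, n_truncated = n_photons - length(kept))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

new_decay <- function(counts, bin_width_ns, n_truncated = 0) {
  n_bins <- length(counts)
  structure(
    tibble(time_ns = (seq_len(n_bins) - 1L) * bin_width_ns,
           counts = as.numeric(counts)),
    class = c("papa_decay", class(tibble())),
    bin_width_ns = bin_width_ns, n_truncated = n_truncated)
}

#' Decay histogram constructor
#'
#' @param counts Non-negative photon counts per bin.
#' @param bin_width_ns Bin width, ns.
#' @return A `papa_decay` tibble.
#' @export
decay_histogram <- function(counts, bin_width_ns) {
  if (any(counts < 0)) abort("counts must be >= 0")
  new_decay(counts, bin_width_ns)
}

#' Fit a mono-exponential lifetime to a decay histogram
#'
#' Maximum-likelihood fit of an exponential decay truncated to the record
#' length, using the multinomial likelihood of the binned counts; no
#' instrument response is deconvolved (a delta-function IRF is assumed).
#' Fits with fewer than `min_photons` are an error.
#'
#' @param decay A `papa_decay` (from [simulate_flim_decay()],
#'   [decay_histogram()], or [read_decay()]).
#' @param min_photons Minimum photons considered reliable (default 50).
#' @return A `papa_lifetime`: `tau_ns`, `se_ns` (from the observed Fisher
#'   information), `n_photons`, `loglik`.
#' @export
fit_monoexponential <- function(decay, min_photons = 50) {
  counts <- decay$counts
  n <- sum(counts)
  if (n < min_photons) {
    abort(sprintf("only %g photons (< %d); lifetime fit unreliable", n,
                  min_photons))
  }
  bw <- attr(decay, "bin_width_ns")
  t_max <- length(counts) * bw
  edges <- c(decay$time_ns, t_max)
  nll <- function(tau) {
    p <- diff(-exp(-edges / tau)) / (1 - exp(-t_max / tau))
    -sum(counts * log(pmax(p, 1e-300)))
  }
  opt <- optimize(nll, interval = c(bw / 100, 100 * t_max),
                  tol = 1e-10 * t_max)
  tau <- opt$minimum
  h <- (nll(tau * (1 + 1e-4)) - 2 * nll(tau) + nll(tau * (1 - 1e-4))) /
    (tau * 1e-4)^2
  se <- if (is.finite(h) && h > 0) 1 / sqrt(h) else NA_real_
  structure(list(tau_ns = tau, se_ns = se, n_photons = n,
                 loglik = -opt$objective),
            class = "papa_lifetime")
}

#' @export
print.papa_lifetime <- function(x, ...) {
  cat(sprintf("<papa_lifetime> tau = %.4g ns (se %.2g), %g photons\n",
              x$tau_ns, x$se_ns, x$n_photons))
  invisible(x)
}

#' Nuclear mask by intensity thresholding
#'
#' Otsu threshold on the intensity image, keeping the largest connected
#' component. A degenerate (uniform) image yields an all-`FALSE` mask with
#' a warning.
#'
#' @param image 2-D intensity matrix.
#' @return Logical matrix of the same dimensions.
#' @export
nuclear_mask <- function(image) {
  if (length(dim(image)) != 2) abort("`image` must be a 2-D matrix")
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("uniform image: no threshold exists; returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Mean nuclear lifetime
#'
#' @param tau_map Per-pixel lifetime matrix.
#' @param mask Logical nuclear mask from [nuclear_mask()].
#' @param weights Optional per-pixel weights (e.g. photon counts); the
#'   default is the unweighted mean within the mask.
#' @return Mean lifetime within the mask, ns.
#' @export
nuclear_lifetime <- function(tau_map, mask, weights = NULL) {
  if (!any(mask)) abort("empty mask")
  if (is.null(weights)) mean(tau_map[mask])
  else weighted.mean(tau_map[mask], weights[mask])
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau / tau0`, where `tau` is the donor lifetime in the presence
#' of the acceptor and `tau0` the donor-only lifetime. Values are clipped
#' to `[0, 1]` with a warning when clipping occurs.
#'
#' @param tau Donor lifetime with acceptor, ns.
#' @param tau0 Donor-only lifetime, ns (> 0).
#' @return FRET efficiency in `[0, 1]`.
#' @export
fret_efficiency <- function(tau, tau0) {
  if (any(tau0 <= 0)) abort("`tau0` must be > 0")
  e <- 1 - tau / tau0
  if (any(e < 0 | e > 1)) {
    warning("FRET efficiency clipped to [0, 1]")
    e <- pmin(pmax(e, 0), 1)
  }
  e
}

#' Read and write decay histograms as CSV
#'
#' CSV columns are `time_ns` (lower bin edge) and `counts`, mirroring the
#' per-pixel export format of TCSPC software.
#'
#' @param path CSV file path.
#' @return `read_decay()` returns a `papa_decay`; `write_decay()` returns
#'   `path` invisibly.
#' @export
read_decay <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_ns", "counts") %in% names(df))) {
    abort("decay file needs columns time_ns, counts")
  }
  bw <- if (nrow(df) > 1) df$time_ns[2] - df$time_ns[1] else 1
  new_decay(df$counts, bw)
}

#' @rdname read_decay
#' @param decay A `papa_decay`.
#' @export
write_decay <- function(decay, path) {
  readr::write_csv(tibble(time_ns = decay$time_ns, counts = decay$counts),
                   path)
  invisible(path)
}
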