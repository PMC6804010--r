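## Anatomical surface parameters fed to the discriminant stage: differential
## entropy of the intensity distribution, roughness/waviness split at a
## cutoff wavelength, fraction of the surface with a periodic (fibril-like)
## texture, and statistics of dark circular excavations.

#' Plug-in differential entropy of image intensities
#'
#' Intensities are normalized to `[0, 1]` and binned into `bins` equal-width
#' bins; the plug-in differential entropy is
#' `H = -sum(p * log(p / delta))` nats, with `delta` the bin width. The
#' entropy deficit is reported against a Gaussian reference of matched
#' variance, `H_ref = 0.5 * log(2 * pi * e * var)`: a surface dominated by
#' amorphous deposits concentrates intensity mass and shows a positive
#' deficit.
#'
#' @param img a [chem_image()] or numeric matrix of 8-bit intensities.
#' @param bins number of equal-width bins on `[0, 1]` (default 64; fixed for
#'   comparability across samples).
#' @return List with `entropy_nats`, `deficit_nats`, `reference_nats`, `bins`.
#' @export
surface_entropy <- function(img, bins = 64) {
  x <- if (inherits(img, "chem_image")) img$data else img
  x <- as.numeric(x) / 255
  if (max(x) == min(x)) stop("degenerate image: constant intensity")
  delta <- 1 / bins
  b <- pmin(bins, floor(x / delta) + 1L)
  p <- tabulate(b, bins) / length(x)
  p <- p[p > 0]
  h <- -sum(p * log(p / delta))
  h_ref <- 0.5 * log(2 * pi * exp(1) * var(x))
  list(entropy_nats = h, deficit_nats = h_ref - h,
       reference_nats = h_ref, bins = bins)
}

#' Roughness and waviness by Gaussian cutoff filtering
#'
#' The image is split into a long-wavelength waviness surface (Gaussian
#' low-pass with 50% amplitude transmission at `cutoff_um`, the standard
#' metrology Gaussian profile filter) and a short-wavelength roughness
#' residual. Reported, in intensity units: `Ra` (mean absolute residual),
#' `Rq` (RMS residual) and `Wa` (mean absolute deviation of the waviness
#' surface from its grand mean).
#'
#' @param img a [chem_image()].
#' @param cutoff_um cutoff wavelength, micrometres; must exceed twice the
#'   pixel size (default 8: above fibril diameters, below lattice
#'   wavelengths).
#' @return List with `Ra`, `Rq`, `Wa`, `cutoff_um`.
#' @export
roughness_waviness <- function(img, cutoff_um = 8) {
  stopifnot(inherits(img, "chem_image"))
  if (cutoff_um <= 2 * img$pixel_size_um)
    stop("`cutoff_um` must exceed twice the pixel size (",
         2 * img$pixel_size_um, " um)")
  ## Gaussian with 50% transmission at the cutoff wavelength:
  ## sigma = sqrt(ln 2 / pi) * cutoff / sqrt(2 * pi)
  sigma_px <- sqrt(log(2) / pi) * (cutoff_um / img$pixel_size_um) / sqrt(2 * pi)
  x <- matrix(as.numeric(img$data), nrow(img$data))
  wav <- gaussian_blur(x, sigma_px)
  res <- x - wav
  list(Ra = mean(abs(res)), Rq = sqrt(mean(res^2)),
       Wa = mean(abs(wav - mean(wav))), cutoff_um = cutoff_um)
}

## Normalized wrapped autocorrelation of a demeaned window, via FFT.
acf2d <- function(w) {
  w <- w - mean(w)
  v <- sum(w^2)
  if (v == 0) return(matrix(0, nrow(w), ncol(w)))
  a <- Re(fft(Mod(fft(w))^2, inverse = TRUE)) / length(w)
  a / a[1, 1]
}

## Does a 1-d autocorrelation profile carry a secondary peak (an interior
## local maximum at lag >= 2) of at least `prominence`?
has_secondary_peak <- function(prof, prominence) {
  n <- length(prof)
  if (n < 4) return(FALSE)
  for (i in 3:(n - 1)) {       # lag index i-1 >= 2
    if (prof[i] >= prominence && prof[i] > prof[i - 1] && prof[i] >= prof[i + 1])
      return(TRUE)
  }
  FALSE
}

#' Fraction of the surface with periodic texture
#'
#' The image is tiled into square windows of `window_um`; a window counts as
#' periodic when its wrapped autocorrelation, collapsed along one of the four
#' principal directions (axes and diagonals), shows a secondary peak of at
#' least `prominence`. White noise has no stable secondary peak; parallel
#' ridge systems score in every window they fill.
#'
#' @param img a [chem_image()].
#' @param window_um window edge, micrometres (default 12; must fit at least
#'   three expected texture periods and be no larger than the image).
#' @param prominence minimum normalized autocorrelation of the secondary
#'   peak (default 0.3).
#' @return Percentage of windows classified periodic, in `[0, 100]`.
#' @export
periodic_area_fraction <- function(img, window_um = 12, prominence = 0.3) {
  stopifnot(inherits(img, "chem_image"))
  w_px <- round(window_um / img$pixel_size_um)
  d <- dim(img$data)
  if (w_px > min(d)) stop("window (", w_px, " px) larger than image")
  nw_r <- d[1] %/% w_px
  nw_c <- d[2] %/% w_px
  half <- w_px %/% 2
  periodic <- logical(nw_r * nw_c)
  k <- 0
  for (i in seq_len(nw_r)) {
    for (j in seq_len(nw_c)) {
      k <- k + 1
      w <- img$data[((i - 1) * w_px + 1):(i * w_px),
                    ((j - 1) * w_px + 1):(j * w_px)]
      a <- acf2d(matrix(as.numeric(w), w_px))
      dirs <- list(a[1, 1:half],                         # x axis
                   a[1:half, 1],                         # y axis
                   a[cbind(1:half, 1:half)],             # main diagonal
                   a[cbind(1:half, c(1, w_px:(w_px - half + 2)))]) # anti-diag
      periodic[k] <- any(vapply(dirs, has_secondary_peak, logical(1),
                                prominence = prominence))
    }
  }
  100 * mean(periodic)
}

#' Detect dark, roughly circular excavations
#'
#' Low-intensity blobs are segmented by the inverted IsoData threshold
#' (`intensity < T`); components with circularity `4*pi*A/P^2` at or above
#' `min_circularity` are retained (perimeter from boundary edge counts with
#' the pi/4 digital-perimeter correction). The count is normalized to a
#' 100 x 100 um^2 field. Depth is an intensity proxy -- background mean minus
#' blob mean -- never a calibrated height in nanometres.
#'
#' @param img a [chem_image()].
#' @param min_circularity retain components at or above this circularity
#'   (default 0.6).
#' @param min_area_um2 ignore components smaller than this (default 0.5,
#'   suppresses pixel-scale noise blobs).
#' @return List with `count` (retained, as observed), `count_per_field`
#'   (per 100 x 100 um^2), `mean_radius_um`, `mean_depth_proxy` and the
#'   per-component table `excavations`.
#' @export
detect_excavations <- function(img, min_circularity = 0.6, min_area_um2 = 0.5) {
  stopifnot(inherits(img, "chem_image"))
  t <- isodata_threshold(img)
  mask <- img$data < t                       # dark phase
  px <- img$pixel_size_um
  lab <- label_components(mask)
  k <- max(lab)
  field_scale <- 1e4 / (prod(dim(img$data)) * px^2)
  empty <- list(count = 0L, count_per_field = 0, mean_radius_um = NA_real_,
                mean_depth_proxy = NA_real_,
                excavations = data.frame(area_um2 = numeric(0),
                                         equivalent_radius_um = numeric(0),
                                         circularity = numeric(0),
                                         depth_proxy = numeric(0)))
  if (k == 0) return(empty)
  idx <- which(lab > 0)
  id <- lab[idx]
  npx <- tabulate(id, k)
  ## boundary edge count: 4-neighbour edges from component pixels to
  ## non-member pixels (image border counts as boundary)
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(k)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    rr <- r + d[1]; cc <- co + d[2]
    inside <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb_lab <- integer(length(idx))
    nb_lab[inside] <- lab[cbind(rr[inside], cc[inside])]
    ext <- !inside | nb_lab != id
    edges <- edges + tabulate(id[ext], k)
  }
  perim <- edges * px * pi / 4               # digital perimeter correction
  area <- npx * px^2
  circ <- pmin(1, 4 * pi * area / perim^2)
  bg_mean <- mean(img$data[!mask])
  depth <- bg_mean - as.numeric(tapply(as.numeric(img$data[idx]), id, mean))
  keep <- circ >= min_circularity & area >= min_area_um2
  exc <- data.frame(area_um2 = area[keep],
                    equivalent_radius_um = sqrt(area[keep] / pi),
                    circularity = circ[keep],
                    depth_proxy = depth[keep])
  if (nrow(exc) == 0) return(empty)
  list(count = nrow(exc),
       count_per_field = nrow(exc) * field_scale,
       mean_radius_um = mean(exc$equivalent_radius_um),
       mean_depth_proxy = mean(exc$depth_proxy),
       excavations = exc)
}

#' All surface metrics for one image as a single row
#'
#' Convenience wrapper bundling [surface_entropy()], [roughness_waviness()],
#' [periodic_area_fraction()] and [detect_excavations()] into the fixed
#' column layout used by the feature assembly.
#'
#' @param img a [chem_image()].
#' @param bins,cutoff_um,window_um,prominence,min_circularity passed to the
#'   respective metrics.
#' @return One-row data frame: `entropy_nats`, `entropy_deficit_nats`,
#'   `roughness_Ra`, `roughness_Rq`, `waviness_Wa`, `periodic_area_pct`,
#'   `excavation_count_per_field`, `excavation_mean_radius_um`,
#'   `excavation_mean_depth_proxy`.
#' @export
surface_metrics <- function(img, bins = 64, cutoff_um = 8, window_um = 12,
                            prominence = 0.3, min_circularity = 0.6) {
  ent <- surface_entropy(img, bins = bins)
  rw <- roughness_waviness(img, cutoff_um = cutoff_um)
  per <- periodic_area_fraction(img, window_um = window_um,
                                prominence = prominence)
  exc <- detect_excavations(img, min_circularity = min_circularity)
  data.frame(entropy_nats = ent$entropy_nats,
             entropy_deficit_nats = ent$deficit_nats,
             roughness_Ra = rw$Ra, roughness_Rq = rw$Rq, waviness_Wa = rw$Wa,
             periodic_area_pct = per,
             excavation_count_per_field = exc$count_per_field,
             excavation_mean_radius_um = ifelse(is.na(exc$mean_radius_um), 0,
                                                exc$mean_radius_um),
             excavation_mean_depth_proxy = ifelse(is.na(exc$mean_depth_proxy),
                                                  0, exc$mean_depth_proxy))
}
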