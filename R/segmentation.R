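#' IsoData (iterative intermeans) automatic threshold
#'
#' Computes the classic Ridler--Calvard intermeans threshold on the 256-bin
#' intensity histogram, the algorithm behind ImageJ's `IJ_IsoData`
#' standardization of chemical images. Starting from the midpoint of the
#' occupied intensity range, the threshold is iterated as
#' `T <- floor((mean(I <= T) + mean(I > T)) / 2)` (integer division, the ImageJ convention) until it reaches a fixed
#' point; a cycle is resolved toward the smaller level. All 256 levels,
#' including 0 and 255, participate (no extreme-bin exclusion).
#'
#' @param img a [chem_image()] or an integer matrix in `[0, 255]`.
#' @return Integer threshold level `T` in `[0, 254]` satisfying
#'   `T == floor((mu_low + mu_high) / 2)`.
#' @export
isodata_threshold <- function(img) {
  x <- if (inherits(img, "chem_image")) img$data else img
  h <- tabulate(as.integer(x) + 1L, nbins = 256)     # counts of levels 0..255
  lev <- 0:255
  occ <- which(h > 0) - 1L
  if (length(occ) < 2)
    stop("degenerate histogram: image has fewer than 2 distinct intensity values")
  lo <- min(occ); hi <- max(occ)
  csum_n <- cumsum(h)                    # pixels at level <= t  (index t+1)
  csum_s <- cumsum(h * lev)              # intensity mass at level <= t
  n <- csum_n[256]; s <- csum_s[256]
  intermeans <- function(t) {
    n_lo <- csum_n[t + 1L]; s_lo <- csum_s[t + 1L]
    if (n_lo == 0 || n_lo == n) return(NA_integer_)
    mu_lo <- s_lo / n_lo
    mu_hi <- (s - s_lo) / (n - n_lo)
    as.integer(floor((mu_lo + mu_hi) / 2))
  }
  t <- as.integer(floor((lo + hi) / 2))
  t <- max(lo, min(t, hi - 1L))          # both classes non-empty at start
  seen <- integer(0)
  repeat {
    t_new <- intermeans(t)
    if (is.na(t_new)) t_new <- t         # one class empty: stay put
    t_new <- max(lo, min(t_new, hi - 1L))
    if (t_new == t) break
    if (t_new %in% seen) { t <- min(t, t_new); break }  # safety; the floor
    seen <- c(seen, t)                   # intermeans map is monotone, so
    t <- t_new                           # cycles cannot actually occur
  }
  ## fixed points come in runs; ties break toward the smaller level
  while (t > lo) {
    tm <- intermeans(t - 1L)
    if (is.na(tm) || tm != t - 1L) break
    t <- t - 1L
  }
  t
}

#' Binarize a chemical image at a threshold
#'
#' Foreground is the high-intensity phase: `mask = intensity > threshold`.
#'
#' @param img a [chem_image()].
#' @param threshold intensity level in `[0, 255]`; defaults to
#'   [isodata_threshold()] of the image.
#' @return An object of class `binary_map`: list with `mask` (logical
#'   matrix), `threshold`, `method` and `source` (the input image).
#' @export
binarize <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "chem_image"))
  method <- if (is.null(threshold)) "isodata" else "manual"
  if (is.null(threshold)) threshold <- isodata_threshold(img)
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  structure(
    list(mask = img$data > threshold, threshold = threshold,
         method = method, source = img),
    class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %s threshold %d, %d / %d px foreground (%.2f%%)\n",
              x$method, x$threshold, sum(x$mask), length(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

## 8-connected component labels of a logical matrix. Returns an integer
## matrix, 0 = background, components numbered in raster-scan order of their
## first pixel. Built on igraph components over the pixel adjacency graph.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  pos <- match(idx, idx)                 # 1..k, raster order (column-major)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  key <- function(rr, cc) (cc - 1L) * nr + rr
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + d[1]; cc <- co + d[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- match(key(rr[ok], cc[ok]), idx)
    hit <- !is.na(nb)
    if (any(hit))
      edges <- c(edges, rbind(pos[ok][hit], nb[hit]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  ## renumber in raster-scan (row-major) order of first appearance
  ord <- order(r, co)
  first <- comp[ord][!duplicated(comp[ord])]
  lab[idx] <- match(comp, first)
  lab
}

#' Particle analysis of a binary map
#'
#' Connected-component statistics under 8-connectivity (the ImageJ particle
#' default): per-particle area, centroid, equivalent radius and mean source
#' intensity, plus the aggregate count / total area / mean size triplet of a
#' standard ion particle table.
#'
#' @param map a [binarize()] result with a calibrated source image.
#' @param min_size_um2 drop particles smaller than this area (default 0; no
#'   filter, matching the published analysis).
#' @return An object of class `particle_stats`: list with `count`,
#'   `total_area_um2`, `mean_size_um2`, `mean_intensity` and a data frame
#'   `particles` (columns `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `equivalent_radius_um`, `mean_intensity`).
#' @export
label_particles <- function(map, min_size_um2 = 0) {
  stopifnot(inherits(map, "binary_map"))
  img <- map$source
  px <- img$pixel_size_um
  lab <- label_components(map$mask)
  k <- max(lab)
  if (k == 0) {
    particles <- data.frame(area_um2 = numeric(0), centroid_x_um = numeric(0),
                            centroid_y_um = numeric(0),
                            equivalent_radius_um = numeric(0),
                            mean_intensity = numeric(0))
  } else {
    idx <- which(lab > 0)
    id <- lab[idx]
    r <- ((idx - 1L) %% nrow(lab)) + 1L
    co <- ((idx - 1L) %/% nrow(lab)) + 1L
    npx <- tabulate(id, k)
    area <- npx * px^2
    cx <- tapply((co - 0.5) * px, id, mean)
    cy <- tapply((r - 0.5) * px, id, mean)
    mi <- tapply(as.numeric(img$data[idx]), id, mean)
    particles <- data.frame(
      area_um2 = area,
      centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy),
      equivalent_radius_um = sqrt(area / pi),
      mean_intensity = as.numeric(mi))
    if (min_size_um2 > 0)
      particles <- particles[particles$area_um2 >= min_size_um2, , drop = FALSE]
    rownames(particles) <- NULL
  }
  count <- nrow(particles)
  total <- sum(particles$area_um2)
  structure(
    list(count = count,
         total_area_um2 = total,
         mean_size_um2 = if (count > 0) total / count else 0,
         mean_intensity = if (count > 0) mean(particles$mean_intensity) else NA_real_,
         particles = particles,
         pixel_size_um = px),
    class = "particle_stats")
}

#' @export
print.particle_stats <- function(x, ...) {
  cat(sprintf("<particle_stats> count %d, area %.3f um^2, average size %.3f um^2\n",
              x$count, x$total_area_um2, x$mean_size_um2))
  invisible(x)
}

#' Pixel coverage of site foreground by ion foreground
#'
#' Percentage of site pixels also in the ion mask (e.g. the share of -OH
#' sites covered by Li+). The companion `free_pct` is the complement, the
#' quantity reported as "percentage of sites uncovered".
#'
#' @param ion,sites [binarize()] results on identical grids.
#' @return List with `coverage_pct`, `free_pct` (summing to 100 exactly),
#'   `site_px`, `overlap_px`.
#' @export
coverage_fraction <- function(ion, sites) {
  stopifnot(inherits(ion, "binary_map"), inherits(sites, "binary_map"))
  if (!identical(dim(ion$mask), dim(sites$mask)))
    stop("ion and site maps must share the same grid shape")
  n_sites <- sum(sites$mask)
  if (n_sites == 0) stop("empty sites mask: coverage is undefined")
  overlap <- sum(ion$mask & sites$mask)
  cov <- 100 * overlap / n_sites
  list(coverage_pct = cov, free_pct = 100 - cov,
       site_px = n_sites, overlap_px = overlap)
}

#' Fraction of site aggregates touched by ion foreground
#'
#' A site connected component counts as co-located when at least one of its
#' pixels overlaps the ion mask (e.g. the share of phosphate site aggregates
#' co-located with Na+).
#'
#' @inheritParams coverage_fraction
#' @return Percentage of site components with >= 1 overlapping pixel.
#' @export
colocated_site_fraction <- function(ion, sites) {
  stopifnot(inherits(ion, "binary_map"), inherits(sites, "binary_map"))
  if (!identical(dim(ion$mask), dim(sites$mask)))
    stop("ion and site maps must share the same grid shape")
  lab <- label_components(sites$mask)
  k <- max(lab)
  if (k == 0) stop("no site components: co-location is undefined")
  hit <- unique(lab[lab > 0 & ion$mask])
  100 * length(hit) / k
}

#' Export a binary map as a 0/255 PNG
#'
#' @param map a [binarize()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_binary_map <- function(map, path) {
  stopifnot(inherits(map, "binary_map"))
  png::writePNG(map$mask * 1, path)
  invisible(path)
}

#' Particle table row in the published column layout
#'
#' @param stats a [label_particles()] result.
#' @return One-row data frame with columns `count`, `area_um2`,
#'   `average_size_um2`, `mean_intensity`.
#' @export
particle_table <- function(stats) {
  stopifnot(inherits(stats, "particle_stats"))
  data.frame(count = stats$count, area_um2 = stats$total_area_um2,
             average_size_um2 = stats$mean_size_um2,
             mean_intensity = stats$mean_intensity)
}
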