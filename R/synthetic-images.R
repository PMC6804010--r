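## Synthetic chemical-image generator.
##
## Emulates the three ion distribution patterns seen on pretreated bagasse
## surfaces -- homogeneous Poisson ("random"), Thomas parent-offspring
## ("clustered") and aggregates strung along parallel ridges
## ("fibril_periodic") -- as planted discs with known centres and radii, so
## the segmentation and discriminant stages can be tested against ground
## truth.

#' Recipe for one synthetic ion map
#'
#' @param field_size_um field edge length in micrometres (default 100, the
#'   largest acquisition field).
#' @param pixels_per_um raster resolution (default 2.56, i.e. 256 px across a
#'   100 um field: desk-scale speed while keeping sub-micron aggregates
#'   resolvable).
#' @param pattern `"random"` (homogeneous Poisson positions),
#'   `"clustered"` (Thomas process) or `"fibril_periodic"` (aggregates on
#'   parallel ridge lines).
#' @param n_aggregates number of planted aggregates (>= 0).
#' @param aggregate_radius_um length-2 vector `(mean, sd)` of the truncated
#'   normal radius distribution, in micrometres.
#' @param intensity_fg,intensity_bg foreground/background levels in
#'   `[0, 255]`; `intensity_fg > intensity_bg`.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param coloc_target optional list `list(channel =, coverage_fraction =)`
#'   for [gen_coloc_pair()]; `coverage_fraction` in `[0, 1]`.
#' @param ridge_period_um ridge spacing for `fibril_periodic`.
#' @param ridge_angle_deg ridge orientation (degrees from the x axis).
#' @param cluster_sd_um offspring spread of the Thomas process.
#' @param seed integer seed; all randomness derives from it via
#'   [split_seed()].
#' @return An object of class `image_recipe`.
#' @export
image_recipe <- function(field_size_um = 100, pixels_per_um = 2.56,
                         pattern = c("random", "clustered", "fibril_periodic"),
                         n_aggregates = 50,
                         aggregate_radius_um = c(0.8, 0.15),
                         intensity_fg = 200, intensity_bg = 30,
                         noise_sd = 8, coloc_target = NULL,
                         ridge_period_um = 4, ridge_angle_deg = 0,
                         cluster_sd_um = 3, seed = 1) {
  pattern <- match.arg(pattern)
  if (n_aggregates < 0) stop("`n_aggregates` must be >= 0")
  if (intensity_fg <= intensity_bg) stop("`intensity_fg` must exceed `intensity_bg`")
  if (!is.null(coloc_target)) {
    cf <- coloc_target$coverage_fraction
    if (is.null(cf) || cf < 0 || cf > 1)
      stop("`coloc_target$coverage_fraction` must lie in [0, 1]")
  }
  if (length(aggregate_radius_um) == 1)
    aggregate_radius_um <- c(aggregate_radius_um, 0)
  structure(
    list(field_size_um = field_size_um, pixels_per_um = pixels_per_um,
         pattern = pattern, n_aggregates = as.integer(n_aggregates),
         aggregate_radius_um = aggregate_radius_um,
         intensity_fg = intensity_fg, intensity_bg = intensity_bg,
         noise_sd = noise_sd, coloc_target = coloc_target,
         ridge_period_um = ridge_period_um, ridge_angle_deg = ridge_angle_deg,
         cluster_sd_um = cluster_sd_um, seed = as.integer(seed)),
    class = "image_recipe")
}

## Draw aggregate centres for a recipe; returns matrix [n, 2] in um.
## Placement is sequential with rejection: a candidate must keep
## centre-to-centre distance > r_i + r_j + gap_um from all accepted discs and
## lie fully inside the field. Bounded retries, then an error.
place_aggregates <- function(recipe, radii, region_mask = NULL, n_inside = 0L) {
  n <- recipe$n_aggregates
  fs <- recipe$field_size_um
  gap_um <- 3 / recipe$pixels_per_um      # >= 3 px so blur cannot merge discs
  if (n == 0) return(matrix(numeric(0), 0, 2))
  in_region <- function(cand) {
    if (is.null(region_mask)) return(FALSE)
    ppu <- recipe$pixels_per_um
    i <- max(1L, min(nrow(region_mask), ceiling(cand[2] * ppu)))
    j <- max(1L, min(ncol(region_mask), ceiling(cand[1] * ppu)))
    region_mask[i, j]
  }
  got_inside <- 0L; got_outside <- 0L
  n_outside <- n - n_inside
  make_propose <- function() switch(recipe$pattern,
    random = function(k) cbind(runif(k, 0, fs), runif(k, 0, fs)),
    clustered = local({
      n_parents <- max(1L, round(n / 8))
      parents <- cbind(runif(n_parents, 0, fs), runif(n_parents, 0, fs))
      function(k) {
        p <- parents[sample.int(n_parents, k, replace = TRUE), , drop = FALSE]
        p + matrix(rnorm(2 * k, 0, recipe$cluster_sd_um), k, 2)
      }
    }),
    fibril_periodic = local({
      th <- recipe$ridge_angle_deg * pi / 180
      per <- recipe$ridge_period_um
      phase <- runif(1, 0, per)
      function(k) {
        along <- runif(k, -fs, 2 * fs)                 # position along ridge
        ridge <- phase + per * sample.int(ceiling(2 * fs / per), k, replace = TRUE)
        across <- ridge - fs / 2 + rnorm(k, 0, per / 12)
        ## rotate (along, across) frame by ridge angle
        cbind(fs / 2 + along * cos(th) - across * sin(th),
              fs / 2 + along * sin(th) + across * cos(th))
      }
    }))
  propose <- make_propose()
  centers <- matrix(NA_real_, n, 2)
  rs <- numeric(n)
  accepted <- 0L
  tries <- 0L
  max_tries <- 400L * n
  while (accepted < n) {
    if (tries >= max_tries)
      stop("overlap placement failed: could not place ", n,
           " non-overlapping aggregates after ", max_tries, " attempts")
    cand <- propose(1L)
    tries <- tries + 1L
    ## a stuck clustered/ridge draw (e.g. all parents near a border) gets a
    ## fresh set of latent positions rather than failing outright
    if (tries %% (100L * n) == 0L) propose <- make_propose()
    r <- radii[accepted + 1L]
    if (any(cand < r) || any(cand > fs - r)) next
    if (!is.null(region_mask)) {          # region quota (e.g. Li on -OH sites)
      if (in_region(cand)) {
        if (got_inside >= n_inside) next
      } else {
        if (got_outside >= n_outside) next
      }
    }
    if (accepted > 0) {
      d <- sqrt((centers[seq_len(accepted), 1] - cand[1])^2 +
                (centers[seq_len(accepted), 2] - cand[2])^2)
      if (any(d <= rs[seq_len(accepted)] + r + gap_um)) next
    }
    if (!is.null(region_mask)) {
      if (in_region(cand)) got_inside <- got_inside + 1L
      else got_outside <- got_outside + 1L
    }
    accepted <- accepted + 1L
    centers[accepted, ] <- cand
    rs[accepted] <- r
  }
  centers
}

## Paint filled discs (fg level) onto a bg-level matrix. Pixel centres within
## the disc radius are painted; the pixel nearest the centre is always
## painted so sub-pixel aggregates remain visible.
paint_discs <- function(n_px, pixels_per_um, centers, radii, fg, bg) {
  img <- matrix(bg, n_px, n_px)
  if (nrow(centers) == 0) return(img)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] * pixels_per_um   # px coordinates
    cy <- centers[i, 2] * pixels_per_um
    r <- radii[i] * pixels_per_um
    j0 <- max(1L, floor(cx - r)); j1 <- min(n_px, ceiling(cx + r) + 1L)
    i0 <- max(1L, floor(cy - r)); i1 <- min(n_px, ceiling(cy + r) + 1L)
    jj <- j0:j1; ii <- i0:i1
    dx <- (jj - 0.5) - cx
    dy <- (ii - 0.5) - cy
    d2 <- outer(dy^2, dx^2, `+`)
    img[ii, jj][d2 <= r^2] <- fg
    ## nearest pixel, clamped into the field
    img[max(1L, min(n_px, ceiling(cy))), max(1L, min(n_px, ceiling(cx)))] <- fg
  }
  img
}

## Separable Gaussian blur, replicate padding, kernel renormalised at edges.
gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  rad <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-rad):rad)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_conv <- function(m) {                 # convolve columns of m with k
    n <- nrow(m)
    top <- m[rep(1L, rad), , drop = FALSE]
    bot <- m[rep(n, rad), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, n, ncol(m))
    for (o in (-rad):rad)
      out <- out + k[o + rad + 1L] * mp[(rad + 1 + o):(rad + n + o), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(x))))
}

## Finish a painted field: edge blur (sigma 0.5 px), additive noise, clamp,
## quantize to 8-bit.
render_field <- function(painted, recipe, key) {
  img <- gaussian_blur(painted, 0.5)
  if (recipe$noise_sd > 0)
    img <- img + with_split_seed(recipe$seed, paste0(key, "/noise"),
                                 matrix(rnorm(length(img), 0, recipe$noise_sd),
                                        nrow(img)))
  img <- matrix(pmin(255, pmax(0, round(img))), nrow(painted))
  storage.mode(img) <- "integer"
  img
}

#' Generate one synthetic ion map with ground truth
#'
#' Aggregates are filled discs with a Gaussian edge blur of sigma = 0.5 px
#' (diffuse sputter spots without committing to an instrument PSF), placed
#' without overlap by bounded rejection sampling.
#'
#' @param recipe an [image_recipe()].
#' @param channel,sample_id metadata for the returned image.
#' @param region_mask optional logical matrix (field grid) restricting a
#'   quota of aggregates to a region, e.g. Li+ aggregates on -OH sites.
#' @param frac_inside fraction of aggregates whose centres must fall inside
#'   `region_mask` (ignored when `region_mask` is `NULL`).
#' @return List with `image` (a [chem_image()]) and `ground_truth` (data
#'   frame `center_x_um`, `center_y_um`, `radius_um`).
#' @export
gen_ion_map <- function(recipe, channel = "ion", sample_id = "synthetic",
                        region_mask = NULL, frac_inside = 0) {
  stopifnot(inherits(recipe, "image_recipe"))
  n_px <- round(recipe$field_size_um * recipe$pixels_per_um)
  key <- paste0("gen_ion_map/", channel, "/", sample_id)
  gt <- with_split_seed(recipe$seed, key, {
    radii <- abs(rnorm(recipe$n_aggregates, recipe$aggregate_radius_um[1],
                       recipe$aggregate_radius_um[2]))
    radii <- pmax(radii, 0.05)
    centers <- place_aggregates(recipe, radii, region_mask = region_mask,
                                n_inside = round(frac_inside * recipe$n_aggregates))
    data.frame(center_x_um = centers[, 1], center_y_um = centers[, 2],
               radius_um = radii[seq_len(nrow(centers))])
  })
  painted <- paint_discs(n_px, recipe$pixels_per_um,
                         as.matrix(gt[, 1:2, drop = FALSE]), gt$radius_um,
                         recipe$intensity_fg, recipe$intensity_bg)
  data <- render_field(painted, recipe, key)
  list(image = chem_image(data, 1 / recipe$pixels_per_um, channel = channel,
                          sample_id = sample_id),
       ground_truth = gt)
}

#' Generate an ion/site image pair with controlled co-location
#'
#' The sites image is a planted-aggregate map (e.g. -OH sites); the ion image
#' covers a requested fraction of the site pixels, component by component in
#' deterministic order, so the realized pixel coverage equals the request to
#' within one partially covered component row (noise-free).
#'
#' @param recipe an [image_recipe()] with `coloc_target` set.
#' @return List with `ion` and `sites` ([chem_image()]s), `site_truth` (the
#'   site ground-truth table) and `requested_coverage`.
#' @export
gen_coloc_pair <- function(recipe) {
  stopifnot(inherits(recipe, "image_recipe"))
  if (is.null(recipe$coloc_target))
    stop("`recipe$coloc_target` must be set for gen_coloc_pair()")
  f <- recipe$coloc_target$coverage_fraction
  n_px <- round(recipe$field_size_um * recipe$pixels_per_um)
  sites <- gen_ion_map(recipe, channel = recipe$coloc_target$channel %||% "OH",
                       sample_id = "coloc_sites")
  site_mask <- sites$image$data > (recipe$intensity_bg + recipe$intensity_fg) / 2
  n_sites <- sum(site_mask)
  if (n_sites == 0 && f > 0)
    stop("infeasible coverage: requested ", f, " but the site mask is empty")
  budget <- round(f * n_sites)
  lab <- label_components(site_mask)
  sel <- matrix(FALSE, n_px, n_px)
  if (budget > 0) {
    for (cid in seq_len(max(lab))) {
      px <- which(lab == cid)
      if (length(px) <= budget) {
        sel[px] <- TRUE
        budget <- budget - length(px)
      } else {
        sel[px[seq_len(budget)]] <- TRUE   # partial cover in raster order
        budget <- 0L
      }
      if (budget == 0L) break
    }
  }
  painted <- matrix(recipe$intensity_bg, n_px, n_px)
  painted[sel] <- recipe$intensity_fg
  key <- paste0("gen_coloc_pair/", recipe$coloc_target$channel %||% "OH")
  ion_data <- render_field(painted, recipe, key)
  list(ion = chem_image(ion_data, 1 / recipe$pixels_per_um, channel = "ion",
                        sample_id = "coloc_ion"),
       sites = sites$image,
       site_truth = sites$ground_truth,
       requested_coverage = f)
}
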