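## Five-treatment synthetic study.
##
## Plants the ionic signatures of the five bagasse conditions (control plus
## four pretreatments) so that the discriminant stage has a known answer:
## Li+ counts follow the published particle-table ordering exactly
## (control 353 > EtOH:DMSO:AO 320 > Steam 88 > Microwave 63, NaOH 16), Li+
## distribution patterns follow the described morphology (ridge-periodic on
## control/EtOH:DMSO:AO, random after Steam/Microwave, one clustered remnant
## after NaOH), and Li+ placement on -OH sites is high for control/EtOH and
## near zero otherwise. Non-Li channels are planted *identically* across
## treatments (the control column of the reference particle table, realized
## independently per treatment): the studied materials shared a very similar
## ionic composition and differed in the relative concentration and
## distribution of lithium, so the Li block is the planted discriminating
## group the jackknife is expected to recover.

suite_treatments <- c("Control", "EtOH_DMSO_AO", "SteamExplosion",
                      "Microwave_H2SO4", "NaOH")

## Planted per-treatment ionic parameters. Li counts/patterns/coverage are
## treatment-specific; remaining ions are shared across all treatments.
suite_plan <- function() {
  trt <- suite_treatments
  li <- data.frame(
    treatment = trt,
    count = c(353L, 320L, 88L, 63L, 16L),
    radius_um = c(0.195, 0.195, 0.093, 0.093, 0.302),
    pattern = c("fibril_periodic", "fibril_periodic", "random", "random",
                "clustered"),
    frac_on_oh = c(0.9, 0.9, 0.1, 0.1, 0.1))
  ions <- list(   # count and mean radius (um) shared by all treatments
    Na     = list(count = 71L,  radius = 1.41, pattern = "clustered"),
    K      = list(count = 19L,  radius = 2.92, pattern = "random"),
    Mg     = list(count = 144L, radius = 0.81, pattern = "random"),
    CaC3H4 = list(count = 44L,  radius = 1.95, pattern = "random"),
    F      = list(count = 197L, radius = 1.14, pattern = "random"),
    Cl     = list(count = 62L,  radius = 1.51, pattern = "random"),
    DDA    = list(count = 7L,   radius = 0.12, pattern = "random"))
  ## NaOH exception: the alkali pretreatment showed the biggest Na+/F-
  ## enrichment on record (1.73-fold mean increase over the control) with
  ## few, large Na aggregates; planted via brighter foreground and the
  ## NaOH-specific count/size of the reference particle table.
  naoh_enrich <- list(
    Na = list(count = 23L, radius = 2.28, pattern = "clustered",
              intensity_fg = 225),
    F  = list(count = 46L, radius = 1.64, pattern = "random",
              intensity_fg = 225))
  ## anatomical plan: periodic-band fraction, excavations per full field,
  ## amorphous deposits (control/EtOH surfaces are covered by deposits)
  anat <- data.frame(
    treatment = trt,
    periodic_frac = c(0.90, 0.90, 0.47, 0.875, 0.087),
    n_excavations = c(0L, 0L, 0L, 72L, 0L),
    n_deposits = c(40L, 40L, 8L, 8L, 8L))
  list(li = li, ions = ions, naoh_enrich = naoh_enrich, anat = anat)
}

## Structure ("matrix") channel: a vertical band of sinusoidal ridges
## covering `periodic_frac` of the field, amorphous elsewhere, optional dark
## circular excavations, plus bright amorphous deposits.
gen_structure_map <- function(periodic_frac, n_excavations, n_deposits,
                              field_size_um = 100, pixels_per_um = 2.56,
                              ridge_period_um = 3, noise_sd = 8, seed = 1,
                              sample_id = "synthetic") {
  n_px <- round(field_size_um * pixels_per_um)
  key <- paste0("structure/", sample_id)
  img <- with_split_seed(seed, key, {
    x_um <- (seq_len(n_px) - 0.5) / pixels_per_um
    ridge <- 110 + 70 * sin(2 * pi * x_um / ridge_period_um)
    base <- matrix(rep(ridge, each = n_px), n_px, n_px)  # ridges vary along x
    n_band <- round(periodic_frac * n_px)
    if (n_band < n_px) {
      amorph <- matrix(110, n_px, n_px) +
        gaussian_blur(matrix(rnorm(n_px^2, 0, 140), n_px), 2.0)
      cols <- seq_len(n_px) > n_band
      base[, cols] <- amorph[, cols]
    }
    if (n_deposits > 0) {                 # bright amorphous organic deposits
      cx <- runif(n_deposits, 3, field_size_um - 3)
      cy <- runif(n_deposits, 3, field_size_um - 3)
      rr <- pmax(0.5, rnorm(n_deposits, 2.2, 0.5))
      dep <- paint_discs(n_px, pixels_per_um, cbind(cx, cy), rr, 1, 0)
      dep <- gaussian_blur(dep, 2.0)
      base <- base + 90 * dep / max(dep)
    }
    if (n_excavations > 0) {              # dark, roughly circular pits
      cx <- runif(n_excavations, 2, field_size_um - 2)
      cy <- runif(n_excavations, 2, field_size_um - 2)
      pit <- paint_discs(n_px, pixels_per_um, cbind(cx, cy),
                         rep(0.72, n_excavations), 1, 0)
      base[pit > 0.5] <- 8
    }
    base <- gaussian_blur(base, 0.5)
    base + matrix(rnorm(n_px^2, 0, noise_sd), n_px)
  })
  img <- matrix(pmin(255, pmax(0, round(img))), n_px)
  storage.mode(img) <- "integer"
  chem_image(img, 1 / pixels_per_um, channel = "matrix",
             polarity = "negative", sample_id = sample_id)
}

#' Generate the five-treatment synthetic image suite
#'
#' Produces, for each of the five conditions (control, EtOH:DMSO:AO, Steam
#' Explosion, Microwave:H2SO4, NaOH), one chemical image per channel: eight
#' ion channels (Li, Na, K, Mg, CaC3H4, F, Cl, DDA), an `OH` site channel and
#' a structural `matrix` channel. Planted ionic parameters are returned as
#' ground truth; the Li channel is the planted discriminating group.
#'
#' @param seed master integer seed.
#' @param field_size_um,pixels_per_um field geometry (defaults 100 um at
#'   2.56 px/um, i.e. 256 x 256 px).
#' @param noise_sd additive Gaussian image noise (intensity units).
#' @return An object of class `treatment_suite`: list with `images`
#'   (`treatment -> channel -> chem_image`), `ground_truth` (planted Li and
#'   ion parameters plus per-image truth tables), `plan` and
#'   `discriminating_group` (`"Li"`).
#' @export
gen_treatment_suite <- function(seed = 1, field_size_um = 100,
                                pixels_per_um = 2.56, noise_sd = 8) {
  plan <- suite_plan()
  images <- list()
  truth <- list()
  n_px <- round(field_size_um * pixels_per_um)
  for (ti in seq_along(suite_treatments)) {
    trt <- suite_treatments[ti]
    imgs <- list()
    tt <- list()
    base_seed <- split_seed(seed, paste0("suite/", trt))

    ## -OH sites first: Li placement takes a quota on them
    oh_recipe <- image_recipe(
      field_size_um = field_size_um, pixels_per_um = pixels_per_um,
      pattern = "random", n_aggregates = 60, aggregate_radius_um = c(4, 0.5),
      noise_sd = noise_sd, seed = split_seed(base_seed, "OH"))
    oh <- gen_ion_map(oh_recipe, channel = "OH", sample_id = trt)
    oh$image$polarity <- "negative"
    imgs$OH <- oh$image
    tt$OH <- oh$ground_truth
    oh_mask <- paint_discs(n_px, pixels_per_um,
                           as.matrix(oh$ground_truth[, 1:2]),
                           oh$ground_truth$radius_um, 1, 0) > 0.5

    ## Li: treatment-specific planted count, pattern and -OH co-location
    li <- plan$li[ti, ]
    li_recipe <- image_recipe(
      field_size_um = field_size_um, pixels_per_um = pixels_per_um,
      pattern = li$pattern, n_aggregates = li$count,
      aggregate_radius_um = c(li$radius_um, 0.12 * li$radius_um),
      noise_sd = noise_sd, ridge_period_um = 4, cluster_sd_um = 2,
      seed = split_seed(base_seed, "Li"))
    li_map <- gen_ion_map(li_recipe, channel = "Li", sample_id = trt,
                          region_mask = oh_mask, frac_inside = li$frac_on_oh)
    imgs$Li <- li_map$image
    tt$Li <- li_map$ground_truth

    ## remaining ions: identical planted parameters for every treatment,
    ## realized independently (treatment-specific seeds); NaOH carries the
    ## planted Na+/F- enrichment (brighter, reference NaOH count/size)
    for (ion in names(plan$ions)) {
      p <- plan$ions[[ion]]
      fg <- if (ion %in% names(plan$naoh_enrich)) 130 else 200
      if (trt == "NaOH" && ion %in% names(plan$naoh_enrich)) {
        p <- plan$naoh_enrich[[ion]]
        fg <- p$intensity_fg
      }
      rec <- image_recipe(
        field_size_um = field_size_um, pixels_per_um = pixels_per_um,
        pattern = p$pattern, n_aggregates = p$count,
        aggregate_radius_um = c(p$radius, 0.12 * p$radius),
        intensity_fg = fg,
        cluster_sd_um = max(3, 2.5 * p$radius),   # keep packing feasible
        noise_sd = noise_sd, seed = split_seed(base_seed, ion))
      m <- gen_ion_map(rec, channel = ion, sample_id = trt)
      if (ion %in% c("F", "Cl")) m$image$polarity <- "negative"
      imgs[[ion]] <- m$image
      tt[[ion]] <- m$ground_truth
    }

    ## structural channel for the anatomical block
    an <- plan$anat[ti, ]
    imgs$matrix <- gen_structure_map(
      an$periodic_frac, an$n_excavations, an$n_deposits,
      field_size_um = field_size_um, pixels_per_um = pixels_per_um,
      noise_sd = noise_sd, seed = base_seed, sample_id = trt)

    images[[trt]] <- imgs
    truth[[trt]] <- tt
  }
  structure(
    list(images = images, ground_truth = truth, plan = plan,
         discriminating_group = "Li", seed = seed,
         field_size_um = field_size_um, pixels_per_um = pixels_per_um),
    class = "treatment_suite")
}

#' @export
print.treatment_suite <- function(x, ...) {
  cat(sprintf("<treatment_suite> %d treatments x %d channels, %g um fields, seed %d\n",
              length(x$images), length(x$images[[1]]), x$field_size_um, x$seed))
  cat("  planted discriminating group:", x$discriminating_group, "\n")
  invisible(x)
}

#' Write a treatment suite to disk
#'
#' One 8-bit grayscale TIFF per treatment/channel, named
#' `<treatment>__<channel>.tif`, with YAML sidecars; ground truth as one CSV
#' per image (`center_x_um`, `center_y_um`, `radius_um`).
#'
#' @param suite a [gen_treatment_suite()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_treatment_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "treatment_suite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (trt in names(suite$images)) {
    for (ch in names(suite$images[[trt]])) {
      base <- file.path(dir, paste0(trt, "__", ch))
      write_chem_image(suite$images[[trt]][[ch]], paste0(base, ".tif"))
      gt <- suite$ground_truth[[trt]][[ch]]
      if (!is.null(gt))
        write.csv(gt, paste0(base, "__truth.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}
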