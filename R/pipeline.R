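## End-to-end orchestration: synthetic suite (or user images) -> per-tile
## particle and surface statistics -> standardized feature matrix ->
## discrimination (string, groups, consensus tree, jackknife) -> curve
## analysis -> report bundle of CSV/Newick/JSON artifacts, reproducible from
## one seed.

## Split an image into an n x n grid of tile images (the replicate
## observations of one treatment).
tile_grid <- function(img, n_side) {
  d <- dim(img$data)
  rs <- floor(d[1] / n_side); cs <- floor(d[2] / n_side)
  tiles <- list()
  for (i in seq_len(n_side)) {
    for (j in seq_len(n_side)) {
      sub <- img$data[((i - 1) * rs + 1):(i * rs), ((j - 1) * cs + 1):(j * cs)]
      tiles[[paste0("t", i, j)]] <- chem_image(
        sub, img$pixel_size_um, channel = img$channel,
        polarity = img$polarity, sample_id = paste0(img$sample_id, "_t", i, j))
    }
  }
  tiles
}

## Binary map for a tile given a threshold fixed at the full-image level
## (standardization happens once per image, as in the source workflow).
tile_binary <- function(tile, threshold) {
  structure(list(mask = tile$data > threshold, threshold = threshold,
                 method = "isodata", source = tile),
            class = "binary_map")
}

#' Extract per-tile features from a treatment suite
#'
#' Each image is standardized once (IsoData threshold at full-image level),
#' then split into `n_tiles_side^2` tiles, the replicate observations per
#' treatment. Per tile and ion channel: particle count, total area, average
#' size and mean intensity; per tile: Li+-on-OH coverage and the surface
#' metrics of the structural channel.
#'
#' @param suite a [gen_treatment_suite()] result (or a compatible
#'   `treatment -> channel -> chem_image` structure with `images` field).
#' @param n_tiles_side tiles per image edge (default 4, i.e. 16 observations
#'   per treatment).
#' @param surface named list of [surface_metrics()] overrides
#'   (`bins`, `cutoff_um`, `window_um`, `prominence`, `min_circularity`).
#' @return List of three tidy data frames: `particle_stats` (one row per
#'   obs x channel), `coverage_stats` and `surface_metrics` (one row per
#'   obs), ready for [assemble_features()].
#' @export
extract_suite_features <- function(suite, n_tiles_side = 4, surface = list()) {
  images <- suite$images
  sm_args <- utils::modifyList(
    list(bins = 64, cutoff_um = 8, window_um = 12, prominence = 0.3,
         min_circularity = 0.6), surface)
  particle <- list(); coverage <- list(); surf <- list()
  for (trt in names(images)) {
    chans <- images[[trt]]
    ion_channels <- setdiff(names(chans), "matrix")
    thresholds <- vapply(ion_channels, function(ch)
      isodata_threshold(chans[[ch]]), numeric(1))
    tiles <- lapply(chans, tile_grid, n_side = n_tiles_side)
    tile_names <- names(tiles[[1]])
    for (tn in tile_names) {
      obs <- paste0(trt, "_", tn)
      masks <- list()
      for (ch in ion_channels) {
        bm <- tile_binary(tiles[[ch]][[tn]], thresholds[[ch]])
        masks[[ch]] <- bm
        st <- label_particles(bm)
        particle[[length(particle) + 1]] <- data.frame(
          obs = obs, treatment = trt, channel = ch,
          count = st$count, area_um2 = st$total_area_um2,
          average_size_um2 = st$mean_size_um2,
          mean_intensity = ifelse(is.na(st$mean_intensity), 0, st$mean_intensity))
      }
      cov <- if (all(c("Li", "OH") %in% ion_channels) &&
                 sum(masks$OH$mask) > 0)
        coverage_fraction(masks$Li, masks$OH)$coverage_pct else 0
      coverage[[length(coverage) + 1]] <- data.frame(
        obs = obs, treatment = trt, li_oh_coverage_pct = cov)
      if ("matrix" %in% names(chans))
        surf[[length(surf) + 1]] <- cbind(
          data.frame(obs = obs, treatment = trt),
          do.call(surface_metrics, c(list(tiles$matrix[[tn]]), sm_args)))
    }
  }
  list(particle_stats = do.call(rbind, particle),
       coverage_stats = do.call(rbind, coverage),
       surface_metrics = if (length(surf)) do.call(rbind, surf) else NULL)
}

## FNV-1a hash of a deparsed object, as an 8-hex-digit run identifier.
config_hash <- function(cfg) {
  h <- 2166136261
  for (b in utf8ToInt(paste(deparse(cfg), collapse = ""))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(stamp, con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full surface-ionomics pipeline
#'
#' Sequences all stages on synthetic data (or user images loaded into a
#' suite-shaped structure): image generation, standardization and particle
#' analysis, surface metrics, feature assembly, mixture discriminant
#' analysis with gatekeeping and jackknife, consensus tree, and
#' saccharification-curve analysis. Every artifact is stamped with the seed
#' and a config hash; identical config + seed reproduces every file
#' byte for byte.
#'
#' @param config list (or path to a YAML file) with any of: `seed` (default
#'   42), `outdir` (required), `n_tiles_side` (4), `n_subclasses` (3),
#'   `alpha` (0.05), `n_perm` (999), `block` (`"ion"`: feature block used for
#'   discrimination; `"all"` uses both blocks), `field_size_um` (100),
#'   `pixels_per_um` (2.56), `noise_sd` (8), `surface` (list of surface
#'   metric overrides), `curves` (list of [curve_recipe()]s; default
#'   [default_curve_recipes()]), `suite` (a pre-built [gen_treatment_suite()]
#'   result, to skip generation).
#' @return Invisibly, a list with the in-memory results: `features`,
#'   `discrimination`, `jackknife`, `tree`, `folds`, `decay`,
#'   `curve_partition`, `artifacts` (paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(seed = 42, outdir = NULL, n_tiles_side = 4, n_subclasses = 3,
         jackknife_subclasses = 1, alpha = 0.05, n_perm = 999, block = "ion",
         field_size_um = 100, pixels_per_um = 2.56, noise_sd = 8,
         surface = list(), curves = NULL),
    config)
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# ionsurf run: seed=%d config_hash=%s", cfg$seed,
                   config_hash(cfg[setdiff(names(cfg), c("suite", "outdir"))]))
  log_stage <- function(stage, detail)
    message(sprintf("[ionsurf] %-12s %s", stage, detail))
  paths <- list()
  put <- function(name, df) {
    p <- file.path(cfg$outdir, name)
    write_stamped_csv(df, p, stamp)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_stage(name, sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  suite <- stage("simulate", cfg$suite %||% gen_treatment_suite(
    seed = cfg$seed, field_size_um = cfg$field_size_um,
    pixels_per_um = cfg$pixels_per_um, noise_sd = cfg$noise_sd))

  feats_in <- stage("segment", extract_suite_features(
    suite, n_tiles_side = cfg$n_tiles_side, surface = cfg$surface))
  put("particles.csv", feats_in$particle_stats)
  put("coverage.csv", feats_in$coverage_stats)
  if (!is.null(feats_in$surface_metrics))
    put("surface_metrics.csv", feats_in$surface_metrics)

  features <- stage("features", assemble_features(
    feats_in$particle_stats, feats_in$surface_metrics, feats_in$coverage_stats))
  put("features.csv", data.frame(obs = features$obs,
                                 treatment = features$treatment,
                                 features$x, check.names = FALSE))

  ## discrimination on the configured block
  keep <- if (identical(cfg$block, "all")) colnames(features$x)
          else names(features$blocks)[features$blocks == cfg$block]
  x <- features$x[, keep, drop = FALSE]
  labels <- features$treatment

  disc <- stage("discriminate", {
    model <- mda_fit(x, labels, n_subclasses = cfg$n_subclasses, seed = cfg$seed)
    discriminate(model, x, labels, merge_alpha = cfg$alpha,
                 n_perm = cfg$n_perm, seed = cfg$seed)
  })
  put("binary_matrix.csv", as.data.frame(disc$binary_matrix))

  ## ion-level jackknife groups: all columns of one channel together
  chan_of <- sub("^ion__([A-Za-z0-9]+)__.*$", "\\1", keep)
  chan_of[keep == "ion__li_oh_coverage_pct"] <- "Li"
  chan_of[startsWith(keep, "anat__")] <- "anatomical"
  groups <- split(keep, chan_of)

  ## importance scoring uses the parsimonious LDA-limit model: with tile
  ## counts close to the parameter count, deeper mixtures memorize the
  ## training set and mask column contributions
  jk <- stage("jackknife", jackknife_importance(
    x, labels, groups = groups, n_subclasses = cfg$jackknife_subclasses,
    seed = cfg$seed))
  put("jackknife.csv", as.data.frame(jk))

  tree <- stage("tree", {
    mats <- list(disc$binary_matrix)
    for (g in names(groups)) {
      xr <- x[, setdiff(keep, groups[[g]]), drop = FALSE]
      if (ncol(xr) < 2) next
      m <- mda_fit(xr, labels, n_subclasses = cfg$n_subclasses, seed = cfg$seed)
      d <- discriminate(m, xr, labels, merge_alpha = cfg$alpha,
                        n_perm = cfg$n_perm, seed = cfg$seed)
      mats[[length(mats) + 1]] <- d$binary_matrix
    }
    build_tree(mats)
  })
  tree_path <- file.path(cfg$outdir, "tree.nwk")
  writeLines(c(stamp, tree$newick), tree_path)
  paths[["tree.nwk"]] <- tree_path

  curves_out <- stage("curves", {
    recipes <- cfg$curves %||% default_curve_recipes()
    tab <- gen_saccharification(recipes, seed = cfg$seed)
    fits <- lapply(split(tab, tab$treatment), fit_curve)
    control <- fits$Control
    folds <- data.frame(
      treatment = names(fits),
      fold_vs_control_10h = vapply(fits, fold_change, numeric(1),
                                   control = control),
      decay_after_10h = vapply(fits, detect_decay, logical(1)))
    cl <- cluster_curves(fits, alpha = cfg$alpha)
    list(table = tab, fits = fits, folds = folds, partition = cl)
  })
  put("saccharification.csv", curves_out$table)
  put("fold_changes.csv", curves_out$folds)
  put("curve_p_matrix.csv", as.data.frame(curves_out$partition$p_matrix))
  part_path <- file.path(cfg$outdir, "curve_partition.json")
  jsonlite::write_json(
    list(seed = cfg$seed, partition = curves_out$partition$partition),
    part_path, auto_unbox = TRUE, pretty = TRUE)
  paths[["curve_partition.json"]] <- part_path

  summary_path <- file.path(cfg$outdir, "summary.txt")
  writeLines(c(
    stamp,
    sprintf("treatments: %s", paste(levels(labels), collapse = ", ")),
    sprintf("discrimination string: %s", paste(disc$string, collapse = " - ")),
    sprintf("merged groups: %s",
            paste(vapply(disc$groups, paste, "", collapse = "+"), collapse = " | ")),
    sprintf("training accuracy: %.3f", disc$accuracy),
    sprintf("top jackknife group: %s (%.1f%%)", jk$group[1], jk$importance_pct[1]),
    sprintf("fold vs control at 10 h: %s",
            paste(sprintf("%s=%.2f", curves_out$folds$treatment,
                          curves_out$folds$fold_vs_control_10h), collapse = ", ")),
    sprintf("curve partition: %s",
            paste(vapply(curves_out$partition$partition, paste, "",
                         collapse = "+"), collapse = " | "))),
    summary_path)
  paths[["summary.txt"]] <- summary_path

  invisible(list(features = features, discrimination = disc, jackknife = jk,
                 tree = tree, folds = curves_out$folds,
                 curve_partition = curves_out$partition$partition,
                 curve_fits = curves_out$fits, suite = suite,
                 artifacts = paths, config = cfg))
}
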