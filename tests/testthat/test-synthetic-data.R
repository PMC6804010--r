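test_that("empty recipes give a constant background and empty ground truth", {
  m <- gen_ion_map(image_recipe(n_aggregates = 0, noise_sd = 0))
  expect_equal(nrow(m$ground_truth), 0)
  expect_length(unique(as.vector(m$image$data)), 1)
  expect_equal(dim(m$image$data), c(256, 256))       # 100 um at 2.56 px/um
})

test_that("ion maps are bit-identical under a fixed seed", {
  r <- image_recipe(n_aggregates = 20, seed = 5)
  a <- gen_ion_map(r); b <- gen_ion_map(r)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("every planted disc lies inside the field", {
  for (pat in c("random", "clustered", "fibril_periodic")) {
    gt <- gen_ion_map(image_recipe(pattern = pat, n_aggregates = 40,
                                   seed = 3))$ground_truth
    expect_true(all(gt$center_x_um - gt$radius_um >= 0))
    expect_true(all(gt$center_x_um + gt$radius_um <= 100))
    expect_true(all(gt$center_y_um - gt$radius_um >= 0))
    expect_true(all(gt$center_y_um + gt$radius_um <= 100))
  }
})

test_that("infeasible packing raises an overlap-placement error", {
  r <- image_recipe(field_size_um = 20, n_aggregates = 200,
                    aggregate_radius_um = c(2, 0.1), seed = 1)
  expect_error(gen_ion_map(r), "overlap placement")
})

test_that("noise-free planted maps segment back to the planted count", {
  for (s in 1:5) {
    r <- image_recipe(n_aggregates = 5 + 3 * s, noise_sd = 0,
                      aggregate_radius_um = c(1.5, 0.2), seed = s)
    m <- gen_ion_map(r)
    ps <- label_particles(binarize(m$image))
    expect_equal(ps$count, nrow(m$ground_truth))
  }
})

test_that("fibril-periodic maps carry the requested spatial period (FFT oracle)", {
  r <- image_recipe(pattern = "fibril_periodic", n_aggregates = 250,
                    noise_sd = 0, aggregate_radius_um = c(0.5, 0.05),
                    ridge_period_um = 4, seed = 11)
  m <- gen_ion_map(r)
  prof <- rowMeans(m$image$data)          # ridges run across rows at angle 0
  prof <- prof - mean(prof)
  a <- Mod(fft(prof))^2
  a[1] <- 0
  k <- which.max(a[1:(length(prof) / 2)]) - 1
  period_um <- (length(prof) / k) / r$pixels_per_um
  expect_lt(abs(period_um - 4) / 4, 0.10)
})

test_that("co-location pairs hit the requested site coverage", {
  base <- function(f, seed) image_recipe(
    n_aggregates = 25, noise_sd = 0, aggregate_radius_um = c(2.5, 0.3),
    coloc_target = list(channel = "OH", coverage_fraction = f), seed = seed)
  ## threshold at the fg/bg midpoint: the f = 0 ion image is pure background
  measure <- function(cp)
    coverage_fraction(binarize(cp$ion, 115), binarize(cp$sites, 115))$coverage_pct
  expect_equal(measure(gen_coloc_pair(base(0, 2))), 0)
  expect_equal(measure(gen_coloc_pair(base(1, 2))), 100)
  got <- measure(gen_coloc_pair(base(0.2208, 3)))
  expect_lt(abs(got - 22.08), 2)                     # within 2 percentage points
  expect_error(image_recipe(coloc_target = list(coverage_fraction = 1.5)),
               "\\[0, 1\\]")
})

test_that("treatment suite plants the reference Li+ ordering and is deterministic", {
  suite <- gen_treatment_suite(seed = 7)
  counts <- vapply(suite$ground_truth, function(tt) nrow(tt$Li), integer(1))
  expect_equal(unname(counts[c("Control", "EtOH_DMSO_AO", "SteamExplosion",
                               "Microwave_H2SO4", "NaOH")]),
               c(353L, 320L, 88L, 63L, 16L))
  seg <- vapply(suite$images, function(ch)
    label_particles(binarize(ch$Li))$count, integer(1))
  expect_true(seg["Control"] > seg["EtOH_DMSO_AO"])
  expect_true(seg["EtOH_DMSO_AO"] > seg["SteamExplosion"])
  expect_true(seg["SteamExplosion"] > seg["Microwave_H2SO4"])
  expect_true(seg["Microwave_H2SO4"] > seg["NaOH"])
  suite2 <- gen_treatment_suite(seed = 7)
  expect_identical(suite$images$NaOH$Li$data, suite2$images$NaOH$Li$data)
  expect_identical(suite$images$Control$matrix$data,
                   suite2$images$Control$matrix$data)
  expect_gte(length(suite$images[[1]]), 8)
  expect_equal(suite$discriminating_group, "Li")
})

test_that("saccharification generator reproduces fold effects exactly (noise-free)", {
  rec <- default_curve_recipes(noise_sd = 0)
  tab <- gen_saccharification(rec, seed = 1)
  at10 <- function(trt) tab$rs_true[tab$treatment == trt & tab$time_h == 10][1]
  expect_equal(at10("NaOH") / at10("Control"), 2.04, tolerance = 1e-9)
  expect_equal(at10("SteamExplosion") / at10("Control"), 1.74, tolerance = 1e-9)
  expect_equal(at10("EtOH_DMSO_AO") / at10("Control"), 0.9, tolerance = 1e-9)
  ## decay curves attain their noise-free maximum at (or before) 10 h
  ctrl <- tab[tab$treatment == "Control" & tab$replicate == 1, ]
  expect_lte(ctrl$time_h[which.max(ctrl$rs_true)], 10)
  ## non-increasing beyond 10 h
  late <- ctrl[ctrl$time_h >= 10, ]
  expect_true(all(diff(late$rs_true) <= 1e-12))
  expect_error(gen_saccharification(list(Control = curve_recipe(2))),
               "fold_vs_control = 1")
  expect_error(curve_recipe(times_h = c(0, 50)), "\\[0, 48\\]")
})

test_that("suite writes standard TIFF + CSV artifacts", {
  dir <- withr::local_tempdir()
  suite <- gen_treatment_suite(seed = 3)
  write_treatment_suite(suite, dir)
  f <- file.path(dir, "NaOH__Li.tif")
  expect_true(file.exists(f))
  back <- read_chem_image(f)
  expect_identical(back$data, suite$images$NaOH$Li$data)
  gt <- read.csv(file.path(dir, "NaOH__Li__truth.csv"))
  expect_named(gt, c("center_x_um", "center_y_um", "radius_um"))
})
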