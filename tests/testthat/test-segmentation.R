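test_that("isodata threshold solves the intermeans fixed point", {
  ## symmetric two-spike histogram: threshold is the midpoint of the means
  two <- ci(matrix(c(rep(50L, 128), rep(200L, 128)), 16))
  expect_equal(isodata_threshold(two), 125)
  ## binary image: smallest fixed point of the floor intermeans map
  bin <- ci(matrix(c(rep(0L, 100), rep(255L, 100)), 20))
  expect_equal(isodata_threshold(bin), 127)
  expect_equal(iso_oracle(bin$data), 127)
  ## fixed-point property and oracle agreement on random images
  for (s in 1:15) {
    img <- rand_img(s)
    t <- isodata_threshold(img)
    x <- as.vector(img$data)
    mu_lo <- mean(x[x <= t]); mu_hi <- mean(x[x > t])
    expect_equal(t, floor((mu_lo + mu_hi) / 2))
    expect_equal(t, iso_oracle(img$data))
  }
  expect_error(isodata_threshold(ci(matrix(7L, 4, 4))), "degenerate")
})

test_that("binarize extracts the high-intensity phase", {
  img <- ci(matrix(sample(10:255, 64 * 64, TRUE), 64))
  expect_false(any(binarize(img, 255)$mask))
  expect_true(all(binarize(img, min(img$data) - 1)$mask))
  expect_error(binarize(img, 300), "\\[0, 255\\]")
  ## isodata foreground area close to the planted disc area
  r <- image_recipe(n_aggregates = 12, noise_sd = 0,
                    aggregate_radius_um = c(2, 0.2), seed = 4)
  m <- gen_ion_map(r)
  planted <- sum(pi * m$ground_truth$radius_um^2)
  got <- area_um2(m$image, sum(binarize(m$image)$mask))
  expect_lt(abs(got - planted) / planted, 0.05)
})

test_that("particle labeling counts planted discs and satisfies its invariants", {
  empty <- label_particles(mask_map(matrix(FALSE, 8, 8)))
  expect_equal(empty$count, 0)
  expect_equal(empty$total_area_um2, 0)

  r <- image_recipe(n_aggregates = 5, noise_sd = 0,
                    aggregate_radius_um = c(1.5, 0.1), seed = 7)
  m <- gen_ion_map(r)
  ps <- label_particles(binarize(m$image))
  expect_equal(ps$count, 5)
  expect_equal(ps$count, nrow(ps$particles))
  expect_equal(ps$total_area_um2, sum(ps$particles$area_um2), tolerance = 1e-9)
  expect_equal(ps$mean_size_um2, ps$total_area_um2 / ps$count, tolerance = 1e-9)
  ## centroids near planted centres (sorted by x)
  got <- ps$particles[order(ps$particles$centroid_x_um), ]
  want <- m$ground_truth[order(m$ground_truth$center_x_um), ]
  expect_lt(max(abs(got$centroid_x_um - want$center_x_um)), 0.5)
  ## min-size filter removes small particles
  ps2 <- label_particles(binarize(m$image), min_size_um2 = 1e4)
  expect_equal(ps2$count, 0)
})

test_that("particle counts are invariant to rotation and translation", {
  r <- image_recipe(n_aggregates = 15, noise_sd = 0,
                    aggregate_radius_um = c(1.2, 0.2), seed = 9)
  m <- gen_ion_map(r)
  thr <- isodata_threshold(m$image)
  count_of <- function(mat) {
    img <- chem_image(mat, m$image$pixel_size_um)
    label_particles(binarize(img, thr))$count
  }
  base <- count_of(m$image$data)
  rot90 <- t(m$image$data)[, rev(seq_len(nrow(m$image$data)))]
  expect_equal(count_of(rot90), base)
  ## embed the field at two offsets on a larger background
  bg <- min(m$image$data)
  canvas <- function(dr, dc) {
    cv <- matrix(bg, 300, 300)
    cv[dr + seq_len(256), dc + seq_len(256)] <- m$image$data
    cv
  }
  expect_equal(count_of(canvas(1, 1)), base)
  expect_equal(count_of(canvas(17, 31)), base)
})

test_that("8-connectivity joins diagonal pixels into one particle", {
  mask <- matrix(FALSE, 6, 6)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE            # touch only diagonally
  expect_equal(label_particles(mask_map(mask))$count, 1)
  mask[5, 2] <- TRUE                                # separated pixel
  expect_equal(label_particles(mask_map(mask))$count, 2)
})

test_that("site coverage and its complement are exact", {
  sites <- matrix(FALSE, 10, 10); sites[3:6, 3:6] <- TRUE
  ion_all <- matrix(TRUE, 10, 10)
  ion_none <- matrix(FALSE, 10, 10); ion_none[9, 9] <- TRUE
  cv <- coverage_fraction(mask_map(ion_all), mask_map(sites))
  expect_equal(cv$coverage_pct, 100)
  expect_equal(coverage_fraction(mask_map(ion_none), mask_map(sites))$coverage_pct, 0)
  half <- matrix(FALSE, 10, 10); half[3:6, 3:4] <- TRUE
  ch <- coverage_fraction(mask_map(half), mask_map(sites))
  expect_equal(ch$coverage_pct + ch$free_pct, 100)
  expect_equal(ch$coverage_pct, 50)
  expect_error(coverage_fraction(mask_map(ion_all), mask_map(ion_none * FALSE)),
               "empty sites")
  ## reported free area complements to the reported coverage
  expect_equal(coverage_from_free(77.92), 22.08)
})

test_that("co-located site aggregates are counted per component", {
  sites <- matrix(FALSE, 12, 12)
  sites[2:3, 2:3] <- TRUE; sites[2:3, 8:9] <- TRUE
  sites[8:9, 2:3] <- TRUE; sites[8:9, 8:9] <- TRUE   # 4 site blobs
  ion <- matrix(FALSE, 12, 12)
  ion[2, 2] <- TRUE; ion[9, 9] <- TRUE               # touches 2 of them
  expect_equal(colocated_site_fraction(mask_map(ion), mask_map(sites)), 50)
  expect_equal(colocated_site_fraction(mask_map(sites), mask_map(sites)), 100)
  none <- matrix(FALSE, 12, 12); none[6, 6] <- TRUE
  expect_equal(colocated_site_fraction(mask_map(none), mask_map(sites)), 0)
  expect_error(colocated_site_fraction(mask_map(ion), mask_map(none & FALSE)),
               "no site components")
})

test_that("particle tables and binary maps export in the standard layout", {
  r <- image_recipe(n_aggregates = 5, noise_sd = 0,
                    aggregate_radius_um = c(1.5, 0.1), seed = 7)
  bm <- binarize(gen_ion_map(r)$image)
  tab <- particle_table(label_particles(bm))
  expect_named(tab, c("count", "area_um2", "average_size_um2", "mean_intensity"))
  path <- withr::local_tempfile(fileext = ".png")
  write_binary_map(bm, path)
  back <- png::readPNG(path)
  expect_equal(back > 0.5, unname(bm$mask))
})
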