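test_that("the penalized spline reproduces polynomial and constant data", {
  tt <- rep(seq(0, 48, by = 4), each = 2)
  lin <- data.frame(time_h = tt, rs_mg_ml = 0.05 * tt + 1)
  fit <- fit_curve(lin)
  expect_lt(max(abs(predict(fit$gam) - lin$rs_mg_ml)), 1e-6)
  const <- data.frame(time_h = tt, rs_mg_ml = 2)
  fc <- fit_curve(const)
  expect_lt(max(abs(fc$grid$fit - 2)), 1e-8)
  expect_error(fit_curve(data.frame(time_h = c(0, 1), rs_mg_ml = c(1, 2))),
               "3 distinct")
})

test_that("smoothed curves track the noise-free saturating truth within 2 SE", {
  ## pointwise 2-SE envelopes of the penalized spline cover the truth at
  ## close to the nominal rate (Bayesian intervals trade a little pointwise
  ## coverage against smoothing bias, so "close" means >= 90% on average)
  rec <- curve_recipe(1.5, FALSE, noise_sd = 0.08, seed = 3)
  cover <- vapply(1:10, function(s) {
    tab <- gen_saccharification(list(Control = curve_recipe(1, FALSE, seed = 1),
                                     X = rec), seed = s)
    xt <- tab[tab$treatment == "X", ]
    fit <- fit_curve(xt)
    truth <- rec$fold_vs_control * rec$vmax * fit$grid$time_h /
      (rec$k + fit$grid$time_h)
    mean(abs(fit$grid$fit - truth) <= 2 * fit$grid$se)
  }, numeric(1))
  expect_gte(mean(cover), 0.90)
  expect_gte(max(cover), 0.95)
})

test_that("curve comparison is exact, symmetric and powered", {
  rc <- curve_recipe(1, FALSE, noise_sd = 0.08, seed = 0)
  a <- gen_saccharification(list(Control = rc), seed = 101)
  ## identical data: F = 0, same
  cc <- compare_curves(a, a)
  expect_equal(cc$F, 0)
  expect_true(cc$same)
  ## a 10-sigma offset is always rejected
  b <- a; b$rs_mg_ml <- b$rs_mg_ml + 10 * 0.08
  cb <- compare_curves(a, b)
  expect_lt(cb$p, 0.05)
  expect_false(cb$same)
  ## symmetry in the arguments
  b2 <- gen_saccharification(list(Control = rc), seed = 102)
  expect_equal(compare_curves(a, b2)$p, compare_curves(b2, a)$p)
  ## non-overlapping supports are an error
  a1 <- a[a$time_h <= 10, ]; a2 <- a[a$time_h > 20, ]
  expect_error(compare_curves(a1, a2), "overlap")
})

test_that("fold change reads the smoothed 10 h ratio", {
  tab <- gen_saccharification(default_curve_recipes(), seed = 42)
  fits <- lapply(split(tab, tab$treatment), fit_curve)
  expect_equal(fold_change(fits$Control, fits$Control), 1)
  expect_lt(abs(fold_change(fits$NaOH, fits$Control) - 2.04), 0.05)
  expect_lt(abs(fold_change(fits$SteamExplosion, fits$Control) - 1.74), 0.05)
  short <- fit_curve(tab[tab$treatment == "NaOH" & tab$time_h <= 8, ])
  expect_error(fold_change(short, fits$Control), "cover")
})

test_that("decay detection follows the post-10 h derivative", {
  tt <- rep(seq(0, 48, by = 2), each = 3)
  up <- data.frame(time_h = tt, rs_mg_ml = 3 * tt / (6 + tt))
  expect_false(detect_decay(fit_curve(up)))
  peaky <- data.frame(time_h = tt,
                      rs_mg_ml = ifelse(tt <= 10, 0.3 * tt, 3 - 0.05 * (tt - 10)))
  expect_true(detect_decay(fit_curve(peaky)))
  expect_error(detect_decay(fit_curve(up), after_h = 47.9), "beyond")
})

test_that("generator decay flags are recovered under noise", {
  rc0 <- default_curve_recipes(noise_sd = 0)
  peak <- max(gen_saccharification(rc0, seed = 1)$rs_true)
  agree <- 0; total <- 0
  for (s in 1:25) {
    rc <- list(Control = curve_recipe(1, TRUE, noise_sd = 0.05 * peak, seed = 1),
               X = curve_recipe(1.5, FALSE, noise_sd = 0.05 * peak, seed = 2))
    tab <- gen_saccharification(rc, seed = s)
    for (trt in names(rc)) {
      total <- total + 1
      got <- detect_decay(fit_curve(tab[tab$treatment == trt, ]))
      if (got == rc[[trt]]$decay_after_10h) agree <- agree + 1
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("curves cluster by the statistically-same relation", {
  rc <- curve_recipe(1, FALSE, noise_sd = 0.05, seed = 0)
  a <- fit_curve(gen_saccharification(list(Control = rc), seed = 7))
  expect_equal(cluster_curves(list(a = a, b = a, c = a))$partition,
               list(c("a", "b", "c")))
  big <- a$points; big$rs_mg_ml <- big$rs_mg_ml + 1
  b <- fit_curve(big)
  part <- cluster_curves(list(a = a, b = b, c = b))$partition
  expect_equal(sort(lengths(part)), c(1, 2))
  expect_true(list("a") %in% part)
  ## five-treatment recipes: the 2.04 curve separates; the 1.74 pair clusters
  tab <- gen_saccharification(default_curve_recipes(), seed = 42)
  fits <- lapply(split(tab, tab$treatment), fit_curve)
  cl <- cluster_curves(fits)
  grp_of <- function(t) which(vapply(cl$partition, function(g) t %in% g,
                                     logical(1)))
  expect_equal(grp_of("SteamExplosion"), grp_of("Microwave_H2SO4"))
  expect_false(grp_of("NaOH") == grp_of("SteamExplosion"))
  expect_false(grp_of("NaOH") == grp_of("Control"))
})

test_that("ion-in-solution tables validate and flag effects", {
  tab <- ion_solution_reference()
  s <- tab$summary
  licl <- s[s$salt == "LiCl" & s$enzyme == "Xylanase", ]
  expect_equal(licl$activity_pct, 130.59)
  expect_equal(licl$effect, "activator")
  nh4f <- s[s$salt == "NH4F" & s$enzyme == "Laccase", ]
  expect_equal(nh4f$activity_pct, 12.34)
  expect_equal(nh4f$effect, "inhibitor")
  ## every salt activates the glycosyl-hydrolases; laccase is inhibited
  expect_true(all(s$effect[s$enzyme == "Laccase"] == "inhibitor"))
  expect_true(all(s$effect[s$enzyme == "Xylanase"] == "activator"))
  ## empty and malformed tables
  empty <- load_ion_effects(data.frame(salt = character(0)))
  expect_equal(nrow(empty$summary), 0)
  expect_error(load_ion_effects(data.frame(salt = c("KCl", "KCl"), X = 1:2)),
               "duplicate")
  expect_error(load_ion_effects(data.frame(salt = "KCl", X = -5)), ">= 0")
})
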