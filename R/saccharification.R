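## Time-dependent release of reducing sugars (RS) during enzymatic
## hydrolysis: synthetic curve generation with stated fold effects, penalized
## spline smoothing, least-squares curve comparison, fold changes at 10 h,
## decay detection and clustering, plus ingestion of the ion-in-solution
## activity table.

#' Recipe for one synthetic saccharification curve
#'
#' Saturating curves (`decay_after_10h = FALSE`) follow a Michaelis-type
#' release `rs0(t) = vmax * t / (k + t)` scaled by `fold_vs_control`.
#' Decaying curves (seen for control and EtOH:DMSO:AO) are smoothly
#' unimodal, `rs(t) = fold * rs0(10) * ((t/10) * exp(1 - t/10))^shape`: the
#' noise-free maximum sits exactly at 10 h, the curve declines beyond it,
#' and at t = 10 h the treatment/control ratio equals `fold_vs_control`
#' exactly for any mixture of shapes.
#'
#' @param fold_vs_control treatment/control ratio of the noise-free curves
#'   at t = 10 h (control recipe: 1.0).
#' @param decay_after_10h logical; decline after 10 h (seen for control and
#'   EtOH:DMSO:AO).
#' @param noise_sd iid Gaussian noise on each measured point, mg/ml
#'   (default 0.08; no noise model is published, this is a convention).
#' @param times_h sampling grid within `[0, 48]` h (default every 2 h).
#' @param n_replicates replicate series (>= 1, default 3).
#' @param vmax,k Michaelis shape of the release (mg/ml and h; defaults 4 and
#'   6, a half-saturation of a few hours as typical for bagasse hydrolysis).
#' @param decay_shape width exponent of the unimodal decay curve
#'   (default 0.5: declines to about a third of the peak by 48 h).
#' @param seed integer seed.
#' @return An object of class `curve_recipe`.
#' @export
curve_recipe <- function(fold_vs_control = 1.0, decay_after_10h = FALSE,
                         noise_sd = 0.08, times_h = seq(0, 48, by = 2),
                         n_replicates = 3, vmax = 4, k = 6,
                         decay_shape = 0.5, seed = 1) {
  if (any(times_h < 0 | times_h > 48)) stop("times must lie within [0, 48] h")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  structure(
    list(fold_vs_control = fold_vs_control,
         decay_after_10h = isTRUE(decay_after_10h), noise_sd = noise_sd,
         times_h = sort(times_h), n_replicates = as.integer(n_replicates),
         vmax = vmax, k = k, decay_shape = decay_shape, seed = as.integer(seed)),
    class = "curve_recipe")
}

## Noise-free mean curve of a recipe at times t.
curve_truth <- function(recipe, t) {
  if (recipe$decay_after_10h) {
    at10 <- recipe$vmax * 10 / (recipe$k + 10)
    u <- pmax(0, t / 10)
    recipe$fold_vs_control * at10 * (u * exp(1 - u))^recipe$decay_shape
  } else {
    recipe$fold_vs_control * recipe$vmax * t / (recipe$k + t)
  }
}

#' Generate saccharification curves for a set of treatments
#'
#' @param recipes named list of [curve_recipe()]s, one per treatment; the
#'   control entry (named `"Control"` or given by `control`) must have
#'   `fold_vs_control = 1`.
#' @param control name of the control recipe (default `"Control"`).
#' @param seed master seed; per-treatment noise derives from it.
#' @return Tidy data frame: `treatment`, `replicate`, `time_h`, `rs_mg_ml`
#'   (negative noisy values truncated at 0), with the noise-free value in
#'   `rs_true`.
#' @export
gen_saccharification <- function(recipes, control = "Control", seed = 1) {
  stopifnot(is.list(recipes), !is.null(names(recipes)))
  if (control %in% names(recipes) &&
      recipes[[control]]$fold_vs_control != 1)
    stop("the control recipe must have fold_vs_control = 1")
  out <- lapply(names(recipes), function(trt) {
    r <- recipes[[trt]]
    truth <- curve_truth(r, r$times_h)
    noise <- with_split_seed(seed + r$seed, paste0("sacch/", trt),
                             matrix(rnorm(length(truth) * r$n_replicates,
                                          0, r$noise_sd),
                                    ncol = r$n_replicates))
    do.call(rbind, lapply(seq_len(r$n_replicates), function(rep)
      data.frame(treatment = trt, replicate = rep, time_h = r$times_h,
                 rs_mg_ml = pmax(0, truth + noise[, rep]),
                 rs_true = truth)))
  })
  do.call(rbind, out)
}

#' Default five-treatment curve recipes
#'
#' Fold effects at 10 h: NaOH 2.04, Steam Explosion and Microwave:H2SO4 both
#' 1.74, EtOH:DMSO:AO 0.9 (the reported "1.1-fold decrease", read as a 0.9
#' ratio), control 1.0; control and EtOH:DMSO:AO decay after 10 h.
#'
#' @param noise_sd,n_replicates,times_h overrides applied to every recipe.
#' @return Named list of [curve_recipe()]s.
#' @export
default_curve_recipes <- function(noise_sd = 0.08, n_replicates = 3,
                                  times_h = seq(0, 48, by = 2)) {
  mk <- function(fold, decay, s)
    curve_recipe(fold_vs_control = fold, decay_after_10h = decay,
                 noise_sd = noise_sd, times_h = times_h,
                 n_replicates = n_replicates, seed = s)
  list(Control = mk(1.0, TRUE, 1),
       EtOH_DMSO_AO = mk(0.9, TRUE, 2),
       SteamExplosion = mk(1.74, FALSE, 3),
       Microwave_H2SO4 = mk(1.74, FALSE, 4),
       NaOH = mk(2.04, FALSE, 5))
}

#' Smooth a saccharification curve with a penalized spline
#'
#' Cubic penalized regression spline (mgcv, `bs = "cr"`), smoothing
#' parameter by generalized cross-validation; fitted values and pointwise
#' standard errors are returned on a uniform grid.
#'
#' @param points data frame with `time_h` and `rs_mg_ml` (replicates as
#'   repeated times), or a generator table filtered to one treatment.
#' @param k spline basis dimension (default 20, capped at the number of
#'   distinct times); generous so that kinked release curves are not
#'   flattened -- GCV still shrinks unneeded wiggliness.
#' @param grid_by grid step for the fitted curve, hours.
#' @return An object of class `sacch_curve`: the mgcv fit plus `grid`
#'   (`time_h`, `fit`, `se`) and the raw points.
#' @export
fit_curve <- function(points, k = 20, grid_by = 0.25) {
  stopifnot(all(c("time_h", "rs_mg_ml") %in% names(points)))
  tt <- points$time_h
  if (length(unique(tt)) < 3) stop("need at least 3 distinct times to smooth")
  k <- min(k, length(unique(tt)))
  fit <- mgcv::gam(rs_mg_ml ~ s(time_h, k = k, bs = "cr"), data = points,
                   method = "GCV.Cp")
  grid <- data.frame(time_h = seq(min(tt), max(tt), by = grid_by))
  pr <- predict(fit, newdata = grid, se.fit = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$se <- as.numeric(pr$se.fit)
  structure(list(gam = fit, grid = grid, points = points,
                 treatment = if ("treatment" %in% names(points))
                   as.character(points$treatment[1]) else NA_character_),
            class = "sacch_curve")
}

#' @export
print.sacch_curve <- function(x, ...) {
  cat(sprintf("<sacch_curve> %s: %d points on [%g, %g] h, edf %.2f\n",
              x$treatment %||% "curve", nrow(x$points), min(x$points$time_h),
              max(x$points$time_h), sum(x$gam$edf)))
  invisible(x)
}

## Evaluate a smoothed curve at arbitrary times.
curve_value <- function(curve, t) {
  as.numeric(predict(curve$gam, newdata = data.frame(time_h = t)))
}

#' Least-squares comparison of two saccharification curves
#'
#' Extra-sum-of-squares F-test between a pooled fit (one mean curve for both
#' data sets) and separate fits, on a shared natural-cubic-spline basis
#' built from the pooled time points. By default the basis is saturated
#' (one degree of freedom per distinct time, capped so residual degrees of
#' freedom remain), which leaves no lack of fit; under the null of a common
#' mean curve and iid Gaussian noise the test is then exact, so its size
#' equals `alpha`. A smaller `df` trades exactness near sharp curve features
#' for power against smooth alternatives.
#'
#' @param a,b [fit_curve()] results, or raw data frames with `time_h`,
#'   `rs_mg_ml`.
#' @param alpha significance level (default 0.05).
#' @param df spline basis dimension of the shared basis; default `NULL` =
#'   saturated (`n_distinct_times - 1`, capped at a quarter of the pooled
#'   observation count).
#' @return List with `F`, `p`, `same` (`p >= alpha`), `df1`, `df2`.
#' @export
compare_curves <- function(a, b, alpha = 0.05, df = NULL) {
  pts <- function(z) if (inherits(z, "sacch_curve")) z$points else z
  pa <- pts(a); pb <- pts(b)
  lo <- max(min(pa$time_h), min(pb$time_h))
  hi <- min(max(pa$time_h), max(pb$time_h))
  if (lo >= hi) stop("curves have no overlapping time support")
  pa <- pa[pa$time_h >= lo & pa$time_h <= hi, ]
  pb <- pb[pb$time_h >= lo & pb$time_h <= hi, ]
  dat <- rbind(
    data.frame(time_h = pa$time_h, rs = pa$rs_mg_ml, curve = "A"),
    data.frame(time_h = pb$time_h, rs = pb$rs_mg_ml, curve = "B"))
  dat$curve <- factor(dat$curve)
  df <- min(df %||% Inf, length(unique(dat$time_h)) - 1,
            max(2, floor(nrow(dat) / 4)))
  basis <- splines::ns(dat$time_h, df = df)
  pooled <- lm(rs ~ basis, data = dat)
  separate <- lm(rs ~ basis * curve, data = dat)
  if (identical(pa$rs_mg_ml, pb$rs_mg_ml) && identical(pa$time_h, pb$time_h))
    return(list(F = 0, p = 1, same = TRUE, df1 = df + 1,
                df2 = nrow(dat) - 2 * (df + 1)))
  av <- anova(pooled, separate)
  f <- av$F[2]; p <- av$`Pr(>F)`[2]
  list(F = f, p = p, same = p >= alpha, df1 = av$Df[2],
       df2 = av$Res.Df[2])
}

#' Fold change of a treatment curve over the control at a time point
#'
#' Ratio of the smoothed (penalized-spline) values at `at_h`, the scale on
#' which 10 h fold effects are reported.
#'
#' @param curve,control [fit_curve()] results covering `at_h`.
#' @param at_h evaluation time (default 10 h).
#' @return The ratio `curve(at_h) / control(at_h)`.
#' @export
fold_change <- function(curve, control, at_h = 10) {
  rng <- function(z) range(z$points$time_h)
  if (at_h < rng(curve)[1] || at_h > rng(curve)[2] ||
      at_h < rng(control)[1] || at_h > rng(control)[2])
    stop("both curves must cover t = ", at_h, " h")
  v0 <- curve_value(control, at_h)
  if (v0 <= 0) stop("control curve is not positive at t = ", at_h, " h")
  curve_value(curve, at_h) / v0
}

#' Detect time-dependent decay after a cutoff
#'
#' `TRUE` when the smoothed derivative is negative over a contiguous span of
#' at least `span_frac` (default 20%) of `(after_h, t_max]`, and the net
#' decline over that span is significantly below zero (one-sided bound at
#' `conf`, from the spline coefficient covariance). The significance
#' requirement keeps noise-induced wiggles on a plateau from being read as
#' decay.
#'
#' @param curve a [fit_curve()] result extending beyond `after_h`.
#' @param after_h cutoff (default 10 h).
#' @param span_frac minimum contiguous negative-derivative span, as a
#'   fraction of the post-cutoff range.
#' @param conf one-sided confidence level for the net-decline test (default
#'   0.95; `conf = 0.5` reduces to the raw sign of the decline).
#' @param k_trend basis dimension of the trend-scale refit used for decay
#'   detection (default 10): a lighter basis than the display smoother, so
#'   high-frequency wiggle does not fragment the negative-derivative span.
#' @return Logical.
#' @export
detect_decay <- function(curve, after_h = 10, span_frac = 0.2, conf = 0.95,
                         k_trend = 10) {
  curve <- fit_curve(curve$points, k = k_trend,
                     grid_by = diff(curve$grid$time_h[1:2]))
  g <- curve$grid
  late <- g$time_h > after_h
  if (sum(late) < 3) stop("smoothed curve does not extend beyond ", after_h, " h")
  tt <- g$time_h[late]; ff <- g$fit[late]
  h <- tt[2] - tt[1]
  neg <- diff(ff) < 0
  r <- rle(neg)
  if (!any(r$values)) return(FALSE)
  spans <- r$lengths * h
  if (max(spans[r$values]) < span_frac * (max(tt) - after_h)) return(FALSE)
  ## net decline over the longest negative-derivative span, with its SE
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  iw <- which(r$values)[which.max(r$lengths[r$values])]
  t1 <- tt[starts[iw]]; t2 <- tt[ends[iw] + 1]
  xp <- mgcv::predict.gam(curve$gam, newdata = data.frame(time_h = c(t1, t2)),
                          type = "lpmatrix")
  dvec <- xp[2, ] - xp[1, ]
  drop <- sum(dvec * stats::coef(curve$gam))
  se <- sqrt(max(0, sum((dvec %*% curve$gam$Vp) * dvec)))
  drop + stats::qnorm(conf) * se < 0
}

#' Cluster saccharification curves by pairwise equality tests
#'
#' All pairs are compared with [compare_curves()]; the partition is the set
#' of connected components of the resulting "statistically same" relation.
#'
#' @param curves named list of [fit_curve()] results (>= 2).
#' @param alpha significance level (default 0.05).
#' @param df shared basis dimension for the comparisons.
#' @return List with `partition` (list of character vectors, deterministic
#'   order), `p_matrix` and `same_matrix`.
#' @export
cluster_curves <- function(curves, alpha = 0.05, df = 8) {
  stopifnot(length(curves) >= 2, !is.null(names(curves)))
  nm <- names(curves)
  k <- length(nm)
  pm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  same <- diag(k) == 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cc <- compare_curves(curves[[i]], curves[[j]], alpha = alpha, df = df)
      pm[i, j] <- pm[j, i] <- cc$p
      same[i, j] <- same[j, i] <- cc$same
    }
  }
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    same, mode = "undirected"))$membership
  partition <- unname(split(nm, comp))
  partition <- partition[order(vapply(partition, min, ""))]
  list(partition = partition, p_matrix = pm, same_matrix = same)
}

#' Load and validate an ion-in-solution enzyme activity table
#'
#' Rows are salts, columns enzyme activities relative to an ion-free control
#' at 100%. Values above 100 flag the salt as an activator of that enzyme,
#' below 100 as an inhibitor.
#'
#' @param path CSV path (first column `salt`), or a data frame.
#' @return An object of class `ion_effect_table`: list with `table` (data
#'   frame) and `summary` (long data frame: `salt`, `enzyme`, `activity_pct`,
#'   `effect` in activator/inhibitor/neutral).
#' @export
load_ion_effects <- function(path) {
  tab <- if (is.data.frame(path)) path else read.csv(path, check.names = FALSE)
  if (nrow(tab) > 0) {
    if (!("salt" %in% names(tab))) names(tab)[1] <- "salt"
    if (anyDuplicated(tab$salt)) stop("duplicate salt rows")
    vals <- tab[, setdiff(names(tab), "salt"), drop = FALSE]
    if (any(vals < 0)) stop("activities must be >= 0")
    if (any(tolower(tab$salt) == "control"))
      stop("control row must be absent (implicit 100%)")
    summary <- do.call(rbind, lapply(setdiff(names(tab), "salt"), function(e)
      data.frame(salt = tab$salt, enzyme = e, activity_pct = tab[[e]],
                 effect = ifelse(tab[[e]] > 100, "activator",
                                 ifelse(tab[[e]] < 100, "inhibitor", "neutral")))))
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(salt = character(0), enzyme = character(0),
                          activity_pct = numeric(0), effect = character(0))
  }
  structure(list(table = tab, summary = summary), class = "ion_effect_table")
}

#' @export
print.ion_effect_table <- function(x, ...) {
  cat(sprintf("<ion_effect_table> %d salts x %d enzymes; %d activator and %d inhibitor flags\n",
              nrow(x$table), max(0, ncol(x$table) - 1),
              sum(x$summary$effect == "activator"),
              sum(x$summary$effect == "inhibitor")))
  invisible(x)
}
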