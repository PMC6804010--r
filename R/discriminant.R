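## Mixture discriminant analysis and the surrounding discrimination
## machinery: feature assembly, EM fitting of per-class Gaussian mixtures
## with a shared covariance, seriation of treatments into a similarity
## string, binary neighbor matrices, consensus trees, and jackknife
## (leave-one-column-out) importance.

#' Assemble a standardized feature matrix from per-observation tables
#'
#' Joins ionic particle statistics, surface metrics and coverage statistics
#' on a shared observation key, z-scores every column, records block
#' membership (`ion` / `anat`) and drops zero-variance columns with a
#' warning.
#'
#' @param particle_stats data frame: one row per observation and channel,
#'   columns `obs`, `treatment`, `channel`, plus numeric parameters (e.g.
#'   `count`, `area_um2`, `average_size_um2`, `mean_intensity`). Spread into
#'   `ion__<channel>__<parameter>` columns.
#' @param surface_metrics data frame: one row per observation, columns
#'   `obs`, `treatment`, plus numeric parameters; becomes the
#'   `anat__<parameter>` block. Optional (`NULL` to skip).
#' @param coverage_stats like `surface_metrics` but joined into the ionic
#'   block as `ion__<parameter>`. Optional.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, observations x parameters, z-scored), `treatment` (factor),
#'   `blocks` (named character vector `"ion"`/`"anat"` per column), `obs`,
#'   and `scaling` (per-column centre/sd).
#' @export
assemble_features <- function(particle_stats, surface_metrics = NULL,
                              coverage_stats = NULL) {
  stopifnot(all(c("obs", "treatment", "channel") %in% names(particle_stats)))
  num_cols <- function(df, drop) names(df)[vapply(df, is.numeric, logical(1)) &
                                             !names(df) %in% drop]
  obs_tab <- unique(particle_stats[, c("obs", "treatment")])
  if (anyDuplicated(obs_tab$obs)) stop("observation ids must map to one treatment")
  obs_tab <- obs_tab[order(obs_tab$obs), ]
  wide <- data.frame(obs = obs_tab$obs)
  for (ch in sort(unique(particle_stats$channel))) {
    sub <- particle_stats[particle_stats$channel == ch, ]
    if (!setequal(sub$obs, obs_tab$obs))
      stop("channel ", ch, " is missing observations")
    sub <- sub[match(obs_tab$obs, sub$obs), ]
    for (p in num_cols(sub, c("obs")))
      wide[[paste0("ion__", ch, "__", p)]] <- sub[[p]]
  }
  add_block <- function(wide, df, prefix) {
    if (is.null(df)) return(wide)
    stopifnot(all(c("obs") %in% names(df)))
    if (!setequal(df$obs, obs_tab$obs)) stop(prefix, " block is missing observations")
    df <- df[match(obs_tab$obs, df$obs), ]
    for (p in num_cols(df, c("obs")))
      wide[[paste0(prefix, "__", p)]] <- df[[p]]
    wide
  }
  wide <- add_block(wide, coverage_stats, "ion")
  wide <- add_block(wide, surface_metrics, "anat")
  x <- as.matrix(wide[, -1, drop = FALSE])
  rownames(x) <- wide$obs
  if (anyNA(x)) stop("missing values after assembly")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  x <- scale(x, center = ctr, scale = sds)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  blocks <- ifelse(startsWith(colnames(x), "anat__"), "anat", "ion")
  names(blocks) <- colnames(x)
  structure(
    list(x = x, treatment = factor(obs_tab$treatment), obs = obs_tab$obs,
         blocks = blocks, scaling = list(center = ctr, sd = sds)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d observations x %d parameters (%d ionic, %d anatomical), %d treatments\n",
              nrow(x$x), ncol(x$x), sum(x$blocks == "ion"),
              sum(x$blocks == "anat"), nlevels(x$treatment)))
  invisible(x)
}

## k-means++ seeding: spread R initial centres over the rows of x.
kmeanspp_centers <- function(x, r) {
  n <- nrow(x)
  centers <- matrix(NA_real_, r, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (r > 1) {
    for (j in 2:r) {
      d2 <- apply(x, 1, function(row)
        min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - row)^2)))
      if (sum(d2) == 0) centers[j, ] <- x[sample.int(n, 1), ]
      else centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

## log density of rows of x under N(mu, Sigma) given the upper Cholesky
## factor R of Sigma.
ldmvnorm_chol <- function(x, mu, chol_r) {
  z <- backsolve(chol_r, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_r))) - 0.5 * ncol(x) * log(2 * pi)
}

## Cholesky with escalating ridge; returns list(R, ridge).
chol_ridge <- function(sigma, eps0) {
  ridge <- 0
  for (i in 0:8) {
    r <- tryCatch(chol(sigma + diag(ridge, nrow(sigma))), error = function(e) NULL)
    if (!is.null(r) && all(diag(r) > sqrt(.Machine$double.eps)))
      return(list(R = r, ridge = ridge))
    ridge <- if (ridge == 0) eps0 else ridge * 10
  }
  stop("covariance could not be regularized")
}

#' Fit a mixture discriminant analysis model
#'
#' Each class density is a Gaussian mixture with `n_subclasses` components;
#' all subclasses of all classes share one covariance matrix. The model is
#' fitted by EM over the latent subclass labels (class labels are observed),
#' initialized by k-means++ seeding under the given seed, so fits are
#' deterministic. A singular shared covariance is ridge-regularized with
#' `eps = 1e-6 * trace(Sigma) / p`, escalating tenfold until Cholesky
#' succeeds; the applied ridge is recorded. With `n_subclasses = 1` the
#' model reduces exactly to linear discriminant analysis.
#'
#' @param features a [assemble_features()] result, or a numeric matrix.
#' @param labels class labels (required when `features` is a matrix;
#'   otherwise taken from the feature matrix treatments).
#' @param n_subclasses mixture components per class (default 3). Classes
#'   with fewer observations get one subclass per observation at most.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` (default 1e-8) or after `max_iter` (default 500)
#'   iterations.
#' @param seed integer seed for the k-means++ initialization.
#' @return An object of class `mda_model`: per-class subclass weights and
#'   means, shared covariance (and its Cholesky factor), class priors, the
#'   log-likelihood trace and the ridge applied (0 when none).
#' @export
mda_fit <- function(features, labels = NULL, n_subclasses = 3,
                    max_iter = 500, tol = 1e-8, seed = 1) {
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    labels <- labels %||% features$treatment
  } else x <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (nrow(x) != length(labels)) stop("labels must match rows of features")
  classes <- levels(labels)
  k <- length(classes)
  n <- nrow(x); p <- ncol(x)
  rc <- pmin(n_subclasses, as.integer(table(labels)[classes]))
  if (n < sum(rc)) stop("need at least as many rows as total subclasses")
  if (any(table(labels) < 1)) stop("degenerate class with no observations")

  ## initial hard responsibilities from k-means++ seeding within each class
  resp <- vector("list", k)
  means <- vector("list", k)
  weights <- vector("list", k)
  with_split_seed(seed, "mda_fit/init", {
    for (ci in seq_len(k)) {
      xi <- x[labels == classes[ci], , drop = FALSE]
      ctr <- kmeanspp_centers(xi, rc[ci])
      d2 <- vapply(seq_len(rc[ci]),
                   function(j) colSums((t(xi) - ctr[j, ])^2), numeric(nrow(xi)))
      d2 <- matrix(d2, nrow(xi), rc[ci])
      hard <- max.col(-d2, ties.method = "first")
      r <- matrix(0, nrow(xi), rc[ci])
      r[cbind(seq_len(nrow(xi)), hard)] <- 1
      resp[[ci]] <- r
    }
  })

  eps0 <- NULL
  loglik <- numeric(0)
  ridge_used <- 0
  cholR <- NULL
  for (iter in seq_len(max_iter + 1L)) {
    ## M-step: weights, means, shared covariance
    sigma <- matrix(0, p, p)
    for (ci in seq_len(k)) {
      xi <- x[labels == classes[ci], , drop = FALSE]
      r <- resp[[ci]]
      nk <- colSums(r)
      nk[nk == 0] <- .Machine$double.eps
      weights[[ci]] <- nk / nrow(xi)
      mu <- t(r) %*% xi / nk
      means[[ci]] <- mu
      for (j in seq_len(ncol(r))) {
        d <- sweep(xi, 2, mu[j, ])
        sigma <- sigma + t(d * r[, j]) %*% d
      }
    }
    sigma <- sigma / n
    if (is.null(eps0)) eps0 <- 1e-6 * sum(diag(sigma)) / p
    cr <- chol_ridge(sigma, eps0)
    cholR <- cr$R
    ridge_used <- max(ridge_used, cr$ridge)

    ## E-step: subclass responsibilities within the observed class,
    ## and the observed-data log-likelihood
    ll <- 0
    new_resp <- resp
    for (ci in seq_len(k)) {
      xi <- x[labels == classes[ci], , drop = FALSE]
      lg <- vapply(seq_len(rc[ci]), function(j)
        log(weights[[ci]][j]) + ldmvnorm_chol(xi, means[[ci]][j, ], cholR),
        numeric(nrow(xi)))
      lg <- matrix(lg, nrow(xi), rc[ci])
      m <- apply(lg, 1, max)
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- ll + sum(lse)
      new_resp[[ci]] <- exp(lg - lse)
    }
    loglik <- c(loglik, ll)
    if (length(loglik) > 1 &&
        loglik[length(loglik)] - loglik[length(loglik) - 1] < tol) break
    resp <- new_resp
  }

  names(means) <- names(weights) <- classes
  priors <- as.numeric(table(labels)[classes]) / n
  names(priors) <- classes
  structure(
    list(classes = classes, n_subclasses = rc, weights = weights,
         means = means, sigma = sigma, chol = cholR, priors = priors,
         loglik = loglik, ridge = ridge_used, p = p,
         feature_names = colnames(x)),
    class = "mda_model")
}

#' @export
print.mda_model <- function(x, ...) {
  cat(sprintf("<mda_model> %d classes, subclasses (%s), %d features, logLik %.4f (%d EM iterations)%s\n",
              length(x$classes), paste(x$n_subclasses, collapse = ","), x$p,
              tail(x$loglik, 1), length(x$loglik),
              if (x$ridge > 0) sprintf(", ridge %.3g", x$ridge) else ""))
  invisible(x)
}

#' Posterior class probabilities and assignments from an MDA model
#'
#' @param object a fitted [mda_fit()] model.
#' @param newdata numeric matrix (or [assemble_features()] result) with the
#'   model's feature columns.
#' @param ... unused.
#' @return List with `class` (factor of assignments) and `posterior`
#'   (matrix of class probabilities).
#' @export
predict.mda_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  k <- length(object$classes)
  lg <- vapply(seq_len(k), function(ci) {
    lj <- vapply(seq_len(object$n_subclasses[ci]), function(j)
      log(object$weights[[ci]][j]) +
        ldmvnorm_chol(x, object$means[[ci]][j, ], object$chol),
      numeric(nrow(x)))
    lj <- matrix(lj, nrow(x))
    m <- apply(lj, 1, max)
    log(object$priors[ci]) + m + log(rowSums(exp(lj - m)))
  }, numeric(nrow(x)))
  lg <- matrix(lg, nrow(x), k)
  m <- apply(lg, 1, max)
  post <- exp(lg - m)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  cls <- factor(object$classes[max.col(post, ties.method = "first")],
                levels = object$classes)
  list(class = cls, posterior = post)
}

## Training accuracy of a fitted model on its own data.
mda_accuracy <- function(model, x, labels) {
  mean(predict(model, x)$class == labels)
}

## Class centroids (subclass-weight-weighted means) in whitened discriminant
## coordinates: whiten by the shared covariance, then rotate onto the
## principal axes of the centroid scatter.
discriminant_coords <- function(model) {
  cents <- t(vapply(model$classes, function(cl)
    colSums(model$means[[cl]] * model$weights[[cl]]), numeric(model$p)))
  zw <- t(backsolve(model$chol, t(cents), transpose = TRUE))
  zc <- sweep(zw, 2, colMeans(zw))
  pc <- svd(zc)
  coords <- zc %*% pc$v
  rownames(coords) <- model$classes
  coords
}

## Permutation test for separation of two label groups: statistic is the
## training accuracy of the nearest-centroid rule (refit under each
## permutation). Distribution-free and reproducible under the seed.
permutation_separation_test <- function(x, lab, n_perm = 999, seed = 1) {
  lab <- factor(lab)
  stopifnot(nlevels(lab) == 2)
  acc <- function(l) {
    m1 <- colMeans(x[l == levels(lab)[1], , drop = FALSE])
    m2 <- colMeans(x[l == levels(lab)[2], , drop = FALSE])
    d1 <- colSums((t(x) - m1)^2)
    d2 <- colSums((t(x) - m2)^2)
    pred <- ifelse(d1 <= d2, levels(lab)[1], levels(lab)[2])
    mean(pred == l)
  }
  obs <- acc(lab)
  with_split_seed(seed, "perm_test", {
    hits <- 0L
    for (b in seq_len(n_perm))
      if (acc(sample(lab)) >= obs) hits <- hits + 1L
    (1 + hits) / (n_perm + 1)
  })
}

#' Discriminate treatments: similarity string, binary neighbor matrix, groups
#'
#' Class centroids are projected into the model's discriminant space and
#' seriated along the first discriminant coordinate (ties broken by the
#' second), producing a string of treatment names in which neighbors are
#' more similar than distant entries. The string is canonicalized to the
#' lexicographically smaller of itself and its reverse, so a global sign
#' flip of the discriminant axis changes nothing.
#'
#' With `merge_alpha` set (e.g. 0.05), every treatment pair is screened by a
#' permutation test (nearest-centroid accuracy statistic, `n_perm`
#' label permutations); pairs that fail to separate are merged, merged
#' groups occupy consecutive positions in the string, and the binary matrix
#' assigns 1 only between string neighbors in the same merged group -- a
#' treatment separable from everything is isolated with an all-zero row.
#' With `merge_alpha = NULL` (default) all treatments form one group and the
#' plain neighbor rule applies: consecutive string entries get 1.
#'
#' @param model a fitted [mda_fit()].
#' @param features the [assemble_features()] result (or matrix) the model
#'   was fitted on.
#' @param labels treatment labels (defaults to the feature matrix
#'   treatments).
#' @param merge_alpha significance level of the separation gatekeeping, or
#'   `NULL` to skip it.
#' @param n_perm permutations for the gatekeeping test (default 999).
#' @param seed seed for the permutation draws.
#' @return An object of class `discrimination_result`: `string` (character
#'   vector, a permutation of treatment names), `binary_matrix` (treatments
#'   x treatments in 0/1, symmetric, zero diagonal), `groups` (list of
#'   merged treatment groups), `accuracy` (training classification rate),
#'   `coords` (centroid discriminant coordinates) and `pairwise_p` (matrix,
#'   `NA` off-tested cells when gatekeeping is off).
#' @export
discriminate <- function(model, features, labels = NULL, merge_alpha = NULL,
                         n_perm = 999, seed = 1) {
  stopifnot(inherits(model, "mda_model"))
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  labels <- labels %||%
    (if (inherits(features, "feature_matrix")) features$treatment else
      stop("`labels` required when `features` is a matrix"))
  labels <- factor(labels, levels = model$classes)
  coords <- discriminant_coords(model)
  k <- length(model$classes)

  ## order along the first discriminant coordinate, ties by the second
  tie <- if (ncol(coords) >= 2) coords[, 2] else seq_len(k)
  ord <- order(coords[, 1], tie)
  string <- model$classes[ord]

  pairwise_p <- matrix(NA_real_, k, k,
                       dimnames = list(model$classes, model$classes))
  groups <- as.list(model$classes)
  if (!is.null(merge_alpha)) {
    same <- diag(k) == 1
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        sel <- labels %in% model$classes[c(i, j)]
        pv <- permutation_separation_test(
          x[sel, , drop = FALSE], droplevels(labels[sel]), n_perm = n_perm,
          seed = split_seed(seed, paste0("pair/", i, "/", j)))
        pairwise_p[i, j] <- pairwise_p[j, i] <- pv
        if (pv >= merge_alpha) same[i, j] <- same[j, i] <- TRUE
      }
    }
    g <- igraph::components(igraph::graph_from_adjacency_matrix(
      same, mode = "undirected"))$membership
    groups <- split(model$classes, g)
    names(groups) <- NULL
    ## group-level seriation: order groups by mean first coordinate, members
    ## within a group by their own coordinate
    gmean <- vapply(groups, function(m) mean(coords[m, 1]), numeric(1))
    groups <- groups[order(gmean)]
    groups <- lapply(groups, function(m) m[order(coords[m, 1], m)])
    string <- unlist(groups)
  }

  ## canonicalize: lexicographically smaller of string and its reverse
  rev_s <- rev(string)
  if (paste(rev_s, collapse = "\r") < paste(string, collapse = "\r")) {
    string <- rev_s
    groups <- rev(lapply(groups, rev))
  }

  bm <- matrix(0L, k, k, dimnames = list(model$classes, model$classes))
  grp_of <- setNames(rep(seq_along(groups), lengths(groups)), unlist(groups))
  for (i in seq_len(k - 1)) {
    a <- string[i]; b <- string[i + 1]
    if (is.null(merge_alpha) || grp_of[[a]] == grp_of[[b]])
      bm[a, b] <- bm[b, a] <- 1L
  }

  acc <- mda_accuracy(model, x, labels)
  structure(
    list(string = string, binary_matrix = bm, groups = groups,
         accuracy = acc, coords = coords, pairwise_p = pairwise_p,
         merge_alpha = merge_alpha),
    class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("<discrimination_result>\n  string:", paste(x$string, collapse = " - "),
      sprintf("\n  training accuracy: %.3f\n", x$accuracy))
  if (!is.null(x$merge_alpha))
    cat("  groups:", paste(vapply(x$groups, paste, "", collapse = "+"),
                           collapse = " | "), "\n")
  invisible(x)
}

#' Consensus tree from binary neighbor matrices
#'
#' The element-wise mean of the binary matrices is a similarity `S`;
#' `1 - S` is clustered by average-linkage hierarchical clustering. Labels
#' are sorted before clustering so tie-breaking is deterministic.
#'
#' @param binary_matrices list of square 0/1 matrices with identical
#'   dimnames (order may differ).
#' @return List with `hclust` (the tree), `similarity`, `distance` and
#'   `newick` (the tree in Newick format, unit heights).
#' @export
build_tree <- function(binary_matrices) {
  if (!length(binary_matrices)) stop("need at least one binary matrix")
  labs <- sort(rownames(binary_matrices[[1]]))
  if (is.null(labs)) stop("binary matrices must carry dimnames")
  ms <- lapply(binary_matrices, function(m) {
    if (!setequal(rownames(m), labs)) stop("label mismatch across matrices")
    m[labs, labs]
  })
  s <- Reduce(`+`, ms) / length(ms)
  d <- 1 - s
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, similarity = s, distance = d,
       newick = ape::write.tree(phy))
}

#' Jackknife (leave-one-column-out) feature importance
#'
#' For each parameter -- or named parameter group, removed jointly -- the
#' discriminant analysis is re-run without it and the drop in discrimination
#' score is attributed to it:
#' `importance_pct = 100 * (full_score - reduced_score) / full_score`, with
#' the score being the training classification accuracy. A
#' misclassification-count variant (`misclass_increase`) is reported
#' alongside for sensitivity.
#'
#' @param features [assemble_features()] result or numeric matrix.
#' @param labels class labels (defaults to feature-matrix treatments).
#' @param groups optional named list mapping group name to column names;
#'   default: every column is its own group.
#' @param n_subclasses,seed passed to [mda_fit()].
#' @return An object of class `jackknife_report`: data frame with `group`,
#'   `importance_pct`, `misclass_increase`, `rank` (1 = most important),
#'   plus attributes `full_score`.
#' @export
jackknife_importance <- function(features, labels = NULL, groups = NULL,
                                 n_subclasses = 3, seed = 1) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  labels <- labels %||%
    (if (inherits(features, "feature_matrix")) features$treatment else
      stop("`labels` required when `features` is a matrix"))
  labels <- droplevels(factor(labels))
  if (ncol(x) < 2) stop("need at least 2 columns to jackknife")
  if (is.null(groups)) {
    groups <- as.list(colnames(x))
    names(groups) <- colnames(x)
  }
  bad <- vapply(groups, function(g) length(setdiff(g, colnames(x))) > 0, logical(1))
  if (any(bad)) stop("unknown columns in group(s): ",
                     paste(names(groups)[bad], collapse = ", "))
  full_model <- mda_fit(x, labels, n_subclasses = n_subclasses, seed = seed)
  full <- mda_accuracy(full_model, x, labels)
  n <- nrow(x)
  res <- lapply(names(groups), function(g) {
    keep <- setdiff(colnames(x), groups[[g]])
    if (length(keep) < 1)
      stop("removing group '", g, "' leaves no columns")
    xr <- x[, keep, drop = FALSE]
    m <- mda_fit(xr, labels, n_subclasses = n_subclasses, seed = seed)
    sc <- mda_accuracy(m, xr, labels)
    data.frame(group = g,
               importance_pct = 100 * (full - sc) / full,
               misclass_increase = round((full - sc) * n))
  })
  out <- do.call(rbind, res)
  out$rank <- rank(-out$importance_pct, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "full_score") <- full
  class(out) <- c("jackknife_report", "data.frame")
  out
}
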