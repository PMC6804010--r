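make_inputs <- function() {
  obs <- paste0(rep(c("A", "B"), each = 3), "_f", 1:3)
  part <- data.frame(obs = obs, treatment = rep(c("A", "B"), each = 3),
                     channel = "Li",
                     count = c(10, 11, 12, 30, 31, 29))
  surf <- data.frame(obs = obs, entropy = c(1, 1.1, 0.9, 2, 2.2, 1.9))
  list(part = part, surf = surf)
}

test_that("feature assembly joins blocks, standardizes and records membership", {
  inp <- make_inputs()
  fm <- assemble_features(inp$part, inp$surf)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$x), c(6, 2))
  expect_equal(unname(colMeans(fm$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(fm$x, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(fm$blocks), c("ion", "anat"))
  ## constant columns are dropped with a warning
  inp$part$area_um2 <- 5
  expect_warning(fm2 <- assemble_features(inp$part, inp$surf), "zero-variance")
  expect_false(any(grepl("area", colnames(fm2$x))))
  ## missing observations are an error
  expect_error(assemble_features(inp$part[-1, ], inp$surf), "missing")
})

test_that("single-subclass MDA reproduces the LDA oracle", {
  skip_if_not_installed("MASS")
  for (s in 1:5) {
    d <- withr::with_seed(s, {
      lab <- factor(rep(c("a", "b", "c"), each = 12))
      x <- matrix(rnorm(36 * 4), 36, 4)
      x <- x + matrix(rnorm(12, sd = 2)[(as.integer(lab) - 1) * 4 +
                                          rep(1:4, each = 36)], 36, 4)
      list(x = x, lab = lab)
    })
    m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = s)
    expect_identical(as.character(predict(m, d$x)$class),
                     as.character(predict(MASS::lda(d$x, d$lab))$class))
    expect_true(all(diff(m$loglik) >= -1e-8))
  }
})

test_that("EM log-likelihood is monotone and separated classes classify perfectly", {
  d <- withr::with_seed(9, list(
    x = rbind(matrix(rnorm(100, -10), 50, 2), matrix(rnorm(100, 10), 50, 2)),
    lab = factor(rep(c("a", "b"), each = 50))))
  m <- mda_fit(d$x, d$lab, n_subclasses = 3, seed = 4)
  expect_true(all(diff(m$loglik) >= -1e-8))
  expect_equal(mean(predict(m, d$x)$class == d$lab), 1)
  expect_equal(sum(m$weights$a), 1, tolerance = 1e-9)
  expect_true(isSymmetric(m$sigma))
  expect_true(all(eigen(m$sigma + diag(m$ridge, ncol(d$x)),
                        only.values = TRUE)$values > 0))
})

test_that("label-permuted data scores near chance", {
  d <- withr::with_seed(10, list(
    x = matrix(rnorm(400 * 5), 400, 5),
    lab = factor(rep(c("a", "b", "c", "d"), each = 100))))
  m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = 1)
  acc <- mean(predict(m, d$x)$class == d$lab)
  expect_lt(abs(acc - 0.25), 0.10)
})

test_that("singular covariance is ridge-regularized, not fatal", {
  d <- withr::with_seed(3, list(x = matrix(rnorm(8 * 20), 8, 20),
                                lab = factor(rep(c("a", "b"), each = 4))))
  m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = 1)
  expect_gt(m$ridge, 0)
})

test_that("discriminate builds the neighbor string and binary matrix", {
  ## collinear centroids at 0, 1, 10: the close pair must be adjacent
  d <- withr::with_seed(2, {
    lab <- factor(rep(c("A", "B", "C"), each = 10))
    x <- cbind(c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 10)) * 1,
               rnorm(30, 0, 0.1))
    x[, 1] <- x[, 1] / 4   # keep sd moderate
    list(x = x, lab = lab)
  })
  m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = 1)
  res <- discriminate(m, d$x, d$lab)
  expect_setequal(res$string, c("A", "B", "C"))
  iA <- which(res$string == "A"); iB <- which(res$string == "B")
  expect_equal(abs(iA - iB), 1)                     # 0 and 1 are neighbors
  bm <- res$binary_matrix
  expect_true(isSymmetric(bm))
  expect_equal(unname(diag(bm)), c(0, 0, 0))
  expect_true(all(rowSums(bm) <= 2))
  s <- res$string
  expect_equal(bm[s[1], s[2]], 1L)
  expect_equal(bm[s[2], s[3]], 1L)
  expect_equal(bm[s[1], s[3]], 0L)
  ## two treatments: always plain neighbors
  m2 <- mda_fit(d$x[1:20, ], droplevels(d$lab[1:20]), n_subclasses = 1, seed = 1)
  r2 <- discriminate(m2, d$x[1:20, ], droplevels(d$lab[1:20]))
  expect_equal(unname(r2$binary_matrix), matrix(c(0L, 1L, 1L, 0L), 2))
})

test_that("the string is invariant to a global sign flip of the axis", {
  d <- withr::with_seed(6, {
    lab <- factor(rep(c("A", "B", "C", "D"), each = 8))
    x <- cbind(rnorm(32) + c(0, 2, 5, 9)[as.integer(lab)], rnorm(32, 0, 0.5))
    list(x = x, lab = lab)
  })
  m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = 1)
  mflip <- mda_fit(-d$x, d$lab, n_subclasses = 1, seed = 1)
  expect_identical(discriminate(m, d$x, d$lab)$string,
                   discriminate(mflip, -d$x, d$lab)$string)
})

test_that("gatekeeping merges indistinguishable treatments and isolates others", {
  d <- withr::with_seed(13, {
    lab <- factor(rep(c("A", "B", "C"), each = 10))
    mu <- c(A = 0, B = 0, C = 8)                    # A,B identical; C far away
    x <- cbind(rnorm(30) + mu[as.integer(lab)], matrix(rnorm(60), 30, 2))
    list(x = x, lab = lab)
  })
  m <- mda_fit(d$x, d$lab, n_subclasses = 1, seed = 1)
  res <- discriminate(m, d$x, d$lab, merge_alpha = 0.01, n_perm = 499, seed = 1)
  grp <- lapply(res$groups, sort)
  expect_true(list(c("A", "B")) %in% grp || any(vapply(grp, function(g)
    identical(g, c("A", "B")), logical(1))))
  expect_true(any(vapply(grp, identical, logical(1), "C")))
  ## the isolated treatment has an all-zero row
  expect_equal(sum(res$binary_matrix["C", ]), 0)
  expect_equal(res$binary_matrix["A", "B"], 1L)
})

test_that("consensus trees follow the mean binary similarity", {
  labs <- c("A", "B", "C")
  m1 <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  m1["A", "B"] <- m1["B", "A"] <- 1L
  tr <- build_tree(list(m1))
  expect_equal(sort(tr$hclust$labels[-tr$hclust$merge[1, ]]), c("A", "B"))
  ## idempotent under repetition
  tr3 <- build_tree(list(m1, m1, m1))
  expect_equal(tr$hclust$merge, tr3$hclust$merge)
  expect_equal(tr$hclust$height, tr3$hclust$height)
  expect_match(tr$newick, "^\\(")
  ## consistent pairing isolates the odd one out until the final merge
  labs5 <- c("Control", "EtOH", "Micro", "NaOH", "Steam")
  mk <- function(pairs) {
    m <- matrix(0L, 5, 5, dimnames = list(labs5, labs5))
    for (p in pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- 1L
    m
  }
  mats <- list(mk(list(c("Steam", "Micro"), c("Control", "EtOH"))),
               mk(list(c("Steam", "Micro"), c("Control", "EtOH"),
                       c("EtOH", "Micro"))))
  tr5 <- build_tree(mats)
  ct <- stats::cutree(tr5$hclust, k = 3)
  expect_equal(unname(ct["Steam"]), unname(ct["Micro"]))
  expect_equal(unname(ct["Control"]), unname(ct["EtOH"]))
  expect_false(ct["NaOH"] %in% ct[c("Steam", "Micro", "Control", "EtOH")])
  expect_error(build_tree(list()), "at least one")
  bad <- mk(list()); rownames(bad)[1] <- colnames(bad)[1] <- "X"
  expect_error(build_tree(list(m1, bad)), "label mismatch")
})

test_that("jackknife attributes importance to the planted column", {
  ## pure noise: importances stay near zero
  d0 <- withr::with_seed(21, list(
    x = matrix(rnorm(30 * 4), 30, 4,
               dimnames = list(NULL, paste0("n", 1:4))),
    lab = factor(rep(c("a", "b", "c"), each = 10))))
  jk0 <- jackknife_importance(d0$x, d0$lab, n_subclasses = 1, seed = 1)
  expect_true(all(abs(jk0$importance_pct) < 10))
  ## planted column ranks first
  pm <- planted_matrix(31)
  jk <- jackknife_importance(pm$x, pm$labels, n_subclasses = 2, seed = 1)
  expect_equal(jk$group[1], "planted")
  expect_equal(sort(jk$rank), 1:6)
  ## a duplicated planted column makes each copy redundant
  x2 <- cbind(pm$x, planted2 = pm$x[, "planted"] +
                withr::with_seed(1, rnorm(30, 0, 1e-3)))
  jk2 <- jackknife_importance(x2, pm$labels, n_subclasses = 2, seed = 1)
  imp_single <- jk$importance_pct[jk$group == "planted"]
  for (g in c("planted", "planted2"))
    expect_lt(jk2$importance_pct[jk2$group == g], imp_single / 2)
  ## groups are removed jointly
  jk3 <- jackknife_importance(
    x2, pm$labels,
    groups = list(planted_pair = c("planted", "planted2"),
                  rest = paste0("noise", 1:5)),
    n_subclasses = 2, seed = 1)
  expect_equal(jk3$group[1], "planted_pair")
  expect_error(jackknife_importance(x2, pm$labels,
                                    groups = list(all = colnames(x2))),
               "no columns")
})
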