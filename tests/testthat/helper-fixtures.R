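# Shared fixtures, built in code at test time.

# chem_image from an integer matrix, 1 um/px unless stated
ci <- function(m, px = 1) chem_image(m, px)

# deterministic pseudo-random 8-bit image
rand_img <- function(seed, n = 64, px = 1) {
  withr::with_seed(seed, ci(matrix(sample(0:255, n * n, TRUE), n), px))
}

# exhaustive smallest-fixed-point IsoData oracle (floor intermeans),
# independent of the package's iterative implementation
iso_oracle <- function(x) {
  h <- tabulate(as.integer(x) + 1L, nbins = 256)
  lev <- 0:255
  cs_n <- cumsum(h); cs_s <- cumsum(h * lev)
  n <- cs_n[256]; s <- cs_s[256]
  for (t in 0:254) {
    n_lo <- cs_n[t + 1]
    if (n_lo == 0 || n_lo == n) next
    mu_lo <- cs_s[t + 1] / n_lo
    mu_hi <- (s - cs_s[t + 1]) / (n - n_lo)
    if (t == floor((mu_lo + mu_hi) / 2)) return(t)
  }
  NA_integer_
}

# binary map over an explicit mask (for coverage fixtures)
mask_map <- function(mask, px = 1) {
  img <- chem_image(matrix(ifelse(mask, 200L, 0L), nrow(mask)), px)
  binarize(img, threshold = 100)
}

# well-separated 3-class feature matrix with one informative column
planted_matrix <- function(seed, n_per = 10, p_noise = 5, sep = 2) {
  withr::with_seed(seed, {
    lab <- factor(rep(c("a", "b", "c"), each = n_per))
    x <- matrix(rnorm(3 * n_per * (p_noise + 1)), 3 * n_per, p_noise + 1)
    x[, 1] <- x[, 1] + c(-sep, 0, sep)[as.integer(lab)]
    colnames(x) <- c("planted", paste0("noise", seq_len(p_noise)))
    list(x = x, labels = lab)
  })
}
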