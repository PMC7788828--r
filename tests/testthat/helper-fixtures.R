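# Shared fixtures: small grids and phantoms built in code at test time.

small_grid <- function(dims = c(32, 32, 24), voxel = 0.5) {
  voxel_grid(dims, voxel)
}

# A desk-scale truth whose volumes fit comfortably on small_grid().
small_truth <- function(...) {
  compartment_truth(volumes = c(gm = 500, wm = 260, csf = 80), ...)
}

small_maps <- function(seed = 3, grid = small_grid(), truth = small_truth()) {
  build_anatomy(grid, truth, seed = seed)
}

# Smoothed template priors for segmentation tests.
template_priors <- function(grid, truth, seed = 1, fwhm = 0.9) {
  tmpl <- build_anatomy(grid, truth, seed = seed)
  tissue_prob_maps(grid,
                   p_gm = smooth_map(tmpl$p_gm, grid, fwhm),
                   p_wm = smooth_map(tmpl$p_wm, grid, fwhm),
                   p_csf = smooth_map(tmpl$p_csf, grid, fwhm))
}

# Independent two-coefficient OLS oracle (normal equations by hand).
ols2_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p, q_level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k / m * q_level) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

# Closed-form paired t oracle.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}
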