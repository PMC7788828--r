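test_that("Gaussian smoothing honours identity, mass and kernel width", {
  grid <- small_grid(c(33, 33, 25), 0.5)
  set.seed(3)
  img <- array(runif(prod(grid$dims)), grid$dims)
  expect_equal(smooth_map(img, grid, 0), img, ignore_attr = TRUE)
  # constant map unchanged
  cst <- array(2.5, grid$dims)
  expect_equal(max(abs(smooth_map(cst, grid, 0.8) - 2.5)), 0,
               tolerance = 1e-12)
  # interior delta: measured FWHM within half a voxel of the request
  delta <- array(0, grid$dims); delta[17, 17, 13] <- 1
  fw <- 1.5
  sm <- smooth_map(delta, grid, fw)
  prof <- sm[, 17, 13]
  half <- max(prof) / 2
  above <- which(prof >= half)
  measured <- (max(above) - min(above)) * grid$voxel_size[1]
  expect_lt(abs(measured - fw), grid$voxel_size[1] / 2 + 0.26)
  # mass preservation for an interior blob
  blob <- array(0, grid$dims); blob[14:20, 14:20, 10:16] <- 1
  expect_lt(abs(sum(smooth_map(blob, grid, 0.8)) / sum(blob) - 1), 1e-3)
  expect_error(smooth_map(img, grid, -1), "non-negative")
})

test_that("bias correction is near-identity on unbiased input", {
  grid <- small_grid()
  maps <- small_maps(seed = 5, grid = grid)
  truth <- small_truth()
  pdw <- simulate_pdw(maps, truth, bias_amplitude = 0, noise_sd = 0, seed = 2)
  priors <- template_priors(grid, truth, seed = 1)
  bcp <- correct_bias(pdw, grid, priors = priors)
  expect_lt(max(abs(bcp$field[bcp$mask] - 1)), 0.01)
  bc <- correct_bias(pdw, grid)     # unsupervised path: looser bound
  expect_lt(max(abs(bc$field[bc$mask] - 1)), 0.02)
  bad <- pdw; bad[bc$mask][1] <- -1
  expect_error(correct_bias(bad, grid, mask = bc$mask), "non-positive")
})

test_that("a known polynomial field is recovered inside the mask", {
  grid <- small_grid(c(48, 48, 32), 0.46)
  truth <- compartment_truth()
  maps <- build_anatomy(grid, truth, seed = 5)
  priors <- template_priors(grid, truth, seed = 1)
  pdw <- simulate_pdw(maps, truth, bias_amplitude = 0.1, noise_sd = 0.02,
                      seed = 6)
  tf <- attr(pdw, "bias_field")
  bc <- correct_bias(pdw, grid, priors = priors)
  expect_gt(cor(bc$field[bc$mask], tf[bc$mask]), 0.95)
})

test_that("dividing a constant image by its field restores the constant", {
  grid <- small_grid(c(32, 32, 24), 0.5)
  set.seed(9)
  field <- qmribrain:::make_bias_field(grid, 0.1)
  img <- 5 * field
  bc <- correct_bias(img, grid, mask = array(TRUE, grid$dims))
  # evaluate over the central (object) region where the field amplitude is
  # defined; empty corners are polynomial extrapolation
  co <- qmribrain:::grid_coords(grid)
  central <- (co$x / max(abs(co$x)))^2 + (co$y / max(abs(co$y)))^2 +
    (co$z / max(abs(co$z)))^2 < 0.7^2
  inner <- bc$corrected[central]
  expect_lt(max(abs(inner / mean(inner) - 1)), 0.02)
  expect_gt(cor(as.vector(bc$field), as.vector(field)), 0.99)
})

test_that("EM segmentation reproduces separable noiseless labels", {
  grid <- small_grid()
  truth <- small_truth()
  maps <- small_maps(seed = 5, grid = grid)
  pdw <- simulate_pdw(maps, truth, bias_amplitude = 0, noise_sd = 0)
  seg <- segment_tissue(pdw, maps)  # exact priors
  # compare argmax labels on unambiguous voxels
  pure <- pmax(maps$p_gm, maps$p_wm, maps$p_csf,
               1 - maps$p_gm - maps$p_wm - maps$p_csf) > 0.99
  lab_true <- max.col(cbind(as.vector(maps$p_gm), as.vector(maps$p_wm),
                            as.vector(maps$p_csf),
                            1 - as.vector(maps$p_gm + maps$p_wm + maps$p_csf)))
  lab_est <- max.col(cbind(as.vector(seg$p_gm), as.vector(seg$p_wm),
                           as.vector(seg$p_csf), as.vector(seg$p_bg)))
  agree <- mean(lab_est[as.vector(pure)] == lab_true[as.vector(pure)])
  expect_gt(agree, 0.999)
  expect_true(all(diff(seg$loglik) >= -1e-6 * abs(seg$loglik[-1])))
})

test_that("EM with flat priors recovers well-separated class means", {
  # pure four-class intensity mixture (no partial volume): flat priors, so
  # only the intensities drive the fit
  grid <- small_grid(c(24, 24, 20), 0.5)
  set.seed(4)
  mus <- c(bg = 0.02, wm = 0.70, gm = 0.85, csf = 1.00)
  z <- sample(1:4, prod(grid$dims), replace = TRUE,
              prob = c(0.4, 0.25, 0.25, 0.1))
  y <- array(mus[z] + rnorm(length(z), 0, 0.015), grid$dims)
  flat <- tissue_prob_maps(grid,
                           p_gm = array(0.25, grid$dims),
                           p_wm = array(0.25, grid$dims),
                           p_csf = array(0.25, grid$dims))
  seg <- segment_tissue(y, flat, mask = array(TRUE, grid$dims))
  expect_equal(sort(seg$means), sort(unname(mus)), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("partial-volume voxels receive soft posteriors", {
  grid <- small_grid()
  truth <- small_truth()
  maps <- small_maps(seed = 5, grid = grid)
  pdw <- simulate_pdw(maps, truth, noise_sd = 0.01, seed = 8)
  seg <- segment_tissue(pdw, maps)
  # clean two-tissue interface voxels (the mixture model is pairwise)
  shell <- maps$p_gm > 0.3 & maps$p_gm < 0.7 & maps$p_csf > 0.2 &
    (maps$p_gm + maps$p_csf) > 0.95
  expect_gt(sum(shell), 10)
  soft <- seg$p_gm[shell]
  expect_gt(mean(soft > 0.05 & soft < 0.95), 0.5)
})

test_that("probabilistic volume counting is exact and conserves the grid", {
  grid <- voxel_grid(c(32, 32, 20), 0.23)
  zeros <- array(0, grid$dims)
  csf <- zeros; csf[seq_len(1000)] <- 1
  maps <- tissue_prob_maps(grid, p_gm = zeros, p_wm = zeros, p_csf = csf)
  v <- compartment_volumes(maps)
  expect_equal(v$csf, 1000 * 0.23^3)
  expect_identical(v$tiv, v$csf + v$parenchyma)
  # posterior volumes + background = grid volume exactly
  seg <- segment_tissue(array(runif(prod(grid$dims)), grid$dims), maps,
                        mask = array(TRUE, grid$dims), max_iter = 3)
  sv <- compartment_volumes(seg)
  expect_equal(sv$tiv + sv$background, prod(grid$dims) * grid$voxel_volume,
               tolerance = 1e-9)
})
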