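test_that("noiseless PDW equals the exact compartment mixture", {
  maps <- small_maps()
  truth <- small_truth()
  pdw <- simulate_pdw(maps, truth, bias_amplitude = 0, noise_sd = 0)
  pd <- truth$proton_density
  oracle <- maps$p_gm * pd[["gm"]] + maps$p_wm * pd[["wm"]] +
    maps$p_csf * pd[["csf"]]
  expect_lt(max(abs(pdw - oracle)), 1e-12 * max(oracle))
  expect_error(simulate_pdw(maps, truth, noise_sd = -1), "non-negative")
})

test_that("PDW noise level and seeding behave as specified", {
  maps <- small_maps()
  truth <- small_truth()
  a <- simulate_pdw(maps, truth, noise_sd = 0.05, seed = 21)
  b <- simulate_pdw(maps, truth, noise_sd = 0.05, seed = 21)
  expect_identical(as.vector(a), as.vector(b))       # bit-identical
  bg <- (maps$p_gm + maps$p_wm + maps$p_csf) == 0
  expect_gt(sum(bg), 1e4)
  expect_equal(sd(a[bg]), 0.05, tolerance = 0.1)     # +-10% at >=1e4 voxels
  # bias field has mean ~1 and the requested amplitude scale
  c <- simulate_pdw(maps, truth, bias_amplitude = 0.1, noise_sd = 0, seed = 3)
  f <- attr(c, "bias_field")
  expect_lt(abs(mean(f) - 1), 0.05)
  expect_gt(max(abs(f - 1)), 0.05)
})

test_that("MGE forward model follows the exact multi-echo decay", {
  grid <- small_grid(c(16, 16, 16), 0.5)
  # single-compartment voxel block: pure GM with T2* = 30 ms
  p1 <- array(0, grid$dims); p1[8, 8, 8] <- 1
  p0 <- array(0, grid$dims)
  maps <- tissue_prob_maps(grid, p_gm = p1, p_wm = p0, p_csf = p0)
  truth <- compartment_truth(t2star = c(gm = 30, wm = 25, csf = 80),
                             volumes = c(gm = 1, wm = 1, csf = 1))
  acq <- acquisition_protocol()
  mge <- simulate_mge(maps, truth, acq, noise_sd = 0)
  sig <- mge[8, 8, 8, ]
  oracle <- truth$proton_density[["gm"]] * exp(-acq$echo_times / 30)
  expect_equal(sig, oracle, tolerance = 1e-12)
  # two-compartment voxel: hand-computed weighted sum
  p_gm2 <- array(0, grid$dims); p_gm2[4, 4, 4] <- 0.6
  p_csf2 <- array(0, grid$dims); p_csf2[4, 4, 4] <- 0.4
  maps2 <- tissue_prob_maps(grid, p_gm = p_gm2, p_wm = p0, p_csf = p_csf2)
  mge2 <- simulate_mge(maps2, truth, acq, noise_sd = 0)
  te5 <- acq$echo_times[5]
  hand <- 0.6 * truth$proton_density[["gm"]] * exp(-te5 / 30) +
    0.4 * truth$proton_density[["csf"]] * exp(-te5 / 80)
  expect_equal(mge2[4, 4, 4, 5], hand, tolerance = 1e-12)
  expect_error(simulate_mge(maps, truth, acquisition_protocol(c(2, 4))),
               "3 echoes")
})

test_that("DWI forward model reduces to Eq-style closed forms", {
  grid <- small_grid(c(16, 16, 16), 0.5)
  p1 <- array(0, grid$dims); p1[2, 2, 2] <- 1
  p0 <- array(0, grid$dims)
  maps <- tissue_prob_maps(grid, p_gm = p1, p_wm = p0, p_csf = p0)
  prot <- diffusion_protocol()
  # degenerate case: f_IVIM = 0, K = 0 -> pure mono-exponential
  truth <- compartment_truth(diffusion = list(
    gm = ivim_kurtosis_params(1, 0, 1e-2, 6e-4, 0),
    wm = ivim_kurtosis_params(1, 0, 1e-2, 6e-4, 0),
    csf = ivim_kurtosis_params(1, 0, 1e-2, 6e-4, 0)),
    volumes = c(gm = 1, wm = 1, csf = 1))
  dwi <- simulate_dwi(maps, truth, prot, noise_sd = 0)
  v <- dwi[2, 2, 2, ]
  nd <- attr(dwi, "n_directions")
  per_b <- v[seq(1, length(v), by = nd)]
  expect_equal(per_b, exp(-prot$b_values * 6e-4), tolerance = 1e-12)
  # all directions identical without noise
  expect_equal(v[seq(2, length(v), by = nd)], per_b, tolerance = 0)

  # general case matches an independently coded one-line signal evaluation
  pars <- ivim_kurtosis_params(s0 = 900, f_ivim = 0.12, d_star = 8e-3,
                               adc0 = 7e-4, k = 0.8)
  truth2 <- compartment_truth(diffusion = list(gm = pars, wm = pars,
                                               csf = pars),
                              volumes = c(gm = 1, wm = 1, csf = 1))
  dwi2 <- simulate_dwi(maps, truth2, prot, noise_sd = 0)
  b <- prot$b_values
  oracle <- 900 * (0.12 * exp(-b * 8e-3) +
                     0.88 * exp(-b * 7e-4 + (b * 7e-4)^2 * 0.8 / 6))
  expect_equal(dwi2[2, 2, 2, seq(1, length(b) * 3, by = 3)], oracle,
               tolerance = 1e-12)

  # kurtosis upturn: high-b signal above the mono-exponential extrapolation
  # fitted on the mid window
  m <- matrix(oracle, nrow = 1)
  midfit <- fit_adc_range(m, prot, "mid")
  hi <- prot$window_of == "high" & !is.na(prot$window_of)
  extrap <- midfit$s0_map * exp(-b[hi] * midfit$adc_map)
  expect_true(all(oracle[hi] > extrap))

  expect_error(simulate_dwi(maps, truth, prot, noise_model = "poisson"),
               "arg")
  # Rician option runs and is non-negative
  dwir <- simulate_dwi(maps, truth, prot, noise_model = "rician",
                       noise_sd = 0.05, seed = 2)
  expect_true(all(dwir >= 0))
})

test_that("DMSO phantom signal is mono-exponential across the full b-range", {
  prot <- diffusion_protocol()
  tab <- simulate_dmso(prot, adc = 6.8e-4, s0 = 1000, noise_sd = 0)
  # log-signal exactly linear with slope -6.8e-4
  fit <- ols2_oracle(tab$b, log(tab$signal))
  expect_equal(unname(fit["slope"]), -6.8e-4, tolerance = 1e-12)
  expect_equal(exp(unname(fit["intercept"])), 1000, tolerance = 1e-9)
  # closed-form attenuation ratio
  r <- tab$signal[tab$b == 2518] / tab$signal[tab$b == 20]
  expect_equal(r, exp(-2498 * 6.8e-4), tolerance = 1e-12)
  expect_error(simulate_dmso(prot, adc = 0), "positive")
})

test_that("simulators are bit-reproducible for a fixed seed", {
  maps <- small_maps()
  truth <- small_truth()
  acq <- acquisition_protocol()
  prot <- diffusion_protocol(b_values = c(20, 100, 300, 700, 1200, 2500))
  for (fn in list(
    function(s) simulate_mge(maps, truth, acq, noise_sd = 0.02, seed = s),
    function(s) simulate_dwi(maps, truth, prot, noise_sd = 0.02, seed = s),
    function(s) simulate_dmso(prot, 6.8e-4, noise_sd = 2, seed = s)$signal)) {
    expect_identical(fn(33), fn(33))
  }
})
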