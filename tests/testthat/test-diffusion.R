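test_that("geometric-mean direction combination is correct", {
  prot <- diffusion_protocol(b_values = c(20, 100, 300))
  # one voxel, 3 b-values x 3 directions (direction fastest)
  m <- matrix(c(1, 4, 16,  2, 2, 2,  9, 3, 1), nrow = 1)
  out <- combine_directions(m, prot)
  expect_equal(as.vector(out), c(4, 2, 3))
  # zero in any direction -> zero
  m0 <- matrix(c(0, 4, 16,  2, 2, 2,  9, 3, 1), nrow = 1)
  expect_equal(combine_directions(m0, prot)[1, 1], 0)
  # single-direction protocol: identity
  prot1 <- diffusion_protocol(b_values = c(20, 100, 300),
                              directions = matrix(c(1, 0, 0), ncol = 1))
  expect_equal(as.vector(combine_directions(m[, c(1, 4, 7), drop = FALSE],
                                            prot1)),
               c(1, 2, 9))
  expect_error(combine_directions(m[, 1:8, drop = FALSE], prot),
               "protocol defines")
})

test_that("direction combining reduces noise variance", {
  prot <- diffusion_protocol(b_values = c(20, 100, 300))
  set.seed(42)
  n <- 1e4
  truth <- 100
  noisy <- matrix(truth + rnorm(n * 9, 0, 5), nrow = n)
  comb <- combine_directions(noisy, prot)
  expect_lt(var(comb[, 1]), var(noisy[, 1]))
  expect_equal(var(comb[, 1]), var(noisy[, 1]) / 3, tolerance = 0.15)
})

test_that("range ADC fits recover a mono-exponential in every window", {
  prot <- diffusion_protocol()
  tab <- simulate_dmso(prot, adc = 6.8e-4, s0 = 1000, noise_sd = 0)
  m <- matrix(tab$signal, nrow = 1)
  for (w in c("low", "mid", "high")) {
    fit <- fit_adc_range(m, prot, w)
    expect_equal(fit$adc_map[1], 6.8e-4, tolerance = 1e-6)
    expect_equal(fit$s0_map[1], 1000, tolerance = 1e-6)
  }
  narrow <- diffusion_protocol(b_values = c(20, 100, 300, 700),
                               windows = list(low = c(20, 150),
                                              mid = c(200, 800),
                                              high = c(1000, 2518)))
  expect_error(fit_adc_range(matrix(1:4, nrow = 1), narrow, "low"),
               "fewer than 3")
})

test_that("range ADC fit matches a hand-rolled normal-equations oracle", {
  prot <- diffusion_protocol()
  set.seed(8)
  n <- 100
  pars <- cbind(s0 = runif(n, 500, 1500), adc = runif(n, 3e-4, 1.2e-3))
  b <- prot$b_values
  m <- t(apply(pars, 1, function(p)
    p[1] * exp(-b * p[2]) * exp(rnorm(length(b), 0, 0.01))))
  for (w in c("low", "mid", "high")) {
    fit <- fit_adc_range(m, prot, w)
    inw <- prot$window_of == w & !is.na(prot$window_of)
    for (v in c(1, 17, 50, 100)) {
      o <- ols2_oracle(b[inw], log(m[v, inw]))
      expect_equal(fit$adc_map[v], -unname(o["slope"]), tolerance = 1e-10)
      expect_equal(log(fit$s0_map[v]), unname(o["intercept"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("ADC ordering across windows reflects IVIM and kurtosis", {
  prot <- diffusion_protocol()
  pars <- ivim_kurtosis_params(s0 = 1000, f_ivim = 0.1, d_star = 1e-2,
                               adc0 = 6e-4, k = 0.6)
  m <- matrix(ivim_kurtosis_signal(prot$b_values, pars), nrow = 1)
  a <- vapply(c("low", "mid", "high"),
              function(w) fit_adc_range(m, prot, w)$adc_map[1], numeric(1))
  expect_true(a[["low"]] > a[["mid"]] && a[["mid"]] > a[["high"]])
  # range consistency: pure mono-exponential gives equal ADCs everywhere
  m2 <- matrix(1000 * exp(-prot$b_values * 6e-4), nrow = 1)
  a2 <- vapply(c("low", "mid", "high"),
               function(w) fit_adc_range(m2, prot, w)$adc_map[1], numeric(1))
  expect_lt(max(abs(a2 / 6e-4 - 1)), 1e-6)
})

test_that("bounded kurtosis fit recovers noiseless parameters exactly", {
  prot <- diffusion_protocol()
  b <- prot$b_values
  sig <- qmribrain:::kurtosis_model(c(1000, 6.2e-4, 0.623), b)
  m <- matrix(sig, nrow = 1)
  mid <- fit_adc_range(m, prot, "mid")
  kf <- fit_ivim_kurtosis(m, prot, mid)
  expect_lt(abs(kf$s0_map[1] / 1000 - 1), 1e-6)
  expect_lt(abs(kf$adc0_map[1] / 6.2e-4 - 1), 1e-6)
  expect_lt(abs(kf$k_map[1] / 0.623 - 1), 1e-6)
  expect_true(kf$converged[1])
  expect_false(kf$pinned[1])
  expect_error(fit_ivim_kurtosis(m, prot), "mid_fit")
})

test_that("K = 0 reduces to the Stejskal-Tanner ADC on the same b-set", {
  prot <- diffusion_protocol()
  b <- prot$b_values
  sig <- 1000 * exp(-b * 6.2e-4)
  m <- matrix(sig, nrow = 1)
  mid <- fit_adc_range(m, prot, "mid")
  kf <- fit_ivim_kurtosis(m, prot, mid)
  # mono-exponential NLS over the same (b >= mid floor) domain
  sel <- b >= prot$windows$mid[1]
  st <- qmribrain:::fit_monoexp_nls(b[sel], sig[sel])
  expect_equal(kf$adc0_map[1], st$adc, tolerance = 1e-6)
  expect_lt(kf$k_map[1], 1e-6)          # at the lower bound
})

test_that("out-of-bounds kurtosis is pinned at 2.0 and flagged", {
  prot <- diffusion_protocol()
  sig <- qmribrain:::kurtosis_model(c(1000, 6.2e-4, 2.5), prot$b_values)
  m <- matrix(sig, nrow = 1)
  kf <- fit_ivim_kurtosis(m, prot, fit_adc_range(m, prot, "mid"))
  expect_equal(kf$k_map[1], 2.0, tolerance = 1e-9)
  expect_true(kf$pinned[1])
})

test_that("every fitted parameter lies inside its per-voxel box", {
  prot <- diffusion_protocol()
  set.seed(4)
  n <- 60
  b <- prot$b_values
  m <- t(sapply(seq_len(n), function(i) {
    p <- c(runif(1, 500, 1500), runif(1, 4e-4, 9e-4), runif(1, 0, 1.5))
    qmribrain:::kurtosis_model(p, b) * exp(rnorm(length(b), 0, 0.02))
  }))
  mid <- fit_adc_range(m, prot, "mid")
  kf <- fit_ivim_kurtosis(m, prot, mid)
  ok <- kf$valid_mask
  expect_true(all(kf$s0_map[ok] >= 0.5 * mid$s0_map[ok] - 1e-9))
  expect_true(all(kf$s0_map[ok] <= 2.0 * mid$s0_map[ok] + 1e-9))
  expect_true(all(kf$adc0_map[ok] >= 0.5 * mid$adc_map[ok] - 1e-12))
  expect_true(all(kf$adc0_map[ok] <= 2.0 * mid$adc_map[ok] + 1e-12))
  expect_true(all(kf$k_map[ok] >= 0 & kf$k_map[ok] <= 2.0))
})

test_that("noisy kurtosis fits recover ADC0 within 5% median error", {
  prot <- diffusion_protocol()
  set.seed(12)
  n <- 1000
  b <- prot$b_values
  truth_adc <- 6.2e-4
  m <- t(sapply(seq_len(n), function(i)
    qmribrain:::kurtosis_model(c(1000, truth_adc, 0.7), b) +
      rnorm(length(b), 0, 20)))      # sigma/S0 = 2%
  mid <- fit_adc_range(m, prot, "mid")
  kf <- fit_ivim_kurtosis(m, prot, mid)
  ok <- kf$valid_mask
  med_err <- median(abs(kf$adc0_map[ok] - truth_adc) / truth_adc)
  expect_lt(med_err, 0.05)
  # K bias shrinks with noise
  k_bias <- sapply(c(0.02, 0.002), function(sig) {
    mm <- t(sapply(seq_len(300), function(i)
      qmribrain:::kurtosis_model(c(1000, truth_adc, 0.7), b) +
        rnorm(length(b), 0, 1000 * sig)))
    kk <- fit_ivim_kurtosis(mm, prot, fit_adc_range(mm, prot, "mid"))
    abs(mean(kk$k_map[kk$valid_mask]) - 0.7)
  })
  expect_lt(k_bias[2], k_bias[1])
  expect_lt(k_bias[2], 0.02)
})

test_that("kurtosis-reduction simulation behaves per its closed form", {
  base <- list(s0 = 1000, adc0 = 6e-4, k = 1.0)
  tab0 <- simulate_kurtosis_effect(base, 0)
  expect_equal(tab0$pct_change, 0, tolerance = 1e-9)
  rr <- seq(0.1, 0.9, by = 0.1)
  tab <- simulate_kurtosis_effect(base, rr)
  expect_true(all(diff(tab$pct_change) > 0))   # strictly increasing
  # independent log-linear oracle over the same window
  b <- seq(1200, 2500, length.out = 21)
  ols_adc <- function(k) {
    s <- base$s0 * exp(-b * base$adc0 + (b * base$adc0)^2 * k / 6)
    -unname(ols2_oracle(b, log(s))["slope"])
  }
  ref <- ols_adc(base$k)
  oracle_pct <- 100 * (vapply(base$k * (1 - rr), ols_adc, numeric(1)) - ref) / ref
  expect_true(all(diff(oracle_pct) > 0))
  expect_equal(tab$pct_change, oracle_pct, tolerance = 0.08)
  expect_error(simulate_kurtosis_effect(base, 1.2), "reductions")
  expect_error(simulate_kurtosis_effect(list(s0 = 1, adc0 = 1e-3, k = 0),
                                        0.2), "positive")
})
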