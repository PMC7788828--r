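#' Evaluate the IVIM-kurtosis diffusion signal model
#'
#' The biexponential IVIM-kurtosis representation of the diffusion-weighted
#' signal:
#' `S(b) = S0 * (f_IVIM * exp(-b D*) + (1 - f_IVIM) * exp(-b ADC0 + (b ADC0)^2 K / 6))`.
#' With `f_ivim = 0` and `k = 0` this reduces to the Stejskal-Tanner
#' mono-exponential decay at `adc0`.
#'
#' @param b b-values in s/mm^2 (vector).
#' @param params an [ivim_kurtosis_params] object, or a list with fields
#'   `s0`, `f_ivim`, `d_star`, `adc0`, `k`.
#' @return Numeric vector of signals, same length as `b`.
#' @export
ivim_kurtosis_signal <- function(b, params) {
  p <- params
  p$s0 * (p$f_ivim * exp(-b * p$d_star) +
            (1 - p$f_ivim) * exp(-b * p$adc0 + (b * p$adc0)^2 * p$k / 6))
}

# Add magnitude noise. Gaussian noise is the default (appropriate for the
# log-linear estimators at moderate-to-high SNR); Rician emulates magnitude
# reconstruction of complex Gaussian noise for bias studies.
add_noise <- function(signal, noise_sd, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") {
    signal + stats::rnorm(n, 0, noise_sd)
  } else {
    sqrt((signal + stats::rnorm(n, 0, noise_sd))^2 +
           stats::rnorm(n, 0, noise_sd)^2)
  }
}

# Smooth multiplicative second-order polynomial field with mean 1 over the
# grid and peak deviation `amplitude`.
make_bias_field <- function(grid, amplitude) {
  if (amplitude == 0) return(array(1, grid$dims))
  co <- grid_coords(grid)
  nx <- co$x / max(abs(co$x)); ny <- co$y / max(abs(co$y))
  nz <- co$z / max(abs(co$z))
  coef <- stats::rnorm(9)
  q <- coef[1] * nx + coef[2] * ny + coef[3] * nz +
    coef[4] * nx * ny + coef[5] * nx * nz + coef[6] * ny * nz +
    coef[7] * nx^2 + coef[8] * ny^2 + coef[9] * nz^2
  # normalise over the central (head) region so `amplitude` is the peak
  # relative deviation across the object, not the empty grid corners
  central <- nx^2 + ny^2 + nz^2 < 0.5^2
  q <- q - mean(q[central])
  field <- 1 + amplitude * q / max(abs(q[central]))
  array(field, grid$dims)
}

#' Simulate a proton-density-weighted (PDW) volume
#'
#' Voxel value = sum over compartments of probability times proton density,
#' multiplied by a smooth second-order polynomial bias field (mean 1, peak
#' relative deviation `bias_amplitude`; B1-inhomogeneity emulation), plus
#' Gaussian noise.
#'
#' @param maps [tissue_prob_maps].
#' @param truth [compartment_truth] (proton densities).
#' @param bias_amplitude peak relative deviation of the bias field (0 = no
#'   bias).
#' @param noise_sd Gaussian noise standard deviation, arbitrary units.
#' @param seed integer RNG seed.
#' @return 3D array; attribute `bias_field` stores the applied field.
#' @export
simulate_pdw <- function(maps, truth, bias_amplitude = 0, noise_sd = 0,
                         seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pd <- truth$proton_density
  ideal <- maps$p_gm * pd[["gm"]] + maps$p_wm * pd[["wm"]] +
    maps$p_csf * pd[["csf"]]
  field <- make_bias_field(maps$grid, bias_amplitude)
  vol <- array(add_noise(as.vector(ideal * field), noise_sd), maps$grid$dims)
  attr(vol, "bias_field") <- field
  vol
}

#' Simulate a multi-gradient-echo (MGE) series
#'
#' Per voxel, `S(TE) = sum_c p_c * PD_c * exp(-TE / T2*_c)` plus Gaussian
#' noise, one 3D volume per echo time.
#'
#' @param maps [tissue_prob_maps].
#' @param truth [compartment_truth] (proton density and T2* per compartment,
#'   T2* in ms).
#' @param protocol [acquisition_protocol]; at least 3 echoes.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param seed integer RNG seed.
#' @return 4D array `dims x n_echoes`; attribute `echo_times`.
#' @export
simulate_mge <- function(maps, truth, protocol = acquisition_protocol(),
                         noise_sd = 0, seed = 1L) {
  te <- protocol$echo_times
  if (length(te) < 3L) stop("at least 3 echoes are required")
  if (any(te <= 0)) stop("echo times must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pd <- truth$proton_density; t2 <- truth$t2star
  d <- maps$grid$dims
  out <- array(0, c(d, length(te)))
  for (i in seq_along(te)) {
    s <- maps$p_gm * pd[["gm"]] * exp(-te[i] / t2[["gm"]]) +
      maps$p_wm * pd[["wm"]] * exp(-te[i] / t2[["wm"]]) +
      maps$p_csf * pd[["csf"]] * exp(-te[i] / t2[["csf"]])
    out[, , , i] <- s
  }
  if (noise_sd > 0)
    out <- array(add_noise(as.vector(out), noise_sd), dim(out))
  attr(out, "echo_times") <- te
  out
}

#' Simulate a diffusion-weighted (DWI) series
#'
#' Per voxel and b-value, the signal is the probability-weighted sum of each
#' compartment's IVIM-kurtosis signal (see [ivim_kurtosis_signal()]),
#' identical across the three orthogonal directions (isotropy assumption)
#' with independent noise per direction.
#'
#' @param maps [tissue_prob_maps].
#' @param truth [compartment_truth] (per-compartment diffusion parameters).
#' @param protocol [diffusion_protocol].
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param noise_sd noise sd (a.u.).
#' @param seed integer RNG seed.
#' @return 4D array `dims x (n_b * n_directions)`, direction fastest;
#'   attributes `b_values`, `n_directions`.
#' @export
simulate_dwi <- function(maps, truth, protocol = diffusion_protocol(),
                         noise_model = c("gaussian", "rician"),
                         noise_sd = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  b <- protocol$b_values
  nd <- ncol(protocol$directions)
  d <- maps$grid$dims
  out <- array(0, c(d, length(b) * nd))
  for (i in seq_along(b)) {
    s <- maps$p_gm * ivim_kurtosis_signal(b[i], truth$diffusion$gm) +
      maps$p_wm * ivim_kurtosis_signal(b[i], truth$diffusion$wm) +
      maps$p_csf * ivim_kurtosis_signal(b[i], truth$diffusion$csf)
    for (j in seq_len(nd)) out[, , , (i - 1L) * nd + j] <- s
  }
  if (noise_sd > 0)
    out <- array(add_noise(as.vector(out), noise_sd, noise_model), dim(out))
  attr(out, "b_values") <- b
  attr(out, "n_directions") <- nd
  out
}

#' Simulate a mono-exponential DMSO-like phantom signal
#'
#' A dimethyl-sulfoxide phantom shows pure mono-exponential diffusion decay
#' over the whole b-range: `S(b) = s0 * exp(-b * adc)` plus noise.
#'
#' @param protocol [diffusion_protocol].
#' @param adc diffusion coefficient in mm^2/s (> 0).
#' @param s0 signal at b = 0.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer RNG seed.
#' @return data.frame with columns `b` (s/mm^2) and `signal` (a.u.).
#' @export
simulate_dmso <- function(protocol = diffusion_protocol(), adc, s0 = 1000,
                          noise_sd = 0, seed = 1L) {
  if (adc <= 0) stop("adc must be positive (mm^2/s)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  b <- protocol$b_values
  data.frame(b = b, signal = add_noise(s0 * exp(-b * adc), noise_sd))
}
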