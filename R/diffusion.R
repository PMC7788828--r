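#' Combine orthogonal-direction DWI volumes by geometric mean
#'
#' For each b-value, the signals measured along the read, phase and slice
#' directions are combined voxel-wise by their geometric mean, yielding one
#' trace-weighted volume per b-value. Negative values (possible under
#' additive noise) are clamped to zero first; the geometric mean is zero
#' whenever any direction is zero.
#'
#' @param dwi_series 4D array from [simulate_dwi()] (direction fastest) or
#'   a voxel-by-volume matrix with attributes preserved.
#' @param protocol [diffusion_protocol].
#' @return 4D array (or matrix) with one volume per b-value; attribute
#'   `b_values`.
#' @export
combine_directions <- function(dwi_series, protocol) {
  b <- protocol$b_values
  nd <- ncol(protocol$directions)
  vm <- as_voxel_matrix(dwi_series, n_expected = length(b) * nd)
  if (ncol(vm$mat) != length(b) * nd)
    stop("series does not contain ", nd, " direction volumes for each of ",
         length(b), " b-values")
  m <- pmax(vm$mat, 0)
  out <- matrix(0, nrow(m), length(b))
  for (i in seq_along(b)) {
    cols <- (i - 1L) * nd + seq_len(nd)
    g <- m[, cols[1]]
    for (j in cols[-1]) g <- g * m[, j]
    out[, i] <- g^(1 / nd)
  }
  res <- if (is.null(vm$dims)) out else array(out, c(vm$dims, length(b)))
  attr(res, "b_values") <- b
  res
}

#' Range-specific ADC mapping (Stejskal-Tanner log-linear fit)
#'
#' Fits `S(b) = S0 * exp(-b * ADC)` by unweighted ordinary least squares of
#' log-signal against b, restricted to the b-values inside one named window
#' of the protocol (low, mid or high). Voxels with any non-positive signal
#' in the window, or a non-positive fitted ADC, are masked invalid.
#'
#' @param series direction-combined series (one volume per b-value), 4D
#'   array or voxel matrix.
#' @param protocol [diffusion_protocol].
#' @param window one of the protocol's window names (`"low"`, `"mid"`,
#'   `"high"`).
#' @return Object of class `adc_fit`: `adc_map` (mm^2/s), `s0_map`,
#'   `r2_map`, `valid_mask`, `window`, `b_used`.
#' @export
fit_adc_range <- function(series, protocol, window = c("low", "mid", "high")) {
  window <- match.arg(window, names(protocol$windows))
  b <- protocol$b_values
  vm <- as_voxel_matrix(series, n_expected = length(b))
  inw <- which(!is.na(protocol$window_of) & protocol$window_of == window)
  if (length(inw) < 3L)
    stop("window '", window, "' contains fewer than 3 b-values")
  fit <- loglinear_fit(vm$mat[, inw, drop = FALSE], b[inw])
  adc <- -fit$slope
  valid <- fit$valid & adc > 0
  structure(
    list(adc_map = reshape_map(ifelse(valid, adc, NA_real_), vm$dims),
         s0_map = reshape_map(ifelse(valid, exp(fit$intercept), NA_real_),
                              vm$dims),
         r2_map = reshape_map(ifelse(valid, fit$r2, NA_real_), vm$dims),
         valid_mask = reshape_map(valid, vm$dims),
         window = window, b_used = b[inw]),
    class = "adc_fit"
  )
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf("adc_fit (%s window, %d b-values %.0f-%.0f s/mm^2): %d/%d voxels valid\n",
              x$window, length(x$b_used), min(x$b_used), max(x$b_used),
              sum(x$valid_mask), length(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  ADC median %.1f um^2/s\n",
                1e6 * stats::median(x$adc_map[x$valid_mask])))
  invisible(x)
}

#' @export
coef.adc_fit <- function(object, ...) {
  list(adc = object$adc_map, s0 = object$s0_map)
}

#' @export
predict.adc_fit <- function(object, b, ...) {
  sapply(b, function(bb) object$s0_map * exp(-bb * object$adc_map))
}

# Simplified (high-b) kurtosis signal model: the IVIM term is dropped, valid
# for b above the mid-window floor where the pseudo-diffusion term has
# decayed away.
kurtosis_model <- function(par, b) {
  par[1] * exp(-b * par[2] + (b * par[2])^2 * par[3] / 6)
}

# Mono-exponential fit on signal amplitudes by nonlinear least squares,
# initialised from the log-linear solution.
fit_monoexp_nls <- function(b, s, control = minpack.lm::nls.lm.control(
  maxiter = 200, ftol = 1e-12, ptol = 1e-12)) {
  init <- loglinear_fit(matrix(s, nrow = 1), b)
  par0 <- c(s0 = exp(init$intercept), adc = max(-init$slope, 1e-6))
  out <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) s - p[1] * exp(-b * p[2]),
    control = control)
  list(s0 = out$par[[1]], adc = out$par[[2]], rsstrace = out$rsstrace)
}

#' Voxel-wise bounded IVIM-kurtosis fit (simplified high-b model)
#'
#' Fits `S(b) = S0 * exp(-b*ADC0 + (b*ADC0)^2 * K/6)` per voxel by
#' Levenberg-Marquardt nonlinear least squares on signal amplitudes with box
#' constraints, over all b-values at or above the mid-window floor (where
#' the IVIM pseudo-diffusion term is negligible). Initialisation uses the
#' mid-range Stejskal-Tanner fit (`S0 <- S0_mid`, `ADC0 <- ADC_mid`) and
#' `K <- k_init`; each voxel's box is `0.5*S0_mid < S0 < 2*S0_mid`,
#' `0.5*ADC_mid < ADC0 < 2*ADC_mid` and `k_bounds` for K. Voxels whose
#' mid-range fit is invalid (or that are all-zero) are masked invalid;
#' non-converged voxels keep their parameters but are flagged.
#'
#' @param series direction-combined series (one volume per b-value).
#' @param protocol [diffusion_protocol].
#' @param mid_fit the mid-window [fit_adc_range()] result (initialisation
#'   and bounds).
#' @param k_init initial kurtosis (default 0.623).
#' @param k_bounds kurtosis box, default `c(0, 2)`.
#' @param mask optional logical array restricting which voxels are fitted.
#' @param on_log fit residuals on log-signal instead of amplitudes.
#' @param max_iter,ftol,ptol Levenberg-Marquardt controls.
#' @return Object of class `ivim_kurtosis_fit` with maps `s0_map`,
#'   `adc0_map`, `k_map`, per-voxel `converged`, `pinned` (any parameter at
#'   its bound), `iterations`, `resnorm`, plus `valid_mask` and bounds
#'   metadata.
#' @export
fit_ivim_kurtosis <- function(series, protocol, mid_fit,
                              k_init = 0.623, k_bounds = c(0, 2),
                              mask = NULL, on_log = FALSE,
                              max_iter = 200, ftol = 1e-10, ptol = 1e-10) {
  if (missing(mid_fit) || !inherits(mid_fit, "adc_fit"))
    stop("mid_fit (mid-window adc_fit) is required for initialisation")
  b_all <- protocol$b_values
  vm <- as_voxel_matrix(series, n_expected = length(b_all))
  sel <- b_all >= protocol$windows$mid[1]
  b <- b_all[sel]
  m <- vm$mat[, sel, drop = FALSE]

  s0m <- as.vector(mid_fit$s0_map)
  adcm <- as.vector(mid_fit$adc_map)
  valid <- as.vector(mid_fit$valid_mask) & rowSums(abs(m)) > 0
  if (!is.null(mask)) valid <- valid & as.vector(mask)

  nv <- nrow(m)
  s0 <- adc0 <- kk <- resnorm <- rep(NA_real_, nv)
  iters <- rep(NA_integer_, nv)
  conv <- pinned <- rep(FALSE, nv)
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                     ptol = ptol)
  for (v in which(valid)) {
    lower <- c(0.5 * s0m[v], 0.5 * adcm[v], k_bounds[1])
    upper <- c(2.0 * s0m[v], 2.0 * adcm[v], k_bounds[2])
    par0 <- pmin(pmax(c(s0m[v], adcm[v], k_init), lower), upper)
    y <- m[v, ]
    resid_fn <- if (on_log) {
      function(p) log(pmax(y, .Machine$double.xmin)) -
        log(pmax(kurtosis_model(p, b), .Machine$double.xmin))
    } else {
      function(p) y - kurtosis_model(p, b)
    }
    out <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                              fn = resid_fn, control = ctrl)
    s0[v] <- out$par[1]; adc0[v] <- out$par[2]; kk[v] <- out$par[3]
    iters[v] <- out$niter
    resnorm[v] <- out$deviance
    conv[v] <- out$info %in% 1:4
    tol_pin <- 1e-6
    pinned[v] <- any(out$par <= lower * (1 + tol_pin) + tol_pin * (lower == 0)) ||
      any(out$par >= upper * (1 - tol_pin))
  }
  structure(
    list(s0_map = reshape_map(s0, vm$dims),
         adc0_map = reshape_map(adc0, vm$dims),
         k_map = reshape_map(kk, vm$dims),
         converged = reshape_map(conv, vm$dims),
         pinned = reshape_map(pinned, vm$dims),
         iterations = reshape_map(iters, vm$dims),
         resnorm = reshape_map(resnorm, vm$dims),
         valid_mask = reshape_map(valid, vm$dims),
         b_used = b, k_init = k_init, k_bounds = k_bounds,
         bounds_factor = c(0.5, 2.0), on_log = on_log),
    class = "ivim_kurtosis_fit"
  )
}

#' @export
print.ivim_kurtosis_fit <- function(x, ...) {
  cat(sprintf("ivim_kurtosis_fit: %d/%d voxels fitted, %d converged, %d at bounds\n",
              sum(x$valid_mask), length(x$valid_mask),
              sum(x$converged), sum(x$pinned)))
  ok <- x$valid_mask
  if (any(ok))
    cat(sprintf("  ADC0 median %.1f um^2/s, K median %.3f\n",
                1e6 * stats::median(x$adc0_map[ok]),
                stats::median(x$k_map[ok])))
  invisible(x)
}

#' @export
coef.ivim_kurtosis_fit <- function(object, ...) {
  list(s0 = object$s0_map, adc0 = object$adc0_map, k = object$k_map)
}

#' @export
predict.ivim_kurtosis_fit <- function(object, b, ...) {
  sapply(b, function(bb)
    object$s0_map * exp(-bb * object$adc0_map +
                          (bb * object$adc0_map)^2 * object$k_map / 6))
}

#' Simulate the effect of kurtosis reduction on high-b ADC
#'
#' Generates noiseless signals from the simplified kurtosis model over a
#' high-b window, fits a mono-exponential model by nonlinear least squares
#' on signal amplitudes at the reference kurtosis and at each reduced
#' kurtosis, and reports the percent change in fitted ADC relative to the
#' reference.
#'
#' @param base parameters (an [ivim_kurtosis_params] or list with `s0`,
#'   `adc0`, `k`); `k` must be positive.
#' @param reductions fractional kurtosis reductions in `[0, 1)`.
#' @param window b-range of the simulation in s/mm^2 (default the
#'   high-b simulation range 1200-2500).
#' @param n_b number of evenly spaced b-values in the window.
#' @return data.frame with columns `reduction`, `k`, `adc_fit` (mm^2/s) and
#'   `pct_change` (%); attribute `adc_ref` stores the reference fit.
#' @export
simulate_kurtosis_effect <- function(base, reductions,
                                     window = c(1200, 2500), n_b = 21) {
  if (base$k <= 0) stop("base kurtosis must be positive")
  if (any(reductions < 0 | reductions >= 1))
    stop("reductions must lie in [0, 1)")
  b <- seq(window[1], window[2], length.out = n_b)
  fit_at <- function(k) {
    s <- kurtosis_model(c(base$s0, base$adc0, k), b)
    fit_monoexp_nls(b, s)$adc
  }
  adc_ref <- fit_at(base$k)
  adc_red <- vapply(reductions, function(r) fit_at(base$k * (1 - r)),
                    numeric(1))
  out <- data.frame(reduction = reductions,
                    k = base$k * (1 - reductions),
                    adc_fit = adc_red,
                    pct_change = 100 * (adc_red - adc_ref) / adc_ref)
  attr(out, "adc_ref") <- adc_ref
  attr(out, "fit_domain") <- c(window, n_b = n_b)
  attr(out, "fit_weighting") <- "amplitude"
  out
}

#' Calibrate the kurtosis-effect simulation to a printed anchor
#'
#' Finds, by monotone 1-D search, the reference tissue diffusivity `adc0`
#' for which a given fractional kurtosis reduction produces a stated percent
#' increase in the mono-exponentially fitted high-b ADC (all other settings
#' as in [simulate_kurtosis_effect()]).
#'
#' @param target_pct percent ADC increase to match at `reduction`.
#' @param reduction the anchoring kurtosis reduction (default 0.2).
#' @param k_ref reference kurtosis (default 1.0).
#' @param s0 signal amplitude.
#' @param window,n_b simulation b-window (s/mm^2) and sampling.
#' @param interval search interval for `adc0` in mm^2/s.
#' @return The calibrated parameter set (list with `s0`, `adc0`, `k`).
#' @export
calibrate_kurtosis_anchor <- function(target_pct = 9, reduction = 0.2,
                                      k_ref = 1.0, s0 = 1000,
                                      window = c(1200, 2500), n_b = 21,
                                      interval = c(5e-5, 1.5e-3)) {
  f <- function(adc0) {
    base <- list(s0 = s0, adc0 = adc0, k = k_ref)
    simulate_kurtosis_effect(base, reduction, window, n_b)$pct_change -
      target_pct
  }
  adc0 <- stats::uniroot(f, interval, tol = 1e-12)$root
  list(s0 = s0, adc0 = adc0, k = k_ref)
}
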