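# Reshape a 4D series (dims x n) or a V x n matrix to voxels-by-measurement
# form, remembering the spatial dims for map reconstruction.
as_voxel_matrix <- function(series, n_expected = NULL) {
  if (is.matrix(series)) {
    if (!is.null(n_expected) && ncol(series) != n_expected)
      stop("series has ", ncol(series), " measurements but the protocol ",
           "defines ", n_expected)
    list(mat = series, dims = NULL)
  } else {
    d <- dim(series)
    if (length(d) != 4L)
      stop("expected a 4D series (x, y, z, measurement) or a voxel matrix")
    if (!is.null(n_expected) && d[4] != n_expected)
      stop("series has ", d[4], " volumes but the protocol defines ",
           n_expected)
    list(mat = matrix(series, nrow = prod(d[1:3]), ncol = d[4]),
         dims = d[1:3])
  }
}

reshape_map <- function(v, dims) {
  if (is.null(dims)) v else array(v, dims)
}

# Ordinary least squares of log-signal against a regressor, vectorised over
# voxels: returns intercept, slope and R^2 per voxel. Rows with any
# non-positive signal are reported invalid.
loglinear_fit <- function(mat, x) {
  valid <- rowSums(mat <= 0) == 0L
  n <- length(x)
  ly <- log(pmax(mat, .Machine$double.xmin))
  sx <- sum(x); sxx <- sum(x^2)
  sy <- rowSums(ly); sxy <- as.vector(ly %*% x)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n
  fitted <- outer(intercept, rep(1, n)) + outer(slope, x)
  rss <- rowSums((ly - fitted)^2)
  tss <- rowSums((ly - sy / n)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 1)
  list(intercept = unname(intercept), slope = unname(slope),
       r2 = unname(r2), valid = unname(valid))
}

#' Fit per-voxel T2* by log-linear least squares
#'
#' Assumes mono-exponential decay `S(TE) = S0 * exp(-TE / T2*)` and fits
#' ordinary least squares of `ln S` against TE per voxel (slope = -1/T2*,
#' intercept = ln S0), unweighted. Voxels with any non-positive signal, or a
#' non-negative slope (non-physical, non-decaying signal), are masked
#' invalid; their map entries are NA, never silently zeroed.
#'
#' @param echo_series 4D array (x, y, z, echo) or voxel-by-echo matrix.
#' @param protocol [acquisition_protocol] supplying the echo times (ms);
#'   at least 3 echoes.
#' @return Object of class `t2star_fit` with `t2star_map` (ms), `s0_map`,
#'   `r2_map`, `valid_mask` and `echo_times`.
#' @export
fit_t2star <- function(echo_series, protocol = acquisition_protocol()) {
  te <- protocol$echo_times
  if (length(te) < 3L) stop("at least 3 echoes are required")
  vm <- as_voxel_matrix(echo_series, n_expected = length(te))
  fit <- loglinear_fit(vm$mat, te)
  valid <- fit$valid & fit$slope < 0
  t2 <- ifelse(valid, -1 / fit$slope, NA_real_)
  s0 <- ifelse(valid, exp(fit$intercept), NA_real_)
  r2 <- ifelse(valid, fit$r2, NA_real_)
  structure(
    list(t2star_map = reshape_map(t2, vm$dims),
         s0_map = reshape_map(s0, vm$dims),
         r2_map = reshape_map(r2, vm$dims),
         valid_mask = reshape_map(valid, vm$dims),
         echo_times = te),
    class = "t2star_fit"
  )
}

#' @export
print.t2star_fit <- function(x, ...) {
  cat(sprintf("t2star_fit: %d voxels, %d valid (%.1f%%)\n",
              length(x$valid_mask), sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  T2* median %.2f ms (IQR %.2f-%.2f)\n",
                stats::median(x$t2star_map[x$valid_mask]),
                stats::quantile(x$t2star_map[x$valid_mask], 0.25),
                stats::quantile(x$t2star_map[x$valid_mask], 0.75)))
  invisible(x)
}

#' @export
coef.t2star_fit <- function(object, ...) {
  list(t2star = object$t2star_map, s0 = object$s0_map)
}

#' Percentile-trimmed compartment mean T2*
#'
#' Averages valid T2* values over voxels whose summed membership
#' probability for the requested compartment set exceeds 0.5, after
#' discarding values outside the given percentile interval (default 0.1 to
#' 99 percent) to exclude outliers.
#'
#' @param fit a [fit_t2star()] result.
#' @param maps [tissue_prob_maps] on the same grid.
#' @param compartments subset of `c("gm", "wm", "csf")`; the default pools
#'   grey and white matter (parenchyma).
#' @param lo_pct,hi_pct trimming percentiles (percent).
#' @return Trimmed mean T2* in ms (scalar). Attributes record voxel counts.
#' @export
compartment_t2star_mean <- function(fit, maps, compartments = c("gm", "wm"),
                                    lo_pct = 0.1, hi_pct = 99) {
  stopifnot(inherits(fit, "t2star_fit"), inherits(maps, "tissue_prob_maps"))
  compartments <- match.arg(compartments, c("gm", "wm", "csf"),
                            several.ok = TRUE)
  p <- 0
  for (cc in compartments) p <- p + maps[[paste0("p_", cc)]]
  sel <- (p > 0.5) & fit$valid_mask
  if (!any(sel)) stop("no valid voxels in the requested compartment set")
  v <- fit$t2star_map[sel]
  qq <- stats::quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE)
  kept <- v[v >= qq[1] & v <= qq[2]]
  out <- mean(kept)
  attr(out, "n_voxels") <- length(v)
  attr(out, "n_kept") <- length(kept)
  out
}
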