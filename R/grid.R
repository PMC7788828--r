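#' Define a regular 3D voxel grid
#'
#' A voxel grid carries the array dimensions, the isotropic or anisotropic
#' voxel size in mm, and the voxel-to-world affine. Voxel indices are 0-based
#' in world-coordinate computations; world coordinates are in mm.
#'
#' @param dims integer vector of length 3, array dimensions (>= 16 each).
#' @param voxel_size numeric voxel edge lengths in mm; length 1 (isotropic)
#'   or 3.
#' @param origin world-space position (mm) of voxel (0,0,0); default centres
#'   the grid on the world origin.
#' @return An object of class `voxel_grid` with fields `dims`, `voxel_size`,
#'   `origin`, `affine` (4x4) and `voxel_volume` (mm^3).
#' @export
voxel_grid <- function(dims, voxel_size = 0.23, origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 16L))
    stop("grid dims must be three integers, each >= 16")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be positive (mm)")
  if (is.null(origin)) origin <- -(dims - 1) / 2 * voxel_size
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_size)
  affine[1:3, 4] <- origin
  structure(
    list(dims = dims, voxel_size = voxel_size, origin = as.numeric(origin),
         affine = affine, voxel_volume = prod(voxel_size)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm (%.4g mm^3/voxel)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$voxel_volume))
  invisible(x)
}

# World-coordinate arrays (mm) for each voxel centre, one 3D array per axis.
grid_coords <- function(grid) {
  d <- grid$dims
  ix <- (seq_len(d[1]) - 1) * grid$voxel_size[1] + grid$origin[1]
  iy <- (seq_len(d[2]) - 1) * grid$voxel_size[2] + grid$origin[2]
  iz <- (seq_len(d[3]) - 1) * grid$voxel_size[3] + grid$origin[3]
  list(
    x = array(ix, d),
    y = array(rep(iy, each = d[1]), d),
    z = array(rep(iz, each = d[1] * d[2]), d)
  )
}

stopifnot_same_dims <- function(a, b, what = "volumes") {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stop("dimension mismatch between ", what)
  invisible(TRUE)
}

#' Tissue probability maps
#'
#' Bundles per-voxel membership probabilities for grey matter, white matter
#' and CSF on a common grid. Probabilities are in \[0,1\] and sum to at most 1
#' per voxel; the remainder is background.
#'
#' @param grid a [voxel_grid].
#' @param p_gm,p_wm,p_csf 3D probability arrays matching `grid$dims`.
#' @return An object of class `tissue_prob_maps`.
#' @export
tissue_prob_maps <- function(grid, p_gm, p_wm, p_csf) {
  for (p in list(p_gm, p_wm, p_csf)) {
    if (!identical(as.integer(dim(p)), grid$dims))
      stop("probability map dimensions do not match the grid")
    if (any(p < -1e-9) || any(p > 1 + 1e-9))
      stop("probabilities must lie in [0, 1]")
  }
  tot <- p_gm + p_wm + p_csf
  if (any(tot > 1 + 1e-6))
    stop("per-voxel GM+WM+CSF probability exceeds 1")
  # clip float dust
  clip01 <- function(p) pmin(pmax(p, 0), 1)
  structure(
    list(grid = grid, p_gm = clip01(p_gm), p_wm = clip01(p_wm),
         p_csf = clip01(p_csf)),
    class = "tissue_prob_maps"
  )
}

#' @export
print.tissue_prob_maps <- function(x, ...) {
  v <- compartment_volumes(x)
  cat("tissue_prob_maps on", paste(x$grid$dims, collapse = " x "), "grid\n")
  cat(sprintf("  volumes (mm^3): CSF %.1f, GM %.1f, WM %.1f, TIV %.1f\n",
              v$csf, v$gm, v$wm, v$tiv))
  invisible(x)
}

#' Per-compartment ground-truth MR parameters
#'
#' Holds, for each compartment (gm, wm, csf), the proton density (arbitrary
#' units), the effective transverse relaxation time T2* (ms) and the
#' diffusion parameters of the IVIM-kurtosis signal model, together with the
#' target compartment volumes used by [build_anatomy()].
#'
#' Defaults are desk-scale values representative of rat brain at high field:
#' parenchymal ADC0 near 0.6e-3 mm^2/s, kurtosis 0.6-0.9, small perfusion
#' fraction, fast pseudo-diffusion D* of 1e-2 mm^2/s, CSF close to free
#' water, and target volumes matching a rat cerebrum (CSF 180 mm^3,
#' parenchyma 1841 mm^3).
#'
#' @param proton_density named numeric (gm, wm, csf), arbitrary units.
#' @param t2star named numeric (gm, wm, csf), ms; all > 0.
#' @param diffusion named list (gm, wm, csf) of [ivim_kurtosis_params()].
#' @param volumes named numeric (gm, wm, csf), target volumes in mm^3.
#' @return Object of class `compartment_truth`.
#' @export
compartment_truth <- function(
    proton_density = c(gm = 0.85, wm = 0.70, csf = 1.00),
    t2star = c(gm = 30, wm = 25, csf = 80),
    diffusion = list(
      gm  = ivim_kurtosis_params(s0 = 0.85, f_ivim = 0.08, d_star = 1e-2,
                                 adc0 = 6.2e-4, k = 0.7),
      wm  = ivim_kurtosis_params(s0 = 0.70, f_ivim = 0.04, d_star = 1e-2,
                                 adc0 = 5.5e-4, k = 0.9),
      csf = ivim_kurtosis_params(s0 = 1.00, f_ivim = 0, d_star = 1e-2,
                                 adc0 = 3.0e-3, k = 0)
    ),
    volumes = c(gm = 1200, wm = 641, csf = 180)) {
  comps <- c("gm", "wm", "csf")
  if (!all(comps %in% names(proton_density)) || any(proton_density < 0))
    stop("proton_density must be named (gm, wm, csf) and non-negative")
  if (!all(comps %in% names(t2star)) || any(t2star <= 0))
    stop("t2star must be named (gm, wm, csf) and positive (ms)")
  if (!all(comps %in% names(diffusion)))
    stop("diffusion must be a named list (gm, wm, csf)")
  if (!all(comps %in% names(volumes)) || any(volumes <= 0))
    stop("target volumes must be named (gm, wm, csf) and positive (mm^3)")
  structure(
    list(proton_density = proton_density[comps], t2star = t2star[comps],
         diffusion = diffusion[comps], volumes = volumes[comps]),
    class = "compartment_truth"
  )
}

#' IVIM-kurtosis signal-model parameters
#'
#' Parameter set (S0, f_IVIM, D*, ADC0, K) of the biexponential
#' IVIM-kurtosis representation of the diffusion-weighted signal:
#' S(b)/S0 = f_IVIM exp(-b D*) + (1 - f_IVIM) exp(-b ADC0 + (b ADC0)^2 K/6).
#'
#' @param s0 signal amplitude at b = 0, arbitrary units (> 0).
#' @param f_ivim perfusion (pseudo-diffusion) signal fraction in \[0, 1).
#' @param d_star pseudo-diffusion coefficient, mm^2/s; must exceed `adc0`.
#' @param adc0 tissue diffusion coefficient, mm^2/s (> 0).
#' @param k unitless excess kurtosis (>= 0).
#' @return Object of class `ivim_kurtosis_params`.
#' @export
ivim_kurtosis_params <- function(s0, f_ivim, d_star, adc0, k) {
  if (s0 <= 0) stop("s0 must be positive")
  if (f_ivim < 0 || f_ivim >= 1) stop("f_ivim must lie in [0, 1)")
  if (adc0 <= 0) stop("adc0 must be positive (mm^2/s)")
  if (d_star <= adc0) stop("d_star must exceed adc0")
  if (k < 0) stop("kurtosis k must be non-negative")
  structure(list(s0 = s0, f_ivim = f_ivim, d_star = d_star,
                 adc0 = adc0, k = k),
            class = "ivim_kurtosis_params")
}

#' Between-condition effect specification
#'
#' Describes how condition A differs from the base condition B in a paired
#' design: a multiplicative CSF volume change (with compensating parenchymal
#' change, conserving total intracranial volume), focal grey-matter swelling
#' sites, and a global additive T2* shift.
#'
#' @param csf_scale CSF volume in condition A as a fraction of condition B
#'   (> 0); 1 means no change.
#' @param gm_sites list of focal swelling sites, each a list with `center`
#'   (world mm, length 3), `radius` (mm) and `magnitude` (peak added GM
#'   probability in \[0,1\]).
#' @param t2star_shift ms added to every compartment's T2* in condition A.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(csf_scale = 1, gm_sites = list(), t2star_shift = 0) {
  if (csf_scale <= 0) stop("csf_scale must be positive")
  for (s in gm_sites) {
    if (!all(c("center", "radius", "magnitude") %in% names(s)))
      stop("each gm_site needs center, radius and magnitude")
    if (s$radius <= 0 || s$magnitude < 0 || s$magnitude > 1)
      stop("gm_site radius must be > 0 and magnitude in [0, 1]")
  }
  structure(list(csf_scale = csf_scale, gm_sites = gm_sites,
                 t2star_shift = t2star_shift),
            class = "effect_spec")
}
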