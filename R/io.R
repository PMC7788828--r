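#' Read and write NIfTI-1 volumes with grid geometry
#'
#' `write_volume()` stores a 3D or 4D array as NIfTI-1 with the grid's voxel
#' sizes (mm) and origin in the header; `read_volume()` reads one back and
#' reconstructs the [voxel_grid]. Round-trips preserve the data bit-exactly
#' (data are written as float64) and the header geometry.
#'
#' @param volume 3D or 4D numeric array.
#' @param grid [voxel_grid] describing the first three dimensions.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns the path invisibly; `read_volume()`
#'   returns a list with `data` (array) and `grid`.
#' @export
write_volume <- function(volume, grid, path) {
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  if (!identical(as.integer(dim(volume)[1:3]), grid$dims))
    stop("volume dimensions do not match the grid")
  a <- array(as.double(volume), dim(volume))  # strip attributes
  d <- dim(a)
  hdr <- RNifti::niftiHeader(list(
    dim = c(nd, d, rep(1L, 7L - nd)),
    pixdim = c(-1, grid$voxel_size, rep(1, 4L))))
  img <- RNifti::asNifti(a, reference = hdr, datatype = "double")
  xf <- structure(grid$affine, code = 2L)
  img <- RNifti::`qform<-`(img, xf)
  img <- RNifti::`sform<-`(img, xf)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param expect_4d require a 4D series (error on 3D input).
#' @export
read_volume <- function(path, expect_4d = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (expect_4d && length(d) != 4L)
    stop("expected a 4D series but '", path, "' is ", length(d), "D")
  pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  grid <- voxel_grid(d[1:3], pd[1:3], origin = xf[1:3, 4])
  list(data = as.array(img), grid = grid)
}

#' Default pipeline configuration
#'
#' Nested list of every knob of [run_pipeline()]: grid, cohort size, noise
#' and bias settings, the between-condition effect, smoothing widths, the
#' FDR level and all seeds. The defaults encode the study conditions the
#' package emulates (12 pairs; CSF 180 mm^3 scaled by 190/180; parenchyma
#' 1841 mm^3; global T2* shift -1.8 ms; 2 percent signal noise; 10 percent
#' bias-field amplitude; 0.6 mm smoothing; q = 0.05).
#'
#' @param grid_dims,voxel_size grid specification.
#' @param n_subjects number of pairs.
#' @param seed master seed.
#' @param include_dwi run the diffusion arm (slowest stage).
#' @return A `run_config` list, YAML-serialisable with
#'   [write_run_config()].
#' @export
default_run_config <- function(grid_dims = c(48, 48, 32), voxel_size = 0.46,
                               n_subjects = 12, seed = 1L,
                               include_dwi = TRUE) {
  structure(list(
    grid = list(dims = as.integer(grid_dims),
                voxel_size = as.numeric(voxel_size)),
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    truth = list(t2star_gm_ms = 30.6, t2star_wm_ms = 30.6,
                 t2star_csf_ms = 80,
                 csf_mm3 = 180, gm_mm3 = 1200, wm_mm3 = 641),
    effect = list(csf_scale = 190 / 180, t2star_shift_ms = -1.8),
    noise = list(pdw_sd = 0.02, mge_sd = 0.02, dwi_sd = 0.02,
                 bias_amplitude = 0.1),
    volume_sd = list(csf_mm3 = 19, parenchyma_mm3 = 90),
    smoothing = list(fwhm_mm = 0.6),
    stats = list(q_level = 0.05, fdr_method = "BH"),
    include_dwi = isTRUE(include_dwi)
  ), class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config()` returns the `run_config`; round-trips are
#'   value-identical.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$grid$dims <- as.integer(cfg$grid$dims)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Short stable hash of a configuration, embedded in every pipeline output.
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
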