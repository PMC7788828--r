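# Soft membership of "r < t" with a linear partial-volume ramp of width w.
soft_inside <- function(r, t, w) pmin(pmax((t - r) / w + 0.5, 0), 1)

#' Build schematic three-compartment brain anatomy
#'
#' Constructs tissue probability maps as nested ellipsoids: a white-matter
#' core with two ventricle-like CSF cavities, a grey-matter rind, and a thin
#' outer CSF shell (subarachnoid-space emulation). Compartment boundaries
#' carry a one-voxel linear partial-volume ramp. The overall brain scale and
#' the two tissue boundaries are solved by monotone 1-D root finding so that
#' each compartment's probabilistic volume (sum of probabilities times voxel
#' volume) matches the requested target essentially exactly.
#'
#' The anatomy is schematic, not an atlas: downstream analyses operate on
#' compartment probabilities, not on anatomical fidelity.
#'
#' @param grid a [voxel_grid].
#' @param truth a [compartment_truth]; `truth$volumes` are the targets (mm^3).
#' @param seed integer; drives a small (about 3 percent) per-subject jitter
#'   of the ellipsoid axis ratios and ventricle placement. Same seed, same
#'   anatomy.
#' @param semi_axes base brain ellipsoid semi-axes in mm (x, y, z).
#' @return A [tissue_prob_maps] object; attribute `boundaries` records the
#'   solved radial thresholds.
#' @export
build_anatomy <- function(grid, truth, seed = 1L,
                          semi_axes = c(9.5, 8.0, 6.3)) {
  vols <- truth$volumes
  if (any(vols <= 0))
    stop("requested volume must be positive for compartment: ",
         paste(names(vols)[vols <= 0], collapse = ", "))
  grid_vol <- prod(grid$dims) * grid$voxel_volume
  if (sum(vols) >= grid_vol)
    stop("requested GM+WM+CSF volume (", round(sum(vols), 1),
         " mm^3) exceeds the grid volume (", round(grid_vol, 1), " mm^3)")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  ax <- semi_axes * (1 + stats::runif(3, -0.03, 0.03))
  vent_shift <- stats::runif(3, -0.3, 0.3)

  co <- grid_coords(grid)
  # normalized elliptical radius; brain surface sits at r = s (solved below)
  r <- sqrt((co$x / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2)
  w <- mean(grid$voxel_size) / exp(mean(log(ax)))  # ~1 voxel ramp in r units

  vv <- grid$voxel_volume
  solve_thresh <- function(f, target, lower, upper, comp) {
    flo <- f(lower) - target
    fhi <- f(upper) - target
    if (sign(flo) == sign(fhi))
      stop("requested ", comp, " volume (", round(target, 1),
           " mm^3) is infeasible on this grid/anatomy")
    stats::uniroot(function(t) f(t) - target, c(lower, upper),
                   tol = 1e-10)$root
  }

  # 1) overall scale: total intracranial volume
  tiv_of <- function(s) sum(soft_inside(r, s, w)) * vv
  s <- solve_thresh(tiv_of, sum(vols), 0.05, 1.45, "total (GM+WM+CSF)")
  brain <- soft_inside(r, s, w)

  # ventricles: two small ellipsoids deep in the core, CSF carved out of WM
  vents <- 0
  for (sgn in c(-1, 1)) {
    ctr <- c(sgn * 1.6, 0.6, -0.8) + vent_shift * c(sgn, 1, 1)
    va <- c(0.9, 2.2, 0.9) * (s * exp(mean(log(ax))) / exp(mean(log(semi_axes))))
    rv <- sqrt(((co$x - ctr[1]) / va[1])^2 + ((co$y - ctr[2]) / va[2])^2 +
                 ((co$z - ctr[3]) / va[3])^2)
    vents <- vents + soft_inside(rv, 1, mean(grid$voxel_size) / exp(mean(log(va))))
  }
  vents <- pmin(vents, 1)

  # cistern-like CSF pockets at the ventral/lateral brain surface: real CSF
  # spaces are not a uniform film -- basal and ambient cisterns are several
  # voxels thick and hold much of the subarachnoid volume
  pocket_dirs <- list(c(0, -0.55, -0.84), c(0.62, -0.30, -0.73),
                      c(-0.62, -0.30, -0.73), c(0, 0.62, -0.79))
  pockets <- 0
  pa <- c(2.3, 2.3, 1.4) * (s * exp(mean(log(ax))) / exp(mean(log(semi_axes))))
  for (u in pocket_dirs) {
    u <- u / sqrt(sum(u^2))
    ctr <- s * u * ax          # point on the (scaled) brain surface
    rp <- sqrt(((co$x - ctr[1]) / pa[1])^2 + ((co$y - ctr[2]) / pa[2])^2 +
                 ((co$z - ctr[3]) / pa[3])^2)
    pockets <- pockets + soft_inside(rp, 1, mean(grid$voxel_size) / exp(mean(log(pa))))
  }
  pockets <- pmin(pockets, 1)

  # intra-core CSF cavity fraction (ventricles + cistern pockets)
  q <- pmin(vents + pockets, 1)

  # 2) GM/CSF boundary t2: shell + cavity CSF = CSF target; the cavity is
  # carved multiplicatively out of the core so probabilities stay exact
  csf_of <- function(t2) {
    core <- pmin(soft_inside(r, t2, w), brain)
    sum(brain - core * (1 - q)) * vv
  }
  t2 <- solve_thresh(csf_of, vols[["csf"]], 0.2 * s, s + 3 * w, "csf")
  core <- pmin(soft_inside(r, t2, w), brain)

  # 3) WM/GM boundary t1: GM band = GM target
  gm_of <- function(t1) {
    wmc <- pmin(soft_inside(r, t1, w), core)
    sum((core - wmc) * (1 - q)) * vv
  }
  t1 <- solve_thresh(gm_of, vols[["gm"]], 0.05 * s, t2, "gm")
  wmc <- pmin(soft_inside(r, t1, w), core)

  p_csf <- (brain - core) + core * q
  p_gm <- (core - wmc) * (1 - q)
  p_wm <- wmc * (1 - q)
  maps <- tissue_prob_maps(grid, p_gm = p_gm, p_wm = p_wm, p_csf = p_csf)
  attr(maps, "boundaries") <- c(scale = s, wm_gm = t1, gm_csf = t2)
  maps
}

# Quadratic focal bump profile in [0, 1] around a world-space centre.
gm_site_profile <- function(grid, site) {
  co <- grid_coords(grid)
  d2 <- ((co$x - site$center[1])^2 + (co$y - site$center[2])^2 +
           (co$z - site$center[3])^2) / site$radius^2
  site$magnitude * pmax(0, 1 - d2)
}

#' Apply a between-condition compartment effect
#'
#' Produces the condition-A tissue maps from the base maps: focal
#' grey-matter swelling sites first (each site adds a quadratic bump to the
#' GM probability, drawing the mass from CSF, then WM, then background, so
#' intracranial volume is conserved wherever brain tissue supplies it), then
#' a CSF volume rescaling implemented as a CSF-parenchyma exchange at
#' partial-volume interface voxels, solved so that the final CSF volume
#' equals `csf_scale` times the post-swelling CSF volume essentially
#' exactly (with no swelling sites: times the input CSF volume). Total
#' intracranial volume is conserved (Monro-Kellie emulation), up to any bump
#' mass drawn from background.
#'
#' @param maps base-condition [tissue_prob_maps].
#' @param effect an [effect_spec].
#' @return New [tissue_prob_maps] for the altered condition.
#' @export
apply_condition_effect <- function(maps, effect) {
  stopifnot(inherits(maps, "tissue_prob_maps"), inherits(effect, "effect_spec"))
  grid <- maps$grid
  p_gm <- maps$p_gm; p_wm <- maps$p_wm; p_csf <- maps$p_csf
  vv <- grid$voxel_volume

  half_fov <- (grid$dims - 1) / 2 * grid$voxel_size
  for (site in effect$gm_sites) {
    if (any(abs(site$center) > half_fov))
      stop("gm_site centre lies outside the grid")
    want <- pmin(gm_site_profile(grid, site), 1 - p_gm)
    from_csf <- pmin(want, p_csf)
    want <- want - from_csf
    from_wm <- pmin(want, p_wm)
    want <- want - from_wm
    bg <- pmax(1 - p_gm - p_wm - p_csf, 0)
    from_bg <- pmin(want, bg)
    p_gm <- p_gm + from_csf + from_wm + from_bg
    p_csf <- p_csf - from_csf
    p_wm <- p_wm - from_wm
  }

  # CSF <-> parenchyma exchange at interface voxels to hit the CSF target
  # (relative to the post-swelling CSF volume, so the two sub-effects
  # compose independently)
  csf_target <- effect$csf_scale * sum(p_csf) * vv
  delta <- csf_target - sum(p_csf) * vv
  if (abs(delta) > 1e-9) {
    paren <- p_gm + p_wm
    if (delta > 0) {           # grow CSF at parenchyma's expense
      cap <- paren
      wgt <- p_csf * paren
    } else {                   # shrink CSF into parenchyma
      cap <- p_csf
      wgt <- p_csf * paren
    }
    if (sum(wgt) <= 0) stop("no CSF/parenchyma interface voxels to adjust")
    need <- abs(delta) / vv
    usable <- wgt > 0
    if (sum(cap[usable]) < need)
      stop("csf_scale infeasible: interface capacity exhausted")
    # capped water-filling: scale uncapped voxels up until the total matches
    a <- need / sum(wgt)
    for (it in 1:100) {
      t_v <- pmin(a * wgt, cap)
      short <- need - sum(t_v)
      if (abs(short) < 1e-12 * max(need, 1)) break
      free <- usable & (a * wgt < cap)
      if (!any(free)) break
      a <- a + short / sum(wgt[free])
    }
    t_v <- pmin(a * wgt, cap)
    share_gm <- ifelse(paren > 0, p_gm / pmax(paren, 1e-300), 0)
    if (delta > 0) {
      p_csf <- p_csf + t_v
      p_gm <- p_gm - t_v * share_gm
      p_wm <- p_wm - t_v * (1 - share_gm)
    } else {
      p_csf <- p_csf - t_v
      p_gm <- p_gm + t_v * share_gm
      p_wm <- p_wm + t_v * (1 - share_gm)
    }
  }
  if (any(p_gm < -1e-8) || any(p_wm < -1e-8) || any(p_csf < -1e-8) ||
      any(p_gm + p_wm + p_csf > 1 + 1e-8))
    stop("condition effect produced probabilities outside [0, 1]")
  out <- tissue_prob_maps(grid, p_gm = p_gm, p_wm = p_wm, p_csf = p_csf)
  attr(out, "boundaries") <- attr(maps, "boundaries")
  out
}
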