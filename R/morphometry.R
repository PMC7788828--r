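# 1D Gaussian kernel matrix with reflective boundaries, as a dense d x d
# operator (rows sum to 1).
gaussian_axis_operator <- function(d, sigma_vox) {
  if (sigma_vox <= 0) return(diag(d))
  radius <- max(1L, ceiling(4 * sigma_vox))
  offs <- -radius:radius
  kern <- exp(-offs^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  op <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- i + offs
    # reflective (mirror) boundary: reflect indices back into 1..d
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > d, 2L * d - j, j)
    for (k in seq_along(j)) op[i, j[k]] <- op[i, j[k]] + kern[k]
  }
  op
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with kernel standard deviation
#' `sigma = fwhm / 2.3548` per axis (mm converted to voxels via the grid's
#' voxel size), using reflective boundary handling. `fwhm = 0` is the
#' identity.
#'
#' @param map 3D array.
#' @param grid [voxel_grid] (supplies voxel sizes in mm).
#' @param fwhm_mm full width at half maximum of the kernel in mm (scalar or
#'   per-axis); must be >= 0.
#' @return Smoothed array of the same dimensions; attribute `boundary`
#'   records the boundary rule.
#' @export
smooth_map <- function(map, grid, fwhm_mm = 0.6) {
  if (any(fwhm_mm < 0)) stop("fwhm must be non-negative")
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  d <- dim(map)
  if (length(d) != 3L) stop("smooth_map expects a 3D array")
  out <- map
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm[ax] / 2.3548 / grid$voxel_size[ax]
    if (sigma_vox <= 0) next
    op <- gaussian_axis_operator(d[ax], sigma_vox)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), nrow = d[ax])
    m <- op %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  attr(out, "boundary") <- "reflective"
  out
}

# Second-order polynomial design matrix over normalised grid coordinates.
poly2_basis <- function(grid, idx = NULL) {
  co <- grid_coords(grid)
  nx <- as.vector(co$x) / max(abs(co$x))
  ny <- as.vector(co$y) / max(abs(co$y))
  nz <- as.vector(co$z) / max(abs(co$z))
  if (!is.null(idx)) {
    nx <- nx[idx]; ny <- ny[idx]; nz <- nz[idx]
  }
  cbind(1, nx, ny, nz, nx * ny, nx * nz, ny * nz, nx^2, ny^2, nz^2)
}

#' Estimate and remove a smooth intensity bias field
#'
#' Models the log-intensity inside the head mask as a tissue offset plus a
#' second-order polynomial bias and alternates (a) polynomial least squares
#' on the tissue-flattened log-intensity and (b) reassignment of voxels to
#' `n_classes` intensity classes (1D k-means style, quantile-initialised) on
#' the bias-free residual. The estimated multiplicative field is normalised
#' to mean 1 inside the mask and divided out of the whole volume.
#'
#' @param volume 3D intensity array, strictly positive inside the mask.
#' @param grid [voxel_grid].
#' @param mask logical array; default thresholds at 20 percent of the 98th
#'   intensity percentile.
#' @param priors optional [tissue_prob_maps]: when given, tissue offsets are
#'   estimated with prior-weighted class responsibilities instead of
#'   unsupervised clustering. Spatial priors break the degeneracy between a
#'   smooth field and tissue that occupies one spatial zone (a thin
#'   boundary compartment and a radial polynomial are otherwise
#'   confoundable).
#' @param n_classes number of tissue classes used to flatten anatomy
#'   (prior-free path).
#' @param n_iter alternation count.
#' @return Object of class `bias_correction`: `corrected`, `field`, `mask`.
#' @export
correct_bias <- function(volume, grid, mask = NULL, priors = NULL,
                         n_classes = 3L, n_iter = 4L) {
  if (is.null(mask))
    mask <- volume > 0.2 * stats::quantile(volume, 0.98, names = FALSE)
  idx <- which(mask)
  if (length(idx) < 50L) stop("head mask is empty or too small")
  if (any(volume[idx] <= 0))
    stop("non-positive voxel values inside the head mask")
  ly <- log(volume[idx])
  X <- poly2_basis(grid, idx)
  offset <- rep(0, length(idx))
  keep <- rep(TRUE, length(idx))
  beta <- NULL
  if (!is.null(priors)) {
    stopifnot(inherits(priors, "tissue_prob_maps"))
    pr <- cbind(gm = as.vector(priors$p_gm)[idx],
                wm = as.vector(priors$p_wm)[idx],
                csf = as.vector(priors$p_csf)[idx])
    pr <- pr + 1e-4
    # class log-means initialised from each class's most confident voxels
    m <- vapply(1:3, function(c) {
      w <- pr[, c]
      conf <- w >= max(0.5, stats::quantile(w, 0.999))
      if (!any(conf)) conf <- w >= stats::quantile(w, 0.999)
      stats::median(ly[conf])
    }, numeric(1))
    s <- 0.05  # initial log-intensity noise scale, shrunk data-driven below
    for (it in seq_len(max(n_iter, 8L))) {
      lf <- if (is.null(beta)) rep(0, length(idx)) else as.vector(X %*% beta)
      r <- ly - lf
      w <- pr * vapply(1:3, function(c) stats::dnorm(r, m[c], s),
                       numeric(length(r)))
      w <- w / pmax(rowSums(w), .Machine$double.xmin)
      a <- max.col(w)
      res <- r - m[a]
      # confident single-tissue voxels only: close to the class mean and
      # unambiguous posterior (drops partial-volume ramp voxels)
      conf <- abs(res) < 2.5 * s & pmax(w[, 1], w[, 2], w[, 3]) > 0.8
      if (sum(conf) < ncol(X) * 5) conf <- rep(TRUE, length(idx))
      for (c in 1:3) {
        sel <- conf & a == c
        if (sum(sel) > 50) m[c] <- mean(r[sel])
      }
      s <- max(stats::sd((r - m[a])[conf]), 5e-3)
      offset <- m[a]
      Xk <- X[conf, , drop = FALSE]
      beta <- solve(crossprod(Xk), crossprod(Xk, (ly - offset)[conf]))
    }
    lf_all <- as.vector(poly2_basis(grid) %*% beta)
    lf_all <- lf_all - mean(lf_all[idx])
    field <- array(exp(lf_all), grid$dims)
    return(structure(
      list(corrected = volume / field, field = field, mask = mask),
      class = "bias_correction"))
  }
  # prior-free path: intensity classes from quantile-initialised 1D k-means
  # on the bias-free residual; confident (trimmed) single-class voxels feed
  # the polynomial fit; indistinct classes are merged so a near-uniform
  # object does not shred the field into class offsets
  m <- stats::quantile(ly, (seq_len(n_classes) - 0.5) / n_classes,
                       names = FALSE)
  s <- 0.05
  for (it in seq_len(max(n_iter, 8L))) {
    lf <- if (is.null(beta)) rep(0, length(idx)) else as.vector(X %*% beta)
    r <- ly - lf
    a <- max.col(-abs(outer(r, m, "-")))
    res <- r - m[a]
    conf <- abs(res) < 2.5 * s
    for (c in seq_along(m)) {
      sel <- conf & a == c
      if (sum(sel) > 50) m[c] <- mean(r[sel])
    }
    # collapse indistinct classes (weighted) so a near-uniform object does
    # not shred the smooth field into class offsets
    repeat {
      m <- sort(m)
      gaps <- diff(m)
      if (length(m) == 1L || all(gaps >= 2.5 * s)) break
      j <- which.min(gaps)
      a0 <- max.col(-abs(outer(r, m, "-")))
      w1 <- sum(a0 == j); w2 <- sum(a0 == j + 1)
      merged <- (m[j] * w1 + m[j + 1] * w2) / max(w1 + w2, 1)
      m <- c(m[-c(j, j + 1)], merged)
    }
    a <- max.col(-abs(outer(r, m, "-")))
    res <- r - m[a]
    conf <- abs(res) < 2.5 * s
    if (sum(conf) < ncol(X) * 5) conf <- rep(TRUE, length(idx))
    s <- max(stats::sd(res[conf]), 5e-3)
    Xk <- X[conf, , drop = FALSE]
    beta <- solve(crossprod(Xk), crossprod(Xk, (ly - m[a])[conf]))
  }
  lf_all <- as.vector(poly2_basis(grid) %*% beta)
  lf_all <- lf_all - mean(lf_all[idx])   # mean-1 field inside the mask
  field <- array(exp(lf_all), grid$dims)
  structure(
    list(corrected = volume / field, field = field, mask = mask),
    class = "bias_correction"
  )
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf("bias_correction: field range %.3f-%.3f inside mask (%d voxels)\n",
              min(x$field[x$mask]), max(x$field[x$mask]), sum(x$mask)))
  invisible(x)
}

#' Prior-weighted Gaussian-mixture tissue segmentation
#'
#' Expectation-maximisation on a four-class Gaussian mixture (grey matter,
#' white matter, CSF, background) with voxel-wise spatial priors: the E-step
#' computes prior-weighted responsibilities, the M-step updates class means
#' and variances, until the log-likelihood improvement falls below `tol`
#' (relative) or `max_iter` is reached. Non-convergence flags the result
#' rather than raising. Priors are floored at a small epsilon so every class
#' remains reachable everywhere.
#'
#' @param volume 3D (bias-corrected) intensity array.
#' @param priors [tissue_prob_maps] supplying GM/WM/CSF priors; background
#'   prior is the per-voxel remainder.
#' @param max_iter,tol EM controls.
#' @param prior_floor epsilon mixed into the priors.
#' @param equal_variance constrain all classes to one pooled variance
#'   (default). Magnitude-MRI noise is class-independent, and the pooled
#'   model keeps a thin-compartment class from degenerating into a
#'   large-variance catch-all for partial-volume voxels.
#' @param partial_volume model interface voxels explicitly (default). In
#'   addition to the four pure classes, each anatomically adjacent tissue
#'   pair (GM/WM, GM/CSF, WM/CSF, CSF/background) gets a mixed class whose
#'   likelihood integrates a uniform mixing fraction between the two parent
#'   means; the posterior mass of a mixed class is reallocated to its
#'   parents by the estimated fraction. Without this, thin-compartment
#'   boundary voxels (e.g. the CSF/background ramp, whose intensity crosses
#'   the parenchymal means) are systematically misassigned.
#' @param mix_weight prior weight of a mixed class relative to the product
#'   of its parents' priors. Smoothed template priors understate how likely
#'   an interface voxel is to be truly mixed; the default was calibrated
#'   once on digital phantoms with known compartment volumes.
#' @param mask logical array restricting the EM to head voxels; off-mask
#'   voxels (no tissue prior, intensity far below tissue) are assigned pure
#'   background. Default: tissue prior > 1e-3 or intensity above 15 percent
#'   of the 98th percentile.
#' @return Object of class `tissue_segmentation`: posterior arrays
#'   `p_gm`, `p_wm`, `p_csf`, `p_bg`, class `means`/`vars`, `loglik` trace,
#'   `iterations`, `converged`, and the `grid`.
#' @export
segment_tissue <- function(volume, priors, max_iter = 50L, tol = 1e-6,
                           prior_floor = 1e-4, equal_variance = TRUE,
                           partial_volume = TRUE, mix_weight = 3,
                           mask = NULL) {
  stopifnot(inherits(priors, "tissue_prob_maps"))
  stopifnot_same_dims(volume, priors$p_gm, "volume and priors")
  grid <- priors$grid
  y_full <- as.vector(volume)
  tissue_prior <- as.vector(priors$p_gm + priors$p_wm + priors$p_csf)
  if (is.null(mask)) {
    # off-mask voxels are unambiguous background: no tissue prior and an
    # intensity far below tissue
    thr <- 0.15 * stats::quantile(y_full, 0.98, names = FALSE)
    mask <- tissue_prior > 1e-3 | y_full > thr
  }
  idx <- which(as.vector(mask))
  if (length(idx) < 100L) stop("segmentation mask is empty or too small")
  y <- y_full[idx]
  pure <- cbind(gm = as.vector(priors$p_gm)[idx],
                wm = as.vector(priors$p_wm)[idx],
                csf = as.vector(priors$p_csf)[idx])
  pure <- cbind(pure, bg = pmax(1 - rowSums(pure), 0))
  pure <- (1 - 4 * prior_floor) * pure + prior_floor
  k <- 4L
  pairs <- if (partial_volume)
    list(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(3L, 4L)) else list()
  # mixed-class priors from parent co-occurrence; renormalise all classes
  pr <- pure
  for (pp in pairs)
    pr <- cbind(pr, mix_weight * pure[, pp[1]] * pure[, pp[2]])
  pr <- pr / rowSums(pr)
  kk <- ncol(pr)

  # initialise each pure class from its most confident prior voxels (median
  # intensity there); thin compartments have few pure voxels, so a plain
  # prior-weighted mean would be dragged toward neighbouring tissue
  mu <- sg2 <- numeric(k)
  for (c in seq_len(k)) {
    w <- pure[, c]
    confident <- w >= max(0.5, stats::quantile(w, 0.999))
    if (!any(confident)) confident <- w >= stats::quantile(w, 0.999)
    mu[c] <- stats::median(y[confident])
    sg2[c] <- sum(w * (y - mu[c])^2) / sum(w)
  }
  var_floor <- (1e-4 * diff(range(y)))^2
  if (max(mu) - min(mu) < 1e-3 * diff(range(y))) {
    # uninformative (e.g. flat) priors: 1D k-means on intensity (farthest-
    # point init, deterministic), centres assigned in the conventional PDW
    # brightness order bg < wm < gm < csf
    cand <- stats::quantile(y, seq(0.001, 0.999, length.out = 256),
                            names = FALSE)
    ctr <- stats::median(y)
    while (length(ctr) < k) {
      dmin <- do.call(pmin, lapply(ctr, function(cc) abs(cand - cc)))
      ctr <- c(ctr, cand[which.max(dmin)])
    }
    for (km in 1:25) {
      a0 <- max.col(-abs(outer(y, ctr, "-")))
      new_ctr <- vapply(seq_len(k), function(c)
        if (any(a0 == c)) mean(y[a0 == c]) else ctr[c], numeric(1))
      if (max(abs(new_ctr - ctr)) < 1e-10) break
      ctr <- new_ctr
    }
    mu <- sort(ctr)[c(3L, 2L, 4L, 1L)]   # gm, wm, csf, bg
    sg2 <- rep(stats::var(y) / k^2, k)
  }
  if (equal_variance) sg2 <- rep(mean(sg2), k)
  sg2 <- pmax(sg2, var_floor)

  # density of a uniform-fraction mix of two Gaussian-noise tissues
  mix_density <- function(y, mu_a, mu_b, sd) {
    hi <- max(mu_a, mu_b); lo <- min(mu_a, mu_b)
    if (hi - lo < 1e-8 * max(abs(hi), 1))
      return(stats::dnorm(y, (hi + lo) / 2, sd))
    (stats::pnorm((y - lo) / sd) - stats::pnorm((y - hi) / sd)) / (hi - lo)
  }
  # conditional moments of the latent mixing fraction f | y for a mixed
  # voxel: f is a priori U(0,1), y | f ~ N(f*mu_a + (1-f)*mu_b, sd), so
  # f | y is a truncated normal on [0, 1]
  frac_moments <- function(y, mu_a, mu_b, sd) {
    gap <- mu_a - mu_b
    if (abs(gap) < 1e-8 * max(abs(mu_a), 1))
      return(list(m1 = rep(0.5, length(y)), m2 = rep(1 / 3, length(y))))
    f0 <- (y - mu_b) / gap
    sf <- sd / abs(gap)
    al <- (0 - f0) / sf
    be <- (1 - f0) / sf
    z <- pmax(stats::pnorm(be) - stats::pnorm(al), 1e-300)
    da <- stats::dnorm(al); db <- stats::dnorm(be)
    m1 <- f0 + sf * (da - db) / z
    m1 <- pmin(pmax(m1, 0), 1)
    v <- sf^2 * pmax(1 + (al * da - be * db) / z - ((da - db) / z)^2, 0)
    list(m1 = m1, m2 = pmin(m1^2 + v, 1))
  }

  loglik <- numeric(0)
  converged <- FALSE
  resp <- matrix(0, length(y), kk)
  for (it in seq_len(max_iter)) {
    for (c in seq_len(k))
      resp[, c] <- pr[, c] * stats::dnorm(y, mu[c], sqrt(sg2[c]))
    for (j in seq_along(pairs)) {
      pp <- pairs[[j]]
      resp[, k + j] <- pr[, k + j] *
        mix_density(y, mu[pp[1]], mu[pp[2]], sqrt(mean(sg2)))
    }
    tot <- rowSums(resp)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- resp / tot
    if (it > 1 && ll < loglik[it - 1]) {
      # safeguard: the approximate M-step (fixed mixing fractions) can in
      # principle overshoot; revert and stop at the best parameters
      mu <- mu_prev; sg2 <- sg2_prev; resp <- resp_prev
      converged <- TRUE
      break
    }
    loglik <- c(loglik, ll)
    mu_prev <- mu; sg2_prev <- sg2; resp_prev <- resp
    # M-step: means by weighted least squares over pure responsibilities
    # and mixed-class voxels (y ~ f*mu_a + (1-f)*mu_b at fixed f-hat) --
    # thin compartments with few pure voxels are anchored by their
    # interface voxels
    A <- matrix(0, k, k)
    bvec <- numeric(k)
    for (c in seq_len(k)) {
      A[c, c] <- A[c, c] + sum(resp[, c])
      bvec[c] <- bvec[c] + sum(resp[, c] * y)
    }
    fmom <- vector("list", length(pairs))
    for (j in seq_along(pairs)) {
      pp <- pairs[[j]]
      w <- resp[, k + j]
      fm <- frac_moments(y, mu[pp[1]], mu[pp[2]], sqrt(mean(sg2)))
      fmom[[j]] <- fm
      A[pp[1], pp[1]] <- A[pp[1], pp[1]] + sum(w * fm$m2)
      A[pp[2], pp[2]] <- A[pp[2], pp[2]] + sum(w * (1 - 2 * fm$m1 + fm$m2))
      off <- sum(w * (fm$m1 - fm$m2))
      A[pp[1], pp[2]] <- A[pp[1], pp[2]] + off
      A[pp[2], pp[1]] <- A[pp[2], pp[1]] + off
      bvec[pp[1]] <- bvec[pp[1]] + sum(w * fm$m1 * y)
      bvec[pp[2]] <- bvec[pp[2]] + sum(w * (1 - fm$m1) * y)
    }
    mu_new <- tryCatch(solve(A, bvec), error = function(e) mu)
    pooled <- 0
    for (c in seq_len(k))
      pooled <- pooled + sum(resp[, c] * (y - mu_new[c])^2)
    for (j in seq_along(pairs)) {
      pp <- pairs[[j]]
      fm <- fmom[[j]]
      gap <- mu_new[pp[1]] - mu_new[pp[2]]
      # E[(y - f*mu_a - (1-f)*mu_b)^2 | y] with the latent-f moments
      pooled <- pooled + sum(resp[, k + j] *
                               ((y - mu_new[pp[2]])^2 -
                                  2 * (y - mu_new[pp[2]]) * gap * fm$m1 +
                                  gap^2 * fm$m2))
    }
    mu <- mu_new
    if (equal_variance) {
      sg2 <- rep(max(pooled / length(y), var_floor), k)
    } else {
      for (c in seq_len(k)) {
        w <- resp[, c]
        if (sum(w) > 0)
          sg2[c] <- max(sum(w * (y - mu[c])^2) / sum(w), var_floor)
      }
    }
    if (it > 1 && abs(ll - loglik[it - 1]) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
  }
  # fold mixed-class mass back into the parents by the posterior expected
  # mixing fraction
  post <- resp[, seq_len(k), drop = FALSE]
  for (j in seq_along(pairs)) {
    pp <- pairs[[j]]
    fm <- frac_moments(y, mu[pp[1]], mu[pp[2]], sqrt(mean(sg2)))
    post[, pp[1]] <- post[, pp[1]] + resp[, k + j] * fm$m1
    post[, pp[2]] <- post[, pp[2]] + resp[, k + j] * (1 - fm$m1)
  }
  d <- grid$dims
  scatter <- function(col, fill) {
    v <- rep(fill, length(y_full))
    v[idx] <- col
    array(v, d)
  }
  structure(
    list(p_gm = scatter(post[, 1], 0), p_wm = scatter(post[, 2], 0),
         p_csf = scatter(post[, 3], 0), p_bg = scatter(post[, 4], 1),
         means = stats::setNames(mu, colnames(pure)),
         vars = stats::setNames(sg2, colnames(pure)),
         loglik = loglik, iterations = length(loglik),
         converged = converged, grid = grid,
         mask = array(as.vector(mask), d)),
    class = "tissue_segmentation"
  )
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat(sprintf("tissue_segmentation: %d EM iterations (%sconverged)\n",
              x$iterations, if (x$converged) "" else "NOT "))
  cat("  class means:",
      paste(sprintf("%s=%.3g", names(x$means), x$means), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.tissue_segmentation <- function(object, ...) {
  v <- compartment_volumes(object)
  cat("Prior-weighted Gaussian-mixture segmentation\n")
  print(object)
  cat(sprintf("  volumes (mm^3): CSF %.1f, GM %.1f, WM %.1f, parenchyma %.1f, TIV %.1f\n",
              v$csf, v$gm, v$wm, v$parenchyma, v$tiv))
  invisible(v)
}

#' Probabilistic compartment volumes
#'
#' Volume of each compartment as the sum of its per-voxel probability (or
#' posterior) times the voxel volume - soft counting without thresholding,
#' unbiased under partial-volume mixing. Parenchyma = GM + WM; total
#' intracranial volume (TIV) = parenchyma + CSF.
#'
#' @param x a [tissue_prob_maps] or [segment_tissue()] result.
#' @param grid optional [voxel_grid] override.
#' @return Object of class `compartment_volumes`: named list `csf`, `gm`,
#'   `wm`, `parenchyma`, `tiv` (mm^3; plus `background` when posteriors
#'   carry an explicit background class).
#' @export
compartment_volumes <- function(x, grid = NULL) {
  if (is.null(grid)) grid <- x$grid
  if (is.null(grid)) stop("a voxel_grid is required")
  vv <- grid$voxel_volume
  gm <- sum(x$p_gm) * vv
  wm <- sum(x$p_wm) * vv
  csf <- sum(x$p_csf) * vv
  out <- list(csf = csf, gm = gm, wm = wm, parenchyma = gm + wm,
              tiv = gm + wm + csf)
  if (!is.null(x$p_bg)) out$background <- sum(x$p_bg) * vv
  structure(out, class = "compartment_volumes")
}

#' @export
print.compartment_volumes <- function(x, ...) {
  cat(sprintf("compartment volumes (mm^3): CSF %.1f | GM %.1f | WM %.1f | parenchyma %.1f | TIV %.1f\n",
              x$csf, x$gm, x$wm, x$parenchyma, x$tiv))
  invisible(x)
}
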