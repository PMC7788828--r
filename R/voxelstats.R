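# Coerce a subject stack (list of 3D arrays, 4D array, or n x V matrix) to
# an n_subjects x n_voxels matrix plus remembered spatial dims.
as_subject_matrix <- function(stack) {
  if (is.list(stack)) {
    d <- dim(stack[[1]])
    m <- do.call(rbind, lapply(stack, as.vector))
    list(mat = m, dims = d)
  } else if (length(dim(stack)) == 4L) {
    d <- dim(stack)
    list(mat = t(matrix(stack, nrow = prod(d[1:3]), ncol = d[4])),
         dims = d[1:3])
  } else if (is.matrix(stack)) {
    list(mat = stack, dims = NULL)
  } else stop("stack must be a list of 3D arrays, a 4D array, or a matrix")
}

#' Voxel-wise paired t-test
#'
#' Computes, per voxel inside the analysis mask, the paired t statistic on
#' within-subject differences (condition A minus condition B) with n-1
#' degrees of freedom and its two-tailed p-value. Zero-variance voxels get
#' t = 0 and p = 1 by convention and are flagged, keeping map geometry
#' intact.
#'
#' @param stack_a,stack_b subject stacks (same subject ordering): lists of
#'   3D arrays, 4D arrays (subject last), or subject-by-voxel matrices.
#' @param analysis_mask logical array/vector of voxels to test; default all.
#' @return Object of class `stat_map`: `t_map`, `p_map`, `diff_map` (mean
#'   difference), `analysis_mask`, `zero_var`, `n_pairs`. Pass to
#'   [fdr_correct()] for q-values.
#' @export
paired_ttest_map <- function(stack_a, stack_b, analysis_mask = NULL) {
  a <- as_subject_matrix(stack_a)
  b <- as_subject_matrix(stack_b)
  if (nrow(a$mat) != nrow(b$mat))
    stop("subject counts differ between conditions")
  if (ncol(a$mat) != ncol(b$mat)) stop("voxel counts differ")
  n <- nrow(a$mat)
  if (n < 2L) stop("at least 2 subject pairs are required")
  if (is.null(analysis_mask)) analysis_mask <- rep(TRUE, ncol(a$mat))
  msk <- as.vector(analysis_mask)
  if (!any(msk)) stop("analysis mask is empty")

  d <- a$mat - b$mat
  mean_d <- colMeans(d)
  sd_d <- sqrt(colSums(sweep(d, 2, mean_d)^2) / (n - 1))
  zero_var <- sd_d == 0
  tt <- ifelse(zero_var, 0, mean_d / (sd_d / sqrt(n)))
  pp <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tt), df = n - 1))
  tt[!msk] <- NA_real_
  pp[!msk] <- NA_real_
  structure(
    list(t_map = reshape_map(tt, a$dims),
         p_map = reshape_map(pp, a$dims),
         diff_map = reshape_map(ifelse(msk, mean_d, NA_real_), a$dims),
         analysis_mask = reshape_map(msk, a$dims),
         zero_var = reshape_map(zero_var & msk, a$dims),
         n_pairs = n),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  nm <- sum(x$analysis_mask)
  cat(sprintf("stat_map: paired t over %d voxels, n = %d pairs (df = %d)\n",
              nm, x$n_pairs, x$n_pairs - 1))
  if (!is.null(x$q_map))
    cat(sprintf("  %d voxels significant at q <= %.3g (FDR %s)\n",
                sum(x$significant, na.rm = TRUE), x$q_level, x$fdr_method))
  invisible(x)
}

#' False-discovery-rate correction of a voxel-wise p map
#'
#' Benjamini-Hochberg step-up adjustment of the p-values inside the
#' analysis mask; a voxel is significant when its adjusted value is at most
#' `q_level` (equivalent to the step-up rejection rule). The conservative
#' Benjamini-Yekutieli variant is available as an option.
#'
#' @param x a [paired_ttest_map()] result, or a numeric p-value map.
#' @param analysis_mask mask (required when `x` is a bare p map; otherwise
#'   taken from the stat map).
#' @param q_level FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return For a `stat_map` input: the same object with `q_map`,
#'   `significant`, `q_level`, `fdr_method` added. For a bare p map: a list
#'   with `q_map` and `significant`.
#' @export
fdr_correct <- function(x, analysis_mask = NULL, q_level = 0.05,
                        method = c("BH", "BY")) {
  method <- match.arg(method)
  is_stat <- inherits(x, "stat_map")
  p_map <- if (is_stat) x$p_map else x
  if (is.null(analysis_mask))
    analysis_mask <- if (is_stat) x$analysis_mask else NULL
  if (is.null(analysis_mask)) analysis_mask <- !is.na(p_map)
  idx <- which(as.vector(analysis_mask))
  if (length(idx) == 0L) stop("analysis mask is empty")
  p <- as.vector(p_map)[idx]
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values inside the mask must lie in [0, 1]")
  q <- stats::p.adjust(p, method = method)
  q_map <- rep(NA_real_, length(as.vector(p_map)))
  q_map[idx] <- q
  sig <- rep(FALSE, length(q_map))
  sig[idx] <- q <= q_level
  dims <- if (is.null(dim(p_map))) NULL else dim(p_map)
  q_map <- reshape_map(q_map, dims)
  sig <- reshape_map(sig, dims)
  if (is_stat) {
    x$q_map <- q_map
    x$significant <- sig
    x$q_level <- q_level
    x$fdr_method <- method
    x
  } else {
    list(q_map = q_map, significant = sig, q_level = q_level,
         fdr_method = method)
  }
}

#' Paired t-test on compartment totals
#'
#' Classical two-tailed paired t-test on per-subject summary values (e.g.
#' compartment volumes in mm^3 or compartment-mean T2* in ms) between two
#' conditions, with group means and the percent difference.
#'
#' @param values_a,values_b numeric vectors ordered by subject, or
#'   data.frames with columns `subject` and `value` (matched by subject).
#' @param metric optional label carried into the output.
#' @return A one-row data.frame: `metric`, `n`, `mean_a`, `mean_b`,
#'   `mean_diff`, `pct_diff`, `t`, `df`, `p`.
#' @export
paired_total_test <- function(values_a, values_b, metric = NA_character_) {
  get_vals <- function(v) {
    if (is.data.frame(v)) {
      if (!all(c("subject", "value") %in% names(v)))
        stop("data.frame input needs 'subject' and 'value' columns")
      v[order(v$subject), ]
    } else data.frame(subject = seq_along(v), value = as.numeric(v))
  }
  a <- get_vals(values_a); b <- get_vals(values_b)
  if (nrow(a) != nrow(b) || !all(a$subject == b$subject))
    stop("subjects are not paired between conditions")
  d <- a$value - b$value
  if (stats::sd(d) == 0) {
    tt <- list(statistic = 0, parameter = nrow(a) - 1, p.value = 1)
    if (any(d != 0)) tt$p.value <- 0  # constant nonzero difference
  } else {
    tt <- stats::t.test(a$value, b$value, paired = TRUE)
  }
  data.frame(
    metric = metric, n = nrow(a),
    mean_a = mean(a$value), mean_b = mean(b$value),
    mean_diff = mean(d),
    pct_diff = 100 * mean(d) / mean(b$value),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Extract ROI means from parameter maps
#'
#' Mean of valid (non-NA) voxels of each metric map inside each region of
#' interest; invalid voxels are excluded and counted.
#'
#' @param metric_maps named list of 3D arrays (NA marks invalid voxels).
#' @param roi_masks named list of logical arrays sharing the maps' geometry.
#' @param subject,condition optional labels carried into the table.
#' @return data.frame with columns `roi`, `subject`, `condition`, `metric`,
#'   `value`, `n_valid`, `n_excluded`.
#' @export
roi_extract <- function(metric_maps, roi_masks, subject = NA,
                        condition = NA) {
  rows <- list()
  for (rn in names(roi_masks)) {
    roi <- roi_masks[[rn]]
    for (mn in names(metric_maps)) {
      map <- metric_maps[[mn]]
      stopifnot_same_dims(map, roi, paste("map", mn, "and ROI", rn))
      v <- map[roi]
      ok <- !is.na(v)
      if (!any(ok))
        stop("ROI '", rn, "' is empty after validity masking for '", mn, "'")
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rn, subject = subject, condition = condition, metric = mn,
        value = mean(v[ok]), n_valid = sum(ok), n_excluded = sum(!ok))
    }
  }
  do.call(rbind, rows)
}
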