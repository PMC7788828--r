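#' Generate a paired two-condition synthetic cohort
#'
#' Defines `n` subjects, each with its own anatomy (seed-jittered ellipsoid
#' shape and per-subject target volumes drawn around the nominal truth) that
#' is shared between the two conditions of a paired design. Condition
#' `"base"` uses the subject's own anatomy and MR parameters; condition
#' `"altered"` applies the [effect_spec]: CSF volume rescaling with
#' compensating parenchymal change, optional focal grey-matter swelling,
#' and a global T2* shift.
#'
#' The cohort object is lightweight (parameters only); materialise a
#' subject's tissue maps on demand with [cohort_subject()].
#'
#' @param n number of subjects (pairs).
#' @param grid [voxel_grid] shared by all subjects (common space).
#' @param truth nominal [compartment_truth]; `truth$volumes` are the
#'   population means of the base condition.
#' @param effect [effect_spec] for the altered condition.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param volume_sd between-subject SD of the CSF and parenchymal target
#'   volumes (mm^3).
#' @return Object of class `phantom_cohort` with a `subjects` table
#'   (per-subject seeds and target volumes).
#' @export
generate_cohort <- function(n = 12, grid = voxel_grid(c(96, 96, 64), 0.23),
                            truth = compartment_truth(),
                            effect = effect_spec(csf_scale = 190 / 180,
                                                 t2star_shift = -1.8),
                            seed = 1L,
                            volume_sd = c(csf = 19, parenchyma = 90)) {
  if (n < 2) stop("a paired cohort needs at least 2 subjects")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  vols <- truth$volumes
  paren <- vols[["gm"]] + vols[["wm"]]
  gm_frac <- vols[["gm"]] / paren
  csf_i <- pmax(vols[["csf"]] + stats::rnorm(n, 0, volume_sd[["csf"]]),
                0.5 * vols[["csf"]])
  paren_i <- pmax(paren + stats::rnorm(n, 0, volume_sd[["parenchyma"]]),
                  0.5 * paren)
  subjects <- data.frame(
    subject = seq_len(n),
    seed_anat = (as.integer(seed) * 10007L + seq_len(n) * 101L) %% 2147483647L,
    csf_mm3 = csf_i,
    gm_mm3 = paren_i * gm_frac,
    wm_mm3 = paren_i * (1 - gm_frac)
  )
  structure(list(n = n, grid = grid, truth = truth, effect = effect,
                 seed = as.integer(seed), subjects = subjects),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d paired subjects on %s grid\n", x$n,
              paste(x$grid$dims, collapse = "x")))
  cat(sprintf("  base volumes (mean mm^3): CSF %.0f, GM %.0f, WM %.0f; effect: CSF x%.4f, T2* %+.2f ms\n",
              mean(x$subjects$csf_mm3), mean(x$subjects$gm_mm3),
              mean(x$subjects$wm_mm3), x$effect$csf_scale,
              x$effect$t2star_shift))
  invisible(x)
}

#' Materialise one cohort subject
#'
#' Builds the subject's tissue probability maps (deterministically from the
#' stored per-subject seed) and the matching [compartment_truth], applying
#' the cohort's [effect_spec] when `condition = "altered"` (CSF/parenchyma
#' exchange on the maps; T2* shift on the truth).
#'
#' @param cohort a [generate_cohort()] result.
#' @param i subject index.
#' @param condition `"base"` or `"altered"`.
#' @return list with elements `maps` ([tissue_prob_maps]), `truth`
#'   ([compartment_truth] with this subject's volumes and condition T2*),
#'   and `true_volumes` ([compartment_volumes] of the returned maps).
#' @export
cohort_subject <- function(cohort, i, condition = c("base", "altered")) {
  condition <- match.arg(condition)
  if (i < 1 || i > cohort$n) stop("subject index out of range")
  s <- cohort$subjects[i, ]
  truth <- cohort$truth
  truth$volumes <- c(gm = s$gm_mm3, wm = s$wm_mm3, csf = s$csf_mm3)
  maps <- build_anatomy(cohort$grid, truth, seed = s$seed_anat)
  if (condition == "altered") {
    maps <- apply_condition_effect(maps, cohort$effect)
    truth$t2star <- truth$t2star + cohort$effect$t2star_shift
    if (any(truth$t2star <= 0)) stop("T2* shift produced non-positive T2*")
  }
  list(maps = maps, truth = truth,
       true_volumes = compartment_volumes(maps))
}

# Deterministic per-subject, per-condition, per-modality simulation seed.
modality_seed <- function(cohort, i, condition, modality) {
  cond_k <- if (condition == "base") 1L else 2L
  mod_k <- match(modality, c("pdw", "mge", "dwi"))
  (cohort$seed * 7919L + i * 613L + cond_k * 97L + mod_k * 13L) %% 2147483647L
}
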