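#' Multi-echo acquisition protocol
#'
#' Echo-time table of a multi-gradient-echo (MGE) sequence. The default is
#' 16 evenly spaced echoes from 2 to 32 ms.
#'
#' @param echo_times strictly increasing echo times in ms, all > 0.
#' @param repetition_time repetition time in ms.
#' @return Object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(echo_times = seq(2, 32, by = 2),
                                 repetition_time = 60) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1L || any(echo_times <= 0))
    stop("echo times must be positive (ms)")
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo times must be strictly increasing")
  structure(list(echo_times = echo_times,
                 repetition_time = as.numeric(repetition_time)),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("acquisition_protocol: %d echoes, TE %.3g-%.3g ms, TR %.3g ms\n",
              length(x$echo_times), min(x$echo_times), max(x$echo_times),
              x$repetition_time))
  invisible(x)
}

# Default b-range windows (s/mm^2): three disjoint intervals used for
# range-specific ADC mapping. The gaps (206-234, 1017-1116) are deliberate:
# a b-value falls in at most one window.
default_b_windows <- function() {
  list(low = c(20, 205), mid = c(235, 1016), high = c(1117, 2518))
}

# 57-b-value table: evenly spaced within each window, endpoints included
# (15 low / 21 mid / 21 high).
default_b_values <- function(windows = default_b_windows()) {
  round(c(seq(windows$low[1], windows$low[2], length.out = 15),
          seq(windows$mid[1], windows$mid[2], length.out = 21),
          seq(windows$high[1], windows$high[2], length.out = 21)), 1)
}

#' Diffusion-weighting protocol
#'
#' The b-value table, the three orthogonal gradient directions, and the
#' named b-range windows used for range-specific ADC mapping. The default is
#' a 57-b-value protocol spanning 20 to 2518 s/mm^2 with windows
#' low = 20-205, mid = 235-1016 and high = 1117-2518 s/mm^2, measured along
#' the read, phase and slice axes.
#'
#' @param b_values ascending b-values in s/mm^2, minimum >= 20 by default
#'   convention (spoiler-gradient floor); values in window gaps are allowed
#'   and simply excluded from every window.
#' @param directions 3 x n matrix of pairwise-orthogonal unit column
#'   vectors (default: the coordinate axes).
#' @param windows named list of `c(lo, hi)` intervals in s/mm^2; must be
#'   pairwise disjoint.
#' @return Object of class `diffusion_protocol`, with a `window_of` factor
#'   assigning each b-value to a window (NA = in a gap).
#' @export
diffusion_protocol <- function(b_values = default_b_values(),
                               directions = diag(3),
                               windows = default_b_windows()) {
  b_values <- as.numeric(b_values)
  if (is.unsorted(b_values)) stop("b_values must be sorted ascending")
  if (any(b_values < 0)) stop("b_values must be non-negative (s/mm^2)")
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L) stop("directions must be a 3 x n matrix")
  nrm <- sqrt(colSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  g <- crossprod(directions)
  if (any(abs(g[upper.tri(g)]) > 1e-6))
    stop("directions must be pairwise orthogonal")
  wmat <- do.call(rbind, windows)
  o <- order(wmat[, 1])
  if (any(wmat[o, 1][-1] <= wmat[o, 2][-length(windows)]))
    stop("windows must be pairwise disjoint")
  window_of <- rep(NA_character_, length(b_values))
  for (w in names(windows)) {
    inw <- b_values >= windows[[w]][1] & b_values <= windows[[w]][2]
    window_of[inw] <- w
  }
  structure(list(b_values = b_values, directions = directions,
                 windows = windows, window_of = window_of),
            class = "diffusion_protocol")
}

#' @export
print.diffusion_protocol <- function(x, ...) {
  cat(sprintf("diffusion_protocol: %d b-values, %.0f-%.0f s/mm^2, %d directions\n",
              length(x$b_values), min(x$b_values), max(x$b_values),
              ncol(x$directions)))
  for (w in names(x$windows))
    cat(sprintf("  %-4s window: %.0f-%.0f s/mm^2 (%d b-values)\n", w,
                x$windows[[w]][1], x$windows[[w]][2],
                sum(x$window_of == w, na.rm = TRUE)))
  invisible(x)
}

#' Write and read FSL-style bval/bvec files
#'
#' `write_bval_bvec()` writes one bval row (b repeated per direction) and
#' three bvec rows; `read_diffusion_protocol()` reads them back together
#' with an optional YAML descriptor carrying the window definitions.
#' The on-disk layout stores, for each b-value, one column per direction
#' (direction fastest), matching the volume ordering of [simulate_dwi()].
#'
#' @param protocol a [diffusion_protocol].
#' @param bval_path,bvec_path output/input text paths.
#' @param yaml_path optional YAML protocol descriptor (windows, echoes).
#' @return `read_diffusion_protocol()` returns a [diffusion_protocol].
#' @export
write_bval_bvec <- function(protocol, bval_path, bvec_path,
                            yaml_path = NULL) {
  nd <- ncol(protocol$directions)
  b_rep <- rep(protocol$b_values, each = nd)
  dirs <- protocol$directions[, rep(seq_len(nd), length(protocol$b_values)),
                              drop = FALSE]
  writeLines(paste(format(b_rep, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(dirs, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")), bvec_path)
  if (!is.null(yaml_path))
    yaml::write_yaml(list(windows = lapply(protocol$windows, as.numeric)),
                     yaml_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @param b_range_warn warn if any b lies outside this range (s/mm^2).
#' @export
read_diffusion_protocol <- function(bval_path, bvec_path, yaml_path = NULL,
                                    b_range_warn = c(20, 2518)) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(bvec_rows) != 3L) stop("bvec file must have exactly 3 rows")
  if (any(lengths(bvec_rows) != length(bvals)))
    stop("bval/bvec entry counts differ")
  bvecs <- do.call(rbind, bvec_rows)
  nrm <- sqrt(colSums(bvecs^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("bvec directions must be unit-norm")
  # collapse repeated (b, direction) columns back to unique bs + directions
  ub <- unique(bvals)
  nd <- length(bvals) / length(ub)
  if (nd != round(nd)) stop("b-value/direction layout is not rectangular")
  dirs <- bvecs[, seq_len(nd), drop = FALSE]
  if (any(bvals < b_range_warn[1] | bvals > b_range_warn[2]))
    warning(sprintf("b-values outside [%g, %g] s/mm^2", b_range_warn[1],
                    b_range_warn[2]))
  windows <- default_b_windows()
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    if (!is.null(y$windows))
      windows <- lapply(y$windows, as.numeric)
  }
  diffusion_protocol(b_values = ub, directions = dirs, windows = windows)
}
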