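#' Diffusion-weighted voxel stack
#'
#' Container for per-voxel diffusion-weighted signals. Axis order is fixed:
#' `signals[voxel, b, direction]`. Exactly one b-value must be 0 and all
#' b-values must be non-negative.
#'
#' @param signals Numeric array `(n_voxel, n_b, n_dir)`, arbitrary units.
#' @param b_values Diffusion weightings in s/mm^2, one per second axis
#'   entry; must contain 0 exactly once.
#' @param directions `n_dir x 3` matrix of gradient directions.
#' @return An object of class `dw_stack`.
#' @export
dw_stack <- function(signals, b_values, directions = default_directions()) {
  stopifnot(is.array(signals), length(dim(signals)) == 3L)
  if (dim(signals)[2] != length(b_values)) {
    stop_validation("second axis of 'signals' must match length(b_values)")
  }
  if (dim(signals)[3] != nrow(directions)) {
    stop_validation("third axis of 'signals' must match nrow(directions)")
  }
  if (any(b_values < 0)) stop_validation("negative b-value")
  if (sum(b_values == 0) != 1L) {
    stop_validation("exactly one b = 0 entry is required")
  }
  if (any(!is.finite(signals))) stop_validation("signals must be finite")
  structure(list(signals = signals, b_values = as.numeric(b_values),
                 directions = directions), class = "dw_stack")
}

#' The six-direction diffusion gradient scheme
#'
#' Normalized versions of the acquisition's gradient directions
#' (1,0,1), (-1,0,1), (0,1,1), (0,1,-1), (1,1,0), (-1,1,0).
#'
#' @return A 6 x 3 matrix of unit vectors.
#' @export
default_directions <- function() {
  d <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1),
             c(0, 1, -1), c(1, 1, 0), c(-1, 1, 0))
  d / sqrt(rowSums(d^2))
}

#' Region-of-interest voxel mask
#'
#' @param indices Voxel indices belonging to the ROI (non-empty, positive,
#'   unique).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0) stop_validation("ROI mask must be non-empty")
  if (any(indices < 1) || anyDuplicated(indices)) {
    stop_validation("ROI indices must be unique positive integers")
  }
  structure(indices, class = "roi_mask")
}

#' Voxel-wise isotropic ADC map from a diffusion-weighted stack
#'
#' Mono-exponential model: per direction `d` and diffusion weighting `b`,
#' `ADC_d = log(S(0, d) / S(b, d)) / b`; the isotropic ADC is the
#' arithmetic mean of the directional estimates, which is identical to the
#' ADC of the geometric-mean signal across directions. Voxels with any
#' non-positive signal cannot be log-transformed and are flagged invalid,
#' never silently zeroed.
#'
#' @param stack A [dw_stack()] with at least one positive b-value.
#' @return A list of class `adc_map`: `adc` (mm^2/s, `NA` where invalid)
#'   and `valid` (logical).
#' @export
compute_adc_map <- function(stack) {
  stopifnot(inherits(stack, "dw_stack"))
  b <- stack$b_values
  pos <- which(b > 0)
  if (length(pos) == 0) stop_validation("no nonzero b-value in the stack")
  i0 <- which(b == 0)
  s0 <- stack$signals[, i0, , drop = FALSE]    # (voxel, 1, dir)
  n_vox <- dim(stack$signals)[1]
  valid <- rep(TRUE, n_vox)
  acc <- numeric(n_vox)
  k <- 0L
  for (ib in pos) {
    sb <- stack$signals[, ib, , drop = FALSE]
    bad <- apply(sb <= 0 | s0 <= 0, 1, any)
    valid <- valid & !bad
    ratio <- log(pmax(s0, .Machine$double.xmin) /
                   pmax(sb, .Machine$double.xmin)) / b[ib]
    acc <- acc + rowMeans(ratio, dims = 1)
    k <- k + 1L
  }
  adc <- acc / k
  adc[!valid] <- NA_real_
  structure(list(adc = adc, valid = valid), class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %d voxels, %d invalid; mean valid ADC = %.4g mm^2/s\n",
              length(x$adc), sum(!x$valid), mean(x$adc[x$valid])))
  invisible(x)
}

#' ROI-mean ADC
#'
#' Arithmetic mean ADC over the valid voxels of a region of interest. The
#' fraction of ROI voxels excluded as invalid is attached as the
#' `excluded_fraction` attribute. Fails explicitly (no silent `NaN`) when
#' every ROI voxel is invalid.
#'
#' @param map An [compute_adc_map()] result.
#' @param roi An [roi_mask()].
#' @return Mean ADC in mm^2/s with an `excluded_fraction` attribute.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "adc_map"), inherits(roi, "roi_mask"))
  idx <- unclass(roi)
  if (any(idx > length(map$adc))) stop_validation("ROI index outside the map")
  ok <- map$valid[idx]
  if (!any(ok)) stop_validation("all ROI voxels are invalid")
  out <- mean(map$adc[idx][ok])
  attr(out, "excluded_fraction") <- mean(!ok)
  out
}
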