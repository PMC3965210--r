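#' Indicator design matrix from a state path
#'
#' `X[t, k] = 1` when `u_t = k`, else 0. Rows sum to 1 (states are
#' mutually exclusive); column sums equal the state dwell counts.
#'
#' @param path a [state_path()] or integer vector.
#' @param K number of states (defaults to the path's K).
#' @return T x K 0/1 matrix.
#' @export
build_design_matrix <- function(path, K = NULL) {
  pm <- path_meta(path, K = K)
  outer(pm$states, seq_len(pm$K), `==`) * 1
}

#' Partial-correlation spatial maps of the states
#'
#' For each voxel and state, the partial correlation between the envelope
#' time course and the state's indicator, given the other states'
#' indicators, in the no-intercept GLM on the indicator design: both voxel
#' and indicator are residualized on the remaining raw indicator columns
#' and the residuals correlated (uncentered), which equals
#' `t / sqrt(t^2 + df)` for that regressor's GLM t statistic. Mutually
#' exclusive indicators sum to one, so an intercept (equivalently, any
#' internal demeaning) would make the design exactly collinear and the
#' statistic degenerate; the GLM therefore carries no intercept and the
#' voxel time course enters as given. Envelope data should be demeaned per
#' voxel upstream (as [normalize_and_concatenate()] does), which is what
#' makes below-baseline states come out negative. The statistic is
#' invariant to rescaling each voxel but, deliberately, not to shifting
#' it.
#'
#' A state absent from the path carries no information: its column is
#' dropped with a warning and its coefficients are returned as `NA`.
#'
#' @param design T x K indicator matrix from [build_design_matrix()].
#' @param envelopes an [envelope_dataset()] or V x T matrix (full-rank
#'   envelope data, not PCA scores).
#' @return object of class `partial_correlation_map`: `coefficients`
#'   (K x V, in `[-1, 1]`), `states_present`, `threshold` (NULL until
#'   [threshold_map()] is applied).
#' @export
partial_correlation_maps <- function(design, envelopes) {
  X <- as.matrix(design)
  Y <- t(as_data_matrix(envelopes))             # T x V
  if (nrow(X) != nrow(Y))
    stop("design and envelope sample counts differ")
  K <- ncol(X); V <- ncol(Y)
  present <- which(colSums(X) > 0)
  if (length(present) < 2L)
    stop("at least 2 distinct states must be present in the path")
  if (length(present) < K)
    warning("state(s) ", paste(setdiff(seq_len(K), present), collapse = ", "),
            " absent from the path; coefficients set to NA")
  coef <- matrix(NA_real_, K, V)
  for (k in present) {
    others <- setdiff(present, k)
    Q <- qr.Q(qr(X[, others, drop = FALSE]))
    ey <- Y - Q %*% crossprod(Q, Y)
    ek <- as.numeric(X[, k] - Q %*% crossprod(Q, X[, k]))
    coef[k, ] <- colSums(ek * ey) /
      (sqrt(sum(ek^2)) * sqrt(colSums(ey^2)))
  }
  structure(list(coefficients = coef, states_present = present,
                 threshold = NULL),
            class = "partial_correlation_map")
}

#' @export
print.partial_correlation_map <- function(x, ...) {
  cat(sprintf("<partial_correlation_map> %d states x %d voxels%s\n",
              nrow(x$coefficients), ncol(x$coefficients),
              if (!is.null(x$threshold))
                sprintf(", thresholded at %g of max", x$threshold) else ""))
  invisible(x)
}

#' Threshold a partial-correlation map for display
#'
#' Per state, voxels with `|value| < lower_fraction * max(|value|)` are set
#' to `NA`; surviving positive and negative values are retained as-is.
#' Presentation only: thresholding never feeds back into statistics.
#'
#' @param map a [partial_correlation_maps()] result.
#' @param lower_fraction lower threshold as a fraction of the per-state
#'   maximum absolute correlation (e.g. 0.6 for a 60--100% display range).
#' @return thresholded `partial_correlation_map`.
#' @export
threshold_map <- function(map, lower_fraction = 0.6) {
  stopifnot(inherits(map, "partial_correlation_map"))
  if (lower_fraction < 0 || lower_fraction > 1)
    stop("lower_fraction must lie in [0, 1]")
  coef <- map$coefficients
  for (k in seq_len(nrow(coef))) {
    v <- coef[k, ]
    if (all(is.na(v))) next
    cut <- lower_fraction * max(abs(v), na.rm = TRUE)
    v[abs(v) < cut] <- NA_real_
    coef[k, ] <- v
  }
  map$coefficients <- coef
  map$threshold <- lower_fraction
  map
}

#' Write a voxel map as NIfTI
#'
#' Places a V-length vector of voxel values onto a regular grid defined by
#' the voxel coordinates (mm) and writes it with the RNifti package.
#'
#' @param values V-length numeric vector.
#' @param voxel_coords V x 3 matrix of coordinates on a regular grid.
#' @param path output `.nii`/`.nii.gz` file path.
#' @param spacing_mm grid spacing in mm (default 8, inferred spacing must
#'   divide the coordinate differences).
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(values, voxel_coords, path, spacing_mm = 8) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  voxel_coords <- as.matrix(voxel_coords)
  idx <- sweep(voxel_coords, 2L, apply(voxel_coords, 2L, min)) / spacing_mm
  if (max(abs(idx - round(idx))) > 1e-6)
    stop("voxel coordinates do not lie on a regular grid of ", spacing_mm,
         " mm")
  idx <- round(idx) + 1L
  dims <- apply(idx, 2L, max)
  arr <- array(NA_real_, dims)
  arr[cbind(idx[, 1L], idx[, 2L], idx[, 3L])] <- values
  img <- RNifti::asNifti(arr, pixdim = rep(spacing_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
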