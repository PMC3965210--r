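#' Estimate the sensor covariance matrix
#'
#' Sample covariance between all sensor pairs, optionally regularized by a
#' diagonal ridge scaled to the mean sensor variance:
#' `C + ridge_fraction * mean(diag(C)) * I`.
#'
#' @param recording a [sensor_recording()] or an N x T numeric matrix.
#' @param ridge_fraction non-negative ridge fraction (default 0, i.e. the
#'   plain sample covariance).
#' @return symmetric N x N covariance matrix.
#' @export
estimate_sensor_covariance <- function(recording, ridge_fraction = 0) {
  X <- if (inherits(recording, "sensor_recording")) recording$data
       else as.matrix(recording)
  if (ridge_fraction < 0) stop("ridge_fraction must be non-negative")
  C <- stats::cov(t(X))
  if (ridge_fraction > 0)
    C <- C + ridge_fraction * mean(diag(C)) * diag(nrow(C))
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("sensor covariance is singular (e.g. a constant channel); ",
         "use a positive ridge_fraction")
  C
}

#' Optimal dipole orientation for a scalar beamformer
#'
#' Returns the unit orientation maximizing the projected signal-to-noise
#' ratio `(v' H' C^-1 H v) / (v' H' C^-2 H v)`, solved as a 3 x 3
#' generalized eigenproblem. When the top generalized eigenvalues are
#' numerically degenerate (e.g. `C` proportional to the identity, where the
#' ratio is flat), the tie is broken by maximizing the projected power
#' `v' H' C^-1 H v` within the degenerate eigenspace, which reduces to the
#' leading right-singular direction of the whitened lead field. The sign is
#' fixed by making the largest-magnitude component positive.
#'
#' @param leadfield N x 3 lead-field matrix (or a list with elements
#'   `H` and optional `location`).
#' @param C invertible N x N sensor covariance.
#' @return unit 3-vector orientation.
#' @export
optimal_orientation <- function(leadfield, C) {
  loc <- NULL
  H <- if (is.list(leadfield) && !is.null(leadfield$H)) {
    loc <- leadfield$location
    as.matrix(leadfield$H)
  } else as.matrix(leadfield)
  # a zero column is an inactive orientation axis (no sensor can see it);
  # solve the reduced problem over the active axes and set its component
  # to zero. Linear dependence among the active columns is a genuine
  # rank deficiency and an error.
  cn <- sqrt(colSums(H^2))
  active <- which(cn > max(cn) * 1e-12)
  Ha <- H[, active, drop = FALSE]
  if (qr(Ha)$rank < length(active))
    stop("rank-deficient lead field",
         if (!is.null(loc)) paste0(" at location (",
                                   paste(signif(loc, 4), collapse = ", "), ")")
         else "")
  CinvH <- solve(C, Ha)
  A <- crossprod(Ha, CinvH)
  A <- (A + t(A)) / 2
  B <- crossprod(CinvH)          # PSD by construction
  s <- mean(diag(B))             # rescaling B leaves the ratio's argmax
  # extremely ill-conditioned C (e.g. near-rank-1 data with a tiny ridge)
  # can push B's smallest eigenvalue below rounding; escalate a relative
  # jitter until the factorization succeeds
  R <- NULL
  for (jit in c(0, 1e-12, 1e-9, 1e-6)) {
    R <- tryCatch(chol(B / s + jit * diag(nrow(B))), error = function(e) NULL)
    if (!is.null(R)) break
  }
  if (is.null(R)) stop("projected-noise matrix is numerically singular")
  Ri <- backsolve(R, diag(length(active)))
  S <- crossprod(Ri, A %*% Ri)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  deg <- which(e$values >= e$values[1L] * (1 - 1e-8))
  if (length(deg) > 1L) {
    # flat ratio: within the degenerate eigenspace, take the unit
    # (Euclidean) direction of maximal projected power v' H' C^-1 H v
    Vb <- Ri %*% e$vectors[, deg, drop = FALSE]
    G <- crossprod(Vb, A %*% Vb)
    Nb <- crossprod(Vb)
    R2 <- chol((Nb + t(Nb)) / 2)
    R2i <- backsolve(R2, diag(ncol(Vb)))
    G2 <- crossprod(R2i, ((G + t(G)) / 2) %*% R2i)
    w <- eigen((G2 + t(G2)) / 2, symmetric = TRUE)$vectors[, 1L]
    va <- as.numeric(Vb %*% (R2i %*% w))
  } else {
    va <- as.numeric(Ri %*% e$vectors[, 1L])
  }
  v <- numeric(3)
  v[active] <- va
  v <- v / sqrt(sum(v^2))
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

#' LCMV beamformer weights
#'
#' Linearly constrained minimum-variance weights
#' `w' = [h' C^-1 h]^-1 h' C^-1` for a scalar (orientation-resolved) lead
#' field `h`, satisfying the unit-gain constraint `w' h = 1`.
#'
#' @param h N-vector lead field at the chosen orientation.
#' @param C invertible N x N sensor covariance.
#' @param orientation optional unit 3-vector recorded with the weights.
#' @param location optional 3-vector recorded with the weights.
#' @return object of class `beamformer_weights` with elements `weights`,
#'   `orientation`, `location`.
#' @export
beamformer_weights <- function(h, C, orientation = NULL, location = NULL) {
  h <- as.numeric(h)
  if (all(h == 0)) stop("lead field is zero")
  Cinv_h <- solve(C, h)
  w <- Cinv_h / sum(h * Cinv_h)
  structure(list(weights = w, orientation = orientation,
                 location = location),
            class = "beamformer_weights")
}

#' Project sensor data and normalize by projected noise
#'
#' Projects the recording through the beamformer weights,
#' `q(t) = w' m(t)`, and scales by the square root of the projected
#' uncorrelated sensor-noise variance `w' w` (identity noise covariance):
#' `z(t) = q(t) / sqrt(w' w)`. This removes the depth bias of the
#' minimum-variance weights: for white sensor noise the normalized source
#' variance is independent of the lead-field scale.
#'
#' @param weights a [beamformer_weights()] object or an N-vector.
#' @param recording a [sensor_recording()] or N x T matrix.
#' @return numeric vector, the normalized source time course `z(t)`.
#' @export
project_and_normalize <- function(weights, recording) {
  w <- if (inherits(weights, "beamformer_weights")) weights$weights
       else as.numeric(weights)
  X <- if (inherits(recording, "sensor_recording")) recording$data
       else as.matrix(recording)
  if (length(w) != nrow(X))
    stop("weights length (", length(w), ") does not match channel count (",
         nrow(X), ")")
  q <- as.numeric(crossprod(w, X))
  q / sqrt(sum(w^2))
}

#' Full scalar-beamformer projection at one location
#'
#' Convenience wrapper: optimal orientation, LCMV weights, projection and
#' projected-noise normalization in one call.
#'
#' @inheritParams optimal_orientation
#' @param recording a [sensor_recording()] or N x T matrix.
#' @param ridge_fraction ridge fraction for the covariance estimate.
#' @return list with `timecourse`, `weights` (a [beamformer_weights()]),
#'   and `covariance`.
#' @export
beamform_location <- function(leadfield, recording, ridge_fraction = 0) {
  C <- estimate_sensor_covariance(recording, ridge_fraction)
  H <- if (is.list(leadfield) && !is.null(leadfield$H)) as.matrix(leadfield$H)
       else as.matrix(leadfield)
  phi <- optimal_orientation(leadfield, C)
  w <- beamformer_weights(as.numeric(H %*% phi), C, orientation = phi,
                          location = if (is.list(leadfield)) leadfield$location)
  list(timecourse = project_and_normalize(w, recording), weights = w,
       covariance = C)
}
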