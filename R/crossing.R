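#' @include tensor-core.R
NULL

#' Middle-to-lowest eigenvalue ratio
#'
#' The crossing-fibre marker \eqn{\lambda_2/\lambda_3}. A single coherent
#' fibre population gives a ratio near 1; two crossing populations inflate
#' \eqn{\lambda_2} and push the ratio up. If \eqn{\lambda_3 \le 0} (possible
#' in noisy fits) the ratio is returned as `Inf`, which any finite
#' threshold flags.
#'
#' @param eig an [EigenSystem-class], a [DiffusionTensor-class], or a
#'   numeric(3) of descending eigenvalues.
#' @return unitless scalar, `Inf` when \eqn{\lambda_3 \le 0}.
#' @examples
#' crossingRatio(c(1.7, 0.3, 0.3))  # 1
#' crossingRatio(c(1.0, 1.0, 0.3))  # 10/3
#' @export
crossingRatio <- function(eig) {
  if (is(eig, "DiffusionTensor")) eig <- eigenSystem(eig)
  v <- if (is(eig, "EigenSystem")) eig@values else as.numeric(eig)
  stopifnot(length(v) == 3L, all(is.finite(v) | v == Inf))
  if (v[3] <= 0) return(Inf)
  v[2] / v[3]
}

#' Flag crossing-fibre voxels of a tensor field
#'
#' A voxel is flagged when its middle-to-lowest eigenvalue ratio *strictly
#' exceeds* the threshold (default 1.8; a ratio of exactly 1.8 is not
#' flagged). Voxels with \eqn{\lambda_3 \le 0} are always flagged; voxels
#' outside the mask never are.
#'
#' @param field a [TensorField-class].
#' @param threshold eigenvalue-ratio threshold, > 1. Default 1.8.
#' @return a [FlagMap-class].
#' @seealso [adjustDecMap()], [criticalAngle()]
#' @export
flagCrossing <- function(field, threshold = 1.8) {
  stopifnot(is(field, "TensorField"), length(threshold) == 1L, threshold > 1)
  dm <- dim(field@tensors)[1:3]
  flags <- array(FALSE, dm)
  idx <- which(field@mask)
  if (length(idx)) {
    ev <- .eigvalsSym3(.tensorMatrixAt(field@tensors, idx))
    ratio <- ifelse(ev[3, ] <= 0, Inf, ev[2, ] / ev[3, ])
    flags[idx] <- ratio > threshold
  }
  new("FlagMap", flags = flags, threshold = threshold)
}

#' Darken flagged voxels of a diffusion-encoded colour map
#'
#' Sets all RGB channels to zero in crossing-flagged voxels; unflagged
#' voxels are returned unchanged.
#'
#' @param dec RGB array (nx, ny, nz, 3) as returned by [decMap()].
#' @param flags a [FlagMap-class] (or logical array) matching the grid.
#' @return RGB array of the same shape.
#' @export
adjustDecMap <- function(dec, flags) {
  f <- if (is(flags, "FlagMap")) flags@flags else flags
  dm <- dim(dec)
  if (length(dm) != 4L || dm[4] != 3L) stop("dec must be (nx, ny, nz, 3)")
  if (!identical(dim(f), dm[1:3])) stop("flag map shape does not match the colour map")
  out <- dec
  idx <- which(f)
  if (length(idx)) {
    n <- prod(dm[1:3])
    m <- matrix(out, n, 3)
    m[idx, ] <- 0
    out <- array(m, dm)
  }
  out
}

# single-fibre tensor: axially symmetric, axis u (unit), AD along u, RD across
.fibreTensor <- function(ad, rd, u) {
  rd * diag(3) + (ad - rd) * tcrossprod(u)
}

#' Two-fibre crossing mixture tensor
#'
#' The voxel-level tensor of two identical axially symmetric fibre
#' populations crossing at angle theta: \eqn{(1-f) D_1 + f D_2}, with the
#' first axis fixed along z and the second rotated by theta in the x--z
#' plane. For equal fractions the eigenvalues are
#' \eqn{\{RD + (AD-RD)(1 \pm \cos\theta)/2,\; RD\}}.
#'
#' @param ad,rd axial and radial diffusivities (\eqn{\mu m^2/ms}),
#'   ad >= rd >= 0.
#' @param theta crossing angle in degrees, in [0, 90].
#' @param fraction volume fraction of the second fibre, in [0, 1].
#'   Default 0.5 (equal fractions).
#' @return a [DiffusionTensor-class].
#' @examples
#' eigenSystem(mixTwoFibres(1.7, 0.3, 90))  # eigenvalues 1.0, 1.0, 0.3
#' @export
mixTwoFibres <- function(ad, rd, theta, fraction = 0.5) {
  stopifnot(ad >= rd, rd >= 0, theta >= 0, theta <= 90,
            fraction >= 0, fraction <= 1)
  th <- theta * pi / 180
  u1 <- c(0, 0, 1)
  u2 <- c(sin(th), 0, cos(th))
  m <- (1 - fraction) * .fibreTensor(ad, rd, u1) +
    fraction * .fibreTensor(ad, rd, u2)
  tensorFromMatrix(m)
}

#' Smallest crossing angle flagged by the eigenvalue-ratio criterion
#'
#' For the equal-fraction two-fibre mixture the ratio is
#' \eqn{\lambda_2/\lambda_3 = 1 + (AD-RD)(1-\cos\theta)/(2\,RD)},
#' monotone increasing on [0, 90] degrees. The boundary angle at which it
#' reaches the threshold is
#' \eqn{\theta_c = \arccos(1 - 2(t-1)\,RD/(AD-RD))}; crossings at angles
#' strictly above \eqn{\theta_c} are flagged. Returns `Inf` (a no-crossing
#' sentinel) when the ratio never exceeds the threshold on [0, 90], e.g.
#' for isotropic fibres.
#'
#' @param ad,rd axial and radial diffusivities, ad > rd > 0.
#' @param threshold eigenvalue-ratio threshold, >= 1.
#' @return boundary angle in degrees, or `Inf`.
#' @examples
#' criticalAngle(1.7, 0.3, 1.8)  # about 48.9 degrees, below 50
#' @export
criticalAngle <- function(ad, rd, threshold = 1.8) {
  if (threshold < 1) stop("threshold must be >= 1")
  stopifnot(ad > rd, rd > 0)
  if (threshold == 1) return(0)
  arg <- 1 - 2 * (threshold - 1) * rd / (ad - rd)
  if (arg <= 0) return(Inf)   # ratio at 90 degrees never exceeds threshold
  acos(arg) * 180 / pi
}

#' Sweep the crossing angle and report the eigenvalue ratio
#'
#' Numeric companion to [criticalAngle()]: evaluates the equal-fraction
#' two-fibre mixture over a grid of angles via full eigendecomposition and
#' reports the ratio profile plus the smallest angle whose ratio exceeds
#' the threshold.
#'
#' @param ad,rd axial and radial diffusivities.
#' @param threshold flagging threshold.
#' @param step angle step in degrees (default 0.01).
#' @return list: `theta` (degrees), `ratio`, `firstFlagged` (smallest swept
#'   angle with ratio > threshold; `Inf` if none).
#' @export
crossingAngleSweep <- function(ad, rd, threshold = 1.8, step = 0.01) {
  theta <- seq(0, 90, by = step)
  ratio <- vapply(theta, function(th)
    crossingRatio(eigenSystem(mixTwoFibres(ad, rd, th))), numeric(1))
  hit <- which(ratio > threshold)
  list(theta = theta, ratio = ratio,
       firstFlagged = if (length(hit)) theta[hit[1]] else Inf)
}
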