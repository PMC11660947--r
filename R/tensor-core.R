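#' @include AllGenerics.R
NULL

# ---- constructors ----------------------------------------------------------

#' Create a diffusion tensor from its six unique components
#'
#' Diffusivities are in \eqn{\mu m^2/ms} (so b = 1000 s/mm\eqn{^2}
#' corresponds to b = 1.0 ms/\eqn{\mu m^2} and white-matter values are O(1)).
#'
#' @param dxx,dyy,dzz,dxy,dxz,dyz tensor components in \eqn{\mu m^2/ms}.
#' @return a [DiffusionTensor-class].
#' @examples
#' diffusionTensor(1.7, 0.3, 0.3)
#' @export
diffusionTensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0) {
  d <- c(dxx = dxx, dyy = dyy, dzz = dzz, dxy = dxy, dxz = dxz, dyz = dyz)
  new("DiffusionTensor", components = d)
}

#' @describeIn diffusionTensor build from a symmetric 3 x 3 matrix.
#' @param m symmetric 3 x 3 matrix.
#' @export
tensorFromMatrix <- function(m) {
  stopifnot(identical(dim(m), c(3L, 3L)))
  if (max(abs(m - t(m))) > 1e-10) stop("matrix is not symmetric")
  diffusionTensor(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' Coerce a DiffusionTensor to a 3 x 3 matrix
#' @param x a [DiffusionTensor-class].
#' @param ... unused.
#' @export
setMethod("as.matrix", "DiffusionTensor", function(x, ...) {
  d <- x@components
  matrix(c(d["dxx"], d["dxy"], d["dxz"],
           d["dxy"], d["dyy"], d["dyz"],
           d["dxz"], d["dyz"], d["dzz"]), 3, 3,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
})

#' Create a gradient scheme from b-values and directions
#'
#' @param bValues numeric b-values in s/mm\eqn{^2}.
#' @param directions n x 3 matrix of unit vectors (rows for b = 0 may be
#'   zero; they are zeroed on construction).
#' @return a [GradientScheme-class].
#' @seealso [makeScheme()] for a synthetic uniformly-spread scheme.
#' @export
gradientScheme <- function(bValues, directions) {
  directions <- as.matrix(directions)
  dimnames(directions) <- NULL
  directions[bValues == 0, ] <- 0
  new("GradientScheme", bValues = as.numeric(bValues), directions = directions)
}

#' Construct a TensorField
#'
#' @param tensors array (nx, ny, nz, 6) with dxx, dyy, dzz, dxy, dxz, dyz
#'   along the 4th dimension.
#' @param mask logical array; defaults to all-TRUE.
#' @param voxelSize numeric(3) mm.
#' @param orientation mapping of grid axes to anatomy, default c("x","y","z").
#' @param labels integer site-label array (0 = none).
#' @param qc logical QC-flag array.
#' @return a [TensorField-class].
#' @export
tensorField <- function(tensors, mask = NULL, voxelSize = c(2, 2, 2),
                        orientation = c("x", "y", "z"), labels = NULL,
                        qc = NULL) {
  dm <- dim(tensors)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (is.null(labels)) labels <- array(0L, dm)
  if (is.null(qc)) qc <- array(FALSE, dm)
  new("TensorField", tensors = tensors, mask = mask,
      voxelSize = as.numeric(voxelSize), orientation = orientation,
      labels = labels, qc = qc)
}

# ---- internal math ---------------------------------------------------------

# b-value in ms/um^2 from s/mm^2: 1000 s/mm^2 == 1.0 ms/um^2
.bEff <- function(b) b / 1000

# Design matrix of the log-linear tensor model. Row i:
#   log S_i = log s0 - b_i (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                           + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
# Parameters: (log s0, dxx, dyy, dzz, dxy, dxz, dyz).
.designMatrix <- function(scheme) {
  b <- .bEff(scheme@bValues)
  g <- scheme@directions
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

# coerce tensor-ish input to named numeric(6)
.tensor6 <- function(tensor) {
  if (is(tensor, "DiffusionTensor")) return(tensor@components)
  if (is.matrix(tensor) && identical(dim(tensor), c(3L, 3L)))
    return(tensorFromMatrix(tensor)@components)
  if (is.numeric(tensor) && length(tensor) == 6L) {
    d <- as.numeric(tensor)
    names(d) <- .tensorNames
    return(d)
  }
  stop("tensor must be a DiffusionTensor, a symmetric 3x3 matrix, or numeric(6)")
}

# Vectorized eigenvalues of symmetric 3x3 tensors (Cardano / trigonometric
# form). `d6` is a 6 x n matrix with rows dxx, dyy, dzz, dxy, dxz, dyz.
# Returns a 3 x n matrix with rows lambda1 >= lambda2 >= lambda3.
.eigvalsSym3 <- function(d6) {
  dxx <- d6[1, ]; dyy <- d6[2, ]; dzz <- d6[3, ]
  dxy <- d6[4, ]; dxz <- d6[5, ]; dyz <- d6[6, ]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    bxx <- (dxx - q) / p; byy <- (dyy - q) / p; bzz <- (dzz - q) / p
    bxy <- dxy / p; bxz <- dxz / p; byz <- dyz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1n <- q + 2 * p * cos(phi)
    l3n <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2n <- 3 * q - l1n - l3n
    l1[nz] <- l1n[nz]; l2[nz] <- l2n[nz]; l3[nz] <- l3n[nz]
  }
  matrix(c(l1, l2, l3), nrow = 3, byrow = TRUE)
}

# FA from a 3 x n eigenvalue matrix; 0 for zero tensors by convention
.faFromEigvals <- function(ev) {
  md <- colMeans(ev)
  num <- (ev[1, ] - md)^2 + (ev[2, ] - md)^2 + (ev[3, ] - md)^2
  den <- ev[1, ]^2 + ev[2, ]^2 + ev[3, ]^2
  fa <- numeric(length(md))
  ok <- den > 0
  fa[ok] <- sqrt(1.5 * num[ok] / den[ok])
  fa
}

# tensors array (nx,ny,nz,6) -> 6 x n matrix for selected linear voxel indices
.tensorMatrixAt <- function(tensors, idx) {
  dm <- dim(tensors)
  nvox <- prod(dm[1:3])
  t(matrix(tensors, nvox, 6)[idx, , drop = FALSE])
}

# ---- operations ------------------------------------------------------------

#' Synthesize diffusion-weighted signals from a tensor
#'
#' Monoexponential tensor model \eqn{S = s_0 \exp(-b\, g^T D g)} evaluated
#' for every measurement of the scheme.
#'
#' @param tensor a positive-semidefinite [DiffusionTensor-class] (or 3 x 3
#'   matrix / numeric(6)).
#' @param scheme a [GradientScheme-class].
#' @param s0 signal at b = 0, > 0.
#' @return numeric vector of signals, one per scheme measurement.
#' @examples
#' sch <- makeScheme(30)
#' s <- synthesizeSignals(diffusionTensor(0.7, 0.7, 0.7), sch, s0 = 1)
#' s[bValues(sch) == 0]  # equals s0
#' @export
synthesizeSignals <- function(tensor, scheme, s0 = 1) {
  stopifnot(is(scheme, "GradientScheme"), s0 > 0)
  d <- .tensor6(tensor)
  if (min(.eigvalsSym3(matrix(d, 6, 1))) < -1e-12)
    stop("tensor has a negative eigenvalue; cannot synthesize signals")
  X <- .designMatrix(scheme)
  as.numeric(exp(X %*% c(log(s0), d)))
}

#' Fit a diffusion tensor by log-linear least squares
#'
#' Ordinary least squares on the log-signal model; deterministic and exact
#' on noiseless monoexponential data. Non-positive signals are clamped to a
#' small positive floor before the log transform and reported via the
#' `clamped` attribute.
#'
#' @param signals numeric vector of signals (one per scheme measurement).
#' @param scheme a [GradientScheme-class].
#' @param weighted if TRUE, follow the ordinary fit with one weighted
#'   refit using the fitted signals squared as weights (the usual
#'   variance model for log-transformed magnitudes). Identical to the
#'   ordinary fit on noiseless data.
#' @return a [DiffusionTensor-class]; attributes `s0` (fitted b = 0 signal)
#'   and `clamped` (TRUE if any signal needed clamping).
#' @export
fitTensor <- function(signals, scheme, weighted = FALSE) {
  stopifnot(is(scheme, "GradientScheme"))
  if (length(signals) != length(scheme@bValues))
    stop("signals and scheme disagree in length")
  if (length(signals) < 7L)
    stop("need at least 7 measurements (6 directions + b=0) to fit a tensor")
  X <- .designMatrix(scheme)
  if (qr(X)$rank < 7L)
    stop("singular design matrix: scheme directions are degenerate")
  floorVal <- max(signals, 0) * 1e-8 + .Machine$double.xmin
  clamped <- any(signals < floorVal)
  y <- log(pmax(signals, floorVal))
  beta <- qr.solve(X, y)
  if (weighted) {
    w <- exp(X %*% beta)^2                 # Var(log S) ~ sigma^2 / S^2
    beta <- qr.solve(X * sqrt(as.vector(w)), y * sqrt(as.vector(w)))
  }
  out <- diffusionTensor(beta[2], beta[3], beta[4], beta[5], beta[6], beta[7])
  attr(out, "s0") <- exp(beta[1])
  attr(out, "clamped") <- clamped
  out
}

#' Fit a diffusion tensor at every voxel of a DWI volume
#'
#' Vectorized log-linear fit over the whole grid. Voxels whose signals
#' needed clamping or whose fitted tensor is not positive semidefinite are
#' marked in the QC slot of the result (the tensor values themselves are
#' retained, so downstream ALPS arithmetic stays auditable).
#'
#' @param dwi numeric array (nx, ny, nz, nMeasurements).
#' @param scheme a [GradientScheme-class].
#' @param mask optional logical array; non-mask voxels get zero tensors.
#' @param voxelSize,orientation,labels passed to [tensorField()].
#' @return a [TensorField-class].
#' @export
fitTensorField <- function(dwi, scheme, mask = NULL, voxelSize = c(2, 2, 2),
                           orientation = c("x", "y", "z"), labels = NULL) {
  dm <- dim(dwi)
  stopifnot(length(dm) == 4L, dm[4] == length(scheme@bValues))
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  nvox <- prod(dm[1:3])
  S <- matrix(dwi, nvox, dm[4])
  idx <- which(mask)
  X <- .designMatrix(scheme)
  if (qr(X)$rank < 7L)
    stop("singular design matrix: scheme directions are degenerate")
  P <- solve(crossprod(X), t(X))        # (X'X)^-1 X'
  Sm <- S[idx, , drop = FALSE]
  floorVal <- max(Sm, 0) * 1e-8 + .Machine$double.xmin
  clampedVox <- rowSums(Sm < floorVal) > 0
  beta <- P %*% t(log(pmax(Sm, floorVal)))     # 7 x nmask
  tensors <- array(0, c(dm[1:3], 6L))
  tm <- matrix(tensors, nvox, 6)
  tm[idx, ] <- t(beta[-1, , drop = FALSE])
  tensors <- array(tm, c(dm[1:3], 6L))
  ev <- .eigvalsSym3(beta[-1, , drop = FALSE])
  nonPsd <- ev[3, ] < -1e-12
  qc <- array(FALSE, dm[1:3])
  qc[idx] <- clampedVox | nonPsd
  tensorField(tensors, mask = mask, voxelSize = voxelSize,
              orientation = orientation, labels = labels, qc = qc)
}

#' @rdname eigenSystem
#' @export
setMethod("eigenSystem", "DiffusionTensor", function(tensor) {
  m <- as.matrix(tensor)
  if (any(!is.finite(m))) stop("tensor components must be finite")
  e <- eigen(m, symmetric = TRUE)        # descending eigenvalues
  V <- e$vectors
  for (i in 1:3) {                       # sign fix: largest |component| > 0
    k <- which.max(abs(V[, i]))
    if (V[k, i] < 0) V[, i] <- -V[, i]
  }
  new("EigenSystem", values = e$values, vectors = V)
})

#' @rdname eigenSystem
#' @export
setMethod("eigenSystem", "matrix", function(tensor)
  eigenSystem(tensorFromMatrix(tensor)))

#' @rdname eigenSystem
#' @export
setMethod("eigenSystem", "numeric", function(tensor) {
  d <- .tensor6(tensor)
  eigenSystem(diffusionTensor(d[1], d[2], d[3], d[4], d[5], d[6]))
})

#' Scalar invariants of a diffusion tensor
#'
#' Fractional anisotropy
#' \eqn{FA = \sqrt{3/2 \cdot \sum_i(\lambda_i - MD)^2 / \sum_i \lambda_i^2}}
#' and mean diffusivity \eqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3}.
#' FA of a zero tensor is defined as 0.
#'
#' @param eig an [EigenSystem-class] (or a [DiffusionTensor-class], which
#'   is decomposed first).
#' @return list with elements `fa` (unitless, in [0, 1] for positive
#'   semidefinite tensors) and `md` (\eqn{\mu m^2/ms}).
#' @examples
#' scalarMaps(eigenSystem(diffusionTensor(1.7, 0.3, 0.3)))
#' @export
scalarMaps <- function(eig) {
  if (is(eig, "DiffusionTensor")) eig <- eigenSystem(eig)
  stopifnot(is(eig, "EigenSystem"))
  ev <- matrix(eig@values, 3, 1)
  list(fa = .faFromEigvals(ev), md = mean(eig@values))
}

#' Whole-field FA and MD maps
#'
#' @param field a [TensorField-class].
#' @return list of two 3D arrays, `fa` and `md`; zero outside the mask.
#' @export
scalarMapVolumes <- function(field) {
  stopifnot(is(field, "TensorField"))
  dm <- dim(field@tensors)[1:3]
  idx <- which(field@mask)
  ev <- .eigvalsSym3(.tensorMatrixAt(field@tensors, idx))
  fa <- md <- array(0, dm)
  fa[idx] <- .faFromEigvals(ev)
  md[idx] <- colMeans(ev)
  list(fa = fa, md = md)
}

#' Diffusion-encoded colour (DEC) map
#'
#' Per voxel the RGB channels are \eqn{FA \cdot |e_1|}: red = left--right
#' (x), green = anterior--posterior (y), blue = superior--inferior (z).
#' Values are clipped to [0, 1]; voxels outside the mask are black.
#'
#' @param field a [TensorField-class].
#' @return numeric array (nx, ny, nz, 3) with values in [0, 1].
#' @export
decMap <- function(field) {
  stopifnot(is(field, "TensorField"))
  dm <- dim(field@tensors)[1:3]
  rgb <- array(0, c(dm, 3L))
  idx <- which(field@mask)
  if (!length(idx)) return(rgb)
  d6 <- .tensorMatrixAt(field@tensors, idx)
  nvox <- prod(dm)
  rgbm <- matrix(rgb, nvox, 3)
  for (k in seq_along(idx)) {
    m <- matrix(c(d6[1, k], d6[4, k], d6[5, k],
                  d6[4, k], d6[2, k], d6[6, k],
                  d6[5, k], d6[6, k], d6[3, k]), 3, 3)
    e <- eigen(m, symmetric = TRUE)
    fa <- .faFromEigvals(matrix(e$values, 3, 1))
    rgbm[idx[k], ] <- pmin(pmax(fa * abs(e$vectors[, 1]), 0), 1)
  }
  array(rgbm, c(dm, 3L))
}
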