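#' @import methods
NULL

#' GradientScheme: a diffusion-weighting acquisition scheme
#'
#' Describes one diffusion-weighted acquisition: per-measurement b-values
#' (s/mm\eqn{^2}) and unit gradient directions in the anatomical frame
#' (x = left--right, y = anterior--posterior, z = superior--inferior).
#' Directions of b = 0 measurements are ignored and stored as zero vectors.
#'
#' @slot bValues numeric vector of b-values in s/mm\eqn{^2}.
#' @slot directions numeric matrix (n x 3) of unit direction vectors for
#'   b > 0 rows; rows may be zero where b = 0.
#'
#' @seealso [makeScheme()], [readGradientScheme()]
#' @export
setClass("GradientScheme",
  representation(bValues = "numeric", directions = "matrix"))

setValidity("GradientScheme", function(object) {
  b <- object@bValues
  g <- object@directions
  msg <- character()
  if (!is.numeric(g) || ncol(g) != 3L)
    msg <- c(msg, "directions must be an n x 3 numeric matrix")
  else if (nrow(g) != length(b))
    msg <- c(msg, "bValues and directions disagree in length")
  else {
    if (any(!is.finite(b)) || any(b < 0))
      msg <- c(msg, "bValues must be finite and non-negative")
    dwi <- b > 0
    if (!any(b == 0))
      msg <- c(msg, "scheme needs at least one b = 0 measurement")
    if (any(dwi)) {
      nrm <- sqrt(rowSums(g[dwi, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-8))
        msg <- c(msg, "diffusion directions must have unit norm (tol 1e-8)")
    }
    if (sum(dwi) >= 6L) {
      # at least 6 non-collinear directions: design for the 6 quadratic
      # forms must have full rank
      gg <- g[dwi, , drop = FALSE]
      X <- cbind(gg[, 1]^2, gg[, 2]^2, gg[, 3]^2,
                 2 * gg[, 1] * gg[, 2], 2 * gg[, 1] * gg[, 3],
                 2 * gg[, 2] * gg[, 3])
      if (qr(X)$rank < 6L)
        msg <- c(msg, "directions are degenerate: fewer than 6 independent orientations")
    } else {
      msg <- c(msg, "scheme needs at least 6 diffusion-weighted directions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DiffusionTensor: a single symmetric diffusion tensor
#'
#' Six unique components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in
#' \eqn{\mu m^2/ms}. Fitted tensors are not forced positive semidefinite;
#' negative eigenvalues are detectable via [eigenSystem()].
#'
#' @slot components named numeric(6): dxx, dyy, dzz, dxy, dxz, dyz.
#' @seealso [diffusionTensor()], [eigenSystem()], [scalarMaps()]
#' @export
setClass("DiffusionTensor", representation(components = "numeric"))

.tensorNames <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")

setValidity("DiffusionTensor", function(object) {
  d <- object@components
  if (length(d) != 6L || !identical(names(d), .tensorNames))
    return("components must be numeric(6) named dxx, dyy, dzz, dxy, dxz, dyz")
  TRUE
})

#' TensorField: a voxel grid of diffusion tensors
#'
#' The pipeline's central object: a 3D grid of symmetric tensors with a
#' brain mask, voxel size, an explicit grid-axis-to-anatomy mapping and
#' per-voxel QC flags from the fit.
#'
#' @slot tensors numeric array (nx, ny, nz, 6); the 4th dimension holds
#'   dxx, dyy, dzz, dxy, dxz, dyz in \eqn{\mu m^2/ms}.
#' @slot mask logical array (nx, ny, nz); TRUE = inside brain.
#' @slot voxelSize numeric(3) in mm.
#' @slot orientation character(3) mapping grid axes 1..3 to anatomical axes;
#'   must be a permutation of c("x", "y", "z") (x = left--right,
#'   y = anterior--posterior, z = superior--inferior).
#' @slot labels integer array (nx, ny, nz) of tissue/site labels (0 = none);
#'   the phantom generator uses 1 = projection-left, 2 = association-left,
#'   3 = projection-right, 4 = association-right.
#' @slot qc logical array (nx, ny, nz); TRUE flags voxels whose fit needed
#'   signal clamping or produced a non-positive-semidefinite tensor.
#' @export
setClass("TensorField",
  representation(tensors = "array", mask = "array", voxelSize = "numeric",
                 orientation = "character", labels = "array", qc = "array"))

setValidity("TensorField", function(object) {
  dt <- dim(object@tensors)
  msg <- character()
  if (length(dt) != 4L || dt[4] != 6L)
    msg <- c(msg, "tensors must be an (nx, ny, nz, 6) array")
  if (!identical(dim(object@mask), dt[1:3]))
    msg <- c(msg, "mask shape must match the tensor grid")
  if (!identical(dim(object@labels), dt[1:3]))
    msg <- c(msg, "labels shape must match the tensor grid")
  if (!identical(dim(object@qc), dt[1:3]))
    msg <- c(msg, "qc shape must match the tensor grid")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be positive numeric(3)")
  if (!identical(sort(object@orientation), c("x", "y", "z")))
    msg <- c(msg, "orientation must be a permutation of c('x','y','z')")
  if (length(msg)) msg else TRUE
})

#' EigenSystem: eigen-decomposition of one diffusion tensor
#'
#' @slot values numeric(3), eigenvalues sorted descending
#'   (\eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}), \eqn{\mu m^2/ms}.
#' @slot vectors 3 x 3 matrix; column i is the unit eigenvector of
#'   \eqn{\lambda_i}, sign-fixed so the largest-magnitude component is
#'   positive.
#' @export
setClass("EigenSystem", representation(values = "numeric", vectors = "matrix"))

setValidity("EigenSystem", function(object) {
  v <- object@values; V <- object@vectors
  msg <- character()
  if (length(v) != 3L || any(!is.finite(v))) msg <- c(msg, "values must be finite numeric(3)")
  else if (is.unsorted(rev(v))) msg <- c(msg, "eigenvalues must be in descending order")
  if (!identical(dim(V), c(3L, 3L))) msg <- c(msg, "vectors must be 3 x 3")
  else if (max(abs(crossprod(V) - diag(3))) > 1e-8)
    msg <- c(msg, "eigenvectors must be orthonormal (tol 1e-8)")
  if (length(msg)) msg else TRUE
})

#' FlagMap: crossing-fibre flags over a tensor field
#'
#' Boolean grid marking voxels whose middle-to-lowest eigenvalue ratio
#' exceeds the flagging threshold (or whose lowest eigenvalue is
#' non-positive). Produced by [flagCrossing()].
#'
#' @slot flags logical array (nx, ny, nz).
#' @slot threshold numeric(1), the eigenvalue-ratio threshold used (> 1).
#' @export
setClass("FlagMap", representation(flags = "array", threshold = "numeric"))

setValidity("FlagMap", function(object) {
  msg <- character()
  if (length(dim(object@flags)) != 3L) msg <- c(msg, "flags must be a 3D array")
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 1)
    msg <- c(msg, "threshold must be a single value > 1")
  if (length(msg)) msg else TRUE
})

#' ROISpec: a region of interest for ALPS extraction
#'
#' A small set of voxels (by default a 2 x 2 in-plane square at one slice)
#' in either the projection- or association-fibre site of one hemisphere.
#' Voxel indices are 1-based grid coordinates; file I/O converts from the
#' 0-based convention used on disk.
#'
#' @slot site "projection" or "association".
#' @slot hemisphere "left" or "right".
#' @slot voxels integer matrix (k x 3) of 1-based voxel indices, all sharing
#'   one slice (equal 3rd coordinate).
#' @slot mode "conventional" or "adjusted" placement.
#' @seealso [roiSpec()], [extractRoiDiffusivities()], [findCleanRoi()]
#' @export
setClass("ROISpec",
  representation(site = "character", hemisphere = "character",
                 voxels = "matrix", mode = "character"))

setValidity("ROISpec", function(object) {
  msg <- character()
  if (!object@site %in% c("projection", "association"))
    msg <- c(msg, "site must be 'projection' or 'association'")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (!object@mode %in% c("conventional", "adjusted"))
    msg <- c(msg, "mode must be 'conventional' or 'adjusted'")
  v <- object@voxels
  if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 1L)
    msg <- c(msg, "voxels must be a non-empty k x 3 index matrix")
  else {
    if (any(v < 1) || any(v != round(v)))
      msg <- c(msg, "voxel indices must be positive integers (1-based)")
    if (length(unique(v[, 3])) != 1L)
      msg <- c(msg, "all ROI voxels must share one slice")
  }
  if (length(msg)) msg else TRUE
})

#' ROIDiffusivities: per-ROI mean tensor diffusivities and scalars
#'
#' Mean Dxx/Dyy/Dzz, FA and MD over the included voxels of one ROI, with
#' bookkeeping of how many voxels were excluded by crossing-fibre flags.
#'
#' @slot site,hemisphere,mode as in [ROISpec-class].
#' @slot dxx,dyy,dzz mean diffusivities (\eqn{\mu m^2/ms}) over included voxels.
#' @slot fa,md mean fractional anisotropy (unitless) and mean diffusivity
#'   (\eqn{\mu m^2/ms}) over included voxels.
#' @slot nIncluded,nExcluded voxel counts; they sum to the ROI size.
#' @export
setClass("ROIDiffusivities",
  representation(site = "character", hemisphere = "character",
                 mode = "character", dxx = "numeric", dyy = "numeric",
                 dzz = "numeric", fa = "numeric", md = "numeric",
                 nIncluded = "integer", nExcluded = "integer"))

setValidity("ROIDiffusivities", function(object) {
  if (object@nIncluded < 1L) return("nIncluded must be >= 1")
  TRUE
})

#' ALPSResult: one ALPS index with its contributing ROI summaries
#'
#' @slot hemisphere "left" or "right".
#' @slot mode "conventional" or "adjusted".
#' @slot alps the ALPS index (unitless, > 0 for positive diffusivities).
#' @slot projection,association the contributing [ROIDiffusivities-class]
#'   pair.
#' @export
setClass("ALPSResult",
  representation(hemisphere = "character", mode = "character",
                 alps = "numeric",
                 projection = "ROIDiffusivities",
                 association = "ROIDiffusivities"))

#' CrossingConfig: parameters of the analytic crossing-fibre bias model
#'
#' The symbol set of the mixture model: axially symmetric projection and
#' association fibres with radial diffusivity Drad and perivascular
#' diffusivity Dpv along x (so Dxx,proj = Dxx,assoc = Drad + Dpv and
#' Dyy,proj = Dzz,assoc = Drad), mixed with an x-oriented crossing fibre
#' population of volume fraction fXp (projection site) and fXa
#' (association site).
#'
#' @slot drad fibre radial diffusivity (\eqn{\mu m^2/ms}), > 0.
#' @slot dpv perivascular diffusivity along x (\eqn{\mu m^2/ms}), >= 0.
#' @slot fxp,fxa crossing volume fractions in [0, 1].
#' @slot dxxCross,dyyCross,dzzCross crossing-fibre diffusivities
#'   (\eqn{\mu m^2/ms}); the closed-form bias is exact when the transverse
#'   values equal drad.
#' @seealso [crossingConfig()], [apparentAlps()], [apparentAlpsClosedForm()]
#' @export
setClass("CrossingConfig",
  representation(drad = "numeric", dpv = "numeric", fxp = "numeric",
                 fxa = "numeric", dxxCross = "numeric", dyyCross = "numeric",
                 dzzCross = "numeric"))

setValidity("CrossingConfig", function(object) {
  msg <- character()
  if (object@drad <= 0) msg <- c(msg, "drad must be > 0")
  if (object@dpv < 0) msg <- c(msg, "dpv must be >= 0")
  if (object@fxp < 0 || object@fxp > 1 || object@fxa < 0 || object@fxa > 1)
    msg <- c(msg, "crossing fractions must lie in [0, 1]")
  if (min(object@dxxCross, object@dyyCross, object@dzzCross) < 0)
    msg <- c(msg, "crossing-fibre diffusivities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: parameters of the synthetic periventricular phantom
#'
#' Describes a slab phantom at the level of the lateral ventricle body:
#' a z-oriented projection-fibre slab and a y-oriented association-fibre
#' slab per hemisphere, bordered by CSF, with perivascular diffusivity Dpv
#' added to Dxx throughout the fibre slabs and optional x-oriented
#' crossing-fibre mixtures inside the ROI annotation zones.
#'
#' @slot dims integer(3) grid shape (nx even and >= 12, ny >= 12, nz >= 1).
#' @slot voxelSize numeric(3) in mm.
#' @slot drad,dax fibre radial and axial diffusivities (\eqn{\mu m^2/ms}).
#' @slot dpv perivascular diffusivity added along x (\eqn{\mu m^2/ms}).
#' @slot dxxCross crossing-fibre axial (x) diffusivity; its transverse
#'   diffusivities equal drad.
#' @slot fxp,fxa per-voxel crossing fractions in the projection /
#'   association annotation zones.
#' @slot crossingPattern "full" (every zone voxel is a mixture) or
#'   "lattice" (period-2 lattice; any in-zone 2 x 2 ROI holds exactly one
#'   crossing voxel).
#' @slot csf CSF diffusivity (\eqn{\mu m^2/ms}).
#' @slot s0 non-diffusion-weighted signal.
#' @slot snr signal-to-noise ratio at b = 0 (Inf = noiseless).
#' @slot seed integer RNG seed for noise.
#' @seealso [phantomConfig()], [makePhantom()]
#' @export
setClass("PhantomConfig",
  representation(dims = "integer", voxelSize = "numeric", drad = "numeric",
                 dax = "numeric", dpv = "numeric", dxxCross = "numeric",
                 fxp = "numeric", fxa = "numeric", crossingPattern = "character",
                 csf = "numeric", s0 = "numeric", snr = "numeric",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  d <- object@dims
  if (length(d) != 3L || d[1] < 12L || d[1] %% 2L != 0L || d[2] < 12L || d[3] < 1L)
    msg <- c(msg, "dims must be (nx, ny, nz) with nx even >= 12, ny >= 12, nz >= 1")
  if (object@fxp < 0 || object@fxp > 1 || object@fxa < 0 || object@fxa > 1)
    msg <- c(msg, "crossing fractions must lie in [0, 1]")
  if (!object@crossingPattern %in% c("full", "lattice"))
    msg <- c(msg, "crossingPattern must be 'full' or 'lattice'")
  if (object@drad <= 0 || object@dax < object@drad)
    msg <- c(msg, "need dax >= drad > 0")
  if (object@dpv < 0) msg <- c(msg, "dpv must be >= 0")
  if (object@s0 <= 0) msg <- c(msg, "s0 must be > 0")
  if (!(object@snr > 0)) msg <- c(msg, "snr must be > 0 (Inf disables noise)")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth of a synthetic phantom
#'
#' @slot tensors generating tensor array (nx, ny, nz, 6), \eqn{\mu m^2/ms}.
#' @slot crossing logical array: TRUE where the voxel contains crossing
#'   fibres (flag ground truth).
#' @slot labels integer site labels as in [TensorField-class].
#' @slot trueAlps the true ALPS index 1 + Dpv/Drad of the phantom.
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("PhantomTruth",
  representation(tensors = "array", crossing = "array", labels = "array",
                 trueAlps = "numeric", config = "PhantomConfig"))

#' AlpsPhantom: a synthetic DWI volume with scheme and ground truth
#'
#' @slot dwi numeric array (nx, ny, nz, nMeasurements) of signals.
#' @slot scheme the [GradientScheme-class] used for synthesis.
#' @slot truth the [PhantomTruth-class].
#' @slot mask logical brain mask.
#' @seealso [makePhantom()], [analyzePhantom()]
#' @export
setClass("AlpsPhantom",
  representation(dwi = "array", scheme = "GradientScheme",
                 truth = "PhantomTruth", mask = "array"))

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Emulates the structure of a three-group study (healthy controls,
#' Parkinson's disease, progressive supranuclear palsy) with per-group
#' distributions of perivascular diffusivity, fibre radial diffusivity and
#' crossing-fibre fraction, plus a synthetic clinical score coupled to the
#' perivascular diffusivity at a stated correlation.
#'
#' @slot groups data.frame with one row per group and columns: group, n,
#'   dpvMean, dpvSd, dradMean, dradSd, fxMean, fxSd, scoreMean, scoreSd,
#'   scoreCor (NA = no score for that group).
#' @slot hemispheres character, subset of c("left", "right").
#' @slot phantomDims integer(3) per-subject phantom grid.
#' @slot snr SNR at b = 0 for subject phantoms.
#' @slot s0 non-weighted signal.
#' @slot searchRadius clean-ROI search radius (voxels) for the adjusted
#'   annotation.
#' @slot seed integer master RNG seed.
#' @seealso [cohortConfig()], [makeCohort()]
#' @export
setClass("CohortConfig",
  representation(groups = "data.frame", hemispheres = "character",
                 phantomDims = "integer", snr = "numeric", s0 = "numeric",
                 searchRadius = "integer", seed = "integer"))

setValidity("CohortConfig", function(object) {
  g <- object@groups
  need <- c("group", "n", "dpvMean", "dpvSd", "dradMean", "dradSd",
            "fxMean", "fxSd", "scoreMean", "scoreSd", "scoreCor")
  msg <- character()
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("groups must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(g$n < 1)) msg <- c(msg, "group sizes must be >= 1")
    if (any(g$dpvSd < 0) || any(g$dradSd < 0) || any(g$fxSd < 0))
      msg <- c(msg, "SDs must be >= 0")
    sc <- g$scoreCor[!is.na(g$scoreCor)]
    if (any(sc < -1 | sc > 1)) msg <- c(msg, "scoreCor must lie in [-1, 1]")
  }
  if (!all(object@hemispheres %in% c("left", "right")) ||
      length(object@hemispheres) < 1L)
    msg <- c(msg, "hemispheres must be a subset of c('left','right')")
  if (length(msg)) msg else TRUE
})
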