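#' @include crossing.R
NULL

#' Create an ROI specification
#'
#' @param site "projection" or "association".
#' @param hemisphere "left" or "right".
#' @param voxels k x 3 matrix of 1-based voxel indices sharing one slice.
#' @param mode "conventional" or "adjusted".
#' @return an [ROISpec-class].
#' @export
roiSpec <- function(site, hemisphere, voxels, mode = "conventional") {
  voxels <- matrix(as.integer(round(voxels)), ncol = 3)
  new("ROISpec", site = site, hemisphere = hemisphere, voxels = voxels,
      mode = mode)
}

#' @describeIn roiSpec a square in-plane ROI (default 2 x 2) whose
#'   lowest-index corner is at `corner = c(x, y)` on slice `slice`.
#' @param corner integer(2), 1-based in-plane position of the ROI corner.
#' @param slice 1-based slice index.
#' @param size side length in voxels (default 2).
#' @export
squareRoi <- function(site, hemisphere, corner, slice, size = 2,
                      mode = "conventional") {
  g <- expand.grid(x = corner[1] + seq_len(size) - 1L,
                   y = corner[2] + seq_len(size) - 1L)
  roiSpec(site, hemisphere, cbind(g$x, g$y, slice), mode)
}

.roiLinearIndex <- function(voxels, dm) {
  voxels[, 1] + dm[1] * (voxels[, 2] - 1L) + dm[1] * dm[2] * (voxels[, 3] - 1L)
}

# shared core of ROI summarisation: means of tensor components and
# FA/MD over the kept voxels (linear indices)
.roiStats <- function(tensors, idx, flagsArr = NULL, adjusted = FALSE) {
  keep <- rep(TRUE, length(idx))
  if (adjusted) {
    keep <- !flagsArr[idx]
    if (!any(keep))
      stop("all ROI voxels are crossing-flagged; relocate ROI (see findCleanRoi)")
  }
  d6 <- .tensorMatrixAt(tensors, idx[keep])
  ev <- .eigvalsSym3(d6)
  list(dxx = mean(d6[1, ]), dyy = mean(d6[2, ]), dzz = mean(d6[3, ]),
       fa = mean(.faFromEigvals(ev)), md = mean(colMeans(ev)),
       nIncluded = sum(keep), nExcluded = sum(!keep))
}

# fast clean-ROI search over square candidates: returns the best corner
# c(x, y) or NULL. Offsets are the ROI voxel positions relative to its
# lowest corner; `lab` restricts to one tissue label (NA = no restriction).
.cleanCorner <- function(flagsArr, maskArr, labArr, dm, corner, offsets,
                         slice, lab, radius) {
  zoff <- dm[1] * dm[2] * (slice - 1L)
  ow <- max(offsets[, 1]); oh <- max(offsets[, 2])
  best <- NULL
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      cx <- corner[1] + dx; cy <- corner[2] + dy
      if (cx < 1L || cy < 1L || cx + ow > dm[1] || cy + oh > dm[2]) next
      idx <- zoff + (cx + offsets[, 1]) + dm[1] * (cy + offsets[, 2] - 1L)
      if (!all(maskArr[idx])) next
      if (!is.na(lab) && !all(labArr[idx] == lab)) next
      nf <- sum(flagsArr[idx])
      dist2 <- dx * dx + dy * dy
      lin <- cx + dm[1] * (cy - 1L)
      if (is.null(best) || nf < best[1] ||
          (nf == best[1] && (dist2 < best[2] ||
                             (dist2 == best[2] && lin < best[3]))))
        best <- c(nf, dist2, lin, cx, cy)
    }
  }
  if (is.null(best) || best[1] >= nrow(offsets)) return(NULL)
  best[4:5]
}

#' Mean diffusivities of an ROI
#'
#' Averages the tensor components (and FA/MD) over the ROI voxels. In
#' "conventional" mode all voxels contribute; in "adjusted" mode
#' crossing-flagged voxels are excluded and counted. Means are taken on
#' the tensor components first; the ALPS ratio is applied afterwards by
#' [alpsIndex()].
#'
#' @param field a [TensorField-class].
#' @param roi an [ROISpec-class], fully inside the grid.
#' @param flags a [FlagMap-class]; required when `mode = "adjusted"`.
#' @param mode "conventional" or "adjusted"; defaults to the ROI's own mode.
#' @return an [ROIDiffusivities-class].
#' @export
extractRoiDiffusivities <- function(field, roi, flags = NULL, mode = NULL) {
  stopifnot(is(field, "TensorField"), is(roi, "ROISpec"))
  if (is.null(mode)) mode <- roi@mode
  mode <- match.arg(mode, c("conventional", "adjusted"))
  dm <- dim(field@tensors)[1:3]
  v <- roi@voxels
  if (any(v[, 1] > dm[1]) || any(v[, 2] > dm[2]) || any(v[, 3] > dm[3]))
    stop("ROI extends outside the grid")
  idx <- .roiLinearIndex(v, dm)
  f <- NULL
  if (mode == "adjusted") {
    if (is.null(flags)) stop("adjusted mode requires a flag map")
    f <- if (is(flags, "FlagMap")) flags@flags else flags
  }
  st <- .roiStats(field@tensors, idx, f, adjusted = mode == "adjusted")
  new("ROIDiffusivities",
      site = roi@site, hemisphere = roi@hemisphere, mode = mode,
      dxx = st$dxx, dyy = st$dyy, dzz = st$dzz, fa = st$fa, md = st$md,
      nIncluded = st$nIncluded, nExcluded = st$nExcluded)
}

#' The ALPS index
#'
#' \deqn{ALPS = \frac{D_{xx,proj} + D_{xx,assoc}}{D_{yy,proj} + D_{zz,assoc}}}
#'
#' the ratio of the x-diffusivities (along the perivascular space of the
#' deep medullary veins) to the fibre-transverse diffusivities in the
#' projection and association ROIs.
#'
#' @param proj [ROIDiffusivities-class] of the projection-fibre ROI (or a
#'   numeric Dxx,proj when called with four scalars, see Details).
#' @param assoc [ROIDiffusivities-class] of the association-fibre ROI.
#' @details For scripted use `alpsIndex(proj, assoc)` also accepts plain
#'   numeric input as `alpsIndex(c(dxx = , dyy = ), c(dxx = , dzz = ))`.
#' @return unitless scalar > 0 for positive diffusivities.
#' @examples
#' alpsIndex(c(dxx = 0.9, dyy = 0.6), c(dxx = 0.9, dzz = 0.6))  # 1.5
#' @export
alpsIndex <- function(proj, assoc) {
  if (is(proj, "ROIDiffusivities")) {
    stopifnot(is(assoc, "ROIDiffusivities"))
    if (proj@site != "projection" || assoc@site != "association")
      stop("alpsIndex expects a (projection, association) ROI pair")
    num <- proj@dxx + assoc@dxx
    den <- proj@dyy + assoc@dzz
  } else {
    num <- proj[["dxx"]] + assoc[["dxx"]]
    den <- proj[["dyy"]] + assoc[["dzz"]]
  }
  if (!(den > 0)) stop("non-positive ALPS denominator")
  num / den
}

#' True ALPS index of the axially symmetric fibre model
#'
#' With Dxx,proj = Dxx,assoc = Drad + Dpv and Dyy,proj = Dzz,assoc = Drad,
#' the ALPS ratio reduces to \eqn{1 + D_{pv}/D_{rad}}.
#'
#' @param dpv perivascular diffusivity (\eqn{\mu m^2/ms}), >= 0.
#' @param drad fibre radial diffusivity (\eqn{\mu m^2/ms}), > 0.
#' @return unitless scalar >= 1.
#' @export
trueAlps <- function(dpv, drad) {
  if (any(drad <= 0)) stop("drad must be > 0")
  if (any(dpv < 0)) stop("dpv must be >= 0")
  1 + dpv / drad
}

#' Relocate an ROI to avoid crossing-flagged voxels
#'
#' Searches, on the seed ROI's slice and within the same site tissue label,
#' for the same-shaped ROI with the fewest crossing-flagged voxels —
#' an automated stand-in for re-annotating ROIs on the adjusted colour
#' map. Ties are broken by distance to the seed, then by smallest linear
#' index (deterministic).
#'
#' @param field a [TensorField-class]; its `labels` slot (when non-zero)
#'   restricts candidates to the seed ROI's tissue label.
#' @param flags a [FlagMap-class].
#' @param seedRoi the conventional [ROISpec-class] to start from.
#' @param searchRadius Chebyshev in-plane radius in voxels (default 3).
#' @return an [ROISpec-class] with mode "adjusted".
#' @export
findCleanRoi <- function(field, flags, seedRoi, searchRadius = 3L) {
  stopifnot(is(field, "TensorField"), is(seedRoi, "ROISpec"))
  f <- if (is(flags, "FlagMap")) flags@flags else flags
  dm <- dim(field@tensors)[1:3]
  v <- seedRoi@voxels
  slice <- v[1, 3]
  corner <- c(min(v[, 1]), min(v[, 2]))
  offsets <- cbind(v[, 1] - corner[1], v[, 2] - corner[2])
  labs <- field@labels
  seedLab <- labs[cbind(v[, 1], v[, 2], v[, 3])]
  lab <- if (all(seedLab == 0L)) NA_integer_ else
    as.integer(names(which.max(table(seedLab[seedLab != 0L]))))
  best <- .cleanCorner(f, field@mask, labs, dm, corner, offsets, slice,
                       lab, as.integer(searchRadius))
  if (is.null(best))
    stop("no candidate ROI with an unflagged voxel in the search window; ",
         "enlarge searchRadius or re-annotate")
  vox <- cbind(best[1] + offsets[, 1], best[2] + offsets[, 2], slice)
  roiSpec(seedRoi@site, seedRoi@hemisphere, vox, mode = "adjusted")
}

#' Compute conventional and/or adjusted ALPS for one hemisphere
#'
#' Combines ROI extraction, optional clean-ROI relocation and the ALPS
#' ratio. Adjusted handling follows `adjust`: "relocate" (default) moves
#' each ROI to the least-flagged candidate via [findCleanRoi()];
#' "exclude" keeps the ROI but averages only unflagged voxels.
#'
#' @param field a [TensorField-class].
#' @param projRoi,assocRoi conventional [ROISpec-class] pair for one
#'   hemisphere.
#' @param flags a [FlagMap-class] (required unless mode = "conventional").
#' @param mode "conventional", "adjusted" or "both".
#' @param adjust "relocate" or "exclude".
#' @param searchRadius passed to [findCleanRoi()].
#' @return list of [ALPSResult-class], one per computed mode.
#' @export
computeAlps <- function(field, projRoi, assocRoi, flags = NULL,
                        mode = c("both", "conventional", "adjusted"),
                        adjust = c("relocate", "exclude"), searchRadius = 3L) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (projRoi@hemisphere != assocRoi@hemisphere)
    stop("projection and association ROIs must be in the same hemisphere")
  out <- list()
  if (mode %in% c("both", "conventional")) {
    p <- extractRoiDiffusivities(field, projRoi, mode = "conventional")
    a <- extractRoiDiffusivities(field, assocRoi, mode = "conventional")
    out$conventional <- new("ALPSResult", hemisphere = projRoi@hemisphere,
                            mode = "conventional", alps = alpsIndex(p, a),
                            projection = p, association = a)
  }
  if (mode %in% c("both", "adjusted")) {
    if (is.null(flags)) stop("adjusted mode requires a flag map")
    if (adjust == "relocate") {
      # a relocated ROI is a fresh annotation on the adjusted map and is
      # measured like any ROI (all voxels); voxel-exclusion is the
      # alternative 'exclude' pathway
      pr <- findCleanRoi(field, flags, projRoi, searchRadius)
      ar <- findCleanRoi(field, flags, assocRoi, searchRadius)
      p <- extractRoiDiffusivities(field, pr, mode = "conventional")
      a <- extractRoiDiffusivities(field, ar, mode = "conventional")
      p@mode <- "adjusted"; a@mode <- "adjusted"
    } else {
      p <- extractRoiDiffusivities(field, projRoi, flags, mode = "adjusted")
      a <- extractRoiDiffusivities(field, assocRoi, flags, mode = "adjusted")
    }
    out$adjusted <- new("ALPSResult", hemisphere = projRoi@hemisphere,
                        mode = "adjusted", alps = alpsIndex(p, a),
                        projection = p, association = a)
  }
  out
}
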