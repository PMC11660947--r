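#' @include phantom.R
NULL

#' Create a cohort configuration
#'
#' Default group structure emulates a three-group movement-disorder study:
#' healthy controls (n = 41), Parkinson's disease (n = 60) and progressive
#' supranuclear palsy (n = 17). Per-group means of perivascular
#' diffusivity, radial diffusivity and crossing-fibre fraction are
#' calibrated so that group-mean conventional and adjusted ALPS indices
#' fall in the ranges reported for such cohorts (adjusted ~1.43 / 1.41 /
#' 1.26 and conventional-minus-adjusted differences ~0.12 / 0.10 / 0.05
#' for HC / PD / PSP). The clinical score emulates a motor-severity scale
#' (PD 10.7 +/- 8.3, PSP 37.8 +/- 16.3), coupled to the per-subject
#' perivascular diffusivity at the configured correlation.
#'
#' @param groups data.frame of group parameters; see
#'   [CohortConfig-class] for required columns. Defaults as above.
#' @param hemispheres subset of c("left", "right"); default both.
#' @param phantomDims per-subject phantom grid (default 16 x 12 x 1).
#' @param snr SNR at b = 0 for subject phantoms (default 80, the effective
#'   SNR of denoised 30-direction data; raw-acquisition SNR is closer to
#'   30).
#' @param s0 b = 0 signal.
#' @param searchRadius clean-ROI search radius for adjusted annotation.
#' @param seed master RNG seed.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(groups = NULL,
                         hemispheres = c("left", "right"),
                         phantomDims = c(16L, 12L, 1L), snr = 80, s0 = 100,
                         searchRadius = 3L, seed = 1L) {
  if (is.null(groups))
    groups <- data.frame(
      group = c("HC", "PD", "PSP"),
      n = c(41L, 60L, 17L),
      dpvMean = c(0.129, 0.123, 0.078),
      dpvSd = c(0.045, 0.055, 0.040),
      dradMean = c(0.30, 0.30, 0.30),
      dradSd = c(0.02, 0.02, 0.02),
      fxMean = c(0.115, 0.095, 0.045),
      fxSd = c(0.03, 0.03, 0.02),
      scoreMean = c(NA, 10.7, 37.8),
      scoreSd = c(NA, 8.3, 16.3),
      scoreCor = c(NA, 0, 0.5),
      stringsAsFactors = FALSE)
  new("CohortConfig", groups = groups, hemispheres = hemispheres,
      phantomDims = as.integer(phantomDims), snr = snr, s0 = s0,
      searchRadius = as.integer(searchRadius), seed = as.integer(seed))
}

# truncated-normal draw by clipping (SDs are small relative to the bounds,
# so clipping barely distorts the distribution)
.rclip <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Generate and analyse a synthetic cohort
#'
#' For every subject, draws Dpv, Drad and a crossing-fibre fraction from
#' the group distributions, builds a noisy slab phantom whose annotation
#' zones contain a period-2 lattice of crossing voxels (one per 2 x 2
#' ROI), and computes conventional and adjusted ALPS per hemisphere.
#' The conventional ROI and the seed of the adjusted ROI are jittered
#' independently within the annotation zone, emulating the two
#' independent manual annotation passes (on the conventional and the
#' adjusted colour map); the adjusted ROI is then relocated away from
#' flagged voxels via [findCleanRoi()] and averages unflagged voxels only.
#'
#' All randomness flows from the single master seed in the config.
#'
#' @param cfg a [CohortConfig-class].
#' @param keepPhantoms if TRUE, attach the per-subject [AlpsPhantom-class]
#'   objects (memory permitting).
#' @return a long-format data.frame (one row per subject x hemisphere x
#'   mode) with columns: subject, group, hemisphere, mode, alps, dxxProj,
#'   dyyProj, dxxAssoc, dzzAssoc, faProj, faAssoc, mdProj, mdAssoc,
#'   excludedVoxels, clinicalScore, trueAlps, dpv, drad, fx. The
#'   generating config is attached as attribute "config"; phantoms (if
#'   kept) as attribute "phantoms".
#' @export
makeCohort <- function(cfg = cohortConfig(), keepPhantoms = FALSE) {
  validObject(cfg)
  set.seed(cfg@seed)
  scheme <- makeScheme()
  X <- .designMatrix(scheme)
  P <- solve(crossprod(X), t(X))
  lay <- .phantomLayout(cfg@phantomDims)
  nRows <- sum(cfg@groups$n) * length(cfg@hemispheres) * 2L
  acc <- list(subject = character(nRows), group = character(nRows),
              hemisphere = character(nRows), mode = character(nRows),
              alps = numeric(nRows), dxxProj = numeric(nRows),
              dyyProj = numeric(nRows), dxxAssoc = numeric(nRows),
              dzzAssoc = numeric(nRows), faProj = numeric(nRows),
              faAssoc = numeric(nRows), mdProj = numeric(nRows),
              mdAssoc = numeric(nRows), excludedVoxels = integer(nRows),
              clinicalScore = numeric(nRows), trueAlps = numeric(nRows),
              dpv = numeric(nRows), drad = numeric(nRows),
              fx = numeric(nRows))
  phantoms <- if (keepPhantoms) list() else NULL
  ri <- 0L
  sid <- 0L
  for (gi in seq_len(nrow(cfg@groups))) {
    gp <- cfg@groups[gi, ]
    dpv <- .rclip(gp$n, gp$dpvMean, gp$dpvSd, 0, Inf)
    drad <- .rclip(gp$n, gp$dradMean, gp$dradSd, 0.05, Inf)
    fx <- .rclip(gp$n, gp$fxMean, gp$fxSd, 0, 1)
    score <- rep(NA_real_, gp$n)
    if (!is.na(gp$scoreCor)) {
      zdpv <- if (gp$dpvSd > 0) (dpv - gp$dpvMean) / gp$dpvSd else rep(0, gp$n)
      z <- gp$scoreCor * zdpv + sqrt(1 - gp$scoreCor^2) * rnorm(gp$n)
      score <- gp$scoreMean + gp$scoreSd * z
    }
    for (si in seq_len(gp$n)) {
      sid <- sid + 1L
      pcfg <- phantomConfig(dims = cfg@phantomDims, drad = drad[si],
                            dpv = dpv[si], fxp = fx[si], fxa = fx[si],
                            crossingPattern = "lattice", s0 = cfg@s0,
                            snr = cfg@snr,
                            seed = sample.int(.Machine$integer.max, 1L))
      ph <- makePhantom(pcfg, scheme)
      if (keepPhantoms) phantoms[[sid]] <- ph
      field <- fitTensorField(ph@dwi, scheme, mask = ph@mask,
                              voxelSize = pcfg@voxelSize,
                              labels = ph@truth@labels)
      flags <- flagCrossing(field)
      for (h in cfg@hemispheres) {
        res <- .annotatedAlps(field, flags, lay, h, cfg@searchRadius)
        for (r in res) {
          ri <- ri + 1L
          p <- r$projection; a <- r$association
          acc$subject[ri] <- sprintf("S%03d", sid)
          acc$group[ri] <- gp$group
          acc$hemisphere[ri] <- r$hemisphere
          acc$mode[ri] <- r$mode
          acc$alps[ri] <- r$alps
          acc$dxxProj[ri] <- p$dxx; acc$dyyProj[ri] <- p$dyy
          acc$dxxAssoc[ri] <- a$dxx; acc$dzzAssoc[ri] <- a$dzz
          acc$faProj[ri] <- p$fa; acc$faAssoc[ri] <- a$fa
          acc$mdProj[ri] <- p$md; acc$mdAssoc[ri] <- a$md
          acc$excludedVoxels[ri] <- p$nExcluded + a$nExcluded
          acc$clinicalScore[ri] <- score[si]
          acc$trueAlps[ri] <- ph@truth@trueAlps
          acc$dpv[ri] <- dpv[si]; acc$drad[ri] <- drad[si]
          acc$fx[ri] <- fx[si]
        }
      }
    }
  }
  out <- as.data.frame(lapply(acc, function(v) v[seq_len(ri)]),
                       stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  if (keepPhantoms) attr(out, "phantoms") <- phantoms
  out
}

# conventional + adjusted ALPS for one hemisphere with independently
# jittered annotations inside the 4x4 zones (3 x 3 possible 2x2 corners).
# Plain-array fast path over the same .roiStats / .cleanCorner cores the
# public extractRoiDiffusivities / findCleanRoi use.
.sqOffsets <- cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))

.annotatedAlps <- function(field, flags, lay, hemisphere, searchRadius) {
  tensors <- field@tensors
  dm <- dim(tensors)[1:3]
  flagsArr <- flags@flags
  zoff <- dm[1] * dm[2] * (lay$slice - 1L)
  sqIdx <- function(corner)
    zoff + (corner[1] + .sqOffsets[, 1]) +
      dm[1] * (corner[2] + .sqOffsets[, 2] - 1L)
  st <- list()
  for (s in c("projection", "association")) {
    site <- lay$sites[[paste(hemisphere, s, sep = ".")]]
    jit <- function() c(site$zoneX[sample.int(3L, 1L)],
                        site$zoneY[sample.int(3L, 1L)])
    conv <- .roiStats(tensors, sqIdx(jit()))
    seedCorner <- jit()
    # annotator model: relocation is prompted only by salient darkening --
    # at least two flagged voxels in the 4x4 neighbourhood of the seed
    # placement. Isolated noise-level dark voxels do not move the ROI, and
    # if the whole window is dark (no clean candidate) placement stays
    # standard.
    corner <- seedCorner
    nx <- pmin(pmax(seedCorner[1] + (-1L:2L), 1L), dm[1])
    ny <- pmin(pmax(seedCorner[2] + (-1L:2L), 1L), dm[2])
    nbIdx <- zoff + rep(unique(nx), times = length(unique(ny))) +
      dm[1] * (rep(unique(ny), each = length(unique(nx))) - 1L)
    if (sum(flagsArr[nbIdx]) >= 2L) {
      cand <- .cleanCorner(flagsArr, field@mask, field@labels, dm,
                           seedCorner, .sqOffsets, lay$slice,
                           site$label, as.integer(searchRadius))
      if (!is.null(cand)) corner <- cand
    }
    # relocated annotation is measured like any ROI (no voxel exclusion)
    adj <- .roiStats(tensors, sqIdx(corner))
    st[[s]] <- list(conv = conv, adj = adj)
  }
  mk <- function(mode, p, a) {
    den <- p$dyy + a$dzz
    if (!(den > 0)) stop("non-positive ALPS denominator")
    list(hemisphere = hemisphere, mode = mode,
         alps = (p$dxx + a$dxx) / den, projection = p, association = a)
  }
  list(conventional = mk("conventional", st$projection$conv,
                         st$association$conv),
       adjusted = mk("adjusted", st$projection$adj, st$association$adj))
}
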